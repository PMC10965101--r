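test_that("the resolvent is the estimation map and shrinks with regularisation", {
  # K~ = K, estimation points = electrodes, lambda = 0: identity
  K <- crossprod(withr::with_seed(1, matrix(rnorm(25), 5)))
  m <- synthetic_kernel_model(K)
  expect_equal(resolvent(m, 0)$E, diag(5), tolerance = 1e-8)

  # E V equals the fitted CSD for arbitrary V
  fx <- random_fixture(1, 31)
  lam <- 1e-4 * max(fx$model$eigvals)
  E <- resolvent(fx$model, lam)$E
  for (seed in 1:5) {
    V <- withr::with_seed(seed, rnorm(length(fx$V)))
    est <- fit_kcsd(fx$model, V, lam)
    expect_equal(drop(E %*% V), drop(est$csd), tolerance = 1e-10)
  }

  # ridge shrinkage: larger lambda, smaller Frobenius norm
  lams <- max(fx$model$eigvals) * c(1e-6, 1e-4, 1e-2, 1)
  norms <- vapply(lams, function(l) {
    sqrt(sum(resolvent(fx$model, l)$E^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 0))
})

test_that("error-propagation maps superpose and inherit grid symmetry", {
  setup <- make_setup_grid(3)
  model <- build_kernels(setup, R = 1, h = 1,
                         space = default_estimation_space(setup, 9))
  lam <- 1e-6 * max(model$eigvals)
  maps <- error_propagation_maps(model, lam)
  V <- withr::with_seed(2, rnorm(9))
  est <- fit_kcsd(model, V, lam)
  # the estimate is the V-weighted superposition of the columns
  expect_equal(drop(maps$E %*% V), drop(est$csd), tolerance = 1e-10)
  # a silent electrode contributes nothing
  V0 <- V; V0[5] <- 0
  expect_equal(drop(maps$E %*% V0),
               drop(est$csd) - V[5] * maps$E[, 5], tolerance = 1e-10)

  # the center electrode of the 3x3 grid: its map carries the mirror
  # symmetries of the geometry (x -> 2 - x, y -> 2 - y, x <-> y)
  center_map <- tidy(maps) |> dplyr::filter(.data$electrode == 5)
  byxy <- function(x, y) {
    center_map$value[match(paste(round(x, 9), round(y, 9)),
                           paste(round(center_map$x, 9),
                                 round(center_map$y, 9)))]
  }
  expect_equal(byxy(center_map$x, center_map$y),
               byxy(2 - center_map$x, center_map$y), tolerance = 1e-8)
  expect_equal(byxy(center_map$x, center_map$y),
               byxy(center_map$y, center_map$x), tolerance = 1e-8)
})

test_that("uncertainty maps propagate electrode noise exactly and match Monte Carlo", {
  setup <- make_setup_grid(3)
  model <- build_kernels(setup, R = 1, h = 1,
                         space = default_estimation_space(setup, 9))
  lam <- default_lambda_range(model)$lambda_min
  E <- resolvent(model, lam)$E

  # zero covariance: zero map
  u0 <- uncertainty_map(model, noise_model(sigma2 = 0, n = 9), lam)
  expect_equal(u0$variance, rep(0, nrow(E)))

  # unit-variance independent noise: squared row norms of the resolvent
  u1 <- uncertainty_map(model, noise_model(sigma2 = 1, n = 9), lam)
  expect_equal(u1$variance, unname(rowSums(E^2)))

  # full covariance path agrees with the scalar shorthand on sigma^2 I
  u2 <- uncertainty_map(model, noise_model(covariance = diag(2.5, 9)), lam)
  expect_equal(u2$variance, 2.5 * u1$variance, tolerance = 1e-12)

  # Monte-Carlo oracle: empirical CSD variance over 10^4 seeded noise draws
  draws <- withr::with_seed(99, matrix(rnorm(9 * 10000), 9))
  sim <- fit_kcsd(model, draws, lam)$csd
  emp <- apply(sim, 1, stats::var)
  expect_lt(max(abs(emp - u1$variance) / u1$variance), 0.05)

  expect_error(uncertainty_map(model, noise_model(covariance = diag(1, 4)),
                               lam),
               "N = 9")
})

test_that("eigensources span the recoverable space and survive re-estimation", {
  setup <- make_setup_1d(8)
  model <- build_kernels(setup,
                         basis_config("gaussian", R = 0.15, h = 0.1,
                                      centers = place_basis_regular(0, 1, 6)),
                         default_estimation_space(setup, 25))
  es <- eigensources(model)
  # numerical rank of a 6-source kernel on 8 electrodes
  expect_equal(length(es$values),
               sum(model$eigvals > 1e-12 * max(model$eigvals)))
  expect_lte(length(es$values), 6)
  # orthonormal coefficient vectors
  expect_equal(crossprod(es$vectors),
               diag(ncol(es$vectors)), tolerance = 1e-10)
  # perfect recoverability: forward-model each eigensource to the
  # electrodes (V = K u_j) and re-estimate at lambda = 0
  for (j in seq_along(es$values)) {
    V <- model$K %*% es$vectors[, j]
    back <- suppressWarnings(fit_kcsd(model, V, lambda = 0))
    expect_lt(max(abs(drop(back$csd) - es$fields[, j])) /
                max(abs(es$fields[, j])), 1e-6)
  }
  expect_error(eigensources(synthetic_kernel_model(diag(0, 3))), "rank")
})

test_that("the point-wise relative-difference error obeys its algebraic identities", {
  truth <- withr::with_seed(8, rnorm(40))
  expect_equal(rdm_pointwise_error(truth, truth), rep(0, 40))
  # positive rescaling of the estimate is invisible
  expect_equal(rdm_pointwise_error(truth, 2 * truth), rep(0, 40))
  expect_equal(rdm_pointwise_error(truth, 0.01 * truth), rep(0, 40),
               tolerance = 1e-12)
  # a sign flip scores 2|C(x)| / max|C|
  expect_equal(rdm_pointwise_error(truth, -truth),
               2 * abs(truth) / max(abs(truth)))
  expect_error(rdm_pointwise_error(rep(0, 4), rnorm(4)), "zero norm")
})

test_that("reliability maps are deterministic, zero for a perfect estimator, and symmetrizable", {
  setup <- make_setup_grid(4)
  # an injected identity estimator reproduces the truth: zero error map
  rel0 <- reliability_map(setup, n_profiles = 1, seed = 5,
                          points_per_axis = 7, R_grid = 1,
                          .estimator = function(truth, Vk, systems) truth)
  expect_equal(rel0$mean_map$reliability, rep(0, 49))

  # equal seeds give bit-identical maps; different seeds differ
  relA <- reliability_map(setup, n_profiles = 3, seed = 7,
                          points_per_axis = 7,
                          R_grid = default_R_range(setup, 3))
  relB <- reliability_map(setup, n_profiles = 3, seed = 7,
                          points_per_axis = 7,
                          R_grid = default_R_range(setup, 3))
  relC <- reliability_map(setup, n_profiles = 3, seed = 8,
                          points_per_axis = 7,
                          R_grid = default_R_range(setup, 3))
  expect_identical(relA$mean_map, relB$mean_map)
  expect_false(identical(relA$mean_map$reliability,
                         relC$mean_map$reliability))

  # dihedral-8 symmetrization yields a map invariant under the mirrors
  relS <- reliability_map(setup, n_profiles = 2, seed = 3,
                          points_per_axis = 7, R_grid = 1,
                          symmetrize = TRUE)
  v <- matrix(relS$mean_map$reliability, 7)
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_equal(v, v[7:1, 7:1], tolerance = 1e-12)

  rect <- electrode_setup(expand.grid(x = 0:3, y = 0:2))
  expect_error(reliability_map(rect, n_profiles = 1, seed = 1,
                               symmetrize = TRUE, points_per_axis = 5),
               "square")
})

test_that("broken-electrode studies are nested and do not gain information", {
  setup <- make_setup_grid(6)
  study <- broken_electrode_study(setup, n_broken = c(0, 2, 5),
                                  n_profiles = 6, seed = 4,
                                  points_per_axis = 9,
                                  R_grid = default_R_range(setup, 3))
  # removing nothing changes nothing
  expect_equal(study$diff_maps[, "broken_0"], rep(0, 81))
  # nested removal sets
  expect_true(all(study$removed$broken_2 %in% study$removed$broken_5))
  # losing contacts does not improve the average reliability
  means <- colMeans(study$diff_maps)
  expect_gte(means["broken_2"], -1e-3)
  expect_gte(means["broken_5"], -1e-3)
  expect_gte(means["broken_5"], means["broken_2"] - 1e-3)
  expect_error(broken_electrode_study(setup, n_broken = 36, seed = 1),
               "0..35")
})
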