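test_that("a single basis source gives a rank-one kernel", {
  setup <- make_setup_1d(5)
  basis <- basis_config("gaussian", R = 0.2, h = 0.1,
                        centers = matrix(0.5))
  model <- build_kernels(setup, basis,
                         estimation_space(tibble::tibble(x = c(0.25, 0.75))),
                         lookup = FALSE)
  v <- potential_basis_1d(0.5, 0.2, 0.1, 1, setup$positions$x)
  expect_equal(model$K, outer(v, v), tolerance = 1e-12)
  expect_equal(sum(model$eigvals > 1e-10 * max(model$eigvals)), 1)
})

test_that("kernel matrices equal brute-force triple-loop assembly", {
  for (seed in 1:7) {
    dim <- (seed %% 3) + 1
    fam <- if (seed %% 2 == 0) "step" else "gaussian"
    fx <- random_fixture(dim, seed, family = fam)
    oracle <- oracle_kernels(fx$setup, fx$basis, fx$space)
    scale <- max(abs(oracle$K))
    expect_lt(max(abs(fx$model$K - oracle$K)) / scale, 1e-10)
    expect_lt(max(abs(fx$model$Ktilde - oracle$Ktilde)) /
                max(abs(oracle$Ktilde)), 1e-10)
    expect_lt(max(abs(fx$model$Ktilde_pot - oracle$Ktilde_pot)) /
                max(abs(oracle$Ktilde_pot)), 1e-10)
    # symmetry and positive semidefiniteness
    expect_equal(fx$model$K, t(fx$model$K), tolerance = 1e-12)
    expect_gt(min(fx$model$eigvals), -1e-8 * max(fx$model$eigvals))
  }
})

test_that("potential cross-kernel at the electrodes reproduces K", {
  setup <- make_setup_1d(6)
  basis <- basis_config("gaussian", R = 0.15, h = 0.1,
                        centers = place_basis_regular(0, 1, 10))
  model <- build_kernels(setup, basis, estimation_space(setup$positions))
  expect_equal(model$Ktilde_pot, model$K, tolerance = 1e-14)
})

test_that("ridge solves behave across the regularisation range", {
  # identity kernel: lambda = 0 returns the data as coefficients
  m <- synthetic_kernel_model(diag(2))
  f <- fit_kcsd(m, c(4, -2), lambda = 0)
  expect_equal(drop(f$beta), c(4, -2))
  expect_equal(drop(f$csd), c(4, -2))

  # huge lambda: flat, underfitted solution with vanishing amplitude
  setup <- make_setup_1d(8)
  model <- build_kernels(setup, R = 0.15, h = 0.1,
                         space = default_estimation_space(setup, 21))
  V <- sin(2 * pi * setup$positions$x)
  ref <- suppressWarnings(fit_kcsd(model, V, lambda = 0))
  big <- fit_kcsd(model, V, lambda = 1e12 * max(model$eigvals))
  expect_lt(max(abs(big$csd)), 1e-6 * max(abs(ref$csd)))

  # estimation is linear in the measurements
  V2 <- cos(3 * setup$positions$x)
  lam <- 1e-3 * max(model$eigvals)
  f1 <- fit_kcsd(model, V, lam)
  f2 <- fit_kcsd(model, V2, lam)
  f12 <- fit_kcsd(model, 2 * V - 0.5 * V2, lam)
  expect_equal(f12$csd, 2 * f1$csd - 0.5 * f2$csd, tolerance = 1e-10)

  # time samples are solved jointly, column by column
  fboth <- fit_kcsd(model, cbind(V, V2), lam)
  expect_equal(fboth$csd[, 1], drop(f1$csd))
  expect_equal(fboth$csd[, 2], drop(f2$csd))
})

test_that("an in-span source is recovered exactly from noise-free data", {
  # 1D: M = 8 basis sources, N = 12 electrodes (full column rank)
  setup <- make_setup_1d(12)
  model <- build_kernels(setup,
                         basis_config("gaussian", R = 0.12, h = 0.1,
                                      centers = place_basis_regular(0, 1, 8)),
                         default_estimation_space(setup, 41))
  alpha <- withr::with_seed(2, rnorm(8))
  truth <- inspan_potentials(model, alpha)
  est <- suppressWarnings(fit_kcsd(model, truth$V, lambda = 0))
  expect_lt(max(abs(est$csd - truth$csd)) / max(abs(truth$csd)), 1e-6)
  # interpolation passes through the data (kernel interpolation identity)
  expect_lt(max(abs(model$K %*% est$beta - truth$V)) / max(abs(truth$V)),
            1e-8)

  # 2D variant
  s2 <- make_setup_grid(4)
  m2 <- build_kernels(s2,
                      basis_config("gaussian", R = 1, h = 1,
                                   centers = place_basis_regular(
                                     c(0, 0), c(3, 3), c(3, 3))),
                      default_estimation_space(s2, 9))
  a2 <- withr::with_seed(3, rnorm(9))
  t2 <- inspan_potentials(m2, a2)
  e2 <- suppressWarnings(fit_kcsd(m2, t2$V, lambda = 0))
  expect_lt(max(abs(e2$csd - t2$csd)) / max(abs(t2$csd)), 1e-6)
})

test_that("explicit basis/estimation placement matches the regular pipeline", {
  setup <- make_setup_1d(6)
  centers <- place_basis_regular(0, 1, 12)
  space <- default_estimation_space(setup, 17)
  regular <- build_kernels(setup,
                           basis_config("gaussian", R = 0.2, h = 0.1,
                                        centers = centers), space)
  explicit <- okcsd_model(setup, centers, space, R = 0.2, h = 0.1)
  expect_identical(explicit$K, regular$K)
  expect_identical(explicit$Ktilde, regular$Ktilde)

  # a single estimation point yields a one-row cross-kernel
  single <- okcsd_model(setup, centers, matrix(0.4), R = 0.2, h = 0.1)
  expect_equal(nrow(single$Ktilde), 1)

  # irregular 2D centers against brute force
  fx <- withr::with_seed(11, {
    setup2 <- electrode_setup(data.frame(x = runif(6, 0, 2),
                                         y = runif(6, 0, 2)))
    centers2 <- cbind(x = runif(7, 0, 2), y = runif(7, 0, 2))
    pts2 <- cbind(x = runif(4, 0, 2), y = runif(4, 0, 2))
    list(setup = setup2,
         basis = basis_config("gaussian", R = 0.5, h = 0.25,
                              centers = centers2),
         space = estimation_space(tibble::as_tibble(pts2)))
  })
  model <- build_kernels(fx$setup, fx$basis, fx$space, lookup = FALSE)
  oracle <- oracle_kernels(fx$setup, fx$basis, fx$space)
  expect_lt(max(abs(model$K - oracle$K)) / max(abs(oracle$K)), 1e-10)
  expect_lt(max(abs(model$Ktilde - oracle$Ktilde)) /
              max(abs(oracle$Ktilde)), 1e-10)
})

test_that("dimension mismatches are rejected", {
  setup <- make_setup_1d(5)
  basis2 <- basis_config("gaussian", R = 0.2, h = 0.1,
                         centers = cbind(0.5, 0.5))
  expect_error(build_kernels(setup, basis2), "dimensionality")
})

test_that("the MoI slice basis reduces, doubles and truncates as derived", {
  pts <- cbind(x = c(0.2, 0.8, 1.5), y = c(0, 0.3, -0.2))
  # no conductivity contrast: W = 0 recovers the infinite-tissue 2D basis
  flat <- slice_geometry(1, 1.3, 1.3, n_images = 10)
  expect_equal(moi_potential_basis(c(0, 0), 0.4, 0.3, flat, pts),
               potential_basis_2d(c(0, 0), 0.4, 0.3, 1.3, pts),
               tolerance = 1e-10)
  expect_equal(moi_potential_basis(c(0, 0), 0.4, 0.3,
                                   slice_geometry(1, 1.3, 0.7, 0), pts),
               potential_basis_2d(c(0, 0), 0.4, 0.3, 1.3, pts),
               tolerance = 1e-10)

  # ideal-insulator image-charge oracle: a point source adjacent to the
  # electrode-plane boundary is doubled by its leading image (W = 1)
  rho <- 1.2; z_src <- 1e-7; d <- 1
  v0 <- kcsdr:::moi_point_images(rho, z_src, d, W = 1, n_images = 0)
  v1 <- kcsdr:::moi_point_images(rho, z_src, d, W = 1, n_images = 1)
  near_image <- v1 - v0 - 1 / sqrt(rho^2 + (2 * d - z_src)^2)
  expect_equal(near_image, v0, tolerance = 1e-10)

  # truncation error is bounded by the geometric tail of the image series
  for (W_pair in list(c(19, 1), c(3, 1), c(1.3, 0.7))) {
    g20 <- slice_geometry(1, W_pair[1], W_pair[2], n_images = 20)
    g40 <- slice_geometry(1, W_pair[1], W_pair[2], n_images = 40)
    W <- (W_pair[1] - W_pair[2]) / (W_pair[1] + W_pair[2])
    a20 <- moi_potential_basis(c(0, 0), 0.4, 0.3, g20, pts)
    a40 <- moi_potential_basis(c(0, 0), 0.4, 0.3, g40, pts)
    # each image term is bounded by 2 W^m asinh(2h / (m d - 2h))
    tail_bound <- sum(2 * W^(21:40) * asinh(0.6 / ((21:40) - 0.6)))
    expect_lt(max(abs(a20 - a40)), tail_bound + 1e-12)
  }
  # with moderate contrast the 20-image truncation is already converged
  gmod <- slice_geometry(1, 1.5, 0.75, n_images = 20)  # W = 1/3
  gmod2 <- slice_geometry(1, 1.5, 0.75, n_images = 40)
  expect_lt(max(abs(moi_potential_basis(c(0, 0), 0.4, 0.3, gmod, pts) -
                      moi_potential_basis(c(0, 0), 0.4, 0.3, gmod2, pts))),
            1e-8)
})
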