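# Fixtures and independent oracles shared across the suite.
# Oracles deliberately avoid the code paths they check: kernel matrices are
# assembled by explicit loops over public per-source evaluators, and
# leave-one-out predictions are reproduced by physically rebuilding the
# reduced electrode setup.

make_setup_1d <- function(n = 8, span = c(0, 1), sigma = 1) {
  electrode_setup(data.frame(x = seq(span[1], span[2], length.out = n)),
                  sigma = sigma)
}

make_setup_grid <- function(nx, ny = nx, spacing = 1, sigma = 1) {
  electrode_setup(
    expand.grid(x = seq(0, by = spacing, length.out = nx),
                y = seq(0, by = spacing, length.out = ny)),
    sigma = sigma
  )
}

# Per-source potential values through the public evaluators (direct
# quadrature / closed form, no lookup table).
pot_basis_values <- function(dim, center, R, h, sigma, pts,
                             family = "gaussian") {
  pts <- as.matrix(pts)
  switch(dim,
    potential_basis_1d(center, R, h, sigma, pts[, 1], family = family),
    potential_basis_2d(center, R, h, sigma, pts, family = family),
    if (family == "gaussian") {
      potential_basis_3d_gaussian(center, R, sigma, pts)
    } else {
      potential_basis_3d_general(center, R, sigma, pts, family = family)
    }
  )
}

csd_basis_values_pub <- function(center, R, pts, family = "gaussian") {
  if (family == "gaussian") csd_basis_gaussian(center, R, pts)
  else csd_basis_step(center, R, pts)
}

# Brute-force kernel assembly: explicit loops over (i, j, m).
oracle_kernels <- function(setup, basis, space) {
  elec <- as.matrix(setup$positions)
  est <- as.matrix(space)
  N <- nrow(elec); M <- basis$M; P <- nrow(est)
  B <- matrix(0, N, M)
  Best <- matrix(0, P, M)
  Btil <- matrix(0, P, M)
  for (m in seq_len(M)) {
    B[, m] <- pot_basis_values(setup$dim, basis$centers[m, ], basis$R,
                               basis$h, setup$sigma, elec, basis$family)
    Best[, m] <- pot_basis_values(setup$dim, basis$centers[m, ], basis$R,
                                  basis$h, setup$sigma, est, basis$family)
    Btil[, m] <- csd_basis_values_pub(basis$centers[m, ], basis$R, est,
                                      basis$family)
  }
  K <- matrix(0, N, N)
  Ktilde <- matrix(0, P, N)
  Ktilde_pot <- matrix(0, P, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      K[i, j] <- sum(B[i, ] * B[j, ])
    }
    for (p in seq_len(P)) {
      Ktilde[p, i] <- sum(Btil[p, ] * B[i, ])
      Ktilde_pot[p, i] <- sum(Best[p, ] * B[i, ])
    }
  }
  list(K = K, Ktilde = Ktilde, Ktilde_pot = Ktilde_pot)
}

# A small random fixture in the requested dimension (direct basis
# evaluation so oracle comparisons are exact).
random_fixture <- function(dim, seed, family = "gaussian") {
  withr::with_seed(seed, {
    if (dim == 1) {
      setup <- electrode_setup(
        data.frame(x = sort(runif(6))), sigma = runif(1, 0.5, 2)
      )
      centers <- matrix(seq(0, 1, length.out = 5), ncol = 1)
      space <- estimation_space(tibble::tibble(x = seq(0, 1, length.out = 9)))
      R <- runif(1, 0.1, 0.3)
    } else if (dim == 2) {
      setup <- electrode_setup(
        data.frame(x = runif(6, 0, 2), y = runif(6, 0, 2)),
        sigma = runif(1, 0.5, 2)
      )
      centers <- as.matrix(expand.grid(x = seq(0, 2, length.out = 2),
                                       y = seq(0, 2, length.out = 2)))
      space <- estimation_space(as.data.frame(expand.grid(
        x = seq(0, 2, length.out = 3), y = seq(0, 2, length.out = 3)
      )))
      R <- runif(1, 0.3, 0.8)
    } else {
      setup <- electrode_setup(
        data.frame(x = runif(6), y = runif(6), z = runif(6)),
        sigma = runif(1, 0.5, 2)
      )
      centers <- as.matrix(expand.grid(x = c(0.2, 0.8), y = c(0.2, 0.8),
                                       z = 0.5))
      space <- estimation_space(as.data.frame(expand.grid(
        x = c(0.1, 0.5, 0.9), y = c(0.3, 0.7), z = 0.5
      )))
      R <- runif(1, 0.2, 0.5)
    }
    basis <- basis_config(family, R = R, h = 0.25, centers = centers)
    model <- build_kernels(setup, basis, space, lookup = FALSE)
    V <- rnorm(nrow(setup$positions))
    list(setup = setup, basis = basis, space = space, model = model, V = V)
  })
}

# Leave-one-out oracle: physically rebuild the reduced setup from scratch,
# refit, and read the prediction at the held-out position from the
# potential cross-kernel.
oracle_loo <- function(fx, lambda, i) {
  setup <- fx$setup
  reduced <- electrode_setup(setup$positions[-i, , drop = FALSE],
                             sigma = setup$sigma)
  space_at_elec <- estimation_space(setup$positions)
  model <- build_kernels(reduced, fx$basis, space_at_elec, lookup = FALSE)
  fit <- suppressWarnings(fit_kcsd(model, fx$V[-i], lambda = lambda))
  fit$pot[i, 1]
}
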