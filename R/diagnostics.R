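# Quality control for kCSD estimates: the resolvent and its column maps,
# measurement-uncertainty maps, eigensources, and reliability maps over
# families of test sources.

#' Synthetic kernel model from explicit matrices
#'
#' Builds a `kcsd_model` directly from kernel matrices, bypassing basis
#' construction.  Intended for algebraic studies and tests (e.g. an identity
#' kernel); electrode positions are dummy 1D indices.
#'
#' @param K N x N symmetric kernel matrix.
#' @param Ktilde P x N cross-kernel (defaults to `K`).
#' @param Ktilde_pot P x N potential cross-kernel (defaults to `Ktilde`).
#' @param lambda Ridge parameter.
#' @export
synthetic_kernel_model <- function(K, Ktilde = K, Ktilde_pot = Ktilde,
                                   lambda = 0) {
  N <- nrow(K)
  P <- nrow(Ktilde)
  setup <- electrode_setup(data.frame(x = as.numeric(seq_len(N))), sigma = 1)
  basis <- basis_config("gaussian", R = 1,
                        centers = matrix(as.numeric(seq_len(N)), ncol = 1))
  space <- estimation_space(tibble(x = as.numeric(seq_len(P))))
  new_kcsd_model(K, Ktilde, Ktilde_pot, lambda, setup, basis, space)
}

#' The resolvent: linear map from potentials to estimated CSD
#'
#' `E = Ktilde (K + lambda I)^{-1}`, computed through symmetric solves of
#' the stored eigensystem (never an explicit inverse).  `E %*% V` equals the
#' CSD of [fit_kcsd()] for any `V`.
#'
#' @param model A `kcsd_model`.
#' @param lambda Ridge parameter; defaults to the model's.
#' @return A `kcsd_resolvent`: list with the P x N matrix `E` and `lambda`.
#' @export
resolvent <- function(model, lambda = NULL) {
  lambda <- lambda %||% model$lambda
  inv_cols <- ridge_solve(model, diag(nrow(model$K)), lambda)
  attr(inv_cols, "dropped") <- NULL
  structure(
    list(E = model$Ktilde %*% inv_cols, lambda = lambda,
         space = model$space),
    class = "kcsd_resolvent"
  )
}

#' Error-propagation maps
#'
#' Column i of the resolvent is the CSD response to a unit potential at
#' electrode i: an error-propagation map for that measurement.
#'
#' @inheritParams resolvent
#' @return A `kcsd_error_maps`: the P x N matrix `E` plus the estimation
#'   space; `tidy()` returns one row per (point, electrode).
#' @export
error_propagation_maps <- function(model, lambda = NULL) {
  rsv <- resolvent(model, lambda)
  structure(
    list(E = rsv$E, lambda = rsv$lambda, space = model$space),
    class = "kcsd_error_maps"
  )
}

#' @method tidy kcsd_error_maps
#' @export
tidy.kcsd_error_maps <- function(x, ...) {
  pts <- as_tibble(as.data.frame(x$space))
  E <- as.data.frame(x$E)
  names(E) <- paste0("e", seq_len(ncol(E)))
  out <- dplyr::bind_cols(pts, E)
  tidyr::pivot_longer(out, dplyr::starts_with("e"),
                      names_to = "electrode", names_prefix = "e",
                      names_transform = as.integer, values_to = "value")
}

#' Map of CSD measurement uncertainty
#'
#' Propagates the electrode-noise covariance through the resolvent: the
#' estimated CSD is normal with covariance `E Sigma_V E'`, whose diagonal is
#' the per-point variance map.  The scalar-noise shorthand uses
#' `sigma2 * diag(E E')`.
#'
#' @inheritParams resolvent
#' @param noise A [noise_model()].
#' @return A `kcsd_uncertainty` tibble: estimation points plus `variance`.
#' @export
uncertainty_map <- function(model, noise, lambda = NULL) {
  stopifnot(inherits(noise, "noise_model"))
  rsv <- resolvent(model, lambda)
  E <- rsv$E
  variance <- if (is.null(noise$covariance)) {
    noise$sigma2 * unname(rowSums(E^2))
  } else {
    Sigma <- noise_covariance(noise, ncol(E))
    unname(rowSums((E %*% Sigma) * E))
  }
  out <- dplyr::bind_cols(as_tibble(as.data.frame(model$space)),
                          tibble(variance = variance))
  structure(out, lambda = rsv$lambda,
            class = c("kcsd_uncertainty", class(out)))
}

#' Eigensources of the estimation operator
#'
#' Eigendecomposition `K = U L U'` (eigenvalues descending, relative cutoff
#' for the numerical rank).  Eigensource j is the CSD field `Ktilde u_j`,
#' i.e. the estimate produced by coefficients `u_j`; these fields span
#' everything the setup can reconstruct, and each survives a
#' forward-model/re-estimate round trip at lambda = 0.
#'
#' @param model A `kcsd_model`.
#' @param cutoff Relative eigenvalue cutoff defining the numerical rank.
#' @return A `kcsd_eigensources`: list with `fields` (P x r), `values`
#'   (eigenvalues), `vectors` (N x r, orthonormal), and the space.
#' @export
eigensources <- function(model, cutoff = 1e-12) {
  keep <- model$eigvals > cutoff * max(model$eigvals)
  if (!any(keep)) abort("kernel matrix has numerical rank 0")
  U <- model$eigvecs[, keep, drop = FALSE]
  structure(
    list(fields = model$Ktilde %*% U, values = model$eigvals[keep],
         vectors = U, space = model$space),
    class = "kcsd_eigensources"
  )
}

#' Point-wise relative-difference reconstruction error
#'
#' The point-wise modification of the Relative Difference Measure: both
#' fields are normalised to unit Euclidean norm over the estimation points,
#' their absolute difference is rescaled by `norm(truth) / max|truth|`.
#' Invariant under positive rescaling of the estimate; a sign-flipped
#' estimate scores `2 |truth(x)| / max|truth|`.
#'
#' @param truth,estimate Numeric vectors of CSD values on the same
#'   estimation points.
#' @return Non-negative error field (vector).
#' @export
rdm_pointwise_error <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate))
  nt <- sqrt(sum(truth^2))
  if (nt == 0) abort("ground-truth field has zero norm")
  ne <- sqrt(sum(estimate^2))
  est_unit <- if (ne > 0) estimate / ne else estimate
  abs(est_unit - truth / nt) * nt / max(abs(truth))
}

# ---- Reliability machinery ------------------------------------------------

# Per-(R, electrode-subset) reduced system, computed once per study.
subset_system <- function(model, keep) {
  Ksub <- model$K[keep, keep, drop = FALSE]
  e <- eigen(Ksub, symmetric = TRUE)
  lambda_min <- max(min(e$values), .Machine$double.eps * max(e$values))
  list(K = Ksub, eig = e, lambda_min = lambda_min,
       Ktilde = model$Ktilde[, keep, drop = FALSE])
}

cv_error_matrix <- function(K, V, lambda) {
  N <- nrow(K)
  err <- 0
  for (i in seq_len(N)) {
    keep <- setdiff(seq_len(N), i)
    beta <- ridge_solve_matrix(K[keep, keep, drop = FALSE],
                               V[keep, drop = FALSE], lambda,
                               warn_singular = FALSE)
    err <- err + sum((drop(crossprod(K[i, keep], beta)) - V[i])^2)
  }
  err
}

# Average the 8 mirror images of a square-grid map (values in row-major,
# last axis fastest order).
symmetrize_d8 <- function(values, counts) {
  n <- counts[1]
  stopifnot(counts[2] == n)
  A <- matrix(values, nrow = n)  # column = fixed x index, rows iterate y
  ops <- list(
    A, t(A), A[n:1, ], A[, n:1],
    t(A)[n:1, ], t(A)[, n:1], A[n:1, n:1], t(A)[n:1, n:1]
  )
  as.vector(Reduce("+", ops) / 8)
}

is_square_grid <- function(space) {
  d <- attr(space, "descriptor")
  !is.null(d) && length(d$counts) == 2 && d$counts[1] == d$counts[2] &&
    isTRUE(all.equal(diff(range(d$upper - d$lower)), 0))
}

reliability_core <- function(models, keep, profiles, V_full, truth_mat,
                             symmetrize, space, estimator = NULL,
                             picks = NULL) {
  systems <- lapply(models, subset_system, keep = keep)
  P <- nrow(truth_mat)
  n_prof <- length(profiles)
  err <- matrix(NA_real_, n_prof, P)
  out_picks <- numeric(n_prof)
  for (i in seq_len(n_prof)) {
    Vk <- V_full[[i]][keep]
    if (is.null(estimator)) {
      # noise-free scenario: lambda pinned to the spectral floor; R by CV
      # unless pinned by the caller (broken-contact studies fix R per
      # profile so difference maps isolate the information loss)
      best <- if (is.null(picks)) {
        which.min(vapply(systems, function(s) {
          cv_error_matrix(s$K, matrix(Vk, ncol = 1), s$lambda_min)
        }, numeric(1)))
      } else picks[i]
      s <- systems[[best]]
      beta <- ridge_solve_matrix(s$K, matrix(Vk, ncol = 1), s$lambda_min,
                                 warn_singular = FALSE)
      est <- drop(s$Ktilde %*% beta)
      out_picks[i] <- best
    } else {
      est <- estimator(truth_mat[, i], Vk, systems)
      out_picks[i] <- NA_real_
    }
    e <- rdm_pointwise_error(truth_mat[, i], est)
    if (symmetrize) {
      e <- symmetrize_d8(e, attr(space, "descriptor")$counts)
    }
    err[i, ] <- e
  }
  list(per_profile = err, mean_map = colMeans(err), picks = out_picks)
}

#' Reliability map over a family of test sources
#'
#' For each seeded ground-truth profile: forward-model its (noise-free)
#' potentials at the electrodes, run the full kCSD reconstruction with the
#' basis radius selected by cross-validation (ridge parameter pinned at the
#' spectral floor, the noise-free limit), and score the point-wise
#' relative-difference error against the truth.  The map is the average
#' error field over the profile family; low values mark regions whose
#' reconstructions can be trusted.
#'
#' @param setup An [electrode_setup()].
#' @param space Estimation space (defaults to the electrode bounding box at
#'   `points_per_axis`).
#' @param profile_family `"small"`, `"large"` or `"both"` (alternating).
#' @param n_profiles Number of test profiles (>= 1).
#' @param seed Integer seed; maps are deterministic given (seed, config).
#' @param symmetrize Average each error field over the 8 mirror symmetries
#'   of a square grid (square setups only).
#' @param R_grid Basis radii scanned by CV; defaults to [default_R_range()].
#' @param h Sheath radius / layer half-thickness; defaults to the minimum
#'   interelectrode distance.
#' @param basis_family Basis family for the reconstruction.
#' @param points_per_axis Estimation grid resolution.
#' @param n_components Gaussian components per test profile.
#' @param .estimator Internal override of the reconstruction step (testing).
#' @return A `kcsd_reliability`: list with `mean_map` (tibble of points +
#'   `reliability`), `per_profile` (n_profiles x P), profile metadata.
#' @export
reliability_map <- function(setup, space = NULL,
                            profile_family = c("both", "small", "large"),
                            n_profiles = 20L, seed = 1L, symmetrize = FALSE,
                            R_grid = NULL, h = NULL,
                            basis_family = "gaussian",
                            points_per_axis = 15L, n_components = 4L,
                            .estimator = NULL) {
  profile_family <- match.arg(profile_family)
  stopifnot(n_profiles >= 1)
  if (is.null(space)) space <- default_estimation_space(setup, points_per_axis)
  if (symmetrize && !is_square_grid(space)) {
    abort("symmetrization needs a square regular estimation grid")
  }
  prep <- reliability_prepare(setup, space, profile_family, n_profiles,
                              seed, R_grid, h, basis_family, n_components)
  core <- reliability_core(prep$models, seq_len(n_electrodes(setup)),
                           prep$profiles, prep$V_full, prep$truth_mat,
                           symmetrize, space, estimator = .estimator)
  mean_map <- dplyr::bind_cols(as_tibble(as.data.frame(space)),
                               tibble(reliability = core$mean_map))
  structure(
    list(mean_map = mean_map, per_profile = core$per_profile,
         space = space, seed = seed, profile_family = profile_family,
         R_grid = prep$R_grid, R_picked = prep$R_grid[core$picks],
         profiles = prep$profiles),
    class = "kcsd_reliability"
  )
}

reliability_prepare <- function(setup, space, profile_family, n_profiles,
                                seed, R_grid, h, basis_family,
                                n_components) {
  elec <- as.matrix(setup$positions)
  dmin <- min(dist(elec))
  h <- h %||% dmin
  R_grid <- R_grid %||% default_R_range(setup)
  centers <- default_basis_centers(setup)
  models <- lapply(R_grid, function(R) {
    build_kernels(setup,
                  basis_config(basis_family, R = R, h = h, centers = centers),
                  space)
  })
  lower <- apply(elec, 2, min)
  upper <- apply(elec, 2, max)
  fams <- switch(profile_family,
    both = rep_len(c("small", "large"), n_profiles),
    rep(profile_family, n_profiles)
  )
  profiles <- lapply(seq_len(n_profiles), function(i) {
    make_profile(fams[i], dim = setup$dim, lower = lower, upper = upper,
                 seed = sub_seed(seed, "reliability-profile", i),
                 scale = dmin, n_components = n_components)
  })
  V_full <- lapply(profiles, function(p) {
    forward_potentials(p, setup, h = h)$potentials
  })
  truth_mat <- vapply(profiles, evaluate_profile, numeric(nrow(space)),
                      points = space)
  list(models = models, profiles = profiles, V_full = V_full,
       truth_mat = truth_mat, R_grid = R_grid, h = h)
}

#' @export
print.kcsd_reliability <- function(x, ...) {
  cat(sprintf(
    "<kcsd_reliability> %d profiles (%s), mean error %.4g (seed %s)\n",
    nrow(x$per_profile), x$profile_family,
    mean(x$mean_map$reliability), format(x$seed)
  ))
  invisible(x)
}

#' @method tidy kcsd_reliability
#' @export
tidy.kcsd_reliability <- function(x, ...) x$mean_map

#' Broken-electrode reliability study
#'
#' Removes nested random subsets of contacts (the 5 worst-case contacts are
#' contained in the 10, the 10 in the 20, within one seed) and recomputes
#' the reliability map on the same estimation space and the same profile
#' family.  The result contrasts each broken map against the intact one.
#'
#' @inheritParams reliability_map
#' @param n_broken Integer vector of broken-contact counts (< N).
#' @return A `kcsd_broken_study`: intact map, per-count mean maps and
#'   (broken - intact) difference maps, removed-electrode sets.
#' @export
broken_electrode_study <- function(setup, n_broken = c(5L, 10L, 20L),
                                   n_profiles = 20L, seed = 1L,
                                   space = NULL,
                                   profile_family = c("both", "small",
                                                      "large"),
                                   R_grid = NULL, h = NULL,
                                   basis_family = "gaussian",
                                   points_per_axis = 15L,
                                   n_components = 4L) {
  profile_family <- match.arg(profile_family)
  N <- n_electrodes(setup)
  n_broken <- sort(unique(as.integer(n_broken)))
  if (any(n_broken < 0) || any(n_broken >= N)) {
    abort(sprintf("n_broken must lie in 0..%d", N - 1))
  }
  if (is.null(space)) space <- default_estimation_space(setup, points_per_axis)
  prep <- reliability_prepare(setup, space, profile_family, n_profiles,
                              seed, R_grid, h, basis_family, n_components)
  removal_order <- with_local_seed(sub_seed(seed, "broken-order"), sample(N))
  counts <- unique(c(0L, n_broken))
  maps <- matrix(NA_real_, nrow(space), length(counts))
  removed <- list()
  picks <- NULL
  for (ci in seq_along(counts)) {
    removed[[ci]] <- sort(removal_order[seq_len(counts[ci])])
    keep <- setdiff(seq_len(N), removed[[ci]])
    core <- reliability_core(prep$models, keep, prep$profiles, prep$V_full,
                             prep$truth_mat, FALSE, space, picks = picks)
    if (ci == 1L) picks <- core$picks  # R fixed at the intact-grid choice
    maps[, ci] <- core$mean_map
  }
  diff_maps <- maps[, match(n_broken, counts), drop = FALSE] - maps[, 1]
  colnames(maps) <- paste0("broken_", counts)
  colnames(diff_maps) <- paste0("broken_", n_broken)
  structure(
    list(counts = n_broken, mean_maps = maps, diff_maps = diff_maps,
         removed = setNames(removed, paste0("broken_", counts)),
         space = space, seed = seed),
    class = "kcsd_broken_study"
  )
}

#' @export
print.kcsd_broken_study <- function(x, ...) {
  cat(sprintf(
    "<kcsd_broken_study> broken counts: %s; mean error increase: %s\n",
    paste(x$counts, collapse = ", "),
    paste(signif(colMeans(x$diff_maps), 3), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy kcsd_broken_study
#' @export
tidy.kcsd_broken_study <- function(x, ...) {
  pts <- as_tibble(as.data.frame(x$space))
  out <- dplyr::bind_cols(pts, as_tibble(as.data.frame(x$diff_maps)))
  tidyr::pivot_longer(out, dplyr::starts_with("broken_"),
                      names_to = "n_broken", names_prefix = "broken_",
                      names_transform = as.integer,
                      values_to = "error_increase")
}
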