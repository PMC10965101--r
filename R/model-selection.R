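# Regularisation parameter selection: leave-one-out cross-validation and the
# L-curve with triangle-area curvature.

#' Leave-one-out prediction at one electrode
#'
#' Removes electrode `i` from the kernel system, refits the remaining
#' electrodes with ridge parameter `lambda`, and predicts the potential at
#' the held-out position through the kernel row `K(x_i, x_j), j != i`.
#'
#' @param model A `kcsd_model`.
#' @param V Measured potentials (vector or one-column matrix).
#' @param lambda Ridge parameter, >= 0.
#' @param i Electrode index to hold out.
#' @return Predicted potential(s) at electrode `i` (one per time sample).
#' @export
loo_prediction <- function(model, V, lambda, i) {
  V <- as_potential_matrix(V, model$setup)
  N <- nrow(model$K)
  stopifnot(N >= 3, i >= 1, i <= N)
  keep <- setdiff(seq_len(N), i)
  Ksub <- model$K[keep, keep, drop = FALSE]
  beta <- ridge_solve_matrix(Ksub, V[keep, , drop = FALSE], lambda)
  drop(crossprod(model$K[i, keep], beta))
}

# Symmetric ridge solve for an ad-hoc kernel submatrix (used by LOO, where
# the reduced system changes at every fold).  Solved through the
# eigendecomposition so a numerically singular system falls back to the
# minimum-norm (pseudo-inverse) solution instead of amplifying round-off.
ridge_solve_matrix <- function(K, B, lambda, cutoff = 1e-12,
                               warn_singular = TRUE) {
  e <- eigen(K + diag(lambda, nrow(K)), symmetric = TRUE)
  keep <- e$values > cutoff * max(abs(e$values))
  if (!all(keep) && warn_singular) {
    warn("singular reduced system; using pseudo-inverse")
  }
  inv <- ifelse(keep, 1 / e$values, 0)
  e$vectors %*% (inv * crossprod(e$vectors, B))
}

#' Cross-validation error for one ridge parameter
#'
#' Sum over electrodes of squared leave-one-out prediction residuals.
#'
#' @inheritParams loo_prediction
#' @return Non-negative scalar (summed over time samples).
#' @export
cv_error <- function(model, V, lambda) {
  V <- as_potential_matrix(V, model$setup)
  N <- nrow(model$K)
  err <- 0
  for (i in seq_len(N)) {
    pred <- loo_prediction(model, V, lambda, i)
    err <- err + sum((pred - V[i, ])^2)
  }
  err
}

#' Default ridge-parameter range from the kernel spectrum
#'
#' The smallest tested lambda is the minimum eigenvalue of `K` (floored at
#' machine precision relative to the largest), the largest is the standard
#' deviation of the eigenvalues, and the grid is log-spaced.
#'
#' @param model A `kcsd_model`.
#' @param n Number of grid points.
#' @return List with `lambda_min`, `lambda_max`, `grid`.
#' @export
default_lambda_range <- function(model, n = 25L) {
  ev <- model$eigvals
  floor_ <- .Machine$double.eps * max(ev)
  lambda_min <- max(min(ev), floor_)
  # population standard deviation of the spectrum
  lambda_max <- sqrt(mean((ev - mean(ev))^2))
  if (lambda_max <= lambda_min) {
    warn("degenerate kernel spectrum; widening the lambda range")
    lambda_max <- lambda_min * 1e6
  }
  list(lambda_min = lambda_min, lambda_max = lambda_max,
       grid = log_space(lambda_min, lambda_max, n))
}

#' Default basis-radius range from the electrode geometry
#'
#' Log-spaced grid from the minimum interelectrode distance to half the
#' maximum interelectrode distance; collapses to the single value `min`
#' when `min >= max/2`.
#'
#' @param setup An [electrode_setup()].
#' @param n Number of grid points.
#' @export
default_R_range <- function(setup, n = 9L) {
  d <- dist(as.matrix(setup$positions))
  lo <- min(d)
  hi <- max(d) / 2
  if (lo >= hi) return(lo)
  log_space(lo, hi, n)
}

#' One point of the L-curve
#'
#' Returns the prediction error `rho = sum_i (V_lambda(x_i) - V_i)^2` and
#' the model norm `eta = |beta' K beta|` at one ridge parameter.
#'
#' @inheritParams loo_prediction
#' @return Named numeric vector `c(rho = , eta = )`.
#' @export
lcurve_point <- function(model, V, lambda) {
  V <- as_potential_matrix(V, model$setup)
  beta <- ridge_solve(model, V, lambda)
  attr(beta, "dropped") <- NULL
  V_hat <- model$K %*% beta
  c(rho = sum((V_hat - V)^2), eta = abs(sum(beta * (model$K %*% beta))))
}

#' Triangle-area curvature of the L-curve
#'
#' For each interior point P of the log-log L-curve, the signed area of the
#' triangle formed by the first endpoint, P, and the last endpoint
#' (cross-product formula).  A clockwise-oriented triangle is negative;
#' endpoints get curvature 0.  The corner of an L-shaped curve maximises
#' this signed area.
#'
#' @param log_rho,log_eta Log-scale coordinates of the L-curve, in lambda
#'   order (at least 3 points).
#' @return Numeric vector of signed areas, one per point.
#' @export
triangle_curvature <- function(log_rho, log_eta) {
  n <- length(log_rho)
  stopifnot(length(log_eta) == n)
  if (n < 3) abort("triangle curvature needs at least 3 points")
  x1 <- log_rho[1]; y1 <- log_eta[1]
  xn <- log_rho[n]; yn <- log_eta[n]
  cur <- 0.5 * ((log_rho - x1) * (yn - y1) - (xn - x1) * (log_eta - y1))
  cur[c(1, n)] <- 0
  cur
}

#' Scan (R, lambda) and select parameters by CV or the L-curve
#'
#' Rebuilds the kernel model for every basis radius in `R_grid` and scans
#' `lambda_grid` with either the leave-one-out cross-validation error
#' (minimised) or the triangle-area curvature of the L-curve (maximised).
#' The winner's position on a grid edge is flagged, since it may indicate
#' that extending the range would give a better result.
#'
#' @param setup An [electrode_setup()].
#' @param V Measured potentials.
#' @param method `"cv"` or `"lcurve"`.
#' @param family Basis family.
#' @param space Estimation space (defaults to the electrode bounding box).
#' @param h Sheath radius (1D) / layer half-thickness (2D).
#' @param R_grid Basis radii to test; defaults to [default_R_range()].
#' @param lambda_grid Ridge parameters; defaults to [default_lambda_range()]
#'   of each model (per R).
#' @param n_lambda Grid size when `lambda_grid` is derived per model.
#' @param geometry Optional [slice_geometry()].
#' @return A `kcsd_scan`: list with the selected `R`, `lambda`,
#'   `boundary_flag`, the scan tibble (`scan`), and the winning model.
#' @export
select_parameters <- function(setup, V, method = c("cv", "lcurve"),
                              family = "gaussian", space = NULL, h = NULL,
                              R_grid = NULL, lambda_grid = NULL,
                              n_lambda = 25L, geometry = NULL) {
  method <- match.arg(method)
  if (is.null(space)) space <- default_estimation_space(setup, 32L)
  R_grid <- R_grid %||% default_R_range(setup)
  if (!length(R_grid)) abort("empty R grid")
  elec <- as.matrix(setup$positions)
  dmin <- min(dist(elec))

  rows <- list()
  models <- vector("list", length(R_grid))
  for (ri in seq_along(R_grid)) {
    R <- R_grid[ri]
    basis <- basis_config(family, R = R, h = h %||% dmin,
                          centers = default_basis_centers(setup))
    model <- build_kernels(setup, basis, space, geometry = geometry)
    models[[ri]] <- model
    lam <- lambda_grid %||% default_lambda_range(model, n_lambda)$grid
    if (method == "cv") {
      # scans sweep lambda down to the spectral floor, where near-singular
      # folds routinely take the pseudo-inverse branch; not worth a warning
      # per fold here
      score <- vapply(lam, function(l) {
        suppressWarnings(cv_error(model, V, l))
      }, numeric(1))
      rows[[ri]] <- tibble(R = R, lambda = lam, cv_error = score,
                           lambda_index = seq_along(lam))
    } else {
      pts <- vapply(lam, function(l) lcurve_point(model, V, l), numeric(2))
      log_rho <- log10(pmax(pts["rho", ], 1e-300))
      log_eta <- log10(pmax(pts["eta", ], 1e-300))
      cur <- if (length(lam) >= 3) triangle_curvature(log_rho, log_eta)
             else rep(0, length(lam))
      rows[[ri]] <- tibble(R = R, lambda = lam, rho = pts["rho", ],
                           eta = pts["eta", ], curvature = cur,
                           lambda_index = seq_along(lam))
    }
  }
  scan <- dplyr::bind_rows(rows)
  if (method == "cv") {
    if (all(!is.finite(scan$cv_error))) abort("all-NaN cross-validation scan")
    best <- which.min(scan$cv_error)
  } else {
    if (all(!is.finite(scan$curvature))) abort("all-NaN L-curve scan")
    # ties broken toward larger lambda (more regularisation)
    mx <- max(scan$curvature)
    best <- max(which(scan$curvature == mx))
  }
  bestrow <- scan[best, ]
  nl <- max(scan$lambda_index)
  boundary <- bestrow$lambda_index %in% c(1L, nl) ||
    bestrow$R %in% range(R_grid) && length(R_grid) > 1
  if (length(R_grid) == 1 && nl == 1) boundary <- TRUE
  structure(
    list(R = bestrow$R, lambda = bestrow$lambda,
         boundary_flag = isTRUE(boundary), method = method, scan = scan,
         model = models[[match(bestrow$R, R_grid)]]),
    class = "kcsd_scan"
  )
}

#' @export
print.kcsd_scan <- function(x, ...) {
  cat(sprintf(
    "<kcsd_scan> method = %s: selected R = %g, lambda = %g%s\n",
    x$method, x$R, x$lambda,
    if (x$boundary_flag) " [on scan boundary]" else ""
  ))
  invisible(x)
}

#' @method tidy kcsd_scan
#' @export
tidy.kcsd_scan <- function(x, ...) x$scan

#' @method glance kcsd_scan
#' @export
glance.kcsd_scan <- function(x, ...) {
  tibble(method = x$method, R = x$R, lambda = x$lambda,
         boundary_flag = x$boundary_flag,
         n_R = dplyr::n_distinct(x$scan$R),
         n_lambda = max(x$scan$lambda_index))
}
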