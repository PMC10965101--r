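# Kernel and cross-kernel construction and regularised kCSD estimation.

#' Slice geometry for the Method-of-Images (MoI) variant
#'
#' Describes a tissue slice of finite thickness on a planar multielectrode
#' array, immersed in a medium (saline) of different conductivity.  The
#' electrode plane is at z = 0 (the lower face of the slice) and the tissue
#' occupies 0..thickness; the conductivity jump at the slice faces is
#' handled with a ladder of mirror images weighted by powers of
#' `W = (sigma_tissue - sigma_saline) / (sigma_tissue + sigma_saline)`.
#'
#' @param thickness Slice thickness, > 0.
#' @param sigma_tissue,sigma_saline Positive conductivities.
#' @param n_images Number of image reflections kept (>= 0); the series tail
#'   is geometric in `W`, so 20 terms suffice for |W| <= 0.9.
#' @export
slice_geometry <- function(thickness, sigma_tissue, sigma_saline,
                           n_images = 20L) {
  stopifnot(thickness > 0, sigma_tissue > 0, sigma_saline > 0, n_images >= 0)
  structure(
    list(thickness = thickness, sigma_tissue = sigma_tissue,
         sigma_saline = sigma_saline, n_images = as.integer(n_images)),
    class = "slice_geometry"
  )
}

moi_reflection_coefficient <- function(geometry) {
  (geometry$sigma_tissue - geometry$sigma_saline) /
    (geometry$sigma_tissue + geometry$sigma_saline)
}

# Segment integral Int_{c_lo}^{c_hi} dz / sqrt(rho^2 + z^2), the in-plane
# kernel of a vertical line segment of source.
asinh_segment <- function(rho, c_lo, c_hi) {
  asinh(c_hi / rho) - asinh(c_lo / rho)
}

# In-plane kernel of the contributing layer (z in 0..2h, electrode plane at
# the bottom face) plus its mirror images across the two slice faces z = 0
# and z = thickness, each reflection weighted by W.  m counts reflections;
# every m >= 1 contributes exactly two images.
moi_image_kernel <- function(rho, h, thickness, W, n_images) {
  out <- asinh_segment(rho, 0, 2 * h)
  if (n_images >= 1 && W != 0) {
    for (m in seq_len(n_images)) {
      if (m %% 2 == 1) {
        a <- (m + 1) * thickness - 2 * h
        b <- -(m - 1) * thickness - 2 * h
      } else {
        a <- m * thickness
        b <- -m * thickness
      }
      out <- out + W^m * (asinh_segment(rho, a, a + 2 * h) +
                            asinh_segment(rho, b, b + 2 * h))
    }
  }
  out
}

# Point-source image ladder at in-plane distance rho, source height z_src in
# (0, thickness), measured at the electrode plane z = 0.  Used as an
# electrostatics oracle for the layer kernel above.
moi_point_images <- function(rho, z_src, thickness, W, n_images) {
  val <- 1 / sqrt(rho^2 + z_src^2)
  if (n_images >= 1 && W != 0) {
    for (m in seq_len(n_images)) {
      if (m %% 2 == 1) {
        z1 <- (m + 1) * thickness - z_src
        z2 <- -(m - 1) * thickness - z_src
      } else {
        z1 <- m * thickness + z_src
        z2 <- -m * thickness + z_src
      }
      val <- val + W^m * (1 / sqrt(rho^2 + z1^2) + 1 / sqrt(rho^2 + z2^2))
    }
  }
  val
}

#' Method-of-Images potential basis for slice recordings
#'
#' Replaces the infinite-tissue 2D potential basis by the image series of
#' [slice_geometry()].  With `sigma_saline == sigma_tissue` (W = 0) or
#' `n_images = 0` it reduces to [potential_basis_2d()].
#'
#' @inheritParams potential_basis_2d
#' @param geometry A [slice_geometry()].
#' @export
moi_potential_basis <- function(center, R, h, geometry, xy_points,
                                family = "gaussian") {
  stopifnot(inherits(geometry, "slice_geometry"), R > 0, h > 0)
  if (2 * h > geometry$thickness + 1e-12) {
    warn("contributing layer (2h) is thicker than the slice; images overlap the source")
  }
  pts <- as_coord_matrix(xy_points, dim = 2)
  d <- drop(cross_dist(pts, matrix(as.numeric(center), nrow = 1)))
  pot_radial_values(d, 2, family, R, h, geometry$sigma_tissue,
                    geometry = geometry)
}

# ---- Kernel model ---------------------------------------------------------

new_kcsd_model <- function(K, Ktilde, Ktilde_pot, lambda, setup, basis, space,
                           geometry = NULL) {
  sym <- max(abs(K - t(K))) / max(abs(K), .Machine$double.xmin)
  if (sym > 1e-10) abort("kernel matrix K is not symmetric")
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(eig$values)) {
    warn("kernel matrix K has a significantly negative eigenvalue")
  }
  structure(
    list(K = K, Ktilde = Ktilde, Ktilde_pot = Ktilde_pot,
         lambda = lambda, eigvals = eig$values, eigvecs = eig$vectors,
         setup = setup, basis = basis, space = space, geometry = geometry),
    class = "kcsd_model"
  )
}

#' @export
print.kcsd_model <- function(x, ...) {
  cat(sprintf(
    "<kcsd_model> %dD, N = %d electrodes, M = %d basis sources, P = %d estimation points\n",
    x$setup$dim, nrow(x$K), x$basis$M, nrow(x$Ktilde)
  ))
  cat(sprintf("  family = %s, R = %g%s, lambda = %g%s\n",
              x$basis$family, x$basis$R,
              if (!is.null(x$basis$h)) sprintf(", h = %g", x$basis$h) else "",
              x$lambda,
              if (!is.null(x$geometry)) " (MoI slice model)" else ""))
  invisible(x)
}

default_basis_centers <- function(setup, refine = 4L) {
  m <- as.matrix(setup$positions)
  lower <- apply(m, 2, min)
  upper <- apply(m, 2, max)
  per_axis <- pmax(2L, ceiling(refine * vapply(
    seq_len(setup$dim),
    function(a) length(unique(m[, a])), numeric(1)
  )))
  place_basis_regular(lower, upper, per_axis)
}

#' Build kernel and cross-kernel matrices
#'
#' Constructs `K[i, j] = sum_m b_m(x_i) b_m(x_j)` over electrode positions,
#' the cross-kernel `Ktilde[p, j] = sum_m b~_m(x_p) b_m(x_j)` mapping
#' coefficients to CSD at the estimation points, and `Ktilde_pot[p, j] =
#' sum_m b_m(x_p) b_m(x_j)` for potential interpolation.  Potential-basis
#' values are drawn from a distance lookup table (cubic spline over radial
#' quadrature values).
#'
#' @param setup An [electrode_setup()].
#' @param basis A [basis_config()]; defaults to Gaussian sources on a
#'   regular grid refined 4x per axis over the electrode bounding box.
#' @param space An [estimation_space()]; defaults to
#'   [default_estimation_space()].
#' @param lambda Regularisation parameter attached to the model (>= 0).
#' @param geometry Optional [slice_geometry()] switching the 2D potential
#'   basis to the Method-of-Images variant.
#' @param R,h Convenience shortcuts used when `basis` is `NULL`.
#' @param lookup Use the distance lookup table (default); `FALSE` evaluates
#'   every potential-basis value by direct radial quadrature (slow, used in
#'   verification studies).
#' @return A `kcsd_model`.
#' @export
build_kernels <- function(setup, basis = NULL, space = NULL, lambda = 0,
                          geometry = NULL, R = NULL, h = NULL,
                          lookup = TRUE) {
  stopifnot(inherits(setup, "electrode_setup"), lambda >= 0)
  if (is.null(space)) space <- default_estimation_space(setup)
  if (is.null(basis)) {
    elec <- as.matrix(setup$positions)
    dmin <- min(dist(elec))
    basis <- basis_config(
      family = "gaussian",
      R = R %||% dmin,
      h = h %||% dmin,
      centers = default_basis_centers(setup)
    )
  }
  if (basis$dim != setup$dim || space_dim(space) != setup$dim) {
    abort("electrodes, basis centers and estimation space must share dimensionality")
  }
  if (!is.null(geometry) && setup$dim != 2) {
    abort("the MoI slice model applies to 2D setups only")
  }
  if (setup$dim > 1 && is.null(basis$h)) basis$h <- basis$R
  if (setup$dim <= 2 && is.null(basis$h)) {
    abort("h (sheath radius / layer half-thickness) is required in 1D and 2D")
  }

  elec <- as.matrix(setup$positions)
  est <- as.matrix(space)
  d_elec <- cross_dist(elec, basis$centers)   # N x M
  d_est <- cross_dist(est, basis$centers)     # P x M
  dmax <- max(d_elec, d_est) * 1.0001 + 1e-12

  if (lookup) {
    lut <- potential_lookup(setup$dim, basis$family, basis$R, basis$h,
                            setup$sigma, dmax, geometry = geometry)
  } else {
    lut <- function(d) pot_radial_values(d, setup$dim, basis$family,
                                         basis$R, basis$h, setup$sigma,
                                         geometry = geometry)
  }
  B_elec <- matrix(lut(d_elec), nrow(d_elec), ncol(d_elec))
  if (!all(is.finite(B_elec))) {
    abort(sprintf("non-finite potential basis value (basis index %d)",
                  which(!is.finite(B_elec), arr.ind = TRUE)[1, 2]))
  }
  B_est <- matrix(lut(d_est), nrow(d_est), ncol(d_est))
  Btilde_est <- csd_radial(d_est, basis$family, basis$R, setup$dim)

  K <- tcrossprod(B_elec)                 # N x N
  Ktilde <- tcrossprod(Btilde_est, B_elec)  # P x N
  Ktilde_pot <- tcrossprod(B_est, B_elec)   # P x N
  model <- new_kcsd_model(K, Ktilde, Ktilde_pot, lambda, setup, basis, space,
                          geometry = geometry)
  model$B_elec <- B_elec
  model$Btilde_est <- Btilde_est
  model
}

#' Kernel model with explicitly placed basis sources and estimation points
#'
#' The oKCSD variant: identical mathematics to [build_kernels()], with basis
#' centers and estimation points specified explicitly (they need not form
#' regular grids).
#'
#' @inheritParams build_kernels
#' @param centers Matrix or data frame of basis centers.
#' @param points Matrix or data frame of estimation points.
#' @param family,R,h Basis family and radii.
#' @export
okcsd_model <- function(setup, centers, points, family = "gaussian",
                        R, h = NULL, lambda = 0, geometry = NULL) {
  basis <- basis_config(family, R = R, h = h, centers = centers)
  pts <- as_coord_matrix(points, dim = setup$dim)
  colnames(pts) <- coord_names(ncol(pts))
  space <- estimation_space(as_tibble(pts))
  build_kernels(setup, basis, space, lambda = lambda, geometry = geometry)
}

# ---- Fitting --------------------------------------------------------------

# Solve (K + lambda I) X = B through the stored eigendecomposition of K.
# Modes with eigenvalue + lambda below `cutoff` relative to the largest are
# dropped (eigendecomposition-based pseudo-inverse); `dropped` reports it.
ridge_solve <- function(model, B, lambda, cutoff = 1e-12) {
  ev <- model$eigvals + lambda
  top <- max(model$eigvals[1] + lambda, .Machine$double.xmin)
  keep <- ev > cutoff * top
  inv <- ifelse(keep, 1 / ev, 0)
  U <- model$eigvecs
  X <- U %*% (inv * crossprod(U, B))
  attr(X, "dropped") <- sum(!keep)
  X
}

#' Fit a kCSD estimate
#'
#' Solves `(K + lambda I) beta = V` per time sample with a symmetric
#' eigendecomposition-based solver and maps the coefficients through the
#' cross-kernels: `csd = Ktilde beta`, `pot = Ktilde_pot beta`.  When
#' `K + lambda I` is numerically singular the solver drops the offending
#' modes (pseudo-inverse with relative cutoff 1e-12) and records it.
#'
#' @param model A `kcsd_model`.
#' @param V Measured potentials: [potential_record()], vector (one time
#'   sample) or N x T matrix.
#' @param lambda Regularisation parameter; defaults to the model's.
#' @return A `kcsd_fit` with `beta` (N x T), `csd` (P x T), `pot` (P x T).
#' @export
fit_kcsd <- function(model, V, lambda = NULL) {
  stopifnot(inherits(model, "kcsd_model"))
  lambda <- lambda %||% model$lambda
  stopifnot(lambda >= 0)
  V <- as_potential_matrix(V, model$setup)
  beta <- ridge_solve(model, V, lambda)
  dropped <- attr(beta, "dropped")
  if (dropped > 0) {
    warn(sprintf(
      "K + lambda I numerically singular: %d mode(s) dropped (pseudo-inverse)",
      dropped
    ))
  }
  attr(beta, "dropped") <- NULL
  structure(
    list(beta = beta, csd = model$Ktilde %*% beta,
         pot = model$Ktilde_pot %*% beta,
         lambda = lambda, pseudo_inverse = dropped > 0, model = model),
    class = "kcsd_fit"
  )
}

#' @export
print.kcsd_fit <- function(x, ...) {
  cat(sprintf(
    "<kcsd_fit> lambda = %g, %d estimation points x %d time sample(s)%s\n",
    x$lambda, nrow(x$csd), ncol(x$csd),
    if (x$pseudo_inverse) " [pseudo-inverse fallback]" else ""
  ))
  invisible(x)
}

#' One-shot kCSD estimation from tabular inputs
#'
#' Convenience wrapper: builds the kernel model from an electrode position
#' table and fits the measured potentials in one call.
#'
#' @param positions Data frame of electrode coordinates: columns `x`,
#'   optionally `y` and `z`.
#' @param potentials Vector or matrix of measured potentials (electrodes x
#'   time).
#' @param sigma Tissue conductivity.
#' @inheritParams build_kernels
#' @param points_per_axis Resolution of the default estimation grid.
#' @export
kcsd <- function(positions, potentials, sigma = 1, R = NULL, h = NULL,
                 lambda = 0, basis = NULL, space = NULL,
                 points_per_axis = 50L, geometry = NULL) {
  setup <- electrode_setup(positions, sigma = sigma)
  if (is.null(space)) {
    space <- default_estimation_space(setup, points_per_axis)
  }
  model <- build_kernels(setup, basis = basis, space = space,
                         lambda = lambda, geometry = geometry, R = R, h = h)
  fit_kcsd(model, potentials)
}

#' @method tidy kcsd_fit
#' @export
tidy.kcsd_fit <- function(x, ...) {
  pts <- as_tibble(as.data.frame(x$model$space))
  csd <- as.data.frame(x$csd)
  names(csd) <- paste0("t", seq_len(ncol(csd)))
  out <- dplyr::bind_cols(pts, csd)
  tidyr::pivot_longer(out, dplyr::starts_with("t"),
                      names_to = "time", names_prefix = "t",
                      names_transform = as.integer, values_to = "csd")
}

#' @method glance kcsd_fit
#' @export
glance.kcsd_fit <- function(x, ...) {
  tibble(
    lambda = x$lambda,
    R = x$model$basis$R,
    n_electrodes = nrow(x$model$K),
    n_basis = x$model$basis$M,
    n_points = nrow(x$csd),
    rank = sum(x$model$eigvals > 1e-12 * max(x$model$eigvals)),
    pseudo_inverse = x$pseudo_inverse
  )
}

#' Forward-model an in-span ground truth through a kernel model
#'
#' Given coefficients over the model's own basis sources, returns the exact
#' electrode potentials and the CSD field on the estimation grid of the CSD
#' `sum_m alpha_m b~_m`.  Useful for in-span recovery studies: with
#' noise-free `V` and `lambda = 0` the kCSD estimate reproduces `csd`.
#'
#' @param model A `kcsd_model` built by [build_kernels()].
#' @param alpha Coefficient vector of length M (the basis count).
#' @return List with `V` (N-vector of potentials) and `csd` (P-vector).
#' @export
inspan_potentials <- function(model, alpha) {
  stopifnot(length(alpha) == model$basis$M, !is.null(model$B_elec))
  list(V = drop(model$B_elec %*% alpha),
       csd = drop(model$Btilde_est %*% alpha))
}
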