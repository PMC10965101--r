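# Seeded ground-truth CSD profiles, forward-modelled potentials, and noise —
# the synthetic harness standing in for experimental recordings.

#' Generate a seeded ground-truth CSD profile
#'
#' Profiles are Gaussian mixtures.  Families:
#' * `"small"` — component scales uniform in 0.1..0.5 of the reference
#'   distance `scale` (typically the minimum interelectrode distance);
#' * `"large"` — scales uniform in 1..2 of `scale`;
#' * `"dipole"` — two opposite-amplitude Gaussians a fixed separation apart;
#' * `"dipole_split_sink"` (1D) — one positive source and two nearby
#'   negative Gaussians carrying half its amplitude each, a dipolar source
#'   whose sink is split in two.
#'
#' Component centers are uniform in the bounding box and amplitudes
#' alternate +1/-1 so the profile has dipolar structure.
#'
#' @param family Profile family.
#' @param dim Spatial dimension (1-3).
#' @param lower,upper Bounding box of the component centers.
#' @param seed Integer seed; equal seeds give identical profiles.
#' @param scale Reference length for component radii; defaults to 1/9 of
#'   the smallest box side (a 10-electrodes-per-axis spacing).
#' @param n_components Number of Gaussian components for the small/large
#'   families.
#' @return A `csd_profile`: tibble of components (center coordinates,
#'   `R_src`, `amplitude`) with family/seed metadata.
#' @export
make_profile <- function(family = c("small", "large", "dipole",
                                    "dipole_split_sink"),
                         dim, lower, upper, seed, scale = NULL,
                         n_components = 4L) {
  family <- match.arg(family)
  stopifnot(length(lower) == dim, length(upper) == dim, all(upper > lower))
  scale <- scale %||% (min(upper - lower) / 9)
  span <- upper - lower
  comp <- with_local_seed(sub_seed(seed, paste0("profile-", family)), {
    if (family %in% c("small", "large")) {
      rng <- if (family == "small") c(0.1, 0.5) else c(1, 2)
      centers <- matrix(runif(n_components * dim), n_components, dim)
      centers <- sweep(sweep(centers, 2, span, "*"), 2, lower, "+")
      tibble(
        as_tibble(`colnames<-`(centers, coord_names(dim))),
        R_src = runif(n_components, rng[1] * scale, rng[2] * scale),
        amplitude = rep_len(c(1, -1), n_components)
      )
    } else if (family == "dipole") {
      Rs <- runif(1, 0.5, 1.5) * scale
      mid <- lower + span * runif(dim, 0.35, 0.65)
      dir <- rnorm(dim)
      dir <- dir / sqrt(sum(dir^2))
      centers <- rbind(mid + dir * Rs, mid - dir * Rs)
      tibble(
        as_tibble(`colnames<-`(centers, coord_names(dim))),
        R_src = rep(Rs, 2),
        amplitude = c(1, -1)
      )
    } else {
      if (dim != 1) abort("dipole_split_sink is a 1D profile family")
      jit <- runif(4, -0.02, 0.02) * span
      tibble(
        x = lower + span * c(0.35 + jit[1], 0.6 + jit[2], 0.75 + jit[3]),
        R_src = span * c(0.08, 0.05, 0.05) * (1 + jit[4]),
        amplitude = c(1, -0.5, -0.5)
      )
    }
  })
  structure(
    list(components = comp, family = family, dim = dim, seed = seed,
         lower = lower, upper = upper, scale = scale),
    class = "csd_profile"
  )
}

#' Evaluate a ground-truth CSD profile at points
#'
#' @param profile A `csd_profile`.
#' @param points Data frame or matrix of coordinates.
#' @return Numeric vector of CSD values.
#' @export
evaluate_profile <- function(profile, points) {
  pts <- as_coord_matrix(points, dim = profile$dim)
  comp <- profile$components
  vals <- numeric(nrow(pts))
  for (j in seq_len(nrow(comp))) {
    center <- as.numeric(comp[j, coord_names(profile$dim)])
    vals <- vals + comp$amplitude[j] *
      csd_basis_gaussian(center, comp$R_src[j], pts)
  }
  vals
}

#' @export
print.csd_profile <- function(x, ...) {
  cat(sprintf("<csd_profile> family = %s, %dD, %d component(s), seed = %s\n",
              x$family, x$dim, nrow(x$components), format(x$seed)))
  invisible(x)
}

#' Forward-model the potentials of a profile at the electrodes
#'
#' Superposes the per-component potential bases: the closed-form erf
#' potential in 3D, and the cylinder/layer integral transforms in 1D/2D
#' (the same radial quadrature machinery the kernel construction uses).
#'
#' @param profile A `csd_profile`.
#' @param setup An [electrode_setup()] of matching dimension.
#' @param h Sheath radius (1D) or layer half-thickness (2D).
#' @param geometry Optional [slice_geometry()] for slice recordings.
#' @return A `forward_result`: list with `potentials` (N-vector), the
#'   physical model tag and quadrature metadata.
#' @export
forward_potentials <- function(profile, setup, h = NULL, geometry = NULL) {
  stopifnot(inherits(profile, "csd_profile"),
            inherits(setup, "electrode_setup"))
  if (profile$dim != setup$dim) {
    abort("profile and setup dimensions differ")
  }
  if (setup$dim <= 2 && is.null(h)) {
    abort("h is required for 1D and 2D forward models")
  }
  elec <- as.matrix(setup$positions)
  comp <- profile$components
  pot <- numeric(nrow(elec))
  for (j in seq_len(nrow(comp))) {
    center <- matrix(as.numeric(comp[j, coord_names(profile$dim)]), nrow = 1)
    d <- drop(cross_dist(elec, center))
    pot <- pot + comp$amplitude[j] *
      pot_radial_values(d, setup$dim, "gaussian", comp$R_src[j], h,
                        setup$sigma, geometry = geometry)
  }
  structure(
    list(
      potentials = pot,
      method = if (setup$dim == 3 && is.null(geometry)) "closed_form"
               else "quadrature",
      model = switch(setup$dim, "1d_cylinder", "2d_layer", "3d_infinite"),
      h = h
    ),
    class = "forward_result"
  )
}

#' Add seeded noise to forward-modelled potentials
#'
#' @param potentials Numeric vector of potentials.
#' @param kind `"uniform"` (i.i.d. on `-amplitude..amplitude`) or
#'   `"gaussian"` (multivariate normal with covariance `Sigma`).
#' @param amplitude Half-width of the uniform noise.  May be given as a
#'   fraction of the peak absolute potential via `relative = TRUE`.
#' @param Sigma Covariance matrix (or scalar variance) for Gaussian noise.
#' @param seed Integer seed.
#' @param relative If `TRUE`, `amplitude` is relative to `max(abs(potentials))`.
#' @return List with `noisy` and the `noise` realisation.
#' @export
add_noise <- function(potentials, kind = c("uniform", "gaussian"),
                      amplitude = 0.05, Sigma = NULL, seed,
                      relative = FALSE) {
  kind <- match.arg(kind)
  n <- length(potentials)
  noise <- with_local_seed(sub_seed(seed, paste0("noise-", kind)), {
    if (kind == "uniform") {
      a <- if (relative) amplitude * max(abs(potentials)) else amplitude
      runif(n, -a, a)
    } else {
      Sigma <- Sigma %||% 1
      if (is.matrix(Sigma)) {
        ch <- chol(Sigma + diag(1e-15 * max(diag(Sigma)), n))
        drop(crossprod(ch, rnorm(n)))
      } else {
        rnorm(n, sd = sqrt(Sigma))
      }
    }
  })
  list(noisy = potentials + noise, noise = noise)
}

#' Demonstration fixture: 1D probe over a dipole with a split sink
#'
#' A regular 32-electrode laminar probe on `[0, 1]` records the potential of
#' a dipolar source whose negative pole (sink) is split in two; i.i.d.
#' uniform noise (5% of the peak potential by default) is added at every
#' electrode.  This is the end-to-end demo and regression fixture.
#'
#' @param seed Integer seed.
#' @param n_electrodes Number of electrodes.
#' @param noise_amplitude Uniform noise half-width relative to the peak
#'   potential; 0 gives the noise-free variant.
#' @param h Cylinder sheath radius of the 1D forward model.
#' @param sigma Conductivity.
#' @return List with `setup`, `potentials` (noisy), `clean`, `noise`,
#'   `profile`, `h`.
#' @export
split_sink_fixture <- function(seed = 1L, n_electrodes = 32L,
                               noise_amplitude = 0.05, h = 0.1, sigma = 1) {
  setup <- electrode_setup(
    data.frame(x = seq(0, 1, length.out = n_electrodes)), sigma = sigma
  )
  profile <- make_profile("dipole_split_sink", dim = 1, lower = 0, upper = 1,
                          seed = seed)
  clean <- forward_potentials(profile, setup, h = h)$potentials
  if (noise_amplitude > 0) {
    nz <- add_noise(clean, "uniform", amplitude = noise_amplitude,
                    seed = seed, relative = TRUE)
  } else {
    nz <- list(noisy = clean, noise = numeric(length(clean)))
  }
  list(setup = setup, potentials = nz$noisy, clean = clean,
       noise = nz$noise, profile = profile, h = h)
}
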