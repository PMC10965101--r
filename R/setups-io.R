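# Electrode setups, estimation spaces, noise models, and on-disk artifacts.

#' Construct an electrode setup
#'
#' An electrode setup pairs the recording positions with the tissue
#' conductivity.  Positions, basis radii and estimation bounds must share one
#' length unit, and `sigma` the matching conductivity unit (e.g. positions in
#' mm and sigma in S/mm); the package never converts units.
#'
#' @param positions Data frame (or matrix) of electrode coordinates with
#'   columns `x`, optionally `y`, `z` — one row per electrode.
#' @param sigma Tissue conductivity, a positive scalar.
#' @return An object of class `electrode_setup`: a list with `positions`
#'   (tibble), `dim` and `sigma`.
#' @examples
#' electrode_setup(data.frame(x = seq(0, 1, length.out = 8)), sigma = 1)
#' @export
electrode_setup <- function(positions, sigma = 1) {
  if (is.matrix(positions)) {
    colnames(positions) <- coord_names(ncol(positions))
    positions <- as_tibble(positions)
  }
  positions <- as_tibble(positions)
  dim <- ncol(positions)
  if (!dim %in% 1:3) {
    abort("electrode positions must have 1, 2 or 3 coordinate columns")
  }
  if (!identical(names(positions), coord_names(dim))) {
    if (all(coord_names(dim) %in% names(positions))) {
      positions <- positions[, coord_names(dim)]
    } else {
      abort(sprintf(
        "coordinate columns must be named %s",
        paste(coord_names(dim), collapse = ", ")
      ))
    }
  }
  m <- as.matrix(positions)
  if (nrow(m) < 2) abort("an electrode setup needs at least 2 electrodes")
  if (!all(is.finite(m))) abort("electrode coordinates must be finite numbers")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("sigma must be a positive scalar conductivity")
  }
  dup <- duplicated(m) | duplicated(m, fromLast = TRUE)
  if (any(dup)) {
    abort(sprintf(
      "duplicate electrode coordinates in rows: %s",
      paste(which(dup), collapse = ", ")
    ))
  }
  structure(
    list(positions = positions, dim = dim, sigma = sigma),
    class = "electrode_setup"
  )
}

#' @export
print.electrode_setup <- function(x, ...) {
  cat(sprintf(
    "<electrode_setup> %d electrodes in %dD, sigma = %g\n",
    nrow(x$positions), x$dim, x$sigma
  ))
  print(x$positions, n = 4)
  invisible(x)
}

n_electrodes <- function(setup) nrow(setup$positions)

#' Read an electrode setup from a delimited text table
#'
#' The table must have a header row with coordinate columns `x`, optionally
#' `y` and `z`, one row per electrode.  Comma and tab delimiters are
#' auto-detected.
#'
#' @param path Path to a CSV/TSV file.
#' @inheritParams electrode_setup
#' @return An [electrode_setup()].
#' @export
read_setup <- function(path, sigma = 1) {
  tab <- read_delim_auto(path)
  dim <- sum(coord_names(3) %in% names(tab))
  if (dim == 0) abort(sprintf("no coordinate columns (x[,y[,z]]) in '%s'", path))
  tab <- tab[, coord_names(dim)]
  num <- as.data.frame(suppressWarnings(lapply(tab, function(col) {
    as.numeric(as.character(col))
  })))
  bad <- which(!stats::complete.cases(num) |
                 rowSums(!is.finite(as.matrix(num))) > 0)
  if (length(bad)) {
    abort(sprintf(
      "non-numeric or missing coordinates in '%s', row(s): %s",
      path, paste(bad, collapse = ", ")
    ))
  }
  electrode_setup(num, sigma = sigma)
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE,
    trim_ws = TRUE
  )
}

#' Attach a matrix of measured potentials to a setup
#'
#' @param values Numeric matrix (electrodes x time samples) or vector of
#'   measured potentials.
#' @param setup The paired [electrode_setup()].
#' @return A `potential_record`: list with the `values` matrix and the
#'   electrode index.
#' @export
potential_record <- function(values, setup) {
  v <- as.matrix(values)
  if (is.data.frame(values)) v <- as.matrix(values)
  if (nrow(v) != n_electrodes(setup)) {
    # a vector read as a 1-row matrix
    if (ncol(v) == n_electrodes(setup) && nrow(v) == 1) v <- t(v)
    else abort(sprintf(
      "potential rows (%d) must match electrode count (%d)",
      nrow(v), n_electrodes(setup)
    ))
  }
  storage.mode(v) <- "double"
  if (!all(is.finite(v))) abort("potentials must be finite")
  structure(
    list(values = v, electrode_index = seq_len(nrow(v))),
    class = "potential_record"
  )
}

#' Read a potential matrix (electrodes x time) from a delimited table
#'
#' @inheritParams read_setup
#' @param setup The paired [electrode_setup()].
#' @export
read_potentials <- function(path, setup) {
  tab <- read_delim_auto(path)
  potential_record(as.matrix(tab), setup)
}

as_potential_matrix <- function(V, setup) {
  if (inherits(V, "potential_record")) V <- V$values
  if (is.null(dim(V))) V <- matrix(V, ncol = 1)
  V <- as.matrix(V)
  if (nrow(V) != n_electrodes(setup)) {
    abort(sprintf(
      "potential rows (%d) must match electrode count (%d)",
      nrow(V), n_electrodes(setup)
    ))
  }
  V
}

#' Estimation space: points where CSD and potential are reconstructed
#'
#' @param points Data frame of coordinates: columns `x`, optionally `y`, `z`.
#' @param descriptor Optional regular-grid descriptor: list with numeric
#'   vectors `lower`, `upper` and integer `counts` (one entry per axis).  When
#'   given, `points` must be its row-major expansion (last axis fastest).
#' @return An `estimation_space`: tibble of points with the descriptor as an
#'   attribute.
#' @export
estimation_space <- function(points, descriptor = NULL) {
  points <- as_tibble(points)
  dim <- ncol(points)
  if (!dim %in% 1:3) abort("estimation points must be 1-3 dimensional")
  names(points) <- coord_names(dim)
  if (nrow(points) < 1) abort("estimation space needs at least one point")
  if (!is.null(descriptor)) {
    expanded <- expand_grid_descriptor(descriptor)
    if (!isTRUE(all.equal(as.matrix(points), as.matrix(expanded),
                          check.attributes = FALSE, tolerance = 1e-12))) {
      abort("descriptor expansion does not match the stored points")
    }
  }
  structure(points,
    descriptor = descriptor,
    class = c("estimation_space", class(points))
  )
}

space_dim <- function(space) ncol(space)

# Row-major expansion, last axis fastest: for axes (x, y), x varies slowest.
expand_grid_descriptor <- function(descriptor) {
  lower <- descriptor$lower
  upper <- descriptor$upper
  counts <- as.integer(descriptor$counts)
  k <- length(counts)
  stopifnot(length(lower) == k, length(upper) == k, all(counts >= 1))
  axes <- lapply(seq_len(k), function(i) {
    if (counts[i] == 1L) (lower[i] + upper[i]) / 2
    else seq(lower[i], upper[i], length.out = counts[i])
  })
  g <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)  # first factor fastest
  g <- g[, rev(seq_len(k)), drop = FALSE]              # reorder to x, y, z
  names(g) <- coord_names(k)
  as_tibble(g)
}

#' Default estimation space spanned by the electrode positions
#'
#' Takes the axis-aligned bounding box of the electrodes and discretises it
#' with `points_per_axis` points per axis (a regular grid, row-major with the
#' last axis fastest).
#'
#' @param setup An [electrode_setup()].
#' @param points_per_axis Positive integer.
#' @export
default_estimation_space <- function(setup, points_per_axis = 50L) {
  stopifnot(points_per_axis >= 1)
  m <- as.matrix(setup$positions)
  lower <- apply(m, 2, min)
  upper <- apply(m, 2, max)
  degenerate <- which(upper - lower <= 0)
  if (length(degenerate)) {
    abort(sprintf(
      "all electrodes share one %s coordinate; supply explicit bounds via estimation_space()",
      paste(coord_names(setup$dim)[degenerate], collapse = "/")
    ))
  }
  descriptor <- list(
    lower = unname(lower), upper = unname(upper),
    counts = rep(as.integer(points_per_axis), setup$dim)
  )
  estimation_space(expand_grid_descriptor(descriptor), descriptor)
}

#' Noise model for the measured potentials
#'
#' Either a full N x N covariance matrix of the electrode noise, or the
#' scalar shorthand `sigma2` meaning `sigma2 * I`.
#'
#' @param covariance Symmetric positive-semidefinite matrix, or `NULL`.
#' @param sigma2 Scalar variance shorthand, or `NULL`.
#' @param n Number of electrodes (required with `sigma2`).
#' @export
noise_model <- function(covariance = NULL, sigma2 = NULL, n = NULL) {
  if (is.null(covariance)) {
    if (is.null(sigma2) || is.null(n)) {
      abort("supply either a covariance matrix or sigma2 together with n")
    }
    stopifnot(sigma2 >= 0, n >= 1)
    return(structure(
      list(covariance = NULL, sigma2 = sigma2, n = as.integer(n)),
      class = "noise_model"
    ))
  }
  covariance <- as.matrix(covariance)
  rel <- max(abs(covariance - t(covariance))) /
    max(abs(covariance), .Machine$double.xmin)
  if (rel > 1e-12) abort("noise covariance must be symmetric (1e-12 relative)")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    abort("noise covariance must be positive semidefinite")
  }
  structure(
    list(covariance = covariance, sigma2 = NULL, n = nrow(covariance)),
    class = "noise_model"
  )
}

noise_covariance <- function(noise, n) {
  if (!is.null(noise$covariance)) {
    if (nrow(noise$covariance) != n) {
      abort(sprintf("noise covariance is %dx%d but N = %d",
                    nrow(noise$covariance), nrow(noise$covariance), n))
    }
    noise$covariance
  } else {
    diag(noise$sigma2, n)
  }
}

#' Write a map (values on an estimation space) to a self-describing archive
#'
#' The archive is a JSON document embedding the values, the point
#' coordinates, and the regular-grid descriptor, written at full double
#' precision so a read-back reproduces the numbers exactly.
#'
#' @param values Numeric vector of length P (one value per estimation point)
#'   or a P x m matrix of m stacked maps.
#' @param space The [estimation_space()] the values live on.
#' @param path Output file path.
#' @param value_names Optional names for the columns of a stacked map.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, space, path, value_names = NULL) {
  v <- if (is.null(dim(values))) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(v) != nrow(space)) {
    abort(sprintf("values have %d rows but the space has %d points",
                  nrow(v), nrow(space)))
  }
  payload <- list(
    format = "kcsd-map/1",
    dim = space_dim(space),
    descriptor = attr(space, "descriptor"),
    points = unname(as.matrix(space)),
    values = unname(v),
    value_names = value_names
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read back a map archive written by [write_map()]
#'
#' @param path Archive path.
#' @return List with `values` (vector or matrix), `space`
#'   ([estimation_space()]) and `value_names`.
#' @export
read_map <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "kcsd-map/1")) {
    abort(sprintf("'%s' is not a kcsd map archive", path))
  }
  pts <- matrix(as.numeric(payload$points), ncol = payload$dim)
  colnames(pts) <- coord_names(payload$dim)
  descriptor <- payload$descriptor
  if (!is.null(descriptor)) {
    descriptor <- list(
      lower = as.numeric(descriptor$lower),
      upper = as.numeric(descriptor$upper),
      counts = as.integer(descriptor$counts)
    )
  }
  space <- estimation_space(as_tibble(pts), descriptor)
  v <- as.matrix(payload$values)
  storage.mode(v) <- "double"
  if (ncol(v) == 1) v <- drop(v)
  list(values = v, space = space, value_names = payload$value_names)
}
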