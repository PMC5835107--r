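#' Create a seeded Sobol quasi-random engine
#'
#' A Sobol sequence is a low-discrepancy quasi-random sequence: it covers
#' a sampling region more evenly than pseudo-random points, which is why
#' it is used here to place batches of candidate designs. The engine is
#' stateful: successive draws continue the sequence without repetition,
#' and the same `(seed, dimensions)` always reproduces the same stream.
#' Scrambling is a seeded digital shift (each dimension's output bits are
#' XORed with a fixed seed-derived word), which preserves the sequence's
#' equidistribution while making distinct seeds give distinct streams;
#' `scramble = FALSE` yields the raw Joe-Kuo sequence (first point at the
#' origin).
#'
#' @param dimensions Number of coordinates per point (1 to 21).
#' @param seed Integer seed controlling the scrambling.
#' @param scramble Apply the seeded digital shift? Default `TRUE`.
#' @return An object of class `sobol_engine`.
#' @export
#' @examples
#' eng <- sobol_engine(2, seed = 1)
#' sobol_unit(eng, 4)
sobol_engine <- function(dimensions, seed = 0L, scramble = TRUE) {
  stop_if_not(dimensions >= 1 && dimensions <= 21,
              "dimensions must be between 1 and 21")
  env <- new.env(parent = emptyenv())
  env$dimensions <- as.integer(dimensions)
  env$seed <- as.integer(seed)
  env$scramble <- isTRUE(scramble)
  env$counter <- 0
  class(env) <- "sobol_engine"
  env
}

#' @export
print.sobol_engine <- function(x, ...) {
  cat(sprintf("<sobol_engine: %d-D, seed %d, next index %g%s>\n",
              x$dimensions, x$seed, x$counter,
              if (x$scramble) ", scrambled" else ""))
  invisible(x)
}

#' Draw points from the unit hypercube
#'
#' Advances the engine by `n` points; every coordinate lies in `[0, 1)`.
#'
#' @param engine A [sobol_engine()].
#' @param n Number of points to draw (>= 1).
#' @return An `n x dimensions` matrix.
#' @export
sobol_unit <- function(engine, n) {
  stop_if_not(inherits(engine, "sobol_engine"), "expected a sobol_engine")
  stop_if_not(n >= 1, "n must be >= 1")
  pts <- .sobol_points_cpp(engine$dimensions, as.integer(n), engine$counter,
                           as.double(engine$seed), engine$scramble)
  engine$counter <- engine$counter + n
  pts
}

#' Sample a normal-shaped cloud of candidate designs around a center
#'
#' Unit-cube Sobol points are mapped through the inverse standard-normal
#' transform per coordinate, so the cloud follows an N-dimensional
#' normal distribution with quasi-random (evenly spread) structure. The
#' normal deviates are scaled by `radius` (the sampling spread sigma, in
#' expression units), optionally sheared by the Cholesky factor of a
#' symmetric positive-definite `shape` matrix (identity unless adapted,
#' e.g. by the CMA variant), translated to `center`, and finally clipped
#' componentwise to `bounds`.
#'
#' @param engine A [sobol_engine()].
#' @param center Coordinate vector, the current sampling center.
#' @param radius Spread sigma >= 0, in expression units.
#' @param n Number of designs to sample.
#' @param bounds 2-row bounds matrix as in [landscape()]; `NULL` skips
#'   clipping.
#' @param shape Optional symmetric positive-definite scaling matrix.
#' @return An object of class `sample_cloud`: list with `center`,
#'   `radius`, `points` (n x d matrix, clipped) and `shape`.
#' @export
sample_cloud <- function(engine, center, radius, n, bounds = NULL,
                         shape = NULL) {
  stop_if_not(inherits(engine, "sobol_engine"), "expected a sobol_engine")
  center <- as.numeric(center)
  d <- length(center)
  stop_if_not(d == engine$dimensions,
              "center has %d coordinates, engine is %d-D", d,
              engine$dimensions)
  stop_if_not(radius >= 0, "radius must be >= 0")
  u <- sobol_unit(engine, n)
  # guard against qnorm(0) = -Inf: nudge into the open interval
  eps <- 2^-53
  u <- pmin(pmax(u, eps), 1 - eps)
  z <- qnorm(u)
  if (!is.null(shape)) {
    shape <- as.matrix(shape)
    stop_if_not(nrow(shape) == d && ncol(shape) == d,
                "shape must be a %d x %d matrix", d, d)
    stop_if_not(isTRUE(all.equal(shape, t(shape), tolerance = 1e-8)),
                "shape matrix must be symmetric")
    ch <- tryCatch(chol(shape),
                   error = function(e) stop("shape matrix must be positive-definite",
                                            call. = FALSE))
    z <- z %*% ch # rows become draws from N(0, shape)
  }
  pts <- sweep(z * radius, 2, center, "+")
  if (!is.null(bounds)) pts <- clip_to_bounds(pts, bounds)
  structure(list(center = center, radius = radius, points = pts,
                 shape = if (is.null(shape)) diag(d) else shape),
            class = "sample_cloud")
}

#' Clip points componentwise to domain bounds
#'
#' Points already inside the bounds are returned unchanged.
#'
#' @param points Matrix of coordinates, one row per point.
#' @param bounds 2-row bounds matrix (`lower`, `upper`).
#' @return The clipped matrix.
#' @export
clip_to_bounds <- function(points, bounds) {
  points <- as.matrix(points)
  bounds <- as.matrix(bounds)
  stop_if_not(ncol(points) == ncol(bounds),
              "points and bounds disagree on dimensionality")
  for (dd in seq_len(ncol(points))) {
    points[, dd] <- pmin(pmax(points[, dd], bounds[1, dd]), bounds[2, dd])
  }
  points
}
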