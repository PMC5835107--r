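#' Construct a sum-of-Gaussians fitness landscape
#'
#' A landscape maps a point in a bounded N-dimensional expression space
#' (one axis per gene, in arbitrary expression units) to a nonnegative
#' fitness value, modeling e.g. the titer of a metabolic product as a
#' function of per-gene expression levels. Fitness is the sum of
#' axis-aligned Gaussian sub-peaks:
#' \deqn{f(p) = \sum_i A_i \exp\left(-\sum_d \frac{(p_d - c_{id})^2}
#'   {2\,s_{id}^2}\right)}
#' where peak \eqn{i} has center \eqn{c_i}, amplitude \eqn{A_i \ge 0} and
#' per-dimension spread \eqn{s_i > 0}.
#'
#' @param centers Numeric matrix, one row per peak, one column per
#'   dimension; peak centers must lie within `bounds`.
#' @param amplitudes Numeric vector of nonnegative peak heights.
#' @param spreads Numeric matrix (same shape as `centers`) of strictly
#'   positive per-dimension Gaussian spreads.
#' @param bounds Numeric matrix with two rows (`lower`, `upper`) and one
#'   column per dimension; defaults to `[0, 1000]` on every axis.
#' @param name Identifier for the landscape.
#' @return An object of class `sobol_landscape`.
#' @export
#' @examples
#' ls1 <- landscape(centers = matrix(c(500, 500), 1),
#'                  amplitudes = 1, spreads = matrix(c(100, 100), 1))
#' evaluate(ls1, c(500, 500))
landscape <- function(centers, amplitudes, spreads,
                      bounds = NULL, name = "landscape") {
  centers <- as.matrix(centers)
  spreads <- as.matrix(spreads)
  amplitudes <- as.numeric(amplitudes)
  d <- ncol(centers)
  if (is.null(bounds)) {
    bounds <- matrix(rep(c(0, 1000), d), nrow = 2,
                     dimnames = list(c("lower", "upper"), NULL))
  }
  bounds <- as.matrix(bounds)
  dimnames(bounds) <- list(c("lower", "upper"), NULL)
  obj <- structure(
    list(name = as.character(name), dimensions = d, bounds = bounds,
         centers = centers, amplitudes = amplitudes, spreads = spreads),
    class = "sobol_landscape"
  )
  validate_landscape(obj)
  obj
}

validate_landscape <- function(x) {
  stop_if_not(inherits(x, "sobol_landscape"), "not a sobol_landscape")
  d <- x$dimensions
  stop_if_not(d >= 1, "dimensions must be >= 1 (got %d)", d)
  stop_if_not(nrow(x$bounds) == 2 && ncol(x$bounds) == d,
              "bounds must be a 2 x %d matrix", d)
  stop_if_not(all(x$bounds[1, ] <= x$bounds[2, ]),
              "bounds: every lower bound must be <= its upper bound")
  k <- nrow(x$centers)
  stop_if_not(k >= 1, "landscape needs at least one peak")
  stop_if_not(ncol(x$centers) == d && identical(dim(x$spreads), dim(x$centers)),
              "centers and spreads must be %d-column matrices of equal shape", d)
  stop_if_not(length(x$amplitudes) == k,
              "amplitudes: expected %d values, got %d", k, length(x$amplitudes))
  stop_if_not(all(is.finite(x$centers)) && all(is.finite(x$spreads)) &&
                all(is.finite(x$amplitudes)),
              "peak parameters must be finite")
  stop_if_not(all(x$amplitudes >= 0), "amplitudes must be nonnegative")
  stop_if_not(all(x$spreads > 0), "every spread component must be > 0")
  inside <- sweep(x$centers, 2, x$bounds[1, ], ">=") &
    sweep(x$centers, 2, x$bounds[2, ], "<=")
  stop_if_not(all(inside), "all peak centers must lie within bounds")
  invisible(x)
}

#' @export
print.sobol_landscape <- function(x, ...) {
  cat(sprintf("<sobol_landscape '%s': %d peaks, %d dimensions>\n",
              x$name, nrow(x$centers), x$dimensions))
  cat(sprintf("  bounds: %s\n", paste(
    sprintf("[%g, %g]", x$bounds[1, ], x$bounds[2, ]), collapse = " x ")))
  invisible(x)
}

#' Evaluate landscape fitness at a single point
#'
#' Points outside the bounds are permitted and evaluated by the same
#' Gaussian-sum formula; bounds are enforced only by the samplers.
#'
#' @param landscape A [landscape()] object.
#' @param point Numeric coordinate vector of length `dimensions`.
#' @return A single nonnegative fitness value.
#' @export
evaluate <- function(landscape, point) {
  validate_landscape(landscape)
  point <- as.numeric(point)
  stop_if_not(length(point) == landscape$dimensions,
              "point has %d coordinates, landscape has %d dimensions",
              length(point), landscape$dimensions)
  drop(evaluate_batch(landscape, matrix(point, nrow = 1)))
}

#' Evaluate landscape fitness at many points
#'
#' @param landscape A [landscape()] object.
#' @param points Numeric matrix, one row per point, or a list of
#'   coordinate vectors.
#' @return Numeric vector of fitness values, one per point, in input
#'   order. Elementwise identical to calling [evaluate()] per point.
#' @export
evaluate_batch <- function(landscape, points) {
  validate_landscape(landscape)
  if (is.list(points)) points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (nrow(points) == 0) return(numeric(0))
  stop_if_not(ncol(points) == landscape$dimensions,
              "points have %d coordinates, landscape has %d dimensions",
              ncol(points), landscape$dimensions)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(landscape$centers))) {
    z <- sweep(points, 2, landscape$centers[i, ], "-")
    z <- sweep(z, 2, landscape$spreads[i, ], "/")
    out <- out + landscape$amplitudes[i] * exp(-0.5 * rowSums(z * z))
  }
  out
}

#' Sample a landscape on a full square grid
#'
#' Coordinates are evenly spaced per axis with both bound endpoints
#' included (spacing = range / (points_per_axis - 1)); the full Cartesian
#' product is returned, `points_per_axis^dimensions` points in all. The
#' default quantification protocol uses 200 points per axis on a 2-D
#' landscape, i.e. 40,000 grid points.
#'
#' @param landscape A [landscape()] object.
#' @param points_per_axis Integer >= 2.
#' @return A list with `points` (matrix) and `fitnesses` (vector).
#' @export
grid_sample <- function(landscape, points_per_axis = 200) {
  validate_landscape(landscape)
  stop_if_not(points_per_axis >= 2, "points_per_axis must be >= 2")
  axes <- lapply(seq_len(landscape$dimensions), function(d) {
    seq(landscape$bounds[1, d], landscape$bounds[2, d],
        length.out = points_per_axis)
  })
  pts <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  list(points = pts, fitnesses = evaluate_batch(landscape, pts))
}

#' Write a grid sample as a tab-separated table
#'
#' One coordinate column per dimension (`x1`, `x2`, ...) plus `fitness`,
#' full floating precision, header row.
#'
#' @param grid A list as returned by [grid_sample()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  df <- as.data.frame(grid$points)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df$fitness <- grid$fitnesses
  write_tsv_table(df, path)
}

#' Save a landscape specification to a JSON file
#'
#' The file is a versioned (`"format": 1`) JSON document with fields
#' `name`, `dimensions`, `bounds` and `peaks` (a list of
#' `{center, amplitude, spread}` records). Numeric fields are written at
#' full precision so a save/load round trip is bit-identical.
#'
#' @param landscape A [landscape()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_landscape <- function(landscape, path) {
  validate_landscape(landscape)
  peaks <- lapply(seq_len(nrow(landscape$centers)), function(i) {
    list(center = landscape$centers[i, ],
         amplitude = landscape$amplitudes[i],
         spread = landscape$spreads[i, ])
  })
  doc <- list(format = 1L, name = landscape$name,
              dimensions = landscape$dimensions,
              bounds = lapply(seq_len(landscape$dimensions),
                              function(d) landscape$bounds[, d]),
              peaks = peaks)
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a landscape specification from a JSON file
#'
#' @param path Path to a file written by [save_landscape()] (or following
#'   the same schema).
#' @return A validated [landscape()] object.
#' @export
load_landscape <- function(path) {
  stop_if_not(file.exists(path), "landscape spec file not found: %s", path)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
    error = function(e) stop(sprintf("cannot parse landscape spec %s: %s",
                                     path, conditionMessage(e)), call. = FALSE))
  for (field in c("format", "name", "dimensions", "bounds", "peaks")) {
    stop_if_not(!is.null(doc[[field]]),
                "landscape spec %s: missing field '%s'", path, field)
  }
  stop_if_not(identical(as.integer(doc$format), 1L),
              "landscape spec %s: unsupported format version '%s'",
              path, doc$format)
  d <- as.integer(doc$dimensions)
  raw_bounds <- doc$bounds
  if (is.matrix(raw_bounds)) {
    raw_bounds <- lapply(seq_len(nrow(raw_bounds)),
                         function(i) raw_bounds[i, ])
  }
  bounds <- vapply(raw_bounds, function(b) {
    stop_if_not(length(b) == 2 && is.numeric(b),
                "landscape spec %s: field 'bounds' must hold [lower, upper] pairs",
                path)
    as.numeric(b)
  }, numeric(2))
  peaks <- doc$peaks
  stop_if_not(length(peaks) >= 1, "landscape spec %s: field 'peaks' is empty", path)
  for (p in peaks) {
    for (field in c("center", "amplitude", "spread")) {
      stop_if_not(!is.null(p[[field]]) && is.numeric(unlist(p[[field]])),
                  "landscape spec %s: peak missing numeric field '%s'",
                  path, field)
    }
  }
  centers <- do.call(rbind, lapply(peaks, function(p) as.numeric(unlist(p$center))))
  spreads <- do.call(rbind, lapply(peaks, function(p) as.numeric(unlist(p$spread))))
  amplitudes <- vapply(peaks, function(p) as.numeric(p$amplitude), numeric(1))
  landscape(centers = centers, amplitudes = amplitudes, spreads = spreads,
            bounds = bounds, name = doc$name)
}

# Shared sub-peak layout of the three builtin model landscapes: 9 peaks on
# [0,1000]^2 whose centers and heights are identical across the trio; the
# landscapes differ only in a per-landscape scaling of the spreads.  The
# global maximum sits at (620, 410).
builtin_peak_table <- function() {
  list(
    centers = rbind(
      c(620, 410), c(220, 750), c(800, 800), c(350, 300),
      c(150, 250), c(500, 600), c(850, 250), c(250, 500), c(650, 850)),
    amplitudes = c(10, 7.5, 6.5, 6, 5, 5.5, 4.5, 4, 3.5),
    base_spreads = rbind(
      c(90, 75), c(70, 85), c(65, 60), c(80, 70),
      c(60, 75), c(70, 65), c(75, 60), c(65, 80), c(60, 70))
  )
}

# spread scale factors calibrated once so the default quantification
# protocol (200x200 grid, 100-unit bins to 700, N = 700) fits
# k ~= 0.83 / 1.07 / 2.07 on smooth / medium / rugged
builtin_spread_scales <- function() {
  c(smooth = 5.35774, medium = 3.08219, rugged = 1.70746)
}

#' Built-in smooth, medium and rugged model landscapes
#'
#' Three two-dimensional model landscapes over `[0, 1000]^2` sharing
#' identical sub-peak centers and heights and differing only in the
#' per-dimension spread of every sub-peak (broadest for `smooth`,
#' narrowest for `rugged`). The spread scaling is calibrated so that the
#' default ruggedness protocol ([quantify_ruggedness()]) fits NK
#' coefficients of approximately 0.83, 1.07 and 2.07 respectively, and
#' the fitted k is strictly increasing from smooth to rugged.
#'
#' @return A named list of three [landscape()] objects: `smooth`,
#'   `medium`, `rugged`.
#' @export
#' @examples
#' trio <- builtin_model_landscapes()
#' evaluate(trio$smooth, c(620, 410))
builtin_model_landscapes <- function() {
  tab <- builtin_peak_table()
  scales <- builtin_spread_scales()
  out <- lapply(names(scales), function(nm) {
    landscape(centers = tab$centers, amplitudes = tab$amplitudes,
              spreads = tab$base_spreads * scales[[nm]], name = nm)
  })
  names(out) <- names(scales)
  out
}

#' Import a landscape from a supplementary surface-definition script
#'
#' Reads Gaussian sub-peak parameters out of a Python surface-definition
#' file (such as `surface_matrix-low.py`). Two layouts are recognized:
#'
#' 1. a list-of-tuples assignment
#'    `peaks = [(amplitude, cx, cy, sx, sy), ...]`;
#' 2. explicit Gaussian terms of the canonical form
#'    `a*exp(-((X-cx)**2/(2*sx**2) + (Y-cy)**2/(2*sy**2)))`
#'    (whitespace-insensitive, `np.exp`/`numpy.exp`/`exp` accepted).
#'
#' @param path Path to the supplementary script.
#' @param name Name for the imported landscape; defaults to the file name.
#' @param bounds Domain bounds; defaults to `[0, 1000]^2`.
#' @return A validated [landscape()] object.
#' @export
import_supplementary_surface <- function(path, name = NULL, bounds = NULL) {
  if (!file.exists(path)) {
    stop(sprintf(paste0("supplementary file required: '%s' does not exist; ",
                        "provide the surface-definition script or use ",
                        "builtin_model_landscapes()"), path), call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  rows <- parse_peak_tuples(txt)
  if (is.null(rows)) rows <- parse_gaussian_terms(txt)
  if (is.null(rows) || nrow(rows) == 0) {
    stop(sprintf(paste0("cannot parse supplementary surface file '%s': no ",
                        "'peaks = [(amp, cx, cy, sx, sy), ...]' assignment ",
                        "and no 'a*exp(-((X-cx)**2/(2*sx**2)+...))' terms ",
                        "found"), path), call. = FALSE)
  }
  if (is.null(name)) name <- sub("\\.py$", "", basename(path))
  landscape(centers = rows[, 2:3, drop = FALSE], amplitudes = rows[, 1],
            spreads = rows[, 4:5, drop = FALSE], bounds = bounds, name = name)
}

num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"

# layout 1: peaks = [(amp, cx, cy, sx, sy), ...]
parse_peak_tuples <- function(txt) {
  block <- regmatches(txt, regexpr("peaks\\s*=\\s*\\[[^]]*\\]", txt, perl = TRUE))
  if (length(block) == 0) return(NULL)
  tuple_re <- sprintf("\\(\\s*(%s)(?:\\s*,\\s*(%s)){4}\\s*\\)", num_re, num_re)
  tuples <- regmatches(block, gregexpr(tuple_re, block, perl = TRUE))[[1]]
  if (length(tuples) == 0) return(NULL)
  do.call(rbind, lapply(tuples, function(tp) {
    vals <- as.numeric(regmatches(tp, gregexpr(num_re, tp, perl = TRUE))[[1]])
    if (length(vals) != 5) {
      stop("supplementary peak tuple must have 5 numbers (amp, cx, cy, sx, sy)",
           call. = FALSE)
    }
    vals
  }))
}

# layout 2: a*exp(-((X-cx)**2/(2*sx**2) + (Y-cy)**2/(2*sy**2)))
parse_gaussian_terms <- function(txt) {
  flat <- gsub("[[:space:]]+", "", txt)
  term_re <- sprintf(paste0(
    "(%s)\\*(?:np\\.|numpy\\.)?exp\\(-\\(",
    "\\([XxYy]-(%s)\\)\\*\\*2/\\(2\\*(%s)\\*\\*2\\)\\+",
    "\\([XxYy]-(%s)\\)\\*\\*2/\\(2\\*(%s)\\*\\*2\\)\\)\\)"),
    num_re, num_re, num_re, num_re, num_re)
  m <- gregexpr(term_re, flat, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- attr(m, "capture.start")
  lens <- attr(m, "capture.length")
  do.call(rbind, lapply(seq_along(m), function(i) {
    vals <- as.numeric(substring(flat, starts[i, ], starts[i, ] + lens[i, ] - 1))
    c(vals[1], vals[2], vals[4], vals[3], vals[5]) # amp, cx, cy, sx, sy
  }))
}
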