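#' Optimizer configuration
#'
#' Bundles the parameters of one batch-optimization run, mirroring the
#' experimental knobs of a design-build-test campaign: where to start
#' (`start`, SC), how broadly to sample each iteration (`sobol_radius`,
#' sigma), how many designs to build per iteration
#' (`samples_per_iteration`, N), how many design-build-test cycles to run
#' (`iterations`, I, default 5), and what fraction of top performers to
#' carry forward as parents (`parent_fraction`, F).
#'
#' @param algorithm One of `"hill_climb"`, `"projection"`, `"cma_es"`.
#' @param start Starting coordinates (SC), within the landscape bounds.
#' @param sobol_radius Sampling spread sigma, expression units (> 0
#'   unless you want a degenerate run).
#' @param samples_per_iteration Designs evaluated per iteration (>= 1).
#' @param iterations Number of iterations I (>= 1, default 5).
#' @param parent_fraction Fraction F in (0, 1] of samples kept as
#'   parents.
#' @param seed Integer seed; with the config it fully determines the run.
#' @param landscape_name Optional landscape identifier (L), recorded in
#'   exports.
#' @param cma_weighting For the CMA variant: `"fitness"` (default;
#'   weights proportional to min-shifted fitness) or `"rank"` (canonical
#'   log-rank weights).
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(algorithm = c("hill_climb", "projection", "cma_es"),
                             start, sobol_radius, samples_per_iteration,
                             iterations = 5L, parent_fraction,
                             seed = 0L, landscape_name = NULL,
                             cma_weighting = c("fitness", "rank")) {
  algorithm <- match.arg(algorithm)
  cma_weighting <- match.arg(cma_weighting)
  cfg <- structure(
    list(algorithm = algorithm, start = as.numeric(start),
         sobol_radius = as.numeric(sobol_radius),
         samples_per_iteration = as.integer(samples_per_iteration),
         iterations = as.integer(iterations),
         parent_fraction = as.numeric(parent_fraction),
         seed = as.integer(seed), landscape_name = landscape_name,
         cma_weighting = cma_weighting),
    class = "optimizer_config"
  )
  stop_if_not(cfg$parent_fraction > 0 && cfg$parent_fraction <= 1,
              "parent_fraction must be in (0, 1], got %g", cfg$parent_fraction)
  stop_if_not(cfg$iterations >= 1, "iterations must be >= 1")
  stop_if_not(cfg$samples_per_iteration >= 1,
              "samples_per_iteration must be >= 1")
  stop_if_not(cfg$sobol_radius >= 0, "sobol_radius must be >= 0")
  cfg
}

#' Select the top-performing designs as parents
#'
#' Keeps the `max(1, round(F * n))` highest fitnesses (half-up rounding).
#' Ties at the cutoff are broken by lower sample index, so selection is
#' stable and deterministic.
#'
#' @param fitnesses Numeric vector of sample fitnesses.
#' @param parent_fraction Fraction F in (0, 1].
#' @return Integer vector of parent indices (into `fitnesses`).
#' @export
#' @examples
#' select_parents(c(5, 1, 4, 2, 3), 0.4) # c(1, 3)
select_parents <- function(fitnesses, parent_fraction) {
  n <- length(fitnesses)
  stop_if_not(n >= 1, "need at least one fitness value")
  stop_if_not(parent_fraction > 0 && parent_fraction <= 1,
              "parent_fraction must be in (0, 1]")
  n_parents <- max(1L, as.integer(floor(parent_fraction * n + 0.5)))
  ord <- order(-fitnesses, seq_len(n))
  sort(ord[seq_len(n_parents)])
}

#' Next center by geometric centering of parents (hill climbing)
#'
#' @param parents Matrix of parent coordinates, one row per parent.
#' @return The componentwise arithmetic mean of the parents.
#' @export
hill_climb_center <- function(parents) {
  parents <- as.matrix(parents)
  stop_if_not(nrow(parents) >= 1, "need at least one parent")
  colMeans(parents)
}

#' Next center by twofold projection through the parent mean
#'
#' Draws the vector from the previous sampling center to the geometric
#' center of the parents and places the next center twice that distance
#' along it: `next = previous + 2 * (mean(parents) - previous)`. Moves
#' uphill faster than plain hill climbing but can over-shoot a maximum.
#'
#' @param previous_center Previous sampling center.
#' @param parents Matrix of parent coordinates.
#' @return The projected next center.
#' @export
projection_center <- function(previous_center, parents) {
  previous_center <- as.numeric(previous_center)
  m <- hill_climb_center(parents)
  previous_center + 2 * (m - previous_center)
}

#' Fitness-weighted center and shape update (simplified CMA)
#'
#' The next center is the fitness-weighted average of the parents,
#' weights proportional to fitness after shifting by the minimum parent
#' fitness (uniform if all parents are equal); `weighting = "rank"`
#' instead uses canonical log-rank weights. The sampling-shape matrix
#' (dimensionless; it multiplies the fixed radius sigma) is updated as
#' \deqn{C' = (1 - c_1 - c_\mu) C + c_\mu C_\mu + c_1 u u^T}
#' where \eqn{C_\mu} is the weighted empirical covariance of the parents
#' about the next center divided by sigma^2, and `u` is the unit vector
#' along the center shift (the rank-one term biases subsequent sampling
#' toward the direction just travelled). The result is symmetrized and
#' ridge-regularized to stay positive-definite; if the parents are
#' (nearly) coincident the ridge floor is applied and a warning logged.
#'
#' @param previous_center Previous sampling center.
#' @param parents Matrix of parent coordinates (>= 2 rows).
#' @param parent_fitnesses Fitness per parent.
#' @param previous_shape Symmetric positive-definite shape matrix.
#' @param radius Sampling sigma used to generate the parents (scales the
#'   empirical covariance back to shape units).
#' @param c_mu Covariance learning rate (default 0.5).
#' @param c_1 Rank-one (direction) learning rate (default 0.2).
#' @param weighting `"fitness"` or `"rank"`.
#' @return List with `center` and `shape`.
#' @export
cma_update <- function(previous_center, parents, parent_fitnesses,
                       previous_shape, radius = 1,
                       c_mu = 0.5, c_1 = 0.2,
                       weighting = c("fitness", "rank")) {
  weighting <- match.arg(weighting)
  parents <- as.matrix(parents)
  previous_center <- as.numeric(previous_center)
  d <- length(previous_center)
  stop_if_not(nrow(parents) >= 2, "CMA update needs at least 2 parents")
  stop_if_not(length(parent_fitnesses) == nrow(parents),
              "one fitness per parent required")
  previous_shape <- as.matrix(previous_shape)
  stop_if_not(isTRUE(all.equal(previous_shape, t(previous_shape),
                               tolerance = 1e-8)),
              "previous_shape must be symmetric")

  if (weighting == "fitness") {
    w <- parent_fitnesses - min(parent_fitnesses)
    if (sum(w) <= 0) w <- rep(1, nrow(parents)) else w <- w / sum(w)
    if (sum(w) != 1) w <- w / sum(w)
  } else {
    mu <- nrow(parents)
    r <- rank(-parent_fitnesses, ties.method = "first")
    w <- log(mu + 0.5) - log(r)
    w <- pmax(w, 0); w <- w / sum(w)
  }

  center <- drop(w %*% parents)
  dev <- sweep(parents, 2, center, "-") / radius
  c_mu_mat <- crossprod(dev * sqrt(w)) # sum_i w_i dev_i dev_i^T
  shift <- (center - previous_center)
  nrm <- sqrt(sum(shift^2))
  rank1 <- if (nrm > 0) tcrossprod(shift / nrm) else matrix(0, d, d)
  shape <- (1 - c_1 - c_mu) * previous_shape + c_mu * c_mu_mat + c_1 * rank1
  shape <- (shape + t(shape)) / 2
  # ridge floor: keep the smallest eigenvalue away from zero
  ev <- eigen(shape, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 1e-6
  if (min(ev) < floor_ev) {
    warning("CMA shape matrix near-degenerate; ridge floor applied",
            call. = FALSE)
    shape <- shape + (floor_ev - min(ev)) * diag(d)
  }
  list(center = center, shape = shape)
}

#' Run one batch optimization on a landscape
#'
#' Iteration 1 samples a Sobol normal cloud around the start coordinates
#' SC; each later iteration samples around the center produced by the
#' algorithm's update rule from the previous iteration's parents. Every
#' iteration records its center (and the center's fitness, evaluated on
#' the landscape), all sampled designs with their fitnesses, and the
#' selected parent indices. The trace is bitwise reproducible from
#' `(config, seed)`.
#'
#' @param config An [optimizer_config()].
#' @param landscape A [landscape()] object.
#' @return An object of class `optimization_trace`: list with `config`,
#'   `iterations` (list of per-iteration records) and `performance`
#'   (area under the center-fitness curve, see [performance()]).
#' @export
run_optimization <- function(config, landscape) {
  stop_if_not(inherits(config, "optimizer_config"),
              "expected an optimizer_config")
  validate_landscape(landscape)
  d <- landscape$dimensions
  stop_if_not(length(config$start) == d,
              "start has %d coordinates, landscape has %d dimensions",
              length(config$start), d)
  inside <- all(config$start >= landscape$bounds[1, ] &
                  config$start <= landscape$bounds[2, ])
  stop_if_not(inside, "start coordinates must lie within the landscape bounds")

  engine <- sobol_engine(d, seed = config$seed)
  center <- config$start
  shape <- diag(d)
  records <- vector("list", config$iterations)
  for (it in seq_len(config$iterations)) {
    cloud <- sample_cloud(engine, center, config$sobol_radius,
                          config$samples_per_iteration,
                          bounds = landscape$bounds,
                          shape = if (config$algorithm == "cma_es") shape else NULL)
    fits <- evaluate_batch(landscape, cloud$points)
    parents <- select_parents(fits, config$parent_fraction)
    records[[it]] <- list(
      index = it, center = center,
      center_fitness = evaluate(landscape, center),
      samples = cloud$points, sample_fitnesses = fits,
      parent_indices = parents
    )
    if (it == config$iterations) break
    pmat <- cloud$points[parents, , drop = FALSE]
    if (config$algorithm == "hill_climb") {
      center <- hill_climb_center(pmat)
    } else if (config$algorithm == "projection") {
      center <- projection_center(center, pmat)
    } else {
      if (length(parents) >= 2) {
        upd <- cma_update(center, pmat, fits[parents], shape,
                          radius = max(config$sobol_radius, .Machine$double.eps),
                          weighting = config$cma_weighting)
        center <- upd$center
        shape <- upd$shape
      } else {
        center <- hill_climb_center(pmat)
      }
    }
    center <- drop(clip_to_bounds(matrix(center, nrow = 1), landscape$bounds))
  }
  trace <- structure(list(config = config, iterations = records,
                          performance = NA_real_),
                     class = "optimization_trace")
  trace$performance <- performance(trace)$value
  trace
}

#' @export
print.optimization_trace <- function(x, ...) {
  cf <- vapply(x$iterations, `[[`, numeric(1), "center_fitness")
  cat(sprintf("<optimization_trace: %s, %d iterations, performance %.4g>\n",
              x$config$algorithm, length(x$iterations), x$performance))
  cat("  center fitness by iteration:",
      paste(sprintf("%.4g", cf), collapse = " "), "\n")
  invisible(x)
}

#' Export an optimization trace as a long tab-separated table
#'
#' One row per (iteration, role, point): roles are `center`, `sample`
#' and `parent` (parents re-listed from among that iteration's samples).
#'
#' @param trace An `optimization_trace`.
#' @param path Output file path.
#' @param run_id Identifier column value (default 1).
#' @return The path, invisibly.
#' @export
write_trace_tsv <- function(trace, path, run_id = 1L) {
  rows <- lapply(trace$iterations, function(rec) {
    d <- length(rec$center)
    coords <- rbind(rec$center, rec$samples,
                    rec$samples[rec$parent_indices, , drop = FALSE])
    role <- c("center", rep("sample", nrow(rec$samples)),
              rep("parent", length(rec$parent_indices)))
    fit <- c(rec$center_fitness, rec$sample_fitnesses,
             rec$sample_fitnesses[rec$parent_indices])
    df <- data.frame(run_id = run_id, iteration = rec$index, role = role)
    for (dd in seq_len(d)) df[[paste0("x", dd)]] <- coords[, dd]
    df$fitness <- fit
    df
  })
  write_tsv_table(do.call(rbind, rows), path)
}
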