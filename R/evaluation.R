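#' Performance of an optimization run
#'
#' The area under the center-point fitness trajectory over the run's
#' iterations: by default the rectangle-rule sum of the per-iteration
#' center fitnesses (unit iteration spacing), so a run that climbs
#' quickly *and* high scores better than one that only gets there late.
#' `rule = "trapezoid"` halves the endpoint weights instead.
#'
#' @param trace An `optimization_trace` from [run_optimization()].
#' @param rule `"rectangle"` (default) or `"trapezoid"`.
#' @return List with `value` and `iterations_used`.
#' @export
performance <- function(trace, rule = c("rectangle", "trapezoid")) {
  rule <- match.arg(rule)
  stop_if_not(inherits(trace, "optimization_trace"),
              "expected an optimization_trace")
  cf <- vapply(trace$iterations, `[[`, numeric(1), "center_fitness")
  stop_if_not(length(cf) >= 1, "trace has no iterations")
  value <- if (rule == "rectangle") {
    sum(cf)
  } else {
    if (length(cf) == 1) cf else sum(cf) - (cf[1] + cf[length(cf)]) / 2
  }
  list(value = value, iterations_used = length(cf))
}

#' Reliability: spread of replicate performances
#'
#' Sample standard deviation (n - 1 denominator) of the performance
#' scores of replicate runs; small values mean the algorithm performs
#' consistently at those parameter settings.
#'
#' @param performances Numeric vector of >= 2 replicate performance
#'   values.
#' @return The sample standard deviation.
#' @export
reliability <- function(performances) {
  stop_if_not(length(performances) >= 2,
              "reliability needs at least 2 replicate performances")
  sd(performances)
}

#' Sweep sampling radius and parent fraction for one algorithm
#'
#' Runs `replicates` independently seeded optimizations for every
#' (sigma, F) cell of the requested lattice and scores each cell's mean
#' performance and reliability (standard deviation over replicates).
#' Per-replicate seeds are derived from `base_seed` and the cell/replicate
#' indices, so results are independent of execution order and fully
#' reproducible.
#'
#' @param algorithm `"hill_climb"`, `"projection"` or `"cma_es"`.
#' @param landscape A [landscape()] object.
#' @param sigma_values Numeric vector of sampling radii to try.
#' @param f_values Numeric vector of parent fractions to try.
#' @param start Starting coordinates shared by all runs.
#' @param samples_per_iteration Designs per iteration (fixed across the
#'   sweep).
#' @param iterations Iterations per run (default 5).
#' @param replicates Replicate runs per cell (default 5, >= 2).
#' @param base_seed Base seed for the whole sweep.
#' @param keep_traces Keep every trace object (memory-heavy; default
#'   FALSE).
#' @return An object of class `sweep_result`: list with `algorithm`,
#'   `landscape_name`, `cells` (data frame: sigma, parent_fraction,
#'   mean_performance, reliability, n_replicates), `replicate_table`
#'   (long data frame with each replicate's performance and seed),
#'   `fixed` (start, samples_per_iteration, iterations, base_seed) and
#'   optionally `traces`.
#' @export
parameter_sweep <- function(algorithm, landscape, sigma_values, f_values,
                            start, samples_per_iteration,
                            iterations = 5L, replicates = 5L,
                            base_seed = 0L, keep_traces = FALSE) {
  stop_if_not(length(sigma_values) >= 1 && length(f_values) >= 1,
              "sigma_values and f_values must be nonempty")
  stop_if_not(replicates >= 2, "replicates must be >= 2 (got %g): reliability is undefined otherwise",
              replicates)
  cells <- expand.grid(sigma = as.numeric(sigma_values),
                       parent_fraction = as.numeric(f_values),
                       KEEP.OUT.ATTRS = FALSE)
  rep_rows <- vector("list", nrow(cells) * replicates)
  traces <- if (keep_traces) vector("list", nrow(cells) * replicates) else NULL
  mean_perf <- numeric(nrow(cells))
  rel <- numeric(nrow(cells))
  row <- 0L
  for (ci in seq_len(nrow(cells))) {
    perfs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      # seeds keyed on the cell's parameter values (not lattice position)
      # so a cell's replicates are identical however the lattice is laid
      # out or executed
      seed <- derive_seed(base_seed, round(cells$sigma[ci] * 1e3),
                          round(cells$parent_fraction[ci] * 1e6), r)
      cfg <- optimizer_config(
        algorithm = algorithm, start = start,
        sobol_radius = cells$sigma[ci],
        samples_per_iteration = samples_per_iteration,
        iterations = iterations,
        parent_fraction = cells$parent_fraction[ci],
        seed = seed, landscape_name = landscape$name)
      tr <- run_optimization(cfg, landscape)
      perfs[r] <- tr$performance
      row <- row + 1L
      rep_rows[[row]] <- data.frame(
        algorithm = algorithm, landscape = landscape$name,
        sigma = cells$sigma[ci], parent_fraction = cells$parent_fraction[ci],
        replicate = r, seed = seed, performance = perfs[r])
      if (keep_traces) traces[[row]] <- tr
    }
    mean_perf[ci] <- mean(perfs)
    rel[ci] <- reliability(perfs)
  }
  cells$mean_performance <- mean_perf
  cells$reliability <- rel
  cells$n_replicates <- replicates
  structure(
    list(algorithm = algorithm, landscape_name = landscape$name,
         cells = cells, replicate_table = do.call(rbind, rep_rows),
         fixed = list(start = start,
                      samples_per_iteration = samples_per_iteration,
                      iterations = iterations, base_seed = base_seed),
         traces = traces),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result: %s on '%s', %d cells x %d replicates>\n",
              x$algorithm, x$landscape_name, nrow(x$cells),
              x$cells$n_replicates[1]))
  best <- x$cells[which.max(x$cells$mean_performance), ]
  cat(sprintf("  best mean performance %.4g at sigma = %g, F = %g\n",
              best$mean_performance, best$sigma, best$parent_fraction))
  invisible(x)
}

#' Write sweep results as heatmap-ready CSV tables
#'
#' Writes the per-cell table (`<prefix>_cells.csv`: algorithm, landscape,
#' sigma, F, mean_performance, reliability, n_replicates) and the
#' per-replicate long table (`<prefix>_replicates.csv`).
#'
#' @param sweep A `sweep_result`.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_sweep_csv <- function(sweep, prefix) {
  stop_if_not(inherits(sweep, "sweep_result"), "expected a sweep_result")
  cells <- data.frame(algorithm = sweep$algorithm,
                      landscape = sweep$landscape_name,
                      sigma = sweep$cells$sigma,
                      F = sweep$cells$parent_fraction,
                      mean_performance = sweep$cells$mean_performance,
                      reliability = sweep$cells$reliability,
                      n_replicates = sweep$cells$n_replicates)
  cells_path <- paste0(prefix, "_cells.csv")
  reps_path <- paste0(prefix, "_replicates.csv")
  write.csv2 <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    lines <- c(paste(names(df), collapse = ","),
               do.call(paste, c(lapply(df, format_full), list(sep = ","))))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  write.csv2(cells, cells_path)
  write.csv2(sweep$replicate_table, reps_path)
  invisible(c(cells_path, reps_path))
}

#' Heatmap of sweep performance or reliability
#'
#' Renders the (sigma, F) lattice as a tile heatmap (requires ggplot2).
#'
#' @param sweep A `sweep_result`.
#' @param metric `"mean_performance"` or `"reliability"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, metric = c("mean_performance", "reliability")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep requires the ggplot2 package", call. = FALSE)
  }
  df <- sweep$cells
  df$sigma_f <- factor(df$sigma)
  df$f_f <- factor(df$parent_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[["sigma_f"]],
                                   y = .data[["f_f"]],
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(sigma), y = "F",
                  title = sprintf("%s on %s", sweep$algorithm,
                                  sweep$landscape_name)) +
    ggplot2::scale_fill_viridis_c(name = metric)
}
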