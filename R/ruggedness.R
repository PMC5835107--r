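#' Default distance bin edges for landscape autocorrelation
#'
#' Euclidean-distance bins of 100 expression units from 0 to 700. Pair
#' distances beyond 700 are constrained by the size of a `[0, 1000]^2`
#' search space (far fewer pairs are sampled there) and are discarded.
#'
#' @return Numeric vector `c(0, 100, ..., 700)`.
#' @export
default_bin_edges <- function() seq(0, 700, by = 100)

#' Per-bin mean squared fitness differences over all point pairs
#'
#' For every unordered pair of points, records the Euclidean distance in
#' coordinate space and the squared difference of the two fitness values,
#' then bins pairs by distance into `[edge_i, edge_{i+1})` intervals (the
#' final bin is closed on both ends; pairs beyond the last edge are
#' discarded). The per-bin mean of the squared fitness differences is the
#' distance-resolved variance estimate underlying landscape
#' autocorrelation analysis.
#'
#' Pair enumeration is a streaming accumulation of per-bin (sum, count)
#' in C++; at the default 200x200 grid this is ~8e8 pairs. For quick
#' approximate runs, `max_pairs` caps the work by uniform seeded
#' subsampling of pairs; the result is then an approximation and is
#' flagged as such in the return value.
#'
#' @param points Numeric matrix of coordinates, one row per point.
#' @param fitnesses Numeric vector, one fitness per point.
#' @param bin_edges Strictly increasing numeric breakpoints
#'   (default [default_bin_edges()]).
#' @param max_pairs Optional cap on the number of pairs; `NULL` (default)
#'   enumerates all pairs exactly.
#' @param subsample_seed Seed for the pair subsample when `max_pairs` is
#'   set.
#' @return An object of class `binned_variance`: list with `bin_edges`,
#'   `mean_sq_diff` (NA marks empty bins), `pair_counts`, `sum_sq_diff`,
#'   and `approximate` (TRUE when pairs were subsampled).
#' @export
binned_pairwise_variance <- function(points, fitnesses,
                                     bin_edges = default_bin_edges(),
                                     max_pairs = NULL,
                                     subsample_seed = 1L) {
  points <- as.matrix(points)
  fitnesses <- as.numeric(fitnesses)
  n <- nrow(points)
  stop_if_not(n == length(fitnesses),
              "points (%d) and fitnesses (%d) differ in length",
              n, length(fitnesses))
  stop_if_not(n >= 2, "need at least 2 points, got %d", n)
  bin_edges <- as.numeric(bin_edges)
  stop_if_not(length(bin_edges) >= 2 && all(diff(bin_edges) > 0),
              "bin_edges must be strictly increasing with >= 2 values")

  approximate <- FALSE
  n_pairs_total <- n * (n - 1) / 2
  if (!is.null(max_pairs) && max_pairs < n_pairs_total) {
    # uniform pair subsample: approximate, seeded, documented as such
    approximate <- TRUE
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(subsample_seed)
    idx <- sample.int(n_pairs_total, max_pairs)
    # map linear pair index (1-based, row-major over i<j) to (i, j)
    i <- n - 1 - floor((sqrt(8 * (n_pairs_total - idx) + 1) - 1) / 2)
    offset <- (i - 1) * n - i * (i - 1) / 2
    j <- i + (idx - offset)
    acc <- .binned_pairs_subset(points, fitnesses, bin_edges,
                                as.integer(i), as.integer(j))
  } else {
    acc <- .binned_pairs_cpp(points, fitnesses, bin_edges)
  }
  msd <- ifelse(acc$count > 0, acc$sum / acc$count, NA_real_)
  structure(
    list(bin_edges = bin_edges, mean_sq_diff = msd,
         pair_counts = acc$count, sum_sq_diff = acc$sum,
         approximate = approximate),
    class = "binned_variance"
  )
}

# R-side pair accumulation over an explicit (i, j) subset
.binned_pairs_subset <- function(points, fitnesses, edges, i, j) {
  nb <- length(edges) - 1
  d <- sqrt(rowSums((points[i, , drop = FALSE] - points[j, , drop = FALSE])^2))
  sq <- (fitnesses[i] - fitnesses[j])^2
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= nb
  list(sum = vapply(seq_len(nb), function(b) sum(sq[keep & bin == b]),
                    numeric(1)),
       count = vapply(seq_len(nb), function(b) sum(keep & bin == b),
                      numeric(1)))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Landscape autocorrelation curve from binned pairwise variances
#'
#' Normalizes the per-bin mean squared fitness differences by the
#' landscape variance \eqn{\sigma^2_{landscape}}, approximated by the
#' mean squared difference of the farthest non-empty bin (600-700 units
#' under the default edges), and returns
#' \deqn{LA(x) = 1 - \frac{\sigma^2_{d=bin(x)}}{\sigma^2_{landscape}}.}
#' The farthest bin's LA is identically 0 by construction.
#'
#' @param binned A `binned_variance` object from
#'   [binned_pairwise_variance()].
#' @return An object of class `autocorrelation_curve`: list with
#'   `bin_midpoints`, `la_values` (NA for empty bins), `sigma2_landscape`,
#'   `normalizing_bin` (index of the farthest non-empty bin), plus the
#'   input's `mean_sq_diff` and `pair_counts`.
#' @export
autocorrelation <- function(binned) {
  stop_if_not(inherits(binned, "binned_variance"),
              "expected a binned_variance object")
  nonempty <- which(binned$pair_counts > 0)
  stop_if_not(length(nonempty) > 0, "all distance bins are empty")
  far <- max(nonempty)
  s2 <- binned$mean_sq_diff[far]
  if (!is.finite(s2) || s2 <= 0) {
    stop(paste("degenerate landscape: the farthest distance bin has zero",
               "fitness variance, so autocorrelation is undefined",
               "(constant landscape?)"), call. = FALSE)
  }
  edges <- binned$bin_edges
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  structure(
    list(bin_edges = edges,
         bin_midpoints = mid,
         la_values = 1 - binned$mean_sq_diff / s2,
         sigma2_landscape = s2,
         normalizing_bin = far,
         mean_sq_diff = binned$mean_sq_diff,
         pair_counts = binned$pair_counts),
    class = "autocorrelation_curve"
  )
}

#' NK-model reference autocorrelation curve
#'
#' Expected autocorrelation at distance `x` for an NK system of `n_ref`
#' components with interaction order `k`:
#' \deqn{f(x) = \left(1 - \frac{x}{N}\right)\left(1 - \frac{k}{N}\right)^x}
#' `k = 0` gives exactly linear decay (independent components, smooth
#' landscape); larger `k` gives faster decay (rugged landscape).
#'
#' @param x Distance value(s), `0 <= x <= n_ref`.
#' @param k Ruggedness coefficient, `0 <= k < n_ref`.
#' @param n_ref Horizon constant N (default 700).
#' @return Expected autocorrelation value(s).
#' @export
#' @examples
#' nk_reference(0, k = 2)    # 1
#' nk_reference(700, k = 2)  # 0
nk_reference <- function(x, k, n_ref = 700) {
  stop_if_not(all(x >= 0 & x <= n_ref),
              "distance x must lie in [0, n_ref]")
  stop_if_not(length(k) == 1 && k >= 0 && k < n_ref,
              "k must be a single value in [0, n_ref)")
  stop_if_not(n_ref > 0, "n_ref must be > 0")
  (1 - x / n_ref) * (1 - k / n_ref)^x
}

#' Fit the NK ruggedness coefficient k to an autocorrelation curve
#'
#' Single-parameter bounded least squares: k minimizes the sum over bins
#' of `(LA - nk_reference(midpoint, k, n_ref))^2`. The normalizing
#' (farthest) bin has LA = 0 by construction and carries no information,
#' so it is excluded from the residual by default
#' (`include_normalizing_bin = FALSE`). Multi-start from
#' k0 in {0.1, 1, 8} guards against local minima; ties go to the smallest
#' k. Convergence tolerance on k is 1e-9.
#'
#' @param curve An `autocorrelation_curve` object.
#' @param n_ref Horizon constant N (default 700).
#' @param include_normalizing_bin Include the farthest bin's zero in the
#'   residual? Default `FALSE`.
#' @return An object of class `ruggedness_fit`: list with `k`, `n_ref`,
#'   `residual_sum_sq`, `converged`, `n_bins_used`.
#' @export
fit_k <- function(curve, n_ref = 700, include_normalizing_bin = FALSE) {
  stop_if_not(inherits(curve, "autocorrelation_curve"),
              "expected an autocorrelation_curve object")
  use <- is.finite(curve$la_values)
  if (!include_normalizing_bin) use[curve$normalizing_bin] <- FALSE
  x <- curve$bin_midpoints[use]
  y <- curve$la_values[use]
  stop_if_not(length(x) >= 3,
              "need at least 3 usable bins to fit k, have %d", length(x))
  # clamped objective: optim's finite-difference steps may probe just
  # outside the [0, n_ref) box
  obj <- function(k) {
    k <- min(max(k, 0), n_ref * (1 - 1e-12))
    sum((y - (1 - x / n_ref) * (1 - k / n_ref)^x)^2)
  }
  eps <- 1e-12
  fits <- lapply(c(0.1, 1, 8), function(k0) {
    coarse <- stats::optim(par = min(max(k0, eps), n_ref / 2), fn = obj,
                           method = "L-BFGS-B", lower = 0,
                           upper = n_ref - eps,
                           control = list(factr = 1e3, pgtol = 0))
    # golden-section polish around the coarse solution to the 1e-9
    # tolerance on k (also our convergence criterion)
    lo <- max(0, coarse$par - 1)
    hi <- min(n_ref - eps, coarse$par + 1)
    fine <- stats::optimize(obj, interval = c(lo, hi), tol = 1e-10)
    k_hat <- if (fine$objective <= coarse$value) fine$minimum else coarse$par
    # snap to the lower bound when it is at least as good
    if (obj(0) <= obj(k_hat) + 1e-15) k_hat <- 0
    list(par = k_hat, value = obj(k_hat),
         converged = abs(fine$minimum - coarse$par) <= 1 + 1e-9)
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  ks <- vapply(fits, `[[`, numeric(1), "par")
  # best residual wins; ties (within fit tolerance) to the smallest k
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-12)
  pick <- cand[which.min(ks[cand])]
  structure(
    list(k = ks[pick], n_ref = n_ref, residual_sum_sq = vals[pick],
         converged = isTRUE(fits[[pick]]$converged),
         n_bins_used = length(x)),
    class = "ruggedness_fit"
  )
}

#' @export
print.ruggedness_fit <- function(x, ...) {
  cat(sprintf("<ruggedness_fit: k = %.4f (N = %g, RSS = %.3g, %s)>\n",
              x$k, x$n_ref, x$residual_sum_sq,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Quantify the ruggedness of a landscape
#'
#' The full default protocol: sample the landscape on a square grid
#' (200 points per axis, 40,000 points in 2-D), accumulate squared
#' fitness differences over all point pairs into 100-unit distance bins
#' up to 700, normalize by the 600-700 bin to form the autocorrelation
#' curve, and fit the NK reference curve with N = 700 by least squares.
#' Deterministic for exact (non-subsampled) pair enumeration.
#'
#' @param landscape A [landscape()] object.
#' @param points_per_axis Grid resolution (default 200).
#' @param bin_edges Distance bin breakpoints (default
#'   [default_bin_edges()]).
#' @param n_ref Horizon constant N (default 700).
#' @param max_pairs Optional pair-subsampling cap (approximate mode); see
#'   [binned_pairwise_variance()].
#' @param subsample_seed Seed used when `max_pairs` is set.
#' @return A `ruggedness_fit` object with the intermediate
#'   `autocorrelation_curve` attached as attribute `curve`.
#' @export
#' @examples
#' broad <- landscape(centers = matrix(c(500, 500), 1), amplitudes = 1,
#'                    spreads = matrix(c(5000, 5000), 1))
#' quantify_ruggedness(broad, points_per_axis = 40)$k  # smooth: k < 1
quantify_ruggedness <- function(landscape, points_per_axis = 200,
                                bin_edges = default_bin_edges(),
                                n_ref = 700, max_pairs = NULL,
                                subsample_seed = 1L) {
  grid <- grid_sample(landscape, points_per_axis)
  binned <- binned_pairwise_variance(grid$points, grid$fitnesses, bin_edges,
                                     max_pairs = max_pairs,
                                     subsample_seed = subsample_seed)
  curve <- autocorrelation(binned)
  fit <- fit_k(curve, n_ref = n_ref)
  attr(fit, "curve") <- curve
  fit
}

#' Write an autocorrelation curve as a tab-separated table
#'
#' Columns: `bin_lo`, `bin_hi`, `midpoint`, `pair_count`, `mean_sq_diff`,
#' `la_value`.
#'
#' @param curve An `autocorrelation_curve` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curve_tsv <- function(curve, path) {
  edges <- curve$bin_edges
  df <- data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    midpoint = curve$bin_midpoints,
    pair_count = curve$pair_counts,
    mean_sq_diff = curve$mean_sq_diff,
    la_value = curve$la_values
  )
  write_tsv_table(df, path)
}

#' Write a ruggedness fit report as structured text (JSON)
#'
#' @param fit A `ruggedness_fit` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stop_if_not(inherits(fit, "ruggedness_fit"), "expected a ruggedness_fit")
  jsonlite::write_json(
    list(k = fit$k, n_ref = fit$n_ref,
         residual_sum_sq = fit$residual_sum_sq,
         converged = fit$converged, n_bins_used = fit$n_bins_used),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
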