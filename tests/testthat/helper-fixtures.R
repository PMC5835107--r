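# shared fixtures and independent oracles for the test suite

single_peak <- function(amplitude = 1, center = c(500, 500),
                        spread = c(100, 100)) {
  landscape(centers = matrix(center, nrow = 1), amplitudes = amplitude,
            spreads = matrix(spread, nrow = 1))
}

# brute-force nested-loop pair binning, same (i < j ascending) accumulation
# order as the streaming implementation so sums are comparable bitwise
oracle_binned_pairs <- function(pts, fit, edges) {
  n <- nrow(pts)
  nb <- length(edges) - 1
  s <- numeric(nb)
  cnt <- numeric(nb)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
      if (d < edges[1] || d > edges[nb + 1]) next
      b <- if (d == edges[nb + 1]) nb else findInterval(d, edges)
      if (b >= 1 && b <= nb) {
        s[b] <- s[b] + (fit[i] - fit[j])^2
        cnt[b] <- cnt[b] + 1
      }
    }
  }
  list(sum = s, count = cnt)
}

# star discrepancy of 2-D points in [0,1)^2 by direct enumeration of
# anchored boxes with corners at the point coordinates (and 1)
oracle_star_discrepancy <- function(pts) {
  n <- nrow(pts)
  xc <- sort(unique(c(pts[, 1], 1)))
  yc <- sort(unique(c(pts[, 2], 1)))
  inx <- outer(pts[, 1], xc, "<")
  iny <- outer(pts[, 2], yc, "<")
  counts <- crossprod(inx, iny) # boxes [0, xc) x [0, yc)
  vol <- outer(xc, yc)
  max(abs(counts / n - vol))
}

# hand-built autocorrelation curve at the default midpoints
make_curve <- function(la, edges = default_bin_edges()) {
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  structure(list(bin_edges = edges, bin_midpoints = mid, la_values = la,
                 sigma2_landscape = 1, normalizing_bin = length(la),
                 mean_sq_diff = 1 - la,
                 pair_counts = rep(10, length(la))),
            class = "autocorrelation_curve")
}
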