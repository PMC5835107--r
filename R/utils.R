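#' Derive a reproducible child seed from a base seed and indices
#'
#' Mixes a base seed with any number of nonnegative integer indices into a
#' new seed in `[0, 2^31)`. Used to give every replicate of every sweep
#' cell its own deterministic stream so results do not depend on execution
#' order.
#'
#' @param base_seed Integer base seed.
#' @param ... Nonnegative integer indices (e.g. cell row, cell column,
#'   replicate number).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1, 2, 3)
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, keeps all arithmetic exact in doubles
  h <- (abs(as.numeric(base_seed)) %% m)
  for (v in as.numeric(idx)) {
    h <- (h * 48271) %% m
    h <- (h + (v %% m) + 1) %% m
  }
  h <- (h * 69621) %% m
  as.integer(h)
}

# internal: write a data frame as a UTF-8, LF, tab-separated table with header
write_tsv_table <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    paste(names(df), collapse = "\t"),
    do.call(paste, c(lapply(df, format_full), list(sep = "\t")))
  )
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# full floating precision formatting (round-trippable doubles)
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}
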