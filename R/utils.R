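#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log-scale values.
#' @return `log(sum(exp(x)))` computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Deterministic golden-spiral point set on the unit sphere
#'
#' Quasi-uniform spherical lattice used as the test-point set for
#' Shrake-Rupley SASA.  Purely deterministic: no RNG is consumed, so surface
#' areas are bit-stable across runs.
#'
#' @param n number of points (>= 1).
#' @return an `n x 3` matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  theta <- pi * (3 - sqrt(5)) * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

# Write a TSV with a commented header block (key: value lines), so every
# output records the parameters that produced it.
write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(paste0("# ", names(header), ": ",
                      vapply(header, paste, "", collapse = ",")), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stream index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483647)
}
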