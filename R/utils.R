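# Internal helpers shared across modules.

# Wilson score interval for a binomial proportion. Returns a list with
# low/high. `conf` is the two-sided coverage.
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = max(0, centre - half), high = min(1, centre + half))
}

# Normal-approximation interval, available behind ci_method = "normal".
normal_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  half <- z * sqrt(p * (1 - p) / n)
  list(low = max(0, p - half), high = min(1, p + half))
}

# Stable identifier for an exon interval within a gene.
exon_key <- function(gene_id, start, end) {
  paste(gene_id, start, end, sep = ":")
}

# Stable identifier for an intron interval (0-based half-open).
intron_key <- function(chrom, start, end) {
  paste(chrom, start, end, sep = ":")
}

assert_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0("`", name, "` must lie in [0, 1]"))
  }
  invisible(x)
}
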