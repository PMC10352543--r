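# shared internal helpers

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# clamp fractions away from 0/1 so logit offsets stay finite
clamp01 <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)

# round a percentage to the nearest integer, halves away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

locus_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
}

# order loci by (chrom, pos); chromosomes in first-appearance order is not
# stable across inputs, so sort chrom lexicographically
order_loci <- function(chrom, pos) order(chrom, pos)

# running mean with window +/- h, shrunk at the edges, via cumsum
running_mean <- function(x, h) {
  n <- length(x)
  if (n == 0L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
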