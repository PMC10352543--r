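# Coverage filtering, percent methylation, fiber ratio, spike-in QC.

#' Filter loci by minimum coverage
#'
#' Retains loci covered at least `min_coverage`-fold; by default the
#' requirement applies in every sample (the literal "covered at least
#' k-fold in all samples" policy), which `min_fraction < 1` relaxes to
#' a fraction of samples.
#'
#' @param dataset a `MethylationDataset` (assembled over the union of
#'   loci, with N = 0 marking missing).
#' @param min_coverage minimum reads per locus per sample (>= 1).
#' @param min_fraction fraction of samples that must meet the
#'   threshold (default 1 = all samples).
#' @return The filtered `MethylationDataset` (locus order preserved).
#' @export
filter_coverage <- function(dataset, min_coverage = 10L,
                            min_fraction = 1) {
  if (min_coverage < 1L) stop("min_coverage must be >= 1", call. = FALSE)
  ok <- rowMeans(dataset$N >= min_coverage) >= min_fraction
  if (!any(ok)) warning("no loci survive the coverage filter")
  dataset[ok, ]
}

#' Muscle fiber ratio from myosin isoform abundances
#'
#' `my7 / (my1 + my2 + my4)` — the type-I over type-II myosin ratio
#' used to adjust muscle models for fiber-type composition.
#'
#' @param my7,my1,my2,my4 non-negative isoform abundances (vectorised).
#' @return Numeric ratio; `NA` (with a warning) where the denominator
#'   is zero.
#' @export
fiber_ratio <- function(my7, my1, my2, my4) {
  if (any(c(my7, my1, my2, my4) < 0))
    stop("abundances must be >= 0", call. = FALSE)
  den <- my1 + my2 + my4
  out <- ifelse(den > 0, my7 / den, NA_real_)
  if (any(is.na(out)))
    warning("zero myosin denominator; subject(s) flagged NA")
  out
}

#' Bisulfite conversion efficiency from an unmethylated spike-in
#'
#' For each sample, `1 - sum(M) / sum(N)` over all loci on the spike
#' contig: the fraction of (truly unmethylated) spike cytosines read as
#' converted.
#'
#' @param dataset a `MethylationDataset` containing the spike contig.
#' @param spike_contig contig name (default `"lambda"`).
#' @return Named numeric vector in `[0, 1]` per sample; `NA` for
#'   samples with no spike coverage.
#' @export
conversion_efficiency <- function(dataset, spike_contig = "lambda") {
  sel <- dataset$loci$chrom == spike_contig
  if (!any(sel))
    stop(sprintf("spike contig '%s' not present", spike_contig),
         call. = FALSE)
  m <- colSums(dataset$M[sel, , drop = FALSE])
  n <- colSums(dataset$N[sel, , drop = FALSE])
  ifelse(n > 0, 1 - m / n, NA_real_)
}

#' Percent methylation matrix
#'
#' @param dataset a `MethylationDataset`.
#' @return loci x samples matrix of `100 * M / N`; `NA` where `N = 0`.
#' @export
percent_methylation <- function(dataset) {
  out <- 100 * dataset$M / dataset$N
  out[dataset$N == 0L] <- NA_real_
  out
}

#' Per-sample QC summary
#'
#' @param dataset a `MethylationDataset`.
#' @param policies integer vector of coverage thresholds to tabulate.
#' @param spike_contig optional spike contig for conversion rates.
#' @return data.frame per sample: mean coverage, loci meeting each
#'   policy in that sample, and conversion rate if available.
#' @export
qc_report <- function(dataset, policies = c(2L, 10L),
                      spike_contig = NULL) {
  out <- data.frame(sample_id = sample_ids(dataset),
                    mean_coverage = colMeans(dataset$N))
  for (k in policies)
    out[[paste0("loci_ge_", k, "x")]] <- colSums(dataset$N >= k)
  if (!is.null(spike_contig) &&
      any(dataset$loci$chrom == spike_contig))
    out$conversion_rate <- conversion_efficiency(dataset, spike_contig)
  rownames(out) <- NULL
  out
}
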