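# Smoothing-based two-group (young vs old) DMR detection: cluster,
# smooth, t-statistic with young-group baseline variance, local mean
# correction, threshold-run grouping into regions.

#' Smoothing parameters
#'
#' Defaults follow the package's genome-scale smoothing choices:
#' windows of at least 70 loci and 1000 bp, loci farther apart than
#' `cluster_maxgap` (or on different chromosomes) smoothed separately.
#' The kernel is tricube and the local polynomial degree is 2; weights
#' are multiplied by read coverage when `coverage_weighting` is on.
#'
#' @param min_loci minimum loci per smoothing window (default 70).
#' @param min_width minimum window span in bp (default 1000).
#' @param cluster_maxgap maximum within-cluster gap in bp
#'   (default 1e8).
#' @param coverage_weighting weight loci by read depth (default TRUE).
#' @return A `smooth_params` list (kernel and degree recorded for
#'   provenance; only tricube/degree-2 is implemented).
#' @export
smooth_params <- function(min_loci = 70L, min_width = 1000,
                          cluster_maxgap = 1e8,
                          coverage_weighting = TRUE) {
  if (min_loci < 2L) stop("min_loci must be >= 2", call. = FALSE)
  if (min_width < 1) stop("min_width must be >= 1", call. = FALSE)
  structure(list(min_loci = as.integer(min_loci),
                 min_width = min_width,
                 cluster_maxgap = cluster_maxgap,
                 kernel = "tricube", degree = 2L,
                 coverage_weighting = coverage_weighting),
            class = "smooth_params")
}

#' t-statistic and region-grouping parameters
#'
#' @param cutoff extreme-value cutoff on the corrected t-statistic
#'   (default 4.6; regions are runs of loci with `|t| >=` cutoff).
#' @param dmr_maxgap loci farther apart than this (bp) are broken into
#'   separate DMRs (default 300).
#' @param sd_floor_quantile denominator floor: the per-locus baseline
#'   sd is floored at this quantile of all per-locus sds
#'   (default 0.75), so zero-variance loci cannot yield infinite t.
#' @param local_correct subtract a running local mean from the t track
#'   (default TRUE), removing regional baseline drift.
#' @param correct_halfwidth half-width of the running mean, in loci
#'   (default 50).
#' @param min_cpgs_per_dmr minimum member CpGs per reported region
#'   (default 1).
#' @param min_mean_diff optional filter on the absolute smoothed mean
#'   difference of a region (fraction units; default 0 = off). Useful
#'   for dropping low-amplitude side lobes that the local mean
#'   correction can introduce next to strong regions.
#' @param scale_sd scale the young-group sd by
#'   `sqrt(1/n_young + 1/n_old)` so t is unit-consistent with a
#'   two-sample statistic (default TRUE).
#' @return A `tstat_params` list.
#' @export
tstat_params <- function(cutoff = 4.6, dmr_maxgap = 300,
                         sd_floor_quantile = 0.75,
                         local_correct = TRUE, correct_halfwidth = 50L,
                         min_cpgs_per_dmr = 1L, min_mean_diff = 0,
                         scale_sd = TRUE) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (dmr_maxgap < 1) stop("dmr_maxgap must be >= 1", call. = FALSE)
  structure(list(cutoff = cutoff, dmr_maxgap = dmr_maxgap,
                 sd_floor_quantile = sd_floor_quantile,
                 local_correct = local_correct,
                 correct_halfwidth = as.integer(correct_halfwidth),
                 min_cpgs_per_dmr = as.integer(min_cpgs_per_dmr),
                 min_mean_diff = min_mean_diff, scale_sd = scale_sd),
            class = "tstat_params")
}

#' Cluster sorted loci by gap
#'
#' Consecutive same-chromosome loci at most `cluster_maxgap` bp apart
#' share a cluster; chromosome boundaries always split.
#'
#' @param loci data.frame `chrom`, `pos`, sorted by `(chrom, pos)`.
#' @param cluster_maxgap maximum within-cluster gap in bp.
#' @return Integer cluster labels (1-based, increasing along input).
#' @export
cluster_loci <- function(loci, cluster_maxgap = 1e8) {
  n <- nrow(loci)
  if (!n) return(integer())
  new_chrom <- c(TRUE, loci$chrom[-1L] != loci$chrom[-n])
  gap <- c(0, diff(loci$pos))
  cumsum(new_chrom | (gap > cluster_maxgap))
}

#' Smooth one sample's methylation profile
#'
#' Per locus, a weighted least-squares quadratic of raw fraction
#' `M/N` on position over the smallest symmetric locus window with at
#' least `min_loci` loci and `min_width` bp, truncated at cluster
#' boundaries; weights are tricube in scaled distance times coverage.
#' Loci with `N = 0` receive the fitted value (imputation). Clusters
#' with fewer than 3 covered loci fall back to the coverage-weighted
#' cluster mean (reported in attribute `fallback_clusters`).
#'
#' @param loci data.frame `chrom`, `pos` (sorted).
#' @param M_col,N_col methylated/total counts for one sample.
#' @param params a [smooth_params()].
#' @param clip clip results into `[0, 1]` (default TRUE).
#' @return Numeric vector of smoothed methylated fractions.
#' @export
smooth_sample <- function(loci, M_col, N_col,
                          params = smooth_params(), clip = TRUE) {
  sm <- smooth_matrix(loci, cbind(M_col), cbind(N_col), params, clip)
  out <- sm[, 1L]
  attr(out, "fallback_clusters") <- attr(sm, "fallback_clusters")
  out
}

smooth_matrix <- function(loci, M, N, params, clip = TRUE) {
  frac <- M / N
  frac[N == 0] <- NA_real_
  clusters <- cluster_loci(loci, params$cluster_maxgap)
  out <- matrix(NA_real_, nrow(loci), ncol(M))
  fallback <- integer()
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    covered <- colSums(N[idx, , drop = FALSE] > 0)
    out[idx, ] <- .smooth_cluster_cpp(
      as.numeric(loci$pos[idx]), frac[idx, , drop = FALSE],
      N[idx, , drop = FALSE] + 0, params$min_loci, params$min_width,
      params$coverage_weighting)
    # too few covered loci to support a local fit: coverage-weighted
    # cluster mean instead, and flag the cluster
    few <- covered < 3L & covered > 0L
    if (any(few)) {
      fallback <- c(fallback, cl)
      for (s in which(few)) {
        obs <- N[idx, s] > 0
        out[idx, s] <- sum(frac[idx, s][obs] * N[idx, s][obs]) /
          sum(N[idx, s][obs])
      }
    }
  }
  if (clip) out <- pmin(pmax(out, 0), 1)
  colnames(out) <- colnames(M)
  attr(out, "fallback_clusters") <- fallback
  out
}

#' Smooth every sample of a dataset
#'
#' @param dataset a `MethylationDataset`.
#' @param params a [smooth_params()].
#' @param clip clip into `[0, 1]` (default TRUE).
#' @return loci x samples matrix of smoothed methylated fractions.
#' @export
smooth_dataset <- function(dataset, params = smooth_params(),
                           clip = TRUE) {
  smooth_matrix(dataset$loci, dataset$M, dataset$N, params, clip)
}

#' Split subjects into young and old groups by a threshold age
#'
#' @param samples covariate table with `subject_id` and `age`.
#' @param old_threshold_age threshold in years.
#' @param inclusive old group is `age >= threshold` if `TRUE` (the
#'   muscle convention); `age > threshold` if `FALSE` (the monocyte
#'   convention).
#' @return list with character vectors `young` and `old`.
#' @export
split_groups <- function(samples, old_threshold_age,
                         inclusive = TRUE) {
  old <- if (inclusive) samples$age >= old_threshold_age
         else samples$age > old_threshold_age
  if (!any(old) || all(old))
    stop("young/old split leaves an empty group", call. = FALSE)
  list(young = samples$subject_id[!old],
       old = samples$subject_id[old])
}

#' Young-baseline t-statistic per locus
#'
#' `t_j = (mean_old_j - mean_young_j) / max(sd_j, floor)` where `sd_j`
#' is the standard deviation of smoothed values within the young group
#' (variability increases with age, so the young group supplies the
#' baseline variance), scaled by `sqrt(1/n_young + 1/n_old)` when
#' `scale_sd` is on, and `floor` is the `sd_floor_quantile` quantile of
#' all per-locus sds. Positive t = hypermethylated in old.
#'
#' @param smoothed loci x samples matrix of smoothed fractions.
#' @param groups list with `young` and `old` sample ids (see
#'   [split_groups()]).
#' @param tparams a [tstat_params()].
#' @return Numeric t per locus, with the smoothed group mean
#'   difference (old - young) in attribute `mean_diff` and the floored
#'   denominator in `sd_used`.
#' @export
tstat <- function(smoothed, groups, tparams = tstat_params()) {
  Yy <- smoothed[, groups$young, drop = FALSE]
  Yo <- smoothed[, groups$old, drop = FALSE]
  if (ncol(Yy) < 2L || ncol(Yo) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  my <- rowMeans(Yy, na.rm = TRUE)
  mo <- rowMeans(Yo, na.rm = TRUE)
  sdy <- apply(Yy, 1L, sd, na.rm = TRUE)
  if (tparams$scale_sd)
    sdy <- sdy * sqrt(1 / ncol(Yy) + 1 / ncol(Yo))
  floor_val <- quantile(sdy, tparams$sd_floor_quantile, na.rm = TRUE,
                        names = FALSE)
  # degenerate all-constant baseline: keep t finite and deterministic
  den <- pmax(sdy, floor_val, 1e-8)
  t <- (mo - my) / den
  attr(t, "mean_diff") <- mo - my
  attr(t, "sd_used") <- den
  t
}

#' Local mean correction of a t-statistic track
#'
#' Subtracts the running mean of t over `+/- correct_halfwidth` loci
#' within each cluster (shrunk at cluster edges), removing large-scale
#' regional drift so the `+/- cutoff` rule picks out local extremes.
#'
#' @param t_values numeric t per locus.
#' @param loci data.frame `chrom`, `pos` (sorted, aligned with `t`).
#' @param tparams a [tstat_params()]; identity if
#'   `tparams$local_correct` is FALSE.
#' @param clusters optional precomputed [cluster_loci()] labels.
#' @param cluster_maxgap used if `clusters` is missing.
#' @return Corrected t, same length.
#' @export
local_correct <- function(t_values, loci, tparams = tstat_params(),
                          clusters = NULL, cluster_maxgap = 1e8) {
  if (!tparams$local_correct) return(t_values)
  if (is.null(clusters)) clusters <- cluster_loci(loci, cluster_maxgap)
  out <- t_values
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    out[idx] <- t_values[idx] -
      running_mean(t_values[idx], tparams$correct_halfwidth)
  }
  out
}

#' Group threshold-exceeding loci into DMRs
#'
#' Maximal runs of consecutive loci with `|t| >= cutoff`, constant
#' sign, consecutive gaps `<= dmr_maxgap` bp, within one cluster.
#'
#' @param corrected_t corrected t per locus.
#' @param mean_diff smoothed old-minus-young mean difference per locus
#'   (fraction units).
#' @param loci data.frame `chrom`, `pos` (sorted, aligned).
#' @param tparams a [tstat_params()].
#' @param clusters optional precomputed cluster labels.
#' @return data.frame with one row per region: `chrom`, `start`,
#'   `end` (1-based inclusive, first/last member CpG), `n_cpgs`,
#'   `direction` (`hyper`/`hypo`, old relative to young), `mean_diff`
#'   (average over member CpGs), `area_stat` (sum of corrected t).
#' @export
call_dmrs <- function(corrected_t, mean_diff, loci,
                      tparams = tstat_params(), clusters = NULL) {
  if (is.null(clusters)) clusters <- cluster_loci(loci)
  ok <- !is.na(corrected_t) & abs(corrected_t) >= tparams$cutoff
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character(), mean_diff = numeric(),
                      area_stat = numeric())
  idx <- which(ok)
  if (!length(idx)) return(empty)
  brk <- c(TRUE, diff(idx) != 1L |
             clusters[idx[-1L]] != clusters[idx[-length(idx)]] |
             sign(corrected_t[idx[-1L]]) !=
               sign(corrected_t[idx[-length(idx)]]) |
             (loci$pos[idx[-1L]] - loci$pos[idx[-length(idx)]]) >
               tparams$dmr_maxgap)
  run <- cumsum(brk)
  rows <- lapply(split(idx, run), function(m) {
    data.frame(chrom = loci$chrom[m[1L]], start = loci$pos[m[1L]],
               end = loci$pos[m[length(m)]], n_cpgs = length(m),
               direction = if (corrected_t[m[1L]] > 0) "hyper"
                           else "hypo",
               mean_diff = mean(mean_diff[m]),
               area_stat = sum(corrected_t[m]))
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_cpgs >= tparams$min_cpgs_per_dmr &
               abs(out$mean_diff) >= (tparams$min_mean_diff %||% 0), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full young-vs-old DMR analysis
#'
#' Chains [cluster_loci()], [smooth_dataset()], [split_groups()],
#' [tstat()], [local_correct()] and [call_dmrs()] on a
#' coverage-filtered dataset.
#'
#' @param dataset a `MethylationDataset` (apply [filter_coverage()]
#'   first; the region analysis expects at least 2x in all samples).
#' @param samples covariate table matching the dataset's samples.
#' @param old_threshold_age young/old split age in years.
#' @param sparams a [smooth_params()].
#' @param tparams a [tstat_params()].
#' @param inclusive see [split_groups()].
#' @return A `dmr_set`: list with `regions` (see [call_dmrs()]),
#'   `t_track` (data.frame `chrom`, `pos`, `t_raw`, `t_corrected`,
#'   `mean_diff`), `groups`, and the parameter objects.
#' @export
dmr_analysis <- function(dataset, samples, old_threshold_age,
                         sparams = smooth_params(),
                         tparams = tstat_params(),
                         inclusive = TRUE) {
  clusters <- cluster_loci(dataset$loci, sparams$cluster_maxgap)
  smoothed <- smooth_matrix(dataset$loci, dataset$M, dataset$N,
                            sparams)
  groups <- split_groups(samples, old_threshold_age, inclusive)
  t_raw <- tstat(smoothed, groups, tparams)
  t_corr <- local_correct(t_raw, dataset$loci, tparams, clusters)
  md <- attr(t_raw, "mean_diff")
  regions <- call_dmrs(t_corr, md, dataset$loci, tparams, clusters)
  structure(list(
    regions = regions,
    t_track = data.frame(chrom = dataset$loci$chrom,
                         pos = dataset$loci$pos,
                         t_raw = as.numeric(t_raw),
                         t_corrected = as.numeric(t_corr),
                         mean_diff = md),
    groups = groups, sparams = sparams, tparams = tparams),
    class = "dmr_set")
}

#' @export
print.dmr_set <- function(x, ...) {
  r <- x$regions
  cat(sprintf(
    "DMR analysis: %d regions (young n=%d vs old n=%d, |t| >= %g)\n",
    nrow(r), length(x$groups$young), length(x$groups$old),
    x$tparams$cutoff))
  if (nrow(r)) {
    cat(sprintf("  hyper: %d, hypo: %d; mean length %.1f CpGs\n",
                sum(r$direction == "hyper"),
                sum(r$direction == "hypo"), mean(r$n_cpgs)))
  }
  invisible(x)
}

#' @method summary dmr_set
#' @export
summary.dmr_set <- function(object, ...) {
  print(object)
  r <- object$regions
  if (nrow(r)) {
    cat(sprintf("  span: median %d bp; |mean_diff|: median %.3f\n",
                as.integer(stats::median(r$end - r$start + 1)),
                stats::median(abs(r$mean_diff))))
  }
  invisible(object)
}

#' Write called DMRs as a BED-compatible TSV
#'
#' Coordinates on disk are 0-based half-open; extra columns `n_cpgs`,
#' `direction`, `mean_diff`, `area_stat` follow the BED fields.
#'
#' @param dmrs a `dmr_set` or a regions data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  r <- if (inherits(dmrs, "dmr_set")) dmrs$regions else dmrs
  out <- data.frame(chrom = r$chrom, start = r$start - 1L,
                    end = r$end, n_cpgs = r$n_cpgs,
                    direction = r$direction, mean_diff = r$mean_diff,
                    area_stat = r$area_stat)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a t-statistic track as bedGraph
#' @param dmrs a `dmr_set`.
#' @param path output path.
#' @param which `"t_corrected"` (default) or `"t_raw"`.
#' @return `path`, invisibly.
#' @export
write_t_track <- function(dmrs, path, which = "t_corrected") {
  tr <- dmrs$t_track
  out <- data.frame(chrom = tr$chrom, start = tr$pos - 1L,
                    end = tr$pos, value = tr[[which]])
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
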