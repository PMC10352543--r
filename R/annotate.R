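# Gene/TSS linkage, CpG-island context, three-method overlap, and
# GMT-based over-representation. Interval arithmetic goes through
# GenomicRanges; all coordinates here are 1-based inclusive.

features_gr <- function(features) {
  stopifnot_cols(features, "chrom", "features")
  if (!"start" %in% names(features)) {
    features$start <- features$pos
    features$end <- features$pos
  }
  GenomicRanges::GRanges(features$chrom,
                         IRanges::IRanges(features$start,
                                          features$end))
}

#' Link features (CpGs or regions) to genes
#'
#' A feature overlapping any transcript span is `intragenic` for that
#' gene (distance 0). A feature not overlapping a given gene whose
#' strand-aware TSS lies within `max_link_dist` bp of the feature (for
#' regions, of either boundary) is `tss_proximal`, with a signed
#' distance: negative upstream of the TSS by gene strand, 0 if the TSS
#' falls inside the feature. One row is emitted per qualifying
#' (feature, gene) pair; features with no qualifying gene get a single
#' `none` row.
#'
#' @param features data.frame with `chrom` and either `pos` (loci) or
#'   `start`/`end` (regions), 1-based inclusive.
#' @param genes gene table as from [read_bed()] `kind = "genes"`.
#' @param max_link_dist TSS linkage distance in bp (default 200,
#'   two-sided).
#' @return data.frame: `feature` (row index into `features`),
#'   `gene_id` (NA for `none`), `link_type`
#'   (`intragenic`/`tss_proximal`/`none`), `signed_distance`.
#' @export
link_genes <- function(features, genes, max_link_dist = 200) {
  fgr <- features_gr(features)
  n_feat <- length(fgr)
  if (!nrow(genes)) {
    return(data.frame(feature = seq_len(n_feat), gene_id = NA_character_,
                      link_type = "none", signed_distance = NA_real_))
  }
  ggr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$tx_start, genes$tx_end))
  hits <- GenomicRanges::findOverlaps(fgr, ggr)
  intr <- data.frame(
    feature = S4Vectors::queryHits(hits),
    gene = S4Vectors::subjectHits(hits))

  tss_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$tss, genes$tss))
  near <- GenomicRanges::findOverlaps(fgr, tss_gr,
                                      maxgap = max_link_dist)
  tssl <- data.frame(
    feature = S4Vectors::queryHits(near),
    gene = S4Vectors::subjectHits(near))
  # drop pairs already intragenic for the same gene
  key <- function(d) paste(d$feature, d$gene)
  tssl <- tssl[!(key(tssl) %in% key(intr)), , drop = FALSE]

  signed_dist <- function(fi, gi) {
    s <- features$start %||% features$pos
    e <- features$end %||% features$pos
    fs <- s[fi]; fe <- e[fi]
    tss <- genes$tss[gi]; strand <- genes$strand[gi]
    inside <- tss >= fs & tss <= fe
    # genomic offset of the nearer feature boundary from the TSS;
    # positive = 3'-ward in genome coordinates
    off <- ifelse(tss < fs, fs - tss, fe - tss)
    # downstream of the TSS is positive; on the minus strand the gene
    # runs toward lower coordinates, so the sign flips
    d <- ifelse(strand == "+", off, -off)
    ifelse(inside, 0, d)
  }
  out <- list()
  if (nrow(intr))
    out$intr <- data.frame(feature = intr$feature,
                           gene_id = genes$gene_id[intr$gene],
                           link_type = "intragenic",
                           signed_distance = 0)
  if (nrow(tssl))
    out$tss <- data.frame(feature = tssl$feature,
                          gene_id = genes$gene_id[tssl$gene],
                          link_type = "tss_proximal",
                          signed_distance = signed_dist(tssl$feature,
                                                        tssl$gene))
  linked <- unique(c(intr$feature, tssl$feature))
  none <- setdiff(seq_len(n_feat), linked)
  if (length(none))
    out$none <- data.frame(feature = none, gene_id = NA_character_,
                           link_type = "none",
                           signed_distance = NA_real_)
  out <- do.call(rbind, out)
  out <- out[order(out$feature, out$link_type, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify features by CpG-island context
#'
#' `island` = overlapping an island (distance 0); `shore` = within
#' 1..2000 bp of an island edge; `shelf` = 2001..4000 bp; `open_sea`
#' beyond (distance `Inf` on chromosomes without islands).
#'
#' @param features data.frame with `chrom` and `pos` or
#'   `start`/`end`.
#' @param islands merged island intervals (data.frame `chrom`,
#'   `start`, `end`, 1-based inclusive; see [read_bed()]).
#' @return data.frame per feature: `class`, `distance_to_island` (bp
#'   gap to the nearest island, 0 if overlapping).
#' @export
classify_island_context <- function(features, islands) {
  fgr <- features_gr(features)
  dist <- rep(Inf, length(fgr))
  if (nrow(islands)) {
    igr <- GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(islands$start, islands$end))
    near <- GenomicRanges::distanceToNearest(fgr, igr)
    # GRanges distance counts bases strictly between ranges (adjacent
    # = 0); the shore convention wants the offset from the island edge
    # (adjacent = 1), so add 1 for non-overlapping features
    d <- as.numeric(S4Vectors::mcols(near)$distance)
    ov <- GenomicRanges::countOverlaps(fgr, igr) > 0
    dist[S4Vectors::queryHits(near)] <- d + 1
    dist[ov] <- 0
  }
  cls <- ifelse(dist == 0, "island",
         ifelse(dist <= 2000, "shore",
         ifelse(dist <= 4000, "shelf", "open_sea")))
  data.frame(class = cls, distance_to_island = dist)
}

#' Intragenic fraction of a feature set
#'
#' Counts each feature once (intragenic wins over TSS-proximal) and
#' reports `n_intragenic / n_features`, plus the percent rounded to
#' the nearest integer (halves away from zero) as printed in study
#' summaries.
#'
#' @param links output of [link_genes()], or a count of intragenic
#'   features (then `n_features` must be given).
#' @param n_features total feature count when `links` is a count.
#' @return list with `n_intragenic`, `n_features`, `fraction`,
#'   `percent`; fraction is `NA` for zero features.
#' @export
intragenic_fraction <- function(links, n_features = NULL) {
  if (is.numeric(links)) {
    n_intr <- links
    if (is.null(n_features))
      stop("n_features required with count input", call. = FALSE)
  } else {
    n_intr <- length(unique(links$feature[
      links$link_type == "intragenic"]))
    n_features <- length(unique(links$feature))
  }
  frac <- if (n_features > 0) n_intr / n_features else NA_real_
  list(n_intragenic = n_intr, n_features = n_features,
       fraction = frac,
       percent = if (is.na(frac)) NA_real_
                 else round_half_away(100 * frac))
}

#' Three-set overlap (Venn) of locus sets
#'
#' @param admp_set,swan_set,dmr_set character vectors of locus keys
#'   (use [dmr_cpg_set()] to expand called regions to their member
#'   loci). Keys must use one shared convention, e.g. `"chr1:100"`.
#' @return Named integer vector of the 7 Venn region counts:
#'   `admp_only`, `swan_only`, `dmr_only`, `admp_swan`, `admp_dmr`,
#'   `swan_dmr`, `all_three`.
#' @export
overlap_analyses <- function(admp_set, swan_set, dmr_set) {
  a <- unique(admp_set); b <- unique(swan_set); d <- unique(dmr_set)
  in_a <- function(x) x %in% a
  in_b <- function(x) x %in% b
  in_d <- function(x) x %in% d
  u <- unique(c(a, b, d))
  code <- paste0(as.integer(in_a(u)), as.integer(in_b(u)),
                 as.integer(in_d(u)))
  cnt <- function(k) sum(code == k)
  c(admp_only = cnt("100"), swan_only = cnt("010"),
    dmr_only = cnt("001"), admp_swan = cnt("110"),
    admp_dmr = cnt("101"), swan_dmr = cnt("011"),
    all_three = cnt("111"))
}

#' Loci falling within called DMRs
#'
#' @param loci data.frame `chrom`, `pos` (the coverage-filtered loci
#'   of the DMR analysis).
#' @param regions a `dmr_set` or regions data.frame.
#' @return Character vector of `"chrom:pos"` keys of member loci.
#' @export
dmr_cpg_set <- function(loci, regions) {
  r <- if (inherits(regions, "dmr_set")) regions$regions else regions
  if (!nrow(r)) return(character())
  fgr <- features_gr(loci)
  rgr <- GenomicRanges::GRanges(r$chrom,
                                IRanges::IRanges(r$start, r$end))
  hit <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(fgr, rgr)))
  locus_key(loci$chrom[hit], loci$pos[hit])
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the selected genes and
#' the set, with the universe as population (equivalent to a one-sided
#' Fisher exact test on the 2x2 table); BH-adjusted across sets.
#'
#' @param selected_genes character vector (must be a subset of
#'   `universe`; others are dropped with a warning).
#' @param universe character vector of all eligible genes.
#' @param gene_sets named list of gene vectors (see [read_gmt()]);
#'   sets are intersected with the universe.
#' @return data.frame: `set_name`, `n_set`, `n_overlap`,
#'   `universe_size`, `n_selected`, `p_value`, `q_value`, sorted by
#'   p-value.
#' @export
ora_hypergeometric <- function(selected_genes, universe, gene_sets) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  selected <- unique(selected_genes)
  if (!all(selected %in% universe)) {
    warning("dropping selected genes outside the universe")
    selected <- intersect(selected, universe)
  }
  n_u <- length(universe); n_s <- length(selected)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(selected, set))
    p <- phyper(k - 1, length(set), n_u - length(set), n_s,
                lower.tail = FALSE)
    data.frame(set_name = nm, n_set = length(set), n_overlap = k,
               universe_size = n_u, n_selected = n_s, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
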