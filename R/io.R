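# On-disk formats. Internal coordinates are 1-based inclusive
# everywhere; BED (0-based half-open) is converted at this boundary only.

#' Read a Bismark-style cytosine report
#'
#' Expects a 7-column TSV: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context (CG/CHG/CHH), trinucleotide. Rows
#' whose context does not match `context_filter` are dropped (a count of
#' dropped rows is attached as attribute `n_context_dropped`).
#'
#' With `collapse_strands = TRUE` (default) the minus-strand cytosine of
#' a symmetric CpG at position `p` is merged into its plus-strand
#' partner at `p - 1` by summing both count columns; a minus-strand CpG
#' with no plus-strand partner is kept as its own plus-strand locus at
#' `p - 1`.
#'
#' @param path file path.
#' @param context_filter sequence context to retain (default `"CG"`).
#' @param collapse_strands merge symmetric CpG strand pairs (default
#'   `TRUE`).
#' @return data.frame with columns `chrom`, `pos`, `M` (methylated
#'   reads), `N` (total reads), sorted by `(chrom, pos)`.
#' @export
read_cytosine_report <- function(path, context_filter = "CG",
                                 collapse_strands = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      M = integer(), N = integer())
    attr(out, "n_context_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("malformed cytosine report row at line %d of %s",
                 which(nf < 6L)[1L], path), call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  strand <- vapply(fields, `[`, "", 3L)
  m <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  u <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  ctx <- vapply(fields, `[`, "", 6L)
  bad <- is.na(pos) | is.na(m) | is.na(u) | !(strand %in% c("+", "-")) |
    pos < 1L | m < 0L | u < 0L
  if (any(bad))
    stop(sprintf("malformed cytosine report row at line %d of %s",
                 which(bad)[1L], path), call. = FALSE)
  keep <- ctx == context_filter
  n_dropped <- sum(!keep)
  chrom <- chrom[keep]; pos <- pos[keep]; strand <- strand[keep]
  m <- m[keep]; u <- u[keep]
  if (collapse_strands) {
    minus <- strand == "-"
    pos[minus] <- pos[minus] - 1L
  }
  key <- locus_key(chrom, pos)
  m <- rowsum(m, key, reorder = FALSE)
  u <- rowsum(u, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = chrom[first], pos = pos[first],
                    M = as.integer(m[, 1L]),
                    N = as.integer(m[, 1L] + u[, 1L]))
  out <- out[order_loci(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_context_dropped") <- n_dropped
  out
}

#' Write one sample of a MethylationDataset as a cytosine report
#'
#' Emits plus-strand collapsed CG rows (strand `+`, context `CG`,
#' trinucleotide `CGN`), so that `read_cytosine_report()` round-trips
#' the data exactly.
#'
#' @param dataset a `MethylationDataset`.
#' @param sample_id sample to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(dataset, sample_id, path) {
  if (!sample_id %in% sample_ids(dataset))
    stop(sprintf("unknown sample id '%s'", sample_id), call. = FALSE)
  m <- dataset$M[, sample_id]
  n <- dataset$N[, sample_id]
  k <- nrow(dataset$loci)
  df <- data.frame(chrom = dataset$loci$chrom, pos = dataset$loci$pos,
                   strand = rep("+", k), M = m, U = n - m,
                   context = rep("CG", k), tri = rep("CGN", k))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of CpG islands or gene models
#'
#' BED is 0-based half-open on disk; records are converted to the
#' package's 1-based inclusive convention
#' (`start_internal = start_bed + 1`, `end_internal = end_bed`).
#'
#' @param path BED3 (islands) or BED6 (genes; column 4 = gene id,
#'   column 6 = strand) file.
#' @param kind `"islands"` or `"genes"`.
#' @return For `kind = "islands"`: data.frame `chrom`, `start`, `end`
#'   with overlapping/adjacent records merged. For `kind = "genes"`:
#'   data.frame `gene_id`, `chrom`, `tx_start`, `tx_end`, `strand`,
#'   `tss` (strand-aware 5' end).
#' @export
read_bed <- function(path, kind = c("islands", "genes")) {
  kind <- match.arg(kind)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  start0 <- as.integer(df[[2L]]); end0 <- as.integer(df[[3L]])
  if (any(end0 <= start0))
    stop("BED record with end <= start", call. = FALSE)
  chrom <- as.character(df[[1L]])
  start <- start0 + 1L; end <- end0
  if (kind == "islands")
    return(merge_intervals(data.frame(chrom = chrom, start = start,
                                      end = end)))
  if (ncol(df) < 6L)
    stop("gene BED needs 6 columns (name in 4, strand in 6)",
         call. = FALSE)
  strand <- as.character(df[[6L]])
  if (!all(strand %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  out <- data.frame(gene_id = as.character(df[[4L]]), chrom = chrom,
                    tx_start = start, tx_end = end, strand = strand)
  out$tss <- ifelse(out$strand == "+", out$tx_start, out$tx_end)
  out[order_loci(out$chrom, out$tx_start), , drop = FALSE]
}

#' Merge overlapping intervals (1-based inclusive)
#' @param islands data.frame `chrom`, `start`, `end`.
#' @return data.frame of disjoint sorted intervals; touching or
#'   overlapping records are unioned.
#' @export
merge_intervals <- function(islands) {
  stopifnot_cols(islands, c("chrom", "start", "end"), "islands")
  if (!nrow(islands)) return(islands)
  islands <- islands[order(islands$chrom, islands$start), , drop = FALSE]
  out <- islands[1L, , drop = FALSE]
  for (i in seq_len(nrow(islands))[-1L]) {
    j <- nrow(out)
    if (islands$chrom[i] == out$chrom[j] &&
        islands$start[i] <= out$end[j] + 1L) {
      out$end[j] <- max(out$end[j], islands$end[i])
    } else {
      out <- rbind(out, islands[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Write intervals as BED (0-based half-open)
#' @param df data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start - 1L,
                    end = df$end)
  if (!is.null(df$name)) {
    out$name <- df$name
    out$score <- df$score %||% 0
    if (!is.null(df$strand)) out$strand <- df$strand
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, `name TAB description TAB
#'   gene TAB gene ...`.
#' @return Named list of character gene vectors; descriptions in
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with no genes", call. = FALSE)
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names", call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(fields, `[`, "", 2L), nm)
  sets
}

#' Read a sample-metadata table
#'
#' @param path TSV with required columns `subject_id` and `age`
#'   (years); recognised optional columns include `sex`, `race`, `bmi`,
#'   `batch`, `tissue`, `fiber_ratio`.
#' @return data.frame of per-subject covariates.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("subject_id", "age"), "metadata")
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in metadata", call. = FALSE)
  if (any(is.na(df$age))) stop("missing age in metadata", call. = FALSE)
  df$age <- as.numeric(df$age)
  df
}
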