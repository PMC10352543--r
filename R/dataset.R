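#' Construct a MethylationDataset
#'
#' The central container of the package: an ordered table of CpG loci
#' together with loci x samples matrices of methylated (`M`) and total
#' (`N`) read counts. All loci are recorded on the plus strand (see
#' [read_cytosine_report()] for strand collapsing) and sorted by
#' `(chrom, pos)` with 1-based positions.
#'
#' @param loci data.frame with columns `chrom` (character) and `pos`
#'   (1-based integer position of the CpG cytosine).
#' @param M,N integer matrices, `nrow(loci)` x `length(sample_ids)`, of
#'   methylated and total read counts; `0 <= M <= N` elementwise.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `MethylationDataset`: a list with elements
#'   `loci`, `M`, `N`. Loci are sorted by `(chrom, pos)`; matrix columns
#'   are named by `sample_ids`.
#' @examples
#' loci <- data.frame(chrom = "chr1", pos = c(100L, 200L))
#' ds <- methylation_dataset(loci, M = cbind(s1 = c(3L, 5L)),
#'                           N = cbind(s1 = c(10L, 10L)))
#' ds
#' @export
methylation_dataset <- function(loci, M, N,
                                sample_ids = colnames(N)) {
  stopifnot_cols(loci, c("chrom", "pos"), "loci")
  M <- as.matrix(M); N <- as.matrix(N)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(N)))
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  if (nrow(M) != nrow(loci) || nrow(N) != nrow(loci) ||
      ncol(M) != length(sample_ids) || ncol(N) != length(sample_ids))
    stop("dimensions of M/N do not match loci and sample_ids",
         call. = FALSE)
  if (any(loci$pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (any(N < 0) || any(M < 0) || any(M > N))
    stop("counts must satisfy 0 <= M <= N", call. = FALSE)
  if (anyDuplicated(locus_key(loci$chrom, loci$pos)))
    stop("duplicate (chrom, pos) loci", call. = FALSE)
  o <- order_loci(loci$chrom, loci$pos)
  loci <- loci[o, c("chrom", "pos"), drop = FALSE]
  rownames(loci) <- NULL
  M <- M[o, , drop = FALSE]; N <- N[o, , drop = FALSE]
  dimnames(M) <- dimnames(N) <- list(NULL, sample_ids)
  structure(list(loci = loci, M = M, N = N),
            class = "MethylationDataset")
}

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset: %d loci x %d samples\n",
              nrow(x$loci), ncol(x$N)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$loci$chrom), collapse = ", ")))
  cov <- mean(x$N)
  cat(sprintf("  mean coverage: %.2f; loci with N=0 in some sample: %d\n",
              cov, sum(apply(x$N == 0L, 1L, any))))
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) c(nrow(x$loci), ncol(x$N))

#' Subset a MethylationDataset by loci and/or samples
#'
#' @param x a `MethylationDataset`.
#' @param i locus index (logical or integer).
#' @param j sample index or sample ids.
#' @param ... ignored.
#' @return A `MethylationDataset`.
#' @export
`[.MethylationDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$loci))
  if (missing(j)) j <- seq_len(ncol(x$N))
  methylation_dataset(x$loci[i, , drop = FALSE],
                      x$M[i, j, drop = FALSE],
                      x$N[i, j, drop = FALSE],
                      sample_ids = colnames(x$N[, j, drop = FALSE]))
}

#' Sample identifiers of a MethylationDataset
#' @param x a `MethylationDataset`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(x) colnames(x$N)

#' Assemble a MethylationDataset from per-sample count tables
#'
#' Takes the union of loci across samples; a locus absent from a sample
#' gets `M = N = 0` there (the missing-data marker that downstream
#' coverage filters act on).
#'
#' @param reports named list of per-sample count tables as returned by
#'   [read_cytosine_report()] (columns `chrom`, `pos`, `M`, `N`).
#' @return A `MethylationDataset` over the union of loci.
#' @export
assemble_dataset <- function(reports) {
  if (is.null(names(reports)) || anyDuplicated(names(reports)))
    stop("reports must be a uniquely named list", call. = FALSE)
  keys <- unique(unlist(lapply(reports, function(r)
    locus_key(r$chrom, r$pos)), use.names = FALSE))
  split_keys <- strsplit(keys, ":", fixed = TRUE)
  loci <- data.frame(
    chrom = vapply(split_keys, `[`, "", 1L),
    pos = as.integer(vapply(split_keys, `[`, "", 2L)))
  o <- order_loci(loci$chrom, loci$pos)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  all_keys <- locus_key(loci$chrom, loci$pos)
  M <- N <- matrix(0L, nrow(loci), length(reports),
                   dimnames = list(NULL, names(reports)))
  for (s in names(reports)) {
    r <- reports[[s]]
    idx <- match(locus_key(r$chrom, r$pos), all_keys)
    M[idx, s] <- as.integer(r$M)
    N[idx, s] <- as.integer(r$N)
  }
  methylation_dataset(loci, M, N)
}
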