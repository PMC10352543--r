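# in-code fixtures shared across test files

# a tiny dataset built directly from matrices
make_ds <- function(pos = c(100L, 200L, 300L), chrom = "chr1",
                    M = NULL, N = NULL, n_samples = 2L) {
  J <- length(pos)
  if (is.null(N)) N <- matrix(10L, J, n_samples)
  if (is.null(M)) M <- matrix(3L, J, n_samples)
  colnames(M) <- colnames(N) <- paste0("s", seq_len(ncol(N)))
  methylation_dataset(data.frame(chrom = chrom, pos = pos), M, N)
}

# write a cytosine report from row vectors
write_report_lines <- function(path, chrom, pos, strand, m, u,
                               ctx = "CG") {
  writeLines(paste(chrom, pos, strand, m, u, ctx, "CGN", sep = "\t"),
             path)
  path
}

# random dataset for property-style tests
random_ds <- function(J = 50L, S = 4L, cov_max = 20L) {
  pos <- sort(sample.int(1e5, J)) * 2L + 1L
  N <- matrix(sample(0:cov_max, J * S, replace = TRUE), J, S)
  M <- matrix(rbinom(J * S, N, 0.4), J, S)
  colnames(M) <- colnames(N) <- paste0("s", seq_len(S))
  methylation_dataset(data.frame(chrom = "chr1", pos = pos), M, N)
}

# interval Jaccard on 1-based inclusive coordinates
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / ((e1 - s1 + 1) + (e2 - s2 + 1) - inter)
}

# brute-force DMR run enumeration: the independent oracle against
# which call_dmrs is checked
brute_force_dmrs <- function(t, pos, chrom, cutoff, maxgap,
                             clusters = NULL) {
  if (is.null(clusters)) clusters <- rep(1L, length(t))
  runs <- list()
  cur <- integer()
  flush <- function() {
    if (length(cur)) runs[[length(runs) + 1L]] <<- cur
    cur <<- integer()
  }
  for (i in seq_along(t)) {
    if (is.na(t[i]) || abs(t[i]) < cutoff) { flush(); next }
    if (length(cur)) {
      j <- cur[length(cur)]
      same <- clusters[i] == clusters[j] && chrom[i] == chrom[j] &&
        sign(t[i]) == sign(t[j]) && (pos[i] - pos[j]) <= maxgap &&
        i == j + 1L
      if (!same) flush()
    }
    cur <- c(cur, i)
  }
  flush()
  if (!length(runs))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpgs = integer(),
                      direction = character(), mean_diff = numeric(),
                      area_stat = numeric()))
  do.call(rbind, lapply(runs, function(m)
    data.frame(chrom = chrom[m[1L]], start = pos[m[1L]],
               end = pos[m[length(m)]], n_cpgs = length(m),
               direction = if (t[m[1L]] > 0) "hyper" else "hypo",
               mean_diff = NA_real_, area_stat = sum(t[m]))))
}
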