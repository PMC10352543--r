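# gene/TSS linkage, island context, Venn overlap, ORA

simple_genes <- function(...) {
  g <- data.frame(...)
  g$tss <- ifelse(g$strand == "+", g$tx_start, g$tx_end)
  g
}

test_that("features inside transcripts link as intragenic", {
  genes <- simple_genes(gene_id = "G1", chrom = "chr1",
                        tx_start = 100L, tx_end = 900L, strand = "+")
  links <- link_genes(data.frame(chrom = "chr1", pos = 150L), genes)
  expect_equal(links$link_type, "intragenic")
  expect_equal(links$signed_distance, 0)
})

test_that("TSS-proximal distances are signed by strand", {
  genes <- simple_genes(gene_id = "G1", chrom = "chr1",
                        tx_start = 1000L, tx_end = 2000L, strand = "+")
  links <- link_genes(data.frame(chrom = "chr1", pos = 950L), genes)
  expect_equal(links$link_type, "tss_proximal")
  expect_equal(links$signed_distance, -50)
  # downstream of a plus-strand TSS but outside the transcript: none
  links2 <- link_genes(data.frame(chrom = "chr1", pos = 3000L), genes)
  expect_equal(links2$link_type, "none")
  # minus-strand gene: TSS at tx_end, downstream = lower coordinates
  gm <- simple_genes(gene_id = "G2", chrom = "chr1",
                     tx_start = 400L, tx_end = 800L, strand = "-")
  lm_ <- link_genes(data.frame(chrom = "chr1", pos = 950L), gm)
  expect_equal(lm_$link_type, "tss_proximal")
  expect_equal(lm_$signed_distance, -150)
})

test_that("a feature can be intragenic and TSS-proximal at once", {
  genes <- simple_genes(gene_id = c("G1", "G2"), chrom = "chr1",
                        tx_start = c(100L, 1000L),
                        tx_end = c(900L, 2000L),
                        strand = c("+", "+"))
  links <- link_genes(data.frame(chrom = "chr1", pos = 850L), genes)
  expect_setequal(links$link_type, c("intragenic", "tss_proximal"))
  # summary counting prioritises intragenic
  fr <- intragenic_fraction(links)
  expect_equal(fr$n_intragenic, 1L)
  expect_equal(fr$n_features, 1L)
})

test_that("gene linkage matches an all-pairs brute force", {
  set.seed(31)
  genes <- simple_genes(
    gene_id = sprintf("G%02d", 1:50),
    chrom = sample(c("chr1", "chr2"), 50L, TRUE),
    tx_start = st <- sample.int(1e6, 50L),
    tx_end = st + sample(500:5000, 50L, TRUE),
    strand = sample(c("+", "-"), 50L, TRUE))
  genes <- genes[order(genes$chrom, genes$tx_start), ]
  feats <- data.frame(chrom = sample(c("chr1", "chr2"), 1000L, TRUE),
                      pos = sample.int(1e6, 1000L))
  links <- link_genes(feats, genes, 200)
  for (i in sample.int(1000L, 60L)) {
    same <- genes$chrom == feats$chrom[i]
    intr <- same & genes$tx_start <= feats$pos[i] &
      genes$tx_end >= feats$pos[i]
    tssp <- same & !intr & abs(genes$tss - feats$pos[i]) <= 200
    got <- links[links$feature == i, ]
    if (!any(intr) && !any(tssp)) {
      expect_equal(got$link_type, "none")
    } else {
      expect_setequal(got$gene_id[got$link_type == "intragenic"],
                      genes$gene_id[intr])
      expect_setequal(got$gene_id[got$link_type == "tss_proximal"],
                      genes$gene_id[tssp])
    }
  }
})

test_that("island context classes follow the 2 kb / 4 kb boundaries", {
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  feats <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                      pos = c(10500L, 13000L, 13001L, 16000L, 500L))
  ctx <- classify_island_context(feats, islands)
  expect_equal(ctx$class,
               c("island", "shore", "shelf", "open_sea", "open_sea"))
  expect_equal(ctx$distance_to_island[1L], 0)
  expect_equal(ctx$distance_to_island[2L], 2000)  # inclusive boundary
  expect_equal(ctx$distance_to_island[3L], 2001)
  expect_equal(ctx$distance_to_island[5L], Inf)
})

test_that("island classification matches brute force and partitions", {
  set.seed(32)
  islands <- merge_intervals(data.frame(
    chrom = "chr1", start = st <- sort(sample.int(1e6, 20L)),
    end = st + 500L))
  feats <- data.frame(chrom = "chr1", pos = sample.int(1e6, 500L))
  ctx <- classify_island_context(feats, islands)
  expect_equal(nrow(ctx), 500L)
  expect_equal(sum(table(ctx$class)), 500L)
  for (i in sample.int(500L, 50L)) {
    d <- pmax(islands$start - feats$pos[i], feats$pos[i] - islands$end)
    d <- max(0, min(d))
    expect_equal(ctx$distance_to_island[i], d)
  }
})

test_that("printed intragenic percentages follow from the count pairs", {
  expect_equal(intragenic_fraction(16842, 29492)$percent, 57)
  expect_equal(intragenic_fraction(1741, 2372)$percent, 73)
  expect_equal(intragenic_fraction(0, 10)$percent, 0)
  expect_true(is.na(intragenic_fraction(0, 0)$fraction))
})

test_that("Venn counts cover all seven regions correctly", {
  v <- overlap_analyses(c("a", "b"), c("b", "c"), "b")
  expect_equal(v[["all_three"]], 1L)
  expect_equal(v[["admp_only"]], 1L)
  expect_equal(v[["swan_only"]], 1L)
  expect_equal(sum(v), 3L)
  v0 <- overlap_analyses("a", "b", "c")
  expect_equal(v0[["all_three"]], 0L)
  expect_equal(sum(v0), 3L)
})

test_that("Venn counts equal brute-force set algebra on random sets", {
  set.seed(33)
  for (rep in 1:10) {
    u <- sprintf("L%03d", 1:200)
    a <- sample(u, 80); b <- sample(u, 60); d <- sample(u, 40)
    v <- overlap_analyses(a, b, d)
    expect_equal(v[["all_three"]],
                 length(intersect(intersect(a, b), d)))
    expect_equal(v[["admp_only"]],
                 length(setdiff(setdiff(a, b), d)))
    expect_equal(v[["swan_dmr"]],
                 length(setdiff(intersect(b, d), a)))
    expect_equal(sum(v), length(unique(c(a, b, d))))
  }
})

test_that("DMR member loci expand from intervals correctly", {
  loci <- data.frame(chrom = "chr1", pos = c(100L, 250L, 400L, 900L))
  regions <- data.frame(chrom = "chr1", start = 200L, end = 500L)
  expect_equal(dmr_cpg_set(loci, regions),
               c("chr1:250", "chr1:400"))
  expect_equal(dmr_cpg_set(loci, regions[0, ]), character())
})

test_that("hypergeometric ORA matches closed forms and Fisher", {
  sets <- list(S1 = sprintf("G%02d", 1:5))
  universe <- sprintf("G%02d", 1:10)
  # full overlap of a 5-set with 5 selected from 10: p = 1/C(10,5)
  r <- ora_hypergeometric(sprintf("G%02d", 1:5), universe, sets)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap: P(X >= 0) = 1
  r0 <- ora_hypergeometric(sprintf("G%02d", 6:10), universe, sets)
  expect_equal(r0$p_value, 1)
  expect_error(ora_hypergeometric("a", character(), sets), "empty")

  set.seed(34)
  for (rep in 1:50) {
    n_u <- sample(20:100, 1L)
    u <- sprintf("g%03d", seq_len(n_u))
    set <- sample(u, sample.int(n_u, 1L))
    sel <- sample(u, sample.int(n_u, 1L))
    p <- ora_hypergeometric(sel, u, list(s = set))$p_value
    k <- length(intersect(sel, set))
    tab <- matrix(c(k, length(set) - k, length(sel) - k,
                    n_u - length(set) - length(sel) + k), 2L)
    ref <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p, ref, tolerance = 1e-10)
  }
})

test_that("regions planted in dense shore-like clusters enrich there", {
  # island at [10000, 11000]; a dense CpG cluster sits in its shore and
  # carries a strong young/old difference, against a sparse background
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  shore_pos <- seq(11101L, 12551L, 50L)   # 30 loci within 2 kb
  sea_pos <- seq(100001L, 298001L, 2000L) # 100 loci far away
  loci <- data.frame(chrom = "chr1",
                     pos = sort(c(shore_pos, sea_pos)))
  in_shore <- loci$pos %in% shore_pos
  set.seed(35)
  S <- 12L
  N <- matrix(50L, nrow(loci), S)
  p <- matrix(0.5, nrow(loci), S)
  p[in_shore, 7:12] <- 0.9  # old samples shifted in the shore cluster
  M <- matrix(rbinom(length(p), N, p), nrow(loci), S)
  colnames(M) <- colnames(N) <- sprintf("s%02d", 1:S)
  ds <- methylation_dataset(loci, M, N)
  samples <- data.frame(subject_id = colnames(M),
                        age = c(rep(30, 6), rep(70, 6)))
  res <- dmr_analysis(ds, samples, 53,
                      smooth_params(min_loci = 10L, min_width = 200),
                      tstat_params(sd_floor_quantile = 0.9))
  expect_gt(nrow(res$regions), 0L)
  member <- dmr_cpg_set(loci, res$regions)
  member_pos <- as.integer(sub("chr1:", "", member))
  ctx_members <- classify_island_context(
    data.frame(chrom = "chr1", pos = member_pos), islands)
  ctx_all <- classify_island_context(loci, islands)
  expect_gt(mean(ctx_members$class == "shore"),
            mean(ctx_all$class == "shore"))
})
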