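# clustering, smoothing, t-statistic, local correction, region calling

test_that("loci cluster by gap with chromosome boundaries splitting", {
  loci <- data.frame(chrom = "chr1", pos = c(100, 200, 1e9 + 100))
  expect_equal(cluster_loci(loci, 1e8), c(1L, 1L, 2L))
  loci2 <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      pos = c(100, 200, 300))
  expect_equal(cluster_loci(loci2, 1e8), c(1L, 1L, 2L))
})

test_that("clustering matches a brute-force pairwise scan", {
  set.seed(20)
  loci <- data.frame(
    chrom = sort(sample(c("chr1", "chr2"), 200L, TRUE)),
    pos = numeric(200L))
  for (ch in unique(loci$chrom))
    loci$pos[loci$chrom == ch] <-
      sort(sample.int(1e6, sum(loci$chrom == ch)))
  maxgap <- 5000
  labels <- cluster_loci(loci, maxgap)
  # oracle: walk pairs
  expected <- 1L
  for (i in 2:200) {
    brk <- loci$chrom[i] != loci$chrom[i - 1L] ||
      (loci$pos[i] - loci$pos[i - 1L]) > maxgap
    expected <- c(expected,
                  expected[i - 1L] + as.integer(brk))
  }
  expect_equal(labels, expected)
})

test_that("smoothing reproduces constants exactly", {
  loci <- data.frame(chrom = "chr1", pos = seq(1000L, 3000L, 100L))
  n <- rep(10L, nrow(loci))
  m <- as.integer(n * 0.4)
  sm <- smooth_sample(loci, m, n, smooth_params(min_loci = 5L,
                                                min_width = 200))
  expect_equal(as.numeric(sm), rep(0.4, nrow(loci)), tolerance = 1e-10)
})

test_that("degree-2 profiles are reproduced to 1e-8 at full coverage", {
  pos <- seq(0, 1000, 25)
  loci <- data.frame(chrom = "chr1", pos = as.integer(pos + 1L))
  frac <- 0.3 + 0.0005 * pos - 4e-7 * pos^2  # stays in (0, 1)
  N <- rep(1000000L, length(pos))
  M <- as.integer(round(frac * N))
  sm <- smooth_sample(loci, M, N,
                      smooth_params(min_loci = length(pos),
                                    min_width = 1))
  expect_equal(as.numeric(sm), M / N, tolerance = 1e-8)
})

test_that("zero-coverage loci are imputed from their neighbours", {
  set.seed(5)
  pos <- seq(1000L, 5000L, 100L)
  loci <- data.frame(chrom = "chr1", pos = pos)
  N <- rep(50L, length(pos)); M <- rbinom(length(pos), N, 0.2)
  j <- 21L
  N[j] <- 0L; M[j] <- 0L
  sm <- smooth_sample(loci, M, N, smooth_params(min_loci = 10L,
                                                min_width = 500))
  expect_false(is.na(sm[j]))
  expect_gte(sm[j], 0.15)
  expect_lte(sm[j], 0.25)
})

test_that("smoothing is equivariant to adding a constant", {
  set.seed(21)
  pos <- sort(sample.int(1e5, 60L)) * 2L
  loci <- data.frame(chrom = "chr1", pos = pos)
  N <- rep(100L, 60L)
  M <- rbinom(60L, N, 0.3)
  sp <- smooth_params(min_loci = 15L, min_width = 500)
  base <- smooth_sample(loci, M, N, sp, clip = FALSE)
  shifted <- smooth_sample(loci, M + as.integer(N * 0.4), N, sp,
                           clip = FALSE)
  expect_equal(as.numeric(shifted), as.numeric(base) + 0.4,
               tolerance = 1e-8)
})

test_that("tiny clusters fall back to the coverage-weighted mean", {
  loci <- data.frame(chrom = "chr1", pos = c(100L, 200L))
  N <- c(10L, 30L); M <- c(2L, 12L)
  sm <- smooth_sample(loci, M, N, smooth_params(min_loci = 5L))
  expect_equal(as.numeric(sm), rep((2 + 12) / 40, 2L))
  expect_equal(attr(sm, "fallback_clusters"), 1L)
})

test_that("young/old splits honour both threshold conventions", {
  samples <- data.frame(subject_id = c("a", "b"), age = c(52, 53))
  g <- split_groups(samples, 53, inclusive = TRUE)
  expect_equal(g$young, "a"); expect_equal(g$old, "b")
  samples2 <- data.frame(subject_id = c("a", "b"), age = c(51, 52))
  g2 <- split_groups(samples2, 51, inclusive = FALSE)
  expect_equal(g2$young, "a"); expect_equal(g2$old, "b")
  expect_error(split_groups(data.frame(subject_id = "a", age = 30),
                            53), "empty group")
})

test_that("the t-statistic uses young-group baseline sd with a floor", {
  set.seed(22)
  J <- 40L
  young <- matrix(rnorm(J * 4, 0.5, 0.05), J, 4L,
                  dimnames = list(NULL, paste0("y", 1:4)))
  old <- young[, 1:4] + 0.1
  colnames(old) <- paste0("o", 1:4)
  sm <- cbind(young, old)
  groups <- list(young = colnames(young), old = colnames(old))
  t <- tstat(sm, groups, tstat_params())
  # closed form: d / (sd_young * sqrt(1/4 + 1/4)) where above floor
  sdy <- apply(young, 1L, sd) * sqrt(1 / 4 + 1 / 4)
  fl <- quantile(sdy, 0.75, names = FALSE)
  expect_equal(as.numeric(t), 0.1 / pmax(sdy, fl), tolerance = 1e-10)
  # identical group means -> t = 0
  t0 <- tstat(cbind(young, setNames(as.data.frame(young),
                                    paste0("o", 1:4))) |> as.matrix(),
              groups, tstat_params())
  expect_equal(as.numeric(t0), rep(0, J))
})

test_that("zero young-group variance engages the floor, keeping t finite", {
  sm <- cbind(y1 = rep(0.5, 10), y2 = rep(0.5, 10),
              o1 = rep(0.6, 10), o2 = rep(0.7, 10))
  t <- tstat(sm, list(young = c("y1", "y2"), old = c("o1", "o2")),
             tstat_params())
  expect_true(all(is.finite(t)))
})

test_that("flipping group labels negates t and swaps direction", {
  # negation is exact when the two groups share per-locus dispersion,
  # so build the flipped group as a per-locus shift of the first
  set.seed(23)
  pos <- sort(sample.int(1e5, 50L)) * 2L
  loci <- data.frame(chrom = "chr1", pos = pos)
  young <- matrix(runif(50 * 4, 0.2, 0.6), 50L, 4L)
  shift <- c(rep(0.3, 10L), runif(40L, -0.1, 0.1))
  sm <- cbind(young, young + shift)
  colnames(sm) <- paste0("s", 1:8)
  g <- list(young = paste0("s", 1:4), old = paste0("s", 5:8))
  gflip <- list(young = g$old, old = g$young)
  tp <- tstat_params(sd_floor_quantile = 0.5)
  t1 <- tstat(sm, g, tp)
  t2 <- tstat(sm, gflip, tp)
  expect_equal(as.numeric(t2), -as.numeric(t1), tolerance = 1e-10)
  d1 <- call_dmrs(as.numeric(t1), attr(t1, "mean_diff"), loci,
                  tstat_params(cutoff = 2))
  d2 <- call_dmrs(as.numeric(t2), attr(t2, "mean_diff"), loci,
                  tstat_params(cutoff = 2))
  expect_equal(d1$start, d2$start)
  expect_equal(d1$direction,
               ifelse(d2$direction == "hyper", "hypo", "hyper"))
})

test_that("local correction removes constants and small backgrounds", {
  loci <- data.frame(chrom = "chr1", pos = seq_len(101L) * 10L)
  tp <- tstat_params(correct_halfwidth = 50L)
  expect_equal(local_correct(rep(3, 101L), loci, tp), rep(0, 101L))
  # single spike among nulls: corrected ~ raw minus its own leakage
  t <- rep(0, 101L); t[51L] <- 10
  corr <- local_correct(t, loci, tp)
  expect_equal(corr[51L], 10 - 10 / 101, tolerance = 1e-10)
  # off -> identity
  expect_identical(local_correct(t, loci,
                                 tstat_params(local_correct = FALSE)),
                   t)
  # hand-computed running mean at an edge locus (window shrinks)
  t2 <- seq(0, 1, length.out = 101L)
  corr2 <- local_correct(t2, loci, tp)
  expect_equal(corr2[1L], t2[1L] - mean(t2[1:51]), tolerance = 1e-12)
})

test_that("region calling follows sign, cutoff and gap rules", {
  loci <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L))
  d <- call_dmrs(c(5, 5, -5, 5), rep(0.1, 4L), loci, tstat_params())
  expect_equal(d$n_cpgs, c(2L, 1L, 1L))
  expect_equal(d$direction, c("hyper", "hypo", "hyper"))
  expect_equal(d$area_stat, c(10, -5, 5))
  # gap > 300 splits
  loci2 <- data.frame(chrom = "chr1", pos = c(100L, 500L))
  d2 <- call_dmrs(c(5, 5), c(0.1, 0.1), loci2, tstat_params())
  expect_equal(nrow(d2), 2L)
  # below cutoff -> empty
  expect_equal(nrow(call_dmrs(c(4.5, -4.5), c(0, 0), loci2,
                              tstat_params())), 0L)
  # min_cpgs filter
  d3 <- call_dmrs(c(5, 5, -5, 5), rep(0.1, 4L), loci,
                  tstat_params(min_cpgs_per_dmr = 2L))
  expect_equal(nrow(d3), 1L)
})

test_that("region calling equals brute-force run enumeration", {
  set.seed(24)
  for (rep in 1:5) {
    J <- 500L
    loci <- data.frame(
      chrom = sort(sample(c("chr1", "chr2"), J, TRUE)),
      pos = numeric(J))
    for (ch in unique(loci$chrom))
      loci$pos[loci$chrom == ch] <-
        sort(sample.int(5e4, sum(loci$chrom == ch)))
    t <- rnorm(J, 0, 3)
    clusters <- cluster_loci(loci, 5000)
    got <- call_dmrs(t, rep(0, J), loci, tstat_params(cutoff = 3),
                     clusters)
    want <- brute_force_dmrs(t, loci$pos, loci$chrom, 3, 300, clusters)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_cpgs, want$n_cpgs)
    expect_equal(got$direction, want$direction)
    expect_equal(got$area_stat, want$area_stat, tolerance = 1e-12)
  }
})

test_that("a planted region is recovered end to end", {
  ages <- c(seq(25, 50, length.out = 10), seq(56, 80, length.out = 10))
  cfg <- sim_config(seed = 30, n_subjects = 20L, ages = ages,
                    n_cpgs = 600L, chrom_length = 1e6,
                    island_count = 30L, coverage_mean = 30,
                    planted_dmr = data.frame(island = 15L, delta = 30,
                                             old_threshold_age = 53))
  s <- simulate_study(cfg)
  ds <- filter_coverage(s$dataset, 2L)
  res <- dmr_analysis(ds, s$cohort, 53)
  truth_keys <- with(s$truth[s$truth$class == "dmr", ],
                     paste0(chrom, ":", pos))
  j <- vapply(seq_len(nrow(res$regions)), function(i) {
    keys <- dmr_cpg_set(ds$loci, res$regions[i, ])
    length(intersect(keys, truth_keys)) /
      length(union(keys, truth_keys))
  }, numeric(1L))
  expect_gte(max(j), 0.8)
  expect_equal(res$regions$direction[which.max(j)], "hyper")
  expect_gt(res$regions$mean_diff[which.max(j)], 0)
})
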