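# Seeded generator for synthetic bisulfite-sequencing cohorts with a
# ground-truth ledger. The generative model is logit-additive:
#   p_sj = plogis(a_j + b_j*(age_s - mid_age) + wave_j(age_s)
#                 + step_j(age_s) + batch_sj + eps_sj)
#   N_sj ~ Poisson(coverage_mean),  M_sj ~ Binomial(N_sj, p_sj)
# with island loci drawn low-methylated and open-sea loci high.
# Planted effects are specified in percentage points at the locus
# baseline p0 and converted to logit offsets:
#   step/wave: delta_logit = qlogis(p0 + delta/100) - qlogis(p0)
#   linear:    b_logit = (slope/100) / (p0 * (1 - p0))   per year
# (the derivative of the logistic at p0), so that small effects have
# the stated size on the percent scale.

# evaluate code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the package targets: ~40 subjects
#' evenly spread over ages 22-83 and ~10x genome-wide read depth, with
#' CpGs clustered into low-methylated islands against a high-methylated
#' open sea.
#'
#' @param seed integer; fixes every downstream draw bit-for-bit.
#' @param genome_seed optional separate seed for the genome layout
#'   (loci, genes, islands); defaults to `seed`. Varying `seed` with
#'   `genome_seed` fixed redraws counts over identical loci.
#' @param n_subjects number of subjects (default 40).
#' @param age_min,age_max age range in years (defaults 22 and 83).
#' @param ages optional explicit age vector (overrides uniform draws).
#' @param n_chroms,chrom_length chromosome count and length in bp.
#' @param n_cpgs total CpG loci to place.
#' @param island_count,island_width CpG islands per genome and their
#'   width in bp.
#' @param island_cpg_frac fraction of CpGs placed inside islands
#'   (default 0.5; islands are far denser than open sea).
#' @param n_genes,gene_length gene count and min/max transcript length.
#' @param genic_planted_frac,tss_planted_frac fractions of planted loci
#'   that get a covering transcript / a TSS within 200 bp.
#' @param coverage_mean mean Poisson read depth (default 10).
#' @param logit_noise_sd between-subject noise sd on the logit scale
#'   (default 0.5; induces beta-binomial-like overdispersion).
#' @param n_batches,batch_effect_sd batches and per-(locus, batch)
#'   logit offset sd (default 0 = no batch effect).
#' @param planted_linear data.frame(`locus`, `slope`): loci (row index
#'   into the genome's loci) with a linear age trend in percentage
#'   points per year.
#' @param planted_wave data.frame(`locus`, `center_age`, `half_width`,
#'   `delta`): loci shifted by `delta` percentage points only for
#'   subjects with `|age - center_age| <= half_width`.
#' @param planted_dmr data.frame with `delta` (percentage points) and
#'   `old_threshold_age` plus either (`chrom`, `start`, `end`) or an
#'   `island` column (index into the genome's islands): all CpGs in the
#'   interval are shifted for subjects at/above the threshold age.
#' @param dmr_inclusive old group is `age >= threshold` if `TRUE`
#'   (default), `age > threshold` otherwise.
#' @param spike_in add an unmethylated lambda spike-in contig.
#' @param spike_cpgs,spike_level CpGs on the spike contig and their
#'   true methylated fraction (default 0.005, i.e. ~99.5% conversion).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_seed = NULL,
                       n_subjects = 40L,
                       age_min = 22, age_max = 83, ages = NULL,
                       n_chroms = 1L, chrom_length = 1e6,
                       n_cpgs = 2000L,
                       island_count = 20L, island_width = 1000L,
                       island_cpg_frac = 0.5,
                       n_genes = 30L, gene_length = c(2000L, 10000L),
                       genic_planted_frac = 0.4,
                       tss_planted_frac = 0.3,
                       coverage_mean = 10,
                       logit_noise_sd = 0.5,
                       n_batches = 2L, batch_effect_sd = 0,
                       planted_linear = NULL, planted_wave = NULL,
                       planted_dmr = NULL, dmr_inclusive = TRUE,
                       spike_in = FALSE, spike_cpgs = 200L,
                       spike_level = 0.005) {
  if (age_min >= age_max) stop("age_min must be < age_max", call. = FALSE)
  cfg <- as.list(environment())
  for (nm in c("planted_wave", "planted_dmr", "planted_linear")) {
    df <- cfg[[nm]]
    if (!is.null(df) && !is.data.frame(df))  # e.g. YAML record lists
      df <- cfg[[nm]] <- do.call(rbind,
                                 lapply(df, as.data.frame))
    if (!is.null(df) && nrow(df)) {
      if ("delta" %in% names(df) && any(abs(df$delta) >= 100))
        stop("planted deltas must lie in (-100, 100)", call. = FALSE)
    }
  }
  structure(cfg, class = "sim_config")
}

# non-overlapping island starts on a coarse grid (3x width spacing)
place_islands <- function(n, chrom_length, width) {
  grid <- seq(1L, chrom_length - width, by = 3L * width)
  if (length(grid) < n)
    stop("island placement infeasible for chromosome length given",
         call. = FALSE)
  sort(sample(grid, n))
}

#' Simulate the genome layout: CpG loci, genes, CpG islands
#'
#' CpG positions are drawn on an odd-position grid (so loci never
#' overlap) and are much denser inside islands than in the open sea.
#' Genes are placed so that configurable fractions of planted loci are
#' covered by a transcript or have a TSS within 200 bp.
#'
#' @param config a [sim_config()].
#' @return list with `loci` (data.frame `chrom`, `pos`), `genes`
#'   (as [read_bed()] `kind = "genes"`), `islands`, and `planted`
#'   (resolved planted-effect tables).
#' @export
simulate_genome <- function(config) {
  with_seed(config$genome_seed %||% config$seed, {
    chroms <- paste0("chr", seq_len(config$n_chroms))
    isl_per_chrom <- diff(round(seq(0, config$island_count,
                                    length.out = config$n_chroms + 1L)))
    islands <- do.call(rbind, lapply(seq_along(chroms), function(i) {
      k <- isl_per_chrom[i]
      if (!k) return(NULL)
      st <- place_islands(k, config$chrom_length, config$island_width)
      data.frame(chrom = chroms[i], start = st,
                 end = st + config$island_width - 1L)
    }))
    if (is.null(islands))
      islands <- data.frame(chrom = character(), start = integer(),
                            end = integer())

    n_isl_cpg <- round(config$n_cpgs * config$island_cpg_frac)
    n_sea_cpg <- config$n_cpgs - n_isl_cpg
    loci <- NULL
    if (n_isl_cpg > 0 && nrow(islands)) {
      per <- diff(round(seq(0, n_isl_cpg,
                            length.out = nrow(islands) + 1L)))
      loci <- do.call(rbind, lapply(seq_len(nrow(islands)), function(i) {
        grid <- seq(islands$start[i] + 1L, islands$end[i], by = 2L)
        data.frame(chrom = islands$chrom[i],
                   pos = sort(sample(grid, min(per[i], length(grid)))))
      }))
    }
    sea_per_chrom <- diff(round(seq(0, n_sea_cpg,
                                    length.out = config$n_chroms + 1L)))
    for (i in seq_along(chroms)) {
      if (!sea_per_chrom[i]) next
      grid <- seq(1L, config$chrom_length, by = 2L)
      pos <- sort(sample(grid, sea_per_chrom[i]))
      isl <- islands[islands$chrom == chroms[i], , drop = FALSE]
      if (nrow(isl)) {
        inside <- vapply(pos, function(p)
          any(p >= isl$start & p <= isl$end), logical(1L))
        pos <- pos[!inside]
      }
      loci <- rbind(loci, data.frame(chrom = chroms[i], pos = pos))
    }
    loci <- unique(loci)
    loci <- loci[order_loci(loci$chrom, loci$pos), , drop = FALSE]
    rownames(loci) <- NULL

    planted <- resolve_planted(config, loci, islands)
    planted_idx <- sort(unique(c(
      planted$linear$locus, planted$wave$locus,
      unlist(lapply(seq_len(nrow(planted$dmr)), function(i)
        which(loci$chrom == planted$dmr$chrom[i] &
              loci$pos >= planted$dmr$start[i] &
              loci$pos <= planted$dmr$end[i]))))))

    genes <- simulate_genes(config, loci, planted_idx)

    if (config$spike_in) {
      grid <- seq(1L, 48501L, by = 2L)
      spike <- data.frame(chrom = "lambda",
                          pos = sort(sample(grid, config$spike_cpgs)))
      loci <- rbind(loci, spike)
      loci <- loci[order_loci(loci$chrom, loci$pos), , drop = FALSE]
      rownames(loci) <- NULL
    }
    list(loci = loci, genes = genes, islands = islands,
         planted = planted)
  })
}

resolve_planted <- function(config, loci, islands) {
  lin <- config$planted_linear %||%
    data.frame(locus = integer(), slope = numeric())
  wav <- config$planted_wave %||%
    data.frame(locus = integer(), center_age = numeric(),
               half_width = numeric(), delta = numeric())
  dmr <- config$planted_dmr %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               delta = numeric(), old_threshold_age = numeric())
  if (nrow(dmr) && "island" %in% names(dmr)) {
    if (any(dmr$island > nrow(islands)))
      stop("planted_dmr refers to a nonexistent island", call. = FALSE)
    dmr$chrom <- islands$chrom[dmr$island]
    dmr$start <- islands$start[dmr$island]
    dmr$end <- islands$end[dmr$island]
    dmr$island <- NULL
  }
  n_nonspike <- nrow(loci)
  if (nrow(lin) && any(lin$locus < 1L | lin$locus > n_nonspike))
    stop("planted_linear locus out of range", call. = FALSE)
  if (nrow(wav) && any(wav$locus < 1L | wav$locus > n_nonspike))
    stop("planted_wave locus out of range", call. = FALSE)
  list(linear = lin, wave = wav, dmr = dmr)
}

simulate_genes <- function(config, loci, planted_idx) {
  if (config$n_genes == 0L)
    return(data.frame(gene_id = character(), chrom = character(),
                      tx_start = integer(), tx_end = integer(),
                      strand = character(), tss = integer()))
  n_genic <- min(round(config$genic_planted_frac * length(planted_idx)),
                 config$n_genes)
  n_tss <- min(round(config$tss_planted_frac * length(planted_idx)),
               config$n_genes - n_genic)
  len <- function(k) round(runif(k, config$gene_length[1L],
                                 config$gene_length[2L]))
  rows <- list()
  gi <- planted_idx[seq_len(n_genic)]
  if (n_genic > 0) {
    L <- len(n_genic)
    rows$genic <- data.frame(
      chrom = loci$chrom[gi],
      tx_start = pmax(1L, loci$pos[gi] - as.integer(L %/% 2)),
      tx_end = pmin(as.integer(config$chrom_length),
                    loci$pos[gi] + as.integer(L %/% 2)),
      strand = sample(c("+", "-"), n_genic, replace = TRUE))
  }
  ti <- planted_idx[n_genic + seq_len(n_tss)]
  if (n_tss > 0) {
    L <- len(n_tss)
    d <- sample(20:200, n_tss, replace = TRUE)
    strand <- sample(c("+", "-"), n_tss, replace = TRUE)
    # TSS downstream of the locus for +, upstream for -, so the gene
    # body points away and the locus stays outside the transcript
    tx_start <- ifelse(strand == "+", loci$pos[ti] + d,
                       loci$pos[ti] - d - L)
    rows$tss <- data.frame(
      chrom = loci$chrom[ti],
      tx_start = pmax(1L, as.integer(tx_start)),
      tx_end = pmin(as.integer(config$chrom_length),
                    as.integer(tx_start + L)),
      strand = strand)
  }
  n_rand <- config$n_genes - n_genic - n_tss
  if (n_rand > 0) {
    L <- len(n_rand)
    st <- round(runif(n_rand, 1, config$chrom_length - L))
    rows$rand <- data.frame(
      chrom = sample(paste0("chr", seq_len(config$n_chroms)), n_rand,
                     replace = TRUE),
      tx_start = as.integer(st), tx_end = as.integer(st + L),
      strand = sample(c("+", "-"), n_rand, replace = TRUE))
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order_loci(genes$chrom, genes$tx_start), , drop = FALSE]
  genes <- data.frame(gene_id = sprintf("G%03d", seq_len(nrow(genes))),
                      genes, stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  rownames(genes) <- NULL
  genes
}

#' Simulate the subject cohort
#'
#' Ages are uniform on `[age_min, age_max]` (or taken verbatim from
#' `config$ages`); sex, race and batch are categorical draws; BMI is
#' Normal(27, 4); the myosin-derived fiber ratio gets a mild positive
#' age trend on the logit scale.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `subject_id`, `age`, `sex`, `race`,
#'   `bmi`, `batch`, `tissue`, `fiber_ratio`.
#' @export
simulate_cohort <- function(config) {
  if (config$n_subjects < 2L) stop("need >= 2 subjects", call. = FALSE)
  with_seed(config$seed + 1L, {
    n <- config$n_subjects
    ages <- config$ages %||% runif(n, config$age_min, config$age_max)
    if (length(ages) != n)
      stop("supplied ages must have length n_subjects", call. = FALSE)
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = ages,
      sex = sample(c("F", "M"), n, replace = TRUE),
      race = sample(c("A", "B", "W"), n, replace = TRUE,
                    prob = c(0.2, 0.3, 0.5)),
      bmi = round(rnorm(n, 27, 4), 1),
      batch = paste0("b", sample(seq_len(config$n_batches), n,
                                 replace = TRUE)),
      tissue = "muscle",
      fiber_ratio = round(plogis(qlogis(0.35) + 0.01 * (ages - 50) +
                                   rnorm(n, 0, 0.2)), 4),
      stringsAsFactors = FALSE)
  })
}

#' Simulate methylation read counts and the truth ledger
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()] (same config).
#' @param cohort output of [simulate_cohort()] (same config).
#' @return list with `dataset` (a [methylation_dataset()]) and `truth`
#'   (per-locus data.frame: `chrom`, `pos`, `baseline`, `class` in
#'   none/linear/wave/dmr/spike, and the effect parameters).
#' @export
simulate_methylation <- function(config, genome, cohort) {
  with_seed(config$seed + 2L, {
    loci <- genome$loci
    J <- nrow(loci); S <- nrow(cohort)
    is_spike <- loci$chrom == "lambda"
    in_island <- rep(FALSE, J)
    isl <- genome$islands
    for (i in seq_len(nrow(isl))) {
      hit <- loci$chrom == isl$chrom[i] & loci$pos >= isl$start[i] &
        loci$pos <= isl$end[i]
      in_island <- in_island | hit
    }
    p0 <- ifelse(in_island, runif(J, 0.05, 0.25), runif(J, 0.70, 0.95))
    p0[is_spike] <- config$spike_level

    truth <- data.frame(chrom = loci$chrom, pos = loci$pos,
                        baseline = p0, class = "none",
                        slope = NA_real_, center_age = NA_real_,
                        half_width = NA_real_, delta = NA_real_,
                        old_threshold_age = NA_real_,
                        stringsAsFactors = FALSE)
    truth$class[is_spike] <- "spike"

    # planted indices refer to the non-spike loci in sorted order
    idx_map <- which(!is_spike)
    mid_age <- (config$age_min + config$age_max) / 2
    ages <- cohort$age
    eta <- matrix(rep(logit(p0), S), J, S)  # loci x subjects

    pl <- genome$planted
    clamped <- FALSE
    if (nrow(pl$linear)) {
      j <- idx_map[pl$linear$locus]
      b_logit <- (pl$linear$slope / 100) / (p0[j] * (1 - p0[j]))
      eta[j, ] <- eta[j, ] + outer(b_logit, ages - mid_age)
      truth$class[j] <- "linear"
      truth$slope[j] <- pl$linear$slope
    }
    delta_logit <- function(p0j, delta) {
      tgt <- p0j + delta / 100
      if (any(tgt <= 0 | tgt >= 1)) clamped <<- TRUE
      logit(clamp01(tgt)) - logit(p0j)
    }
    if (nrow(pl$wave)) {
      j <- idx_map[pl$wave$locus]
      dl <- delta_logit(p0[j], pl$wave$delta)
      on_w <- outer(pl$wave$center_age, ages,
                    function(c, a) abs(a - c)) <=
        matrix(pl$wave$half_width, length(j), S)
      eta[j, ] <- eta[j, ] + dl * on_w
      truth$class[j] <- "wave"
      truth$center_age[j] <- pl$wave$center_age
      truth$half_width[j] <- pl$wave$half_width
      truth$delta[j] <- pl$wave$delta
    }
    if (nrow(pl$dmr)) {
      for (i in seq_len(nrow(pl$dmr))) {
        j <- which(loci$chrom == pl$dmr$chrom[i] &
                   loci$pos >= pl$dmr$start[i] &
                   loci$pos <= pl$dmr$end[i] & !is_spike)
        if (!length(j)) next
        dl <- delta_logit(p0[j], rep(pl$dmr$delta[i], length(j)))
        thr <- pl$dmr$old_threshold_age[i]
        old <- if (config$dmr_inclusive) ages >= thr else ages > thr
        eta[j, old] <- eta[j, old] + dl
        truth$class[j] <- "dmr"
        truth$delta[j] <- pl$dmr$delta[i]
        truth$old_threshold_age[j] <- thr
      }
    }
    if (clamped)
      warning("planted effect pushed a true fraction outside (0,1); clamped")

    if (config$logit_noise_sd > 0)
      eta <- eta + matrix(rnorm(J * S, 0, config$logit_noise_sd), J, S)
    if (config$batch_effect_sd > 0) {
      batches <- unique(cohort$batch)
      off <- matrix(rnorm(J * length(batches), 0,
                          config$batch_effect_sd), J, length(batches),
                    dimnames = list(NULL, batches))
      eta <- eta + off[, cohort$batch, drop = FALSE]
    }
    p <- plogis(eta)
    N <- matrix(rpois(J * S, config$coverage_mean), J, S)
    M <- matrix(rbinom(J * S, N, p), J, S)
    colnames(M) <- colnames(N) <- cohort$subject_id
    list(dataset = methylation_dataset(loci, M, N), truth = truth)
  })
}

#' Run the whole generator and optionally write a study directory
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; if given, writes one cytosine
#'   report per subject (`<subject_id>.cov.tsv`), `metadata.tsv`,
#'   `genes.bed`, `islands.bed` and `truth.tsv`.
#' @return (invisibly) list with `genome`, `cohort`, `dataset`,
#'   `truth`.
#' @export
simulate_study <- function(config, outdir = NULL) {
  genome <- simulate_genome(config)
  cohort <- simulate_cohort(config)
  sim <- simulate_methylation(config, genome, cohort)
  out <- list(genome = genome, cohort = cohort,
              dataset = sim$dataset, truth = sim$truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (s in cohort$subject_id)
      write_cytosine_report(sim$dataset, s,
                            file.path(outdir, paste0(s, ".cov.tsv")))
    write.table(cohort, file.path(outdir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_bed(genome$islands, file.path(outdir, "islands.bed"))
    g <- genome$genes
    write_bed(data.frame(chrom = g$chrom, start = g$tx_start,
                         end = g$tx_end, name = g$gene_id, score = 0,
                         strand = g$strand),
              file.path(outdir, "genes.bed"))
    write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
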