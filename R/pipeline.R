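# Stage orchestration: one config, deterministic artifacts. The
# exported functions are the interface; `run_pipeline()` chains the
# stages in analysis order (simulate -> qc -> regress/swan/dmr ->
# annotate -> enrich -> overlap) and writes TSV/JSON artifacts plus a
# parameter-echo log under the output directory.

#' Default run configuration
#'
#' @param outdir output directory for all artifacts.
#' @param seed master seed; every random draw derives from it.
#' @param sim named list of [sim_config()] overrides (used by the
#'   `simulate` stage).
#' @param paths named list of input paths (`reports` directory of
#'   cytosine reports, `metadata`, `genes`, `islands`, `gmt`); filled
#'   in automatically when the `simulate` stage runs.
#' @param coverage per-stage minimum coverage: `regression` and `swan`
#'   default to 10x in all samples, `dmr` to 2x.
#' @param covariates,alpha regression adjustment columns and per-CpG
#'   significance level.
#' @param swan named list of [swan_config()] overrides.
#' @param smooth named list of [smooth_params()] overrides.
#' @param tstat named list of [tstat_params()] overrides.
#' @param old_threshold_age,inclusive young/old split for the DMR
#'   stage.
#' @param max_link_dist TSS linkage distance for annotation (bp).
#' @return A `run_config` list.
#' @export
run_config <- function(outdir = tempfile("methylaging_run_"),
                       seed = 1L, sim = list(), paths = list(),
                       coverage = list(regression = 10L, swan = 10L,
                                       dmr = 2L),
                       covariates = c("sex", "race", "bmi"),
                       alpha = 0.05, swan = list(), smooth = list(),
                       tstat = list(), old_threshold_age = 53,
                       inclusive = TRUE, max_link_dist = 200) {
  cfg <- as.list(environment())
  cfg$coverage <- utils::modifyList(
    list(regression = 10L, swan = 10L, dmr = 2L), as.list(coverage))
  structure(cfg, class = "run_config")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_config()]; missing keys keep
#' their defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, y)
}

pipeline_inputs <- function(cfg) {
  p <- cfg$paths
  for (nm in c("metadata", "genes", "islands")) {
    if (is.null(p[[nm]]) || !file.exists(p[[nm]]))
      stop(sprintf("input '%s' missing (run the simulate stage or set paths$%s)",
                   nm, nm), call. = FALSE)
  }
  reports <- list.files(p$reports, pattern = "\\.cov\\.tsv$",
                        full.names = TRUE)
  if (!length(reports))
    stop("no cytosine reports under paths$reports", call. = FALSE)
  names(reports) <- sub("\\.cov\\.tsv$", "", basename(reports))
  ds <- assemble_dataset(lapply(reports, read_cytosine_report))
  meta <- read_metadata(p$metadata)
  meta <- meta[match(sample_ids(ds), meta$subject_id), , drop = FALSE]
  if (any(is.na(meta$subject_id)))
    stop("metadata does not cover all samples", call. = FALSE)
  list(dataset = ds, meta = meta,
       genes = read_bed(p$genes, "genes"),
       islands = read_bed(p$islands, "islands"),
       gmt = if (!is.null(p$gmt)) read_gmt(p$gmt))
}

# deterministic GMT over the simulated genes, for the enrich stage
write_sim_gmt <- function(genes, path, seed, n_sets = 8L) {
  with_seed(seed + 3L, {
    ids <- genes$gene_id
    lines <- vapply(seq_len(n_sets), function(i) {
      k <- max(2L, min(length(ids), stats::rbinom(1L, length(ids), 0.3)))
      paste(c(sprintf("SET%02d", i), "simulated gene set",
              sort(sample(ids, k))), collapse = "\t")
    }, "")
    writeLines(lines, path)
  })
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Chains the requested stages; each writes its artifacts under
#' `cfg$outdir` and the combined run summary lands in
#' `run_summary.json`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param cfg a [run_config()], or the path to a YAML file for
#'   [read_run_config()].
#' @param stages character vector of stages, or `"all"`; known stages
#'   are `simulate`, `qc`, `regress`, `swan`, `dmr`, `annotate`,
#'   `enrich`, `overlap`.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(cfg = run_config(), stages = "all") {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  all_stages <- c("simulate", "qc", "regress", "swan", "dmr",
                  "annotate", "enrich", "overlap")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  summary <- list(seed = cfg$seed,
                  package_version =
                    as.character(utils::packageVersion("methylaging")),
                  stages = stages)

  if ("simulate" %in% stages) {
    scfg <- do.call(sim_config, utils::modifyList(
      list(seed = cfg$seed), as.list(cfg$sim)))
    simdir <- file.path(cfg$outdir, "sim")
    out$sim <- simulate_study(scfg, simdir)
    write_sim_gmt(out$sim$genome$genes,
                  file.path(simdir, "gene_sets.gmt"), cfg$seed)
    cfg$paths <- list(reports = simdir,
                      metadata = file.path(simdir, "metadata.tsv"),
                      genes = file.path(simdir, "genes.bed"),
                      islands = file.path(simdir, "islands.bed"),
                      gmt = file.path(simdir, "gene_sets.gmt"))
    summary$sim <- list(n_subjects = scfg$n_subjects,
                        n_loci = nrow(out$sim$dataset$loci))
  }

  inp <- pipeline_inputs(cfg)
  ds <- inp$dataset
  spike <- ds$loci$chrom == "lambda"
  ds_main <- if (any(spike)) ds[!spike, ] else ds

  if ("qc" %in% stages) {
    qc <- qc_report(ds, policies = unique(unlist(cfg$coverage)),
                    spike_contig = if (any(spike)) "lambda")
    write.table(qc, file.path(cfg$outdir, "qc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$qc <- qc
  }

  sw_cfg <- do.call(swan_config, as.list(cfg$swan))
  sp <- do.call(smooth_params, as.list(cfg$smooth))
  tp <- do.call(tstat_params, as.list(cfg$tstat))

  if (any(c("regress", "swan", "overlap", "annotate", "enrich")
          %in% stages)) {
    ds10 <- filter_coverage(ds_main, cfg$coverage$regression)
    pct <- percent_methylation(ds10)
  }
  if (any(c("regress", "annotate", "enrich", "overlap") %in% stages)) {
    out$admp <- fit_admp(pct, inp$meta, cfg$covariates, cfg$alpha,
                         loci = ds10$loci)
    write_admp(out$admp, file.path(cfg$outdir, "admp.tsv"))
  }
  if (any(c("swan", "overlap") %in% stages)) {
    rownames(pct) <- locus_key(ds10$loci$chrom, ds10$loci$pos)
    out$swan <- swan_profile(pct, inp$meta$age, sw_cfg, inp$meta)
    write.table(out$swan$profile,
                file.path(cfg$outdir, "swan_profile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(as.character(out$swan$union_set),
               file.path(cfg$outdir, "swan_union_set.tsv"))
  }
  if (any(c("dmr", "annotate", "overlap") %in% stages)) {
    ds2 <- filter_coverage(ds_main, cfg$coverage$dmr)
    out$dmr <- dmr_analysis(ds2, inp$meta, cfg$old_threshold_age,
                            sp, tp, cfg$inclusive)
    write_dmrs(out$dmr, file.path(cfg$outdir, "dmrs.tsv"))
    write_t_track(out$dmr, file.path(cfg$outdir, "t_track.bedgraph"))
  }

  if ("annotate" %in% stages) {
    sig <- out$admp[which(out$admp$significant), c("chrom", "pos")]
    admp_links <- link_genes(sig, inp$genes, cfg$max_link_dist)
    dmr_links <- link_genes(out$dmr$regions, inp$genes,
                            cfg$max_link_dist)
    ctx <- classify_island_context(out$dmr$regions, inp$islands)
    write.table(admp_links, file.path(cfg$outdir, "admp_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(dmr_links, file.path(cfg$outdir, "dmr_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(out$dmr$regions, ctx),
                file.path(cfg$outdir, "dmr_island_context.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$annotate <- list(admp_links = admp_links,
                         dmr_links = dmr_links, island_context = ctx)
    summary$intragenic <- list(
      admp = intragenic_fraction(admp_links)[c("n_intragenic",
                                               "n_features",
                                               "percent")],
      dmr = intragenic_fraction(dmr_links)[c("n_intragenic",
                                             "n_features", "percent")])
  }

  if ("enrich" %in% stages) {
    if (is.null(inp$gmt))
      stop("enrich stage needs paths$gmt", call. = FALSE)
    sig <- out$admp[which(out$admp$significant), c("chrom", "pos")]
    links <- link_genes(sig, inp$genes, cfg$max_link_dist)
    selected <- unique(links$gene_id[!is.na(links$gene_id)])
    out$enrich <- ora_hypergeometric(selected, inp$genes$gene_id,
                                     inp$gmt)
    write.table(out$enrich, file.path(cfg$outdir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("overlap" %in% stages) {
    admp_keys <- locus_key(out$admp$chrom, out$admp$pos)[
      which(out$admp$significant)]
    venn <- overlap_analyses(admp_keys, out$swan$union_set,
                             dmr_cpg_set(ds2$loci, out$dmr))
    jsonlite::write_json(as.list(venn),
                         file.path(cfg$outdir, "venn.json"),
                         auto_unbox = TRUE)
    out$venn <- venn
    summary$venn <- as.list(venn)
  }

  if (!is.null(out$admp))
    summary$n_admp <- sum(out$admp$significant)
  if (!is.null(out$dmr))
    summary$n_dmr <- nrow(out$dmr$regions)
  if (!is.null(out$swan))
    summary$swan_peak_center <- out$swan$profile$center[
      which.max(out$swan$profile$n_significant)]
  summary$params <- list(coverage = cfg$coverage,
                         covariates = cfg$covariates,
                         alpha = cfg$alpha,
                         old_threshold_age = cfg$old_threshold_age,
                         swan = unclass(sw_cfg),
                         smooth = unclass(sp), tstat = unclass(tp))
  jsonlite::write_json(summary,
                       file.path(cfg$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
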