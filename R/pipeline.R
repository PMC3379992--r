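PIPELINE_KEYS <- c(
  "sg_fasta", "wb_fasta", "sg_reads", "wb_reads", "terms", "topology_sp",
  "topology_tm", "ct", "homolog_hits", "outdir", "min_identity",
  "min_overlap", "fdr", "lfc", "enrich_p", "e_cut", "max_mismatches",
  "reference_gene", "seed"
)

PIPELINE_DEFAULTS <- list(
  min_identity = 0.99, min_overlap = 150L, fdr = 1e-3, lfc = 1,
  enrich_p = 5e-3, e_cut = 1e-5, max_mismatches = 0L, seed = 1L
)

#' Read and validate a pipeline configuration
#'
#' A flat YAML file of `key: value` pairs. Required keys: `sg_fasta`,
#' `wb_fasta`, `sg_reads`, `wb_reads`, `outdir`. Optional inputs: `terms`,
#' `topology_sp` + `topology_tm`, `ct`, `homolog_hits`, `reference_gene`.
#' Thresholds (with their defaults): `min_identity` 0.99, `min_overlap`
#' 150, `fdr` 1e-3, `lfc` 1, `enrich_p` 5e-3, `e_cut` 1e-5,
#' `max_mismatches` 0; plus `seed`. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg A named list of configuration values.
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  required <- c("sg_fasta", "wb_fasta", "sg_reads", "wb_reads", "outdir")
  missing_keys <- setdiff(required, names(cfg))
  if (length(missing_keys)) {
    stop("missing config key(s): ", paste(missing_keys, collapse = ", "))
  }
  cfg <- modifyList(PIPELINE_DEFAULTS, cfg)
  if (cfg$min_identity <= 0 || cfg$min_identity > 1) {
    stop("min_identity must be in (0, 1]")
  }
  if (cfg$min_overlap < 1) stop("min_overlap must be positive")
  for (k in c("fdr", "enrich_p", "e_cut")) {
    if (cfg[[k]] <= 0 || cfg[[k]] > 1) stop(k, " must be in (0, 1]")
  }
  if (cfg$lfc < 0) stop("lfc must be nonnegative")
  cfg
}

# internal: run one stage with a named error context
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparative pipeline
#'
#' Stages, in order: ortholog pairing, region clipping, read counting +
#' RPKM, Audic-Claverie differential-expression calling, term enrichment
#' of the up-regulated set (when `terms` is configured), secretome triage
#' (when topology files are configured), homolog screening (when
#' `homolog_hits` is configured), and qPCR concordance (when `ct` is
#' configured). Each stage writes its TSV into `outdir` and the returned
#' report aggregates the headline counts.
#'
#' @param config A config list from [read_pipeline_config()] /
#'   [validate_pipeline_config()], or a path to a YAML config.
#' @return A `glandscope_report` list: per-stage record counts plus the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  for (k in c("sg_fasta", "wb_fasta", "sg_reads", "wb_reads", "terms",
              "topology_sp", "topology_tm", "ct", "homolog_hits")) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("pipeline stage '", stage_of_input(k), "': input not found: ",
           config[[k]])
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(outdir = config$outdir, thresholds = config[
    c("min_identity", "min_overlap", "fdr", "lfc", "enrich_p", "e_cut")])

  sg <- run_stage("pair", load_transcripts(config$sg_fasta))
  wb <- run_stage("pair", load_transcripts(config$wb_fasta))
  message("pair: ", length(sg), " SG and ", length(wb), " WB transcripts")
  pairs <- run_stage("pair", find_ortholog_pairs(
    sg, wb, min_identity = config$min_identity,
    min_overlap = config$min_overlap))
  write_pairs_tsv(pairs, out("pairs.tsv"))
  regions <- run_stage("pair", clip_overlaps(pairs, sg, wb))
  write_regions_fasta(regions, out("regions.fasta"))
  report$n_sg <- length(sg)
  report$n_wb <- length(wb)
  report$n_pairs <- nrow(pairs)
  message("pair: ", nrow(pairs), " ortholog pairs accepted")

  sg_reads <- run_stage("quantify", load_reads(config$sg_reads))
  wb_reads <- run_stage("quantify", load_reads(config$wb_reads))
  quant <- run_stage("quantify", quantify_regions(
    regions, sg_reads, wb_reads, max_mismatches = config$max_mismatches))
  write_counts_tsv(quant$counts, out("counts.tsv"))
  report$n_reads_sg <- length(sg_reads)
  report$n_reads_wb <- length(wb_reads)
  report$n1 <- quant$n1
  report$n2 <- quant$n2
  report$mapping_sg <- quant$summary_sg
  report$mapping_wb <- quant$summary_wb
  message("quantify: ", quant$n1, " / ", quant$n2,
          " reads mapped (SG / WB)")

  de <- run_stage("de", call_de(quant$counts, quant$n1, quant$n2,
                                fdr_cut = config$fdr,
                                lfc_cut = config$lfc))
  de$sg_id <- pairs$sg_id[match(de$pair_id, pairs$pair_id)]
  de$wb_id <- pairs$wb_id[match(de$pair_id, pairs$pair_id)]
  write_de_tsv(de, out("de.tsv"))
  report$de_total <- sum(de$call != "not_de")
  report$de_higher <- sum(de$call == "higher_in_sg")
  report$de_lower <- sum(de$call == "lower_in_sg")
  message("de: ", report$de_total, " differentially expressed (",
          report$de_higher, " higher / ", report$de_lower, " lower in SG)")

  if (!is.null(config$terms)) {
    assignments <- run_stage("enrich", read_term_assignments(config$terms))
    study <- de$wb_id[de$call == "higher_in_sg"]
    background <- de$wb_id
    enr <- run_stage("enrich", run_enrichment(
      study, background, assignments, p_cut = config$enrich_p))
    write_enrichment_tsv(enr, out("enrichment.tsv"))
    report$n_terms_tested <- nrow(enr)
    report$n_terms_enriched <- sum(enr$enriched)
    message("enrich: ", sum(enr$enriched), " of ", nrow(enr),
            " terms enriched at p <= ", config$enrich_p)
  }

  if (!is.null(config$topology_sp) && !is.null(config$topology_tm)) {
    topo <- run_stage("secretome", load_topology(config$topology_sp,
                                                 config$topology_tm))
    cds_list <- run_stage("secretome", {
      lst <- lapply(topo$sp$gene_id, function(g) {
        if (!g %in% names(sg)) return(NULL)
        extract_cds(sg[g])
      })
      lst[!vapply(lst, is.null, logical(1))]
    })
    verdicts <- run_stage("secretome",
                          classify_secretion_batch(cds_list, topo))
    write.table(verdicts, out("secretome.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$n_cds <- length(cds_list)
    report$n_sp_positive <- sum(verdicts$verdict %in%
                                  c("secreted", "membrane_anchored"))
    report$n_tm_removed <- sum(verdicts$verdict == "membrane_anchored")
    report$n_secreted <- sum(verdicts$verdict == "secreted")
    report$n_incomplete_5p <- sum(verdicts$verdict == "incomplete_5p")
    message("secretome: ", report$n_secreted, " secreted of ",
            report$n_sp_positive, " signal-positive (",
            report$n_tm_removed, " removed by extra TM)")
  }

  if (!is.null(config$homolog_hits)) {
    hits <- run_stage("homologs", read_blast_tab(config$homolog_hits))
    best <- run_stage("homologs", filter_homologs(hits,
                                                  e_cut = config$e_cut))
    write.table(best, out("homologs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report$n_homologs <- nrow(best)
    message("homologs: ", nrow(best), " queries with a hit at E <= ",
            config$e_cut)
  }

  if (!is.null(config$ct)) {
    ct <- run_stage("qpcr", read_ct_table(config$ct))
    fc <- run_stage("qpcr", qpcr_fold_changes(
      ct, reference_gene = config$reference_gene))
    de_key <- de
    de_key$gene_id <- de_key$sg_id
    conc <- run_stage("qpcr", qpcr_concordance(fc, de_key,
                                               on_missing = "drop"))
    write_qpcr_tsv(conc, out("qpcr.tsv"))
    report$qpcr_n <- conc$n
    report$qpcr_concordant <- conc$n_concordant
    message("qpcr: ", conc$n_concordant, " of ", conc$n,
            " genes direction-concordant")
  }

  class(report) <- "glandscope_report"
  report
}

stage_of_input <- function(key) {
  switch(key,
         sg_fasta = , wb_fasta = "pair",
         sg_reads = , wb_reads = "quantify",
         terms = "enrich",
         topology_sp = , topology_tm = "secretome",
         homolog_hits = "homologs",
         ct = "qpcr", key)
}

#' @export
print.glandscope_report <- function(x, ...) {
  cat("glandscope pipeline report\n")
  cat("  transcripts:      ", x$n_sg, "SG /", x$n_wb, "WB\n")
  cat("  ortholog pairs:   ", x$n_pairs, "\n")
  if (!is.null(x$n1)) {
    cat("  mapped reads:     ", x$n1, "SG /", x$n2, "WB\n")
  }
  if (!is.null(x$de_total)) {
    cat("  DE genes:         ", x$de_total, "(", x$de_higher, "higher /",
        x$de_lower, "lower in SG )\n")
  }
  if (!is.null(x$n_terms_enriched)) {
    cat("  enriched terms:   ", x$n_terms_enriched, "of",
        x$n_terms_tested, "\n")
  }
  if (!is.null(x$n_secreted)) {
    cat("  secretome:        ", x$n_secreted, "secreted,",
        x$n_tm_removed, "membrane-anchored,", x$n_incomplete_5p,
        "5'-incomplete\n")
  }
  if (!is.null(x$qpcr_n)) {
    cat("  qPCR concordance: ", x$qpcr_concordant, "of", x$qpcr_n, "\n")
  }
  invisible(x)
}
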