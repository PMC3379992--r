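# internal: random DNA of given lengths, named
random_seqs <- function(ids, lens) {
  out <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  setNames(out, ids)
}

# internal: substitute each base independently at `rate` to a *different*
# base, so the realized mismatch count is Binomial(length, rate)
mutate_seq <- function(seq, rate) {
  L <- nchar(seq)
  nmut <- rbinom(1L, L, rate)
  if (nmut == 0L) return(list(seq = seq, n_mut = 0L))
  pos <- sample.int(L, nmut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_mut = nmut)
}

# internal: shifted log-normal gene lengths with the requested mean;
# sd = 0 gives fixed lengths
gene_lengths <- function(n, length_mean, length_sdlog = 0.6) {
  if (length_sdlog == 0) return(rep(as.integer(length_mean), n))
  meanlog <- log(length_mean - 150) - length_sdlog^2 / 2
  pmax(150L, as.integer(round(150 + rlnorm(n, meanlog, length_sdlog))))
}

#' Simulate a pair of transcriptome assemblies with shared orthologs
#'
#' Shared genes occur in both assemblies and differ by independent
#' per-base substitutions at `mutation_rate` (substitutions always change
#' the base, so the mismatch count of a shared pair is exactly
#' Binomial(length, rate)); unique genes are unrelated random sequences.
#' Gene lengths follow a shifted log-normal (minimum 150 bases) with the
#' requested mean, or are fixed when `length_sdlog = 0`.
#'
#' @param n_shared Number of shared (ortholog) genes.
#' @param n_unique_each Unrelated genes added to each assembly.
#' @param length_mean Mean gene length in bases (default 300).
#' @param length_sdlog Log-scale sd of the length distribution (0 = fixed).
#' @param mutation_rate Per-base substitution rate between orthologs
#'   (default 0.003).
#' @param seed Random seed (required).
#' @return List with named character vectors `sg` and `wb` and a `truth`
#'   data.frame (`sg_id`, `wb_id`, `shared`, `len_sg`, `len_wb`, `n_mut`).
#' @export
simulate_transcriptomes <- function(n_shared, n_unique_each,
                                    length_mean = 300, length_sdlog = 0.6,
                                    mutation_rate = 0.003, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_shared >= 0, n_unique_each >= 0, mutation_rate >= 0,
            mutation_rate < 1)
  set.seed(seed)
  lens <- gene_lengths(n_shared, length_mean, length_sdlog)
  sg_ids <- sprintf("SG_sh%05d", seq_len(n_shared))
  wb_ids <- sprintf("WB_sh%05d", seq_len(n_shared))
  wb_shared <- random_seqs(wb_ids, lens)
  sg_shared <- character(n_shared)
  n_mut <- integer(n_shared)
  for (i in seq_len(n_shared)) {
    mu <- mutate_seq(wb_shared[[i]], mutation_rate)
    sg_shared[i] <- mu$seq
    n_mut[i] <- mu$n_mut
  }
  names(sg_shared) <- sg_ids
  u_lens_sg <- gene_lengths(n_unique_each, length_mean, length_sdlog)
  u_lens_wb <- gene_lengths(n_unique_each, length_mean, length_sdlog)
  sg_unique <- random_seqs(sprintf("SG_un%05d", seq_len(n_unique_each)),
                          u_lens_sg)
  wb_unique <- random_seqs(sprintf("WB_un%05d", seq_len(n_unique_each)),
                          u_lens_wb)
  truth <- data.frame(
    sg_id = c(sg_ids, names(sg_unique), rep(NA_character_, n_unique_each)),
    wb_id = c(wb_ids, rep(NA_character_, n_unique_each), names(wb_unique)),
    shared = c(rep(TRUE, n_shared), rep(FALSE, 2L * n_unique_each)),
    len_sg = c(lens, u_lens_sg, rep(NA_integer_, n_unique_each)),
    len_wb = c(lens, rep(NA_integer_, n_unique_each), u_lens_wb),
    n_mut = c(n_mut, rep(NA_integer_, 2L * n_unique_each)),
    stringsAsFactors = FALSE
  )
  list(sg = c(sg_shared, sg_unique), wb = c(wb_shared, wb_unique),
       truth = truth)
}

#' Simulate an error-free read library from known expression
#'
#' Reads are drawn from genes with probability proportional to
#' `expression * (length - read_len + 1)` (i.e. to expression times the
#' number of possible start positions), uniform start positions, and
#' uniform strand. Genes shorter than the read length produce no reads. An
#' optional substitution error rate is available for stress testing.
#'
#' @param transcriptome Named character vector of gene sequences.
#' @param expression Nonnegative expression values, named by gene or in
#'   `transcriptome` order.
#' @param depth Total number of reads to draw.
#' @param read_len Read length in bases (default 90).
#' @param seed Random seed (required; output is byte-reproducible).
#' @param error_rate Per-base substitution error rate (default 0).
#' @return Named character vector of reads (`rd0000001`, ...), with
#'   attribute `source_gene` giving each read's gene of origin.
#' @export
simulate_reads <- function(transcriptome, expression, depth, read_len = 90L,
                           seed, error_rate = 0) {
  if (missing(seed)) stop("seed is required")
  if (is.null(names(expression))) {
    names(expression) <- names(transcriptome)
  }
  expression <- expression[names(transcriptome)]
  expression[is.na(expression)] <- 0
  if (any(expression < 0)) stop("expression must be nonnegative")
  lens <- nchar(transcriptome)
  if (all(lens < read_len)) {
    stop("read_len (", read_len, ") exceeds every transcript length")
  }
  w <- expression * pmax(lens - read_len + 1L, 0L)
  if (sum(w) == 0) stop("expression must not be all zero on usable genes")
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1L, depth, w))
  gene_idx <- rep(seq_along(transcriptome), counts)
  nstart <- lens[gene_idx] - read_len + 1L
  starts <- 1L + as.integer(floor(runif(depth) * nstart))
  fwd <- runif(depth) < 0.5
  reads <- substring(transcriptome[gene_idx], starts,
                     starts + read_len - 1L)
  reads[!fwd] <- revcomp_chr(reads[!fwd])
  if (error_rate > 0) {
    for (i in seq_along(reads)) {
      mu <- mutate_seq(reads[i], error_rate)
      reads[i] <- mu$seq
    }
  }
  names(reads) <- sprintf("rd%07d", seq_along(reads))
  attr(reads, "source_gene") <- names(transcriptome)[gene_idx]
  reads
}

#' Write reads as FASTQ (constant quality)
#' @param reads Named character vector from [simulate_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(L) {
    paste(rep("I", L), collapse = "")
  }, character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate term assignments and topology predictions
#'
#' Annotations attach to background (WB) gene ids: every shared gene draws
#' `terms_per_gene` terms uniformly from the universe, and each planted
#' term is additionally assigned to planted-up-regulated genes
#' (`de_log2 > 0` in `truth`) at rate `planted_rate`, so planted terms are
#' over-represented in the up-regulated set by construction. Topology
#' attaches to study (SG) gene ids: secreted-labelled genes get a signal
#' peptide with cleavage position uniform in `cleavage_range` and no
#' transmembrane segment; exactly `round(extra_tm_fraction * k)` of the
#' `k` signal-positive genes get one extra transmembrane segment beyond
#' the signal peptide (exercising the membrane-anchored removal path).
#'
#' @param truth Data.frame with at least `sg_id`, `wb_id`, `shared`,
#'   `de_log2` (see [simulate_scenario()]).
#' @param n_terms Size of the term universe.
#' @param n_planted_terms Number of planted (enriched) terms.
#' @param terms_per_gene Uniform background assignments per gene.
#' @param planted_rate Assignment rate of planted terms among up-regulated
#'   genes.
#' @param secreted_fraction Fraction of shared genes labelled secreted.
#' @param extra_tm_fraction Fraction of signal-positive genes given an
#'   extra transmembrane segment (default 61/356, the canonical removal
#'   proportion of this triage).
#' @param cleavage_range Integer range for cleavage positions.
#' @param seed Random seed (required).
#' @return List with `assignments` (gene_id/term_id/namespace),
#'   `topology` (a topology object), `planted_terms`, and `truth` with
#'   added columns `secreted`, `extra_tm`.
#' @export
simulate_annotations_and_topology <- function(truth, n_terms = 40L,
                                              n_planted_terms = 4L,
                                              terms_per_gene = 2L,
                                              planted_rate = 0.6,
                                              secreted_fraction = 0.1,
                                              extra_tm_fraction = 61 / 356,
                                              cleavage_range = 16:30,
                                              seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  terms <- sprintf("term%03d", seq_len(n_terms))
  planted <- terms[seq_len(n_planted_terms)]
  shared <- truth[truth$shared, , drop = FALSE]
  genes <- shared$wb_id
  assignments <- data.frame(
    gene_id = rep(genes, each = terms_per_gene),
    term_id = unlist(lapply(genes, function(g) sample(terms, terms_per_gene))),
    stringsAsFactors = FALSE
  )
  up <- shared$wb_id[shared$de_log2 > 0]
  extra <- up[runif(length(up)) < planted_rate]
  if (length(extra)) {
    assignments <- rbind(assignments, data.frame(
      gene_id = rep(extra, times = length(planted)),
      term_id = rep(planted, each = length(extra)),
      stringsAsFactors = FALSE
    ))
  }
  assignments$namespace <- "molecular_function"
  assignments <- assignments[!duplicated(assignments[c("gene_id", "term_id")]),
                             , drop = FALSE]
  rownames(assignments) <- NULL
  # topology over SG gene ids
  sg_genes <- shared$sg_id
  n_secreted <- round(secreted_fraction * length(sg_genes))
  secreted_ids <- sample(sg_genes, n_secreted)
  n_tm <- round(extra_tm_fraction * n_secreted)
  tm_ids <- if (n_tm > 0L) sample(secreted_ids, n_tm) else character()
  sp <- data.frame(
    gene_id = sg_genes,
    sp_present = sg_genes %in% secreted_ids,
    cleavage_pos = 0L,
    stringsAsFactors = FALSE
  )
  sp$cleavage_pos[sp$sp_present] <-
    sample(cleavage_range, sum(sp$sp_present), replace = TRUE)
  tm <- data.frame(gene_id = character(), tm_start = integer(),
                   tm_end = integer(), stringsAsFactors = FALSE)
  for (g in tm_ids) {
    cl <- sp$cleavage_pos[sp$gene_id == g]
    tm[nrow(tm) + 1L, ] <- list(g, cl + 10L, cl + 28L)
  }
  truth$secreted <- FALSE
  truth$extra_tm <- FALSE
  truth$secreted[match(secreted_ids, truth$sg_id)] <- TRUE
  truth$extra_tm[match(tm_ids, truth$sg_id)] <- TRUE
  list(
    assignments = assignments,
    topology = structure(list(sp = sp, tm = tm),
                         class = "glandscope_topology"),
    planted_terms = planted,
    truth = truth
  )
}

#' Simulate a qPCR Ct table from known expression
#'
#' `Ct = intercept - log2(expression) + Normal(0, sigma)` per replicate,
#' both tissues, for the selected target genes plus a stable reference
#' gene.
#'
#' @param expression Data.frame `gene_id`, `expr_sg`, `expr_wb`.
#' @param genes Target gene ids (subset of `expression$gene_id`).
#' @param reference_gene Reference gene id (also in `expression`).
#' @param intercept Ct of one expression unit (default 35 cycles).
#' @param sigma Replicate noise sd in cycles (default 0.2).
#' @param n_rep Replicates per gene and tissue (default 3).
#' @param seed Random seed (required).
#' @return Data.frame in the canonical Ct-table layout (see
#'   [read_ct_table()]).
#' @export
simulate_qpcr <- function(expression, genes, reference_gene,
                          intercept = 35, sigma = 0.2, n_rep = 3L, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  all_genes <- c(genes, reference_gene)
  idx <- match(all_genes, expression$gene_id)
  if (any(is.na(idx))) {
    stop("gene(s) missing from expression table: ",
         paste(all_genes[is.na(idx)], collapse = ", "))
  }
  ex <- expression[idx, , drop = FALSE]
  if (any(ex$expr_sg <= 0) || any(ex$expr_wb <= 0)) {
    bad <- ex$gene_id[ex$expr_sg <= 0 | ex$expr_wb <= 0]
    stop("zero expression for qPCR gene(s): ", paste(bad, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    for (tis in c("SG", "WB")) {
      e <- if (tis == "SG") ex$expr_sg[i] else ex$expr_wb[i]
      ct <- intercept - log2(e) + rnorm(n_rep, 0, sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ex$gene_id[i], tissue = tis,
        role = if (ex$gene_id[i] == reference_gene) "reference" else "target",
        t(setNames(ct, paste0("ct_rep", seq_len(n_rep)))),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate the default end-to-end scenario
#'
#' Generates the full set of pipeline inputs with known ground truth: two
#' assemblies with `n_shared` orthologs and `n_unique_each` unrelated genes
#' per side, log-normal baseline expression, `n_de` planted differentially
#' expressed genes at `fold`-fold (half up, half down in the study tissue),
#' two error-free 90 bp read libraries of `depth` reads each, term
#' assignments with planted enriched terms, topology with planted secreted
#' proteins, and a Ct table for `n_qpcr` genes plus a stable reference
#' gene.
#'
#' @param seed Random seed (required; drives every generator).
#' @param n_shared,n_unique_each,n_de,fold,depth,read_len,mutation_rate
#'   Scenario parameters (defaults: 2000 shared, 250 unique per side, 200
#'   DE at 4-fold, 500k reads per library, 90 bp, substitution rate 0.003).
#' @param length_mean,length_sdlog Gene-length distribution.
#' @param n_qpcr Number of qPCR target genes (default 20).
#' @param outdir Optional directory: when given, all inputs are written
#'   (`sg.fasta`, `wb.fasta`, `sg.fastq`, `wb.fastq`, `terms.tsv`,
#'   `topology_sp.tsv`, `topology_tm.tsv`, `ct.tsv`, `truth.tsv`).
#' @param ... Passed to [simulate_annotations_and_topology()].
#' @return List with `sg`, `wb` (sequences), `sg_reads`, `wb_reads`,
#'   `assignments`, `topology`, `planted_terms`, `ct`, `truth`,
#'   `reference_gene`, `qpcr_genes`, and the scenario `params`.
#' @export
simulate_scenario <- function(seed, n_shared = 2000L, n_unique_each = 250L,
                              n_de = 200L, fold = 4, depth = 500000L,
                              read_len = 90L, mutation_rate = 0.003,
                              length_mean = 300, length_sdlog = 0.6,
                              n_qpcr = 20L, outdir = NULL, ...) {
  if (missing(seed)) stop("seed is required")
  tr <- simulate_transcriptomes(n_shared, n_unique_each,
                                length_mean = length_mean,
                                length_sdlog = length_sdlog,
                                mutation_rate = mutation_rate, seed = seed)
  truth <- tr$truth
  set.seed(seed + 1L)
  base_shared <- rlnorm(n_shared, 0, 1)
  de_idx <- sample.int(n_shared, n_de)
  up_idx <- de_idx[seq_len(n_de %/% 2L)]
  dn_idx <- setdiff(de_idx, up_idx)
  expr_sg_shared <- base_shared
  expr_sg_shared[up_idx] <- base_shared[up_idx] * fold
  expr_sg_shared[dn_idx] <- base_shared[dn_idx] / fold
  expr_wb_shared <- base_shared
  expr_sg <- setNames(c(expr_sg_shared, rlnorm(n_unique_each, 0, 1)),
                      names(tr$sg))
  expr_wb <- setNames(c(expr_wb_shared, rlnorm(n_unique_each, 0, 1)),
                      names(tr$wb))
  de_log2 <- numeric(nrow(truth))
  de_log2[truth$shared] <- log2(expr_sg_shared / expr_wb_shared)
  truth$de_log2 <- de_log2
  truth$expr_sg <- expr_sg[truth$sg_id]
  truth$expr_wb <- expr_wb[truth$wb_id]
  # exact expected read counts per gene under the sampling model
  w_sg <- expr_sg * pmax(nchar(tr$sg) - read_len + 1L, 0L)
  w_wb <- expr_wb * pmax(nchar(tr$wb) - read_len + 1L, 0L)
  truth$expected_sg <- (depth * w_sg / sum(w_sg))[truth$sg_id]
  truth$expected_wb <- (depth * w_wb / sum(w_wb))[truth$wb_id]
  sg_reads <- simulate_reads(tr$sg, expr_sg, depth, read_len,
                             seed = seed + 2L)
  wb_reads <- simulate_reads(tr$wb, expr_wb, depth, read_len,
                             seed = seed + 3L)
  ann <- simulate_annotations_and_topology(truth, seed = seed + 4L, ...)
  truth <- ann$truth
  # qPCR targets: planted DE genes (up and down) topped up with nulls
  shared_truth <- truth[truth$shared, , drop = FALSE]
  de_genes <- shared_truth$sg_id[shared_truth$de_log2 != 0]
  null_genes <- shared_truth$sg_id[shared_truth$de_log2 == 0]
  # reference: the highest-expressed null gene (stable across tissues),
  # kept out of the target pool
  ref_gene <- null_genes[which.max(shared_truth$expr_sg[
    match(null_genes, shared_truth$sg_id)])]
  null_pool <- setdiff(null_genes, ref_gene)
  set.seed(seed + 5L)
  n_from_de <- min(length(de_genes), max(0L, n_qpcr - 4L))
  qpcr_genes <- c(sample(de_genes, n_from_de),
                  sample(null_pool, n_qpcr - n_from_de))
  expr_tab <- data.frame(gene_id = shared_truth$sg_id,
                         expr_sg = shared_truth$expr_sg,
                         expr_wb = shared_truth$expr_wb,
                         stringsAsFactors = FALSE)
  ct <- simulate_qpcr(expr_tab, qpcr_genes, ref_gene, seed = seed + 6L)
  out <- list(sg = tr$sg, wb = tr$wb, sg_reads = sg_reads,
              wb_reads = wb_reads, assignments = ann$assignments,
              topology = ann$topology, planted_terms = ann$planted_terms,
              ct = ct, truth = truth, reference_gene = ref_gene,
              qpcr_genes = qpcr_genes,
              params = list(seed = seed, n_shared = n_shared,
                            n_unique_each = n_unique_each, n_de = n_de,
                            fold = fold, depth = depth, read_len = read_len,
                            mutation_rate = mutation_rate))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$sg, file.path(outdir, "sg.fasta"))
    write_fasta(out$wb, file.path(outdir, "wb.fasta"))
    write_fastq(out$sg_reads, file.path(outdir, "sg.fastq"))
    write_fastq(out$wb_reads, file.path(outdir, "wb.fastq"))
    write.table(out$assignments, file.path(outdir, "terms.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sp_out <- out$topology$sp
    sp_out$sp_present <- ifelse(sp_out$sp_present, "Y", "N")
    write.table(sp_out, file.path(outdir, "topology_sp.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$topology$tm, file.path(outdir, "topology_tm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$ct, file.path(outdir, "ct.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
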