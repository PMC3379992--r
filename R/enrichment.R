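#' Upper-tail hypergeometric probability for term enrichment
#'
#' Probability of observing at least `m` study genes annotated to a term,
#' when `n` study genes are drawn from a background of `N` annotated genes
#' of which `M` carry the term:
#' \deqn{P(X \ge m) = 1 - \sum_{i<m} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' Evaluated with [stats::phyper] (log-gamma based, numerically stable far
#' into the tail).
#'
#' @param N Background genes with at least one annotation.
#' @param n Study genes with at least one annotation.
#' @param M Background genes annotated to the term.
#' @param m Study genes annotated to the term.
#' @return `P(X >= m)`; vectorized.
#' @examples
#' hypergeom_upper_tail(N = 10, n = 5, M = 4, m = 3)  # 66/252
#' @export
hypergeom_upper_tail <- function(N, n, M, m) {
  if (any(m > n)) stop("m must not exceed n")
  if (any(m > M)) stop("m must not exceed M (term missing from background?)")
  if (any(M > N)) stop("M must not exceed N")
  if (any(n > N)) stop("n must not exceed N")
  if (any(c(N, n, M, m) < 0)) stop("all counts must be nonnegative")
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Read a term-assignment table
#'
#' Tab-separated `gene_id<TAB>term_id<TAB>namespace` (header optional,
#' detected). Duplicate (gene, term) rows are collapsed.
#'
#' @param path TSV path.
#' @return Data.frame `gene_id`, `term_id`, `namespace`.
#' @export
read_term_assignments <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^gene_id\\t", first)
  df <- read.table(path, header = has_header, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df) <- c("gene_id", "term_id", "namespace")[seq_len(ncol(df))]
  if (!"namespace" %in% names(df)) df$namespace <- NA_character_
  df[!duplicated(df[c("gene_id", "term_id")]), , drop = FALSE]
}

#' Term enrichment of a study gene set against a background
#'
#' Tests every term that occurs in the study set with the upper-tail
#' hypergeometric probability. Following the usual convention for
#' annotation-based enrichment, `N` and `n` count the background and study
#' genes that carry at least one annotation (in the tested namespace, if
#' `namespace` is given); genes without annotations do not enter the
#' universe. No multiple-testing correction is applied by default -- the
#' conventional raw cut-off (default 5e-3) flags enrichment; set
#' `adjust = TRUE` to add a BH-adjusted column and flag on it instead.
#'
#' @param study_genes,background_genes Character vectors of gene ids.
#' @param assignments Data.frame `gene_id`, `term_id`, `namespace` (e.g.
#'   from [read_term_assignments()]).
#' @param p_cut Enrichment cut-off on the p-value (default 5e-3).
#' @param namespace Optional: restrict to one namespace.
#' @param adjust Apply BH adjustment and flag on the adjusted value
#'   (default FALSE).
#' @return Data.frame sorted by p ascending: `term_id`, `namespace`, `m`,
#'   `n`, `M`, `N`, `p_value`, (`fdr` when `adjust`), `enriched`.
#' @export
run_enrichment <- function(study_genes, background_genes, assignments,
                           p_cut = 5e-3, namespace = NULL, adjust = FALSE) {
  if (!is.null(namespace)) {
    assignments <- assignments[assignments$namespace %in% namespace, ,
                               drop = FALSE]
  }
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  ann_genes <- unique(assignments$gene_id)
  bg_ann <- intersect(background_genes, ann_genes)
  st_ann <- intersect(study_genes, ann_genes)
  if (length(bg_ann) == 0L || length(st_ann) == 0L) {
    stop("study and background sets must be nonempty after intersecting ",
         "with annotated genes")
  }
  N <- length(bg_ann)
  n <- length(st_ann)
  a_bg <- assignments[assignments$gene_id %in% bg_ann, , drop = FALSE]
  a_st <- assignments[assignments$gene_id %in% st_ann, , drop = FALSE]
  m_tab <- table(a_st$term_id)
  M_tab <- table(a_bg$term_id)
  terms <- names(m_tab)  # only terms present in the study set are reported
  M <- as.integer(M_tab[terms])
  m <- as.integer(m_tab[terms])
  if (any(is.na(M)) || any(m > M)) {
    bad <- terms[is.na(M) | m > M]
    stop("term(s) present in the study set but under-represented in the ",
         "background (violates M >= m): ", paste(bad, collapse = ", "))
  }
  ns <- vapply(terms, function(tm) {
    u <- unique(assignments$namespace[assignments$term_id == tm])
    if (length(u) == 1L) u else NA_character_
  }, character(1))
  p <- hypergeom_upper_tail(N, n, M, m)
  out <- data.frame(term_id = terms, namespace = ns, m = m, n = n, M = M,
                    N = N, p_value = p, stringsAsFactors = FALSE)
  if (adjust) {
    out$fdr <- bh_fdr(out$p_value)
    out$enriched <- out$fdr <= p_cut
  } else {
    out$enriched <- out$p_value <= p_cut
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the enrichment table as TSV
#' @param enr Data.frame from [run_enrichment()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(enr, path) {
  write.table(enr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
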