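#' Relative expression by the 2^-ddCt method
#'
#' Replicate threshold cycles are averaged (arithmetic mean) per gene and
#' tissue, then
#' `dCt_tissue = mean(Ct_target) - mean(Ct_reference)` within each tissue,
#' `ddCt = dCt_sg - dCt_wb`, and `fold_change = 2^(-ddCt)`. Amplification
#' efficiency is taken as exactly 2 per cycle (no efficiency correction).
#'
#' @param ct_target_sg,ct_target_wb Numeric vectors of replicate Ct values
#'   for the target gene in the two tissues.
#' @param ct_ref_sg,ct_ref_wb Replicate Ct values for the reference gene.
#' @return A list with `ddct` and `fold_change`.
#' @examples
#' relative_expression(c(20.1, 20.0, 19.9), 25, 22, 22)$fold_change
#' @export
relative_expression <- function(ct_target_sg, ct_target_wb,
                                ct_ref_sg, ct_ref_wb) {
  for (v in list(ct_target_sg, ct_target_wb, ct_ref_sg, ct_ref_wb)) {
    if (length(v) == 0L) stop("replicate Ct lists must be nonempty")
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("Ct values must be positive and finite")
    }
  }
  dct_sg <- mean(ct_target_sg) - mean(ct_ref_sg)
  dct_wb <- mean(ct_target_wb) - mean(ct_ref_wb)
  ddct <- dct_sg - dct_wb
  list(ddct = ddct, fold_change = 2^(-ddct))
}

#' Reference-gene stability check on RPKM values
#'
#' A reference gene is acceptable when its expression is at the same level
#' in both libraries: `|log2(rpkm_a / rpkm_b)| < max_abs_log2`.
#'
#' @param rpkm_a,rpkm_b RPKM of the candidate reference gene in the two
#'   libraries.
#' @param max_abs_log2 Stability bound in log2 units (default 1).
#' @return List with `pass` and `abs_log2`.
#' @export
reference_gene_check <- function(rpkm_a, rpkm_b, max_abs_log2 = 1.0) {
  if (rpkm_a <= 0 || rpkm_b <= 0) stop("RPKM values must be positive")
  al <- abs(log2(rpkm_a / rpkm_b))
  list(pass = al < max_abs_log2, abs_log2 = al)
}

#' Direction concordance between qPCR and sequencing-based calls
#'
#' A gene is concordant when the sign of its qPCR log2 fold change equals
#' the sign of its RPKM log2 ratio. A zero on either side (fold change
#' exactly 1, or ratio exactly 0) is concordant with nothing.
#'
#' @param qpcr_fold Fold changes from [relative_expression()] (same gene
#'   order as `rpkm_log2`).
#' @param rpkm_log2 Log2 RPKM ratios from the differential-expression
#'   table.
#' @return List with `n`, `n_concordant`, and the per-gene logical
#'   `concordant`.
#' @export
direction_concordance <- function(qpcr_fold, rpkm_log2) {
  if (length(qpcr_fold) != length(rpkm_log2)) {
    stop("vectors must have equal length and the same gene order")
  }
  s1 <- sign(log2(qpcr_fold))
  s2 <- sign(rpkm_log2)
  conc <- s1 != 0 & s2 != 0 & s1 == s2
  list(n = length(conc), n_concordant = sum(conc), concordant = conc)
}

#' Read a Ct table
#'
#' Tab-separated with header
#' `gene_id tissue role ct_rep1 ct_rep2 ct_rep3` where `tissue` is `SG` or
#' `WB` and `role` is `target` or `reference`.
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_ct_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "tissue", "role")
  if (!all(need %in% names(df))) {
    stop("Ct table must have columns gene_id, tissue, role, ct_rep*")
  }
  if (!all(df$tissue %in% c("SG", "WB"))) stop("tissue must be SG or WB")
  if (!all(df$role %in% c("target", "reference"))) {
    stop("role must be target or reference")
  }
  df
}

#' Fold changes for all target genes of a Ct table
#'
#' Averages replicates, subtracts the reference gene within each tissue and
#' returns the 2^-ddCt fold change per target gene.
#'
#' @param ct Data.frame from [read_ct_table()].
#' @param reference_gene Gene id of the reference rows (defaults to the
#'   gene marked `role == "reference"`).
#' @return Data.frame `gene_id`, `ddct`, `fold_change`, `log2_fold`.
#' @export
qpcr_fold_changes <- function(ct, reference_gene = NULL) {
  rep_cols <- grep("^ct_rep", names(ct), value = TRUE)
  if (length(rep_cols) == 0L) stop("no ct_rep* columns found")
  if (is.null(reference_gene)) {
    reference_gene <- unique(ct$gene_id[ct$role == "reference"])
    if (length(reference_gene) != 1L) {
      stop("expected exactly one reference gene; found ",
           length(reference_gene))
    }
  }
  cts_of <- function(gene, tissue) {
    row <- ct[ct$gene_id == gene & ct$tissue == tissue, rep_cols,
              drop = FALSE]
    if (nrow(row) != 1L) {
      stop("expected one row for ", gene, " in ", tissue, "; found ",
           nrow(row))
    }
    v <- as.numeric(row[1L, ])
    v[!is.na(v)]
  }
  targets <- unique(ct$gene_id[ct$role == "target"])
  out <- data.frame(gene_id = targets, ddct = NA_real_,
                    fold_change = NA_real_, log2_fold = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    g <- targets[i]
    re <- relative_expression(cts_of(g, "SG"), cts_of(g, "WB"),
                              cts_of(reference_gene, "SG"),
                              cts_of(reference_gene, "WB"))
    out$ddct[i] <- re$ddct
    out$fold_change[i] <- re$fold_change
    out$log2_fold[i] <- -re$ddct
  }
  out
}

#' Score qPCR concordance against a differential-expression table
#'
#' Joins qPCR fold changes with the `log2_ratio` column of a [call_de()]
#' result (by gene/pair id) and scores direction concordance.
#'
#' @param qpcr Data.frame from [qpcr_fold_changes()].
#' @param de Data.frame from [call_de()]; matched on `pair_id` unless it
#'   has a `gene_id` column.
#' @param on_missing `"error"` (default) or `"drop"`: what to do with qPCR
#'   genes absent from the DE table (e.g. ortholog pair not recovered).
#' @return List with the joined data.frame (`table`) and the
#'   [direction_concordance()] summary.
#' @export
qpcr_concordance <- function(qpcr, de, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  key <- if ("gene_id" %in% names(de)) "gene_id" else "pair_id"
  idx <- match(qpcr$gene_id, de[[key]])
  if (any(is.na(idx))) {
    if (on_missing == "error") {
      stop("qPCR gene(s) missing from the DE table: ",
           paste(qpcr$gene_id[is.na(idx)], collapse = ", "))
    }
    message("qpcr: dropping ", sum(is.na(idx)),
            " gene(s) without a DE entry")
    qpcr <- qpcr[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  tab <- cbind(qpcr, rpkm_log2 = de$log2_ratio[idx])
  dc <- direction_concordance(tab$fold_change, tab$rpkm_log2)
  tab$concordant <- dc$concordant
  list(table = tab, n = dc$n, n_concordant = dc$n_concordant)
}

#' Write the qPCR concordance table as TSV
#' @param x Result of [qpcr_concordance()] or its `table`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_tsv <- function(x, path) {
  tab <- if (is.data.frame(x)) x else x$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
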