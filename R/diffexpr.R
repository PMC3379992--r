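#' Audic-Claverie p-value for two read counts
#'
#' Exact conditional test for a difference between counts `x` and `y` of the
#' same gene in two libraries of sizes `n1` and `n2`. Conditional on `x`,
#' the count in the second library follows
#' \deqn{p(y|x) = (n2/n1)^y \frac{(x+y)!}{x!\,y!\,(1+n2/n1)^{x+y+1}}}
#' which is a negative binomial with size `x + 1` and success probability
#' `n1/(n1+n2)`; tails are therefore evaluated exactly (in log space) with
#' [stats::pnbinom]. The one-sided p is the smaller inclusive tail
#' `min(P(Y <= y), P(Y >= y))`; the two-sided p doubles it and clamps at 1.
#'
#' Note the inclusive-tail convention makes the statistic only approximately
#' symmetric in the two libraries: the point mass at the observed pair
#' enters the two orientations differently, so their p-values agree in
#' magnitude but not exactly for small counts. The underlying tails obey an
#' exact duality, `P(Y <= y | x; n1, n2) + P(X <= x | y; n2, n1) = 1`.
#'
#' @param x,y Observed counts (vectors recycle).
#' @param n1,n2 Library sizes (total mapped reads).
#' @param sided `"two"` (default) or `"one"`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' ac_pvalue(5, 0, 1e6, 1e6)          # 0.03125
#' ac_pvalue(5, 0, 1e6, 1e6, "one")   # 0.015625
#' @export
ac_pvalue <- function(x, y, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (any(x < 0) || any(y < 0)) stop("counts must be nonnegative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  if (any(x != floor(x)) || any(y != floor(y))) {
    stop("counts must be integers")
  }
  prob <- n1 / (n1 + n2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- ifelse(y == 0, 1,
                  pnbinom(y - 1, size = x + 1, prob = prob,
                          lower.tail = FALSE))
  one <- pmin(lower, upper)
  if (sided == "one") one else pmin(1, 2 * one)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output order matches input order. A thin
#' validated wrapper around [stats::p.adjust].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call differential expression on a counts table
#'
#' Computes the two-sided Audic-Claverie p-value per pair, adjusts across
#' the whole set with [bh_fdr()], and calls each pair `higher_in_sg`
#' (`fdr < fdr_cut` and `log2_ratio >= lfc_cut`), `lower_in_sg`
#' (`fdr < fdr_cut` and `log2_ratio <= -lfc_cut`) or `not_de`. The log2
#' ratio is `log2(rpkm_sg / rpkm_wb)`. When exactly one RPKM is zero the
#' smallest nonzero RPKM in the table is substituted on the zero side and
#' the row is flagged (`ratio_flagged`); when both are zero the pair is
#' `not_de` with an `NA` ratio.
#'
#' @param counts Data.frame with columns `pair_id`, `count_sg`, `count_wb`,
#'   `rpkm_sg`, `rpkm_wb` (from [quantify_regions()]).
#' @param n1,n2 Library sizes (total mapped reads, SG and WB).
#' @param fdr_cut FDR threshold (default 1e-3).
#' @param lfc_cut Absolute log2-ratio threshold (default 1).
#' @return Data.frame with `pair_id`, `x`, `y`, `rpkm_sg`, `rpkm_wb`,
#'   `log2_ratio`, `p_value`, `fdr`, `call`, `ratio_flagged`.
#' @export
call_de <- function(counts, n1, n2, fdr_cut = 1e-3, lfc_cut = 1) {
  stopifnot(all(c("pair_id", "count_sg", "count_wb", "rpkm_sg", "rpkm_wb")
                %in% names(counts)))
  p <- ac_pvalue(counts$count_sg, counts$count_wb, n1, n2, sided = "two")
  fdr <- bh_fdr(p)
  a <- counts$rpkm_sg
  b <- counts$rpkm_wb
  flagged <- xor(a == 0, b == 0)
  floor_rpkm <- suppressWarnings(min(c(a[a > 0], b[b > 0])))
  a2 <- ifelse(a == 0 & b > 0, floor_rpkm, a)
  b2 <- ifelse(b == 0 & a > 0, floor_rpkm, b)
  log2_ratio <- ifelse(a == 0 & b == 0, NA_real_, log2(a2 / b2))
  call <- rep("not_de", nrow(counts))
  sig <- !is.na(log2_ratio) & fdr < fdr_cut
  call[sig & log2_ratio >= lfc_cut] <- "higher_in_sg"
  call[sig & log2_ratio <= -lfc_cut] <- "lower_in_sg"
  data.frame(
    pair_id = counts$pair_id,
    x = counts$count_sg, y = counts$count_wb,
    rpkm_sg = a, rpkm_wb = b,
    log2_ratio = log2_ratio,
    p_value = p, fdr = fdr, call = call,
    ratio_flagged = flagged,
    stringsAsFactors = FALSE
  )
}

#' Annotation rate of each differential-expression class
#'
#' For each call class, the number of pairs, the number whose gene id is in
#' the annotated set, and the percentage (one decimal, as conventionally
#' reported).
#'
#' @param calls Data.frame from [call_de()]; a column `gene_id` is used for
#'   the annotation lookup if present, else `pair_id`.
#' @param annotated_ids Character set of annotated gene ids.
#' @return Data.frame `call`, `n`, `n_annotated`, `percent` (NA when
#'   `n` is 0).
#' @export
annotation_rate <- function(calls, annotated_ids) {
  ids <- if ("gene_id" %in% names(calls)) calls$gene_id else calls$pair_id
  classes <- c("higher_in_sg", "lower_in_sg", "not_de")
  out <- data.frame(call = classes, n = 0L, n_annotated = 0L,
                    percent = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(classes)) {
    sel <- calls$call == classes[i]
    out$n[i] <- sum(sel)
    out$n_annotated[i] <- sum(ids[sel] %in% annotated_ids)
    if (out$n[i] > 0L) {
      out$percent[i] <- round(100 * out$n_annotated[i] / out$n[i], 1)
    }
  }
  out
}

#' Write / read the differential-expression table
#' @param de Data.frame from [call_de()].
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_de_tsv <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_tsv
#' @export
read_de_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
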