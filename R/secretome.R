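GENETIC_FRAMES <- c(1L, 2L, 3L, -1L, -2L, -3L)

# internal: translate one frame of a forward-strand sequence; returns the
# aa string (stops as '*'), with X for codons containing N. Vectorized
# standard-code lookup (much faster than per-sequence XString translation).
translate_frame <- function(seq, frame) {
  s <- if (frame > 0) seq else revcomp_chr(seq)
  f <- abs(frame)
  n_cod <- (nchar(s) - f + 1L) %/% 3L
  if (n_cod < 1L) return("")
  starts <- f + 3L * (seq_len(n_cod) - 1L)
  aa <- Biostrings::GENETIC_CODE[substring(s, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Extract the coding sequence of a transcript
#'
#' When BLAST tabular `hits` are supplied, the best hit (lowest E-value,
#' ties by bit score) fixes the reading frame and strand, and the longest
#' stop-free stretch in that frame is taken. Without hits, all six frames
#' are scanned and the longest open reading frame wins (a declared
#' longest-ORF fallback standing in for dedicated CDS predictors). Within
#' the chosen stretch, if an in-frame ATG exists the CDS starts at the
#' first one and is flagged 5'-complete; otherwise the CDS starts at the
#' stretch boundary and is flagged 5'-incomplete (typical of assemblies
#' truncated before the start codon). The terminal stop codon is not part
#' of the CDS span.
#'
#' @param x A single transcript: named character scalar or length-1
#'   [Biostrings::DNAStringSet].
#' @param hits Optional data.frame of 12-column BLAST tabular rows for this
#'   transcript (see [read_blast_tab()]).
#' @param min_codons Minimum protein length in codons (default 30); shorter
#'   candidates yield `NULL`.
#' @return `NULL`, or a list with `gene_id`, `frame` (one of +1..+3,
#'   -1..-3), `cds_start`, `cds_end` (1-based inclusive on the forward
#'   strand), `protein`, `complete_5p`.
#' @export
extract_cds <- function(x, hits = NULL, min_codons = 30L) {
  seqs <- as_seq_chr(x)
  if (length(seqs) != 1L) stop("extract_cds() takes a single transcript")
  gene_id <- names(seqs)
  seq <- seqs[[1L]]
  frames <- GENETIC_FRAMES
  if (!is.null(hits) && nrow(hits) > 0L) {
    hits <- hits[order(hits$evalue, -hits$bitscore), , drop = FALSE]
    qs <- hits$qstart[1L]
    qe <- hits$qend[1L]
    if (qs <= qe) {
      frames <- ((qs - 1L) %% 3L) + 1L
    } else {
      rc_start <- nchar(seq) - qs + 1L
      frames <- -(((rc_start - 1L) %% 3L) + 1L)
    }
  }
  best <- NULL
  for (frame in frames) {
    aa <- translate_frame(seq, frame)
    if (nchar(aa) == 0L) next
    # stop-free stretches and their aa start offsets within the frame
    segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
    starts <- cumsum(c(1L, nchar(segs) + 1L))[seq_along(segs)]
    for (si in seq_along(segs)) {
      seg <- segs[si]
      if (nchar(seg) == 0L) next
      mpos <- regexpr("M", seg, fixed = TRUE)
      if (mpos > 0L) {
        prot <- substr(seg, mpos, nchar(seg))
        aa_start <- starts[si] + mpos - 1L
        complete <- TRUE
      } else {
        prot <- seg
        aa_start <- starts[si]
        complete <- FALSE
      }
      if (nchar(prot) < min_codons) next
      if (is.null(best) || nchar(prot) > nchar(best$protein) ||
          (nchar(prot) == nchar(best$protein) && complete &&
           !best$complete_5p)) {
        best <- list(frame = frame, aa_start = aa_start, protein = prot,
                     complete_5p = complete)
      }
    }
  }
  if (is.null(best)) return(NULL)
  L <- nchar(seq)
  f <- abs(best$frame)
  nt_start_local <- f + 3L * (best$aa_start - 1L)
  nt_end_local <- nt_start_local + 3L * nchar(best$protein) - 1L
  if (best$frame > 0L) {
    span <- c(nt_start_local, nt_end_local)
  } else {
    span <- c(L - nt_end_local + 1L, L - nt_start_local + 1L)
  }
  list(gene_id = gene_id, frame = best$frame,
       cds_start = span[1L], cds_end = span[2L],
       protein = best$protein, complete_5p = best$complete_5p)
}

#' Load signal-peptide and transmembrane topology predictions
#'
#' Accepts either the canonical tab-separated formats
#' (`gene_id<TAB>sp_present(Y/N)<TAB>cleavage_pos` and
#' `gene_id<TAB>tm_start<TAB>tm_end`, one segment per row, header optional)
#' or the short output formats of the classic external predictors:
#' SignalP 3.0 NN short lines (14 whitespace fields; the `D` decision in
#' field 14 gives presence, the `Ymax` position in field 6 the cleavage
#' site) and TMHMM short lines
#' (`name len=.. ExpAA=.. First60=.. PredHel=.. Topology=..`).
#'
#' @param sp_path Signal-peptide file.
#' @param tm_path Transmembrane file.
#' @param sp_format,tm_format `"auto"`, `"tsv"`, `"signalp3"` / `"tmhmm"`.
#' @return A topology object: list with data.frames `sp` (`gene_id`,
#'   `sp_present`, `cleavage_pos`) and `tm` (`gene_id`, `tm_start`,
#'   `tm_end`).
#' @export
load_topology <- function(sp_path, tm_path,
                          sp_format = c("auto", "tsv", "signalp3"),
                          tm_format = c("auto", "tsv", "tmhmm")) {
  sp_format <- match.arg(sp_format)
  tm_format <- match.arg(tm_format)
  sp_lines <- readLines(sp_path)
  tm_lines <- readLines(tm_path)
  if (sp_format == "auto") {
    body <- grep("^#", sp_lines, invert = TRUE, value = TRUE)
    nf <- length(strsplit(trimws(body[1L]), "\\s+")[[1L]])
    sp_format <- if (nf >= 14L) "signalp3" else "tsv"
  }
  if (tm_format == "auto") {
    tm_format <- if (any(grepl("PredHel=", tm_lines))) "tmhmm" else "tsv"
  }
  sp <- if (sp_format == "tsv") parse_sp_tsv(sp_lines) else
    parse_signalp3(sp_lines)
  tm <- if (tm_format == "tsv") parse_tm_tsv(tm_lines) else
    parse_tmhmm(tm_lines)
  validate_topology(sp, tm)
  structure(list(sp = sp, tm = tm), class = "glandscope_topology")
}

parse_sp_tsv <- function(lines) {
  lines <- grep("^#", lines, invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^gene_id\\t", lines[1L])) lines <- lines[-1L]
  out <- data.frame(gene_id = character(), sp_present = logical(),
                    cleavage_pos = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !f[2L] %in% c("Y", "N") ||
        is.na(suppressWarnings(as.integer(f[3L])))) {
      stop("malformed signal-peptide TSV at line ", i, ": ", lines[i])
    }
    out[nrow(out) + 1L, ] <- list(f[1L], f[2L] == "Y", as.integer(f[3L]))
  }
  out
}

parse_tm_tsv <- function(lines) {
  lines <- grep("^#", lines, invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^gene_id\\t", lines[1L])) lines <- lines[-1L]
  out <- data.frame(gene_id = character(), tm_start = integer(),
                    tm_end = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    st <- suppressWarnings(as.integer(f[2L]))
    en <- suppressWarnings(as.integer(f[3L]))
    if (length(f) < 3L || is.na(st) || is.na(en) || st > en) {
      stop("malformed transmembrane TSV at line ", i, ": ", lines[i])
    }
    out[nrow(out) + 1L, ] <- list(f[1L], st, en)
  }
  out
}

parse_signalp3 <- function(lines) {
  body_idx <- grep("^#", lines, invert = TRUE)
  out <- data.frame(gene_id = character(), sp_present = logical(),
                    cleavage_pos = integer(), stringsAsFactors = FALSE)
  for (i in body_idx) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 14L || !f[14L] %in% c("Y", "N") ||
        is.na(suppressWarnings(as.integer(f[6L])))) {
      stop("malformed SignalP 3.0 short line ", i, ": ", lines[i])
    }
    out[nrow(out) + 1L, ] <- list(f[1L], f[14L] == "Y", as.integer(f[6L]))
  }
  out
}

parse_tmhmm <- function(lines) {
  out <- data.frame(gene_id = character(), tm_start = integer(),
                    tm_end = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    gene <- f[1L]
    predhel <- sub("^PredHel=", "", grep("^PredHel=", f, value = TRUE))
    topo <- sub("^Topology=", "", grep("^Topology=", f, value = TRUE))
    if (length(predhel) != 1L || length(topo) != 1L ||
        is.na(suppressWarnings(as.integer(predhel)))) {
      stop("malformed TMHMM short line ", i, ": ", ln)
    }
    ivs <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1L]]
    if (length(ivs) != as.integer(predhel)) {
      stop("TMHMM line ", i, ": PredHel=", predhel, " but ",
           length(ivs), " interval(s) parsed from Topology=", topo)
    }
    for (iv in ivs) {
      se <- as.integer(strsplit(iv, "-", fixed = TRUE)[[1L]])
      out[nrow(out) + 1L, ] <- list(gene, se[1L], se[2L])
    }
  }
  out
}

validate_topology <- function(sp, tm) {
  bad <- sp$sp_present & sp$cleavage_pos < 1L
  if (any(bad)) {
    stop("cleavage_pos must be >= 1 when a signal peptide is present: ",
         paste(sp$gene_id[bad], collapse = ", "))
  }
  if (nrow(tm)) {
    tm_sorted <- tm[order(tm$gene_id, tm$tm_start), , drop = FALSE]
    ov <- unlist(lapply(split(tm_sorted, tm_sorted$gene_id), function(g) {
      nrow(g) > 1L && any(g$tm_start[-1L] <= g$tm_end[-nrow(g)])
    }))
    if (any(ov)) {
      stop("overlapping transmembrane segments for: ",
           paste(names(ov)[ov], collapse = ", "))
    }
  }
  invisible(TRUE)
}

# internal: the topology call of one gene
topology_for <- function(topo, gene_id) {
  i <- match(gene_id, topo$sp$gene_id)
  sp_present <- if (is.na(i)) FALSE else topo$sp$sp_present[i]
  cleavage <- if (is.na(i)) NA_integer_ else topo$sp$cleavage_pos[i]
  seg <- topo$tm[topo$tm$gene_id == gene_id, c("tm_start", "tm_end"),
                 drop = FALSE]
  seg <- seg[order(seg$tm_start), , drop = FALSE]
  list(gene_id = gene_id, sp_present = sp_present, cleavage_pos = cleavage,
       tm_segments = as.matrix(seg))
}

#' Secretion verdict for one coding sequence
#'
#' Retention rule: a protein is a secretion candidate when it has a signal
#' peptide and either no transmembrane segment, or exactly one that
#' coincides with the signal peptide itself (operationalized as interval
#' overlap with residues 1..cleavage_pos-1). Proteins with additional or
#' downstream transmembrane segments are called membrane-anchored.
#' 5'-incomplete coding sequences are excluded outright
#' (`incomplete_5p`): without the true N-terminus a signal peptide cannot
#' be assessed.
#'
#' @param cds A coding sequence from [extract_cds()].
#' @param topo Either a topology object from [load_topology()] /
#'   [predict_topology_toy()], or a single-gene call (list with
#'   `sp_present`, `cleavage_pos`, `tm_segments`).
#' @return A list with `gene_id`, `verdict` (one of `secreted`,
#'   `membrane_anchored`, `no_signal`, `incomplete_5p`) and `reason`.
#' @export
classify_secretion <- function(cds, topo) {
  tc <- if (inherits(topo, "glandscope_topology")) {
    topology_for(topo, cds$gene_id)
  } else {
    topo
  }
  if (!isTRUE(cds$complete_5p)) {
    return(list(gene_id = cds$gene_id, verdict = "incomplete_5p",
                reason = "CDS lacks its 5' end; signal peptide unassessable"))
  }
  if (!isTRUE(tc$sp_present)) {
    return(list(gene_id = cds$gene_id, verdict = "no_signal",
                reason = "no signal peptide predicted"))
  }
  ntm <- nrow(tc$tm_segments)
  if (is.null(ntm)) ntm <- 0L
  if (ntm == 0L) {
    return(list(gene_id = cds$gene_id, verdict = "secreted",
                reason = "signal peptide, no transmembrane segment"))
  }
  sp_end <- tc$cleavage_pos - 1L
  if (ntm == 1L && tc$tm_segments[1L, 1L] <= sp_end) {
    return(list(gene_id = cds$gene_id, verdict = "secreted",
                reason = "single transmembrane segment coincides with the signal peptide"))
  }
  list(gene_id = cds$gene_id, verdict = "membrane_anchored",
       reason = "transmembrane segment(s) beyond the signal peptide")
}

#' Classify a batch of coding sequences
#'
#' @param cds_list List of coding sequences ([extract_cds()] results).
#' @param topo Topology object from [load_topology()] or
#'   [predict_topology_toy()].
#' @return Data.frame `gene_id`, `verdict`, `reason`, one row per CDS.
#' @export
classify_secretion_batch <- function(cds_list, topo) {
  rows <- lapply(cds_list, function(cds) {
    as.data.frame(classify_secretion(cds, topo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read 12-column BLAST tabular output (outfmt 6)
#'
#' @param path Path to a tab-separated BLAST result.
#' @return Data.frame with the standard columns `qseqid sseqid pident
#'   length mismatch gapopen qstart qend sstart send evalue bitscore`.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, col.names = cols,
                   colClasses = c("character", "character", rep("numeric", 4),
                                  rep("integer", 4), "character", "numeric"))
  ev <- suppressWarnings(as.numeric(df$evalue))
  if (any(is.na(ev))) {
    stop("non-numeric E-value field in ", path, " (row ",
         which(is.na(ev))[1L], ")")
  }
  df$evalue <- ev
  df
}

#' Best significant BLAST hit per query
#'
#' Keeps rows with E-value at or below the cut-off and deduplicates to one
#' row per query: lowest E-value, ties broken by highest bit score.
#'
#' @param hits Data.frame of BLAST tabular rows ([read_blast_tab()]).
#' @param e_cut E-value cut-off (default 1e-5, inclusive).
#' @return Filtered data.frame, one row per passing query.
#' @export
filter_homologs <- function(hits, e_cut = 1e-5) {
  if (!is.numeric(hits$evalue)) stop("evalue column must be numeric")
  keep <- hits[hits$evalue <= e_cut, , drop = FALSE]
  keep <- keep[order(keep$evalue, -keep$bitscore, keep$sseqid), ,
               drop = FALSE]
  keep <- keep[!duplicated(keep$qseqid), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}
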