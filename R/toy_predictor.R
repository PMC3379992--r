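# Kyte-Doolittle hydropathy scale
KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0
)

# internal: hydropathy profile of one protein
hydropathy <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1L]]
  v <- KD_SCALE[aa]
  v[is.na(v)] <- 0
  unname(v)
}

# internal: sliding-window means
window_means <- function(v, w) {
  if (length(v) < w) return(numeric())
  cs <- cumsum(c(0, v))
  (cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Toy hydropathy-based topology predictor
#'
#' A deliberately simple stand-in predictor so the secretome triage can be
#' exercised with no external tools: it is NOT a model of real signal
#' peptides. A signal peptide is called when some 10-residue window within
#' the first 35 residues has mean Kyte-Doolittle hydropathy at or above
#' `sp_cut`; the cleavage position is placed just after the hydrophobic
#' run. Transmembrane segments are called where a 19-residue window beyond
#' the cleavage site reaches `tm_cut`; overlapping windows merge into one
#' segment.
#'
#' @param proteins Named character vector of protein sequences.
#' @param sp_cut Window-mean hydropathy threshold for the signal peptide
#'   (default 2.0).
#' @param tm_cut Threshold for transmembrane windows (default 2.0).
#' @return A topology object as from [load_topology()].
#' @export
predict_topology_toy <- function(proteins, sp_cut = 2.0, tm_cut = 2.0) {
  sp <- data.frame(gene_id = character(), sp_present = logical(),
                   cleavage_pos = integer(), stringsAsFactors = FALSE)
  tm <- data.frame(gene_id = character(), tm_start = integer(),
                   tm_end = integer(), stringsAsFactors = FALSE)
  for (g in names(proteins)) {
    h <- hydropathy(proteins[[g]])
    nterm <- h[seq_len(min(35L, length(h)))]
    wm <- window_means(nterm, 10L)
    present <- length(wm) > 0L && max(wm) >= sp_cut
    cleave <- NA_integer_
    if (present) {
      wstart <- which.max(wm)
      run_end <- wstart + 9L
      while (run_end + 1L <= length(nterm) && nterm[run_end + 1L] >= 0) {
        run_end <- run_end + 1L
      }
      cleave <- min(run_end + 2L, length(h))
    }
    sp[nrow(sp) + 1L, ] <- list(g, present,
                                if (present) cleave else 0L)
    scan_from <- if (present) cleave else 1L
    rest <- h[scan_from:length(h)]
    wm_tm <- window_means(rest, 19L)
    hit <- which(wm_tm >= tm_cut)
    if (length(hit)) {
      # merge runs of overlapping windows
      brk <- c(0L, which(diff(hit) > 19L), length(hit))
      for (b in seq_len(length(brk) - 1L)) {
        idx <- hit[(brk[b] + 1L):brk[b + 1L]]
        tm[nrow(tm) + 1L, ] <- list(
          g, scan_from + min(idx) - 1L, scan_from + max(idx) + 17L)
      }
    }
  }
  structure(list(sp = sp, tm = tm), class = "glandscope_topology")
}

#' Generate toy proteins with or without a planted signal peptide
#'
#' Companion generator for [predict_topology_toy()]. Secreted-labelled
#' proteins get an N-terminal hydrophobic core (residues from
#' A/V/L/I/F) of `sp_len` residues after an initial Met, followed by a
#' hydrophilic mature region; non-secreted proteins are hydrophilic
#' throughout. Optionally a hydrophobic 19-mer is inserted downstream to
#' mimic a membrane anchor.
#'
#' @param n Number of proteins.
#' @param secreted Logical vector (recycled) of planted labels.
#' @param extra_tm Logical vector (recycled): plant a downstream
#'   transmembrane segment.
#' @param length Mature-protein length (default 120).
#' @param sp_len Hydrophobic core length (default 14).
#' @param seed Random seed (required; generation is fully reproducible).
#' @return Named character vector `toyprot1..n` with attributes
#'   `secreted` and `extra_tm` (the planted labels).
#' @export
make_toy_proteins <- function(n, secreted = TRUE, extra_tm = FALSE,
                              length = 120L, sp_len = 14L, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  secreted <- rep_len(secreted, n)
  extra_tm <- rep_len(extra_tm, n)
  hydrophobic <- c("A", "V", "L", "I", "F")
  polar <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H", "Y")
  out <- character(n)
  for (i in seq_len(n)) {
    mature <- paste(sample(polar, length, replace = TRUE), collapse = "")
    if (extra_tm[i]) {
      anchor <- paste(sample(hydrophobic, 19L, replace = TRUE),
                      collapse = "")
      at <- 40L
      mature <- paste0(substr(mature, 1L, at), anchor,
                       substr(mature, at + 1L, nchar(mature)))
    }
    if (secreted[i]) {
      core <- paste(sample(hydrophobic, sp_len, replace = TRUE),
                    collapse = "")
      out[i] <- paste0("M", "K", core, "A", mature)
    } else {
      out[i] <- paste0("M", mature)
    }
  }
  names(out) <- paste0("toyprot", seq_len(n))
  attr(out, "secreted") <- secreted
  attr(out, "extra_tm") <- extra_tm
  out
}
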