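#' Banded global alignment of two DNA strings
#'
#' Needleman-Wunsch with linear gap penalties, restricted to a diagonal band.
#' Used by [find_ortholog_pairs()] to refine seed-anchored overlaps when a
#' plain diagonal comparison falls below the identity threshold (i.e. when
#' small indels may be present). Identity is matching columns over total
#' alignment columns; gap columns count as non-matching, and `N` never
#' matches anything (including another `N`).
#'
#' @param a,b DNA strings (plain character scalars).
#' @param band Half-width of the band: alignments may drift at most `band`
#'   columns off the main diagonal. The two lengths must differ by at most
#'   `band`.
#' @param match,mismatch,gap Scoring parameters (linear gap model).
#' @return A list with `score`, `columns` (alignment length), `matches`, and
#'   `identity` = matches / columns.
#' @export
align_banded <- function(a, b, band = 5L, match = 1, mismatch = -2, gap = -3) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av)
  m <- length(bv)
  if (n == 0L || m == 0L) stop("empty sequence")
  band <- as.integer(band)
  if (abs(n - m) > band) {
    stop("sequence length difference (", abs(n - m),
         ") exceeds band width (", band, ")")
  }
  W <- 2L * band + 1L
  NEG <- -1e18
  S <- matrix(NEG, n + 1L, W)  # S[i+1, d]: j = i + d - band - 1
  P <- matrix(NA_integer_, n + 1L, W)
  for (d in seq_len(W)) {
    j <- d - band - 1L
    if (j >= 0L && j <= m) S[1L, d] <- gap * j
  }
  for (i in seq_len(n)) {
    for (d in seq_len(W)) {
      j <- i + d - band - 1L
      if (j < 0L || j > m) next
      if (j == 0L) {
        S[i + 1L, d] <- gap * i
        P[i + 1L, d] <- 1L
        next
      }
      best <- NEG
      ptr <- NA_integer_
      sdiag <- S[i, d]  # (i-1, j-1)
      if (sdiag > NEG / 2) {
        sc <- sdiag + (if (av[i] == bv[j] && av[i] != "N") match else mismatch)
        if (sc > best) {
          best <- sc
          ptr <- 0L
        }
      }
      if (d < W) {  # up: (i-1, j), gap in b
        sup <- S[i, d + 1L]
        if (sup > NEG / 2) {
          sc <- sup + gap
          if (sc > best) {
            best <- sc
            ptr <- 1L
          }
        }
      }
      if (d > 1L) {  # left: (i, j-1), gap in a
        slf <- S[i + 1L, d - 1L]
        if (slf > NEG / 2) {
          sc <- slf + gap
          if (sc > best) {
            best <- sc
            ptr <- 2L
          }
        }
      }
      S[i + 1L, d] <- best
      P[i + 1L, d] <- ptr
    }
  }
  dend <- m - n + band + 1L
  score <- S[n + 1L, dend]
  i <- n
  j <- m
  matches <- 0L
  cols <- 0L
  while (i > 0L || j > 0L) {
    ptr <- if (i == 0L) 2L else if (j == 0L) 1L else P[i + 1L, j - i + band + 1L]
    cols <- cols + 1L
    if (ptr == 0L) {
      if (av[i] == bv[j] && av[i] != "N") matches <- matches + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (ptr == 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = score, columns = cols, matches = matches,
       identity = matches / cols)
}

# internal: k-mer table of a sequence set as a data.table(id, pos, kmer);
# k-mers containing N are dropped (they can never seed a match)
kmer_table <- function(seqs, k) {
  lens <- nchar(seqs)
  keep <- lens >= k
  seqs <- seqs[keep]
  lens <- lens[keep]
  if (length(seqs) == 0L) {
    return(data.table(id = character(), pos = integer(), kmer = character()))
  }
  nk <- lens - k + 1L
  dt <- data.table(
    id = rep(names(seqs), times = nk),
    pos = unlist(lapply(nk, seq_len), use.names = FALSE)
  )
  dt[, kmer := substring(seqs[id], pos, pos + k - 1L)]
  dt[!grepl("N", kmer, fixed = TRUE)]
}

# internal: exact column stats of two equal-length strings (no gaps);
# N matches nothing
diag_stats <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  rn <- charToRaw("N")
  matches <- sum(ra == rb & ra != rn)
  list(columns = length(ra), matches = matches,
       identity = matches / length(ra))
}

#' Discover ortholog gene pairs between two assemblies
#'
#' Matches each study (SG) transcript to at most one background (WB)
#' transcript by exact k-mer seeding followed by extension over the full
#' seed diagonal. Candidates whose plain diagonal comparison misses the
#' identity threshold are re-scored by banded gapped alignment
#' ([align_banded()]), so isolated short indels still count as single
#' non-matching columns rather than frame-shifting the comparison. A pair is
#' accepted when identity is strictly greater than `min_identity` and the
#' alignment spans at least `min_overlap` columns. One-to-many conflicts are
#' resolved by highest identity, then longest overlap, then lexicographic
#' ids; each transcript appears in at most one accepted pair.
#'
#' @param sg,wb Named [Biostrings::DNAStringSet] or named character vectors
#'   (the study and background assemblies).
#' @param min_identity Minimum identity, exclusive (default 0.99: accepted
#'   pairs have identity strictly greater).
#' @param min_overlap Minimum number of alignment columns (default 150).
#' @param k Seed k-mer length.
#' @param band Band half-width passed to [align_banded()].
#' @param search_revcomp Also search the reverse complement of the
#'   background set (off by default: de novo assemblies compared here are
#'   taken as consistently oriented).
#' @return A data.frame with one row per accepted pair: `pair_id`, `sg_id`,
#'   `wb_id`, `identity`, `overlap_len`, 1-based inclusive spans `sg_start`,
#'   `sg_end`, `wb_start`, `wb_end`, and `strand` (`+`, or `-` when the
#'   match was found on the reverse complement).
#' @export
find_ortholog_pairs <- function(sg, wb, min_identity = 0.99,
                                min_overlap = 150L, k = 20L, band = 5L,
                                search_revcomp = FALSE) {
  sgc <- as_seq_chr(sg)
  wbc <- as_seq_chr(wb)
  if (length(sgc) == 0L || length(wbc) == 0L) {
    stop("both transcript sets must be nonempty")
  }
  cand <- rbind(
    seed_candidates(sgc, wbc, k, strand = "+"),
    if (search_revcomp) {
      seed_candidates(sgc, setNames(revcomp_chr(wbc), names(wbc)), k,
                      strand = "-")
    }
  )
  if (is.null(cand) || nrow(cand) == 0L) {
    return(empty_pairs_df())
  }
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    sid <- cand$sg_id[r]
    wid <- cand$wb_id[r]
    strand <- cand$strand[r]
    sseq <- sgc[[sid]]
    wseq <- if (strand == "+") wbc[[wid]] else revcomp_chr(wbc[[wid]])
    d <- cand$diag_off[r]
    Ls <- nchar(sseq)
    Lw <- nchar(wseq)
    sg_start <- max(1L, 1L + d)
    wb_start <- sg_start - d
    len_ov <- min(Ls - sg_start, Lw - wb_start) + 1L
    if (len_ov < min_overlap) next
    a <- substr(sseq, sg_start, sg_start + len_ov - 1L)
    b <- substr(wseq, wb_start, wb_start + len_ov - 1L)
    st <- diag_stats(a, b)
    if (st$identity <= min_identity && band > 0L) {
      st <- align_banded(a, b, band = band)
    }
    if (st$identity <= min_identity || st$columns < min_overlap) next
    wb_end_local <- wb_start + len_ov - 1L
    if (strand == "+") {
      wspan <- c(wb_start, wb_end_local)
    } else {
      # map the reverse-complement coordinates back onto the forward strand
      wspan <- c(Lw - wb_end_local + 1L, Lw - wb_start + 1L)
    }
    rows[[r]] <- data.frame(
      sg_id = sid, wb_id = wid,
      identity = st$identity, overlap_len = st$columns,
      sg_start = sg_start, sg_end = sg_start + len_ov - 1L,
      wb_start = wspan[1], wb_end = wspan[2],
      strand = strand, stringsAsFactors = FALSE
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(empty_pairs_df())
  }
  out <- do.call(rbind, rows)
  # best pair wins: identity desc, overlap desc, then lexicographic ids
  out <- out[order(-out$identity, -out$overlap_len, out$sg_id, out$wb_id), ]
  # greedy pass: a row is kept only if neither side was used by a better row
  used_sg <- character()
  used_wb <- character()
  keep <- logical(nrow(out))
  for (r in seq_len(nrow(out))) {
    if (!(out$sg_id[r] %in% used_sg) && !(out$wb_id[r] %in% used_wb)) {
      keep[r] <- TRUE
      used_sg <- c(used_sg, out$sg_id[r])
      used_wb <- c(used_wb, out$wb_id[r])
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$sg_id, out$wb_id), , drop = FALSE]
  out <- cbind(pair_id = sprintf("pair%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# internal: candidate (sg_id, wb_id) pairs with their dominant seed diagonal
seed_candidates <- function(sgc, wbc, k, strand) {
  sk <- kmer_table(sgc, k)
  wk <- kmer_table(wbc, k)
  if (nrow(sk) == 0L || nrow(wk) == 0L) return(NULL)
  setnames(sk, c("sg_id", "sg_pos", "kmer"))
  setnames(wk, c("wb_id", "wb_pos", "kmer"))
  hits <- sk[wk, on = "kmer", nomatch = 0L, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(NULL)
  hits[, diag_off := sg_pos - wb_pos]
  byd <- hits[, .(n_seeds = .N), by = .(sg_id, wb_id, diag_off)]
  setorder(byd, sg_id, wb_id, -n_seeds, diag_off)
  dom <- byd[, head(.SD, 1L), by = .(sg_id, wb_id)]
  dom[, strand := strand]
  as.data.frame(dom)
}

empty_pairs_df <- function() {
  data.frame(pair_id = character(), sg_id = character(),
             wb_id = character(), identity = numeric(),
             overlap_len = integer(), sg_start = integer(),
             sg_end = integer(), wb_start = integer(), wb_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Clip the overlapping aligned region of an ortholog pair
#'
#' Cuts the recorded spans out of the two parent transcripts. The returned
#' region sequences are exact substrings of the parents at the recorded
#' 1-based inclusive coordinates (for reverse-strand pairs the background
#' span is reported on the forward strand, and the forward-strand substring
#' is returned).
#'
#' @param pair A one-row data.frame (or list) with the fields produced by
#'   [find_ortholog_pairs()].
#' @param sg,wb The parent transcripts: containers holding `pair$sg_id` /
#'   `pair$wb_id`, or the two sequences themselves (named).
#' @return A list with `pair_id`, `sg_region_seq`, `wb_region_seq`,
#'   `len_sg`, `len_wb`.
#' @export
clip_overlap <- function(pair, sg, wb) {
  sgc <- as_seq_chr(sg)
  wbc <- as_seq_chr(wb)
  if (!pair$sg_id %in% names(sgc)) stop("sg transcript not found: ", pair$sg_id)
  if (!pair$wb_id %in% names(wbc)) stop("wb transcript not found: ", pair$wb_id)
  sseq <- sgc[[pair$sg_id]]
  wseq <- wbc[[pair$wb_id]]
  if (pair$sg_start < 1L || pair$sg_end > nchar(sseq) ||
      pair$sg_start > pair$sg_end) {
    stop("sg span [", pair$sg_start, ",", pair$sg_end,
         "] outside transcript ", pair$sg_id, " (length ", nchar(sseq), ")")
  }
  if (pair$wb_start < 1L || pair$wb_end > nchar(wseq) ||
      pair$wb_start > pair$wb_end) {
    stop("wb span [", pair$wb_start, ",", pair$wb_end,
         "] outside transcript ", pair$wb_id, " (length ", nchar(wseq), ")")
  }
  list(
    pair_id = pair$pair_id,
    sg_region_seq = substr(sseq, pair$sg_start, pair$sg_end),
    wb_region_seq = substr(wseq, pair$wb_start, pair$wb_end),
    len_sg = pair$sg_end - pair$sg_start + 1L,
    len_wb = pair$wb_end - pair$wb_start + 1L
  )
}

#' Clip all pairs of a pairing result
#'
#' @param pairs Data.frame from [find_ortholog_pairs()].
#' @param sg,wb The two transcript sets.
#' @return A list with two named character vectors, `sg` and `wb`, keyed by
#'   pair id (the clipped region sequences for each side).
#' @export
clip_overlaps <- function(pairs, sg, wb) {
  sg_regions <- character(nrow(pairs))
  wb_regions <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    cl <- clip_overlap(pairs[r, ], sg, wb)
    sg_regions[r] <- cl$sg_region_seq
    wb_regions[r] <- cl$wb_region_seq
  }
  list(sg = setNames(sg_regions, pairs$pair_id),
       wb = setNames(wb_regions, pairs$pair_id))
}

#' Write a pairing result as TSV
#' @param pairs Data.frame from [find_ortholog_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(pairs, path) {
  cols <- c("pair_id", "sg_id", "wb_id", "identity", "overlap_len",
            "sg_start", "sg_end", "wb_start", "wb_end")
  write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write clipped regions as FASTA with `pair|side` headers
#' @param regions List from [clip_overlaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_fasta <- function(regions, path) {
  seqs <- c(setNames(regions$sg, paste0(names(regions$sg), "|sg")),
            setNames(regions$wb, paste0(names(regions$wb), "|wb")))
  write_fasta(seqs, path)
}

#' Read clipped regions written by [write_regions_fasta()]
#' @param path FASTA path with `pair|sg` / `pair|wb` headers.
#' @return A list with named character vectors `sg` and `wb`.
#' @export
read_regions_fasta <- function(path) {
  x <- as_seq_chr(load_transcripts(path))
  side <- sub("^.*\\|", "", names(x))
  pid <- sub("\\|[^|]*$", "", names(x))
  list(sg = setNames(unname(x[side == "sg"]), pid[side == "sg"]),
       wb = setNames(unname(x[side == "wb"]), pid[side == "wb"]))
}
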