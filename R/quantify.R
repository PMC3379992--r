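#' Load sequencing reads from FASTQ or FASTA
#'
#' Quality strings are ignored: the downstream mapper is exact-match by
#' default and the generator emits error-free reads.
#'
#' @param path Path to a FASTQ (`.fastq`/`.fq`) or FASTA file; format is
#'   guessed from the extension unless given.
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @return A named character vector of read sequences (upper-cased).
#' @export
load_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# internal: index of every read-length substring of the regions.
# Returns a data.table keyed by seqstr with columns seqstr, region
# (region id, or NA for substrings shared by >1 distinct region).
region_substring_index <- function(regions, read_len) {
  lens <- nchar(regions)
  keep <- lens >= read_len
  regions <- regions[keep]
  lens <- lens[keep]
  if (length(regions) == 0L) return(NULL)
  nsub <- lens - read_len + 1L
  dt <- data.table(
    region = rep(names(regions), times = nsub),
    pos = unlist(lapply(nsub, seq_len), use.names = FALSE)
  )
  dt[, seqstr := substring(regions[region], pos, pos + read_len - 1L)]
  idx <- dt[, .(n_regions = uniqueN(region), region = region[1L]),
            by = seqstr]
  idx[n_regions > 1L, region := NA_character_]
  setkey(idx, seqstr)
  idx[, .(seqstr, region)]
}

#' Count reads on clipped ortholog regions
#'
#' Each read is assigned to at most one region. By default matching is exact
#' (no mismatches) and both orientations of the read are tried. A read whose
#' sequence occurs in two or more distinct regions (on either strand) is
#' discarded as ambiguous and excluded from `total_mapped`, so near-identical
#' orthologs are never double-counted. `total_mapped` is the count of reads
#' assigned to any region of this set -- it is both the RPKM denominator and
#' the Audic-Claverie library size for this library.
#'
#' @param reads Character vector of read sequences (e.g. from
#'   [load_reads()]).
#' @param regions Named character vector of region sequences for one side
#'   (e.g. `clip_overlaps(...)$sg`), keyed by pair id.
#' @param max_mismatches Mismatch tolerance per read (default 0). Positive
#'   values use a pigeonhole seed-and-verify scan and are substantially
#'   slower.
#' @return A list with `counts` (named integer vector over all region ids),
#'   `total_mapped`, `n_ambiguous`, `n_unmapped`.
#' @export
map_reads_to_regions <- function(reads, regions, max_mismatches = 0L) {
  if (length(regions) == 0L) stop("regions must be nonempty")
  reads <- toupper(unname(reads))
  counts <- setNames(integer(length(regions)), names(regions))
  n_ambiguous <- 0L
  n_unmapped <- 0L
  for (L in sort(unique(nchar(reads)))) {
    rd <- reads[nchar(reads) == L]
    assigned <- if (max_mismatches == 0L) {
      assign_exact(rd, regions, L)
    } else {
      assign_mismatch(rd, regions, L, max_mismatches)
    }
    tab <- table(assigned$region)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    n_ambiguous <- n_ambiguous + assigned$n_ambiguous
    n_unmapped <- n_unmapped + assigned$n_unmapped
  }
  list(counts = counts, total_mapped = sum(counts),
       n_ambiguous = n_ambiguous, n_unmapped = n_unmapped)
}

# internal: exact assignment of equal-length reads; returns the region of
# each mapped read plus ambiguity/unmapped tallies
assign_exact <- function(rd, regions, L) {
  idx <- region_substring_index(regions, L)
  if (is.null(idx)) {
    return(list(region = character(), n_ambiguous = 0L,
                n_unmapped = length(rd)))
  }
  lookup <- setNames(idx$region, idx$seqstr)
  fwd_hit <- rd %in% idx$seqstr
  rc <- revcomp_chr(rd)
  rc_hit <- rc %in% idx$seqstr
  r_fwd <- ifelse(fwd_hit, lookup[rd], NA_character_)
  r_rc <- ifelse(rc_hit, lookup[rc], NA_character_)
  # a hit on a substring shared by several regions is itself ambiguous
  amb <- (fwd_hit & is.na(r_fwd)) | (rc_hit & is.na(r_rc)) |
    (!is.na(r_fwd) & !is.na(r_rc) & r_fwd != r_rc)
  region <- ifelse(!is.na(r_fwd), r_fwd, r_rc)
  mapped <- !amb & !is.na(region)
  list(region = region[mapped],
       n_ambiguous = sum(amb),
       n_unmapped = sum(!amb & is.na(region)))
}

# internal: mismatch-tolerant assignment via pigeonhole seeding -- a read
# with <= k mismatches must carry at least one exact chunk among k+1 chunks
assign_mismatch <- function(rd, regions, L, k) {
  chunk_len <- L %/% (k + 1L)
  if (chunk_len < 1L) stop("reads too short for ", k, " mismatches")
  region_of <- character(length(rd))
  amb <- logical(length(rd))
  for (i in seq_along(rd)) {
    hits <- character()
    for (strand_seq in c(rd[i], revcomp_chr(rd[i]))) {
      for (rg in names(regions)) {
        if (nchar(regions[[rg]]) < L) next
        if (rg %in% hits) next
        if (min_hamming_at_most(strand_seq, regions[[rg]], k)) {
          hits <- c(hits, rg)
        }
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) {
      region_of[i] <- hits
    } else if (length(hits) > 1L) {
      amb[i] <- TRUE
    }
  }
  mapped <- region_of != "" & !amb
  list(region = region_of[mapped], n_ambiguous = sum(amb),
       n_unmapped = sum(region_of == "" & !amb))
}

# internal: does `read` occur in `region` with <= k mismatches at any offset?
min_hamming_at_most <- function(read, region, k) {
  L <- nchar(read)
  rr <- charToRaw(read)
  rg <- charToRaw(region)
  for (s in 0:(length(rg) - L)) {
    if (sum(rr != rg[(s + 1L):(s + L)]) <= k) return(TRUE)
  }
  FALSE
}

#' Reads per kilobase per million mapped reads
#'
#' `1e9 * count / (total_mapped * length)`. Vectorized over `count` and
#' `length`.
#'
#' @param count Raw mapped-read count(s) for the region.
#' @param total_mapped Total reads mapped in the library (RPKM's N).
#' @param length Region length in bases.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1e6, 1000)  # 10
#' @export
rpkm <- function(count, total_mapped, length) {
  if (any(count < 0)) stop("counts must be nonnegative")
  if (any(total_mapped <= 0)) stop("total_mapped must be positive")
  if (any(length <= 0)) stop("length must be positive")
  1e9 * count / (total_mapped * length)
}

#' Quantify both libraries on the clipped regions
#'
#' Maps the SG library onto the SG-side regions and the WB library onto the
#' WB-side regions, then computes RPKM for each side using that library's
#' own `total_mapped` as denominator.
#'
#' @param regions List from [clip_overlaps()] (elements `sg`, `wb`).
#' @param sg_reads,wb_reads Read sequence vectors.
#' @param max_mismatches Passed to [map_reads_to_regions()].
#' @return A list with `counts` (data.frame `pair_id count_sg count_wb
#'   len_sg len_wb rpkm_sg rpkm_wb`), `n1`, `n2` (total mapped per library)
#'   and the two mapping summaries.
#' @export
quantify_regions <- function(regions, sg_reads, wb_reads,
                             max_mismatches = 0L) {
  map_sg <- map_reads_to_regions(sg_reads, regions$sg, max_mismatches)
  map_wb <- map_reads_to_regions(wb_reads, regions$wb, max_mismatches)
  pid <- names(regions$sg)
  counts <- data.frame(
    pair_id = pid,
    count_sg = as.integer(map_sg$counts[pid]),
    count_wb = as.integer(map_wb$counts[pid]),
    len_sg = nchar(regions$sg[pid]),
    len_wb = nchar(regions$wb[pid]),
    stringsAsFactors = FALSE
  )
  counts$rpkm_sg <- rpkm(counts$count_sg, max(map_sg$total_mapped, 1L),
                         counts$len_sg)
  counts$rpkm_wb <- rpkm(counts$count_wb, max(map_wb$total_mapped, 1L),
                         counts$len_wb)
  rownames(counts) <- NULL
  list(counts = counts, n1 = map_sg$total_mapped, n2 = map_wb$total_mapped,
       summary_sg = map_sg[c("total_mapped", "n_ambiguous", "n_unmapped")],
       summary_wb = map_wb[c("total_mapped", "n_ambiguous", "n_unmapped")])
}

#' Write / read the counts table
#' @param counts Data.frame from [quantify_regions()]`$counts`.
#' @param path TSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
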