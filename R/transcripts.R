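#' Load assembled transcripts ("unigenes") from a FASTA file
#'
#' Reads a multi-record FASTA (wrapped or unwrapped), upper-cases the
#' sequences and validates the set: identifiers must be unique and every
#' sequence non-empty. Identifiers are taken as the first whitespace-separated
#' token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet]; names are transcript ids,
#'   order follows the file.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">t1", "acgtacgt", ">t2", "GGGTTTAA"), fa)
#' tx <- load_transcripts(fa)
#' width(tx)
#' @export
load_transcripts <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  names(x) <- ids
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate transcript id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  if (any(Biostrings::width(x) == 0L)) {
    empty <- ids[Biostrings::width(x) == 0L]
    stop("empty sequence(s) in ", path, ": ", paste(empty, collapse = ", "))
  }
  # upper-case; keep the alphabet constrained to A/C/G/T/N
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(x) <- ids
  bad <- grepl("[^ACGTN]", as.character(x))
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,T,N}: ",
         paste(ids[bad], collapse = ", "))
  }
  x
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = 70L)
  invisible(path)
}

# internal: coerce a transcript container to a named character vector
as_seq_chr <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("expected a DNAStringSet or named character vector")
  }
  if (is.null(names(out)) || any(names(out) == "")) {
    stop("sequences must be named")
  }
  out
}

# internal: reverse complement of plain character sequences. Biostrings is
# efficient for large vectors but its S4 dispatch dominates for one-off
# calls, so short inputs take a base-R path.
revcomp_chr <- function(x) {
  if (length(x) >= 100L) {
    return(as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
  }
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
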