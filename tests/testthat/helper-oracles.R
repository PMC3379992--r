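# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: plain summation, enumeration and
# quadratic scans instead of closed-form library calls.

# Audic-Claverie conditional pmf by direct log-space summation.
# p(k | x) = (n2/n1)^k (x+k)! / (x! k! (1 + n2/n1)^(x+k+1))
ac_pmf_oracle <- function(k, x, n1, n2) {
  r <- n2 / n1
  exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
        (x + k + 1) * log(1 + r))
}

ac_oracle <- function(x, y, n1, n2, sided = "two") {
  lower <- sum(ac_pmf_oracle(0:y, x, n1, n2))
  # upper tail: sum upward from y until terms vanish
  upper <- 0
  k <- y
  repeat {
    term <- ac_pmf_oracle(k, x, n1, n2)
    upper <- upper + term
    k <- k + 1
    if (term < 1e-18 * max(upper, 1e-300) && k > (x + 1) * n2 / n1 + y + 10) {
      break
    }
    if (k > 100000) break
  }
  one <- min(lower, upper, 1)
  if (sided == "one") one else min(1, 2 * one)
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_enum_oracle <- function(N, n, M, m) {
  if (n == 0) return(as.numeric(m <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(M)  # the first M background genes carry the term
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= m)
}

# Benjamini-Hochberg by a naive quadratic scan: for each p_i, the minimum
# over all p_j >= p_i of n * p_j / rank(p_j), clamped at 1
bh_oracle <- function(p) {
  n <- length(p)
  r <- vapply(p, function(pi) sum(p <= pi), numeric(1))
  vapply(seq_len(n), function(i) {
    cand <- which(p >= p[i])
    min(1, min(n * p[cand] / r[cand]))
  }, numeric(1))
}

# random DNA string
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# plant exactly nmut substitutions into a sequence (all bases changed)
plant_mismatches <- function(seq, nmut) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), nmut)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# full-DP alignment oracle via Biostrings (global, same linear gap model as
# the production banded aligner: match 1, mismatch -2, gap -3)
dp_align_oracle <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 3)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  pv <- strsplit(pat, "")[[1]]
  sv <- strsplit(sub, "")[[1]]
  list(score = Biostrings::score(aln),
       columns = length(pv),
       matches = sum(pv == sv & pv != "-"))
}
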