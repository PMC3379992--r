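test_that("an identical sequence present in both sets pairs at identity 1", {
  set.seed(101)
  s <- random_dna(200)
  pairs <- find_ortholog_pairs(c(g1 = s), c(h1 = s))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$identity, 1.0)
  expect_equal(pairs$overlap_len, 200L)
  expect_equal(c(pairs$sg_start, pairs$sg_end), c(1L, 200L))
})

test_that("a 100 bp shared block does not meet the overlap threshold", {
  set.seed(102)
  block <- random_dna(100)
  sg <- c(g1 = paste0(random_dna(100), block, random_dna(100)))
  wb <- c(h1 = paste0(random_dna(100), block, random_dna(100)))
  pairs <- find_ortholog_pairs(sg, wb)
  expect_equal(nrow(pairs), 0L)
})

test_that("identity is strictly greater-than: 2 mismatches in 300 pass, 3 fail", {
  set.seed(103)
  base <- random_dna(300)
  two <- plant_mismatches(base, 2)   # 298/300 = 0.99333 > 0.99
  three <- plant_mismatches(base, 3) # 297/300 = 0.99 exactly, not > 0.99
  p2 <- find_ortholog_pairs(c(g = two), c(h = base))
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$identity, 298 / 300)
  st <- dp_align_oracle(two, base)   # full-DP oracle agrees
  expect_equal(st$matches / st$columns, 298 / 300)
  p3 <- find_ortholog_pairs(c(g = three), c(h = base))
  expect_equal(nrow(p3), 0L)
})

test_that("pairing is symmetric under swapping the SG and WB roles", {
  set.seed(104)
  tr <- simulate_transcriptomes(30, 5, length_sdlog = 0,
                                mutation_rate = 0.004, seed = 17)
  fwd <- find_ortholog_pairs(tr$sg, tr$wb)
  rev <- find_ortholog_pairs(tr$wb, tr$sg)
  expect_equal(nrow(fwd), nrow(rev))
  fwd_sorted <- fwd[order(fwd$sg_id), ]
  rev_sorted <- rev[order(rev$wb_id), ]
  expect_equal(fwd_sorted$sg_id, rev_sorted$wb_id)
  expect_equal(fwd_sorted$wb_id, rev_sorted$sg_id)
  expect_equal(fwd_sorted$identity, rev_sorted$identity)
  expect_equal(fwd_sorted$sg_start, rev_sorted$wb_start)
  expect_equal(fwd_sorted$wb_end, rev_sorted$sg_end)
})

test_that("banded aligner equals full dynamic programming on small instances", {
  set.seed(105)
  for (i in 1:25) {
    len <- sample(150:500, 1)
    a <- random_dna(len)
    b <- plant_mismatches(a, sample(0:5, 1))
    got <- align_banded(a, b)
    want <- dp_align_oracle(a, b)
    expect_equal(got$score, want$score)
    expect_equal(got$columns, want$columns)
    expect_equal(got$matches, want$matches)
  }
  # instances with a small indel: the optimum must still be found within
  # the band, so scores agree with unrestricted DP
  for (i in 1:10) {
    a <- random_dna(200)
    cut <- sample(50:150, 1)
    b <- paste0(substr(a, 1, cut), substr(a, cut + sample(1:3, 1) + 1, 200))
    got <- align_banded(a, b)
    want <- dp_align_oracle(a, b)
    expect_equal(got$score, want$score)
  }
})

test_that("one-to-many conflicts resolve to the best pair only", {
  set.seed(106)
  s <- random_dna(300)
  near <- plant_mismatches(s, 1)
  # two SG copies compete for one WB gene; the exact copy must win
  pairs <- find_ortholog_pairs(c(exact = s, nearby = near), c(h = s))
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$sg_id, "exact")
  expect_equal(pairs$identity, 1.0)
})

test_that("reverse-complement matches are only found when enabled", {
  set.seed(107)
  s <- random_dna(250)
  wb_rc <- c(h = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  expect_equal(nrow(find_ortholog_pairs(c(g = s), wb_rc)), 0L)
  p <- find_ortholog_pairs(c(g = s), wb_rc, search_revcomp = TRUE)
  expect_equal(nrow(p), 1L)
  expect_equal(p$strand, "-")
  expect_equal(p$identity, 1.0)
  # spans are reported on the forward strand of both transcripts
  cl <- clip_overlap(p[1, ], c(g = s), wb_rc)
  expect_equal(cl$sg_region_seq, s)
  expect_equal(cl$wb_region_seq, wb_rc[["h"]])
})

test_that("clipping returns exact substrings and validates spans", {
  set.seed(108)
  core <- random_dna(200)
  sg <- c(g = paste0(random_dna(50), core))   # core at [51, 250]
  wb <- c(h = paste0(core, random_dna(60)))   # core at [1, 200]
  pairs <- find_ortholog_pairs(sg, wb)
  expect_equal(nrow(pairs), 1L)
  expect_equal(c(pairs$sg_start, pairs$sg_end), c(51L, 250L))
  expect_equal(c(pairs$wb_start, pairs$wb_end), c(1L, 200L))
  cl <- clip_overlap(pairs[1, ], sg, wb)
  expect_equal(cl$sg_region_seq, core)
  expect_equal(cl$wb_region_seq, core)
  expect_equal(cl$len_sg, 200L)
  bad <- pairs[1, ]
  bad$sg_end <- 999L
  expect_error(clip_overlap(bad, sg, wb), "outside")
})

test_that("pair recovery matches the binomial mismatch model", {
  # at per-base rate 0.005 and fixed length 300 a pair survives iff it
  # carries <= 2 mismatches; the expected recovery is P(Bin(300, 0.005) <= 2)
  n <- 600
  tr <- simulate_transcriptomes(n, 0, length_mean = 300, length_sdlog = 0,
                                mutation_rate = 0.005, seed = 2024)
  pairs <- find_ortholog_pairs(tr$sg, tr$wb)
  phat <- nrow(pairs) / n
  p0 <- pbinom(2, 300, 0.005)
  half_width <- qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), half_width)
  # and the generator's own bookkeeping agrees with which pairs survive
  expect_equal(nrow(pairs), sum(tr$truth$n_mut <= 2))
})
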