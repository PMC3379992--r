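test_that("Audic-Claverie p matches hand-derived small cases", {
  expect_equal(ac_pvalue(0, 0, 1e6, 1e6), 1.0)
  # x=5, y=0, equal libraries: P(Y<=0) = (1/2)^6
  expect_equal(ac_pvalue(5, 0, 1e6, 1e6, sided = "one"), 0.015625)
  expect_equal(ac_pvalue(5, 0, 1e6, 1e6), 0.03125)
  expect_error(ac_pvalue(-1, 0, 1e6, 1e6), "nonnegative")
  expect_error(ac_pvalue(1, 1, 0, 1e6), "positive")
})

test_that("Audic-Claverie p equals the summation oracle on a count grid", {
  for (ratio in c(0.5, 1, 2)) {
    n1 <- 1e6
    n2 <- ratio * 1e6
    for (x in c(0, 1, 2, 5, 9, 12)) {
      for (y in c(0, 1, 3, 7, 12)) {
        expect_equal(ac_pvalue(x, y, n1, n2), ac_oracle(x, y, n1, n2),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("swapping the libraries obeys the exact tail duality", {
  # the inclusive-tail convention is not exactly symmetric under swapping
  # the two libraries (the point mass at the observed pair enters the two
  # orientations differently), but the inclusive lower tails of the two
  # orientations are exact complements: P(Y<=y | x; n1,n2) +
  # P(X<=x | y; n2,n1) = 1. Verified against the summation oracle.
  set.seed(41)
  for (i in 1:40) {
    x <- sample(0:30, 1)
    y <- sample(0:30, 1)
    n1 <- sample(c(5e5, 1e6, 2e6), 1)
    n2 <- sample(c(5e5, 1e6, 2e6), 1)
    lower1 <- sum(ac_pmf_oracle(0:y, x, n1, n2))
    lower2 <- sum(ac_pmf_oracle(0:x, y, n2, n1))
    expect_equal(lower1 + lower2, 1, tolerance = 1e-10)
    # consequently the two p-value orientations agree in magnitude
    p1 <- ac_pvalue(x, y, n1, n2)
    p2 <- ac_pvalue(y, x, n2, n1)
    expect_lte(max(p1, p2) / min(p1, p2), 10)
  }
})

test_that("conditional distribution sums to one (summation oracle sanity)", {
  for (x in c(0, 3, 10)) {
    total <- sum(ac_pmf_oracle(0:2000, x, 1e6, 2e6))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches hand computation and the naive oracle", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0, 5)), rep(0, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  # with ties
  p <- c(0.01, 0.01, 0.5, 0.2, 0.2)
  expect_equal(bh_fdr(p), bh_oracle(p))
})

test_that("call_de applies FDR and log2-ratio thresholds jointly", {
  n <- 1e6
  counts <- data.frame(
    pair_id = c("ref_like", "sym", "strong_up", "strong_down"),
    count_sg = c(2218, 500, 100, 10),
    count_wb = c(2372, 500, 10, 100),
    len_sg = 300, len_wb = 300,
    rpkm_sg = c(2217.95, 500, 100, 10) / 0.3,
    rpkm_wb = c(2371.84, 500, 10, 100) / 0.3
  )
  de <- call_de(counts, n, n)
  # a reference-level gene: ratio well under a doubling -> not_de
  expect_equal(de$call[1], "not_de")
  expect_equal(abs(de$log2_ratio[1]), 0.0968, tolerance = 1e-3)
  # exact symmetry -> not_de with p = 1 region
  expect_equal(de$call[2], "not_de")
  # 10-fold with strong counts -> called, in both directions
  expect_equal(de$log2_ratio[3], log2(10), tolerance = 1e-9)
  expect_lt(de$p_value[3], 1e-12)
  expect_equal(de$call[3], "higher_in_sg")
  expect_equal(de$call[4], "lower_in_sg")
  # invariant: not_de whenever fdr >= cut or |log2| < cut
  weak <- de$fdr >= 1e-3 | abs(de$log2_ratio) < 1
  expect_true(all(de$call[weak] == "not_de"))
})

test_that("zero RPKMs are floored and flagged, double zeros stay not_de", {
  counts <- data.frame(
    pair_id = c("one_zero", "both_zero", "filler"),
    count_sg = c(40, 0, 5), count_wb = c(0, 0, 5),
    len_sg = 300, len_wb = 300,
    rpkm_sg = c(40, 0, 5), rpkm_wb = c(0, 0, 5)
  )
  de <- call_de(counts, 1e5, 1e5)
  expect_true(de$ratio_flagged[1])
  expect_equal(de$log2_ratio[1], log2(40 / 5))  # floored at min nonzero
  expect_false(de$ratio_flagged[2])
  expect_true(is.na(de$log2_ratio[2]))
  expect_equal(de$call[2], "not_de")
})

test_that("type-I error of the AC test stays at or below nominal", {
  # null pairs: equal true expression, equal library sizes
  set.seed(43)
  n_pairs <- 2000
  lambda <- rlnorm(n_pairs, 3, 1)
  x <- rpois(n_pairs, lambda)
  y <- rpois(n_pairs, lambda)
  p <- ac_pvalue(x, y, 1e6, 1e6)
  rate <- mean(p < 0.05)
  upper <- 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / n_pairs)
  expect_lte(rate, upper)
})

test_that("annotation rates are reported per class to one decimal", {
  calls <- data.frame(
    pair_id = sprintf("p%04d", 1:1100),
    call = rep(c("lower_in_sg", "higher_in_sg", "not_de"),
               c(443, 565, 92)),
    stringsAsFactors = FALSE
  )
  annotated <- c(calls$pair_id[1:214],          # 214 of the 443 low
                 calls$pair_id[444:517])        # 74 of the 565 high
  ar <- annotation_rate(calls, annotated)
  expect_equal(ar$percent[ar$call == "lower_in_sg"], 48.3)
  expect_equal(ar$percent[ar$call == "higher_in_sg"], 13.1)
  none <- annotation_rate(calls[calls$call == "not_de", ], character())
  expect_equal(none$percent[none$call == "not_de"], 0.0)
  expect_true(is.na(none$percent[none$call == "higher_in_sg"]))
})
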