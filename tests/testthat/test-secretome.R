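# codons helper: encode a protein (no stops) as DNA. The chosen codons
# poison the other reading frames: in-frame TTA (Leu) puts a TAA stop on
# the minus strand, and the LT / DY digrams put TTA substrings (= minus
# strand stops) at the other two phases.
encode_protein <- function(protein) {
  codon_of <- c(M = "ATG", K = "AAA", P = "CCA", G = "GGA", F = "TTT",
                L = "TTA", A = "GCC", D = "GAT", E = "GAA", S = "TCT",
                V = "GTT", R = "CGT", T = "ACG", N = "AAC", Q = "CAA",
                Y = "TAT", W = "TGG", I = "ATC")
  paste(codon_of[strsplit(protein, "")[[1]]], collapse = "")
}

test_that("a full-length ORF in frame +1 is extracted with its ATG", {
  prot <- "MKLPGFLTDYESVRLTDYNQKLTAGFDYVW"
  dna <- paste0(encode_protein(prot), "TAA")
  cds <- extract_cds(setNames(dna, "g1"), min_codons = 10)
  expect_equal(cds$frame, 1L)
  expect_equal(cds$protein, prot)
  expect_true(cds$complete_5p)
  expect_equal(c(cds$cds_start, cds$cds_end), c(1L, nchar(dna) - 3L))
  # translation oracle: the recorded span in the recorded frame
  # reproduces the protein
  oracle <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(dna, cds$cds_start, cds$cds_end))))
  expect_equal(oracle, prot)
})

test_that("a hit on the reverse strand yields forward coordinates", {
  prot <- "MKPGFLADESVRTNQKLMGA"
  fwd_cds <- paste0(encode_protein(prot), "TGA")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd_cds)))
  dna <- paste0(rc, "C")  # ORF now on the minus strand, frame -2
  hits <- data.frame(qseqid = "g1", sseqid = "ref", pident = 98,
                     length = 60, mismatch = 1, gapopen = 0,
                     qstart = nchar(dna) - 1, qend = 2, sstart = 1, send = 20,
                     evalue = 1e-30, bitscore = 120)
  cds <- extract_cds(setNames(dna, "g1"), hits = hits, min_codons = 10)
  expect_equal(cds$frame, -2L)
  expect_equal(cds$protein, prot)
  # manual six-frame oracle: translate the reverse complement
  oracle <- as.character(Biostrings::translate(
    Biostrings::reverseComplement(Biostrings::DNAString(
      substr(dna, cds$cds_start, cds$cds_end)))))
  expect_equal(oracle, prot)
})

test_that("5'-truncated coding sequences are flagged incomplete", {
  prot <- "KPGFLADESVRTNQKLGA"  # no Met: transcript starts mid-CDS
  dna <- paste0(encode_protein(prot), "TAA")
  cds <- extract_cds(setNames(dna, "g1"), min_codons = 10)
  expect_false(cds$complete_5p)
  v <- classify_secretion(cds, list(sp_present = TRUE, cleavage_pos = 20,
                                    tm_segments = NULL))
  expect_equal(v$verdict, "incomplete_5p")
})

test_that("transcripts without a long ORF yield no CDS", {
  # a 60-base transcript cannot hold 30 codons in any frame
  set.seed(61)
  dna <- random_dna(60)
  expect_null(extract_cds(setNames(dna, "g1")))
})

test_that("canonical topology TSVs and predictor short formats parse alike", {
  sp_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsp_present\tcleavage_pos",
               "g1\tY\t23", "g2\tN\t0"), sp_tsv)
  tm_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttm_start\ttm_end", "g1\t5\t27"), tm_tsv)
  topo <- load_topology(sp_tsv, tm_tsv)
  expect_equal(topo$sp$sp_present, c(TRUE, FALSE))
  expect_equal(topo$sp$cleavage_pos[1], 23L)
  expect_equal(topo$tm$tm_start, 5L)

  sp3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# SignalP-NN euk predictions",
    "# name Cmax pos ? Ymax pos ? Smax pos ? Smean ? D ?",
    "g1 0.823 23 Y 0.802 23 Y 0.972 12 Y 0.882 Y 0.842 Y",
    "g2 0.102 11 N 0.090 11 N 0.141 2 N 0.101 N 0.096 N"), sp3)
  tmh <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "g1\tlen=236\tExpAA=23.10\tFirst60=0.03\tPredHel=1\tTopology=o5-27i",
    "g2\tlen=120\tExpAA=0.10\tFirst60=0.01\tPredHel=0\tTopology=o"), tmh)
  topo2 <- load_topology(sp3, tmh)
  expect_equal(topo2$sp$sp_present, c(TRUE, FALSE))
  expect_equal(topo2$sp$cleavage_pos[1], 23L)
  expect_equal(topo2$tm$gene_id, "g1")
  expect_equal(unname(unlist(topo2$tm[1, c("tm_start", "tm_end")])),
               c(5L, 27L))
})

test_that("inconsistent TMHMM lines are rejected with their line number", {
  tmh <- withr::local_tempfile(fileext = ".txt")
  writeLines(
    "g1\tlen=236\tExpAA=23.10\tFirst60=0.03\tPredHel=2\tTopology=o5-27i",
    tmh)
  sp_tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tY\t23", sp_tsv)
  expect_error(load_topology(sp_tsv, tmh), "line 1")
})

test_that("the retention rule distinguishes secreted from anchored", {
  cds <- list(gene_id = "g1", complete_5p = TRUE)
  no_sp <- list(sp_present = FALSE, cleavage_pos = NA, tm_segments = NULL)
  expect_equal(classify_secretion(cds, no_sp)$verdict, "no_signal")
  sp_only <- list(sp_present = TRUE, cleavage_pos = 23, tm_segments = NULL)
  expect_equal(classify_secretion(cds, sp_only)$verdict, "secreted")
  # one TM overlapping the signal peptide (residues 1..22) is tolerated
  tm_in_sp <- list(sp_present = TRUE, cleavage_pos = 23,
                   tm_segments = matrix(c(7, 24), 1))
  expect_equal(classify_secretion(cds, tm_in_sp)$verdict, "secreted")
  tm_out <- list(sp_present = TRUE, cleavage_pos = 23,
                 tm_segments = matrix(c(30, 52), 1))
  expect_equal(classify_secretion(cds, tm_out)$verdict, "membrane_anchored")
  two_tm <- list(sp_present = TRUE, cleavage_pos = 23,
                 tm_segments = matrix(c(7, 30, 24, 52), 2))
  expect_equal(classify_secretion(cds, two_tm)$verdict, "membrane_anchored")
})

test_that("batch classification is deterministic and order-independent", {
  set.seed(62)
  n <- 30
  cds_list <- lapply(sprintf("g%02d", 1:n), function(g) {
    list(gene_id = g, complete_5p = TRUE)
  })
  sp <- data.frame(gene_id = sprintf("g%02d", 1:n),
                   sp_present = rep(c(TRUE, FALSE), length.out = n),
                   cleavage_pos = 20L)
  tm <- data.frame(gene_id = c("g01", "g03"), tm_start = 40L, tm_end = 60L)
  topo <- structure(list(sp = sp, tm = tm), class = "glandscope_topology")
  v1 <- classify_secretion_batch(cds_list, topo)
  v2 <- classify_secretion_batch(rev(cds_list), topo)
  expect_equal(v1[order(v1$gene_id), "verdict"],
               v2[order(v2$gene_id), "verdict"])
})

test_that("toy predictor recovers planted secretion labels cleanly", {
  n <- 60
  planted <- rep(c(TRUE, FALSE), length.out = n)
  prot <- make_toy_proteins(n, secreted = planted, seed = 63)
  topo <- predict_topology_toy(prot)
  expect_equal(topo$sp$sp_present, planted)  # zero crossovers
  # planted anchors demote signal-positive proteins to membrane_anchored
  prot2 <- make_toy_proteins(20, secreted = TRUE,
                             extra_tm = rep(c(TRUE, FALSE), 10), seed = 64)
  topo2 <- predict_topology_toy(prot2)
  cds_list <- lapply(names(prot2), function(g) {
    list(gene_id = g, complete_5p = TRUE)
  })
  v <- classify_secretion_batch(cds_list, topo2)
  expect_equal(v$verdict == "membrane_anchored", attr(prot2, "extra_tm"))
  expect_equal(v$verdict == "secreted", !attr(prot2, "extra_tm"))
})

test_that("homolog screening keeps the best hit per query at the cut-off", {
  tab <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-4\t80",   # above cut-off
    "q2\ts1\t97.0\t100\t3\t0\t1\t100\t1\t100\t1e-6\t90",
    "q3\ts2\t99.0\t100\t1\t0\t1\t100\t1\t100\t1e-6\t95",
    "q3\ts3\t99.5\t100\t1\t0\t1\t100\t1\t100\t1e-9\t110"
  )
  writeLines(rows, tab)
  hits <- read_blast_tab(tab)
  best <- filter_homologs(hits)
  expect_false("q1" %in% best$qseqid)    # E = 1e-4 excluded
  expect_true("q2" %in% best$qseqid)     # E = 1e-6 retained
  expect_equal(best$sseqid[best$qseqid == "q3"], "s3")  # lowest E wins
  expect_equal(nrow(best[best$qseqid == "q3", ]), 1L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\tnot_a_number\t80",
             bad)
  expect_error(read_blast_tab(bad), "E-value")
})
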