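# Nei-Gojobori site/difference counting, Jukes-Cantor correction,
# partitioned pairwise rates and simulation recovery.

SENSE <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

test_that("site counts match exhaustive enumeration for all 61 sense codons", {
  for (strict in c(FALSE, TRUE)) {
    got <- codonSites(SENSE, strict = strict)
    for (i in seq_along(SENSE)) {
      orc <- oracleSites(SENSE[i], strict = strict)
      expect_equal(got$s[i], orc[["s"]], tolerance = 1e-12)
    }
    expect_equal(got$s + got$n, rep(3, 61))
  }
  expect_equal(codonSites("TTT")$s, 1 / 3)
  expect_equal(codonSites("ATG")$s, 0)
  expect_identical(codonSites("ATG")$n, 3)
  expect_error(codonSites("TAA"), "stop codon")
  expect_error(codonSites("AT-"), "not a 3-nt")
})

test_that("pathway-averaged differences match the path-enumeration oracle", {
  expect_equal(codonDifferences("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(codonDifferences("AAA", "AAA"), c(sd = 0, nd = 0))
  expect_equal(codonDifferences("TTT", "GTA"), oracleDiffs("TTT", "GTA"))
  set.seed(55)
  for (i in 1:150) {
    a <- sample(SENSE, 1); b <- sample(SENSE, 1)
    got <- codonDifferences(a, b)
    orc <- oracleDiffs(a, b)
    expect_equal(got, orc, tolerance = 1e-12)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(got[1] + got[2]), k)
  }
  expect_error(codonDifferences("TAA", "TAC"), "stop codon")
})

test_that("Jukes-Cantor correction has the closed form and saturates", {
  expect_equal(jcCorrect(0), 0)
  expect_equal(jcCorrect(0.1), 0.10732, tolerance = 1e-4)
  expect_equal(jcCorrect(0.1), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_true(is.na(jcCorrect(0.75)))
  expect_true(is.na(jcCorrect(0.9)))
  grid <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jcCorrect(grid)) > 0))
})

test_that("pairwise NG86 is symmetric, zero on identity, oracle-equal on toys", {
  set.seed(66)
  a <- paste(sample(SENSE, 20, replace = TRUE), collapse = "")
  same <- pairwiseNG86(a, a)
  expect_equal(same$Sd, 0); expect_equal(same$Nd, 0)
  expect_equal(same$dS, 0); expect_equal(same$dN, 0)
  expect_identical(same$status, "dS_zero")

  for (i in 1:10) {
    x <- paste(sample(SENSE, 20, replace = TRUE), collapse = "")
    y <- paste(sample(SENSE, 20, replace = TRUE), collapse = "")
    ab <- pairwiseNG86(x, y); ba <- pairwiseNG86(y, x)
    expect_equal(ab$S, ba$S); expect_equal(ab$Sd, ba$Sd)
    expect_equal(ab$dN, ba$dN)
    orc <- oracleNG86(x, y)
    expect_equal(ab$S, orc$S, tolerance = 1e-10)
    expect_equal(ab$N, orc$N, tolerance = 1e-10)
    expect_equal(ab$Sd, orc$Sd, tolerance = 1e-10)
    expect_equal(ab$Nd, orc$Nd, tolerance = 1e-10)
    # pathway-averaged differences sum to the raw nucleotide differences
    rawDiff <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    expect_equal(ab$Sd + ab$Nd, rawDiff, tolerance = 1e-10)
  }
})

test_that("gap and N codons are excluded pairwise", {
  x <- "ATGAAATTTCCC"
  y <- "ATG---TTTCCC"
  r <- pairwiseNG86(x, y)
  expect_identical(r$n_codons, 3L)
  expect_identical(r$n_excluded, 1L)
  yn <- "ATGANATTTCCC"
  expect_identical(pairwiseNG86(x, yn)$n_codons, 3L)
  expect_error(pairwiseNG86("---", "---"), "no comparable")
  expect_error(pairwiseNG86("ATGC", "ATGC"), "divisible by 3")
})

test_that("codon alignments validate frame-aligned whole-codon gaps", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATGAAATTT", ">s2", "ATG---TTT"), f)
  aln <- readCodonAlignment(f)
  expect_s4_class(aln, "CodonAlignment")
  bad <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATGAAATTT", ">s2", "ATGA--TTT"), bad)
  expect_error(readCodonAlignment(bad), "whole codons")
  uneq <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ATGAAATTT", ">s2", "ATGAAA"), uneq)
  expect_error(readCodonAlignment(uneq), "equal length")
})

test_that("partition handling restricts, validates and degenerates correctly", {
  set.seed(77)
  sim <- simulateCodonAlignment(3, 60, 0.2, 0.5, seed = 78)
  aln <- codonAlignment(sim$alignment)
  whole <- partitionSummary(aln)
  part <- partitionSummary(aln, list(all = matrix(c(1L, 180L), nrow = 1)))
  expect_equal(whole$summary$mean_ratio, part$summary$mean_ratio)
  # split partition halves reassemble the coordinate space
  halves <- partitionSummary(aln, list(h1 = matrix(c(1L, 90L), nrow = 1),
                                       h2 = matrix(c(91L, 180L), nrow = 1)))
  expect_identical(nrow(halves$pairs), 6L)
  expect_error(partitionSummary(aln, list(bad = matrix(c(1L, 200L), nrow = 1))),
               "exceeds alignment")
  expect_error(partitionSummary(aln, list(bad = matrix(c(1L, 4L), nrow = 1))),
               "divisible by 3")
  # identical sequences: every pair excluded as dS_zero
  two <- codonAlignment(c(s1 = "ATGAAATTT", s2 = "ATGAAATTT"))
  res <- partitionSummary(two)
  expect_identical(res$summary$n_excluded, 1L)
  expect_identical(res$summary$n_ok, 0L)
})

test_that("simulated omega is recovered within 0.1 over 20 seeded replicates", {
  for (om in c(0.2, 0.5)) {
    est <- vapply(1:20, function(s) {
      sim <- simulateCodonAlignment(2, 300, 0.3, om, seed = 9000 + s)
      pairwiseNG86(as.character(sim$alignment[[1]]),
                   as.character(sim$alignment[[2]]))$ratio
    }, numeric(1))
    expect_lt(abs(mean(est, na.rm = TRUE) - om), 0.1)
  }
})

test_that("contrasting partitions are ranked correctly and called purifying", {
  ok <- 0L
  for (r in 1:6) {
    sim <- simulatePartitionedAlignment(
      8, list(conserved = list(nCodons = 100, omega = 0.05),
              relaxed = list(nCodons = 100, omega = 0.4)),
      subsPerCodon = 0.3, seed = 500 + r)
    s <- partitionSummary(sim$alignment, sim$partitions)$summary
    expect_identical(unique(s$classification), "purifying")
    if (s$mean_ratio[s$partition == "conserved"] <
        s$mean_ratio[s$partition == "relaxed"]) ok <- ok + 1L
  }
  expect_identical(ok, 6L)
})

test_that("aligned identity reports the printed percentage", {
  ai <- alignedIdentity(166, 282)
  expect_equal(ai$percent, 100 * 166 / 282)
  expect_identical(ai$reported, 59)
  expect_equal(alignedIdentity(0, 100)$percent, 0)
  expect_equal(alignedIdentity(100, 100)$percent, 100)
  expect_error(alignedIdentity(1, 0))
})
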