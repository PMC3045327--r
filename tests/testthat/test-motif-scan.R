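# IUPAC motif scanning, purine runs, and bipartite region summaries.

test_that("the bundled catalogue carries the five doublesex elements", {
  cat <- defaultMotifCatalogue()
  d <- as.data.frame(cat)
  expect_identical(length(cat), 5L)
  expect_setequal(d$name, c("dsxRE", "NvdsxRE", "RBP1_A", "RBP1_B", "TRA2_ISS"))
  expect_identical(nchar(d$iupac[match(c("dsxRE", "NvdsxRE", "RBP1_A",
                                         "RBP1_B", "TRA2_ISS"), d$name)]),
                   c(13L, 8L, 9L, 7L, 5L))
})

test_that("catalogue validation rejects bad codes and duplicates", {
  expect_error(MotifCatalogue(c("a", "a"), c("ACGT", "ACGT")), "duplicated")
  expect_error(MotifCatalogue("a", "ACJT"), "invalid IUPAC")
  f <- tempfile(fileext = ".json")
  writeLines("[]", f)
  expect_warning(cat <- readMotifCatalogue(f), "empty")
  expect_identical(length(cat), 0L)
})

test_that("IUPAC expansion is the cartesian product of position sets", {
  expect_setequal(expandIupac("KGAAGATW"),
                  c("TGAAGATT", "TGAAGATA", "GGAAGATT", "GGAAGATA"))
  expect_setequal(expandIupac("CAAGR"), c("CAAGA", "CAAGG"))
  expect_length(expandIupac("NNN"), 64L)
  expect_error(expandIupac("NNNNNNN"), "cap")
})

test_that("planted motifs are recalled exactly, with mismatch control", {
  set.seed(101)
  bg <- randomSeq(50)
  planted <- paste0(substr(bg, 1, 10), "TCATCAATCAACA", substr(bg, 24, 50))
  cat <- defaultMotifCatalogue()["dsxRE"]
  hits <- scanMotifs(planted, cat, maxMismatch = 0L)
  orc <- oracleScan(planted, "TCWWCAATCAACA", 0L)
  expect_identical(hits$start, orc$start)
  expect_true(11L %in% hits$start)
  # mutate one planted base: lost at mm 0, found at mm 1
  mut <- planted
  substr(mut, 13, 13) <- "G"
  expect_false(11L %in% scanMotifs(mut, cat, maxMismatch = 0L)$start)
  h1 <- scanMotifs(mut, cat, maxMismatch = 1L)
  expect_true(11L %in% h1$start)
  expect_identical(h1$mismatches[h1$start == 11L], 1L)
})

test_that("scanning equals the naive sliding-window oracle on random inputs", {
  set.seed(202)
  for (i in 1:300) {
    seq <- randomSeq(sample(30:120, 1), withN = TRUE)
    motif <- randomIupac(sample(3:10, 1))
    k <- sample(0:2, 1)
    cat <- MotifCatalogue("m", motif)
    hits <- scanMotifs(seq, cat, maxMismatch = k)
    orc <- oracleScan(seq, motif, k)
    expect_identical(hits$start, orc$start)
    expect_identical(hits$mismatches, as.integer(orc$mismatches))
  }
})

test_that("forward hits equal reverse-strand hits on the reverse complement", {
  set.seed(303)
  cat <- defaultMotifCatalogue()
  for (i in 1:20) {
    seq <- randomSeq(300)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    fwd <- scanMotifs(seq, cat, strands = "forward")
    both <- scanMotifs(rc, cat, strands = "both")
    rev <- both[both$strand == "-", ]
    expect_identical(nrow(rev), nrow(fwd))
  }
})

test_that("purine runs match the hand case and the maximal-run oracle", {
  r <- detectPurineRuns("CCAAGAAGAAGAAACC", minLen = 10)
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 3L)
  expect_identical(r$end, 14L)
  expect_identical(r$length, 12L)
  expect_equal(r$purine_fraction, 1.0)
  expect_identical(nrow(detectPurineRuns(strrep("CT", 20), minLen = 10)), 0L)

  set.seed(404)
  for (i in 1:200) {
    seq <- randomSeq(sample(30:150, 1))
    got <- detectPurineRuns(seq, minLen = 6)
    orc <- oracleRuns(seq, 6)
    if (is.null(orc)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got$start, as.integer(orc[, "start"]))
      expect_identical(got$end, as.integer(orc[, "end"]))
    }
  }
  # relaxed-fraction mode merges qualifying windows
  r2 <- detectPurineRuns("AAAAACAAAAA", minLen = 5, minFrac = 0.8)
  expect_identical(nrow(r2), 1L)
  expect_identical(c(r2$start, r2$end), c(1L, 11L))
})

test_that("chance-hit counts match the closed-form expectation over seeds", {
  motif <- "KGAAGATW"
  L <- 500L
  expe <- expectedChanceHits(motif, L)
  expect_equal(expe, (L - 8 + 1) * 4 / 4^8)
  cat <- MotifCatalogue("m", motif)
  set.seed(505)
  counts <- vapply(1:200, function(i)
    nrow(scanMotifs(randomSeq(L), cat)), numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expe), 3 * max(se, 1e-3))
})

test_that("bipartite summaries count, estimate chance and test exclusivity", {
  regions <- data.frame(region = c("exon5a", "exon5b"),
                        start = c(1L, 501L), end = c(500L, 1000L))
  set.seed(606)
  bg <- randomSeq(1000)
  pl <- plantMotifs(bg, data.frame(motif = "NvdsxRE", iupac = "KGAAGATW",
                                   region = "exon5a", count = 4),
                    regions = regions, seed = 607)
  cat <- defaultMotifCatalogue()
  hits <- scanMotifs(pl$sequence, cat, regions = regions)
  bs <- summarizeRegions(hits, regions, cat, compare = c("exon5a", "exon5b"))
  expect_gte(bs$counts["NvdsxRE", "exon5a"], 4)
  expect_equal(unname(bs$expected["NvdsxRE", "exon5a"]), 493 * 4 / 4^8,
               tolerance = 1e-12)
  # counts split per region sum to the labelled total
  expect_identical(sum(bs$counts), sum(!is.na(hits$region_label)))

  # the exact test agrees with an independent hypergeometric computation
  tst <- bs$tests[bs$tests$motif_name == "NvdsxRE", ]
  expect_equal(tst$p_value,
               oracleFisher2x2(tst$count_A, tst$positions_A,
                               tst$count_B, tst$positions_B),
               tolerance = 1e-9)
  # no hits anywhere -> p = 1
  none <- summarizeRegions(hits[0, ], regions, cat,
                           compare = c("exon5a", "exon5b"))
  expect_true(all(none$tests$p_value == 1))
  expect_true(all(none$counts == 0))
})

test_that("a 5-vs-0 split in equal regions is called exclusive", {
  regions <- data.frame(region = c("A", "B"),
                        start = c(1L, 501L), end = c(500L, 1000L))
  set.seed(707)
  bg <- randomSeq(1000)
  pl <- plantMotifs(bg, data.frame(motif = "dsxRE", iupac = "TCWWCAATCAACA",
                                   region = "A", count = 5),
                    regions = regions, seed = 708)
  cat <- defaultMotifCatalogue()["dsxRE"]
  hits <- scanMotifs(pl$sequence, cat, regions = regions)
  bs <- summarizeRegions(hits, regions, cat, compare = c("A", "B"))
  tst <- bs$tests
  expect_gte(tst$count_A, 5)
  expect_equal(tst$p_value,
               oracleFisher2x2(tst$count_A, tst$positions_A,
                               tst$count_B, tst$positions_B),
               tolerance = 1e-9)
})

test_that("hit clustering groups nearby occurrences of one motif", {
  hits <- data.frame(motif_name = "m",
                     start = c(1L, 20L, 200L), end = c(8L, 27L, 207L))
  cl <- clusterHits(hits, maxGap = 50L)
  expect_identical(cl$cluster, c("m_c1", "m_c1", "m_c2"))
})
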