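# Ground-truth generators: determinism, truth verification, and
# controllability of the planted signal.

smallLocusConfig <- function(seed = 1L, p = 0.7, fid = 6L) {
  list(seed = seed,
       exons = data.frame(
         exon_id = paste0("e", 1:4),
         size = c(60L, 45L, 80L, 50L),
         class = c("common", "female_specific", "male_specific", "common")),
       intronSizes = c(120L, 208L, 64L),
       acceptorP = p, donorFidelity = fid)
}

test_that("locus simulation is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "locA"); d2 <- file.path(tempdir(), "locB")
  writeLocus(simulateLocus(smallLocusConfig(seed = 5L)), d1)
  writeLocus(simulateLocus(smallLocusConfig(seed = 5L)), d2)
  for (f in c("genome.fa", "model.gff3", "class_map.json", "truth.json"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  # and a different seed changes the genome
  d3 <- file.path(tempdir(), "locC")
  writeLocus(simulateLocus(smallLocusConfig(seed = 6L)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fa"))),
                         unname(tools::md5sum(file.path(d3, "genome.fa")))))
})

test_that("emitted fixtures load cleanly and truth matches the sequence", {
  loc <- simulateLocus(smallLocusConfig(seed = 11L))
  dir <- file.path(tempdir(), "locLoad")
  files <- writeLocus(loc, dir)
  expect_no_warning(g <- readGenome(files[["genome"]]))
  expect_no_warning(m <- readGeneModel(files[["gff3"]],
                                       classMap = files[["class_map"]]))
  expect_identical(S4Vectors::mcols(exons(m))$class_label,
                   S4Vectors::mcols(exons(loc$model))$class_label)
  # the planted junction windows are recovered verbatim by extraction
  jx <- junctionContexts(m, g)
  expect_identical(jx$donor_intronic,
                   paste0(loc$truth$windows$donor_window,
                          substr(jx$donor_intronic, 7, 16)))
  expect_identical(jx$acceptor_intronic, loc$truth$windows$acceptor_window)
})

test_that("acceptor composition and donor fidelity are controllable", {
  all12 <- simulateLocus(smallLocusConfig(seed = 2L, p = 1))
  jxA <- junctionContexts(all12$model, all12$genome)
  expect_identical(scoreAcceptor(jxA$acceptor_intronic)$y_count,
                   rep(12L, 3))
  none <- simulateLocus(smallLocusConfig(seed = 3L, p = 0))
  jxN <- junctionContexts(none$model, none$genome)
  expect_identical(scoreAcceptor(jxN$acceptor_intronic)$y_count, rep(0L, 3))
  for (fid in c(0L, 3L, 6L)) {
    loc <- simulateLocus(smallLocusConfig(seed = 4L + fid, fid = fid))
    jx <- junctionContexts(loc$model, loc$genome)
    expect_identical(scoreDonor(substr(jx$donor_intronic, 1, 6))$match_count,
                     rep(fid, 3))
  }
  expect_error(simulateLocus(modifyList(smallLocusConfig(),
                                        list(intronSizes = c(20L, 208L, 64L)))),
               "cannot host")
  expect_error(simulateLocus(list(exons = data.frame())), "seed is mandatory")
})

test_that("a large simulated intron sample recovers the target consensus", {
  w <- simulateAcceptorWindows(4688, 0.668, seed = 17)
  st <- consensusFromIntrons(w)
  se <- sqrt(12 * 0.668 * 0.332) / sqrt(4688)
  expect_lt(abs(st$mean_y - 8.016), 3 * se)
  expect_true(all(substr(w, 15, 16) == "AG"))
})

test_that("motif planting records exact truth and detects collisions", {
  set.seed(21)
  bg <- randomSeq(400)
  regions <- data.frame(region = c("A", "B"), start = c(1L, 201L),
                        end = c(200L, 400L))
  pl <- plantMotifs(bg, data.frame(
    motif = c("NvdsxRE", "dsxRE"), iupac = c("KGAAGATW", "TCWWCAATCAACA"),
    region = c("A", "B"), count = c(4L, 5L)), regions = regions, seed = 22)
  expect_identical(nrow(pl$truth), 9L)
  for (i in seq_len(nrow(pl$truth)))
    expect_identical(substr(pl$sequence, pl$truth$start[i], pl$truth$end[i]),
                     pl$truth$word[i])
  # full recall by the scanner at the recorded offsets
  cat <- defaultMotifCatalogue()
  hits <- scanMotifs(pl$sequence, cat)
  expect_true(all(pl$truth$start %in% hits$start))

  expect_error(
    plantMotifs(bg, data.frame(motif = "m", iupac = "ACGTACGT", start = 399L),
                seed = 23), "does not fit")
  expect_error(
    plantMotifs(bg, data.frame(motif = c("m", "m2"),
                               iupac = c("ACGTACGT", "ACGTACGT"),
                               start = c(10L, 12L)), seed = 24), "collision")
  tiny <- data.frame(region = "t", start = 1L, end = 7L)
  expect_error(
    plantMotifs(bg, data.frame(motif = "m", iupac = "ACGTACGTA",
                               region = "t", count = 1L),
                regions = tiny, seed = 25), "cannot host")
})

test_that("repeat simulation is deterministic and clipped to introns", {
  lens <- c(i1 = 5000, i2 = 8000)
  s1 <- simulateRepeats(lens, 1.5, seed = 31)
  s2 <- simulateRepeats(lens, 1.5, seed = 31)
  expect_identical(s1$repeats, s2$repeats)
  f1 <- tempfile(); f2 <- tempfile()
  writeRepeats(s1$repeats, f1); writeRepeats(s2$repeats, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(all(s1$repeats$end <= lens[s1$repeats$contig]))
  expect_true(all(s1$repeats$start >= 1))
})

test_that("omega 0 forbids amino-acid change; stops never appear", {
  sim <- simulateCodonAlignment(3, 150, 0.8, 0, seed = 41)
  ps <- partitionSummary(codonAlignment(sim$alignment))
  expect_true(all(ps$pairs$Nd == 0))
  expect_true(all(ps$pairs$dN == 0))
  aa <- Biostrings::translate(sim$alignment)
  expect_false(any(grepl("\\*", as.character(aa))))
  expect_error(simulateCodonAlignment(2, 10, 0.1, 6, seed = 1), "omega")
})
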