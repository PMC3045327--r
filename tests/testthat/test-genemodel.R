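# Genome/gene-model I/O, intron derivation and junction windows.

test_that("FASTA loading enforces the alphabet and unique ids", {
  f <- writeTempFasta("acgt", "c1")
  g <- readGenome(f)
  expect_identical(as.character(g[["c1"]]), "ACGT")
  expect_identical(Biostrings::width(g), 4L)

  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f2)
  expect_error(readGenome(f2), "duplicate contig id 'c1'")

  f3 <- writeTempFasta("ACGXACGT", "c1")
  expect_error(readGenome(f3), "illegal character 'X' at position 4")
})

test_that("gene models round-trip through GFF3 with identical coordinates", {
  for (strand in c("+", "-")) {
    m <- GeneModel("g1", "ctg", strand,
                   start = c(10L, 200L, 400L), end = c(80L, 300L, 520L),
                   exonId = c("a", "b", "c"),
                   classLabel = c("common", "female_specific", "utr"))
    gff <- tempfile(fileext = ".gff3")
    writeGeneModel(m, gff)
    m2 <- readGeneModel(gff)
    ex1 <- exons(m); ex2 <- exons(m2)
    expect_identical(BiocGenerics::start(ex1), BiocGenerics::start(ex2))
    expect_identical(BiocGenerics::end(ex1), BiocGenerics::end(ex2))
    expect_identical(S4Vectors::mcols(ex1)$exon_id,
                     S4Vectors::mcols(ex2)$exon_id)
    expect_identical(S4Vectors::mcols(ex1)$class_label,
                     S4Vectors::mcols(ex2)$class_label)
    expect_identical(geneId(m2), "g1")
  }
})

test_that("class maps assign labels by exact id and by pattern", {
  cm <- tempfile(fileext = ".json")
  jsonlite::write_json(list(e2 = "female_specific", "^u" = "utr"), cm,
                       auto_unbox = TRUE)
  m <- GeneModel("g", "c", "+", c(1L, 100L, 200L), c(50L, 150L, 260L),
                 exonId = c("e1", "e2", "u3"))
  gff <- tempfile(fileext = ".gff3")
  writeGeneModel(m, gff)
  m2 <- readGeneModel(gff, classMap = cm)
  expect_identical(S4Vectors::mcols(exons(m2))$class_label,
                   c("common", "female_specific", "utr"))
})

test_that("invalid gene structures are rejected", {
  expect_error(GeneModel("g", "c", "+", c(1L, 50L), c(100L, 300L)),
               "overlap")
  expect_error(
    introns(GeneModel("g", "c", "+", 1L, 100L)), "< 2 exons")
  # abutting exons leave no room for an intron
  expect_error(
    introns(GeneModel("g", "c", "+", c(1L, 101L), c(100L, 200L))),
    "zero-length intron")
  f <- writeTempFasta("ACGT", "c1")
  g <- readGenome(f)
  m <- GeneModel("g", "c1", "+", 1L, 10L)
  gff <- tempfile(fileext = ".gff3")
  writeGeneModel(m, gff)
  expect_error(readGeneModel(gff, genome = g), "exceed contig")
  noexon <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "c1\t.\tgene\t1\t10\t.\t+\t.\tID=g"), noexon)
  expect_error(readGeneModel(noexon), "no exon features")
})

test_that("introns derive per adjacent exon pair with sex-specific flags", {
  m <- GeneModel("g", "c", "+", c(1L, 111L, 221L), c(100L, 210L, 320L),
                 exonId = c("e1", "e2", "e3"),
                 classLabel = c("common", "male_specific", "common"))
  ir <- introns(m)
  expect_length(ir, 2L)
  expect_identical(BiocGenerics::width(ir), c(10L, 10L))
  expect_identical(S4Vectors::mcols(ir)$preceding_exon_id, c("e1", "e2"))
  expect_identical(S4Vectors::mcols(ir)$sex_specific, c(TRUE, TRUE))
  # on '-' the transcription order reverses but the genomic gaps are equal
  m2 <- GeneModel("g", "c", "-", c(1L, 111L, 221L), c(100L, 210L, 320L),
                  exonId = c("e1", "e2", "e3"))
  ir2 <- introns(m2)
  expect_identical(S4Vectors::mcols(ir2)$preceding_exon_id, c("e3", "e2"))
  expect_identical(sort(BiocGenerics::start(ir2)),
                   sort(BiocGenerics::start(ir)))
})

test_that("junction windows match hand-built sequence on both strands", {
  h <- handLocus()
  jx <- junctionContexts(h$model, h$genome)
  expect_identical(nrow(jx), 1L)
  expect_identical(jx$donor_exonic, h$donor_exonic)
  expect_identical(jx$donor_intronic, h$donor_intronic)
  expect_identical(jx$acceptor_intronic, h$acceptor_intronic)
  expect_identical(jx$acceptor_exonic, h$acceptor_exonic)
  expect_false(jx$truncated)
  expect_true(jx$sex_specific)

  mir <- mirrorLocus(h$genome, h$model)
  jx2 <- junctionContexts(mir$model, mir$genome)
  cols <- c("donor_exonic", "donor_intronic", "acceptor_intronic",
            "acceptor_exonic", "intron_size")
  expect_identical(jx2[cols], jx[cols])
})

test_that("windows truncate (with a flag) at short flanking features", {
  # 4-bp first exon: donor-exonic window cannot reach 6 nt
  intron <- paste0("GTAAGT", strrep("C", 18), "TTCTTCTTTTTTACAG")  # 40 nt
  seq <- paste0("TTAG", intron, "GCAACC")
  g <- Biostrings::DNAStringSet(seq); names(g) <- "c"
  m <- GeneModel("g", "c", "+", c(1L, 45L), c(4L, 50L))
  jx <- junctionContexts(m, g)
  expect_identical(jx$donor_exonic, "TTAG")
  expect_true(jx$truncated)
  # 16-nt windows always end/start exactly at the intron boundary
  expect_identical(nchar(jx$acceptor_intronic), 16L)
})

test_that("junction windows under strand mirroring agree on random loci", {
  set.seed(42)
  for (rep in 1:5) {
    cfg <- list(seed = rep, exons = data.frame(
      exon_id = paste0("e", 1:4), size = sample(40:120, 4),
      class = c("common", "common", "female_specific", "common")),
      intronSizes = sample(40:200, 3), acceptorP = runif(1),
      donorFidelity = sample(0:6, 1))
    loc <- simulateLocus(cfg)
    jx <- junctionContexts(loc$model, loc$genome)
    mir <- mirrorLocus(loc$genome, loc$model)
    jx2 <- junctionContexts(mir$model, mir$genome)
    cols <- c("donor_exonic", "donor_intronic", "acceptor_intronic",
              "acceptor_exonic")
    expect_identical(jx2[cols], jx[cols])
  }
})

test_that("gene summary adds up and reproduces the published locus figures", {
  m <- aedsxModel()
  gs <- geneSummary(m)
  expect_identical(gs$n_exons, 8L)
  expect_identical(gs$n_introns, 7L)
  expect_identical(gs$intron_min_bp, 208L)
  expect_identical(gs$intron_max_bp, 274879L)
  expect_equal(gs$intron_mean_bp, 451243 / 7)
  expect_identical(gs$intron_mean_kb, 64)
  expect_identical(gs$span_bp, gs$exon_bp + gs$intron_bp)

  m1 <- GeneModel("g", "c", "+", c(1L, 1101L), c(100L, 1200L))
  gs1 <- geneSummary(m1)
  expect_identical(gs1$intron_min_bp, gs1$intron_max_bp)
  expect_equal(gs1$intron_mean_bp, 1000)
})
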