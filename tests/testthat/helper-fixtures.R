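# Fixture builders shared across test files. Everything is generated
# in code; nothing binary ships with the tests.

# a tiny two-exon locus with hand-known junction windows
handLocus <- function() {
  e1 <- "AAAACCTTGCAG"                       # ends with the donor-exonic window
  i1 <- paste0("GTAGGTGTGAGGCATA",           # first 16 nt (donor side)
               "CCCCCCCC",
               "TCTCCTCTCTTTTCAG")           # last 16 nt (acceptor side)
  e2 <- "GCAACCAAAA"
  seq <- paste0(e1, i1, e2)
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "ctg"
  model <- GeneModel("g1", "ctg", "+",
                     start = c(1L, nchar(e1) + nchar(i1) + 1L),
                     end = c(nchar(e1), nchar(seq)),
                     exonId = c("e1", "e2"),
                     classLabel = c("common", "female_specific"))
  list(genome = genome, model = model,
       donor_exonic = "TTGCAG", donor_intronic = "GTAGGTGTGAGGCATA",
       acceptor_intronic = "TCTCCTCTCTTTTCAG", acceptor_exonic = "GCAACC")
}

# mirror a (+)-strand locus onto the reverse complement / '-' strand
mirrorLocus <- function(genome, model) {
  L <- Biostrings::width(genome)[1L]
  rcGenome <- Biostrings::reverseComplement(genome)
  names(rcGenome) <- names(genome)
  ex <- exons(model)
  s <- BiocGenerics::start(ex); e <- BiocGenerics::end(ex)
  rcModel <- GeneModel(geneId(model), names(genome)[1L], "-",
                       start = L - e + 1L, end = L - s + 1L,
                       exonId = S4Vectors::mcols(ex)$exon_id,
                       classLabel = S4Vectors::mcols(ex)$class_label)
  list(genome = rcGenome, model = rcModel)
}

# GeneModel built from the published exon/intron sizes of the Aeadsx
# junction table (coordinates laid out head-to-tail from position 1)
aedsxModel <- function() {
  jx <- aedsxJunctions()
  sz <- jx$exon_size
  isz <- jx$intron_size[!is.na(jx$intron_size)]
  starts <- integer(length(sz)); ends <- integer(length(sz)); pos <- 0L
  for (i in seq_along(sz)) {
    starts[i] <- pos + 1L
    ends[i] <- pos + sz[i]
    pos <- ends[i] + if (i <= length(isz)) isz[i] else 0L
  }
  GeneModel("Aeadsx", "supercontig", "+", starts, ends,
            exonId = jx$exon_id, classLabel = jx$exon_class)
}

writeTempFasta <- function(seqs, ids = names(seqs)) {
  f <- tempfile(fileext = ".fa")
  writeLines(paste0(">", ids, "\n", seqs), f)
  f
}
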