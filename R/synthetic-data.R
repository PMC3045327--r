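# Ground-truth synthetic fixtures: loci with controlled splice-site
# composition, planted motifs, repeat annotations and codon alignments
# evolved at a target dN/dS. Every generator takes an explicit seed and
# is a pure function of (config, seed).

.randBases <- function(n, prob = c(A = .25, C = .25, G = .25, T = .25)) {
  sample(names(prob), n, replace = TRUE, prob = prob)
}

#' Simulate acceptor windows with controlled pyrimidine content
#'
#' Each 16-nt window is built position-wise: the 12 polypyrimidine-tract
#' positions are pyrimidine (C/T, equiprobable) with probability `p` and
#' purine (A/G) otherwise; positions 13-14 are uniform random; positions
#' 15-16 are the terminal dinucleotide (default `AG`). The pyrimidine
#' count of such a window is Binomial(12, p), so a large sample has mean
#' close to `12 p`.
#'
#' @param n number of windows.
#' @param p per-position pyrimidine probability.
#' @param seed RNG seed (required).
#' @param terminal terminal dinucleotide (default `"AG"`).
#' @return character vector of 16-nt windows.
#' @export
simulateAcceptorWindows <- function(n, p, seed, terminal = "AG") {
  stopifnot(p >= 0, p <= 1, n >= 1)
  set.seed(seed)
  isY <- matrix(stats::runif(12L * n) < p, nrow = n)
  ch <- matrix("", nrow = n, ncol = 16L)
  ch[, 1:12][isY] <- sample(c("C", "T"), sum(isY), replace = TRUE)
  ch[, 1:12][!isY] <- sample(c("A", "G"), sum(!isY), replace = TRUE)
  ch[, 13:14] <- .randBases(2L * n)
  ch[, 15L] <- substr(terminal, 1L, 1L)
  ch[, 16L] <- substr(terminal, 2L, 2L)
  apply(ch, 1L, paste, collapse = "")
}

.simulateDonor <- function(fidelity, consensus = "GTRAGT") {
  sets <- strsplit(iupacSets()[strsplit(consensus, "")[[1L]]], "")
  m <- length(sets)
  stopifnot(fidelity >= 0, fidelity <= m)
  matchPos <- sort(sample.int(m, fidelity))
  vapply(seq_len(m), function(j) {
    if (j %in% matchPos) sample(sets[[j]], 1L)
    else sample(setdiff(.BASES, sets[[j]]), 1L)
  }, character(1)) |> paste(collapse = "")
}

#' Simulate a multi-exon locus with sex-specific exons
#'
#' Builds a contig holding one gene with the configured exon sizes and
#' classes and intron sizes. Each intron's acceptor window (last 16 nt)
#' is generated with a controllable per-position pyrimidine probability
#' and terminal dinucleotide, and its donor (first 6 nt) from the
#' `GTRAGT` consensus with a configurable number of matching positions,
#' giving known ground truth for the splice-site statistics.
#'
#' @param config list with elements:
#'   \describe{
#'     \item{seed}{RNG seed (mandatory).}
#'     \item{exons}{data.frame with `exon_id`, `size`, `class`.}
#'     \item{intronSizes}{numeric vector, length `nrow(exons) - 1`;
#'       every intron must be at least 32 nt (the two windows).}
#'     \item{acceptorP}{pyrimidine probability per intron (recycled).}
#'     \item{donorFidelity}{donor consensus matches per intron, 0-6
#'       (recycled; default 6).}
#'     \item{acceptorTerminal}{terminal dinucleotide per intron
#'       (recycled; default `"AG"`).}
#'     \item{contigName, geneId, flank, strand}{optional; defaults
#'       `"contig_1"`, `"synthetic_gene"`, 200, `"+"`.}
#'   }
#' @return list: `genome` ([Biostrings::DNAStringSet]), `model`
#'   ([GeneModel-class]), `truth` (per-intron generation parameters and
#'   the planted windows).
#' @export
simulateLocus <- function(config) {
  if (is.null(config$seed)) .fail("simulateLocus: config$seed is mandatory")
  exdf <- config$exons
  stopifnot(is.data.frame(exdf), all(c("exon_id", "size", "class") %in% names(exdf)))
  nInt <- nrow(exdf) - 1L
  intronSizes <- config$intronSizes
  stopifnot(length(intronSizes) == nInt)
  if (any(intronSizes < 32L))
    .fail("intron of %d nt cannot host both 16-nt junction windows",
          min(intronSizes))
  p <- rep_len(if (is.null(config$acceptorP)) 1.0 else config$acceptorP, nInt)
  fid <- rep_len(if (is.null(config$donorFidelity)) 6L else config$donorFidelity, nInt)
  term <- rep_len(if (is.null(config$acceptorTerminal)) "AG" else config$acceptorTerminal, nInt)
  flank <- if (is.null(config$flank)) 200L else config$flank
  contig <- if (is.null(config$contigName)) "contig_1" else config$contigName
  gid <- if (is.null(config$geneId)) "synthetic_gene" else config$geneId
  strand <- if (is.null(config$strand)) "+" else config$strand

  set.seed(config$seed)
  pieces <- character(0)
  starts <- integer(nrow(exdf)); ends <- integer(nrow(exdf))
  pos <- flank
  truthWin <- list()
  for (i in seq_len(nrow(exdf))) {
    starts[i] <- pos + 1L
    pieces <- c(pieces, paste(.randBases(exdf$size[i]), collapse = ""))
    pos <- pos + exdf$size[i]
    ends[i] <- pos
    if (i <= nInt) {
      L <- intronSizes[i]
      donor <- .simulateDonor(fid[i])
      acceptor <- simulateAcceptorWindowsInline(p[i], term[i])
      mid <- if (L > 22L) paste(.randBases(L - 22L), collapse = "") else ""
      intronSeq <- paste0(donor, mid, acceptor)
      intronSeq <- substr(intronSeq, 1L, L)  # L >= 32 guarantees no clash
      pieces <- c(pieces, intronSeq)
      truthWin[[i]] <- data.frame(
        ordinal = i, donor_window = donor, acceptor_window = acceptor,
        acceptor_p = p[i], donor_fidelity = fid[i], terminal = term[i],
        stringsAsFactors = FALSE)
      pos <- pos + L
    }
  }
  body <- paste(pieces, collapse = "")
  seqStr <- paste0(paste(.randBases(flank), collapse = ""), body,
                   paste(.randBases(flank), collapse = ""))
  genome <- Biostrings::DNAStringSet(seqStr)
  names(genome) <- contig
  model <- GeneModel(gid, contig, strand, starts, ends,
                     exonId = exdf$exon_id, classLabel = exdf$class)
  list(genome = genome, model = model,
       truth = list(windows = do.call(rbind, truthWin),
                    acceptor_p = p, donor_fidelity = fid, seed = config$seed))
}

# one acceptor window without touching the seed state management
simulateAcceptorWindowsInline <- function(p, terminal) {
  isY <- stats::runif(12L) < p
  tract <- ifelse(isY, sample(c("C", "T"), 12L, replace = TRUE),
                  sample(c("A", "G"), 12L, replace = TRUE))
  paste0(paste(tract, collapse = ""),
         paste(.randBases(2L), collapse = ""), terminal)
}

#' Write a simulated locus to disk
#'
#' Emits `genome.fa`, `model.gff3`, `class_map.json` and `truth.json`
#' in `dir`; the fixture files load cleanly through [readGenome()] /
#' [readGeneModel()]. Byte-identical across re-runs of the same config.
#'
#' @param locus output of [simulateLocus()].
#' @param dir output directory (created).
#' @return named vector of file paths, invisibly.
#' @export
writeLocus <- function(locus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "model.gff3")
  cm <- file.path(dir, "class_map.json")
  tr <- file.path(dir, "truth.json")
  Biostrings::writeXStringSet(locus$genome, fa)
  writeGeneModel(locus$model, gff)
  ex <- exons(locus$model)
  cmap <- as.list(stats::setNames(mcols(ex)$class_label, mcols(ex)$exon_id))
  jsonlite::write_json(cmap, cm, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(locus$truth, tr, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(genome = fa, gff3 = gff, class_map = cm, truth = tr))
}

#' Plant motif instances into a sequence
#'
#' Inserts literal instances (drawn uniformly from each motif's IUPAC
#' expansion) at explicit offsets or at random non-overlapping offsets
#' within named regions; the background is untouched elsewhere.
#' Overlapping plantings are an error.
#'
#' @param sequence background sequence (character).
#' @param plantings data.frame with columns `motif`, `iupac` and either
#'   `start` (explicit 1-based offsets) or `region` + `count`.
#' @param regions region annotation (required for region plantings).
#' @param seed RNG seed (required).
#' @return list `sequence` (with motifs planted) and `truth`
#'   (data.frame `motif`, `start`, `end`, `word`).
#' @export
plantMotifs <- function(sequence, plantings, regions = NULL, seed) {
  if (missing(seed)) .fail("plantMotifs: seed is mandatory")
  set.seed(seed)
  s <- strsplit(toupper(sequence), "")[[1L]]
  placed <- IRanges()
  truth <- list()
  placeOne <- function(iupac, startPos, motif) {
    m <- nchar(iupac)
    if (startPos < 1L || startPos + m - 1L > length(s))
      .fail("motif '%s' (%d nt) does not fit at offset %d", motif, m, startPos)
    rng <- IRanges(startPos, startPos + m - 1L)
    if (length(IRanges::findOverlaps(rng, placed)))
      .fail("planting collision at offset %d (motif '%s')", startPos, motif)
    sets <- strsplit(iupacSets()[strsplit(toupper(iupac), "")[[1L]]], "")
    word <- vapply(sets, function(x) sample(x, 1L), character(1))
    s[startPos:(startPos + m - 1L)] <<- word
    placed <<- c(placed, rng)
    truth[[length(truth) + 1L]] <<- data.frame(
      motif = motif, start = startPos, end = startPos + m - 1L,
      word = paste(word, collapse = ""), stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(plantings))) {
    iu <- plantings$iupac[i]; m <- nchar(iu)
    if (!is.null(plantings$start) && !is.na(plantings$start[i])) {
      placeOne(iu, plantings$start[i], plantings$motif[i])
    } else {
      rf <- .asRegionFrame(regions)
      r <- rf[rf$region == plantings$region[i], , drop = FALSE]
      if (nrow(r) != 1L) .fail("unknown planting region '%s'", plantings$region[i])
      if (r$end - r$start + 1L < m)
        .fail("region '%s' (%d nt) cannot host a %d-nt motif",
              plantings$region[i], r$end - r$start + 1L, m)
      for (k in seq_len(plantings$count[i])) {
        ok <- FALSE
        for (try in seq_len(1000L)) {
          cand <- sample(seq(r$start, r$end - m + 1L), 1L)
          rng <- IRanges(cand, cand + m - 1L)
          if (!length(IRanges::findOverlaps(rng, placed))) {
            placeOne(iu, cand, plantings$motif[i]); ok <- TRUE; break
          }
        }
        if (!ok) .fail("could not place motif '%s' in region '%s' without collision",
                       plantings$motif[i], plantings$region[i])
      }
    }
  }
  list(sequence = paste(s, collapse = ""), truth = do.call(rbind, truth))
}

#' Simulate repeat annotations at a target density
#'
#' Element counts per intron are Poisson with mean
#' `densityPerKb * length/1000`; starts are uniform within the intron;
#' lengths are exponential with the given mean (minimum 10 bp), clipped
#' at the intron end. Deterministic under a fixed seed.
#'
#' @param intronLengths named numeric vector (names become contig ids of
#'   the emitted table, one intron per contig in intron-local
#'   coordinates).
#' @param densityPerKb target elements per kb.
#' @param meanLength mean element length in bp (default 300).
#' @param seed RNG seed (required).
#' @return list `repeats` (data.frame `contig`, `start`, `end`,
#'   `family`, `class`) and `truth`.
#' @export
simulateRepeats <- function(intronLengths, densityPerKb, meanLength = 300,
                            seed) {
  if (missing(seed)) .fail("simulateRepeats: seed is mandatory")
  stopifnot(densityPerKb >= 0, !is.null(names(intronLengths)))
  set.seed(seed)
  rows <- list()
  for (id in names(intronLengths)) {
    L <- intronLengths[[id]]
    nEl <- stats::rpois(1L, densityPerKb * L / 1000)
    if (nEl == 0L) next
    st <- sort(sample.int(L, nEl, replace = TRUE))
    len <- pmax(10L, round(stats::rexp(nEl, 1 / meanLength)))
    en <- pmin(L, st + len - 1L)
    rows[[id]] <- data.frame(contig = id, start = st, end = en,
                             family = "SynTE", class = "synthetic_repeat",
                             stringsAsFactors = FALSE)
  }
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               family = character(), class = character())
  rownames(rep) <- NULL
  list(repeats = rep,
       truth = list(density_per_kb = densityPerKb, mean_length = meanLength,
                    seed = seed))
}

#' Write a repeat table TSV
#' @param repeats data.frame from [simulateRepeats()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeRepeats <- function(repeats, path) {
  utils::write.table(repeats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a codon alignment at a target dN/dS
#'
#' Star-tree simulation: a random stop-free ancestor of `nCodons`
#' codons; on each of the `nTaxa` terminal branches, a Poisson number of
#' substitution events (mean `subsPerCodon * nCodons`) is proposed.
#' Each event mutates one random position of one random codon to a
#' random different base; proposals creating a stop codon are discarded;
#' synonymous proposals are always accepted and non-synonymous proposals
#' are accepted with probability `omega`. The acceptance probability is
#' a simulation device for tuning the realized dN/dS, not a mechanistic
#' model of protein evolution.
#'
#' @param nTaxa number of sequences.
#' @param nCodons alignment length in codons.
#' @param subsPerCodon expected proposed events per codon per branch.
#' @param omega target dN/dS in \[0, 5\].
#' @param seed RNG seed (required).
#' @param code genetic code (default standard).
#' @return list `alignment` (named [Biostrings::DNAStringSet]) and
#'   `truth` (`omega`, `subsPerCodon`, `ancestor`).
#' @export
simulateCodonAlignment <- function(nTaxa, nCodons, subsPerCodon, omega, seed,
                                   code = Biostrings::GENETIC_CODE) {
  if (missing(seed)) .fail("simulateCodonAlignment: seed is mandatory")
  if (omega < 0 || omega > 5) .fail("omega must be in [0, 5]")
  set.seed(seed)
  sense <- .senseCodons(code)
  anc <- sample(sense, nCodons, replace = TRUE)
  evolve <- function(codons) {
    nEv <- stats::rpois(1L, subsPerCodon * nCodons)
    for (e in seq_len(nEv)) {
      i <- sample.int(nCodons, 1L)
      pos <- sample.int(3L, 1L)
      ch <- strsplit(codons[i], "")[[1L]]
      newBase <- sample(setdiff(.BASES, ch[pos]), 1L)
      mut <- ch; mut[pos] <- newBase
      mutCod <- paste(mut, collapse = "")
      if (code[mutCod] == "*") next                       # reject stop
      if (code[mutCod] != code[codons[i]] && stats::runif(1L) > omega) next
      codons[i] <- mutCod
    }
    codons
  }
  seqs <- vapply(seq_len(nTaxa), function(t)
    paste(evolve(anc), collapse = ""), character(1))
  aln <- Biostrings::DNAStringSet(seqs)
  names(aln) <- sprintf("taxon_%02d", seq_len(nTaxa))
  list(alignment = aln,
       truth = list(omega = omega, subsPerCodon = subsPerCodon,
                    ancestor = paste(anc, collapse = ""), seed = seed))
}

#' Simulate a partitioned codon alignment
#'
#' Concatenates independently simulated blocks, each with its own codon
#' count and target dN/dS, and returns the matching partition
#' definition.
#'
#' @param nTaxa number of sequences.
#' @param blocks named list; each element a list with `nCodons` and
#'   `omega`.
#' @param subsPerCodon expected proposed events per codon per branch.
#' @param seed RNG seed; block `i` uses `seed + i`.
#' @param code genetic code.
#' @return list `alignment`, `partitions` (named list of range
#'   matrices), `truth` (per-block omegas).
#' @export
simulatePartitionedAlignment <- function(nTaxa, blocks, subsPerCodon, seed,
                                         code = Biostrings::GENETIC_CODE) {
  if (missing(seed)) .fail("simulatePartitionedAlignment: seed is mandatory")
  parts <- list(); seqs <- NULL; offset <- 0L
  omegas <- vapply(blocks, `[[`, numeric(1), "omega")
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    sim <- simulateCodonAlignment(nTaxa, b$nCodons, subsPerCodon, b$omega,
                                  seed = seed + i, code = code)
    blockSeqs <- as.character(sim$alignment)
    seqs <- if (is.null(seqs)) blockSeqs else paste0(seqs, blockSeqs)
    parts[[names(blocks)[i]]] <- matrix(
      c(offset + 1L, offset + 3L * b$nCodons), nrow = 1L)
    offset <- offset + 3L * b$nCodons
  }
  aln <- Biostrings::DNAStringSet(seqs)
  names(aln) <- sprintf("taxon_%02d", seq_len(nTaxa))
  list(alignment = aln, partitions = parts,
       truth = list(omega = omegas, subsPerCodon = subsPerCodon, seed = seed))
}
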