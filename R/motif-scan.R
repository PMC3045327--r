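# Degenerate (IUPAC) cis-element scanning, purine-run detection and
# bipartite region summaries.

#' Motif catalogue constructors
#'
#' `MotifCatalogue()` builds a catalogue from vectors;
#' `readMotifCatalogue()` loads a JSON array of
#' `{"name","iupac","class","source"}` objects;
#' `defaultMotifCatalogue()` returns the bundled insect doublesex
#' cis-element catalogue (dsxRE `TCWWCAATCAACA`, NvdsxRE `KGAAGATW`,
#' RBP1 type A `DCADCTTTA`, RBP1 type B `ATCYNNA`, TRA-2-ISS `CAAGR`).
#' The 20-bp lepidopteran CE1 element is deliberately not bundled: its
#' sequence must be supplied by the user.
#'
#' @param name,iupac,elementClass,source per-motif vectors.
#' @return a [MotifCatalogue-class].
#' @export
MotifCatalogue <- function(name, iupac, elementClass = "other", source = "") {
  d <- DataFrame(name = as.character(name), iupac = toupper(iupac),
                 element_class = rep_len(elementClass, length(name)),
                 source = rep_len(source, length(name)))
  new("MotifCatalogue", defs = d)
}

#' @rdname MotifCatalogue
#' @param path JSON file.
#' @export
readMotifCatalogue <- function(path) {
  j <- jsonlite::fromJSON(path)
  if (length(j) == 0L || (is.data.frame(j) && nrow(j) == 0L)) {
    warning("empty motif catalogue: ", path)
    return(MotifCatalogue(character(), character()))
  }
  if (!is.data.frame(j)) .fail("catalogue JSON must be an array of objects")
  cls <- if ("class" %in% names(j)) j$class else "other"
  src <- if ("source" %in% names(j)) j$source else ""
  MotifCatalogue(j$name, j$iupac, cls, src)
}

#' @rdname MotifCatalogue
#' @export
defaultMotifCatalogue <- function() {
  readMotifCatalogue(system.file("extdata", "cis_element_catalogue.json",
                                 package = "dsxSplice", mustWork = TRUE))
}

#' @rdname MotifCatalogue-class
#' @export
setMethod("motifNames", "MotifCatalogue", function(x) x@defs$name)

#' @rdname MotifCatalogue-class
#' @export
setMethod("length", "MotifCatalogue", function(x) nrow(x@defs))

#' @rdname MotifCatalogue-class
#' @param i index or motif name.
#' @export
setMethod("[", "MotifCatalogue", function(x, i) {
  if (is.character(i)) i <- match(i, x@defs$name)
  initialize(x, defs = x@defs[i, , drop = FALSE])
})

#' @rdname MotifCatalogue-class
#' @export
setMethod("as.data.frame", "MotifCatalogue",
          function(x) as.data.frame(x@defs))

#' Expand an IUPAC consensus into literal words
#'
#' Cartesian expansion of the per-position base sets. Refuses expansions
#' larger than `cap` (heavily degenerate motifs should be scanned by
#' consensus instead).
#'
#' @param iupac a single IUPAC string (or a [MotifCatalogue-class] row).
#' @param cap maximum number of words (default 4096).
#' @return character vector of literal words.
#' @examples
#' expandIupac("KGAAGATW")  # 4 words
#' @export
expandIupac <- function(iupac, cap = 4096L) {
  if (is(iupac, "MotifCatalogue")) {
    stopifnot(length(iupac) == 1L)
    iupac <- iupac@defs$iupac
  }
  .assertIupac(iupac)
  sets <- strsplit(iupacSets()[strsplit(toupper(iupac), "")[[1L]]], "")
  size <- prod(lengths(sets))
  if (size > cap)
    .fail("expansion of '%s' has %d words (> cap %d); scan by consensus instead",
          iupac, size, cap)
  g <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  words <- do.call(paste0, rev(g))
  sort(words)
}

# strict per-hit mismatch count: subject char must be inside the IUPAC
# set of the pattern char; N in the subject never matches.
.mismatchCount <- function(words, iupac) {
  sets <- iupacSets()[strsplit(toupper(iupac), "")[[1L]]]
  ch <- .charMatrix(words)
  miss <- vapply(seq_along(sets), function(j)
    !grepl(sprintf("[%s]", sets[j]), ch[, j]), logical(length(words)))
  rowSums(matrix(miss, ncol = length(sets)))
}

.regionLabel <- function(startPos, regions) {
  if (is.null(regions)) return(rep(NA_character_, length(startPos)))
  regions <- .asRegionFrame(regions)
  lab <- rep(NA_character_, length(startPos))
  for (k in seq_len(nrow(regions))) {
    inR <- startPos >= regions$start[k] & startPos <= regions$end[k]
    lab[inR] <- regions$region[k]
  }
  lab
}

# regions: data.frame(region, start, end) or GRanges with region names
.asRegionFrame <- function(regions) {
  if (is(regions, "GRanges")) {
    lab <- if (!is.null(mcols(regions)$region)) mcols(regions)$region
           else names(regions)
    regions <- data.frame(region = lab, start = start(regions),
                          end = end(regions), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  o <- order(regions$start)
  r <- regions[o, , drop = FALSE]
  if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
    .fail("region annotation intervals overlap")
  r
}

#' Scan sequence for degenerate motifs
#'
#' Reports a hit at every offset where at most `maxMismatch` positions
#' violate the motif's IUPAC sets (an `N` in the sequence always counts
#' as a violation). Overlapping hits are all reported. Reverse-strand
#' hits (with `strands = "both"`) are found by matching the reverse
#' complement of the motif and are reported in forward coordinates with
#' strand `-`. Matching is delegated to
#' [Biostrings::matchPattern()] and re-checked with the strict mismatch
#' rule.
#'
#' @param sequence character string, [Biostrings::DNAString] or
#'   single-record [Biostrings::DNAStringSet].
#' @param catalogue a [MotifCatalogue-class].
#' @param maxMismatch maximum mismatches per hit (default 0).
#' @param strands `"forward"` (default; classic sense-strand annotation)
#'   or `"both"`.
#' @param regions optional region annotation (data.frame
#'   `region`/`start`/`end` or named GRanges); hits are labelled by
#'   their start position.
#' @param contig contig id to record in the hit table.
#' @return data.frame of hits: `motif_name`, `contig_id`, `start`, `end`
#'   (1-based inclusive), `strand`, `matched_sequence` (forward-strand
#'   subject substring), `mismatches`, `region_label`.
#' @export
scanMotifs <- function(sequence, catalogue, maxMismatch = 0L,
                       strands = c("forward", "both"), regions = NULL,
                       contig = "seq") {
  strands <- match.arg(strands)
  if (is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    if (!is.null(names(sequence))) contig <- names(sequence)
    sequence <- sequence[[1L]]
  }
  subject <- Biostrings::DNAString(toupper(as.character(sequence)))
  defs <- as.data.frame(catalogue)
  hits <- list()
  for (i in seq_len(nrow(defs))) {
    iu <- defs$iupac[i]
    m <- nchar(iu)
    if (m > length(subject)) next
    orients <- if (strands == "both") c("+", "-") else "+"
    for (o in orients) {
      pat <- Biostrings::DNAString(iu)
      if (o == "-") pat <- Biostrings::reverseComplement(pat)
      mp <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = maxMismatch,
                                     fixed = "subject")
      # with mismatches allowed, matchPattern may report views hanging
      # over the sequence ends; only fully in-bounds offsets are hits
      mp <- mp[BiocGenerics::start(mp) >= 1L &
                 BiocGenerics::end(mp) <= length(subject)]
      if (length(mp) == 0L) next
      words <- as.character(mp)
      patChr <- as.character(pat)
      mm <- .mismatchCount(words, patChr)
      keep <- mm <= maxMismatch
      if (!any(keep)) next
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = defs$name[i], contig_id = contig,
        start = BiocGenerics::start(mp)[keep], end = BiocGenerics::end(mp)[keep],
        strand = o, matched_sequence = words[keep],
        mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    out <- data.frame(motif_name = character(), contig_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      matched_sequence = character(), mismatches = integer(),
                      region_label = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  out$region_label <- .regionLabel(out$start, regions)
  out
}

#' Detect purine-rich runs (candidate PRE elements)
#'
#' With `minFrac = 1` (default): maximal runs of `A`/`G` of length at
#' least `minLen`. With `minFrac < 1`: all windows of length `minLen`
#' whose purine fraction reaches `minFrac`, merged when overlapping, each
#' merged interval reported with its overall purine fraction. These are
#' *candidate* purine-rich elements (PRE); no sequence consensus is
#' implied.
#'
#' @param sequence character/DNAString.
#' @param minLen minimum run length (default 10, must be >= 2).
#' @param minFrac minimum purine fraction in \[0,1\] (default 1).
#' @return data.frame `start`, `end` (1-based inclusive), `length`,
#'   `purine_fraction`.
#' @export
detectPurineRuns <- function(sequence, minLen = 10L, minFrac = 1.0) {
  stopifnot(minLen >= 2L, minFrac > 0, minFrac <= 1)
  s <- toupper(as.character(sequence))
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  pur <- ch == "A" | ch == "G"
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      purine_fraction = numeric())
  n <- length(pur)
  if (n < minLen) return(empty)
  if (minFrac >= 1) {
    r <- rle(pur)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minLen
    if (!any(keep)) return(empty)
    out <- data.frame(start = starts[keep], end = ends[keep],
                      length = r$lengths[keep], purine_fraction = 1.0)
    return(out)
  }
  cs <- cumsum(c(0L, pur))
  winSum <- cs[(minLen + 1L):(n + 1L)] - cs[1:(n - minLen + 1L)]
  hitStart <- which(winSum / minLen >= minFrac)
  if (!length(hitStart)) return(empty)
  ir <- IRanges::reduce(IRanges(hitStart, hitStart + minLen - 1L))
  data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
             length = BiocGenerics::width(ir),
             purine_fraction = vapply(seq_along(ir), function(k)
               mean(pur[BiocGenerics::start(ir)[k]:BiocGenerics::end(ir)[k]]),
               numeric(1)))
}

#' Group motif hits into clusters
#'
#' Hits of one motif separated by at most `maxGap` nt are grouped, for
#' reporting clustered occurrences (e.g. "a cluster of four repeats").
#'
#' @param hits data.frame from [scanMotifs()].
#' @param maxGap maximum gap between clustered hits (default 50).
#' @return `hits` with a `cluster` column (`<motif>_c<k>`).
#' @export
clusterHits <- function(hits, maxGap = 50L) {
  hits$cluster <- NA_character_
  for (m in unique(hits$motif_name)) {
    idx <- which(hits$motif_name == m)
    idx <- idx[order(hits$start[idx])]
    gap <- c(0L, hits$start[idx][-1L] - hits$end[idx][-length(idx)] - 1L)
    grp <- cumsum(gap > maxGap) + 1L
    hits$cluster[idx] <- sprintf("%s_c%d", m, grp)
  }
  hits
}

#' Expected chance hits of a degenerate motif
#'
#' Closed-form expectation of the number of (possibly overlapping)
#' zero-mismatch hits of an IUPAC motif in a random i.i.d. sequence of
#' length `L`: `(L - m + 1) * prod_i P(base in set_i)` under the supplied
#' base composition (uniform by default).
#'
#' @param iupac motif consensus.
#' @param L sequence length.
#' @param baseComposition named probabilities for `A`,`C`,`G`,`T`
#'   (default uniform).
#' @return expected hit count (numeric).
#' @export
expectedChanceHits <- function(iupac, L,
                               baseComposition = c(A = .25, C = .25,
                                                   G = .25, T = .25)) {
  .assertIupac(iupac)
  stopifnot(abs(sum(baseComposition) - 1) < 1e-8)
  sets <- strsplit(iupacSets()[strsplit(toupper(iupac), "")[[1L]]], "")
  m <- length(sets)
  if (L < m) return(0)
  pPos <- vapply(sets, function(s) sum(baseComposition[s]), numeric(1))
  (L - m + 1) * prod(pPos)
}

#' Bipartite summary of motif hits across labelled regions
#'
#' Tabulates hits per (motif, region), computes the expected chance hits
#' per region from the closed form of [expectedChanceHits()], and, for a
#' designated pair of regions, a Fisher exact test on the 2x2 table of
#' hit-bearing start positions versus non-hit positions in region A
#' versus region B -- a simple quantification of "exclusively present in
#' one exon".
#'
#' @param hits data.frame from [scanMotifs()] (hits must carry
#'   `region_label`, or `regions` is used to label them).
#' @param regions region annotation (see [scanMotifs()]).
#' @param catalogue the [MotifCatalogue-class] scanned (for motif lengths
#'   and degeneracy).
#' @param compare character vector of two region labels to contrast;
#'   `NULL` skips the exact tests.
#' @param runs optional purine-run table from [detectPurineRuns()],
#'   counted as pseudo-motif `purine_run`.
#' @param baseComposition base probabilities for the chance expectation.
#' @return a `bipartiteSummary` list: `counts` (motif x region matrix),
#'   `expected`, `tests` (per-motif Fisher p-values for the contrast),
#'   `compare`.
#' @export
summarizeRegions <- function(hits, regions, catalogue, compare = NULL,
                             runs = NULL,
                             baseComposition = c(A = .25, C = .25,
                                                 G = .25, T = .25)) {
  regions <- .asRegionFrame(regions)
  if (!"region_label" %in% names(hits) || all(is.na(hits$region_label)))
    hits$region_label <- .regionLabel(hits$start, regions)
  defs <- as.data.frame(catalogue)
  motifs <- defs$name
  if (!is.null(runs) && nrow(runs)) {
    runHits <- data.frame(motif_name = "purine_run",
                          region_label = .regionLabel(runs$start, regions),
                          stringsAsFactors = FALSE)
    hits <- rbind(hits[, c("motif_name", "region_label")], runHits)
    motifs <- c(motifs, "purine_run")
  } else hits <- hits[, c("motif_name", "region_label"), drop = FALSE]
  counts <- table(factor(hits$motif_name, levels = motifs),
                  factor(hits$region_label, levels = regions$region))
  counts <- unclass(counts)
  regLen <- regions$end - regions$start + 1L
  names(regLen) <- regions$region
  expected <- matrix(0, nrow = length(motifs), ncol = nrow(regions),
                     dimnames = dimnames(counts))
  for (i in seq_len(nrow(defs)))
    expected[defs$name[i], ] <- vapply(regLen, function(L)
      expectedChanceHits(defs$iupac[i], L, baseComposition), numeric(1))
  tests <- NULL
  if (!is.null(compare)) {
    stopifnot(length(compare) == 2L)
    if (!all(compare %in% regions$region))
      .fail("comparison region(s) missing from the annotation: %s",
            paste(setdiff(compare, regions$region), collapse = ", "))
    tests <- do.call(rbind, lapply(seq_along(motifs), function(i) {
      m <- motifs[i]
      len <- if (m %in% defs$name) nchar(defs$iupac[match(m, defs$name)]) else 1L
      posA <- max(regLen[compare[1L]] - len + 1L, 0L)
      posB <- max(regLen[compare[2L]] - len + 1L, 0L)
      hA <- counts[m, compare[1L]]; hB <- counts[m, compare[2L]]
      tab <- matrix(c(hA, posA - hA, hB, posB - hB), nrow = 2L, byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      data.frame(motif_name = m, count_A = hA, count_B = hB,
                 positions_A = posA, positions_B = posB, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(counts = counts, expected = expected, tests = tests,
                 compare = compare), class = "bipartiteSummary")
}

#' @export
print.bipartiteSummary <- function(x, ...) {
  cat("Motif hits per region:\n")
  print(x$counts)
  if (!is.null(x$tests)) {
    cat(sprintf("\nExact tests (%s vs %s):\n", x$compare[1L], x$compare[2L]))
    print(x$tests[, c("motif_name", "count_A", "count_B", "p_value")],
          row.names = FALSE)
  }
  invisible(x)
}
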