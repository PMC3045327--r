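# Genome and gene-model I/O, intron derivation and junction windows.

#' @importFrom Biostrings readBStringSet DNAStringSet width subseq
#'   reverseComplement
NULL

#' Read a genome (FASTA) with strict alphabet checking
#'
#' Records are stored uppercase. Only `A C G T N` are accepted; any other
#' character is a load error naming the record and offset. Duplicate
#' contig ids and empty records are rejected.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @return a named [Biostrings::DNAStringSet].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    .fail("duplicate contig id '%s' in %s", ids[duplicated(ids)][1L], path)
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    .fail("empty sequence for contig '%s'", ids[!nzchar(seqs)][1L])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    .fail("illegal character '%s' at position %d of contig '%s'",
          substr(seqs[i], bad[i], bad[i]), bad[i], ids[i])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Construct a gene model from coordinates
#'
#' @param geneId gene identifier.
#' @param contig contig id.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive exon coordinates.
#' @param exonId exon identifiers (unique); defaults to `exon_1..n` in
#'   transcription order.
#' @param classLabel exon classes (`common`, `female_specific`,
#'   `male_specific`, `utr`); recycled; default `common`.
#' @return a [GeneModel-class].
#' @export
GeneModel <- function(geneId, contig, strand, start, end,
                      exonId = NULL, classLabel = "common") {
  stopifnot(length(start) == length(end))
  n <- length(start)
  if (any(end < start))
    .fail("exon end < start (exon %d)", which(end < start)[1L])
  o <- if (strand == "+") order(start) else order(-start)
  start <- start[o]; end <- end[o]
  classLabel <- rep_len(classLabel, n)[o]
  exonId <- if (is.null(exonId)) paste0("exon_", seq_len(n)) else exonId[o]
  gr <- GRanges(contig, IRanges(start, end), strand = strand)
  mcols(gr)$exon_id <- exonId
  mcols(gr)$class_label <- classLabel
  new("GeneModel", geneId = geneId, exons = gr)
}

#' @rdname GeneModel-class
#' @export
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname GeneModel-class
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

#' Read a class map (exon id or pattern to exon class)
#'
#' JSON object mapping an exon id -- or a regular expression matched
#' against exon ids -- to a class label, e.g.
#' `{"exon_5a": "female_specific", "^utr": "utr"}`. Exact id matches take
#' precedence over pattern matches; unmatched exons default to `common`.
#'
#' @param path JSON file.
#' @return named character vector.
#' @export
readClassMap <- function(path) {
  m <- jsonlite::fromJSON(path)
  if (length(m) == 0L) return(character())
  v <- unlist(m)
  if (!all(v %in% .EXON_CLASSES))
    .fail("class map value '%s' is not a valid exon class",
          setdiff(v, .EXON_CLASSES)[1L])
  v
}

.applyClassMap <- function(exonIds, classMap) {
  cls <- rep("common", length(exonIds))
  if (is.null(classMap) || length(classMap) == 0L) return(cls)
  pats <- names(classMap)
  for (i in seq_along(exonIds)) {
    hitExact <- match(exonIds[i], pats)
    if (!is.na(hitExact)) { cls[i] <- classMap[[hitExact]]; next }
    hitPat <- which(vapply(pats, function(p)
      grepl(p, exonIds[i]), logical(1)))
    if (length(hitPat)) cls[i] <- classMap[[hitPat[1L]]]
  }
  cls
}

#' Read a gene model from GFF3
#'
#' Exon features sharing a `Parent` (or `gene_id`) attribute are
#' collected into one [GeneModel-class]. Classes come from a sidecar
#' class map ([readClassMap()]), or from a `class_label` GFF attribute
#' when present; unmatched exons default to `common`.
#'
#' @param path GFF3 file with exon features.
#' @param classMap path to a class-map JSON, or a named character vector,
#'   or `NULL`.
#' @param geneId select this gene when the file holds several; default:
#'   the file must contain exactly one gene.
#' @param genome optional [Biostrings::DNAStringSet]; when given, exon
#'   coordinates are checked against contig length.
#' @return a [GeneModel-class].
#' @export
readGeneModel <- function(path, classMap = NULL, geneId = NULL, genome = NULL) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) .fail("no exon features in %s", path)
  parent <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
           character(1))
  } else if (!is.null(gr$gene_id)) {
    as.character(gr$gene_id)
  } else rep("gene_1", length(gr))
  if (is.null(geneId)) {
    ug <- unique(parent)
    if (length(ug) > 1L)
      .fail("multiple genes in %s (%s); pick one with geneId=",
            path, paste(ug, collapse = ", "))
    geneId <- ug
  }
  gr <- gr[parent == geneId]
  if (length(gr) == 0L) .fail("no exons for gene '%s' in %s", geneId, path)
  exonIds <- if (!is.null(gr$ID) && !anyNA(gr$ID)) as.character(gr$ID)
             else if (!is.null(gr$Name) && !anyNA(gr$Name)) as.character(gr$Name)
             else paste0("exon_", seq_along(gr))
  str <- unique(as.character(strand(gr)))
  if (length(str) > 1L) .fail("mixed strands within gene '%s'", geneId)
  if (!str %in% c("+", "-")) .fail("gene '%s' needs an explicit strand", geneId)
  if (is.character(classMap) && length(classMap) == 1L && is.null(names(classMap)) &&
      file.exists(classMap))
    classMap <- readClassMap(classMap)
  cls <- if (!is.null(gr$class_label) && is.null(classMap))
    as.character(gr$class_label) else .applyClassMap(exonIds, classMap)
  if (!is.null(genome)) {
    contig <- as.character(seqnames(gr))[1L]
    if (!contig %in% names(genome))
      .fail("contig '%s' absent from the supplied genome", contig)
    if (any(end(gr) > length(genome[[contig]])))
      .fail("exon coordinates exceed contig '%s' length", contig)
  }
  GeneModel(geneId, as.character(seqnames(gr))[1L], str,
            start(gr), end(gr), exonIds, cls)
}

#' Write a gene model to GFF3
#'
#' Exon features with `ID` and `Parent` attributes plus a `class_label`
#' attribute; round-trips through [readGeneModel()] with identical
#' coordinates.
#'
#' @param model a [GeneModel-class].
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
writeGeneModel <- function(model, path) {
  ex <- exons(model)
  out <- GRanges(seqnames(ex), IRanges(start(ex), end(ex)), strand = strand(ex))
  mcols(out)$type <- "exon"
  mcols(out)$ID <- mcols(ex)$exon_id
  mcols(out)$Parent <- as.character(geneId(model))
  mcols(out)$class_label <- mcols(ex)$class_label
  out <- sort(out)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' @rdname introns
#' @param sexClasses exon classes whose flanking introns count as
#'   sex-specific.
#' @export
setMethod("introns", "GeneModel", function(x,
    sexClasses = c("female_specific", "male_specific"), ...) {
  ex <- exons(x)
  if (length(ex) < 2L)
    .fail("gene '%s' has < 2 exons; no introns to derive", geneId(x))
  # ex is in transcription order; adjacent pairs flank the introns
  n <- length(ex) - 1L
  str <- as.character(strand(ex))[1L]
  up <- ex[seq_len(n)]          # transcriptionally preceding exon
  dn <- ex[seq_len(n) + 1L]     # following exon
  if (str == "+") {
    s <- end(up) + 1L; e <- start(dn) - 1L
  } else {
    s <- end(dn) + 1L; e <- start(up) - 1L
  }
  if (any(e < s))
    .fail("zero-length intron between exons '%s' and '%s'",
          mcols(up)$exon_id[which(e < s)[1L]],
          mcols(dn)$exon_id[which(e < s)[1L]])
  gr <- GRanges(seqnames(ex)[1L], IRanges(s, e), strand = str)
  mcols(gr)$intron_id <- paste0(geneId(x), "_intron_", seq_len(n))
  mcols(gr)$ordinal <- seq_len(n)
  mcols(gr)$length <- width(gr)
  mcols(gr)$preceding_exon_id <- mcols(up)$exon_id
  mcols(gr)$following_exon_id <- mcols(dn)$exon_id
  mcols(gr)$sex_specific <- mcols(up)$class_label %in% sexClasses |
    mcols(dn)$class_label %in% sexClasses
  gr
})

# Transcript-oriented window: clip [s, e] to the contig, reverse
# complement on '-', flag truncation relative to the requested width.
.txWindow <- function(contigSeq, s, e, strandChr, wanted) {
  cs <- max(1L, s); ce <- min(length(contigSeq), e)
  if (ce < cs) return(list(seq = "", truncated = TRUE))
  w <- as.character(Biostrings::subseq(contigSeq, cs, ce))
  if (strandChr == "-") w <- .revComp(w)
  list(seq = w, truncated = nchar(w) < wanted)
}

#' @rdname junctionContexts
#' @export
setMethod("junctionContexts", "GeneModel", function(x, genome, ...) {
  ex <- exons(x)
  inr <- introns(x)
  contig <- as.character(seqnames(ex))[1L]
  if (is(genome, "DNAStringSet")) {
    if (!contig %in% names(genome))
      .fail("contig '%s' absent from the supplied genome", contig)
    cseq <- genome[[contig]]
  } else cseq <- genome
  str <- as.character(strand(ex))[1L]
  rows <- lapply(seq_along(inr), function(i) {
    it <- inr[i]
    up <- ex[mcols(ex)$exon_id == mcols(it)$preceding_exon_id]
    dn <- ex[mcols(ex)$exon_id == mcols(it)$following_exon_id]
    # windows are clipped to their host feature (a 4-bp exon yields a
    # truncated 4-nt window, never sequence from the neighbouring feature)
    if (str == "+") {
      de <- .txWindow(cseq, max(start(up), end(up) - 5L), end(up), str, 6L)
      di <- .txWindow(cseq, start(it), min(end(it), start(it) + 15L), str, 16L)
      ai <- .txWindow(cseq, max(start(it), end(it) - 15L), end(it), str, 16L)
      ae <- .txWindow(cseq, start(dn), min(end(dn), start(dn) + 5L), str, 6L)
    } else {
      de <- .txWindow(cseq, start(up), min(end(up), start(up) + 5L), str, 6L)
      di <- .txWindow(cseq, max(start(it), end(it) - 15L), end(it), str, 16L)
      ai <- .txWindow(cseq, start(it), min(end(it), start(it) + 15L), str, 16L)
      ae <- .txWindow(cseq, max(start(dn), end(dn) - 5L), end(dn), str, 6L)
    }
    data.frame(
      intron_id = mcols(it)$intron_id, ordinal = mcols(it)$ordinal,
      preceding_exon_id = mcols(it)$preceding_exon_id,
      following_exon_id = mcols(it)$following_exon_id,
      exon_size = width(up),
      donor_exonic = de$seq, donor_intronic = di$seq,
      intron_size = width(it),
      acceptor_intronic = ai$seq, acceptor_exonic = ae$seq,
      sex_specific = mcols(it)$sex_specific,
      truncated = de$truncated || di$truncated || ai$truncated || ae$truncated,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
})

#' @rdname geneSummary
#' @export
setMethod("geneSummary", "GeneModel", function(x, ...) {
  ex <- exons(x)
  exonBp <- sum(width(ex))
  if (length(ex) >= 2L) {
    il <- width(introns(x))
  } else il <- integer()
  intronBp <- sum(il)
  list(gene_id = geneId(x),
       contig_id = as.character(seqnames(ex))[1L],
       strand = as.character(strand(ex))[1L],
       n_exons = length(ex),
       n_introns = length(il),
       exon_bp = exonBp,
       intron_bp = intronBp,
       span_bp = exonBp + intronBp,
       intron_min_bp = if (length(il)) min(il) else NA_integer_,
       intron_max_bp = if (length(il)) max(il) else NA_integer_,
       intron_mean_bp = if (length(il)) mean(il) else NA_real_,
       intron_mean_kb = if (length(il)) .report(mean(il) / 1000) else NA_real_)
})

#' Write a junction report TSV (Table-1 style)
#'
#' One row per intron, keyed by the transcriptionally preceding exon,
#' with the four junction windows and the intron size.
#'
#' @param jx output of [junctionContexts()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeJunctionReport <- function(jx, path) {
  cols <- c("preceding_exon_id", "exon_size", "donor_exonic", "donor_intronic",
            "intron_size", "acceptor_intronic", "acceptor_exonic")
  out <- jx[, cols]
  names(out)[1L] <- "exon_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
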