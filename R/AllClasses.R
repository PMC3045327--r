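#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end width strand sort
#' @importFrom GenomeInfoDb seqnames
NULL

.EXON_CLASSES <- c("common", "female_specific", "male_specific", "utr")

#' GeneModel: ordered classified exons of one gene
#'
#' A gene model is an ordered set of non-overlapping exons on one contig
#' and one strand, each carrying a class label describing its role in
#' sex-specific alternative splicing (`common`, `female_specific`,
#' `male_specific` or `utr`). Exons are stored in transcription order:
#' ascending genomic coordinates on `+`, descending on `-`. Introns,
#' junction windows and summary statistics all derive from this object.
#'
#' @slot geneId single gene identifier.
#' @slot exons a [GenomicRanges::GRanges] with metadata columns
#'   `exon_id` (unique) and `class_label`.
#' @export
setClass("GeneModel", representation(geneId = "character", exons = "GRanges"))

setValidity("GeneModel", function(object) {
  ex <- object@exons
  msg <- character()
  if (length(object@geneId) != 1L || is.na(object@geneId) || !nzchar(object@geneId))
    msg <- c(msg, "geneId must be a single non-empty string")
  if (length(ex) < 1L)
    msg <- c(msg, "a GeneModel needs at least one exon")
  mc <- mcols(ex)
  if (!all(c("exon_id", "class_label") %in% colnames(mc)))
    return(c(msg, "exons must carry exon_id and class_label metadata columns"))
  if (anyDuplicated(mc$exon_id))
    msg <- c(msg, "duplicated exon_id")
  if (!all(mc$class_label %in% .EXON_CLASSES))
    msg <- c(msg, sprintf("class_label must be one of: %s",
                          paste(.EXON_CLASSES, collapse = ", ")))
  if (length(unique(as.character(seqnames(ex)))) > 1L)
    msg <- c(msg, "all exons of a gene must lie on one contig")
  str <- unique(as.character(strand(ex)))
  if (length(str) > 1L || !str %in% c("+", "-"))
    msg <- c(msg, "all exons must share a single strand, '+' or '-'")
  if (length(ex) > 1L) {
    o <- order(start(ex))
    s <- start(ex)[o]; e <- end(ex)[o]
    if (any(s[-1L] <= e[-length(e)]))
      msg <- c(msg, "exons overlap")
    # transcription order: ascending starts on '+', descending on '-'
    expected <- if (str == "+") order(start(ex)) else order(-start(ex))
    if (!identical(expected, seq_along(ex)))
      msg <- c(msg, "exons must be stored in transcription order")
  }
  if (length(msg)) msg else TRUE
})

#' MotifCatalogue: degenerate splicing cis-element definitions
#'
#' Named IUPAC consensus elements (splicing enhancers/silencers) to be
#' scanned against genomic sequence. The bundled default catalogue holds
#' the classic insect doublesex regulators: the 13-nt TRA/TRA-2 binding
#' repeat (dsxRE), the 8-nt hymenopteran repeat (NvdsxRE), the two RBP1
#' target types and the TRA-2 intronic splicing silencer.
#'
#' @slot defs a [S4Vectors::DataFrame] with columns `name`, `iupac`,
#'   `element_class` (`activator`/`silencer`/`other`) and `source`.
#' @export
setClass("MotifCatalogue", representation(defs = "DataFrame"))

setValidity("MotifCatalogue", function(object) {
  d <- object@defs
  msg <- character()
  need <- c("name", "iupac", "element_class", "source")
  if (!all(need %in% colnames(d)))
    return(sprintf("defs must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(d)) {
    if (anyDuplicated(d$name))
      msg <- c(msg, "duplicated motif name")
    if (any(!nzchar(d$iupac)))
      msg <- c(msg, "empty IUPAC string")
    ok <- vapply(strsplit(toupper(d$iupac), ""), function(ch)
      all(ch %in% names(Biostrings::IUPAC_CODE_MAP)), logical(1))
    if (!all(ok))
      msg <- c(msg, sprintf("invalid IUPAC code in motif '%s'",
                            d$name[which(!ok)[1L]]))
    if (!all(d$element_class %in% c("activator", "silencer", "other")))
      msg <- c(msg, "element_class must be activator, silencer or other")
  }
  if (length(msg)) msg else TRUE
})

#' CodonAlignment: in-frame aligned coding sequences
#'
#' An aligned set of coding nucleotide sequences, all of equal length
#' divisible by three, over the alphabet `A C G T N -`. Gaps must occur
#' as whole codon triples aligned to codon boundaries, so that every
#' aligned column triple is a comparable codon site.
#'
#' @slot seqs a named [Biostrings::DNAStringSet] of aligned sequences.
#' @export
setClass("CodonAlignment", representation(seqs = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  s <- object@seqs
  msg <- character()
  if (length(s) < 1L) return("alignment is empty")
  if (is.null(names(s)) || anyDuplicated(names(s)) || any(!nzchar(names(s))))
    msg <- c(msg, "sequences must carry unique non-empty names")
  w <- unique(Biostrings::width(s))
  if (length(w) != 1L)
    msg <- c(msg, "aligned sequences must have equal length")
  if (length(w) == 1L && w %% 3L != 0L)
    msg <- c(msg, "alignment length must be divisible by 3")
  ch <- strsplit(as.character(s), "", fixed = TRUE)
  okAlpha <- vapply(ch, function(x) all(x %in% c("A", "C", "G", "T", "N", "-")),
                    logical(1))
  if (!all(okAlpha))
    msg <- c(msg, sprintf("sequence '%s' has characters outside {A,C,G,T,N,-}",
                          names(s)[which(!okAlpha)[1L]]))
  if (length(w) == 1L && w %% 3L == 0L && all(okAlpha)) {
    badGap <- vapply(ch, function(x) {
      cod <- matrix(x, nrow = 3L)
      ng <- colSums(cod == "-")
      any(ng > 0L & ng < 3L)
    }, logical(1))
    if (any(badGap))
      msg <- c(msg, sprintf(
        "sequence '%s': gaps must span whole codons on codon boundaries",
        names(s)[which(badGap)[1L]]))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneModel", function(object) {
  ex <- object@exons
  cat(sprintf("GeneModel '%s': %d exon(s) on %s (%s strand)\n",
              object@geneId, length(ex),
              as.character(seqnames(ex))[1L],
              as.character(strand(ex))[1L]))
  cls <- table(factor(mcols(ex)$class_label, levels = .EXON_CLASSES))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  cat(sprintf("  genomic span: %d..%d (%d bp)\n",
              min(start(ex)), max(end(ex)), max(end(ex)) - min(start(ex)) + 1L))
})

setMethod("show", "MotifCatalogue", function(object) {
  d <- object@defs
  cat(sprintf("MotifCatalogue with %d element(s)\n", nrow(d)))
  if (nrow(d))
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-10s %-15s %-9s (%d nt)\n", d$name[i], d$iupac[i],
                  d$element_class[i], nchar(d$iupac[i])))
})

setMethod("show", "CodonAlignment", function(object) {
  cat(sprintf("CodonAlignment: %d sequence(s), %d aligned codons\n",
              length(object@seqs), unique(Biostrings::width(object@seqs)) %/% 3L))
})
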