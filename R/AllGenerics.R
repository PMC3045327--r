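# Generics for the package's S4 classes.

#' @rdname GeneModel-class
#' @param x,object a `GeneModel` (or other class as documented).
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneModel-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' Derive introns from a gene model
#'
#' One intron per adjacent exon pair in transcription order. An intron is
#' flagged `sex_specific` when either flanking exon carries a sex-specific
#' class label (configurable through `sexClasses`).
#'
#' @param x a [GeneModel-class].
#' @param ... further arguments (`sexClasses`).
#' @return a [GenomicRanges::GRanges] in transcription order with metadata
#'   columns `intron_id`, `ordinal`, `length`, `preceding_exon_id`,
#'   `following_exon_id`, `sex_specific`.
#' @export
setGeneric("introns", function(x, ...) standardGeneric("introns"))

#' Extract exon-intron junction windows
#'
#' For every intron, the four windows of the classic junction table:
#' last 6 exonic nt before the donor, first 16 intronic nt (donor side),
#' last 16 intronic nt ending at the terminal dinucleotide (acceptor
#' side), and first 6 nt of the following exon. On the `-` strand all
#' windows are read off the reverse complement, so the donor always sits
#' at the intron's transcriptional 5' end.
#'
#' @param x a [GeneModel-class].
#' @param genome a [Biostrings::DNAStringSet] holding the model's contig.
#' @param ... unused.
#' @return a data.frame, one row per intron (transcription order).
#' @export
setGeneric("junctionContexts", function(x, genome, ...)
  standardGeneric("junctionContexts"))

#' Summarize a gene model
#'
#' Span (exon + intron bp), exon/intron counts, and intron length
#' minimum, maximum and mean (bp and rounded kb).
#'
#' @param x a [GeneModel-class].
#' @param ... unused.
#' @return a list of summary figures.
#' @export
setGeneric("geneSummary", function(x, ...) standardGeneric("geneSummary"))

#' @rdname MotifCatalogue-class
#' @param x a `MotifCatalogue`.
#' @export
setGeneric("motifNames", function(x) standardGeneric("motifNames"))
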