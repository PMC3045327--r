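# Bundled worked example: the published exon-intron junction table of
# the Aedes aegypti doublesex (Aeadsx) gene.

#' Aedes aegypti doublesex junction table
#'
#' The published exon-intron junction windows and sizes of the *Aeadsx*
#' gene (supercontig 1.370; cDNAs GenBank DQ440532-DQ440534): eight
#' annotated exons (the true first exon is unidentified) and seven
#' introns. Each row is keyed by an exon; its donor window, intron size
#' and acceptor window belong to the intron *following* that exon, so
#' the row of exon 5a carries the acceptor preceding the female-specific
#' exon 5b. The last exon row carries `NA` junction fields.
#'
#' The 16-nt acceptor windows feed [scoreAcceptor()] (pyrimidine counts
#' 12, 10, 9, 11, 5, 8, 11 in row order) and the first 6 intronic nt
#' feed [scoreDonor()].
#'
#' @return data.frame with columns `exon_id`, `exon_size`,
#'   `donor_exonic`, `donor_intronic`, `intron_size`,
#'   `acceptor_intronic`, `acceptor_exonic`, `exon_class`.
#' @examples
#' jx <- aedsxJunctions()
#' scoreAcceptor(jx$acceptor_intronic[!is.na(jx$acceptor_intronic)])
#' @export
aedsxJunctions <- function() {
  path <- system.file("extdata", "aedsx_junctions.tsv",
                      package = "dsxSplice", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(exon_id = "character"))
}
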