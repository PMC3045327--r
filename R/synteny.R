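# Microsynteny quality between two genomic regions and order/strand
# conservation of homologous gene pairs.

.asGeneSet <- function(x, label = "region") {
  if (is.character(x))
    x <- data.frame(gene_id = x, start = seq_along(x), end = seq_along(x),
                    strand = "+", stringsAsFactors = FALSE)
  stopifnot("gene_id" %in% names(x))
  if (anyDuplicated(x$gene_id))
    .fail("duplicated gene id in %s: %s", label,
          x$gene_id[duplicated(x$gene_id)][1L])
  if (!"start" %in% names(x)) x$start <- seq_len(nrow(x))
  if (!"strand" %in% names(x)) x$strand <- "+"
  x
}

.checkPairs <- function(pairs, setA, setB) {
  stopifnot(ncol(pairs) >= 2L)
  a <- pairs[[1L]]; b <- pairs[[2L]]
  if (!all(a %in% setA$gene_id))
    .fail("pair references unknown gene in region A: %s",
          setdiff(a, setA$gene_id)[1L])
  if (!all(b %in% setB$gene_id))
    .fail("pair references unknown gene in region B: %s",
          setdiff(b, setB$gene_id)[1L])
  if (anyDuplicated(a) || anyDuplicated(b))
    .fail("a gene appears in more than one homology pair")
  data.frame(geneA = a, geneB = b, stringsAsFactors = FALSE)
}

#' Relative synteny quality of two regions
#'
#' The share of conserved (homologous) genes among the genes of two
#' compared regions, as a percentage. Two conventions are exposed:
#' `pairs_over_printed_total` (default) divides the number of conserved
#' *pairs* by a total gene count `nTotal` -- when `nTotal` is omitted it
#' is the union count `|A| + |B| - |pairs|`, each conserved pair counted
#' once; `pairs_over_combined_total` divides the conserved genes
#' (`2 * |pairs|`) by `|A| + |B|`, which is symmetric and literal.
#'
#' @param setA,setB region gene sets: character vectors of gene ids or
#'   data.frames with `gene_id`, `start`, `end`, `strand`.
#' @param pairs two-column data.frame of homologous pairs (gene in A,
#'   gene in B); no gene may appear twice.
#' @param convention see Description.
#' @param nTotal total gene count for the printed-total convention
#'   (optional).
#' @return a `syntenyResult` list: `n_conserved`, `n_total`,
#'   `quality_percent` (full precision), `reported_percent` (integer),
#'   `convention`.
#' @examples
#' a <- paste0("A", 1:13); b <- paste0("B", 1:13)
#' p <- data.frame(a[1:10], b[1:10])
#' syntenyQuality(a, b, p)  # 10 of 16 -> 62%
#' @export
syntenyQuality <- function(setA, setB, pairs,
                           convention = c("pairs_over_printed_total",
                                          "pairs_over_combined_total"),
                           nTotal = NULL) {
  convention <- match.arg(convention)
  setA <- .asGeneSet(setA, "region A")
  setB <- .asGeneSet(setB, "region B")
  pairs <- .checkPairs(pairs, setA, setB)
  np <- nrow(pairs)
  if (convention == "pairs_over_printed_total") {
    if (is.null(nTotal)) nTotal <- nrow(setA) + nrow(setB) - np
    q <- if (nTotal > 0) 100 * np / nTotal else 0
  } else {
    nTotal <- nrow(setA) + nrow(setB)
    q <- if (nTotal > 0) 100 * 2 * np / nTotal else 0
  }
  structure(list(n_conserved = np, n_total = nTotal, quality_percent = q,
                 reported_percent = .report(q), convention = convention),
            class = "syntenyResult")
}

#' @export
print.syntenyResult <- function(x, ...) {
  cat(sprintf("Synteny quality: %d conserved of %d genes = %.1f%% (reported %d%%; %s)\n",
              x$n_conserved, x$n_total, x$quality_percent,
              x$reported_percent, x$convention))
  invisible(x)
}

#' Order and strand conservation of homologous pairs
#'
#' Pairs are sorted by gene position in region A; inversions are the
#' discordant pairs of pairs relative to the position order in region B
#' (0 for identical order, `choose(n,2)` for a fully reversed order).
#' Strand agreement is flagged per pair to surface genes transcribed in
#' the opposite direction in the two regions.
#'
#' @inheritParams syntenyQuality
#' @return list: `pairs` (data.frame with positions, ranks and
#'   `strand_flip`), `n_inversions`.
#' @export
orderConservation <- function(setA, setB, pairs) {
  setA <- .asGeneSet(setA, "region A")
  setB <- .asGeneSet(setB, "region B")
  pairs <- .checkPairs(pairs, setA, setB)
  ia <- match(pairs$geneA, setA$gene_id)
  ib <- match(pairs$geneB, setB$gene_id)
  d <- data.frame(geneA = pairs$geneA, geneB = pairs$geneB,
                  posA = setA$start[ia], posB = setB$start[ib],
                  strand_flip = setA$strand[ia] != setB$strand[ib],
                  stringsAsFactors = FALSE)
  d <- d[order(d$posA), , drop = FALSE]
  d$rankB <- rank(d$posB)
  n <- nrow(d)
  inv <- 0L
  if (n > 1L)
    for (i in seq_len(n - 1L))
      inv <- inv + sum(d$rankB[(i + 1L):n] < d$rankB[i])
  rownames(d) <- NULL
  list(pairs = d, n_inversions = as.integer(inv))
}

#' Fold ratio of two genomic spans
#'
#' E.g. a 450-kb region versus an 85-kb orthologous region is
#' 5.3-fold larger.
#'
#' @param spanA,spanB spans in the same unit.
#' @param digits decimals for the reported value (default 1).
#' @return list `fold` (full precision) and `reported`.
#' @export
spanFold <- function(spanA, spanB, digits = 1) {
  stopifnot(spanB > 0)
  f <- spanA / spanB
  list(fold = f, reported = .report(f, digits))
}
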