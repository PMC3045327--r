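# Splice-site strength statistics: acceptor polypyrimidine counts,
# donor consensus matches, genome-wide consensus estimation, weak-site
# classification.

#' Score 3' splice acceptor windows
#'
#' The acceptor window is the last 16 intronic nucleotides, ending at the
#' terminal dinucleotide. Site strength is the pyrimidine count
#' (`y_count`, "number of Y") over the *first 12* positions -- the
#' polypyrimidine-tract positions of the acceptor consensus
#' `YYYYYYYYYYYYNYag/G`; positions 13-14 are not counted and 15-16 form
#' the terminal dinucleotide (canonically `AG`). `N` counts as a
#' non-pyrimidine. Case-insensitive.
#'
#' @param window character vector of 16-nt acceptor windows.
#' @return data.frame with columns `window`, `y_count` (0-12),
#'   `terminal` and `canonical` (terminal == `AG`).
#' @examples
#' scoreAcceptor("tctcctctcttttcag")  # y_count 12, canonical
#' scoreAcceptor("acataatgaccacagt")  # y_count 5, terminal GT
#' @export
scoreAcceptor <- function(window) {
  if (length(window) == 0L) .fail("no acceptor windows supplied")
  n <- nchar(window)
  if (any(n != 16L))
    .fail("acceptor window must be exactly 16 nt (got %d nt: '%s')",
          n[n != 16L][1L], window[n != 16L][1L])
  ch <- .charMatrix(window)
  yc <- rowSums(matrix(.isPyrimidine(ch[, 1:12, drop = FALSE]), ncol = 12L))
  terminal <- toupper(substr(window, 15L, 16L))
  data.frame(window = window, y_count = as.integer(yc), terminal = terminal,
             canonical = terminal == "AG", stringsAsFactors = FALSE)
}

#' Score 5' splice donor sites against an IUPAC consensus
#'
#' The donor window is the first 6 intronic nucleotides, compared
#' position-wise with a degenerate consensus (default `GTRAGT`, the
#' junction-table form; `GTRAGY` is the common literature alternative).
#' A position matches when the observed base belongs to the IUPAC set of
#' the consensus character; `N` never matches.
#'
#' @param window character vector of 6-nt donor windows.
#' @param consensus IUPAC consensus of the same length (default
#'   `"GTRAGT"`).
#' @return data.frame with columns `window`, `match_count` and
#'   `canonical_gt` (positions 1-2 == `GT`).
#' @examples
#' scoreDonor("gtactg")  # 3/6
#' scoreDonor("gtgagt")  # 6/6
#' @export
scoreDonor <- function(window, consensus = "GTRAGT") {
  if (length(window) == 0L) .fail("no donor windows supplied")
  .assertIupac(consensus, "donor consensus")
  m <- nchar(consensus)
  if (any(nchar(window) != m))
    .fail("donor window must be %d nt to match consensus '%s'", m, consensus)
  sets <- iupacSets()[strsplit(toupper(consensus), "")[[1L]]]
  ch <- .charMatrix(window)
  hit <- vapply(seq_len(m), function(j)
    grepl(sprintf("[%s]", sets[j]), ch[, j]), logical(length(window)))
  hit <- matrix(hit, ncol = m)
  data.frame(window = window,
             match_count = as.integer(rowSums(hit)),
             canonical_gt = toupper(substr(window, 1L, 2L)) == "GT",
             stringsAsFactors = FALSE)
}

#' Estimate the genome-wide acceptor consensus
#'
#' Mean and sample standard deviation of the acceptor pyrimidine count
#' over a collection of 16-nt windows (typically several thousand random
#' introns from a genome annotation). Windows of the wrong length are
#' skipped with a warning.
#'
#' @param windows character vector of acceptor windows.
#' @return a `consensusStats` list: `n_introns`, `mean_y`, `sd_y`
#'   (sample sd), `n_skipped`.
#' @export
consensusFromIntrons <- function(windows) {
  ok <- !is.na(windows) & nchar(windows) == 16L
  nSkip <- sum(!ok)
  if (nSkip) warning(sprintf("skipped %d window(s) not 16 nt long", nSkip))
  windows <- windows[ok]
  if (length(windows) < 2L)
    .fail("need at least 2 valid acceptor windows (got %d)", length(windows))
  y <- scoreAcceptor(windows)$y_count
  structure(list(n_introns = length(y), mean_y = mean(y),
                 sd_y = stats::sd(y), n_skipped = nSkip),
            class = "consensusStats")
}

#' @export
print.consensusStats <- function(x, ...) {
  cat(sprintf("Acceptor consensus over %d introns: %.2f +/- %.2f pyrimidines\n",
              x$n_introns, x$mean_y, x$sd_y))
  invisible(x)
}

#' Build consensus stats from known figures
#'
#' For classifying sites against a published genome-wide consensus
#' (e.g. mean 8.02, sd 2.15) without re-tabulating the introns.
#'
#' @param meanY,sdY consensus mean and standard deviation.
#' @param nIntrons number of introns behind the estimate (informational).
#' @return a `consensusStats` list.
#' @export
consensusStats <- function(meanY, sdY, nIntrons = NA_integer_) {
  stopifnot(meanY >= 0, meanY <= 12, sdY >= 0)
  structure(list(n_introns = nIntrons, mean_y = meanY, sd_y = sdY,
                 n_skipped = 0L), class = "consensusStats")
}

#' Classify splice sites as weak or not
#'
#' An acceptor is weak when its terminal dinucleotide is non-canonical
#' (not `AG`) or its pyrimidine count falls below
#' `mean_y - kSd * sd_y` of the genome-wide consensus. A donor is weak
#' when it does not begin with `GT` or matches fewer than
#' `donorMinMatch` of the six consensus positions.
#'
#' @param acceptors output of [scoreAcceptor()] (optionally with a
#'   `site_id` column), or `NULL`.
#' @param donors output of [scoreDonor()] (optionally with `site_id`),
#'   or `NULL`.
#' @param stats a `consensusStats` object ([consensusFromIntrons()] or
#'   [consensusStats()]); required when acceptors are given.
#' @param kSd acceptor threshold in consensus standard deviations
#'   (default 1).
#' @param donorMinMatch minimum donor consensus matches (default 4).
#' @return data.frame with columns `site_id`, `site_kind`, `weak`,
#'   `reasons` (comma-separated; empty iff not weak).
#' @export
classifySites <- function(acceptors = NULL, donors = NULL, stats = NULL,
                          kSd = 1.0, donorMinMatch = 4L) {
  out <- list()
  if (!is.null(acceptors) && nrow(acceptors)) {
    if (is.null(stats)) .fail("acceptor classification needs consensus stats")
    thr <- stats$mean_y - kSd * stats$sd_y
    ids <- if ("site_id" %in% names(acceptors)) acceptors$site_id
           else paste0("acceptor_", seq_len(nrow(acceptors)))
    reasons <- mapply(function(canon, y) {
      r <- character()
      if (!canon) r <- c(r, "non_canonical_terminus")
      if (y < thr) r <- c(r, "low_y_count")
      paste(r, collapse = ",")
    }, acceptors$canonical, acceptors$y_count)
    out$acc <- data.frame(site_id = ids, site_kind = "acceptor",
                          weak = nzchar(reasons), reasons = reasons,
                          stringsAsFactors = FALSE)
  }
  if (!is.null(donors) && nrow(donors)) {
    ids <- if ("site_id" %in% names(donors)) donors$site_id
           else paste0("donor_", seq_len(nrow(donors)))
    reasons <- mapply(function(canon, m) {
      r <- character()
      if (!canon) r <- c(r, "non_canonical_terminus")
      if (m < donorMinMatch) r <- c(r, "low_donor_match")
      paste(r, collapse = ",")
    }, donors$canonical_gt, donors$match_count)
    out$don <- data.frame(site_id = ids, site_kind = "donor",
                          weak = nzchar(reasons), reasons = reasons,
                          stringsAsFactors = FALSE)
  }
  if (!length(out)) .fail("nothing to classify")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score a junction table
#'
#' Convenience wrapper over [scoreAcceptor()], [scoreDonor()] and
#' [classifySites()] for the junction report of [junctionContexts()]:
#' appends `y_count`, `terminal`, `donor_match`, `canonical_gt` and the
#' weak flags to each intron row. Truncated windows are scored as `NA`.
#'
#' @param jx junction data.frame from [junctionContexts()] (or a TSV
#'   read back with the same columns).
#' @param stats consensus stats for acceptor classification.
#' @param consensus donor consensus (default `GTRAGT`).
#' @inheritParams classifySites
#' @return `jx` with score and classification columns appended.
#' @export
scoreJunctions <- function(jx, stats, consensus = "GTRAGT",
                           kSd = 1.0, donorMinMatch = 4L) {
  okA <- nchar(jx$acceptor_intronic) == 16L
  okD <- nchar(jx$donor_intronic) >= nchar(consensus)
  jx$y_count <- NA_integer_; jx$terminal <- NA_character_
  jx$acceptor_canonical <- NA
  jx$donor_match <- NA_integer_; jx$canonical_gt <- NA
  jx$acceptor_weak <- NA; jx$acceptor_reasons <- NA_character_
  jx$donor_weak <- NA; jx$donor_reasons <- NA_character_
  if (any(okA)) {
    acc <- scoreAcceptor(jx$acceptor_intronic[okA])
    acc$site_id <- jx$intron_id[okA]
    cls <- classifySites(acceptors = acc, stats = stats, kSd = kSd)
    jx$y_count[okA] <- acc$y_count
    jx$terminal[okA] <- acc$terminal
    jx$acceptor_canonical[okA] <- acc$canonical
    jx$acceptor_weak[okA] <- cls$weak
    jx$acceptor_reasons[okA] <- cls$reasons
  }
  if (any(okD)) {
    don <- scoreDonor(substr(jx$donor_intronic[okD], 1L, nchar(consensus)),
                      consensus = consensus)
    don$site_id <- jx$intron_id[okD]
    cls <- classifySites(donors = don, donorMinMatch = donorMinMatch)
    jx$donor_match[okD] <- don$match_count
    jx$canonical_gt[okD] <- don$canonical_gt
    jx$donor_weak[okD] <- cls$weak
    jx$donor_reasons[okD] <- cls$reasons
  }
  jx
}
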