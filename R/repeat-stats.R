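# Per-intron repeat-element density statistics (NoRE/kb, REbp) and
# group comparisons between sex-specific and non-sex-specific introns.

#' Read a repeat annotation table
#'
#' Tab-separated with header columns `contig`, `start`, `end` (1-based
#' inclusive), `family`, `class` (a CENSOR-style table), or BED4
#' (`format = "bed"`: 0-based half-open, fourth column = family).
#' Rows with `end < start` or non-numeric coordinates raise an error
#' naming the line.
#'
#' @param path input file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return a [GenomicRanges::GRanges], sorted, with metadata columns
#'   `family` and `repeat_class`.
#' @export
readRepeats <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    names(d)[1:4] <- c("contig", "start", "end", "family")
    d$start <- d$start + 1L   # to 1-based inclusive
    d$class <- "unknown"
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "start", "end", "family", "class")
    if (!all(need %in% names(d)))
      .fail("repeat table needs columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(d) == 0L) {
    warning("empty repeat table: ", path)
    return(GRanges(family = character(), repeat_class = character()))
  }
  sNum <- suppressWarnings(as.numeric(d$start))
  eNum <- suppressWarnings(as.numeric(d$end))
  if (anyNA(sNum) || anyNA(eNum))
    .fail("non-numeric coordinate at line %d of %s",
          which(is.na(sNum) | is.na(eNum))[1L] + 1L, path)
  if (any(eNum < sNum))
    .fail("end < start at line %d of %s", which(eNum < sNum)[1L] + 1L, path)
  gr <- GRanges(d$contig, IRanges(as.integer(sNum), as.integer(eNum)))
  mcols(gr)$family <- d$family
  mcols(gr)$repeat_class <- d$class
  sort(gr)
}

#' Per-intron repeat density statistics
#'
#' For each intron: the number of repeat features overlapping it by at
#' least 1 bp (each counted once), `NoRE/kb` = count / (length/1000),
#' and `REbp` = 100 x covered bp / intron length, where coverage is the
#' union of the features clipped to the intron (so REbp never exceeds
#' 100). `sumCoverage = TRUE` instead sums the clipped widths without
#' merging overlaps, for comparison with raw annotation output.
#'
#' @param introns a [GenomicRanges::GRanges] of introns carrying an
#'   `intron_id` metadata column (e.g. from [introns()]). Repeat
#'   features are matched by contig.
#' @param repeats a [GenomicRanges::GRanges] from [readRepeats()].
#' @param sumCoverage merge overlapping repeats (default) or sum raw
#'   clipped widths.
#' @return data.frame: `intron_id`, `intron_length`, `n_elements`,
#'   `nore_per_kb`, `rebp_percent` (full precision).
#' @export
intronRepeatStats <- function(introns, repeats, sumCoverage = FALSE) {
  ov <- GenomicRanges::findOverlaps(introns, repeats)
  n <- GenomicRanges::countOverlaps(introns, repeats)
  cov <- numeric(length(introns))
  if (length(ov)) {
    clipped <- GenomicRanges::pintersect(
      introns[S4Vectors::queryHits(ov)], repeats[S4Vectors::subjectHits(ov)])
    covList <- split(clipped, S4Vectors::queryHits(ov))
    for (q in names(covList)) {
      ir <- IRanges::ranges(covList[[q]])
      cov[as.integer(q)] <- if (sumCoverage) sum(BiocGenerics::width(ir))
                            else sum(BiocGenerics::width(IRanges::reduce(ir)))
    }
  }
  len <- width(introns)
  data.frame(intron_id = mcols(introns)$intron_id,
             intron_length = len,
             n_elements = as.integer(n),
             nore_per_kb = n / (len / 1000),
             rebp_percent = 100 * cov / len,
             stringsAsFactors = FALSE)
}

#' Compare repeat densities between intron groups
#'
#' Arithmetic group means of NoRE/kb and REbp for sex-specific versus
#' non-sex-specific introns, plus each intron's deviation from the
#' non-sex-specific group mean. An intron is flagged `deviates` when its
#' value falls below `mean/factor` or above `mean*factor` of the
#' reference (non-sex-specific) mean -- a descriptive flag, not a test.
#'
#' @param stats data.frame from [intronRepeatStats()].
#' @param sexSpecific logical vector, one per intron row.
#' @param factor deviation factor (default 2).
#' @return list with `group_means` (data.frame) and `per_intron`
#'   (data.frame with ratios and deviation flags).
#' @export
compareRepeatGroups <- function(stats, sexSpecific, factor = 2) {
  stopifnot(nrow(stats) == length(sexSpecific))
  if (!any(sexSpecific) || all(sexSpecific))
    .fail("both groups (sex-specific and non-sex-specific) must be non-empty")
  gm <- do.call(rbind, lapply(c(FALSE, TRUE), function(g) {
    sel <- sexSpecific == g
    data.frame(group = if (g) "sex_specific" else "non_sex_specific",
               n_introns = sum(sel),
               mean_nore_per_kb = mean(stats$nore_per_kb[sel]),
               mean_rebp_percent = mean(stats$rebp_percent[sel]),
               stringsAsFactors = FALSE)
  }))
  refN <- gm$mean_nore_per_kb[gm$group == "non_sex_specific"]
  refR <- gm$mean_rebp_percent[gm$group == "non_sex_specific"]
  per <- data.frame(
    intron_id = stats$intron_id,
    sex_specific = sexSpecific,
    nore_per_kb = stats$nore_per_kb,
    rebp_percent = stats$rebp_percent,
    nore_ratio_to_ref = stats$nore_per_kb / refN,
    rebp_ratio_to_ref = stats$rebp_percent / refR,
    stringsAsFactors = FALSE)
  per$deviates <- per$nore_per_kb < refN / factor |
    per$nore_per_kb > refN * factor |
    per$rebp_percent < refR / factor |
    per$rebp_percent > refR * factor
  list(group_means = gm, per_intron = per)
}

#' Format repeat statistics at report precision
#'
#' NoRE/kb to 2 decimals, REbp to the nearest integer percent -- the
#' conventional reporting precision for these figures.
#'
#' @param stats data.frame from [intronRepeatStats()].
#' @return `stats` with `nore_per_kb_report` and `rebp_report` columns.
#' @export
formatRepeatStats <- function(stats) {
  stats$nore_per_kb_report <- .report(stats$nore_per_kb, 2)
  stats$rebp_report <- .report(stats$rebp_percent, 0)
  stats
}
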