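# Shared low-level helpers: IUPAC sets, rounding, sequence handling.

# Per-code base sets from Biostrings; values are strings over ACGT only,
# so an N in a *subject* sequence is never a member of any set and always
# counts as a mismatch / non-pyrimidine.
iupacSets <- function() Biostrings::IUPAC_CODE_MAP

.assertIupac <- function(x, what = "motif") {
  codes <- names(iupacSets())
  chars <- strsplit(toupper(x), "", fixed = TRUE)
  bad <- vapply(chars, function(ch) {
    w <- which(!ch %in% codes)
    if (length(w)) w[1L] else 0L
  }, integer(1))
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid IUPAC code '%s' at position %d of %s '%s'",
                 substr(toupper(x[i]), bad[i], bad[i]), bad[i], what, x[i]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Character matrix (one row per string), all strings same length.
.charMatrix <- function(x) {
  do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
}

# Reported figures (integer percents, 1-decimal fold ratios, kb means)
# use base round(), i.e. IEC 60559 round-half-to-even, which reproduces
# the conventional printed values for this locus (62.5 -> 62, 58.87 -> 59,
# 5.294 -> 5.3, 64.46 -> 64).
.report <- function(x, digits = 0) round(x, digits)

# Reverse complement of plain character strings (ACGTN + IUPAC).
.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.isPyrimidine <- function(ch) ch == "C" | ch == "T"

# uniform helper: stop with a prefixed message
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
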