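# Pairwise synonymous / non-synonymous substitution analysis:
# Nei-Gojobori (1986) site and difference counting with pathway
# averaging, Jukes-Cantor multiple-hit correction, partitioned codon
# alignments, and aligned-identity arithmetic.

.molevolCache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

# permutations of 1..k for k <= 3 (pathway orderings)
.PERMS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

.senseCodons <- function(code) names(code)[code != "*"]

#' Synonymous and non-synonymous site counts of a codon
#'
#' Nei-Gojobori site counting: each codon position contributes a
#' synonymous fraction equal to the number of synonymous one-step
#' changes at that position divided by the number of admissible one-step
#' changes there. By default changes creating a stop codon are excluded
#' from the denominator (the convention of the dominant modern
#' implementations); `strict = TRUE` keeps the original 3-change
#' denominator with stop-creating changes counted as non-synonymous.
#' `s + n = 3` always holds under `strict`; under the default the total
#' remains 3 because each position is still one site, split by the
#' admissible-change fractions.
#'
#' @param codon character vector of 3-nt codons over `ACGT`; stop codons
#'   are rejected.
#' @param code named genetic code vector (default
#'   [Biostrings::GENETIC_CODE]); swappable.
#' @param strict use the literal 3-change denominator.
#' @return data.frame `codon`, `s`, `n` (with `s + n = 3`).
#' @examples
#' codonSites("TTT")  # s = 1/3
#' codonSites("ATG")  # s = 0
#' @export
codonSites <- function(codon, code = Biostrings::GENETIC_CODE,
                       strict = FALSE) {
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad))
    .fail("codon '%s' is not a 3-nt ACGT codon (gap/N codons are excluded upstream)",
          codon[bad][1L])
  if (any(code[codon] == "*"))
    .fail("stop codon '%s' has no site counts", codon[code[codon] == "*"][1L])
  tab <- .sitesTable(code, strict)
  data.frame(codon = codon, s = tab[codon, "s"], n = tab[codon, "n"],
             row.names = NULL, stringsAsFactors = FALSE)
}

.sitesTable <- function(code, strict) {
  key <- paste0("sites_", strict, "_", digestCode(code))
  if (!is.null(.molevolCache[[key]])) return(.molevolCache[[key]])
  sense <- .senseCodons(code)
  s <- vapply(sense, function(cod) {
    ch <- strsplit(cod, "")[[1L]]
    total <- 0
    for (pos in 1:3) {
      alts <- setdiff(.BASES, ch[pos])
      syn <- 0L; adm <- 0L
      for (b in alts) {
        mut <- ch; mut[pos] <- b
        mutCod <- paste(mut, collapse = "")
        if (code[mutCod] == "*") {
          if (strict) adm <- adm + 1L  # counted, non-synonymous
          next
        }
        adm <- adm + 1L
        if (code[mutCod] == code[cod]) syn <- syn + 1L
      }
      denom <- if (strict) 3L else adm
      if (denom > 0L) total <- total + syn / denom
    }
    total
  }, numeric(1))
  tab <- cbind(s = s, n = 3 - s)
  rownames(tab) <- sense
  .molevolCache[[key]] <- tab
  tab
}

# cheap identity key for a genetic code vector
digestCode <- function(code) {
  paste0(length(code), "_", sum(utf8ToInt(paste(code, collapse = ""))))
}

#' Synonymous and non-synonymous differences between two codons
#'
#' For codons differing at `k` positions, the `k` single-step changes
#' are applied in every one of the `k!` orderings; synonymous and
#' non-synonymous steps are tallied along each pathway and averaged over
#' pathways. Pathways passing through a stop codon are excluded; when
#' every pathway hits a stop, all pathways are used (steps into or out
#' of a stop count as non-synonymous). `sd + nd = k` always.
#'
#' @param codonA,codonB sense codons (3-nt over `ACGT`).
#' @inheritParams codonSites
#' @param excludeStopPaths drop stop-crossing pathways (default `TRUE`).
#' @return named numeric vector `c(sd, nd)`.
#' @examples
#' codonDifferences("TTT", "TTC")  # c(sd = 1, nd = 0)
#' @export
codonDifferences <- function(codonA, codonB, code = Biostrings::GENETIC_CODE,
                             excludeStopPaths = TRUE) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  for (cod in c(codonA, codonB)) {
    if (!grepl("^[ACGT]{3}$", cod)) .fail("'%s' is not an ACGT codon", cod)
    if (code[cod] == "*") .fail("stop codon '%s' cannot be compared", cod)
  }
  if (codonA == codonB) return(c(sd = 0, nd = 0))
  key <- paste0("diff_", codonA, codonB, "_", excludeStopPaths, "_",
                digestCode(code))
  if (!is.null(.molevolCache[[key]])) return(.molevolCache[[key]])
  a <- strsplit(codonA, "")[[1L]]
  b <- strsplit(codonB, "")[[1L]]
  diffPos <- which(a != b)
  k <- length(diffPos)
  paths <- lapply(.PERMS[[k]], function(ord) diffPos[ord])
  walk <- function(order) {
    cur <- a
    sd <- 0; nd <- 0; hitStop <- FALSE
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b[pos]
      aaCur <- code[paste(cur, collapse = "")]
      aaNxt <- code[paste(nxt, collapse = "")]
      if (aaNxt == "*") hitStop <- TRUE
      if (aaCur == aaNxt && aaCur != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, hitStop = hitStop)
  }
  res <- lapply(paths, walk)
  if (excludeStopPaths) {
    keep <- !vapply(res, `[[`, logical(1), "hitStop")
    if (any(keep)) res <- res[keep]
  }
  out <- c(sd = mean(vapply(res, `[[`, numeric(1), "sd")),
           nd = mean(vapply(res, `[[`, numeric(1), "nd")))
  .molevolCache[[key]] <- out
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * ln(1 - (4/3) p)`: the one-parameter multiple-hit
#' correction applied to the proportions of synonymous and
#' non-synonymous differences. Undefined (saturated) at `p >= 3/4`;
#' returns `NA` there.
#'
#' @param p proportion(s) of differences, `0 <= p`.
#' @return corrected distance(s); `NA` where saturated.
#' @examples
#' jcCorrect(0.1)  # ~0.10732
#' @export
jcCorrect <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE))
  d <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
  d[p == 0] <- 0
  d
}

# split an aligned sequence into codon strings
.codonSplit <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise Nei-Gojobori rates with Jukes-Cantor correction
#'
#' Counts average synonymous/non-synonymous sites (`S`, `N`) over the
#' two sequences, pathway-averaged synonymous/non-synonymous differences
#' (`Sd`, `Nd`) summed over codon sites, their proportions
#' (`pS = Sd/S`, `pN = Nd/N`) and Jukes-Cantor corrected distances
#' (`dS`, `dN`). Codon sites containing a gap, `N`, or a stop codon in
#' either sequence are excluded pair-wise. The dN/dS ratio is undefined
#' when `dS = 0` (status `dS_zero`); a proportion at or beyond 3/4 sets
#' status `saturated`.
#'
#' @param seqA,seqB aligned coding sequences (equal length, divisible by
#'   3): character strings or `DNAString`s.
#' @param partition optional list/matrix of 1-based inclusive CDS
#'   coordinate ranges (each of length divisible by 3) restricting the
#'   comparison.
#' @inheritParams codonSites
#' @param excludeStopPaths see [codonDifferences()].
#' @return one-row data.frame: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `ratio`, `status`, `n_codons`, `n_excluded`.
#' @export
pairwiseNG86 <- function(seqA, seqB, partition = NULL,
                         code = Biostrings::GENETIC_CODE, strict = FALSE,
                         excludeStopPaths = TRUE) {
  a <- toupper(as.character(seqA)); b <- toupper(as.character(seqB))
  if (nchar(a) != nchar(b)) .fail("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) .fail("aligned length not divisible by 3")
  if (!is.null(partition)) {
    idx <- .partitionIndex(partition, nchar(a))
    a <- paste(strsplit(a, "")[[1L]][idx], collapse = "")
    b <- paste(strsplit(b, "")[[1L]][idx], collapse = "")
  }
  ca <- .codonSplit(a); cb <- .codonSplit(b)
  okChar <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  okStop <- okChar
  okStop[okChar] <- code[ca[okChar]] != "*" & code[cb[okChar]] != "*"
  ca <- ca[okStop]; cb <- cb[okStop]
  nCod <- length(ca)
  if (nCod < 1L) .fail("no comparable codon sites in this pair")
  tab <- .sitesTable(code, strict)
  S <- (sum(tab[ca, "s"]) + sum(tab[cb, "s"])) / 2
  N <- (sum(tab[ca, "n"]) + sum(tab[cb, "n"])) / 2
  Sd <- 0; Nd <- 0
  neq <- which(ca != cb)
  for (i in neq) {
    d <- codonDifferences(ca[i], cb[i], code, excludeStopPaths)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jcCorrect(pS); dN <- jcCorrect(pN)
  status <- "ok"
  if (!is.na(pS) && pS >= 0.75 || !is.na(pN) && pN >= 0.75) status <- "saturated"
  else if (isTRUE(dS == 0)) status <- "dS_zero"
  ratio <- if (status == "ok" && !is.na(dS) && dS > 0) dN / dS else NA_real_
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             dS = dS, dN = dN, ratio = ratio, status = status,
             n_codons = nCod, n_excluded = sum(!okStop),
             stringsAsFactors = FALSE)
}

# partition spec -> flat vector of column indices, validated
.partitionIndex <- function(partition, alnLen) {
  rng <- .asRanges(partition)
  idx <- unlist(lapply(seq_len(nrow(rng)), function(i)
    seq(rng[i, 1L], rng[i, 2L])))
  if (any(idx < 1L) || any(idx > alnLen))
    .fail("partition range exceeds alignment length %d", alnLen)
  if (anyDuplicated(idx)) .fail("partition ranges overlap")
  if (length(idx) %% 3L != 0L)
    .fail("partition length %d is not divisible by 3", length(idx))
  idx
}

.asRanges <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.list(x)) return(do.call(rbind, lapply(x, function(r) r[1:2])))
  matrix(x[1:2], nrow = 1L)
}

#' Read a codon alignment (aligned FASTA)
#'
#' @param path aligned FASTA; equal lengths divisible by 3, alphabet
#'   `ACGTN-`, gaps as whole codons (validity enforced by
#'   [CodonAlignment-class]).
#' @return a [CodonAlignment-class].
#' @export
readCodonAlignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  s <- Biostrings::DNAStringSet(toupper(as.character(raw)))
  names(s) <- names(raw)
  new("CodonAlignment", seqs = s)
}

#' @rdname readCodonAlignment
#' @param seqs named character vector or `DNAStringSet` of aligned
#'   sequences.
#' @export
codonAlignment <- function(seqs) {
  if (!is(seqs, "DNAStringSet")) {
    s <- Biostrings::DNAStringSet(toupper(seqs))
    names(s) <- names(seqs)
  } else s <- seqs
  new("CodonAlignment", seqs = s)
}

#' Read a partition definition (JSON)
#'
#' JSON object mapping partition names to arrays of
#' `[start, end]` CDS coordinate ranges (1-based inclusive), e.g.
#' `{"OD1": [[94, 288]], "OD2": [[607, 837]]}`.
#'
#' @param path JSON file.
#' @return named list of 2-column range matrices.
#' @export
readPartitions <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(j, function(x) {
    m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = 2L, byrow = TRUE)
    storage.mode(m) <- "integer"
    m
  })
}

#' Partitioned pairwise dN/dS summary
#'
#' Evaluates all unordered sequence pairs per partition and summarizes:
#' mean pairwise dN, dS, and the *mean of per-pair dN/dS ratios* over
#' pairs with status `ok` (the alternative ratio-of-means is reported
#' alongside). Pairs with `dS = 0` or saturation are excluded from the
#' ratio mean and counted. Classification: `purifying` when the mean
#' ratio < 1, `positive` when > 1.
#'
#' @param alignment a [CodonAlignment-class] (or named character /
#'   `DNAStringSet` of aligned sequences).
#' @param partitions named list of range matrices
#'   (see [readPartitions()]); `NULL` analyses the whole alignment as
#'   one partition `all`.
#' @inheritParams pairwiseNG86
#' @return list with `pairs` (long data.frame, one row per pair x
#'   partition) and `summary` (one row per partition).
#' @export
partitionSummary <- function(alignment, partitions = NULL,
                             code = Biostrings::GENETIC_CODE,
                             strict = FALSE, excludeStopPaths = TRUE) {
  if (!is(alignment, "CodonAlignment")) alignment <- codonAlignment(alignment)
  s <- as.character(alignment@seqs)
  if (length(s) < 2L) .fail("need at least 2 sequences")
  if (is.null(partitions))
    partitions <- list(all = matrix(c(1L, nchar(s[[1L]])), nrow = 1L))
  cmb <- utils::combn(names(s), 2L)
  rows <- list()
  for (pname in names(partitions)) {
    for (j in seq_len(ncol(cmb))) {
      pr <- pairwiseNG86(s[[cmb[1L, j]]], s[[cmb[2L, j]]],
                         partition = partitions[[pname]],
                         code = code, strict = strict,
                         excludeStopPaths = excludeStopPaths)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(idA = cmb[1L, j], idB = cmb[2L, j], partition = pname,
                   stringsAsFactors = FALSE), pr)
    }
  }
  pairs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(names(partitions), function(pname) {
    sub <- pairs[pairs$partition == pname, , drop = FALSE]
    ok <- sub$status == "ok"
    meanRatio <- if (any(ok)) mean(sub$ratio[ok]) else NA_real_
    meanDN <- if (any(ok)) mean(sub$dN[ok]) else NA_real_
    meanDS <- if (any(ok)) mean(sub$dS[ok]) else NA_real_
    rom <- if (any(ok) && meanDS > 0) meanDN / meanDS else NA_real_
    cls <- if (is.na(meanRatio)) NA_character_
           else if (meanRatio < 1) "purifying"
           else if (meanRatio > 1) "positive" else "neutral"
    data.frame(partition = pname, n_pairs = nrow(sub), n_ok = sum(ok),
               n_excluded = sum(!ok), mean_dN = meanDN, mean_dS = meanDS,
               mean_ratio = meanRatio, ratio_of_means = rom,
               classification = cls, stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summary)
}

#' Aligned-identity percentage
#'
#' @param identical count of identical aligned positions.
#' @param aligned count of aligned positions (> 0).
#' @return list `percent` (full precision) and `reported` (integer).
#' @examples
#' alignedIdentity(166, 282)  # 58.87 -> reported 59
#' @export
alignedIdentity <- function(identical, aligned) {
  stopifnot(aligned > 0, identical >= 0, identical <= aligned)
  p <- 100 * identical / aligned
  list(percent = p, reported = .report(p))
}
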