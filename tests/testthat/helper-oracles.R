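# Independent brute-force oracles. These deliberately share no code
# with the package: their own IUPAC map, their own genetic-code walks,
# base-resolution interval arithmetic, naive O(n*m) scans.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# every offset (1-based) where <= maxMM positions of `motif` are violated;
# an N in the sequence matches nothing (sets contain only ACGT)
oracleScan <- function(seq, motif, maxMM = 0L) {
  s <- strsplit(toupper(seq), "")[[1L]]
  m <- strsplit(toupper(motif), "")[[1L]]
  n <- length(s); k <- length(m)
  if (n < k) return(data.frame(start = integer(), mismatches = integer()))
  res <- lapply(seq_len(n - k + 1L), function(i) {
    mm <- sum(vapply(seq_len(k), function(j)
      !(s[i + j - 1L] %in% ORACLE_IUPAC[[m[j]]]), logical(1)))
    if (mm <= maxMM) data.frame(start = i, mismatches = mm) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out)) data.frame(start = integer(), mismatches = integer())
  else out
}

# maximal pure purine runs of length >= minLen
oracleRuns <- function(seq, minLen) {
  s <- strsplit(toupper(seq), "")[[1L]]
  runs <- list(); i <- 1L; n <- length(s)
  while (i <= n) {
    if (s[i] %in% c("A", "G")) {
      j <- i
      while (j < n && s[j + 1L] %in% c("A", "G")) j <- j + 1L
      if (j - i + 1L >= minLen)
        runs[[length(runs) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  do.call(rbind, runs)
}

# per-base membership count of repeat coverage within [intStart, intEnd]
oracleCoverage <- function(intStart, intEnd, featStarts, featEnds) {
  covered <- logical(intEnd - intStart + 1L)
  for (k in seq_along(featStarts)) {
    a <- max(intStart, featStarts[k]); b <- min(intEnd, featEnds[k])
    if (a <= b) covered[(a:b) - intStart + 1L] <- TRUE
  }
  sum(covered)
}

# --- literal-transcription Nei-Gojobori oracle -------------------------
GC <- Biostrings::GENETIC_CODE

oraclePerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in oraclePerms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracleSites <- function(codon, strict = FALSE) {
  ch <- strsplit(codon, "")[[1L]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; poss <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[pos])) {
      mut <- ch; mut[pos] <- b
      mc <- paste(mut, collapse = "")
      if (GC[[mc]] == "*") { if (strict) poss <- poss + 1; next }
      poss <- poss + 1
      if (GC[[mc]] == GC[[codon]]) syn <- syn + 1
    }
    if (strict) poss <- 3
    if (poss > 0) s <- s + syn / poss
  }
  c(s = s, n = 3 - s)
}

oracleDiffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1L]]; b <- strsplit(cb, "")[[1L]]
  pos <- which(a != b)
  if (!length(pos)) return(c(sd = 0, nd = 0))
  paths <- oraclePerms(pos)
  tallies <- list()
  for (p in paths) {
    cur <- a; sd <- 0; nd <- 0; stop <- FALSE
    for (x in p) {
      nxt <- cur; nxt[x] <- b[x]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (GC[[c2]] == "*") stop <- TRUE
      if (GC[[c1]] == GC[[c2]] && GC[[c1]] != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    tallies[[length(tallies) + 1L]] <- list(sd = sd, nd = nd, stop = stop)
  }
  ok <- Filter(function(t) !t$stop, tallies)
  if (!length(ok)) ok <- tallies
  c(sd = mean(vapply(ok, `[[`, numeric(1), "sd")),
    nd = mean(vapply(ok, `[[`, numeric(1), "nd")))
}

# full pairwise NG86 counts on two gap-free aligned CDS strings
oracleNG86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  keep[keep] <- GC[ca[keep]] != "*" & GC[cb[keep]] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  stA <- t(vapply(ca, oracleSites, numeric(2)))
  stB <- t(vapply(cb, oracleSites, numeric(2)))
  S <- (sum(stA[, "s"]) + sum(stB[, "s"])) / 2
  N <- (sum(stA[, "n"]) + sum(stB[, "n"])) / 2
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    d <- oracleDiffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

# discordant-pair count for order conservation
oracleInversions <- function(posA, posB) {
  n <- length(posA); inv <- 0L
  if (n < 2L) return(0L)
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    if ((posA[i] - posA[j]) * (posB[i] - posB[j]) < 0) inv <- inv + 1L
  inv
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracleFisher2x2 <- function(hA, nA, hB, nB) {
  k <- hA + hB
  support <- max(0L, k - nB):min(k, nA)
  probs <- stats::dhyper(support, nA, nB, k)
  pObs <- stats::dhyper(hA, nA, nB, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

randomSeq <- function(n, withN = FALSE) {
  pool <- if (withN) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (withN) c(.24, .24, .24, .24, .04) else rep(.25, 4)
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

randomIupac <- function(len) {
  paste(sample(names(ORACLE_IUPAC), len, replace = TRUE,
               prob = c(rep(.2, 4), rep(.02, 11))), collapse = "")
}
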