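# High-level pipeline stages tying the modules together. Each stage
# reads standard-format inputs, writes diff-friendly TSV/JSON outputs
# into an output directory, and records a run report (config echo,
# record counts, output manifest with md5 checksums).

.pkgVersion <- function() as.character(utils::packageVersion("dsxSplice"))

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.runReport <- function(stage, config, counts, files, outDir,
                       warnings = character()) {
  manifest <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  rep <- list(tool = "dsxSplice", version = .pkgVersion(), stage = stage,
              config = config, counts = counts, warnings = warnings,
              outputs = manifest)
  path <- file.path(outDir, paste0(stage, "_report.json"))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rep)
}

#' Junction pipeline: gene model to scored junction table
#'
#' Loads genome and gene model, extracts the junction windows, scores
#' acceptors and donors and classifies weak sites against the supplied
#' genome-wide consensus. Writes `junctions.tsv` (Table-style report),
#' `junctions_scored.tsv` and `junctions_report.json`.
#'
#' @param genomeFile FASTA.
#' @param gffFile GFF3 gene model.
#' @param classMapFile class-map JSON (or `NULL`).
#' @param outDir output directory (created).
#' @param consensusMean,consensusSd genome-wide acceptor consensus used
#'   for weak-site calls.
#' @inheritParams classifySites
#' @param consensus donor consensus (default `GTRAGT`).
#' @return the scored junction data.frame, invisibly.
#' @export
runJunctionPipeline <- function(genomeFile, gffFile, classMapFile = NULL,
                                outDir, consensusMean = 8.02,
                                consensusSd = 2.15, kSd = 1.0,
                                donorMinMatch = 4L, consensus = "GTRAGT") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  genome <- readGenome(genomeFile)
  model <- readGeneModel(gffFile, classMap = classMapFile, genome = genome)
  jx <- junctionContexts(model, genome)
  stats <- consensusStats(consensusMean, consensusSd)
  scored <- scoreJunctions(jx, stats, consensus = consensus, kSd = kSd,
                           donorMinMatch = donorMinMatch)
  f1 <- .writeTsv(scored, file.path(outDir, "junctions_scored.tsv"))
  f2 <- writeJunctionReport(jx, file.path(outDir, "junctions.tsv"))
  .runReport("junctions",
             list(genome = genomeFile, gff = gffFile, k_sd = kSd,
                  donor_min_match = donorMinMatch, consensus = consensus,
                  consensus_mean = consensusMean, consensus_sd = consensusSd),
             list(introns = nrow(jx),
                  weak_acceptors = sum(scored$acceptor_weak, na.rm = TRUE),
                  weak_donors = sum(scored$donor_weak, na.rm = TRUE)),
             c(f1, f2), outDir)
  invisible(scored)
}

#' Motif-scan pipeline
#'
#' Scans a sequence for a motif catalogue, writes hits as BED6 (name =
#' motif, score = mismatches, 0-based half-open) and TSV (with region
#' labels), and -- when two comparison regions are designated -- a
#' bipartite summary JSON.
#'
#' @param fastaFile sequence FASTA (first record scanned).
#' @param catalogueFile catalogue JSON; `NULL` uses the bundled default.
#' @param regionsFile optional BED file of labelled regions (name column
#'   = region label).
#' @param outDir output directory.
#' @param maxMismatch,strands see [scanMotifs()].
#' @param compare two region labels for the bipartite contrast, or
#'   `NULL`.
#' @param preMinLen,preMinFrac purine-run (candidate PRE) parameters.
#' @return the hit data.frame, invisibly.
#' @export
runMotifScan <- function(fastaFile, catalogueFile = NULL, regionsFile = NULL,
                         outDir, maxMismatch = 0L, strands = "forward",
                         compare = NULL, preMinLen = 10L, preMinFrac = 1.0) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  genome <- readGenome(fastaFile)
  cat <- if (is.null(catalogueFile)) defaultMotifCatalogue()
         else readMotifCatalogue(catalogueFile)
  regions <- NULL
  if (!is.null(regionsFile)) {
    bed <- rtracklayer::import(regionsFile, format = "BED")
    regions <- data.frame(region = bed$name, start = BiocGenerics::start(bed),
                          end = BiocGenerics::end(bed))
  }
  hits <- scanMotifs(genome[1L], cat, maxMismatch = maxMismatch,
                     strands = strands, regions = regions)
  runs <- detectPurineRuns(genome[[1L]], minLen = preMinLen,
                           minFrac = preMinFrac)
  fTsv <- .writeTsv(hits, file.path(outDir, "motif_hits.tsv"))
  fBed <- file.path(outDir, "motif_hits.bed")
  bed <- data.frame(chrom = hits$contig_id, start = hits$start - 1L,
                    end = hits$end, name = hits$motif_name,
                    score = hits$mismatches, strand = hits$strand)
  utils::write.table(bed, fBed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(fTsv, fBed)
  if (!is.null(compare) && !is.null(regions)) {
    bs <- summarizeRegions(hits, regions, cat, compare = compare, runs = runs)
    fJson <- file.path(outDir, "bipartite_summary.json")
    jsonlite::write_json(
      list(counts = as.data.frame.table(bs$counts, responseName = "hits"),
           tests = bs$tests, compare = compare),
      fJson, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, fJson)
  }
  .runReport("scan",
             list(fasta = fastaFile, max_mismatch = maxMismatch,
                  strands = strands),
             list(motifs = length(cat), hits = nrow(hits),
                  purine_runs = nrow(runs)),
             files, outDir)
  invisible(hits)
}

#' Repeat-density pipeline
#'
#' Derives introns from a gene model, computes per-intron NoRE/kb and
#' REbp from a repeat annotation, and compares sex-specific versus
#' non-sex-specific introns. Writes `intron_repeat_stats.tsv` and
#' `repeat_group_comparison.tsv`.
#'
#' @param gffFile GFF3 gene model.
#' @param classMapFile class-map JSON (drives the sex-specific flags).
#' @param repeatsFile repeat TSV (see [readRepeats()]).
#' @param outDir output directory.
#' @param sumCoverage see [intronRepeatStats()].
#' @return the per-intron stats data.frame, invisibly.
#' @export
runRepeatStats <- function(gffFile, classMapFile = NULL, repeatsFile, outDir,
                           sumCoverage = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  model <- readGeneModel(gffFile, classMap = classMapFile)
  inr <- introns(model)
  reps <- readRepeats(repeatsFile)
  stats <- formatRepeatStats(intronRepeatStats(inr, reps,
                                               sumCoverage = sumCoverage))
  f1 <- .writeTsv(stats, file.path(outDir, "intron_repeat_stats.tsv"))
  files <- f1
  counts <- list(introns = nrow(stats), repeats = length(reps))
  flags <- mcols(inr)$sex_specific
  if (any(flags) && !all(flags)) {
    cmp <- compareRepeatGroups(stats, flags)
    f2 <- .writeTsv(cmp$group_means,
                    file.path(outDir, "repeat_group_comparison.tsv"))
    f3 <- .writeTsv(cmp$per_intron,
                    file.path(outDir, "repeat_per_intron_deviation.tsv"))
    files <- c(files, f2, f3)
  }
  .runReport("repeats", list(gff = gffFile, repeats = repeatsFile,
                             sum_coverage = sumCoverage),
             counts, files, outDir)
  invisible(stats)
}

#' Synteny pipeline
#'
#' @param setAFile,setBFile region gene TSVs (`gene_id`, `start`, `end`,
#'   `strand`).
#' @param pairsFile two-column homology TSV.
#' @param outDir output directory.
#' @inheritParams syntenyQuality
#' @return the `syntenyResult`, invisibly.
#' @export
runSynteny <- function(setAFile, setBFile, pairsFile, outDir,
                       convention = "pairs_over_printed_total",
                       nTotal = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  a <- utils::read.delim(setAFile, stringsAsFactors = FALSE)
  b <- utils::read.delim(setBFile, stringsAsFactors = FALSE)
  p <- utils::read.delim(pairsFile, stringsAsFactors = FALSE)
  q <- syntenyQuality(a, b, p, convention = convention, nTotal = nTotal)
  oc <- orderConservation(a, b, p)
  fJson <- file.path(outDir, "synteny.json")
  jsonlite::write_json(
    list(n_conserved = q$n_conserved, n_total = q$n_total,
         quality_percent = q$quality_percent,
         reported_percent = q$reported_percent, convention = q$convention,
         n_inversions = oc$n_inversions,
         strand_flips = sum(oc$pairs$strand_flip)),
    fJson, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .runReport("synteny", list(setA = setAFile, setB = setBFile,
                             pairs = pairsFile, convention = convention),
             list(genes_A = nrow(a), genes_B = nrow(b), pairs = nrow(p)),
             fJson, outDir)
  invisible(q)
}

#' dN/dS pipeline
#'
#' @param alignmentFile aligned FASTA (codon alignment).
#' @param partitionsFile partition JSON (see [readPartitions()]), or
#'   `NULL` for a single whole-alignment partition.
#' @param outDir output directory.
#' @inheritParams partitionSummary
#' @return the partition summary list, invisibly.
#' @export
runDnds <- function(alignmentFile, partitionsFile = NULL, outDir,
                    strict = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  aln <- readCodonAlignment(alignmentFile)
  parts <- if (is.null(partitionsFile)) NULL else readPartitions(partitionsFile)
  res <- partitionSummary(aln, parts, strict = strict)
  f1 <- .writeTsv(res$pairs, file.path(outDir, "pairwise_rates.tsv"))
  f2 <- .writeTsv(res$summary, file.path(outDir, "partition_summary.tsv"))
  .runReport("dnds", list(alignment = alignmentFile,
                          partitions = partitionsFile, strict = strict),
             list(sequences = length(aln@seqs), pairs = nrow(res$pairs)),
             c(f1, f2), outDir)
  invisible(res)
}

#' Simulation pipeline
#'
#' Generates a synthetic locus from a JSON config (the fields of
#' [simulateLocus()], with `exons` as an array of objects) and writes
#' the fixture files plus the ground truth. Re-running with the same
#' config reproduces the manifest checksums.
#'
#' @param configFile JSON config.
#' @param outDir output directory.
#' @param seed overrides the config seed when given.
#' @return the locus list, invisibly.
#' @export
runSimulateLocus <- function(configFile, outDir, seed = NULL) {
  cfg <- jsonlite::fromJSON(configFile)
  if (!is.null(seed)) cfg$seed <- seed
  locus <- simulateLocus(cfg)
  files <- writeLocus(locus, outDir)
  .runReport("simulate", list(config = configFile, seed = cfg$seed),
             list(exons = length(exons(locus$model)),
                  introns = length(exons(locus$model)) - 1L),
             files, outDir)
  invisible(locus)
}
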