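#' Pipeline configuration
#'
#' Bundles every stage parameter and threshold of the processing chain.
#' Exactly one input source must be given: a [simConfig()] (`sim`) for a
#' synthetic run, or a `fastq` path plus `knownIndices` for existing reads.
#' With no germline paths the bundled [syntheticGermline()] reference is
#' used.
#'
#' @param sim a [simConfig()] object, or `NULL`.
#' @param fastq path to a FASTQ file, or `NULL`.
#' @param knownIndices character vector of valid 5-base sample indices
#'   (required with `fastq`; defaults to the simulated index otherwise).
#' @param germlineFasta,germlineAnchors optional paths to a user germline
#'   reference ([readGermlineReference()] format).
#' @param sampleId sample identifier for the clonotype tables.
#' @param minReadLen minimum spacer + payload length (bases).
#' @param errorFreeCut minimum error-free tag fraction per bin.
#' @param readCap maximum reads used per consensus.
#' @param majority strict per-column consensus majority.
#' @param minScoreV,minScoreJ minimum V/J local alignment scores.
#' @param anchorConvention `"inclusive"` or `"exclusive"` CDR3 anchors.
#' @param rareCutoff ACE rare-group cutoff.
#' @param subsampleSize fixed-size subsample for abundance-class reporting
#'   (used when the sample holds at least this many molecules).
#' @param outDir optional output directory for tables, reports and the
#'   run manifest.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(sim = NULL, fastq = NULL, knownIndices = NULL,
                           germlineFasta = NULL, germlineAnchors = NULL,
                           sampleId = "sample1", minReadLen = 150L,
                           errorFreeCut = 0.90, readCap = 50L,
                           majority = 0.80, minScoreV = 20, minScoreJ = 15,
                           anchorConvention = "inclusive", rareCutoff = 10L,
                           subsampleSize = 100000L, outDir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `PipelineConfig` (or plain list with the same fields).
#' @return invisibly `TRUE`; otherwise an error naming the offending field.
#' @export
validatePipelineConfig <- function(cfg) {
  fail <- function(field, why) stop("config field '", field, "': ", why,
                                    call. = FALSE)
  if (is.null(cfg$sim) && is.null(cfg$fastq))
    fail("sim/fastq", "one input source is required")
  if (!is.null(cfg$sim) && !is.null(cfg$fastq))
    fail("sim/fastq", "give either a simulation config or a FASTQ, not both")
  if (!is.null(cfg$sim) && !inherits(cfg$sim, "SimConfig"))
    fail("sim", "must be a simConfig() object")
  if (!is.null(cfg$fastq)) {
    if (!file.exists(cfg$fastq)) fail("fastq", "file not found")
    if (is.null(cfg$knownIndices)) fail("knownIndices",
                                        "required with a FASTQ input")
  }
  if (xor(is.null(cfg$germlineFasta), is.null(cfg$germlineAnchors)))
    fail("germlineAnchors", "germline FASTA and anchor table go together")
  for (f in c("minReadLen", "readCap", "rareCutoff", "subsampleSize"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) fail(f, "must be >= 1")
  for (f in c("errorFreeCut", "majority"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] >= 1)
      fail(f, "must be in (0, 1)")
  if (!cfg$anchorConvention %in% c("inclusive", "exclusive"))
    fail("anchorConvention", "must be 'inclusive' or 'exclusive'")
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> parse/filter -> tag grouping and
#' error-tag removal -> consensus -> V/J + CDR3 annotation -> clonotype
#' aggregation -> repertoire statistics, and assembles a run manifest with
#' every threshold applied and per-stage record counts (outputs plus
#' discards equal inputs at every stage). Identical configuration and seed
#' give identical outputs.
#'
#' @param cfg a [pipelineConfig()].
#' @return list with `truth` (simulated runs only), `profile`
#'   ([TagLengthReport-class]), `consensus`, `annotation`, `clonotypes`
#'   (list `nt`/`aa`/`discarded`), `stats` (ACE at nt and aa level,
#'   rarefaction curve, abundance classes, V/J usage) and `manifest`.
#' @export
runPipeline <- function(cfg) {
  validatePipelineConfig(cfg)
  ref <- if (is.null(cfg$germlineFasta)) syntheticGermline()
         else readGermlineReference(cfg$germlineFasta, cfg$germlineAnchors)
  if (!is.null(cfg$sim)) {
    repertoire <- simulateRepertoire(cfg$sim, ref)
    run <- generateRun(repertoire, cfg$sim)
    reads <- run$reads; readIds <- run$readIds; truth <- run$truth
    knownIndices <- cfg$sim$sampleIndex
    seed <- cfg$sim$seed
  } else {
    fq <- readFastqReads(cfg$fastq)
    reads <- fq$reads; readIds <- fq$readIds; truth <- NULL
    knownIndices <- cfg$knownIndices
    seed <- NA_integer_
  }
  parsed <- parseReads(reads, knownIndices, readIds)
  kept <- lengthFilter(parsed, cfg$minReadLen)
  groups <- tagGroups(parsed, minLen = cfg$minReadLen)
  groups <- mergeLengthVariants(groups)
  profile <- tagErrorProfile(groups, cfg$errorFreeCut)
  retained <- applyThreshold(groups, readThreshold(profile))
  cons <- buildConsensus(retained, cfg$readCap, cfg$majority)
  ann <- annotateConsensus(cons, ref, minScoreV = cfg$minScoreV,
                           minScoreJ = cfg$minScoreJ,
                           convention = cfg$anchorConvention)
  clono <- aggregateClonotypes(ann, cfg$sampleId)

  stats <- .repertoireStats(clono, cfg, seed)
  manifest <- list(
    tool = paste0("noirss ", as.character(utils::packageVersion("noirss"))),
    sample_id = cfg$sampleId, seed = seed,
    thresholds = list(min_read_len = cfg$minReadLen,
                      error_free_cut = cfg$errorFreeCut,
                      r_star = readThreshold(profile),
                      read_cap = cfg$readCap, majority = cfg$majority,
                      min_score_v = cfg$minScoreV,
                      min_score_j = cfg$minScoreJ,
                      anchor_convention = cfg$anchorConvention,
                      rare_cutoff = cfg$rareCutoff,
                      subsample_size = cfg$subsampleSize),
    counts = list(
      reads_total = length(reads),
      rejected_unknown_index = sum(parsed$status == "unknown_index"),
      rejected_no_spacer = sum(parsed$status == "no_spacer"),
      dropped_short = sum(parsed$status == "ok" & !kept),
      reads_grouped = sum(kept),
      tags_total = length(groups),
      tags_12bp = sum(groups@lengthClass == "12"),
      tags_derivative = sum(!is.na(groups@derivativeOf)),
      molecules_retained = length(retained),
      consensus_built = nrow(cons),
      annotated_ok = sum(ann$status == "ok"),
      discarded_annotation = sum(ann$status != "ok"),
      nt_clonotypes = nrow(clono$nt),
      aa_clonotypes = nrow(clono$aa)))
  out <- list(truth = truth, profile = profile, consensus = cons,
              annotation = ann, clonotypes = clono, stats = stats,
              manifest = manifest)
  if (!is.null(cfg$outDir)) .writePipelineOutputs(out, cfg)
  out
}

.repertoireStats <- function(clono, cfg, seed) {
  k <- cfg$rareCutoff
  one <- function(tab) {
    if (!nrow(tab)) return(NULL)
    cnt <- tab$n_molecules
    ace <- aceRichness(cnt, k)
    N <- sum(cnt)
    sub <- if (N >= cfg$subsampleSize) {
      s <- subsampleCounts(cnt, cfg$subsampleSize,
                           seed = if (is.na(seed)) NULL else seed + 2L)
      s[s > 0L]
    } else cnt
    list(ace = ace,
         rarefaction = rarefactionCurve(cnt, rarefactionGrid(N)),
         classes = attr(frequencyClasses(sub), "summary"))
  }
  list(nt = one(clono$nt), aa = one(clono$aa),
       usage = if (nrow(clono$nt)) vjUsage(clono$nt) else NULL)
}

.writePipelineOutputs <- function(out, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(cfg$outDir, ...)
  wt <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(out$clonotypes$nt, "clonotypes_nt.tsv")
  wt(out$clonotypes$aa, "clonotypes_aa.tsv")
  wt(out$clonotypes$discarded, "discard_reasons.tsv")
  wt(out$profile@table, "tag_length_report.tsv")
  writeConsensus(out$consensus, p("consensus.fasta"))
  if (!is.null(out$stats$nt)) {
    wt(out$stats$nt$rarefaction, "rarefaction_nt.tsv")
    wt(out$stats$nt$classes, "classes_nt.tsv")
    wt(out$stats$aa$classes, "classes_aa.tsv")
    wt(out$stats$usage$v, "usage_v.tsv")
    wt(out$stats$usage$j, "usage_j.tsv")
    rep <- list(
      nt = out$stats$nt$ace[c("s_ace", "s_obs", "c_ace", "gamma2", "method")],
      aa = out$stats$aa$ace[c("s_ace", "s_obs", "c_ace", "gamma2", "method")])
    jsonlite::write_json(rep, p("richness.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
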