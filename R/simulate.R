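#' Simulation configuration
#'
#' Collects the parameters of the synthetic sequencing run generator. The
#' defaults define the reference study conditions used throughout the test
#' suite: an indel-dominant, Ion-Torrent-like error profile
#' (`insRate = delRate = 0.004`, `subRate = 0.001` per base), a mean of 10
#' reads per molecule with mild overdispersion (counts are
#' `1 + NB(mu = meanReads - 1, size = readDispersion)`, so the minimum is
#' 1 read), 250-base reads, and independent uniform random 12-mer barcodes.
#'
#' @param nClones number of distinct clones in the repertoire.
#' @param abundance clone abundance model, `"uniform"` or `"power_law"`.
#' @param alpha power-law exponent (clone ranked `i` has frequency
#'   proportional to `i^-alpha`).
#' @param nMolecules number of cDNA molecules sampled from the repertoire.
#' @param meanReads mean sequencing reads per molecule (PCR duplication).
#' @param readDispersion negative-binomial size parameter of the
#'   reads-per-molecule distribution (larger = closer to Poisson).
#' @param subRate,insRate,delRate per-base substitution / insertion /
#'   deletion probabilities, in `[0, 1)`.
#' @param readLength total read length in bases before error injection
#'   (index + barcode + spacer + payload); payloads are truncated to fit.
#' @param sampleIndex 5-base sample index sequence.
#' @param distinctBarcodes if `TRUE`, barcode 12-mers are redrawn until all
#'   molecules carry distinct barcodes (used for exact round-trip checks);
#'   if `FALSE` (default) barcodes are independent uniform 12-mers and
#'   collisions can occur at the birthday-bound rate.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(nClones = 1000L, abundance = c("uniform", "power_law"),
                      alpha = 1.5, nMolecules = 10000L, meanReads = 10,
                      readDispersion = 20, subRate = 0.001, insRate = 0.004,
                      delRate = 0.004, readLength = 250L,
                      sampleIndex = "ACGTC", distinctBarcodes = FALSE,
                      seed = 1L) {
  abundance <- match.arg(abundance)
  cfg <- list(nClones = as.integer(nClones), abundance = abundance,
              alpha = alpha, nMolecules = as.integer(nMolecules),
              meanReads = meanReads, readDispersion = readDispersion,
              subRate = subRate, insRate = insRate, delRate = delRate,
              readLength = as.integer(readLength),
              sampleIndex = toupper(sampleIndex),
              distinctBarcodes = isTRUE(distinctBarcodes),
              seed = as.integer(seed))
  for (r in c("subRate", "insRate", "delRate"))
    if (cfg[[r]] < 0 || cfg[[r]] >= 1) stop(r, " must be in [0, 1)")
  if (cfg$nClones < 1L) stop("nClones must be >= 1")
  if (cfg$meanReads < 1) stop("meanReads must be >= 1")
  if (nchar(cfg$sampleIndex) != 5L || grepl("[^ACGT]", cfg$sampleIndex))
    stop("sampleIndex must be a 5-base DNA sequence")
  if (cfg$readLength < 40L) stop("readLength too short for the read layout")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate one V(D)J recombination junction
#'
#' Emulates junctional diversification between a V and a J segment: 0-6 nt
#' are trimmed from the V 3' end (never into the cysteine anchor codon), 0-6
#' nt from the J 5' end (never into the phenylalanine anchor), and 0-15
#' random non-templated nt are inserted, with the insertion length padded so
#' that the CDR3 (cysteine codon through phenylalanine codon, inclusive) is
#' divisible by 3. Draws from the current RNG stream.
#'
#' @param ref a [GermlineReference-class].
#' @param vName,jName segment names.
#' @param vTrimRange,jTrimRange,insRange integer vectors the trim and
#'   insertion lengths are drawn from (uniformly).
#' @return list with `cdr3_nt`, `junction_nt` (the inserted bases),
#'   `v_trim`, `j_trim`, and `sense_nt` (trimmed V + insert + trimmed J,
#'   i.e. the recombined sequence up to the J 3' end).
#' @export
recombine <- function(ref, vName, jName, vTrimRange = 0:6, jTrimRange = 0:6,
                      insRange = 0:15) {
  vi <- match(vName, segmentNames(ref)); ji <- match(jName, segmentNames(ref))
  if (is.na(vi) || is.na(ji)) stop("unknown segment name")
  if (ref@kind[vi] != "V" || ref@kind[ji] != "J")
    stop("vName/jName must name a V and a J segment")
  v <- as.character(ref@segments[[vi]]); j <- as.character(ref@segments[[ji]])
  va <- ref@anchor[vi]; ja <- ref@anchor[ji]
  if (max(vTrimRange) > nchar(v) - va - 3L)
    stop("vTrimRange would trim into the cysteine anchor of ", vName)
  if (max(jTrimRange) > ja)
    stop("jTrimRange would trim into the phenylalanine anchor of ", jName)
  tv <- if (length(vTrimRange) == 1L) vTrimRange else sample(vTrimRange, 1L)
  tj <- if (length(jTrimRange) == 1L) jTrimRange else sample(jTrimRange, 1L)
  ni <- if (length(insRange) == 1L) insRange else sample(insRange, 1L)
  b <- .recombineBatch(v, va, j, ja, tv, tj, ni)
  list(cdr3_nt = b$cdr3_nt, junction_nt = b$junction_nt, v_trim = tv,
       j_trim = tj, sense_nt = b$sense_nt)
}

# vectorised core of the recombination rules; all arguments are parallel
# vectors over candidates (segment sequences already expanded)
.recombineBatch <- function(v, va, j, ja, tv, tj, ni) {
  vPart <- substr(v, va + 1L, nchar(v) - tv)          # Cys codon .. trimmed 3'
  jHead <- substr(j, tj + 1L, ja + 3L)                # trimmed 5' .. Phe codon
  ni <- ni + (3L - (nchar(vPart) + ni + nchar(jHead)) %% 3L) %% 3L
  ins <- rep("", length(ni))
  tot <- sum(ni)
  if (tot > 0L) {
    bases <- sample(DNA_BASES4, tot, replace = TRUE)
    grp <- factor(rep.int(seq_along(ni), ni), levels = seq_along(ni))
    ins <- unname(vapply(split(bases, grp), paste, character(1),
                         collapse = ""))
  }
  list(cdr3_nt = unname(paste0(vPart, ins, jHead)), junction_nt = ins,
       sense_nt = unname(paste0(substr(v, 1L, nchar(v) - tv), ins,
                                substr(j, tj + 1L, nchar(j)))))
}

#' Simulate a clonal TCRB repertoire
#'
#' Generates `nClones` clones with distinct, productive (in-frame,
#' stop-free) CDR3 nucleotide sequences by repeated V-J recombination, and
#' assigns clone frequencies under the configured abundance model
#' (`uniform`: all `1/nClones`; `power_law`: frequency of rank `i`
#' proportional to `i^-alpha`). Deterministic given `cfg$seed`.
#'
#' @param cfg a [simConfig()] object.
#' @param ref a [GermlineReference-class].
#' @return data.frame with one row per clone: `clone_id`, `v_name`,
#'   `j_name`, `v_trim`, `j_trim`, `junction_nt`, `cdr3_nt`, `cdr3_aa`,
#'   `frequency`, `sense_nt` (the full mRNA-sense sequence V..CDR3..J..C
#'   covered by the assay).
#' @export
simulateRepertoire <- function(cfg, ref) {
  stopifnot(inherits(cfg, "SimConfig"), is(ref, "GermlineReference"))
  set.seed(cfg$seed)
  vNames <- segmentNames(ref)[ref@kind == "V"]
  jNames <- segmentNames(ref)[ref@kind == "J"]
  cSeq <- as.character(segmentSeqs(ref, "C")[[1L]])
  # the assay covers the sense sequence up to the end of the C-region primer
  # site (reverse transcription starts there)
  site <- regexpr(revComp(C_PRIMER_SEQ), cSeq, fixed = TRUE)
  if (site < 0L)
    stop("C segment does not contain the reverse complement of the C-region primer")
  cAssayed <- substr(cSeq, 1L, site + nchar(C_PRIMER_SEQ) - 1L)
  n <- cfg$nClones
  vSeqs <- as.character(segmentSeqs(ref, "V")); names(vSeqs) <- vNames
  jSeqs <- as.character(segmentSeqs(ref, "J")); names(jSeqs) <- jNames
  vAnch <- anchorPos(ref)[vNames]; jAnch <- anchorPos(ref)[jNames]
  out <- NULL
  tries <- 0L; budget <- 50L * n
  # candidates are generated in batches; unproductive (in-frame stop) and
  # duplicate junctions are rejected and redrawn
  while (is.null(out) || nrow(out) < n) {
    made <- if (is.null(out)) 0L else nrow(out)
    b <- min(max(2L * (n - made), 200L), 100000L)
    tries <- tries + b
    if (tries > budget + b)
      stop("could not generate ", n, " distinct productive junctions in ",
           budget, " attempts")
    vi <- sample(length(vNames), b, replace = TRUE)
    ji <- sample(length(jNames), b, replace = TRUE)
    tv <- sample(0:6, b, replace = TRUE)
    tj <- sample(0:6, b, replace = TRUE)
    ni <- sample(0:15, b, replace = TRUE)
    rec <- .recombineBatch(vSeqs[vi], vAnch[vi], jSeqs[ji], jAnch[ji],
                           tv, tj, ni)
    aa <- translateDNA(rec$cdr3_nt)
    cand <- data.frame(clone_id = NA_integer_, v_name = vNames[vi],
                       j_name = jNames[ji], v_trim = tv, j_trim = tj,
                       junction_nt = rec$junction_nt, cdr3_nt = rec$cdr3_nt,
                       cdr3_aa = aa,
                       sense_nt = paste0(rec$sense_nt, cAssayed),
                       stringsAsFactors = FALSE)
    cand <- cand[!grepl("*", aa, fixed = TRUE), , drop = FALSE]
    out <- rbind(out, cand)
    out <- out[!duplicated(out$cdr3_nt), , drop = FALSE]
  }
  rep <- out[seq_len(n), , drop = FALSE]
  rownames(rep) <- NULL
  rep$clone_id <- seq_len(n)
  rep$frequency <- switch(cfg$abundance,
    uniform = rep(1 / n, n),
    power_law = { w <- seq_len(n)^(-cfg$alpha); w / sum(w) })
  rep
}

#' Generate a synthetic sequencing run
#'
#' Samples `nMolecules` molecule clone identities from the clone
#' frequencies, labels each molecule with a random 12-mer barcode, draws a
#' read count per molecule, lays each read out 5'->3' as
#' `sample index (5) + barcode (12) + spacer + C-region primer +
#' reverse complement of the molecule's sense sequence` (the cDNA
#' orientation produced by reverse transcription from the C region),
#' truncated at `cfg$readLength`, and injects per-base substitution /
#' insertion / deletion errors everywhere, including inside the barcode.
#' Deterministic given `cfg$seed`.
#'
#' @param repertoire output of [simulateRepertoire()].
#' @param cfg the [simConfig()] used (or a compatible one).
#' @return list of class `SimulatedRun`: `reads` (character), `readIds`,
#'   `truth` (data.frame `molecule_id`, `clone_id`, `barcode`, `v_name`,
#'   `j_name`, `cdr3_nt`, `n_reads`), and `cfg`.
#' @export
generateRun <- function(repertoire, cfg) {
  stopifnot(inherits(cfg, "SimConfig"), is.data.frame(repertoire))
  set.seed(cfg$seed + 1L)
  nm <- cfg$nMolecules
  truthCols <- c("molecule_id", "clone_id", "barcode", "v_name", "j_name",
                 "cdr3_nt", "n_reads")
  if (nm == 0L) {
    warning("nMolecules is 0; returning an empty run")
    truth <- as.data.frame(setNames(rep(list(character(0)), 7), truthCols))
    return(structure(list(reads = character(0), readIds = character(0),
                          truth = truth, cfg = cfg), class = "SimulatedRun"))
  }
  # payload template per clone: C primer + antisense of J/CDR3/V, truncated
  template <- substr(revComp(repertoire$sense_nt), 1L, cfg$readLength - 32L)
  cloneIdx <- sample.int(nrow(repertoire), nm, replace = TRUE,
                         prob = repertoire$frequency)
  barcode <- randomDNA(nm, 12L)
  if (cfg$distinctBarcodes) {
    while (anyDuplicated(barcode)) {
      dup <- which(duplicated(barcode))
      barcode[dup] <- randomDNA(length(dup), 12L)
    }
  }
  nReads <- 1L + rnbinom(nm, size = cfg$readDispersion, mu = cfg$meanReads - 1)
  clean <- paste0(cfg$sampleIndex, barcode, SPACER_SEQ, template[cloneIdx])
  reads <- rep(clean, nReads)
  molOfRead <- rep(seq_len(nm), nReads)
  if (cfg$subRate > 0 || cfg$insRate > 0 || cfg$delRate > 0)
    reads <- .C_inject_errors(reads, cfg$subRate, cfg$insRate, cfg$delRate)
  readIds <- paste0("M", molOfRead, "_R",
                    sequence(nReads))
  truth <- data.frame(molecule_id = seq_len(nm), clone_id = cloneIdx,
                      barcode = barcode,
                      v_name = repertoire$v_name[cloneIdx],
                      j_name = repertoire$j_name[cloneIdx],
                      cdr3_nt = repertoire$cdr3_nt[cloneIdx],
                      n_reads = nReads, stringsAsFactors = FALSE)
  structure(list(reads = reads, readIds = readIds, truth = truth, cfg = cfg),
            class = "SimulatedRun")
}

#' Write a simulated run to FASTQ and a truth table
#'
#' @param run a `SimulatedRun` from [generateRun()].
#' @param fastq output FASTQ path (4-line records, constant Phred+33
#'   quality).
#' @param truth output path for the tab-separated truth table.
#' @return invisibly, the paths.
#' @export
writeRun <- function(run, fastq, truth) {
  stopifnot(inherits(run, "SimulatedRun"))
  qual <- strrep("I", nchar(run$reads))
  rec <- rbind(paste0("@", run$readIds), run$reads, "+", qual)
  writeLines(as.vector(rec), fastq)
  write.table(run$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastq, truth))
}
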