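#' Orient consensus sequences onto the mRNA sense strand
#'
#' Library reads are sequenced in the cDNA (antisense) orientation, so the
#' default simply reverse-complements. With `orientation = "auto"` the
#' strand is chosen per sequence by the better local J-segment seed score;
#' sequences with no seed on either strand are passed through unchanged and
#' flagged in the `"unoriented"` attribute of the result.
#'
#' @param x character vector of consensus sequences.
#' @param orientation `"antisense"` (default: reverse-complement),
#'   `"sense"` (leave unchanged) or `"auto"`.
#' @param ref a [GermlineReference-class]; required for `"auto"`.
#' @param minSeed minimum local alignment score for a usable seed.
#' @return character vector of sense-strand sequences; in `"auto"` mode the
#'   logical attribute `"unoriented"` marks sequences with no usable seed.
#' @export
orientSequence <- function(x, orientation = c("antisense", "sense", "auto"),
                           ref = NULL, minSeed = 15) {
  orientation <- match.arg(orientation)
  if (orientation == "antisense") return(revComp(x))
  if (orientation == "sense") return(x)
  if (is.null(ref)) stop("orientation = 'auto' requires a reference")
  segs <- segmentSeqs(ref, "J")
  fwd <- .maxLocalScore(x, segs)
  rev <- .maxLocalScore(revComp(x), segs)
  out <- ifelse(rev > fwd, revComp(x), x)
  unoriented <- pmax(fwd, rev) < minSeed
  out[unoriented] <- x[unoriented]
  attr(out, "unoriented") <- unoriented
  out
}

.nucMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.maxLocalScore <- function(x, segs) {
  vapply(x, function(s) {
    max(Biostrings::pairwiseAlignment(
      pattern = segs, subject = Biostrings::DNAString(s), type = "local",
      substitutionMatrix = .nucMat(), gapOpening = 1, gapExtension = 1,
      scoreOnly = TRUE))
  }, numeric(1), USE.NAMES = FALSE)
}

# batched local alignment of many sense sequences against a segment set:
# one scoreOnly pass per segment, then one full alignment call per chosen
# segment. Sequences with tied best scores are flagged for the per-sequence
# path (which applies the identity/name tie-break).
.fastHits <- function(senses, segs, minScore) {
  n <- length(senses)
  pat <- Biostrings::DNAStringSet(senses)
  sc <- vapply(seq_along(segs), function(k)
    Biostrings::pairwiseAlignment(
      pattern = pat, subject = segs[[k]], type = "local",
      substitutionMatrix = .nucMat(), gapOpening = 1, gapExtension = 1,
      scoreOnly = TRUE), numeric(n))
  if (n == 1L) sc <- matrix(sc, nrow = 1L)
  best <- max.col(sc, ties.method = "first")
  bestScore <- sc[cbind(seq_len(n), best)]
  nTied <- rowSums(sc == bestScore)
  hits <- vector("list", n)
  ok <- bestScore >= minScore & nTied == 1L
  for (k in unique(best[ok])) {
    idx <- which(ok & best == k)
    aln <- Biostrings::pairwiseAlignment(
      pattern = pat[idx], subject = segs[[k]], type = "local",
      substitutionMatrix = .nucMat(), gapOpening = 1, gapExtension = 1)
    qs <- BiocGenerics::start(Biostrings::pattern(aln))
    qe <- BiocGenerics::end(Biostrings::pattern(aln))
    ts <- BiocGenerics::start(Biostrings::subject(aln))
    te <- BiocGenerics::end(Biostrings::subject(aln))
    aq <- as.character(Biostrings::alignedPattern(aln))
    at <- as.character(Biostrings::alignedSubject(aln))
    idt <- Biostrings::pid(aln) / 100
    scs <- BiocGenerics::score(aln)
    for (m in seq_along(idx))
      hits[[idx[m]]] <- list(
        segment_name = names(segs)[k], score = scs[m], identity = idt[m],
        query_start = qs[m] - 1L, query_end = qe[m],
        target_start = ts[m] - 1L, target_end = te[m],
        aligned_target = at[m], aligned_query = aq[m])
  }
  list(hits = hits, needSlow = bestScore >= minScore & nTied > 1L,
       none = bestScore < minScore)
}

# best local hit of a set of segments against one sense sequence.
# ties: higher identity, then lexicographically smallest segment name.
# minQueryStart0: only accept hits starting at/after this sense position.
.bestHit <- function(sense, segs, minScore, minQueryStart0 = NULL) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = segs, subject = Biostrings::DNAString(sense), type = "local",
    substitutionMatrix = .nucMat(), gapOpening = 1, gapExtension = 1)
  sc <- BiocGenerics::score(aln)
  idt <- Biostrings::pid(aln) / 100
  ok <- sc >= minScore
  if (!is.null(minQueryStart0))
    ok <- ok & (BiocGenerics::start(Biostrings::subject(aln)) - 1L >=
                  minQueryStart0)
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  cand <- cand[order(-sc[cand], -idt[cand], names(segs)[cand])]
  b <- cand[1L]
  a1 <- aln[b]
  list(segment_name = names(segs)[b], score = sc[b], identity = idt[b],
       query_start = BiocGenerics::start(Biostrings::subject(a1)) - 1L,
       query_end = BiocGenerics::end(Biostrings::subject(a1)),
       target_start = BiocGenerics::start(Biostrings::pattern(a1)) - 1L,
       target_end = BiocGenerics::end(Biostrings::pattern(a1)),
       aligned_target = as.character(Biostrings::alignedPattern(a1)),
       aligned_query = as.character(Biostrings::alignedSubject(a1)))
}

#' Find the best V and J germline hits in a sense-strand sequence
#'
#' Local alignment (match +1, mismatch -1, first gap base -2, each further
#' gap base -1) of every V and J segment against the sequence; the
#' best-scoring hit per kind is returned, ties resolved by higher identity
#' and then by lexicographically smallest segment name. The J hit must lie
#' 3' of the V hit; the two hits may overlap by a few bases where the
#' germline V continuation happens to match junction bases, so only the J
#' start is constrained here and the final junction geometry is enforced by
#' the anchor-order check in [extractCDR3()].
#'
#' @param sense a single sense-strand sequence.
#' @param ref a [GermlineReference-class].
#' @param minScoreV,minScoreJ minimum local alignment scores (J segments
#'   are short, hence the lower default).
#' @return list with elements `v` and `j` (each a hit list with
#'   `segment_name`, `score`, `identity`, 0-based half-open `query_*` and
#'   `target_*` coordinates and the aligned strings) and `status` (`"ok"`,
#'   `"no_v_hit"` or `"no_j_hit"`).
#' @export
alignSegments <- function(sense, ref, minScoreV = 20, minScoreJ = 15) {
  stopifnot(is(ref, "GermlineReference"))
  v <- .bestHit(sense, segmentSeqs(ref, "V"), minScoreV)
  if (is.null(v)) return(list(v = NULL, j = NULL, status = "no_v_hit"))
  j <- .bestHit(sense, segmentSeqs(ref, "J"), minScoreJ,
                minQueryStart0 = v$query_start + 1L)
  if (is.null(j)) return(list(v = v, j = NULL, status = "no_j_hit"))
  list(v = v, j = j, status = "ok")
}

# map a 0-based target (segment) position to its 0-based query (sense)
# position through an alignment given as two gapped strings; NA if the
# position aligns to a gap.
.mapThroughAlignment <- function(alignedTarget, alignedQuery, targetStart0,
                                 queryStart0, pos0) {
  tch <- strsplit(alignedTarget, "", fixed = TRUE)[[1L]]
  qch <- strsplit(alignedQuery, "", fixed = TRUE)[[1L]]
  tpos <- targetStart0; qpos <- queryStart0
  for (k in seq_along(tch)) {
    if (tch[k] != "-") {
      if (tpos == pos0) return(if (qch[k] != "-") qpos else NA_integer_)
      tpos <- tpos + 1L
    }
    if (qch[k] != "-") qpos <- qpos + 1L
  }
  NA_integer_
}

#' Extract the CDR3 junction between the conserved anchors
#'
#' Maps the V segment's cysteine codon and the J segment's phenylalanine
#' codon onto the sense sequence through the local alignments and returns
#' the junction sequence. With the default inclusive convention the CDR3
#' runs from the first base of the cysteine codon through the last base of
#' the phenylalanine codon; `"exclusive"` drops both anchor codons.
#'
#' @param sense the sense-strand sequence.
#' @param hits result of [alignSegments()] with `status == "ok"`.
#' @param ref a [GermlineReference-class].
#' @param convention `"inclusive"` (default) or `"exclusive"`.
#' @return list with `status` (`"ok"` or `"anchor_outside_alignment"`) and
#'   `cdr3_nt`.
#' @export
extractCDR3 <- function(sense, hits, ref,
                        convention = c("inclusive", "exclusive")) {
  convention <- match.arg(convention)
  v <- hits$v; j <- hits$j
  anchors <- anchorPos(ref)
  va <- anchors[[v$segment_name]]; ja <- anchors[[j$segment_name]]
  fail <- list(status = "anchor_outside_alignment", cdr3_nt = NA_character_)
  if (va < v$target_start || va + 3L > v$target_end) return(fail)
  if (ja < j$target_start || ja + 3L > j$target_end) return(fail)
  mapV <- function(p) .mapThroughAlignment(v$aligned_target, v$aligned_query,
                                           v$target_start, v$query_start, p)
  mapJ <- function(p) .mapThroughAlignment(j$aligned_target, j$aligned_query,
                                           j$target_start, j$query_start, p)
  if (convention == "inclusive") {
    s0 <- mapV(va); e0 <- mapJ(ja + 2L)
  } else {
    s2 <- mapV(va + 2L); e2 <- mapJ(ja)
    s0 <- if (is.na(s2)) NA_integer_ else s2 + 1L
    e0 <- if (is.na(e2)) NA_integer_ else e2 - 1L
  }
  if (is.na(s0) || is.na(e0) || s0 > e0) return(fail)
  list(status = "ok", cdr3_nt = substr(sense, s0 + 1L, e0 + 1L))
}

#' Translate a CDR3 and filter unproductive sequences
#'
#' Rejects junctions whose length is not divisible by 3 (`"frame_shift"`),
#' that contain an ambiguous base (`"ambiguous_base"`), or whose
#' translation contains a termination codon (`"stop_codon"`).
#'
#' @param cdr3_nt CDR3 nucleotide sequence.
#' @return list with `status` (`"ok"` or the rejection reason) and
#'   `cdr3_aa`.
#' @export
translateFilter <- function(cdr3_nt) {
  if (nchar(cdr3_nt) %% 3L != 0L)
    return(list(status = "frame_shift", cdr3_aa = NA_character_))
  if (grepl("[^ACGT]", cdr3_nt))
    return(list(status = "ambiguous_base", cdr3_aa = NA_character_))
  aa <- translateDNA(cdr3_nt)
  if (grepl("*", aa, fixed = TRUE))
    return(list(status = "stop_codon", cdr3_aa = NA_character_))
  list(status = "ok", cdr3_aa = aa)
}

#' Annotate consensus molecules with V/J segments and CDR3
#'
#' Orients each consensus onto the sense strand, finds the best V and J
#' germline hits, extracts the CDR3 between the conserved cysteine and
#' phenylalanine anchors, translates it and discards unproductive
#' sequences. Identical consensus sequences are annotated once and the
#' result reused, so the cost scales with the number of distinct molecules.
#'
#' @param cons data.frame from [buildConsensus()] (columns `tag`,
#'   `consensus_nt`).
#' @param ref a [GermlineReference-class].
#' @param orientation passed to [orientSequence()].
#' @param minScoreV,minScoreJ passed to [alignSegments()].
#' @param convention passed to [extractCDR3()].
#' @return data.frame with one row per molecule: `tag`, `status` (`"ok"` or
#'   a discard reason), `v_name`, `j_name`, `cdr3_nt`, `cdr3_aa`.
#' @export
annotateConsensus <- function(cons, ref, orientation = "antisense",
                              minScoreV = 20, minScoreJ = 15,
                              convention = "inclusive") {
  stopifnot(is.data.frame(cons), is(ref, "GermlineReference"))
  seqs <- cons$consensus_nt
  uniq <- unique(seqs)
  sense <- orientSequence(uniq, orientation, ref = ref)
  unor <- attr(sense, "unoriented") %||% rep(FALSE, length(uniq))
  vb <- .fastHits(sense, segmentSeqs(ref, "V"), minScoreV)
  jb <- .fastHits(sense, segmentSeqs(ref, "J"), minScoreJ)
  ann1 <- lapply(seq_along(uniq), function(i) {
    blank <- list(v_name = NA_character_, j_name = NA_character_,
                  cdr3_nt = NA_character_, cdr3_aa = NA_character_)
    if (unor[i]) return(c(list(status = "unoriented"), blank))
    if (vb$none[i]) return(c(list(status = "no_v_hit"), blank))
    if (jb$none[i]) return(c(list(status = "no_j_hit"), blank))
    hits <- NULL
    if (!vb$needSlow[i] && !jb$needSlow[i]) {
      v <- vb$hits[[i]]; j <- jb$hits[[i]]
      if (j$query_start >= v$query_start + 1L)
        hits <- list(v = v, j = j, status = "ok")
    }
    if (is.null(hits))                       # ties or ordering conflict
      hits <- alignSegments(sense[i], ref, minScoreV, minScoreJ)
    if (hits$status != "ok") return(c(list(status = hits$status), blank))
    blank$v_name <- hits$v$segment_name
    blank$j_name <- hits$j$segment_name
    cd <- extractCDR3(sense[i], hits, ref, convention)
    if (cd$status != "ok") return(c(list(status = cd$status), blank))
    blank$cdr3_nt <- cd$cdr3_nt
    tr <- translateFilter(cd$cdr3_nt)
    blank$cdr3_aa <- tr$cdr3_aa
    c(list(status = tr$status), blank)
  })
  idx <- match(seqs, uniq)
  pick <- function(f, mode) vapply(ann1, `[[`, vector(mode, 1L), f)[idx]
  data.frame(tag = cons$tag, status = pick("status", "character"),
             v_name = pick("v_name", "character"),
             j_name = pick("j_name", "character"),
             cdr3_nt = pick("cdr3_nt", "character"),
             cdr3_aa = pick("cdr3_aa", "character"),
             stringsAsFactors = FALSE)
}

#' Aggregate annotated molecules into clonotypes
#'
#' Nucleotide-level clonotypes group molecules by `(v_name, j_name,
#' cdr3_nt)`; amino-acid-level clonotypes group nucleotide clonotypes by
#' `cdr3_aa` alone (convergent recombination: distinct rearrangements can
#' encode the same CDR3 amino-acid sequence, and shared amino-acid
#' sequences need not use the same V segment).
#'
#' @param ann data.frame from [annotateConsensus()].
#' @param sampleId sample identifier attached to the tables.
#' @return list with `nt` (data.frame `sample_id`, `v_name`, `j_name`,
#'   `cdr3_nt`, `cdr3_aa`, `n_molecules`), `aa` (data.frame `sample_id`,
#'   `cdr3_aa`, `n_nt_variants`, `n_molecules`) and `discarded`
#'   (data.frame `reason`, `n`).
#' @export
aggregateClonotypes <- function(ann, sampleId = "sample1") {
  ok <- ann[ann$status == "ok", , drop = FALSE]
  ntKey <- paste(ok$v_name, ok$j_name, ok$cdr3_nt, sep = "\r")
  cnt <- table(ntKey)
  first <- ok[!duplicated(ntKey), , drop = FALSE]
  first <- first[order(paste(first$v_name, first$j_name, first$cdr3_nt,
                             sep = "\r")), , drop = FALSE]
  nt <- data.frame(sample_id = sampleId, v_name = first$v_name,
                   j_name = first$j_name, cdr3_nt = first$cdr3_nt,
                   cdr3_aa = first$cdr3_aa,
                   n_molecules = as.integer(cnt[sort(names(cnt))]),
                   stringsAsFactors = FALSE)
  aaMol <- tapply(nt$n_molecules, nt$cdr3_aa, sum)
  aaVar <- tapply(nt$cdr3_nt, nt$cdr3_aa, function(x) length(unique(x)))
  aa <- data.frame(sample_id = sampleId, cdr3_aa = names(aaMol),
                   n_nt_variants = as.integer(aaVar),
                   n_molecules = as.integer(aaMol), stringsAsFactors = FALSE)
  rownames(aa) <- NULL
  disc <- ann$status[ann$status != "ok"]
  discarded <- if (length(disc)) {
    tb <- table(disc)
    data.frame(reason = names(tb), n = as.integer(tb),
               stringsAsFactors = FALSE)
  } else data.frame(reason = character(0), n = integer(0))
  list(nt = nt, aa = aa, discarded = discarded)
}
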