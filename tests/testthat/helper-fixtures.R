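# in-code fixtures shared across test files

SPACER <- "GTACATATTGTCGTT"
C_PRIMER <- "CTCTGCTTCTGATGGCTCAAAC"

rcStr <- function(x) chartr("ACGT", "TGCA",
                            vapply(strsplit(x, ""), function(s)
                              paste(rev(s), collapse = ""), character(1)))

rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")

# small germline reference built in code: V segments 80 nt (Cys anchor at
# 0-based 68), J segments 50 nt (Phe anchor at 9, F-G-X-G motif), C segment
# starting with the reverse complement of the C-region primer
makeTestRef <- function(nV = 2, nJ = 2, seed = 99) {
  set.seed(seed)
  nonstop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  segs <- character(0); kind <- character(0); anchor <- integer(0)
  for (i in seq_len(nV)) {
    segs <- c(segs, paste0(rdna(68), "TGT",
                           paste(sample(nonstop, 3), collapse = "")))
    kind <- c(kind, "V"); anchor <- c(anchor, 68L)
  }
  for (i in seq_len(nJ)) {
    segs <- c(segs, paste0(rdna(9), "TTC", "GGG",
                           sample(nonstop, 1), "GGA", rdna(29)))
    kind <- c(kind, "J"); anchor <- c(anchor, 9L)
  }
  segs <- c(segs, paste0(rcStr(C_PRIMER), rdna(18)))
  kind <- c(kind, "C"); anchor <- c(anchor, NA_integer_)
  names(segs) <- c(sprintf("V%02d", seq_len(nV)),
                   sprintf("J%02d", seq_len(nJ)), "C01")
  GermlineReference(segs, kind, anchor)
}

# construct a TagGroupSet directly (payloads are dummies of the right count)
makeGroups <- function(tags, nReads, derivativeOf = NULL) {
  reads <- lapply(nReads, function(k) rep("ACGT", k))
  g <- new("TagGroupSet", tag = tags, nReads = as.integer(nReads),
           lengthClass = ifelse(nchar(tags) %in% 11:13,
                                as.character(nchar(tags)), "other"),
           derivativeOf = derivativeOf %||%
             rep(NA_character_, length(tags)),
           reads = reads)
  validObject(g)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run the demux + counting stages on a simulated run
countMolecules <- function(run, cfg) {
  parsed <- parseReads(run$reads, cfg$sampleIndex, run$readIds)
  g <- mergeLengthVariants(tagGroups(parsed))
  prof <- tagErrorProfile(g)
  list(parsed = parsed, groups = g, profile = prof,
       retained = applyThreshold(g, readThreshold(prof)))
}
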