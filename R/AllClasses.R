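#' Germline V/J/C segment reference
#'
#' Holds germline gene segments (as a [Biostrings::DNAStringSet]) together
#' with their kind (`"V"`, `"J"` or `"C"`) and, for V and J segments, the
#' 0-based offset of the conserved anchor codon: the cysteine codon
#' (TGT/TGC) near the 3' end of a V segment and the phenylalanine codon
#' (TTT/TTC) of the J segment's F-G-X-G motif. The CDR3 junction is defined
#' between these two anchors. Coordinates are 0-based and half-open
#' throughout the package.
#'
#' @slot segments [Biostrings::DNAStringSet] of uppercase segment sequences,
#'   uniquely named.
#' @slot kind character vector, one of `"V"`, `"J"`, `"C"` per segment.
#' @slot anchor integer vector of 0-based anchor codon offsets (`NA` for C
#'   segments).
#' @seealso [readGermlineReference()], [syntheticGermline()],
#'   [anchorMotifCheck()]
#' @export
setClass("GermlineReference",
  slots = c(segments = "DNAStringSet", kind = "character", anchor = "integer"))

.validGermlineReference <- function(object) {
  seg <- object@segments
  nm <- names(seg)
  n <- length(seg)
  if (length(object@kind) != n || length(object@anchor) != n)
    return("segments, kind and anchor must have equal length")
  if (is.null(nm) || any(!nzchar(nm)))
    return("all segments must be named")
  if (anyDuplicated(nm))
    return(sprintf("duplicate segment name: %s",
                   paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (!all(object@kind %in% c("V", "J", "C")))
    return("kind must be one of V, J, C")
  for (k in c("V", "J", "C"))
    if (!any(object@kind == k))
      return(sprintf("reference must contain at least one %s segment", k))
  if (any(width(seg) == 0L))
    return("segments must be non-empty")
  bad <- grepl("[^ACGT]", as.character(seg))
  if (any(bad))
    return(sprintf("segment %s contains characters outside ACGT",
                   nm[bad][1L]))
  for (i in seq_len(n)) {
    k <- object@kind[i]
    a <- object@anchor[i]
    if (k == "C") {
      if (!is.na(a)) return(sprintf("C segment %s must not carry an anchor", nm[i]))
      next
    }
    if (is.na(a) || a < 0L || a + 3L > width(seg)[i])
      return(sprintf("segment %s: anchor_nt out of range", nm[i]))
    msg <- .checkAnchor(as.character(seg[[i]]), a, k)
    if (!isTRUE(msg)) return(sprintf("segment %s: %s", nm[i], msg))
  }
  TRUE
}
setValidity("GermlineReference", .validGermlineReference)

# TRUE or a reason string; seq is a single character string, anchor 0-based
.checkAnchor <- function(seq, anchor, kind) {
  codon <- substr(seq, anchor + 1L, anchor + 3L)
  if (kind == "V") {
    if (!codon %in% c("TGT", "TGC"))
      return(sprintf("anchor codon %s does not encode cysteine", codon))
    return(TRUE)
  }
  if (!codon %in% c("TTT", "TTC"))
    return(sprintf("anchor codon %s does not encode phenylalanine", codon))
  if (anchor + 12L > nchar(seq))
    return("too short for the F-G-X-G motif after the anchor")
  aa <- translateDNA(substr(seq, anchor + 1L, anchor + 12L))
  if (!grepl("^FG.G$", aa))
    return(sprintf("motif %s after the anchor is not F-G-X-G", aa))
  TRUE
}

#' Barcode tag groups
#'
#' One element per distinct barcode tag observed in a sample: the tag
#' sequence, its read payloads, the tag-length class and, after
#' [mergeLengthVariants()], the 12-bp parent tag of single-indel length
#' variants (11/13-bp derivative tags).
#'
#' @slot tag character vector of tag sequences.
#' @slot nReads integer read count per tag.
#' @slot lengthClass character, one of `"11"`, `"12"`, `"13"`, `"other"`.
#' @slot derivativeOf character; for derivative tags the parent 12-bp tag,
#'   otherwise `NA`.
#' @slot reads list of character vectors (the payload sequences per tag).
#' @seealso [tagGroups()], [tagErrorProfile()], [applyThreshold()]
#' @export
setClass("TagGroupSet",
  slots = c(tag = "character", nReads = "integer", lengthClass = "character",
            derivativeOf = "character", reads = "list"))

.validTagGroupSet <- function(object) {
  n <- length(object@tag)
  if (length(object@nReads) != n || length(object@lengthClass) != n ||
      length(object@derivativeOf) != n || length(object@reads) != n)
    return("all slots must have equal length")
  if (n && any(object@nReads < 1L)) return("nReads must be >= 1")
  if (n && any(lengths(object@reads) != object@nReads))
    return("nReads must equal the number of stored payloads")
  expect <- ifelse(nchar(object@tag) %in% 11:13,
                   as.character(nchar(object@tag)), "other")
  if (n && any(object@lengthClass != expect))
    return("lengthClass inconsistent with tag length")
  TRUE
}
setValidity("TagGroupSet", .validTagGroupSet)

#' Tag-length error report
#'
#' Per reads-per-tag bin: the number of 12-bp tags, the number of merged
#' single-indel derivative (11/13-bp) tags, and the error-free fraction
#' `n12 / (n12 + n_derivative)`; plus the read-count threshold `r*` chosen
#' so that every bin at or above it has an error-free fraction of at least
#' the cut (default 90%).
#'
#' @slot table data.frame with columns `reads_per_tag`, `n12`,
#'   `n_derivative`, `fraction` (`NA` where the bin is empty).
#' @slot threshold integer, the chosen threshold `r*`.
#' @slot cut numeric, the error-free fraction cut applied.
#' @seealso [tagErrorProfile()]
#' @export
setClass("TagLengthReport",
  slots = c(table = "data.frame", threshold = "integer", cut = "numeric"))
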