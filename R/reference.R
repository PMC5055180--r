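#' Construct a germline reference
#'
#' @param segments named [Biostrings::DNAStringSet] (or named character
#'   vector) of segment sequences.
#' @param kind character vector of segment kinds (`"V"`, `"J"`, `"C"`).
#' @param anchor integer vector of 0-based anchor codon offsets (`NA` for C
#'   segments).
#' @return a validated [GermlineReference-class] object.
#' @examples
#' ref <- syntheticGermline()
#' segmentNames(ref)
#' @export
GermlineReference <- function(segments, kind, anchor) {
  if (is.character(segments)) segments <- Biostrings::DNAStringSet(segments)
  new("GermlineReference", segments = segments, kind = as.character(kind),
      anchor = as.integer(anchor))
}

#' @rdname GermlineReference-class
#' @export
setMethod("segmentNames", "GermlineReference", function(object)
  names(object@segments))

#' @rdname GermlineReference-class
#' @export
setMethod("segmentKind", "GermlineReference", function(object)
  setNames(object@kind, names(object@segments)))

#' @rdname GermlineReference-class
#' @export
setMethod("anchorPos", "GermlineReference", function(object)
  setNames(object@anchor, names(object@segments)))

#' @rdname GermlineReference-class
#' @export
setMethod("segmentSeqs", "GermlineReference", function(object, kind = NULL) {
  if (is.null(kind)) return(object@segments)
  object@segments[object@kind %in% kind]
})

#' @rdname GermlineReference-class
#' @export
setMethod("length", "GermlineReference", function(x) length(x@segments))

setMethod("show", "GermlineReference", function(object) {
  cat(sprintf("GermlineReference with %d segments (%d V, %d J, %d C)\n",
              length(object@segments), sum(object@kind == "V"),
              sum(object@kind == "J"), sum(object@kind == "C")))
})

#' Read a germline reference from FASTA plus an anchor table
#'
#' The reference is a plain FASTA of segment sequences and a tab-separated
#' sidecar table with columns `name`, `kind`, `anchor_nt` (0-based offset of
#' the conserved anchor codon; empty/NA for C segments).
#'
#' @param fasta path to the segment FASTA.
#' @param anchors path to the tab-separated anchor table.
#' @return a validated [GermlineReference-class].
#' @seealso [writeGermlineReference()], [syntheticGermline()]
#' @export
readGermlineReference <- function(fasta, anchors) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  if (!file.exists(anchors)) stop("anchor table not found: ", anchors)
  seg <- tryCatch(Biostrings::readDNAStringSet(fasta),
                  error = function(e) stop("FASTA parse failure in ", fasta,
                                           ": ", conditionMessage(e)))
  tab <- read.table(anchors, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("name", "kind", "anchor_nt")
  if (!all(need %in% names(tab)))
    stop("anchor table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name))
    stop("duplicate segment name in anchor table: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  if (anyDuplicated(names(seg)))
    stop("duplicate segment name in FASTA: ",
         paste(unique(names(seg)[duplicated(names(seg))]), collapse = ", "))
  miss <- setdiff(names(seg), tab$name)
  if (length(miss))
    stop("segments missing from anchor table: ", paste(miss, collapse = ", "))
  tab <- tab[match(names(seg), tab$name), ]
  GermlineReference(seg, tab$kind, tab$anchor_nt)
}

#' Write a germline reference to FASTA plus an anchor table
#'
#' @param ref a [GermlineReference-class].
#' @param fasta,anchors output paths.
#' @return invisibly, the two paths.
#' @export
writeGermlineReference <- function(ref, fasta, anchors) {
  Biostrings::writeXStringSet(ref@segments, fasta)
  tab <- data.frame(name = names(ref@segments), kind = ref@kind,
                    anchor_nt = ref@anchor)
  write.table(tab, anchors, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, anchors))
}

#' The bundled synthetic germline mini-reference
#'
#' A small synthetic germline set (8 V, 6 J, 1 C segments) shipped with the
#' package so that simulation and annotation run without any download. The
#' segments are random but structurally realistic: V segments are 280 nt
#' with the conserved cysteine codon near the 3' end, J segments are 50 nt
#' with the phenylalanine anchor of an F-G-X-G motif near the 5' end, and
#' the C segment begins with the reverse complement of the C-region primer
#' site. A user-supplied IMGT-style reference in the same FASTA + anchor
#' table format can be used instead via [readGermlineReference()].
#'
#' @return a [GermlineReference-class] with 15 segments.
#' @export
syntheticGermline <- function() {
  readGermlineReference(
    system.file("extdata", "synthetic_germline.fasta", package = "noirss",
                mustWork = TRUE),
    system.file("extdata", "synthetic_germline_anchors.tsv",
                package = "noirss", mustWork = TRUE))
}

#' Check the conserved anchor codon of a V or J segment
#'
#' Returns `TRUE` iff the segment's anchor codon translates to cysteine (V
#' segments) or phenylalanine followed by the F-G-X-G motif (J segments).
#' Accepts either a reference plus a segment name, or a raw sequence with
#' explicit `anchor` and `kind` (useful for vetting candidate segments
#' before constructing a reference).
#'
#' @param x a [GermlineReference-class], or a DNA sequence string.
#' @param name segment name (reference form).
#' @param anchor 0-based anchor codon offset (raw form).
#' @param kind `"V"` or `"J"` (raw form).
#' @return logical scalar.
#' @export
anchorMotifCheck <- function(x, name = NULL, anchor = NULL, kind = NULL) {
  if (is(x, "GermlineReference")) {
    i <- match(name, names(x@segments))
    if (is.na(i)) stop("unknown segment: ", name)
    if (x@kind[i] == "C")
      stop("anchor check is not supported for C segments")
    return(isTRUE(.checkAnchor(as.character(x@segments[[i]]), x@anchor[i],
                               x@kind[i])))
  }
  if (is.null(anchor) || is.null(kind))
    stop("raw-sequence form requires 'anchor' and 'kind'")
  if (!kind %in% c("V", "J"))
    stop("anchor check is not supported for kind ", kind)
  isTRUE(.checkAnchor(as.character(x), as.integer(anchor), kind))
}
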