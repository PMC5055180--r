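#' Cap a tag group at the longest reads
#'
#' If a tag group holds more than `cap` reads, only the `cap` longest are
#' used for the consensus; ties are broken by order of appearance.
#'
#' @param reads character vector of payload sequences.
#' @param cap maximum number of reads (default 50).
#' @return character vector of at most `cap` reads.
#' @export
capReads <- function(reads, cap = 50L) {
  if (length(reads) <= cap) return(reads)
  reads[sort(order(-nchar(reads), seq_along(reads))[seq_len(cap)])]
}

#' Center-star multiple alignment of a tag group
#'
#' The longest read (first on ties) is the center; every other read is
#' globally aligned to it (match +1, mismatch -1, first gap base -2, each
#' further gap base -1) and the pairwise gaps are projected into a common
#' coordinate frame ("once a gap, always a gap"). At the near-identical
#' within-tag-group divergence this is equivalent to a full progressive
#' multiple alignment.
#'
#' @param reads character vector of reads (length >= 1).
#' @return character matrix, one row per read (input order), one column per
#'   alignment position, gap symbol `"-"`.
#' @export
starAlign <- function(reads) {
  if (!length(reads)) stop("empty read group")
  rows <- .C_star_align(as.character(reads))
  do.call(rbind, strsplit(rows, "", fixed = TRUE))
}

#' Call a majority consensus from an aligned matrix
#'
#' Per column, among the rows covering that column (terminal gaps from
#' length differences do not vote), the symbol with relative frequency
#' strictly greater than `majority` (default 0.80) is emitted; a winning
#' gap emits nothing, and columns with no winner emit `N`.
#'
#' @param mat character matrix from [starAlign()] (or a single read).
#' @param majority strict per-column majority fraction.
#' @return list with `consensus` (character scalar, may contain `N`) and
#'   `n_ambiguous` (number of `N` columns).
#' @export
callConsensus <- function(mat, majority = 0.80) {
  if (is.character(mat) && is.null(dim(mat)))
    mat <- matrix(mat, nrow = 1L)
  nr <- nrow(mat); nc <- ncol(mat)
  # coverage: from first to last non-gap position per row
  cover <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) {
    ng <- which(mat[i, ] != "-")
    if (!length(ng)) { cover[i, ] <- FALSE; next }
    cover[i, seq_len(ng[1L] - 1L)] <- FALSE
    if (ng[length(ng)] < nc) cover[i, (ng[length(ng)] + 1L):nc] <- FALSE
  }
  syms <- unique(as.vector(mat))
  counts <- vapply(syms, function(s) .colSums((mat == s) & cover, nr, nc),
                   numeric(nc))
  if (nc == 1L) counts <- matrix(counts, nrow = 1L)
  denom <- .colSums(cover, nr, nc)
  top <- max.col(counts, ties.method = "first")
  win <- counts[cbind(seq_len(nc), top)] / pmax(denom, 1L) > majority
  out <- ifelse(win, syms[top], "N")
  out[denom == 0L] <- ""            # column covered by no row (cannot occur
                                    # for non-empty reads; kept for safety)
  nAmb <- sum(out == "N")
  out[out == "-"] <- ""             # winning gap: emit nothing
  list(consensus = paste(out, collapse = ""), n_ambiguous = nAmb)
}

#' Build consensus sequences for retained tag groups
#'
#' For every retained molecule (tag group), caps the group at the `cap`
#' longest reads, center-star aligns them and calls the strict per-column
#' majority consensus.
#'
#' @param groups a retained [TagGroupSet-class] from [applyThreshold()].
#' @param cap read cap per group (default 50).
#' @param majority strict per-column majority fraction (default 0.80).
#' @return data.frame with one row per molecule: `tag`, `n_reads_used`,
#'   `consensus_nt`, `n_ambiguous`.
#' @export
buildConsensus <- function(groups, cap = 50L, majority = 0.80) {
  stopifnot(is(groups, "TagGroupSet"))
  n <- length(groups)
  cons <- character(n); used <- integer(n); amb <- integer(n)
  for (i in seq_len(n)) {
    reads <- capReads(groups@reads[[i]], cap)
    used[i] <- length(reads)
    u <- unique(reads)
    if (length(u) == 1L) {          # identical reads: consensus is the read
      cons[i] <- u
      next
    }
    cc <- callConsensus(starAlign(reads), majority)
    cons[i] <- cc$consensus
    amb[i] <- cc$n_ambiguous
  }
  data.frame(tag = groups@tag, n_reads_used = used, consensus_nt = cons,
             n_ambiguous = amb, stringsAsFactors = FALSE)
}

#' Write consensus sequences as FASTA
#'
#' Headers are `tag|n_reads_used|n_ambiguous`.
#'
#' @param cons data.frame from [buildConsensus()].
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
writeConsensus <- function(cons, path) {
  x <- Biostrings::DNAStringSet(cons$consensus_nt)
  names(x) <- sprintf("%s|%d|%d", cons$tag, cons$n_reads_used,
                      cons$n_ambiguous)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
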