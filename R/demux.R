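#' Read a FASTQ file into a character vector of sequences
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return list with `reads` (character) and `readIds`.
#' @export
readFastqReads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  list(reads = as.character(unname(x)),
       readIds = sub("\\s.*$", "", names(x)))
}

#' Parse raw reads into sample index, barcode tag and payload
#'
#' The first 5 bases are matched exactly against the known sample indices.
#' The spacer is then located as the best match (at most `maxSpacerEdit`
#' edits, default 1) starting within `window` (0-based offsets from the read
#' start; the default 15-20 tolerates barcode tags of 10-15 bases). The
#' barcode tag is everything between the index and the spacer start, the
#' payload everything after the spacer end. Exact spacer matches are
#' preferred over 1-edit matches; remaining ties resolve to the offset
#' closest to the nominal 17 (a 12-base tag), then to the smaller offset.
#'
#' @param reads character vector of read sequences.
#' @param knownIndices character vector of valid 5-base sample indices.
#' @param readIds optional read identifiers.
#' @param spacer the spacer sequence between barcode and C-region primer.
#' @param window 0-based candidate spacer start offsets.
#' @param maxSpacerEdit maximum edit distance for the spacer match.
#' @return data.frame with one row per read: `read_id`, `status` (`"ok"`,
#'   `"unknown_index"` or `"no_spacer"`), `index`, `tag`, `payload`,
#'   `spacer_len` and `payload_plus_spacer_len` (the quantity the 150-base
#'   length filter applies to); non-`"ok"` rows carry `NA` fields.
#' @export
parseReads <- function(reads, knownIndices, readIds = NULL,
                       spacer = SPACER_SEQ, window = 15:20,
                       maxSpacerEdit = 1L) {
  n <- length(reads)
  if (is.null(readIds)) readIds <- paste0("read", seq_len(n))
  sl <- nchar(spacer)
  out <- data.frame(read_id = readIds, status = rep("ok", n),
                    index = substr(reads, 1L, 5L), tag = NA_character_,
                    payload = NA_character_, spacer_len = NA_integer_,
                    payload_plus_spacer_len = NA_integer_,
                    stringsAsFactors = FALSE)
  bad <- !(out$index %in% knownIndices)
  out$status[bad] <- "unknown_index"
  out$index[bad] <- NA_character_

  todo <- which(!bad)
  off <- rep(NA_integer_, n)       # chosen 0-based spacer start
  mlen <- rep(NA_integer_, n)      # matched spacer length in the read
  # pass 1: exact matches, offsets in preference order
  pref <- window[order(abs(window - 17L), window)]
  for (o in pref) {
    sel <- todo[is.na(off[todo]) &
                  substr(reads[todo], o + 1L, o + sl) == spacer]
    off[sel] <- o; mlen[sel] <- sl
  }
  # pass 2: <= maxSpacerEdit edits, trying match lengths sl-1, sl, sl+1
  if (maxSpacerEdit > 0L) {
    rest <- todo[is.na(off[todo])]
    if (length(rest)) {
      bestD <- rep(Inf, n)
      for (o in pref) {
        for (L in (sl - maxSpacerEdit):(sl + maxSpacerEdit)) {
          cand <- substr(reads[rest], o + 1L, o + L)
          ok <- nchar(cand) == L
          d <- rep(Inf, length(rest))
          if (any(ok))
            d[ok] <- utils::adist(spacer, cand[ok])[1L, ]
          upd <- d <= maxSpacerEdit & d < bestD[rest]
          ii <- rest[upd]
          off[ii] <- o; mlen[ii] <- L; bestD[ii] <- d[upd]
        }
      }
    }
  }
  miss <- todo[is.na(off[todo])]
  out$status[miss] <- "no_spacer"
  got <- todo[!is.na(off[todo])]
  out$tag[got] <- substr(reads[got], 6L, off[got])
  out$payload[got] <- substr(reads[got], off[got] + mlen[got] + 1L,
                             nchar(reads[got]))
  out$spacer_len[got] <- mlen[got]
  out$payload_plus_spacer_len[got] <- mlen[got] + nchar(out$payload[got])
  out
}

#' Apply the minimum-length filter
#'
#' Reads whose spacer plus following sequence is shorter than `minLen`
#' (default 150) bases are discarded.
#'
#' @param parsed data.frame from [parseReads()].
#' @param minLen minimum spacer + payload length in bases.
#' @return logical vector: `TRUE` where the read is kept (`NA`-safe:
#'   non-parsed reads are `FALSE`).
#' @export
lengthFilter <- function(parsed, minLen = 150L) {
  keep <- parsed$status == "ok" & parsed$payload_plus_spacer_len >= minLen
  keep & !is.na(keep)
}

#' Group parsed reads by barcode tag
#'
#' @param parsed data.frame from [parseReads()].
#' @param index sample index to select (default: all parsed reads; supply
#'   one index per call when demultiplexing several samples).
#' @param minLen minimum spacer + payload length ([lengthFilter()]).
#' @return a [TagGroupSet-class] keyed by exact tag sequence.
#' @export
tagGroups <- function(parsed, index = NULL, minLen = 150L) {
  keep <- lengthFilter(parsed, minLen)
  if (!is.null(index)) keep <- keep & parsed$index == index
  p <- parsed[keep, , drop = FALSE]
  reads <- split(p$payload, p$tag)
  tag <- names(reads)
  new("TagGroupSet", tag = tag, nReads = lengths(reads, use.names = FALSE),
      lengthClass = ifelse(nchar(tag) %in% 11:13, as.character(nchar(tag)),
                           "other"),
      derivativeOf = rep(NA_character_, length(tag)),
      reads = unname(reads))
}

#' @rdname TagGroupSet-class
#' @export
setMethod("tags", "TagGroupSet", function(object) object@tag)

#' @rdname TagGroupSet-class
#' @export
setMethod("readCounts", "TagGroupSet", function(object)
  setNames(object@nReads, object@tag))

#' @rdname TagGroupSet-class
#' @export
setMethod("derivativeOf", "TagGroupSet", function(object)
  setNames(object@derivativeOf, object@tag))

#' @rdname TagGroupSet-class
#' @export
setMethod("tagReads", "TagGroupSet", function(object)
  setNames(object@reads, object@tag))

#' @rdname TagGroupSet-class
#' @export
setMethod("length", "TagGroupSet", function(x) length(x@tag))

#' @rdname TagGroupSet-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TagGroupSet", function(x, i, j, ..., drop = FALSE) {
  new("TagGroupSet", tag = x@tag[i], nReads = x@nReads[i],
      lengthClass = x@lengthClass[i], derivativeOf = x@derivativeOf[i],
      reads = x@reads[i])
})

setMethod("show", "TagGroupSet", function(object) {
  cat(sprintf(
    "TagGroupSet with %d tags (%d reads; %d x 12 bp, %d derivative)\n",
    length(object@tag), sum(object@nReads), sum(object@lengthClass == "12"),
    sum(!is.na(object@derivativeOf))))
})

# all single-deletion variants of each sequence (returns data.frame
# variant/parent index, deduplicated within parent)
.deletionVariants <- function(seqs) {
  w <- nchar(seqs[1L])
  var <- lapply(seq_len(w), function(p)
    paste0(substr(seqs, 1L, p - 1L), substr(seqs, p + 1L, w)))
  data.frame(variant = unlist(var),
             parent = rep(seq_along(seqs), times = w),
             stringsAsFactors = FALSE)
}

#' Mark single-indel length variants of 12-bp tags
#'
#' Every 11- or 13-bp tag that differs from some 12-bp tag only by the
#' deletion or insertion of a single base is recorded as that tag's
#' derivative. Derivative reads are used only for the tag-length error
#' profile and never pooled into the parent's consensus. A derivative
#' within one indel of several 12-bp tags is assigned to the parent with
#' the most reads, ties going to the lexicographically smallest tag.
#'
#' @param groups a [TagGroupSet-class] keyed by exact tag sequence.
#' @return the same `TagGroupSet` with `derivativeOf` filled in.
#' @export
mergeLengthVariants <- function(groups) {
  stopifnot(is(groups, "TagGroupSet"))
  i12 <- which(groups@lengthClass == "12")
  if (!length(i12)) return(groups)
  t12 <- groups@tag[i12]
  deriv <- groups@derivativeOf

  assign_parents <- function(candIdx, parentOf) {
    # parentOf: list of integer vectors of candidate parents (into i12)
    for (k in seq_along(candIdx)) {
      p <- unique(parentOf[[k]])
      if (!length(p)) next
      if (length(p) > 1L) {
        nr <- groups@nReads[i12[p]]
        p <- p[nr == max(nr)]
        if (length(p) > 1L) p <- p[order(t12[p])][1L]
      }
      deriv[candIdx[k]] <<- t12[p]
    }
  }

  # 11-bp tags: parents are 12-bp tags one of whose deletions equals the tag
  i11 <- which(groups@lengthClass == "11")
  if (length(i11)) {
    dv <- .deletionVariants(t12)
    hits <- split(dv$parent, dv$variant)
    assign_parents(i11, lapply(groups@tag[i11], function(t)
      hits[[t]] %||% integer(0)))
  }
  # 13-bp tags: parents are 12-bp tags equal to one of the tag's deletions
  i13 <- which(groups@lengthClass == "13")
  if (length(i13)) {
    dv13 <- .deletionVariants(groups@tag[i13])
    m <- match(dv13$variant, t12)
    byCand <- split(m[!is.na(m)], dv13$parent[!is.na(m)])
    assign_parents(i13, lapply(as.character(seq_along(i13)), function(k)
      byCand[[k]] %||% integer(0)))
  }
  groups@derivativeOf <- deriv
  validObject(groups)
  groups
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tag-length error profile and read-count threshold
#'
#' For each reads-per-tag bin `r`, computes the error-free fraction
#' `n12 / (n12 + n_derivative)` where `n12` counts 12-bp tags and
#' `n_derivative` counts the 11/13-bp single-indel derivatives identified
#' by [mergeLengthVariants()]. Erroneous tags accumulate in the low
#' reads-per-tag bins, so the threshold `r*` is the smallest `r` such that
#' every non-empty bin at or above `r` has an error-free fraction of at
#' least `cut` (default 0.90).
#'
#' @param groups a [TagGroupSet-class] after [mergeLengthVariants()].
#' @param cut minimum error-free fraction (default 0.90).
#' @return a [TagLengthReport-class]. If no threshold satisfies the rule
#'   (all bins fail), the pipeline cannot count molecules and an error with
#'   the full per-bin table is raised.
#' @export
tagErrorProfile <- function(groups, cut = 0.90) {
  stopifnot(is(groups, "TagGroupSet"))
  is12 <- groups@lengthClass == "12"
  isDer <- !is.na(groups@derivativeOf)
  use <- is12 | isDer
  if (!any(use)) stop("no 12-bp or derivative tags to profile")
  rmax <- max(groups@nReads[use])
  r <- seq_len(rmax)
  n12 <- tabulate(groups@nReads[is12], nbins = rmax)
  nDer <- tabulate(groups@nReads[isDer], nbins = rmax)
  frac <- ifelse(n12 + nDer > 0L, n12 / (n12 + nDer), NA_real_)
  tab <- data.frame(reads_per_tag = r, n12 = n12, n_derivative = nDer,
                    fraction = frac)
  defined <- !is.na(frac)
  fail <- defined & frac < cut
  if (!any(defined & !fail))
    stop("error-free tag fraction below ", cut,
         " in every reads-per-tag bin; no threshold can be chosen.\n",
         paste(utils::capture.output(print(tab)), collapse = "\n"))
  rstar <- if (any(fail)) max(r[fail]) + 1L else 1L
  if (!any(defined & r >= rstar))
    stop("no bin at or above the candidate threshold r*=", rstar,
         " contains tags; no threshold can be chosen")
  new("TagLengthReport", table = tab, threshold = as.integer(rstar),
      cut = cut)
}

#' @rdname TagLengthReport-class
#' @export
setMethod("readThreshold", "TagLengthReport", function(object)
  object@threshold)

setMethod("show", "TagLengthReport", function(object) {
  cat(sprintf("TagLengthReport: %d bins, threshold r* = %d (cut %.2f)\n",
              nrow(object@table), object@threshold, object@cut))
})

#' Apply the read-count threshold: counted molecules
#'
#' Retains 12-bp, non-derivative tags with at least `rstar` reads; the
#' number of retained tag groups is the sample's absolute molecule count.
#' Derivative tags are never retained.
#'
#' @param groups a [TagGroupSet-class] after [mergeLengthVariants()].
#' @param rstar read-count threshold, typically
#'   `readThreshold(tagErrorProfile(groups))`.
#' @return a [TagGroupSet-class] of retained molecules.
#' @export
applyThreshold <- function(groups, rstar) {
  stopifnot(is(groups, "TagGroupSet"), rstar >= 1L)
  keep <- groups@lengthClass == "12" & is.na(groups@derivativeOf) &
    groups@nReads >= rstar
  groups[keep]
}
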