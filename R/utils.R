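# small sequence helpers shared across modules

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to amino acids (standard genetic code)
#'
#' Vectorised translation; sequence lengths must be multiples of 3. Codons
#' containing characters outside ACGT translate to `X`.
#' @param x character vector of in-frame DNA sequences.
#' @return character vector of amino-acid sequences (`*` marks stops).
#' @export
translateDNA <- function(x) {
  if (any(nchar(x) %% 3L != 0L)) stop("sequence length not divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}

# n random DNA sequences of fixed width (uses the current RNG stream)
randomDNA <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES4, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}
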