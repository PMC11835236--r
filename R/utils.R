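#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Gap characters accepted in alignment rows (Stockholm conventions).
ALN_GAP_CHARS <- c("-", ".", "_", "~")

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out, so pipeline code never has to juggle
#' `DNAString` objects. IUPAC ambiguity codes are complemented correctly.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp_dna("ATGC")
revcomp_dna <- function(x) {
  stopifnot(is.character(x))
  out <- x
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x[ok])))
    )
  }
  out
}

# Split a sequence into its codons starting at `offset` (0, 1 or 2 skipped
# bases); trailing partial codon dropped.
codons_of <- function(seq, offset = 0L) {
  n <- nchar(seq)
  n_codons <- (n - offset) %/% 3L
  if (n_codons <= 0L) {
    return(character(0))
  }
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  substring(seq, starts, starts + 2L)
}

# Stop with a classed error carrying a short machine-usable class tag.
abort_fmt <- function(msg, class) {
  rlang::abort(msg, class = c(class, "intronforge_error"))
}
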