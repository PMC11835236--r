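#' Find open reading frames under a genetic code
#'
#' Scans all six reading frames (three per strand) of a DNA sequence for
#' ORFs. An ORF runs from a valid start codon of the code to the first
#' in-frame stop codon; when no stop occurs before the end of the sequence
#' the ORF is open-ended and still reported. Within a frame, ORFs sharing a
#' stop are collapsed to the longest one (earliest valid start). Codons
#' containing ambiguity characters neither start nor stop an ORF.
#'
#' Coordinates are 1-based inclusive positions on the input sequence as
#' given; for minus-strand ORFs `start`/`end` are the mirrored interval on
#' the plus strand while `frame` counts skipped bases on the scanned
#' (reverse-complemented) strand. `end` includes the stop codon when one is
#' present; the reported `peptide` never includes the stop.
#'
#' @param seq DNA string.
#' @param code Genetic code from [genetic_code()], or a table id.
#' @param min_aa Minimum peptide length in amino acids (default 120, the
#'   conventional floor for homing-endonuclease-sized ORFs).
#' @return Tibble with one row per ORF: `start`, `end`, `strand`, `frame`,
#'   `table_id`, `aa_length`, `has_stop`, `peptide`.
#' @export
#' @examples
#' find_orfs(paste0("CC", "ATG", strrep("GCA", 10), "TAA"), 1, min_aa = 5)
find_orfs <- function(seq, code = 1, min_aa = 120) {
  if (!is.list(code)) code <- get_code(code)
  seq <- chartr("U", "T", toupper(seq))
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_dna(seq)
    for (frame in 0:2) {
      cods <- codons_of(s, frame)
      if (length(cods) == 0L) next
      hits <- scan_frame(cods, code, min_aa)
      if (nrow(hits) == 0L) next
      # codon indices -> nt coords on the scanned strand
      nt_start <- frame + 3L * (hits$first - 1L) + 1L
      nt_end <- frame + 3L * hits$last
      if (strand == "-") {
        tmp <- nt_start
        nt_start <- n - nt_end + 1L
        nt_end <- n - tmp + 1L
      }
      pep <- vapply(seq_len(nrow(hits)), function(i) {
        paste(
          vapply(cods[hits$first[i]:hits$pep_last[i]], translate_codon,
            character(1),
            code = code
          ),
          collapse = ""
        )
      }, character(1))
      out[[length(out) + 1L]] <- tibble::tibble(
        start = nt_start, end = nt_end, strand = strand, frame = frame,
        table_id = code$table_id, aa_length = hits$pep_last - hits$first + 1L,
        has_stop = hits$has_stop, peptide = pep
      )
    }
  }
  if (length(out) == 0L) {
    return(empty_orfs())
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end, .data$strand)
}

empty_orfs <- function() {
  tibble::tibble(
    start = integer(), end = integer(), strand = character(),
    frame = integer(), table_id = integer(), aa_length = integer(),
    has_stop = logical(), peptide = character()
  )
}

# One linear scan over the codons of a frame. Returns codon-index spans:
# `first` = start codon, `last` = final codon included in the interval
# (the stop when present), `pep_last` = final translated codon.
scan_frame <- function(cods, code, min_aa) {
  is_start <- cods %in% code$start_codons
  is_stop <- cods %in% code$stop_codons
  first <- integer(0)
  last <- integer(0)
  pep_last <- integer(0)
  has_stop <- logical(0)
  open <- NA_integer_
  for (i in seq_along(cods)) {
    if (is_stop[i]) {
      if (!is.na(open) && (i - open) >= min_aa) {
        first <- c(first, open)
        last <- c(last, i)
        pep_last <- c(pep_last, i - 1L)
        has_stop <- c(has_stop, TRUE)
      }
      open <- NA_integer_
    } else if (is.na(open) && is_start[i]) {
      open <- i
    }
  }
  nc <- length(cods)
  if (!is.na(open) && (nc - open + 1L) >= min_aa) {
    first <- c(first, open)
    last <- c(last, nc)
    pep_last <- c(pep_last, nc)
    has_stop <- c(has_stop, FALSE)
  }
  tibble::tibble(first = first, last = last, pep_last = pep_last, has_stop = has_stop)
}

#' Drop ORFs nested inside a larger same-strand ORF
#'
#' "Nested" means genomic-interval containment on the same strand,
#' irrespective of reading frame: only the largest ORF of a containment
#' chain is kept. Partially overlapping ORFs are all retained — homing
#' endonucleases encoded in different frames can genuinely overlap by a few
#' dozen nucleotides. Applied greedily from longest to shortest with
#' deterministic tie-breaking.
#'
#' @param orfs Tibble of ORFs as returned by [find_orfs()] (only `start`,
#'   `end`, `strand` are consulted).
#' @return The retained subset, in ascending `start` order.
#' @export
prune_nested <- function(orfs) {
  if (nrow(orfs) == 0L) {
    return(orfs)
  }
  ord <- order(-(orfs$end - orfs$start), orfs$start, orfs$strand,
    if ("frame" %in% names(orfs)) orfs$frame else seq_len(nrow(orfs)))
  kept <- integer(0)
  for (i in ord) {
    contained <- any(
      orfs$strand[kept] == orfs$strand[i] &
        orfs$start[kept] <= orfs$start[i] &
        orfs$end[kept] >= orfs$end[i]
    )
    if (!contained) kept <- c(kept, i)
  }
  dplyr::arrange(orfs[sort(kept), , drop = FALSE], .data$start, .data$end, .data$strand)
}
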