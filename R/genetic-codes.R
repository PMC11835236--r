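#' NCBI genetic-code tables
#'
#' Genetic codes are taken from the curated tables shipped with
#' \pkg{Biostrings} (`GENETIC_CODE_TABLE`), indexed by their NCBI
#' translation-table id. Organelles and taxa differ in their codes (for
#' example table 4, the mold-mitochondrial code, reads TGA as Trp), which is
#' why ORF scanning for homing endonucleases runs under every known table
#' rather than only the host's expected one.
#'
#' @param table_id NCBI translation-table id (integer or string), e.g. `1`
#'   (standard), `4` (mold mitochondrial), `11` (bacterial/plastid).
#' @return For `genetic_code()`, a list with elements `table_id`, `name`,
#'   `codons` (named character vector over all 64 codons, `"*"` for stops),
#'   `start_codons`, and `stop_codons`. For `known_code_tables()`, an integer
#'   vector of every available table id.
#' @export
#' @examples
#' gc4 <- genetic_code(4)
#' gc4$codons[["TGA"]]
#' known_code_tables()
genetic_code <- function(table_id) {
  id <- as.character(as.integer(table_id))
  tbl <- Biostrings::GENETIC_CODE_TABLE
  if (!id %in% tbl$id) {
    abort_fmt(
      sprintf("unknown NCBI genetic-code table id: %s", id),
      "intronforge_config_error"
    )
  }
  codons <- Biostrings::getGeneticCode(id, full.search = TRUE)
  # ATG initiates in every NCBI table; the attribute lists the alternatives.
  starts <- sort(unique(c("ATG", attr(codons, "alt_init_codons"))))
  stops <- sort(names(codons)[codons == "*"])
  codons_chr <- as.character(codons)
  names(codons_chr) <- names(codons)
  list(
    table_id = as.integer(id),
    name = tbl$name[tbl$id == id],
    codons = codons_chr,
    start_codons = starts,
    stop_codons = stops
  )
}

#' @rdname genetic_code
#' @export
known_code_tables <- function() {
  sort(as.integer(Biostrings::GENETIC_CODE_TABLE$id))
}

# Cache of genetic_code() results (the table set is small and static).
code_cache <- new.env(parent = emptyenv())

get_code <- function(table_id) {
  key <- as.character(as.integer(table_id))
  if (is.null(code_cache[[key]])) {
    code_cache[[key]] <- genetic_code(key)
  }
  code_cache[[key]]
}

#' Translate DNA codon-wise under a genetic code
#'
#' Translates a DNA string whose length is a multiple of three. Codons
#' containing IUPAC ambiguity characters are expanded to all their
#' resolutions: if every resolution gives the same amino acid the codon
#' translates to it, otherwise to `X`. An ambiguous codon never terminates
#' translation even if some resolutions are stops.
#'
#' @param dna DNA string, length divisible by 3. `U` is accepted and treated
#'   as `T`.
#' @param code A genetic code from [genetic_code()], or a table id.
#' @return Single amino-acid string (`*` marks stop codons).
#' @export
#' @examples
#' translate_dna("ATGAAATAG", 1)
#' translate_dna("TGA", 4)
translate_dna <- function(dna, code = 1) {
  if (!is.list(code)) code <- get_code(code)
  dna <- chartr("U", "T", toupper(dna))
  if (nchar(dna) %% 3L != 0L) {
    abort_fmt("sequence length must be divisible by 3", "intronforge_input_error")
  }
  cods <- codons_of(dna, 0L)
  paste(vapply(cods, translate_codon, character(1), code = code), collapse = "")
}

translate_codon <- function(codon, code) {
  aa <- code$codons[codon]
  if (!is.na(aa)) {
    return(unname(aa))
  }
  # Ambiguous codon: translate to the consensus of all resolutions, else X.
  res <- resolve_codon(codon)
  if (length(res) == 0L) {
    return("X")
  }
  aas <- unique(unname(code$codons[res]))
  if (length(aas) == 1L && !anyNA(aas)) aas else "X"
}

resolve_codon <- function(codon) {
  bases <- strsplit(codon, "")[[1]]
  opts <- lapply(bases, function(b) {
    hit <- Biostrings::IUPAC_CODE_MAP[b]
    if (is.na(hit)) character(0) else strsplit(unname(hit), "")[[1]]
  })
  if (any(lengths(opts) == 0L)) {
    return(character(0))
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}
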