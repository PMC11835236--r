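#' Read a pre-extracted taxonomy table
#'
#' Taxonomy is consumed as a TSV extracted once from the NCBI Taxonomy
#' database rather than queried live: columns `taxid`, `name`, `lineage`
#' (semicolon-separated rank names, most inclusive first), and the
#' NCBI genetic-code table ids per compartment (`nuclear_code`,
#' `mito_code`, `plastid_code`; the latter two empty where the organism
#' has no such compartment).
#'
#' @param path Path to the taxonomy TSV.
#' @return Tibble with the columns above.
#' @export
read_taxonomy <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      taxid = readr::col_integer(), name = readr::col_character(),
      lineage = readr::col_character(),
      nuclear_code = readr::col_integer(), mito_code = readr::col_integer(),
      plastid_code = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' Default organism-category rules
#'
#' Ordered first-match-wins rules mapping a lineage name to a broad
#' organism category (plants, fungi, placozoans, corals, sponges,
#' bacteria, archaea, viruses, other-protist, other). The set follows the
#' categories conventionally used to summarise group I intron hosts and
#' is fully user-editable.
#'
#' @return Tibble with `pattern` (a lineage taxon name) and `category`.
#' @export
default_category_rules <- function() {
  tibble::tribble(
    ~pattern, ~category,
    "Viridiplantae", "plants",
    "Fungi", "fungi",
    "Placozoa", "placozoans",
    "Cnidaria", "corals",
    "Porifera", "sponges",
    "Metazoa", "other",
    "Bacteria", "bacteria",
    "Archaea", "archaea",
    "Viruses", "viruses",
    "Eukaryota", "other-protist"
  )
}

#' Categorize an organism from its lineage
#'
#' The first rule whose pattern appears among the lineage's taxon names
#' wins; a lineage matching no rule is `"other"`. Deterministic and total.
#'
#' @param lineage Character vector of semicolon-separated lineage strings.
#' @param rules Ordered rule tibble (default [default_category_rules()]).
#' @return Character vector of categories.
#' @export
#' @examples
#' categorize("Eukaryota; Viridiplantae; Streptophyta")
categorize <- function(lineage, rules = default_category_rules()) {
  vapply(lineage, function(lin) {
    if (is.na(lin)) {
      return("other")
    }
    names_in <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    hit <- which(rules$pattern %in% names_in)
    if (length(hit) == 0L) "other" else rules$category[min(hit)]
  }, character(1), USE.NAMES = FALSE)
}

#' Infer the subcellular location of a record
#'
#' Decided from the GenBank source feature's `/organelle` qualifier
#' (`mitochondrion` variants map to mitochondria; `plastid`/`chloroplast`
#' to plastid); records without one default to the nucleus for eukaryotes
#' and `n/a` otherwise. Conflicting qualifiers: the first wins, with a
#' warning.
#'
#' @param features A record's feature tibble.
#' @param lineage The organism's lineage string (used to detect
#'   eukaryotes).
#' @return One of `"mitochondria"`, `"plastid"`, `"nucleus"`, `"n/a"`.
#' @export
infer_location <- function(features, lineage) {
  organelles <- character(0)
  for (i in which(features$ftype == "source")) {
    org <- features$qualifiers[[i]][["organelle"]]
    if (!is.null(org) && is.character(org)) organelles <- c(organelles, org)
  }
  mapped <- vapply(organelles, function(o) {
    o <- tolower(o)
    if (grepl("mitochondrion", o, fixed = TRUE)) {
      "mitochondria"
    } else if (grepl("plastid", o, fixed = TRUE) || grepl("chloroplast", o, fixed = TRUE)) {
      "plastid"
    } else {
      NA_character_
    }
  }, character(1), USE.NAMES = FALSE)
  mapped <- mapped[!is.na(mapped)]
  if (length(unique(mapped)) > 1L) {
    warning("conflicting organelle qualifiers; using the first", call. = FALSE)
  }
  if (length(mapped) > 0L) {
    return(mapped[1])
  }
  is_euk <- !is.na(lineage) && "Eukaryota" %in% trimws(strsplit(lineage, ";")[[1]])
  if (is_euk) "nucleus" else "n/a"
}

#' Attach organism metadata to refined introns
#'
#' Joins species name, taxid, organism category, subcellular location and
#' per-compartment genetic codes onto the intron table, using the records'
#' source features and a taxonomy table.
#'
#' @param introns Intron tibble (from [refine_hits()] via `tidy()`).
#' @param records Records tibble from [read_genbank()].
#' @param taxonomy Taxonomy tibble from [read_taxonomy()] (optional;
#'   lineage falls back to the GenBank ORGANISM block).
#' @param rules Category rules (default [default_category_rules()]).
#' @return `introns` with `organism`, `taxid`, `organism_category`,
#'   `subcellular_location`, `nuclear_code`, `mito_code`, `plastid_code`
#'   columns added.
#' @export
annotate_metadata <- function(introns, records, taxonomy = NULL,
                              rules = default_category_rules()) {
  ri <- match(introns$genbank_id, records$entry_id)
  organism <- records$organism[ri]
  taxid <- records$taxid[ri]
  lineage <- records$lineage[ri]
  nuclear_code <- rep(NA_integer_, nrow(introns))
  mito_code <- rep(NA_integer_, nrow(introns))
  plastid_code <- rep(NA_integer_, nrow(introns))
  if (!is.null(taxonomy) && nrow(taxonomy) > 0L) {
    ti <- match(taxid, taxonomy$taxid)
    use <- !is.na(ti)
    organism[use] <- taxonomy$name[ti[use]]
    lineage[use] <- taxonomy$lineage[ti[use]]
    nuclear_code[use] <- taxonomy$nuclear_code[ti[use]]
    mito_code[use] <- taxonomy$mito_code[ti[use]]
    plastid_code[use] <- taxonomy$plastid_code[ti[use]]
  }
  location <- vapply(seq_len(nrow(introns)), function(i) {
    if (is.na(ri[i])) {
      return(NA_character_)
    }
    infer_location(records$features[[ri[i]]], lineage[i])
  }, character(1))
  introns |>
    dplyr::mutate(
      organism = organism, taxid = taxid,
      organism_category = categorize(lineage, rules),
      subcellular_location = location,
      nuclear_code = nuclear_code, mito_code = mito_code,
      plastid_code = plastid_code
    )
}

#' Summarise an intron/HEG database
#'
#' Produces the standard descriptive tables for a populated database:
#' counts by organism category, by category and subtype, by category and
#' subcellular location, and intron length distributions overall, by
#' subtype, and split by HEG presence. Counts always sum to the number of
#' database rows.
#'
#' @param introns Intron database tibble.
#' @param hegs HEG database tibble (may be empty/NULL).
#' @return List of tibbles: `by_category`, `by_category_subtype`,
#'   `by_category_location`, `lengths` (per-intron length, subtype,
#'   `has_heg`), `length_summary` (n/mean/median by HEG presence).
#' @export
summarize_database <- function(introns, hegs = NULL) {
  if (nrow(introns) == 0L) {
    empty <- tibble::tibble(organism_category = character(), n = integer())
    return(list(
      by_category = empty,
      by_category_subtype = tibble::tibble(
        organism_category = character(), subtype = character(), n = integer()
      ),
      by_category_location = tibble::tibble(
        organism_category = character(), subcellular_location = character(),
        n = integer()
      ),
      lengths = tibble::tibble(
        intron_id = character(), length = integer(), subtype = character(),
        has_heg = logical()
      ),
      length_summary = tibble::tibble(
        has_heg = logical(), n = integer(), mean_length = double(),
        median_length = double()
      )
    ))
  }
  for (col in c("subtype", "organism_category", "subcellular_location")) {
    if (!col %in% names(introns)) introns[[col]] <- NA_character_
  }
  heg_introns <- if (!is.null(hegs) && nrow(hegs) > 0L) unique(hegs$intron_id) else character(0)
  lengths <- introns |>
    dplyr::transmute(
      .data$intron_id,
      length = nchar(.data$intron_seq),
      subtype = .data$subtype,
      has_heg = .data$intron_id %in% heg_introns
    )
  list(
    by_category = dplyr::count(introns, .data$organism_category),
    by_category_subtype = dplyr::count(introns, .data$organism_category, .data$subtype),
    by_category_location = dplyr::count(
      introns, .data$organism_category, .data$subcellular_location
    ),
    lengths = lengths,
    length_summary = lengths |>
      dplyr::group_by(.data$has_heg) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_length = mean(.data$length),
        median_length = stats::median(.data$length),
        .groups = "drop"
      )
  )
}
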