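# Default keyword stems marking a homing-endonuclease-related annotation.
HEG_KEYWORDS <- c("endonuc", "homing", "nuclease")

#' Match homing-endonuclease keywords in domain annotations
#'
#' Returns the first domain hit (in input order) any of whose annotation
#' strings contains, case-insensitively, one of the keyword stems
#' (defaults: `endonuc`, `homing`, `nuclease`).
#'
#' @param hits Domain-hit tibble ([read_interproscan_tsv()] /
#'   [read_blast_tabular()]).
#' @param keywords Character vector of stems (fixed substrings).
#' @return One-row tibble of the matching hit with a `matched_annotation`
#'   column, or a zero-row tibble when nothing matches.
#' @export
match_heg_keywords <- function(hits, keywords = HEG_KEYWORDS) {
  kw <- tolower(keywords)
  for (i in seq_len(nrow(hits))) {
    ann <- hits$annotation[[i]]
    low <- tolower(ann)
    m <- which(vapply(low, function(a) {
      any(vapply(kw, function(k) grepl(k, a, fixed = TRUE), logical(1)))
    }, logical(1)))
    if (length(m) > 0L) {
      out <- hits[i, , drop = FALSE]
      out$matched_annotation <- ann[m[1]]
      return(out)
    }
  }
  out <- hits[0, , drop = FALSE]
  out$matched_annotation <- character(0)
  out
}

#' Classify the genetic-code provenance of an ORF
#'
#' An ORF detected under table `table_id` inside an intron whose organism
#' context is known is labelled `expected` when the table is the code of
#' the intron's own compartment, `other_location` when it is the code of
#' another compartment of the same organism, and `foreign` otherwise.
#' For non-eukaryotic records (subcellular location `n/a`) the genomic
#' code plays the role of the own-compartment code. An unknown
#' own-compartment code yields `foreign` with a warning.
#'
#' @param table_id NCBI translation-table id the ORF was found under.
#' @param context One-row tibble or list with `subcellular_location`,
#'   `nuclear_code`, `mito_code`, `plastid_code`.
#' @return One of `"expected"`, `"other_location"`, `"foreign"`.
#' @export
classify_code_provenance <- function(table_id, context) {
  loc <- context$subcellular_location %||% "n/a"
  codes <- c(
    nucleus = as_int_or_na(context$nuclear_code),
    mitochondria = as_int_or_na(context$mito_code),
    plastid = as_int_or_na(context$plastid_code)
  )
  own_key <- if (loc %in% names(codes)) loc else "nucleus"
  own <- codes[[own_key]]
  if (is.na(own)) {
    warning(sprintf(
      "unknown genetic code for compartment '%s'; provenance set to foreign", loc
    ), call. = FALSE)
    return("foreign")
  }
  if (table_id == own) {
    return("expected")
  }
  others <- codes[setdiff(names(codes), own_key)]
  if (table_id %in% others[!is.na(others)]) {
    return("other_location")
  }
  "foreign"
}

as_int_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) NA_integer_ else as.integer(x)
}

# Ranked preference of code tables used when merging ORFs that are
# identical under several codes: own compartment first, then the
# organism's other compartments, then everything else by ascending id.
code_preference <- function(table_ids, context) {
  prov <- vapply(table_ids, function(t) {
    suppressWarnings(classify_code_provenance(t, context))
  }, character(1))
  rank <- match(prov, c("expected", "other_location", "foreign"))
  order(rank, table_ids)
}

#' Enumerate candidate ORFs of an intron under all genetic codes
#'
#' Runs [find_orfs()] under every table in `codes`, merges ORFs that are
#' identical (same strand, interval and peptide) under several codes —
#' keeping the table preferred by provenance (own compartment, then other
#' compartments, then lowest id) — and prunes nested ORFs. Resulting ORFs
#' get deterministic ids `<intron_id>_orf<k>` in ascending start order.
#'
#' @param intron_seq Intron DNA sequence (already in intron orientation).
#' @param intron_id Intron identifier used to derive ORF ids.
#' @param context Organism context (see [classify_code_provenance()]).
#' @param codes Integer vector of table ids (default: all known).
#' @param min_aa Minimum peptide length (default 120).
#' @return Tibble of ORFs with `orf_id` and find_orfs() columns.
#' @export
enumerate_orfs <- function(intron_seq, intron_id, context,
                           codes = known_code_tables(), min_aa = 120) {
  all_orfs <- dplyr::bind_rows(lapply(codes, function(tid) {
    find_orfs(intron_seq, tid, min_aa)
  }))
  if (nrow(all_orfs) == 0L) {
    out <- empty_orfs()
    out$orf_id <- character(0)
    return(out)
  }
  merged <- all_orfs |>
    dplyr::group_by(.data$strand, .data$start, .data$end, .data$peptide) |>
    dplyr::group_modify(function(g, key) {
      g[code_preference(g$table_id, context)[1L], , drop = FALSE]
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(names(empty_orfs())))
  pruned <- prune_nested(merged)
  pruned <- dplyr::arrange(pruned, .data$start, .data$end, .data$strand, .data$frame)
  pruned$orf_id <- paste0(intron_id, "_orf", seq_len(nrow(pruned)))
  pruned
}

#' Annotate putative homing endonucleases in one intron
#'
#' ORFs are enumerated under all applicable genetic codes, pruned, and
#' passed through InterProScan evidence first: every ORF whose domain
#' annotations contain a homing-endonuclease keyword becomes a HEG with
#' `evidence_source = "interproscan"`. Only when an intron has candidate
#' ORFs but not a single InterProScan-based HEG is DELTA-BLAST evidence
#' consulted, with the same keyword rule applied to subject titles. Each
#' HEG carries the genetic-code provenance of its ORF.
#'
#' @inheritParams enumerate_orfs
#' @param interpro,blast Domain-hit tibbles keyed by `orf_id` (may be
#'   empty).
#' @param keywords Keyword stems (default `endonuc`, `homing`,
#'   `nuclease`).
#' @param blast_evalue_max Optional E-value ceiling applied to BLAST
#'   evidence before matching (default `NULL`: none).
#' @param orfs Pre-computed result of [enumerate_orfs()] for this intron;
#'   when `NULL` the ORFs are enumerated here.
#' @return Tibble of HEG annotations in hegs.tsv shape (plus `orf_id`),
#'   zero rows when none found.
#' @export
annotate_hegs <- function(intron_seq, intron_id, context, interpro, blast,
                          codes = known_code_tables(), min_aa = 120,
                          keywords = HEG_KEYWORDS, blast_evalue_max = NULL,
                          orfs = NULL) {
  if (is.null(orfs)) {
    orfs <- enumerate_orfs(intron_seq, intron_id, context, codes, min_aa)
  }
  if (nrow(orfs) == 0L) {
    return(empty_hegs())
  }
  call_from <- function(evidence) {
    rows <- purrr::map(seq_len(nrow(orfs)), function(i) {
      ev <- evidence[evidence$orf_id == orfs$orf_id[i], , drop = FALSE]
      m <- match_heg_keywords(ev, keywords)
      if (nrow(m) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        orf_id = orfs$orf_id[i],
        start_in_intron = orfs$start[i], end_in_intron = orfs$end[i],
        frame = orfs$frame[i], strand = orfs$strand[i],
        genetic_code_id = orfs$table_id[i],
        code_provenance = suppressWarnings(
          classify_code_provenance(orfs$table_id[i], context)
        ),
        evidence_source = m$source, evidence_annotation = m$matched_annotation,
        peptide_seq = orfs$peptide[i]
      )
    })
    dplyr::bind_rows(purrr::compact(rows))
  }
  hegs <- call_from(interpro)
  if (nrow(hegs) == 0L) {
    bl <- blast
    if (!is.null(blast_evalue_max) && nrow(bl) > 0L) {
      bl <- bl[!is.na(bl$e_value) & bl$e_value <= blast_evalue_max, , drop = FALSE]
    }
    hegs <- call_from(bl)
  }
  if (nrow(hegs) == 0L) {
    return(empty_hegs())
  }
  hegs$intron_id <- intron_id
  hegs$heg_id <- paste0(intron_id, "_heg", seq_len(nrow(hegs)))
  hegs[, c(names(empty_hegs()))]
}

empty_hegs <- function() {
  tibble::tibble(
    heg_id = character(), intron_id = character(),
    start_in_intron = integer(), end_in_intron = integer(),
    frame = integer(), strand = character(), genetic_code_id = integer(),
    code_provenance = character(), evidence_source = character(),
    evidence_annotation = character(), peptide_seq = character(),
    orf_id = character()
  )
}
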