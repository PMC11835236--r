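#' Assign intron subtypes from covariance-model scan scores
#'
#' Each intron is classified into the subtype whose covariance model gave
#' the highest-scoring hit in a `cmscan` of the intron sequence against
#' the per-subtype CM database. Ties break lexicographically by subtype
#' name, so the assignment is deterministic and invariant under the input
#' order of hits. No score or E-value floor is applied before taking the
#' maximum.
#'
#' `assign_subtype()` works on the hits of a single intron;
#' `assign_subtypes()` maps a whole scan table (grouping by `target_id`).
#'
#' @param scan_hits Tibble of hits with at least `model_name` and `score`
#'   (for `assign_subtypes()`, also `target_id` naming the intron).
#' @return `assign_subtype()`: one-row tibble `subtype`, `subtype_score`,
#'   `all_scores` (list-column of named numeric vectors), or a zero-row
#'   tibble when there are no hits (unclassified). `assign_subtypes()`:
#'   one row per intron with `intron_id`, `subtype`, `subtype_score`.
#' @export
#' @examples
#' assign_subtype(tibble::tibble(
#'   model_name = c("IC1", "IB4"), score = c(85.2, 40.1)
#' ))
assign_subtype <- function(scan_hits) {
  if (nrow(scan_hits) == 0L) {
    return(tibble::tibble(
      subtype = character(), subtype_score = double(), all_scores = list()
    ))
  }
  best <- scan_hits |>
    dplyr::arrange(dplyr::desc(.data$score), .data$model_name) |>
    dplyr::slice(1L)
  scores <- rlang::set_names(scan_hits$score, scan_hits$model_name)
  scores <- scores[order(names(scores))]
  tibble::tibble(
    subtype = best$model_name, subtype_score = best$score,
    all_scores = list(scores)
  )
}

#' @rdname assign_subtype
#' @export
assign_subtypes <- function(scan_hits) {
  if (nrow(scan_hits) == 0L) {
    return(tibble::tibble(
      intron_id = character(), subtype = character(), subtype_score = double()
    ))
  }
  scan_hits |>
    dplyr::group_by(intron_id = .data$target_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$model_name, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("intron_id", subtype = "model_name", subtype_score = "score")
}

#' Column ranges of named structural elements from a label line
#'
#' A subtype's consensus structural elements (P1-P9, P5a-d, ...) are
#' supplied as a sidecar annotation line over the alignment columns: one
#' character per column, `.` for unlabeled columns. Maximal runs of an
#' identical label become column ranges; an element may own several
#' ranges (the two strands of a paired region).
#'
#' @param label_line Gapped annotation string, one character per column.
#' @param legend Optional named character vector mapping label characters
#'   to element names (e.g. `c("1" = "P1")`); unlisted characters name
#'   themselves.
#' @return Tibble with `element`, `col_start`, `col_end` (1-based
#'   inclusive alignment columns).
#' @export
#' @examples
#' element_spans_from_labels("..111..22..", c("1" = "P1", "2" = "P2"))
element_spans_from_labels <- function(label_line, legend = NULL) {
  chars <- strsplit(label_line, "")[[1]]
  if (length(chars) == 0L) {
    return(tibble::tibble(
      element = character(), col_start = integer(), col_end = integer()
    ))
  }
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "."
  if (!any(keep)) {
    return(tibble::tibble(
      element = character(), col_start = integer(), col_end = integer()
    ))
  }
  labels <- r$values[keep]
  named <- if (!is.null(legend)) {
    ifelse(labels %in% names(legend), unname(legend[labels]), labels)
  } else {
    labels
  }
  tibble::tibble(
    element = named, col_start = starts[keep], col_end = ends[keep]
  )
}

#' Map consensus structural elements onto one aligned intron
#'
#' For each named element, counts the row's non-gap residues falling in
#' the element's alignment columns. The element is present when at least
#' `min_residues` residues occupy it; its span is reported in intron-local
#' ungapped coordinates (1-based inclusive, first to last such residue).
#'
#' @param aligned_seq The intron's gapped row from the subtype alignment.
#' @param element_spans Tibble from [element_spans_from_labels()].
#' @param min_residues Presence threshold in residues (default 1).
#' @return Tibble with `element`, `present`, `start`, `end` (NA when
#'   absent), one row per distinct element.
#' @export
map_elements <- function(aligned_seq, element_spans, min_residues = 1) {
  chars <- strsplit(aligned_seq, "")[[1]]
  ncol_aln <- length(chars)
  if (nrow(element_spans) > 0L && max(element_spans$col_end) > ncol_aln) {
    abort_fmt(
      "element span exceeds alignment length",
      "intronforge_config_error"
    )
  }
  is_res <- !(chars %in% ALN_GAP_CHARS)
  res_index <- cumsum(is_res) # column -> residue ordinal (valid where is_res)
  elements <- unique(element_spans$element)
  rows <- purrr::map(elements, function(el) {
    spans <- element_spans[element_spans$element == el, , drop = FALSE]
    cols <- unlist(purrr::map2(spans$col_start, spans$col_end, seq.int))
    occ <- cols[is_res[cols]]
    if (length(occ) >= min_residues && length(occ) > 0L) {
      tibble::tibble(
        element = el, present = TRUE,
        start = res_index[min(occ)], end = res_index[max(occ)]
      )
    } else {
      tibble::tibble(
        element = el, present = FALSE, start = NA_integer_, end = NA_integer_
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      element = character(), present = logical(),
      start = integer(), end = integer()
    ))
  }
  out
}

# Serialise an element map to the semicolon list stored in introns.tsv,
# e.g. "P1:1-45;P5a:102-131".
structural_elements_string <- function(element_map) {
  pres <- element_map[element_map$present, , drop = FALSE]
  if (nrow(pres) == 0L) {
    return(NA_character_)
  }
  paste(sprintf("%s:%d-%d", pres$element, pres$start, pres$end), collapse = ";")
}

#' Annotate structural elements for classified introns
#'
#' Given per-subtype Stockholm alignments (with an element-label `#=GC`
#' line) containing the introns' aligned rows, annotates each intron with
#' the semicolon list of present elements and their intron-local spans.
#'
#' @param introns Intron tibble with `intron_id` and `subtype` columns.
#' @param alignments Named list (by subtype) of results from
#'   [read_stockholm()]; element labels are taken from the `#=GC` tag
#'   `ELEMENTS` (falling back to any non-`SS_cons` `#=GC` line).
#' @param legends Optional named list (by subtype) of label legends.
#' @param min_residues Presence threshold (default 1).
#' @return `introns` with a `structural_elements` column added/filled.
#' @export
annotate_elements <- function(introns, alignments, legends = NULL, min_residues = 1) {
  if (!"structural_elements" %in% names(introns)) {
    introns$structural_elements <- NA_character_
  }
  for (i in seq_len(nrow(introns))) {
    st <- introns$subtype[i]
    if (is.na(st) || is.null(alignments[[st]])) next
    aln <- alignments[[st]]
    row <- aln$alignment[introns$intron_id[i]]
    if (is.na(row)) next
    label_tag <- if (!is.null(aln$gc[["ELEMENTS"]])) {
      "ELEMENTS"
    } else {
      setdiff(names(aln$gc), "SS_cons")[1]
    }
    if (is.na(label_tag) || is.null(aln$gc[[label_tag]])) next
    spans <- element_spans_from_labels(
      aln$gc[[label_tag]],
      if (!is.null(legends)) legends[[st]] else NULL
    )
    emap <- map_elements(unname(row), spans, min_residues)
    introns$structural_elements[i] <- structural_elements_string(emap)
  }
  introns
}
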