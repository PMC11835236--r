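#' Read Infernal tabular hit output (`--tblout`)
#'
#' Parses the whitespace-delimited per-hit table written by Infernal 1.1
#' `cmsearch`/`cmscan` with `--tblout`. Minus-strand hits (seq-from >
#' seq-to) are normalised so that `start <= end` always holds, with the
#' strand kept as an explicit column.
#'
#' @param path Path to a tblout file.
#' @param format `"cmsearch"` (target = sequence, query = model; the
#'   default) or `"cmscan"` (target = model, query = sequence). The parsed
#'   tibble always has the sequence in `target_id` and the model in
#'   `model_name`.
#' @return Tibble of hits: `target_id`, `model_name`, `start`, `end`,
#'   `strand`, `score`, `e_value`.
#' @export
read_tblout <- function(path, format = c("cmsearch", "cmscan")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(empty_hits())
  }
  rows <- purrr::map(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) < 16L) {
      abort_fmt(
        sprintf("%s: line %d has %d fields, expected >= 16", path, i, length(tok)),
        "intronforge_format_error"
      )
    }
    from <- suppressWarnings(as.integer(tok[8]))
    to <- suppressWarnings(as.integer(tok[9]))
    score <- suppressWarnings(as.numeric(tok[15]))
    eval <- suppressWarnings(as.numeric(tok[16]))
    if (anyNA(c(from, to, score, eval))) {
      abort_fmt(
        sprintf("%s: non-numeric coordinate or score field at line %d", path, i),
        "intronforge_format_error"
      )
    }
    seq_name <- if (format == "cmsearch") tok[1] else tok[3]
    model <- if (format == "cmsearch") tok[3] else tok[1]
    strand <- tok[10]
    if (from > to) {
      tmp <- from
      from <- to
      to <- tmp
      strand <- "-"
    }
    tibble::tibble(
      target_id = seq_name, model_name = model, start = from, end = to,
      strand = strand, score = score, e_value = eval
    )
  })
  dplyr::bind_rows(rows)
}

empty_hits <- function() {
  tibble::tibble(
    target_id = character(), model_name = character(), start = integer(),
    end = integer(), strand = character(), score = double(),
    e_value = double()
  )
}

empty_domain_hits <- function() {
  tibble::tibble(
    orf_id = character(), source = character(), annotation = list(),
    query_start = integer(), query_end = integer(), e_value = double()
  )
}

#' Read InterProScan TSV reports
#'
#' Collects, per row, every free-text annotation column that can carry a
#' protein-family description: the signature description, the InterPro
#' entry description, and GO/pathway annotation columns when present.
#' These strings are what downstream homing-endonuclease keyword matching
#' inspects. Rows with fewer than 11 columns are skipped with a warning.
#'
#' @param path Path to an InterProScan `.tsv` output file.
#' @return Tibble of domain hits: `orf_id`, `source` (`"interproscan"`),
#'   `annotation` (list-column of character vectors), `query_start`,
#'   `query_end`, `e_value` (the analysis score column when numeric).
#' @export
read_interproscan_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_domain_hits())
  }
  rows <- purrr::imap(lines, function(l, i) {
    tok <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 11L) {
      warning(sprintf(
        "%s: line %d has %d columns (< 11); row skipped", path, i, length(tok)
      ), call. = FALSE)
      return(NULL)
    }
    ann <- tok[c(6L, 13L, 14L, 15L)[c(6L, 13L, 14L, 15L) <= length(tok)]]
    ann <- ann[!is.na(ann) & nzchar(ann) & ann != "-"]
    if (length(ann) == 0L) ann <- character(0)
    tibble::tibble(
      orf_id = tok[1], source = "interproscan", annotation = list(ann),
      query_start = suppressWarnings(as.integer(tok[7])),
      query_end = suppressWarnings(as.integer(tok[8])),
      e_value = suppressWarnings(as.numeric(tok[9]))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0L) empty_domain_hits() else out
}

#' Read BLAST tabular reports with subject titles
#'
#' Expects BLAST `-outfmt "6 std stitle"` (or the commented variant 7):
#' the 12 standard columns followed by the subject title, which becomes
#' the annotation text used for endonuclease keyword matching. A file
#' whose rows carry only the 12 standard columns lacks the subject title
#' and is rejected with instructions.
#'
#' @param path Path to a BLAST tabular file.
#' @return Tibble of domain hits (same shape as [read_interproscan_tsv()],
#'   `source` = `"deltablast"`).
#' @export
read_blast_tabular <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_domain_hits())
  }
  rows <- purrr::imap(lines, function(l, i) {
    tok <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(tok) < 13L) {
      abort_fmt(
        paste0(
          path, ": line ", i, " has no subject-title column; ",
          "run BLAST with -outfmt \"6 std stitle\" (or 7) so titles are present"
        ),
        "intronforge_config_error"
      )
    }
    tibble::tibble(
      orf_id = tok[1], source = "deltablast",
      annotation = list(paste(tok[13:length(tok)], collapse = "\t")),
      query_start = suppressWarnings(as.integer(tok[7])),
      query_end = suppressWarnings(as.integer(tok[8])),
      e_value = suppressWarnings(as.numeric(tok[11]))
    )
  })
  dplyr::bind_rows(rows)
}

#' Read a Stockholm alignment with consensus annotation
#'
#' Minimal Stockholm 1.0 reader supporting interleaved blocks, per-column
#' `#=GC` annotation lines (e.g. `SS_cons` consensus structure and a
#' structural-element label line), and `//` termination.
#'
#' @param path Path to a Stockholm file.
#' @return List with `alignment` (named character vector of gapped rows),
#'   `ss_cons` (consensus structure string or `NA`), and `gc` (named list
#'   of all `#=GC` lines).
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  aln <- list()
  gc <- list()
  for (l in lines) {
    if (startsWith(l, "# STOCKHOLM") || trimws(l) == "//" || !nzchar(trimws(l))) next
    if (startsWith(l, "#=GC")) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      tag <- tok[2]
      gc[[tag]] <- paste0(gc[[tag]] %||% "", tok[3])
    } else if (startsWith(l, "#")) {
      next
    } else {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(tok) >= 2L) {
        aln[[tok[1]]] <- paste0(aln[[tok[1]]] %||% "", tok[2])
      }
    }
  }
  aln <- unlist(aln)
  if (length(aln) > 0L && length(unique(nchar(aln))) > 1L) {
    abort_fmt(
      sprintf("%s: alignment rows have unequal lengths", path),
      "intronforge_format_error"
    )
  }
  list(
    alignment = aln,
    ss_cons = gc[["SS_cons"]] %||% NA_character_,
    gc = gc
  )
}
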