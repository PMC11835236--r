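# Column schemas of the two database tables. Free-text columns are
# backslash-escaped on write so embedded tabs/newlines can never corrupt
# the column count.
INTRON_COLS <- c(
  intron_id = "c", genbank_id = "c", start_1based = "i", end_1based = "i",
  strand = "c", intron_seq = "c", exon5_seq = "c", exon3_seq = "c",
  boundary_source = "c", overlap_with_hit = "i", subtype = "c",
  subtype_score = "d", structural_elements = "c", organism = "c",
  taxid = "i", organism_category = "c", subcellular_location = "c",
  n_hegs = "i"
)

HEG_COLS <- c(
  heg_id = "c", intron_id = "c", start_in_intron = "i", end_in_intron = "i",
  frame = "i", strand = "c", genetic_code_id = "i", code_provenance = "c",
  evidence_source = "c", evidence_annotation = "c", peptide_seq = "c"
)

escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

unescape_field <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !grepl("\\", s, fixed = TRUE)) {
      return(s)
    }
    chars <- strsplit(s, "")[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt,
          "t" = "\t", "n" = "\n", "r" = "\r", "\\" = "\\",
          paste0("\\", nxt)
        ))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

format_tsv_table <- function(df, schema) {
  cells <- lapply(names(schema), function(col) {
    v <- df[[col]]
    if (schema[[col]] == "d") {
      out <- vapply(v, function(x) {
        if (is.na(x)) "" else format(x, scientific = FALSE, trim = TRUE, digits = 15)
      }, character(1))
    } else {
      out <- ifelse(is.na(v), "", escape_field(as.character(v)))
    }
    out
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  c(paste(names(schema), collapse = "\t"), body)
}

parse_tsv_table <- function(path, schema) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    abort_fmt(sprintf("%s: empty database file (no header)", path),
      "intronforge_format_error")
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, names(schema))) {
    abort_fmt(sprintf("%s: unexpected column header", path),
      "intronforge_format_error")
  }
  body <- lines[-1]
  cols <- lapply(seq_along(schema), function(j) character(length(body)))
  if (length(body) > 0L) {
    split_rows <- strsplit(body, "\t", fixed = TRUE)
    for (j in seq_along(schema)) {
      cols[[j]] <- vapply(split_rows, function(r) {
        if (j <= length(r)) r[j] else ""
      }, character(1))
    }
  }
  names(cols) <- names(schema)
  out <- purrr::imap(cols, function(v, col) {
    v[v == ""] <- NA_character_
    switch(schema[[col]],
      c = unescape_field(v),
      i = as.integer(v),
      d = as.numeric(v)
    )
  })
  tibble::as_tibble(out)
}

#' Write and read the intron/HEG database TSV pair
#'
#' The database is two plain TSV tables: one row per intron and one row
#' per putative homing endonuclease, linked by `intron_id`. Free-text
#' fields (organism names, evidence annotations) are backslash-escaped so
#' embedded tabs or newlines survive a round trip;
#' `read_database_tsv(write_database_tsv(...))` reproduces every field
#' exactly. Missing values are written as empty fields.
#'
#' @param introns Tibble of intron entries (see [refine_hits()] for the
#'   core columns; annotation stages add the rest — absent columns are
#'   written as missing).
#' @param hegs Tibble of HEG annotations (may be empty).
#' @param intron_path,heg_path Output file paths.
#' @return `write_database_tsv()` returns the paths invisibly;
#'   `read_database_tsv()` returns `list(introns =, hegs =)`.
#' @export
write_database_tsv <- function(introns, hegs, intron_path, heg_path) {
  introns <- complete_columns(introns, INTRON_COLS)
  hegs <- complete_columns(hegs, HEG_COLS)
  writeLines(format_tsv_table(introns, INTRON_COLS), intron_path)
  writeLines(format_tsv_table(hegs, HEG_COLS), heg_path)
  invisible(c(intron_path, heg_path))
}

#' @rdname write_database_tsv
#' @export
read_database_tsv <- function(intron_path, heg_path) {
  list(
    introns = parse_tsv_table(intron_path, INTRON_COLS),
    hegs = parse_tsv_table(heg_path, HEG_COLS)
  )
}

complete_columns <- function(df, schema) {
  for (col in names(schema)) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(schema[[col]],
        c = NA_character_, i = NA_integer_, d = NA_real_
      )
    }
  }
  df[names(schema)]
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (DNA or peptide sequences).
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (length(seqs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Documented command templates for the external tools
#'
#' The pipeline consumes the *outputs* of Infernal, InterProScan and
#' DELTA-BLAST; it never invokes them. These are the invocations whose
#' products the readers expect, for users preparing inputs themselves.
#'
#' @return Named character vector of shell command templates.
#' @export
external_command_templates <- function() {
  c(
    cmsearch = "cmsearch --nohmmonly -E 1000 -Z 1300000 --tblout {output_file} {cm_file} {nt_fasta_file}",
    cmscan = "cmscan --max --tblout {output_cmscan_file} {cm_database_file} {intron_fasta_file}",
    cmalign = "cmalign --ileaved --mxsize 900000 --nonbanded -o {output_alignment_file} {subtype_cm_file} {intron_fasta_file}",
    interproscan = "interproscan.sh -i {orf_peptides_fasta} -f tsv -o {output_tsv}",
    deltablast = "deltablast -query {orf_peptides_fasta} -db nr -rpsdb cdd_delta -outfmt \"7 std stitle\" -out {output_tsv}"
  )
}
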