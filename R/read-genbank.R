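#' Read GenBank flat files
#'
#' Parses one or more GenBank flat files (possibly multi-record) into a
#' tibble of records. Sequences are upper-cased; features keep their file
#' order; compound locations (`join`/`order`, with or without
#' `complement`) are decomposed into parts stored in ascending coordinate
#' order with a per-part strand. Features with coordinates outside the
#' record raise a warning and are dropped, never silently clamped.
#'
#' @param path Path(s) to GenBank flat files.
#' @return Tibble with one row per record: `entry_id` (VERSION, falling
#'   back to ACCESSION then LOCUS name), `length`, `organism`, `taxid`,
#'   `lineage` (semicolon-separated string, `NA` if absent), `definition`,
#'   `sequence`, and `features`, a list-column of per-record feature
#'   tibbles (`ftype`, `start`, `end`, `strand`, `compound`, `parts`
#'   list-column, `qualifiers` list-column).
#' @export
read_genbank <- function(path) {
  recs <- purrr::map(path, read_genbank_one)
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    return(empty_genbank())
  }
  out
}

empty_genbank <- function() {
  tibble::tibble(
    entry_id = character(), length = integer(), organism = character(),
    taxid = integer(), lineage = character(), definition = character(),
    sequence = character(), features = list()
  )
}

read_genbank_one <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(empty_genbank())
  }
  # Record boundaries: terminator lines "//"
  terms <- which(trimws(lines) == "//")
  starts <- c(1L, utils::head(terms, -1L) + 1L)
  if (length(terms) == 0L) {
    # tolerate a single unterminated record
    starts <- 1L
    terms <- length(lines) + 1L
  }
  recs <- purrr::map2(starts, terms, function(s, e) {
    chunk <- lines[s:(e - 1L)]
    if (all(!nzchar(trimws(chunk)))) {
      return(NULL)
    }
    parse_genbank_record(chunk, first_line = s, path = path)
  })
  dplyr::bind_rows(purrr::compact(recs))
}

parse_genbank_record <- function(lines, first_line, path) {
  locus_i <- which(startsWith(lines, "LOCUS"))
  if (length(locus_i) != 1L) {
    abort_fmt(
      sprintf("%s: missing or duplicated LOCUS line near line %d", path, first_line),
      "intronforge_format_error"
    )
  }
  locus_tok <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  if (length(locus_tok) < 3L || is.na(suppressWarnings(as.integer(locus_tok[3])))) {
    abort_fmt(
      sprintf("%s: malformed LOCUS line at line %d", path, first_line + locus_i - 1L),
      "intronforge_format_error"
    )
  }
  locus_name <- locus_tok[2]
  declared_len <- as.integer(locus_tok[3])

  keyword_of <- function(l) {
    if (grepl("^[A-Z]", l)) sub("^([A-Z]+).*", "\\1", l) else NA_character_
  }
  field_value <- function(kw) {
    i <- which(startsWith(lines, kw))
    if (length(i) == 0L) {
      return(NA_character_)
    }
    trimws(sub(sprintf("^%s\\s*", kw), "", lines[i[1]]))
  }

  accession <- strsplit(field_value("ACCESSION") %||% "", "\\s+")[[1]][1]
  version <- strsplit(field_value("VERSION") %||% "", "\\s+")[[1]][1]
  entry_id <- if (!is.na(version) && nzchar(version)) {
    version
  } else if (!is.na(accession) && nzchar(accession)) {
    accession
  } else {
    locus_name
  }
  definition <- field_value("DEFINITION")

  # ORGANISM: name on the keyword line, lineage on the indented lines below.
  org_i <- grep("^\\s{2}ORGANISM", lines)
  organism <- NA_character_
  lineage <- NA_character_
  if (length(org_i) > 0L) {
    organism <- trimws(sub("^\\s{2}ORGANISM\\s*", "", lines[org_i[1]]))
    j <- org_i[1] + 1L
    lin <- character(0)
    while (j <= length(lines) && grepl("^\\s{4,}\\S", lines[j]) &&
      !grepl("^[A-Z]", lines[j])) {
      lin <- c(lin, trimws(lines[j]))
      j <- j + 1L
    }
    if (length(lin) > 0L) {
      lineage <- sub("\\.$", "", paste(lin, collapse = " "))
    }
  }

  # Sequence: ORIGIN .. end of record.
  origin_i <- which(startsWith(lines, "ORIGIN"))
  sequence <- ""
  if (length(origin_i) > 0L) {
    seq_lines <- lines[(origin_i[1] + 1L):length(lines)]
    bad <- grepl("[^0-9A-Za-z* \t]", seq_lines) & nzchar(trimws(seq_lines))
    if (any(bad)) {
      abort_fmt(
        sprintf(
          "%s: malformed ORIGIN block at line %d",
          path, first_line + origin_i[1] + which(bad)[1] - 1L
        ),
        "intronforge_format_error"
      )
    }
    sequence <- toupper(gsub("[0-9 \t]", "", paste(seq_lines, collapse = "")))
  }
  seq_len_actual <- nchar(sequence)
  len <- if (seq_len_actual > 0L) seq_len_actual else declared_len
  if (seq_len_actual > 0L && seq_len_actual != declared_len) {
    warning(sprintf(
      "%s: LOCUS length %d != sequence length %d for %s; using sequence length",
      path, declared_len, seq_len_actual, entry_id
    ), call. = FALSE)
  }

  features <- parse_feature_table(lines, entry_id, len)

  tibble::tibble(
    entry_id = entry_id, length = len, organism = organism,
    taxid = feature_taxid(features), lineage = lineage,
    definition = definition, sequence = sequence, features = list(features)
  )
}

empty_features <- function() {
  tibble::tibble(
    ftype = character(), start = integer(), end = integer(),
    strand = character(), compound = logical(),
    parts = list(), qualifiers = list()
  )
}

parse_feature_table <- function(lines, entry_id, record_length) {
  fi <- which(startsWith(lines, "FEATURES"))
  if (length(fi) == 0L) {
    return(empty_features())
  }
  end_i <- which(startsWith(lines, "ORIGIN") |
    startsWith(lines, "BASE COUNT") | startsWith(lines, "CONTIG"))
  end_i <- if (length(end_i) > 0L) min(end_i[end_i > fi[1]]) else length(lines) + 1L
  body <- lines[(fi[1] + 1L):(end_i - 1L)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    return(empty_features())
  }

  # A key line has its feature key starting at column 6.
  is_key <- grepl("^\\s{5}\\S", body)
  key_idx <- which(is_key)
  if (length(key_idx) == 0L) {
    return(empty_features())
  }

  feats <- purrr::map(seq_along(key_idx), function(k) {
    from <- key_idx[k]
    to <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(body)
    chunk <- body[from:to]
    ftype <- trimws(substr(chunk[1], 6, 20))
    rest <- trimws(substr(chunk[1], 21, nchar(chunk[1])))
    cont <- if (length(chunk) > 1L) trimws(chunk[-1]) else character(0)
    # location may continue on lines until the first qualifier
    qual_start <- which(startsWith(cont, "/"))
    loc_extra <- if (length(qual_start) > 0L) {
      utils::head(cont, qual_start[1] - 1L)
    } else {
      cont
    }
    loc_str <- paste(c(rest, loc_extra), collapse = "")
    qual_lines <- if (length(qual_start) > 0L) {
      cont[qual_start[1]:length(cont)]
    } else {
      character(0)
    }
    parts <- tryCatch(parse_location(loc_str), error = function(e) NULL)
    if (is.null(parts) || nrow(parts) == 0L) {
      warning(sprintf(
        "%s: unparseable location '%s' for %s feature; feature dropped",
        entry_id, loc_str, ftype
      ), call. = FALSE)
      return(NULL)
    }
    if (any(parts$start < 1L | parts$end > record_length | parts$start > parts$end)) {
      warning(sprintf(
        "%s: %s feature location %s outside record of length %d; feature dropped",
        entry_id, ftype, loc_str, record_length
      ), call. = FALSE)
      return(NULL)
    }
    ord <- order(parts$start, parts$end)
    parts <- parts[ord, , drop = FALSE]
    strand <- if (all(parts$strand == "-")) "-" else "+"
    tibble::tibble(
      ftype = ftype, start = min(parts$start), end = max(parts$end),
      strand = strand, compound = nrow(parts) > 1L,
      parts = list(parts), qualifiers = list(parse_qualifiers(qual_lines))
    )
  })
  out <- dplyr::bind_rows(purrr::compact(feats))
  if (nrow(out) == 0L) empty_features() else out
}

# Recursive-descent parser for GenBank location strings. Partiality markers
# (< and >) are stripped; parts referring to other entries (acc:range) are
# rejected so the caller drops the feature with a warning.
parse_location <- function(s) {
  s <- gsub("\\s", "", s)
  s <- gsub("[<>]", "", s)
  if (grepl("^complement\\(", s)) {
    inner <- substr(s, nchar("complement(") + 1L, nchar(s) - 1L)
    parts <- parse_location(inner)
    parts$strand <- ifelse(parts$strand == "+", "-", "+")
    return(parts)
  }
  if (grepl("^(join|order)\\(", s)) {
    op_len <- if (startsWith(s, "join")) 5L else 6L
    inner <- substr(s, op_len + 1L, nchar(s) - 1L)
    pieces <- split_top_level(inner)
    return(dplyr::bind_rows(lapply(pieces, parse_location)))
  }
  if (grepl(":", s, fixed = TRUE)) {
    stop("remote location")
  }
  m <- regmatches(s, regexec("^(\\d+)\\.\\.(\\d+)$", s))[[1]]
  if (length(m) == 3L) {
    return(tibble::tibble(
      start = as.integer(m[2]), end = as.integer(m[3]), strand = "+"
    ))
  }
  if (grepl("^\\d+$", s)) {
    p <- as.integer(s)
    return(tibble::tibble(start = p, end = p, strand = "+"))
  }
  m <- regmatches(s, regexec("^(\\d+)[\\^.](\\d+)$", s))[[1]]
  if (length(m) == 3L) {
    return(tibble::tibble(
      start = as.integer(m[2]), end = as.integer(m[3]), strand = "+"
    ))
  }
  stop(sprintf("cannot parse location '%s'", s))
}

split_top_level <- function(s) {
  depth <- 0L
  cut <- integer(0)
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  vapply(seq_along(starts), function(i) {
    paste(chars[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

parse_qualifiers <- function(qual_lines) {
  if (length(qual_lines) == 0L) {
    return(list())
  }
  # Re-group continuation lines under their /qualifier line.
  grp <- cumsum(startsWith(qual_lines, "/"))
  quals <- list()
  for (g in unique(grp[grp > 0L])) {
    txt <- paste(qual_lines[grp == g], collapse = " ")
    m <- regmatches(txt, regexec("^/([^=]+)(=(.*))?$", txt))[[1]]
    name <- m[2]
    val <- if (nchar(m[3]) > 0L) gsub("^\"|\"$", "", m[4]) else TRUE
    if (is.character(val)) {
      quals[[name]] <- c(quals[[name]], val)
    } else {
      quals[[name]] <- TRUE
    }
  }
  quals
}

# taxid from the source feature's /db_xref="taxon:NNN"
feature_taxid <- function(features) {
  src <- which(features$ftype == "source")
  for (i in src) {
    dbx <- features$qualifiers[[i]][["db_xref"]]
    if (!is.null(dbx)) {
      hit <- grep("^taxon:", dbx, value = TRUE)
      if (length(hit) > 0L) {
        return(as.integer(sub("^taxon:", "", hit[1])))
      }
    }
  }
  NA_integer_
}
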