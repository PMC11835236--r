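# Brute-force ORF oracle: enumerates every (valid start codon, first
# in-frame stop) pair per frame and strand, keeps ORFs meeting the length
# floor, and collapses starts sharing a stop (or the open sequence end) to
# the earliest one. Independent of the scanning implementation in the
# package: works from explicit start/stop index sets.
oracle_orfs <- function(seq, code, min_aa) {
  if (!is.list(code)) code <- genetic_code(code)
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp_dna(seq)
    for (frame in 0:2) {
      n_cod <- (nchar(s) - frame) %/% 3L
      if (n_cod < 1L) next
      first_nt <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
      cods <- substring(s, first_nt, first_nt + 2L)
      start_idx <- which(cods %in% code$start_codons)
      stop_idx <- which(cods %in% code$stop_codons)
      # candidate ORFs: one per start
      cand <- data.frame(st = start_idx)
      if (nrow(cand) == 0L) next
      cand$stop <- vapply(cand$st, function(st) {
        after <- stop_idx[stop_idx > st]
        if (length(after) > 0L) min(after) else NA_integer_
      }, integer(1))
      # collapse shared stops (incl. the shared open end) to earliest start
      key <- ifelse(is.na(cand$stop), "open", as.character(cand$stop))
      keep <- unlist(lapply(split(seq_len(nrow(cand)), key), function(ix) {
        ix[which.min(cand$st[ix])]
      }))
      cand <- cand[sort(keep), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        st <- cand$st[r]
        has_stop <- !is.na(cand$stop[r])
        last <- if (has_stop) cand$stop[r] else n_cod
        aa <- if (has_stop) last - st else last - st + 1L
        if (aa < min_aa) next
        a <- frame + 3L * (st - 1L) + 1L
        b <- frame + 3L * last
        if (strand == "-") {
          tmp <- a
          a <- n - b + 1L
          b <- n - tmp + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          start = a, end = b, strand = strand, frame = frame,
          aa_length = aa, has_stop = has_stop
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      start = integer(), end = integer(), strand = character(),
      frame = integer(), aa_length = integer(), has_stop = logical()
    )
  }
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

orf_key_frame <- function(df) {
  df <- as.data.frame(df)[, c("start", "end", "strand", "frame", "aa_length", "has_stop")]
  rownames(df) <- NULL
  df[order(df$start, df$end, df$strand, df$frame), , drop = FALSE]
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Minimal in-code record builder for boundary tests: a record tibble row
# with arbitrary features, bypassing GenBank text.
make_record <- function(entry_id, sequence, features) {
  tibble::tibble(
    entry_id = entry_id, length = nchar(sequence), organism = "Testus testus",
    taxid = 1L, lineage = "Eukaryota; Fungi", definition = "test",
    sequence = sequence, features = list(features)
  )
}

make_feature <- function(ftype, parts, strand = "+", qualifiers = list()) {
  tibble::tibble(
    ftype = ftype, start = min(parts$start), end = max(parts$end),
    strand = strand, compound = nrow(parts) > 1L,
    parts = list(parts), qualifiers = list(qualifiers)
  )
}

parts_tbl <- function(starts, ends, strand = "+") {
  tibble::tibble(start = as.integer(starts), end = as.integer(ends), strand = strand)
}

fungal_context <- function() {
  tibble::tibble(
    subcellular_location = "mitochondria",
    nuclear_code = 1L, mito_code = 4L, plastid_code = NA_integer_
  )
}
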