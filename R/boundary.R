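#' Overlap between two closed integer ranges
#'
#' Number of positions shared by two 1-based inclusive ranges; 0 when they
#' are disjoint or merely adjacent. Vectorised and symmetric.
#'
#' @param start1,end1,start2,end2 Integer range bounds (1-based inclusive).
#' @return Non-negative integer vector of overlap sizes.
#' @export
#' @examples
#' compute_overlap(100, 300, 250, 400) # 51
compute_overlap <- function(start1, end1, start2, end2) {
  pmax(0L, pmin(end1, end2) - pmax(start1, start2) + 1L)
}

#' Extract candidate intron boundaries for a covariance-model hit
#'
#' Iterates a record's features in file order and collects candidate intron
#' ranges under two rules. (i) A feature of type `intron` whose span
#' overlaps the hit by at least `min_overlap` positions is a candidate
#' (`boundary_source = "intron_feature"`). (ii) For every compound-location
#' feature, each gap between consecutive parts — exclusive of the parts
#' themselves — overlapping the hit by at least `min_overlap` is a
#' candidate (`boundary_source = "compound_gap"`): regions between
#' annotated exons of a spliced gene are unannotated introns.
#'
#' @param features A record's feature tibble (as in [read_genbank()]).
#' @param hit_start,hit_end Hit range, 1-based inclusive.
#' @param min_overlap Minimum shared positions (default 50).
#' @return Tibble of candidates: `start`, `end`, `strand`,
#'   `boundary_source`, `overlap`, `feature_index` — in feature iteration
#'   order.
#' @export
extract_candidates <- function(features, hit_start, hit_end, min_overlap = 50) {
  cands <- list()
  for (i in seq_len(nrow(features))) {
    ftype <- features$ftype[i]
    parts <- features$parts[[i]]
    if (identical(ftype, "intron")) {
      ov <- compute_overlap(features$start[i], features$end[i], hit_start, hit_end)
      if (ov >= min_overlap) {
        cands[[length(cands) + 1L]] <- tibble::tibble(
          start = features$start[i], end = features$end[i],
          strand = features$strand[i], boundary_source = "intron_feature",
          overlap = ov, feature_index = i
        )
      }
    }
    if (isTRUE(features$compound[i]) && nrow(parts) > 1L) {
      for (k in seq_len(nrow(parts) - 1L)) {
        gs <- parts$end[k] + 1L
        ge <- parts$start[k + 1L] - 1L
        if (gs > ge) next
        ov <- compute_overlap(gs, ge, hit_start, hit_end)
        if (ov >= min_overlap) {
          cands[[length(cands) + 1L]] <- tibble::tibble(
            start = gs, end = ge, strand = features$strand[i],
            boundary_source = "compound_gap", overlap = ov, feature_index = i
          )
        }
      }
    }
  }
  if (length(cands) == 0L) {
    return(tibble::tibble(
      start = integer(), end = integer(), strand = character(),
      boundary_source = character(), overlap = integer(),
      feature_index = integer()
    ))
  }
  dplyr::bind_rows(cands)
}

#' Select the candidate with the largest overlap
#'
#' Argmax of overlap with the hit range; ties go to the candidate from the
#' earliest feature (smallest `feature_index`, then smallest `start`), so
#' selection is deterministic.
#'
#' @param candidates Candidate tibble from [extract_candidates()].
#' @return One-row tibble, or a zero-row tibble when there are no
#'   candidates.
#' @export
select_best_candidate <- function(candidates) {
  if (nrow(candidates) == 0L) {
    return(candidates)
  }
  candidates |>
    dplyr::arrange(dplyr::desc(.data$overlap), .data$feature_index, .data$start) |>
    dplyr::slice(1L)
}

#' Validate a candidate intron boundary
#'
#' Three checks, applied in order with the first failure reported:
#' the intron must not begin at the record's first position nor end at its
#' last (otherwise the flanking exonic context is unknown), and the intron
#' sequence must start with a U (T in DNA) — the nucleotide that forms the
#' conserved catalytic U-G pair. On the minus strand the initial base of
#' the reverse-complemented intron is checked. `u_check_position =
#' "before_range"` instead tests the last nucleotide of the preceding exon,
#' the alternative reading of where the conserved U sits.
#'
#' @param sequence Record sequence (plus strand).
#' @param start,end Candidate range, 1-based inclusive.
#' @param strand `"+"` or `"-"`.
#' @param u_check_position `"first_of_range"` (default) or `"before_range"`.
#' @return List with `ok` (logical) and `reason` (`NA` when accepted, else
#'   one of `"at_entry_start"`, `"at_entry_end"`, `"no_initial_U"`).
#' @export
validate_candidate <- function(sequence, start, end, strand = "+",
                               u_check_position = c("first_of_range", "before_range")) {
  u_check_position <- match.arg(u_check_position)
  n <- nchar(sequence)
  if (start <= 1L) {
    return(list(ok = FALSE, reason = "at_entry_start"))
  }
  if (end >= n) {
    return(list(ok = FALSE, reason = "at_entry_end"))
  }
  base <- if (strand == "+") {
    pos <- if (u_check_position == "first_of_range") start else start - 1L
    substr(sequence, pos, pos)
  } else {
    pos <- if (u_check_position == "first_of_range") end else end + 1L
    revcomp_dna(substr(sequence, pos, pos))
  }
  if (!identical(base, "T")) {
    return(list(ok = FALSE, reason = "no_initial_U"))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Extract flanking exonic context
#'
#' Up to `max_len` nucleotides on each side of an accepted intron,
#' truncated at the record edges. On the minus strand the contexts are
#' reverse-complemented and swapped so `exon5_seq` is always the exon
#' biologically upstream of the intron.
#'
#' @inheritParams validate_candidate
#' @param max_len Maximum context length per side (default 150).
#' @return List with `exon5_seq` and `exon3_seq`.
#' @export
extract_exonic_context <- function(sequence, start, end, strand = "+", max_len = 150) {
  n <- nchar(sequence)
  left <- substr(sequence, max(1L, start - max_len), start - 1L)
  right <- substr(sequence, end + 1L, min(n, end + max_len))
  if (strand == "+") {
    list(exon5_seq = left, exon3_seq = right)
  } else {
    list(exon5_seq = revcomp_dna(right), exon3_seq = revcomp_dna(left))
  }
}

#' Refine covariance-model hits into validated intron boundaries
#'
#' The full boundary pipeline, per hit: candidate extraction from the
#' target record's features, largest-overlap selection, boundary
#' validation, exonic-context extraction. Hits are accounted for
#' exhaustively: every input hit ends up either as an accepted intron or
#' in the rejected table with a reason (`no_candidate`, `missing_record`,
#' `at_entry_start`, `at_entry_end`, `no_initial_U`, or
#' `duplicate_boundary` when deduplication is on and several hits resolve
#' to the same boundaries).
#'
#' @param records Records tibble from [read_genbank()].
#' @param hits Hits tibble from [read_tblout()].
#' @param min_overlap Minimum hit/candidate overlap (default 50).
#' @param max_context Maximum exonic context per side (default 150).
#' @param u_check_position See [validate_candidate()].
#' @param dedupe_identical_boundaries Drop all but the first hit resolving
#'   to identical boundaries (default `TRUE`).
#' @return Object of class `intron_refinement`: a list with `introns`
#'   (accepted entries; `intron_id` ordinals are 1-based in ascending
#'   start order within each entry), `rejected` (hit + `reason`), and
#'   `params`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
refine_hits <- function(records, hits, min_overlap = 50, max_context = 150,
                        u_check_position = "first_of_range",
                        dedupe_identical_boundaries = TRUE) {
  rec_index <- match(hits$target_id, records$entry_id)
  accepted <- list()
  rejected <- list()
  reject <- function(i, reason) {
    tibble::tibble(
      target_id = hits$target_id[i], model_name = hits$model_name[i],
      hit_start = hits$start[i], hit_end = hits$end[i],
      strand = hits$strand[i], reason = reason
    )
  }
  for (i in seq_len(nrow(hits))) {
    ri <- rec_index[i]
    if (is.na(ri)) {
      rejected[[length(rejected) + 1L]] <- reject(i, "missing_record")
      next
    }
    cands <- extract_candidates(
      records$features[[ri]], hits$start[i], hits$end[i], min_overlap
    )
    if (nrow(cands) == 0L) {
      rejected[[length(rejected) + 1L]] <- reject(i, "no_candidate")
      next
    }
    best <- select_best_candidate(cands)
    seqn <- records$sequence[[ri]]
    v <- validate_candidate(seqn, best$start, best$end, best$strand, u_check_position)
    if (!v$ok) {
      rejected[[length(rejected) + 1L]] <- reject(i, v$reason)
      next
    }
    ctx <- extract_exonic_context(seqn, best$start, best$end, best$strand, max_context)
    iseq <- substr(seqn, best$start, best$end)
    if (best$strand == "-") iseq <- revcomp_dna(iseq)
    accepted[[length(accepted) + 1L]] <- tibble::tibble(
      genbank_id = records$entry_id[[ri]],
      start_1based = best$start, end_1based = best$end, strand = best$strand,
      intron_seq = iseq, exon5_seq = ctx$exon5_seq, exon3_seq = ctx$exon3_seq,
      boundary_source = best$boundary_source, overlap_with_hit = best$overlap,
      hit_index = i
    )
  }
  introns <- dplyr::bind_rows(accepted)
  rejected <- dplyr::bind_rows(rejected)
  if (nrow(introns) > 0L && dedupe_identical_boundaries) {
    dup <- duplicated(introns[, c("genbank_id", "start_1based", "end_1based", "strand")])
    if (any(dup)) {
      dup_idx <- introns$hit_index[dup]
      rejected <- dplyr::bind_rows(
        rejected,
        dplyr::bind_rows(lapply(dup_idx, reject, reason = "duplicate_boundary"))
      )
      introns <- introns[!dup, , drop = FALSE]
    }
  }
  if (nrow(introns) > 0L) {
    introns <- introns |>
      dplyr::group_by(.data$genbank_id) |>
      dplyr::arrange(.data$start_1based, .by_group = TRUE) |>
      dplyr::mutate(intron_id = paste0(
        .data$genbank_id, "_", dplyr::row_number()
      )) |>
      dplyr::ungroup() |>
      dplyr::select(-"hit_index") |>
      dplyr::relocate("intron_id")
  } else {
    introns <- tibble::tibble(
      intron_id = character(), genbank_id = character(),
      start_1based = integer(), end_1based = integer(), strand = character(),
      intron_seq = character(), exon5_seq = character(),
      exon3_seq = character(), boundary_source = character(),
      overlap_with_hit = integer()
    )
  }
  if (nrow(rejected) == 0L) {
    rejected <- tibble::tibble(
      target_id = character(), model_name = character(),
      hit_start = integer(), hit_end = integer(), strand = character(),
      reason = character()
    )
  }
  structure(
    list(
      introns = introns, rejected = rejected,
      params = list(
        min_overlap = min_overlap, max_context = max_context,
        u_check_position = u_check_position,
        dedupe_identical_boundaries = dedupe_identical_boundaries,
        n_hits = nrow(hits)
      )
    ),
    class = "intron_refinement"
  )
}

#' @export
print.intron_refinement <- function(x, ...) {
  cat(sprintf(
    "<intron_refinement> %d hits -> %d accepted introns, %d rejected\n",
    x$params$n_hits, nrow(x$introns), nrow(x$rejected)
  ))
  if (nrow(x$rejected) > 0L) {
    tab <- table(x$rejected$reason)
    cat("rejections:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidiers for refinement results
#'
#' `tidy()` returns the accepted intron table (or the rejected table with
#' `which = "rejected"`); `glance()` returns a one-row summary with hit
#' and acceptance counts and per-reason rejection tallies.
#'
#' @param x An `intron_refinement` object from [refine_hits()].
#' @param which `"introns"` or `"rejected"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.intron_refinement <- function(x, which = c("introns", "rejected"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.intron_refinement
#' @export
glance.intron_refinement <- function(x, ...) {
  reasons <- c(
    "no_candidate", "missing_record", "at_entry_start", "at_entry_end",
    "no_initial_U", "duplicate_boundary"
  )
  counts <- vapply(reasons, function(r) sum(x$rejected$reason == r), integer(1))
  tibble::tibble(
    n_hits = x$params$n_hits,
    n_accepted = nrow(x$introns),
    n_rejected = nrow(x$rejected),
    !!!rlang::set_names(as.list(counts), paste0("rejected_", reasons))
  )
}
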