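#' Specification for synthetic pipeline fixtures
#'
#' Describes a seeded cohort of synthetic GenBank records with one planted
#' group I intron each, plus the matching mock external-tool outputs
#' (Infernal tblout, cmscan subtype scores, InterProScan/DELTA-BLAST
#' evidence, taxonomy table) and a ground-truth manifest. Defaults model a
#' fungal mitochondrial cohort (the classic HEG-rich habitat): introns of
#' 500-1200 nt flanked by 200-400 nt exons, every intron starting with the
#' conserved U, hits jittered up to 30 nt around the planted boundaries —
#' safely above the 50-position overlap rule.
#'
#' @param seed Integer RNG seed; fixture sets are byte-identical per seed.
#' @param n_records Number of records (one planted intron each).
#' @param intron_length,exon_length Length ranges `c(min, max)` in nt.
#' @param boundary_pathway `"intron_feature"`, `"compound_gap"`, or
#'   `"both"` (alternating).
#' @param fraction_u_start Probability the planted intron starts with U.
#' @param fraction_minus Probability a record's intron lies on the minus
#'   strand.
#' @param plant_heg Plant a homing-endonuclease-sized ORF (with mock
#'   domain evidence) in each U-starting intron?
#' @param heg_code NCBI table id the planted ORF is stop-scrubbed under.
#' @param heg_aa ORF length range in amino acids (excluding stop).
#' @param heg_evidence `"interproscan"` or `"deltablast"` — which mock
#'   evidence file carries the endonuclease annotation.
#' @param subtypes Subtype names used for mock cmscan scores.
#' @param organism List: `taxid`, `name`, `lineage`, `location`
#'   (`"nucleus"`, `"mitochondria"`, `"plastid"`, `"n/a"`),
#'   `nuclear_code`, `mito_code`, `plastid_code`.
#' @param edge_cases Plant three deliberate rejection records (intron at
#'   the entry start, at the entry end, and a sub-threshold overlap)?
#' @param hit_jitter Maximum absolute jitter of hit bounds in nt.
#' @param min_overlap Overlap rule the fixtures must stay above.
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_records = 20,
                         intron_length = c(500, 1200),
                         exon_length = c(200, 400),
                         boundary_pathway = c("both", "intron_feature", "compound_gap"),
                         fraction_u_start = 1, fraction_minus = 0,
                         plant_heg = FALSE, heg_code = 4,
                         heg_aa = c(130, 160),
                         heg_evidence = c("interproscan", "deltablast"),
                         subtypes = c("IA1", "IB4", "IC1", "IC2", "IC3"),
                         organism = NULL,
                         edge_cases = FALSE, hit_jitter = 30, min_overlap = 50) {
  boundary_pathway <- match.arg(boundary_pathway)
  heg_evidence <- match.arg(heg_evidence)
  organism <- organism %||% list(
    taxid = 93612L, name = "Exserohilum exemplum",
    lineage = "Eukaryota; Fungi; Ascomycota; Dothideomycetes; Pleosporales",
    location = "mitochondria",
    nuclear_code = 1L, mito_code = 4L, plastid_code = NA_integer_
  )
  spec <- list(
    seed = as.integer(seed), n_records = as.integer(n_records),
    intron_length = as.integer(intron_length),
    exon_length = as.integer(exon_length),
    boundary_pathway = boundary_pathway,
    fraction_u_start = fraction_u_start, fraction_minus = fraction_minus,
    plant_heg = isTRUE(plant_heg), heg_code = as.integer(heg_code),
    heg_aa = as.integer(heg_aa), heg_evidence = heg_evidence,
    subtypes = subtypes, organism = organism,
    edge_cases = isTRUE(edge_cases), hit_jitter = as.integer(hit_jitter),
    min_overlap = as.integer(min_overlap)
  )
  if (spec$fraction_u_start < 0 || spec$fraction_u_start > 1 ||
    spec$fraction_minus < 0 || spec$fraction_minus > 1) {
    abort_fmt("fractions must lie in [0, 1]", "intronforge_config_error")
  }
  if (any(spec$intron_length <= 0) || any(spec$exon_length <= 0)) {
    abort_fmt("length ranges must be positive", "intronforge_config_error")
  }
  if (spec$intron_length[1] - 2L * spec$hit_jitter < spec$min_overlap) {
    abort_fmt(
      "shortest intron minus twice the hit jitter falls below the overlap rule",
      "intronforge_config_error"
    )
  }
  if (spec$plant_heg &&
    spec$intron_length[1] < 3L * (spec$heg_aa[2] + 2L) + 12L) {
    abort_fmt(
      "introns too short to host the planted ORF",
      "intronforge_config_error"
    )
  }
  structure(spec, class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A stop-scrubbed ORF cassette under `code`: in-frame stop, start codon,
# aa-1 non-stop codons, stop codon. Guarantees the ORF is detected exactly
# at its planted start (the leading stop blocks upstream extension).
orf_cassette <- function(aa, code) {
  all64 <- names(code$codons)
  body <- sample(setdiff(all64, code$stop_codons), aa - 1L, replace = TRUE)
  stopc <- code$stop_codons[1]
  list(
    cassette = paste(c(stopc, "ATG", body, stopc), collapse = ""),
    orf_offset = 3L, # ORF begins after the leading stop codon
    orf_nt = 3L * (aa + 1L) # ATG..stop inclusive
  )
}

#' Generate a synthetic fixture set
#'
#' Writes, under `out_dir`: `records.gbk` (annotated GenBank records with
#' the planted exon-intron-exon structure), `hits.tbl` (Infernal-style
#' tblout with jittered hit ranges), `scans.tbl` (mock per-subtype cmscan
#' scores), `interproscan.tsv` / `blast.tsv` (mock domain evidence for
#' planted ORFs), `taxonomy.tsv`, and `truth.tsv` (the ground-truth
#' manifest). Fully reproducible: the same spec yields byte-identical
#' files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `truth` (manifest tibble) and `files`
#'   (named paths).
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, generate_fixtures_impl(spec, out_dir))
}

generate_fixtures_impl <- function(spec, out_dir) {
  org <- spec$organism
  context <- tibble::tibble(
    subcellular_location = org$location,
    nuclear_code = org$nuclear_code, mito_code = org$mito_code,
    plastid_code = org$plastid_code
  )
  heg_gc <- get_code(spec$heg_code)

  gbk_lines <- character(0)
  hit_lines <- tblout_header("cmsearch")
  scan_lines <- tblout_header("cmscan")
  ipr_lines <- character(0)
  blast_lines <- character(0)
  truth <- list()

  for (i in seq_len(spec$n_records)) {
    entry_id <- sprintf("SYN%06d.1", i)
    case <- if (spec$edge_cases && i <= 3L) {
      c("at_entry_start", "at_entry_end", "sub_threshold")[i]
    } else {
      "normal"
    }
    pathway <- switch(spec$boundary_pathway,
      both = if (i %% 2L == 1L) "intron_feature" else "compound_gap",
      spec$boundary_pathway
    )
    # entry-edge introns leave no room for a flanking exon part, so the
    # compound-location encoding is impossible for them
    if (case %in% c("at_entry_start", "at_entry_end")) pathway <- "intron_feature"
    exon5 <- sample(spec$exon_length[1]:spec$exon_length[2], 1L)
    exon3 <- sample(spec$exon_length[1]:spec$exon_length[2], 1L)
    ilen <- sample(spec$intron_length[1]:spec$intron_length[2], 1L)
    if (case == "at_entry_start") exon5 <- 0L
    if (case == "at_entry_end") exon3 <- 0L
    strand <- if (stats::runif(1) < spec$fraction_minus) "-" else "+"
    u_start <- stats::runif(1) < spec$fraction_u_start

    # biological intron sequence (intron orientation)
    iseq <- random_dna(ilen)
    first <- if (u_start) "T" else sample(c("A", "C", "G"), 1L)
    substr(iseq, 1L, 1L) <- first

    orf_start <- NA_integer_
    orf_end <- NA_integer_
    plant_this <- spec$plant_heg && u_start && case == "normal"
    if (plant_this) {
      aa <- sample(spec$heg_aa[1]:spec$heg_aa[2], 1L)
      cas <- orf_cassette(aa, heg_gc)
      cas_len <- nchar(cas$cassette)
      # keep the conserved first base and a margin at both ends
      off <- sample(7L:(ilen - cas_len - 3L), 1L)
      substr(iseq, off, off + cas_len - 1L) <- cas$cassette
      orf_start <- off + cas$orf_offset
      orf_end <- orf_start + cas$orf_nt - 1L
      substr(iseq, 1L, 1L) <- first # cassette never reaches position 1
    }

    L <- exon5 + ilen + exon3
    istart <- exon5 + 1L
    iend <- exon5 + ilen
    record_seq <- random_dna(L)
    ins <- if (strand == "+") iseq else revcomp_dna(iseq)
    substr(record_seq, istart, iend) <- ins

    # expected pipeline outcome
    expected <- if (case == "at_entry_start") {
      "at_entry_start"
    } else if (case == "at_entry_end") {
      "at_entry_end"
    } else if (case == "sub_threshold") {
      "no_candidate"
    } else if (!u_start) {
      "no_initial_U"
    } else {
      "accepted"
    }
    intron_id <- if (expected == "accepted") paste0(entry_id, "_1") else NA_character_
    subtype <- sample(spec$subtypes, 1L)

    gbk_lines <- c(gbk_lines, format_gbk_record(
      entry_id, record_seq, org, istart, iend, strand, pathway
    ))

    # jittered hit; sub-threshold case deliberately overlaps < min_overlap
    if (case == "sub_threshold") {
      hs <- iend - spec$min_overlap + 2L
      he <- min(L, iend + 120L)
      # overlap with the annotated intron is exactly min_overlap - 1
    } else {
      hs <- max(1L, istart + sample(-spec$hit_jitter:spec$hit_jitter, 1L))
      he <- min(L, iend + sample(-spec$hit_jitter:spec$hit_jitter, 1L))
    }
    hit_lines <- c(hit_lines, format_tblout_line(
      target = entry_id, model = "Intron_gpI", from = hs, to = he,
      strand = "+", score = round(stats::runif(1, 40, 90), 1),
      e_value = "1.2e-10"
    ))

    if (expected == "accepted") {
      win <- round(stats::runif(1, 70, 95), 1)
      scan_lines <- c(scan_lines, format_tblout_line(
        target = subtype, model = intron_id, from = 1L, to = ilen,
        strand = "+", score = win, e_value = "3.1e-12", format = "cmscan"
      ))
      decoy <- sample(setdiff(spec$subtypes, subtype), 1L)
      scan_lines <- c(scan_lines, format_tblout_line(
        target = decoy, model = intron_id, from = 1L, to = ilen,
        strand = "+", score = round(win - stats::runif(1, 10, 30), 1),
        e_value = "4.0e-04", format = "cmscan"
      ))
    }

    orf_id_evid <- NA_character_
    if (plant_this) {
      # evidence must name the pruned ORF covering the planted span
      orfs <- enumerate_orfs(iseq, intron_id, context)
      cover <- which(orfs$strand == "+" & orfs$start <= orf_start &
        orfs$end >= orf_end)
      if (length(cover) > 0L) {
        orf_id_evid <- orfs$orf_id[cover[1]]
        aa_len <- orfs$aa_length[cover[1]]
        if (spec$heg_evidence == "interproscan") {
          ipr_lines <- c(ipr_lines, paste(
            c(
              orf_id_evid, "md5", aa_len, "Pfam", "PF00961",
              "LAGLIDADG catalytic domain homing endonuclease",
              "5", as.character(max(10L, aa_len - 5L)), "1.2E-30", "T",
              "01-01-2024", "IPR004860", "Homing endonuclease, LAGLIDADG"
            ),
            collapse = "\t"
          ))
        } else {
          blast_lines <- c(blast_lines, paste(
            c(
              orf_id_evid, "WP_000001.1", "48.2", as.character(aa_len), "60",
              "2", "1", as.character(aa_len), "10",
              as.character(aa_len + 9L), "2e-40", "180",
              "LAGLIDADG family homing endonuclease"
            ),
            collapse = "\t"
          ))
        }
      }
    }

    truth[[i]] <- tibble::tibble(
      entry_id = entry_id, intron_id = intron_id,
      intron_start = istart, intron_end = iend, strand = strand,
      pathway = pathway, u_start = u_start, expected = expected,
      subtype = if (expected == "accepted") subtype else NA_character_,
      heg_planted = plant_this && !is.na(orf_id_evid),
      orf_start_in_intron = orf_start, orf_end_in_intron = orf_end,
      heg_code = if (plant_this) spec$heg_code else NA_integer_
    )
  }

  files <- list(
    genbank = file.path(out_dir, "records.gbk"),
    tblout = file.path(out_dir, "hits.tbl"),
    cmscan = file.path(out_dir, "scans.tbl"),
    interproscan = file.path(out_dir, "interproscan.tsv"),
    blast = file.path(out_dir, "blast.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  writeLines(gbk_lines, files$genbank)
  writeLines(hit_lines, files$tblout)
  writeLines(scan_lines, files$cmscan)
  writeLines(ipr_lines, files$interproscan)
  writeLines(blast_lines, files$blast)
  writeLines(c(
    "taxid\tname\tlineage\tnuclear_code\tmito_code\tplastid_code",
    paste(
      c(
        org$taxid, org$name, org$lineage, org$nuclear_code,
        ifelse(is.na(org$mito_code), "", org$mito_code),
        ifelse(is.na(org$plastid_code), "", org$plastid_code)
      ),
      collapse = "\t"
    )
  ), files$taxonomy)
  truth_tbl <- dplyr::bind_rows(truth)
  readr::write_tsv(truth_tbl, files$truth, progress = FALSE)
  invisible(list(truth = truth_tbl, files = files, spec = spec))
}

tblout_header <- function(format) {
  c(
    "#target name         accession query name           accession mdl mdl from   mdl to seq from   seq to strand trunc pass   gc  bias  score   E-value inc description of target",
    "#------------------- --------- -------------------- --------- --- -------- -------- -------- -------- ------ ----- ---- ---- ----- ------ --------- --- ---------------------"
  )
}

format_tblout_line <- function(target, model, from, to, strand, score,
                               e_value, format = "cmsearch") {
  paste(
    sprintf("%-20s", target), "-", sprintf("%-20s", model), "-", "cm",
    "1", "250", from, to, strand, "no", "1", "0.50", "0.0",
    sprintf("%6.1f", score), e_value, "!", "synthetic fixture",
    sep = " "
  )
}

format_gbk_record <- function(entry_id, seq, org, istart, iend, strand, pathway) {
  L <- nchar(seq)
  accession <- sub("\\.\\d+$", "", entry_id)
  loc <- function(s, e) sprintf("%d..%d", s, e)
  wrap_strand <- function(x) if (strand == "-") sprintf("complement(%s)", x) else x
  feat <- character(0)
  if (pathway == "intron_feature") {
    feat <- c(
      sprintf("     %-16s%s", "gene", wrap_strand(loc(1, L))),
      "                     /gene=\"cob\"",
      sprintf("     %-16s%s", "intron", wrap_strand(loc(istart, iend))),
      "                     /note=\"group I intron\""
    )
  } else {
    feat <- c(
      sprintf("     %-16s%s", "gene", wrap_strand(loc(1, L))),
      "                     /gene=\"cob\"",
      sprintf(
        "     %-16s%s", "CDS",
        wrap_strand(sprintf(
          "join(%s,%s)", loc(1, istart - 1L), loc(iend + 1L, L)
        ))
      ),
      "                     /gene=\"cob\"",
      "                     /product=\"cytochrome b\""
    )
  }
  organelle_q <- switch(org$location,
    mitochondria = "                     /organelle=\"mitochondrion\"",
    plastid = "                     /organelle=\"plastid:chloroplast\"",
    NULL
  )
  seq_lines <- format_origin(seq)
  c(
    sprintf("LOCUS       %-17s%d bp    DNA     linear   SYN 01-JAN-2024", accession, L),
    sprintf("DEFINITION  %s synthetic fixture record.", org$name),
    sprintf("ACCESSION   %s", accession),
    sprintf("VERSION     %s", entry_id),
    sprintf("SOURCE      %s", org$name),
    sprintf("  ORGANISM  %s", org$name),
    sprintf("            %s.", org$lineage),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", loc(1, L)),
    sprintf("                     /organism=\"%s\"", org$name),
    "                     /mol_type=\"genomic DNA\"",
    organelle_q,
    sprintf("                     /db_xref=\"taxon:%d\"", org$taxid),
    feat,
    "ORIGIN",
    seq_lines,
    "//"
  )
}

format_origin <- function(seq) {
  seq <- tolower(seq)
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(n, s + 59L))
    groups <- substring(chunk, seq.int(1L, nchar(chunk), 10L),
      pmin(nchar(chunk), seq.int(10L, nchar(chunk) + 9L, 10L)))
    sprintf("%9d %s", s, paste(groups, collapse = " "))
  }, character(1))
}
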