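#' Pipeline configuration
#'
#' Collects paths and tunables for [build_db()]. Defaults are the
#' pipeline's standard constants: a 50-position minimum overlap between a
#' hit and a candidate boundary, up to 150 nt of exonic context per side,
#' and a 120 amino-acid floor for candidate homing-endonuclease ORFs.
#'
#' @param genbank Path(s) to GenBank flat files.
#' @param tblout Path to the Infernal cmsearch `--tblout` file.
#' @param out_dir Output directory for the database files.
#' @param taxonomy Optional taxonomy TSV path ([read_taxonomy()]).
#' @param cmscan Optional cmscan `--tblout` path with per-subtype scores.
#' @param alignments Optional named character vector (by subtype) of
#'   Stockholm alignment paths for structural-element annotation.
#' @param interproscan,blast Optional domain-evidence file paths.
#' @param min_overlap,max_context,min_aa Numeric constants (see above).
#' @param u_check_position See [validate_candidate()].
#' @param keywords HEG keyword stems (default `endonuc`, `homing`,
#'   `nuclease`).
#' @param category_rules Organism-category rules tibble.
#' @param dedupe_identical_boundaries See [refine_hits()].
#' @param codes Genetic-code table ids scanned for ORFs.
#' @param blast_evalue_max Optional E-value ceiling on BLAST evidence.
#' @param quiet Suppress per-stage progress messages?
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genbank, tblout, out_dir,
                            taxonomy = NULL, cmscan = NULL, alignments = NULL,
                            interproscan = NULL, blast = NULL,
                            min_overlap = 50, max_context = 150, min_aa = 120,
                            u_check_position = "first_of_range",
                            keywords = HEG_KEYWORDS,
                            category_rules = default_category_rules(),
                            dedupe_identical_boundaries = TRUE,
                            codes = known_code_tables(),
                            blast_evalue_max = NULL, quiet = FALSE) {
  if (min_overlap <= 0 || max_context <= 0 || min_aa <= 0) {
    abort_fmt(
      "min_overlap, max_context and min_aa must be positive",
      "intronforge_config_error"
    )
  }
  structure(
    list(
      genbank = genbank, tblout = tblout, out_dir = out_dir,
      taxonomy = taxonomy, cmscan = cmscan, alignments = alignments,
      interproscan = interproscan, blast = blast,
      min_overlap = min_overlap, max_context = max_context, min_aa = min_aa,
      u_check_position = u_check_position, keywords = keywords,
      category_rules = category_rules,
      dedupe_identical_boundaries = dedupe_identical_boundaries,
      codes = codes, blast_evalue_max = blast_evalue_max, quiet = quiet
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; an
#' `organism_categories` block (ordered `pattern: category` maps) becomes
#' the category rule table.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$organism_categories)) {
    y$category_rules <- dplyr::bind_rows(lapply(y$organism_categories, function(r) {
      tibble::tibble(pattern = names(r), category = unname(unlist(r)))
    }))
    y$organism_categories <- NULL
  }
  missing_req <- setdiff(c("genbank", "tblout", "out_dir"), names(y))
  if (length(missing_req) > 0L) {
    abort_fmt(
      sprintf("config is missing required keys: %s", paste(missing_req, collapse = ", ")),
      "intronforge_config_error"
    )
  }
  do.call(pipeline_config, y)
}

stage_msg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

require_input <- function(path, stage) {
  missing <- path[!file.exists(path)]
  if (length(missing) > 0L) {
    abort_fmt(
      sprintf("stage '%s': missing input file(s): %s", stage,
        paste(missing, collapse = ", ")),
      "intronforge_input_error"
    )
  }
}

#' Build the intron/HEG database
#'
#' One-shot orchestration of all stages: read GenBank records and Infernal
#' hits, refine and validate intron boundaries, assign subtypes from
#' cmscan scores, map structural elements from subtype alignments, attach
#' organism metadata, enumerate candidate ORFs under all genetic codes and
#' call putative homing endonucleases from InterProScan (with DELTA-BLAST
#' fallback) evidence. Writes `introns.tsv`, `hegs.tsv`, `rejected.tsv`,
#' `introns.fasta`, `orfs.fasta` (candidate ORF peptides, for feeding the
#' external annotation tools) and `report.json` (stage-by-stage counts)
#' under the configured output directory. Fully deterministic: the same
#' inputs yield byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `intron_db`: list with `introns`, `hegs`,
#'   `rejected`, `orfs`, `report`, `files`. Use [tidy()]/[glance()].
#' @export
build_db <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  q <- config$quiet
  require_input(config$genbank, "read_genbank")
  require_input(config$tblout, "read_tblout")

  t0 <- proc.time()[["elapsed"]]
  records <- read_genbank(config$genbank)
  hits <- read_tblout(config$tblout)
  stage_msg(q, "inputs: %d records, %d hits (%.2fs)",
    nrow(records), nrow(hits), proc.time()[["elapsed"]] - t0)

  t0 <- proc.time()[["elapsed"]]
  ref <- refine_hits(
    records, hits,
    min_overlap = config$min_overlap, max_context = config$max_context,
    u_check_position = config$u_check_position,
    dedupe_identical_boundaries = config$dedupe_identical_boundaries
  )
  introns <- ref$introns
  stage_msg(q, "boundaries: %d accepted, %d rejected (%.2fs)",
    nrow(introns), nrow(ref$rejected), proc.time()[["elapsed"]] - t0)

  if (!is.null(config$cmscan)) {
    require_input(config$cmscan, "subtype_classification")
    scans <- read_tblout(config$cmscan, format = "cmscan")
    introns <- dplyr::left_join(introns, assign_subtypes(scans), by = "intron_id")
  } else {
    introns$subtype <- NA_character_
    introns$subtype_score <- NA_real_
  }
  stage_msg(q, "subtypes: %d classified", sum(!is.na(introns$subtype)))

  if (!is.null(config$alignments)) {
    require_input(unlist(config$alignments), "structural_elements")
    alns <- lapply(config$alignments, read_stockholm)
    introns <- annotate_elements(introns, alns)
  } else {
    introns$structural_elements <- NA_character_
  }

  taxonomy <- NULL
  if (!is.null(config$taxonomy)) {
    require_input(config$taxonomy, "annotate_metadata")
    taxonomy <- read_taxonomy(config$taxonomy)
  }
  introns <- annotate_metadata(introns, records, taxonomy, config$category_rules)

  t0 <- proc.time()[["elapsed"]]
  interpro <- if (!is.null(config$interproscan)) {
    require_input(config$interproscan, "heg_annotation")
    read_interproscan_tsv(config$interproscan)
  } else {
    empty_domain_hits()
  }
  blast <- if (!is.null(config$blast)) {
    require_input(config$blast, "heg_annotation")
    read_blast_tabular(config$blast)
  } else {
    empty_domain_hits()
  }
  orf_list <- list()
  heg_list <- list()
  for (i in seq_len(nrow(introns))) {
    context <- introns[i, c(
      "subcellular_location", "nuclear_code", "mito_code", "plastid_code"
    )]
    orfs <- enumerate_orfs(
      introns$intron_seq[i], introns$intron_id[i], context,
      codes = config$codes, min_aa = config$min_aa
    )
    orf_list[[length(orf_list) + 1L]] <- orfs
    heg_list[[length(heg_list) + 1L]] <- annotate_hegs(
      introns$intron_seq[i], introns$intron_id[i], context,
      interpro, blast,
      codes = config$codes, min_aa = config$min_aa,
      keywords = config$keywords, blast_evalue_max = config$blast_evalue_max,
      orfs = orfs
    )
  }
  all_orfs <- dplyr::bind_rows(orf_list)
  if (nrow(all_orfs) == 0L) {
    all_orfs <- empty_orfs()
    all_orfs$orf_id <- character(0)
  }
  hegs <- dplyr::bind_rows(heg_list)
  if (nrow(hegs) == 0L) hegs <- empty_hegs()
  stage_msg(q, "HEGs: %d ORFs, %d putative HEGs in %d introns (%.2fs)",
    nrow(all_orfs), nrow(hegs), length(unique(hegs$intron_id)),
    proc.time()[["elapsed"]] - t0)

  heg_counts <- if (nrow(hegs) > 0L) {
    dplyr::count(hegs, .data$intron_id, name = "n_hegs")
  } else {
    tibble::tibble(intron_id = character(), n_hegs = integer())
  }
  introns <- introns |>
    dplyr::left_join(heg_counts, by = "intron_id") |>
    dplyr::mutate(n_hegs = dplyr::coalesce(.data$n_hegs, 0L))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- list(
    introns = file.path(config$out_dir, "introns.tsv"),
    hegs = file.path(config$out_dir, "hegs.tsv"),
    rejected = file.path(config$out_dir, "rejected.tsv"),
    introns_fasta = file.path(config$out_dir, "introns.fasta"),
    orfs_fasta = file.path(config$out_dir, "orfs.fasta"),
    report = file.path(config$out_dir, "report.json")
  )
  write_database_tsv(introns, hegs, files$introns, files$hegs)
  readr::write_tsv(ref$rejected, files$rejected, progress = FALSE)
  write_fasta(
    rlang::set_names(introns$intron_seq, introns$intron_id),
    files$introns_fasta, "dna"
  )
  write_fasta(
    rlang::set_names(all_orfs$peptide, all_orfs$orf_id),
    files$orfs_fasta, "aa"
  )

  rejected_by_reason <- as.list(table(ref$rejected$reason))
  report <- list(
    n_records = nrow(records),
    n_hits = nrow(hits),
    n_accepted = nrow(introns),
    n_rejected = nrow(ref$rejected),
    rejected_by_reason = rejected_by_reason,
    n_subtyped = sum(!is.na(introns$subtype)),
    n_orfs = nrow(all_orfs),
    n_hegs = nrow(hegs),
    n_introns_with_hegs = length(unique(hegs$intron_id)),
    hegs_by_provenance = as.list(table(hegs$code_provenance)),
    hegs_by_evidence = as.list(table(hegs$evidence_source))
  )
  jsonlite::write_json(report, files$report, auto_unbox = TRUE, pretty = TRUE)

  structure(
    list(
      introns = introns, hegs = hegs, rejected = ref$rejected,
      orfs = all_orfs, report = report, files = files
    ),
    class = "intron_db"
  )
}

#' @export
print.intron_db <- function(x, ...) {
  cat(sprintf(
    "<intron_db> %d introns (%d with HEGs), %d HEGs, %d rejected hits\n",
    nrow(x$introns), x$report$n_introns_with_hegs, nrow(x$hegs),
    nrow(x$rejected)
  ))
  invisible(x)
}

#' Tidiers for built databases
#'
#' `tidy()` extracts one of the database tables; `glance()` returns the
#' run report as a one-row tibble.
#'
#' @param x An `intron_db` from [build_db()].
#' @param which `"introns"`, `"hegs"`, `"rejected"` or `"orfs"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.intron_db <- function(x, which = c("introns", "hegs", "rejected", "orfs"), ...) {
  which <- match.arg(which)
  x[[which]]
}

#' @rdname tidy.intron_db
#' @export
glance.intron_db <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_records = r$n_records, n_hits = r$n_hits,
    n_accepted = r$n_accepted, n_rejected = r$n_rejected,
    n_subtyped = r$n_subtyped, n_orfs = r$n_orfs, n_hegs = r$n_hegs,
    n_introns_with_hegs = r$n_introns_with_hegs
  )
}
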