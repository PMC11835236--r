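# I/O layer: GenBank, tblout, InterProScan, BLAST, Stockholm, database TSVs.

gbk_fixture_lines <- function() {
  seq <- strrep("acgt", 375) # 1500 nt
  c(
    "LOCUS       TEST001           1500 bp    DNA     linear   SYN 01-JAN-2024",
    "DEFINITION  test record.",
    "ACCESSION   TEST001",
    "VERSION     TEST001.1",
    "SOURCE      Testus testus",
    "  ORGANISM  Testus testus",
    "            Eukaryota; Fungi; Ascomycota.",
    "FEATURES             Location/Qualifiers",
    "     source          1..1500",
    "                     /organism=\"Testus testus\"",
    "                     /db_xref=\"taxon:562\"",
    "     gene            1..1500",
    "                     /gene=\"cob\"",
    "     CDS             join(1..200,951..1500)",
    "                     /product=\"cytochrome b\"",
    "     intron          201..950",
    "ORIGIN",
    vapply(seq.int(1, 1500, 60), function(s) {
      chunk <- substr(seq, s, s + 59)
      sprintf("%9d %s", s, paste(
        substring(chunk, seq(1, 51, 10), seq(10, 60, 10)),
        collapse = " "
      ))
    }, character(1)),
    "//"
  )
}

test_that("GenBank records parse with features in file order and compound parts", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk_fixture_lines(), f)
  recs <- read_genbank(f)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$entry_id, "TEST001.1")
  expect_equal(recs$length, 1500L)
  expect_equal(nchar(recs$sequence), 1500L)
  expect_equal(recs$taxid, 562L)
  expect_equal(recs$organism, "Testus testus")
  feats <- recs$features[[1]]
  expect_equal(feats$ftype, c("source", "gene", "CDS", "intron"))
  cds <- feats[feats$ftype == "CDS", ]
  expect_true(cds$compound)
  expect_equal(cds$parts[[1]]$start, c(1L, 951L))
  expect_equal(cds$parts[[1]]$end, c(200L, 1500L))
  intron <- feats[feats$ftype == "intron", ]
  expect_false(intron$compound)
  expect_equal(c(intron$start, intron$end), c(201L, 950L))
})

test_that("complement(join(...)) parses to minus-strand parts in ascending order", {
  f <- withr::local_tempfile(fileext = ".gbk")
  lines <- gbk_fixture_lines()
  lines[14] <- "     CDS             complement(join(1..200,951..1500))"
  writeLines(lines, f)
  feats <- read_genbank(f)$features[[1]]
  cds <- feats[feats$ftype == "CDS", ]
  expect_equal(cds$strand, "-")
  expect_equal(cds$parts[[1]]$start, c(1L, 951L)) # ascending despite complement
  expect_true(all(cds$parts[[1]]$strand == "-"))
})

test_that("out-of-range features are dropped with a warning, never clamped", {
  f <- withr::local_tempfile(fileext = ".gbk")
  lines <- gbk_fixture_lines()
  lines[16] <- "     intron          201..2950"
  writeLines(lines, f)
  expect_warning(recs <- read_genbank(f), "outside record")
  expect_false("intron" %in% recs$features[[1]]$ftype)
  # all surviving locations lie within the record
  parts <- dplyr::bind_rows(recs$features[[1]]$parts)
  expect_true(all(parts$start >= 1 & parts$end <= recs$length))
})

test_that("empty and malformed GenBank inputs behave as specified", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(character(0), f)
  expect_equal(nrow(read_genbank(f)), 0L)

  writeLines(c("LOCUS", "//"), f)
  expect_error(read_genbank(f), "LOCUS", class = "intronforge_format_error")
})

test_that("tblout parsing normalises minus-strand hits to start <= end", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeLines(c(
    "# comment",
    paste("SEQ1 - Intron_gpI - cm 1 250 180 1000 + no 1 0.5 0.0 65.2 1.2e-10 ! -"),
    paste("SEQ2 - Intron_gpI - cm 1 250 1000 180 - no 1 0.5 0.0 40.0 3e-04 ! -")
  ), f)
  hits <- read_tblout(f)
  expect_equal(hits$start, c(180L, 180L))
  expect_equal(hits$end, c(1000L, 1000L))
  expect_equal(hits$strand, c("+", "-"))
  expect_true(all(hits$start <= hits$end))
  expect_equal(hits$score, c(65.2, 40.0))

  writeLines("# only comments", f)
  expect_equal(nrow(read_tblout(f)), 0L)

  writeLines("SEQ1 - M - cm 1 250 abc 1000 + no 1 0.5 0.0 65.2 1e-10 ! -", f)
  expect_error(read_tblout(f), "line 1", class = "intronforge_format_error")
})

test_that("InterProScan rows yield annotation strings; short rows are skipped", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste(c(
      "orf1", "md5", "300", "Pfam", "PF00961", "Homing endonuclease, LAGLIDADG",
      "1", "250", "1e-30", "T", "01-01-2024", "IPR004860",
      "Homing endonuclease, LAGLIDADG"
    ), collapse = "\t"),
    paste(c(
      "orf2", "md5", "200", "Pfam", "PF99999", "Some signature",
      "1", "100", "1e-5", "T", "01-01-2024"
    ), collapse = "\t"),
    paste(c("orf3", "too", "short"), collapse = "\t")
  ), f)
  expect_warning(hits <- read_interproscan_tsv(f), "skipped")
  expect_equal(hits$orf_id, c("orf1", "orf2"))
  expect_true("Homing endonuclease, LAGLIDADG" %in% hits$annotation[[1]])
  expect_equal(hits$annotation[[2]], "Some signature")

  writeLines(character(0), f)
  expect_equal(nrow(read_interproscan_tsv(f)), 0L)
})

test_that("BLAST tabular requires the subject-title column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c(
    "orf1", "sbj1", "45.1", "200", "80", "3", "1", "200", "10", "210",
    "2e-40", "180", "LAGLIDADG family homing endonuclease"
  ), collapse = "\t"), f)
  hits <- read_blast_tabular(f)
  expect_equal(hits$orf_id, "orf1")
  expect_equal(hits$annotation[[1]], "LAGLIDADG family homing endonuclease")
  expect_equal(hits$e_value, 2e-40)

  writeLines(paste(as.character(1:12), collapse = "\t"), f)
  expect_error(read_blast_tabular(f), "stitle", class = "intronforge_config_error")
})

test_that("Stockholm reader handles interleaved blocks and #=GC lines", {
  f <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "seqA           AC-GU",
    "seqB           ACAGU",
    "#=GC SS_cons   <<.>>",
    "#=GC ELEMENTS  11.22",
    "",
    "seqA           AC--A",
    "seqB           ACGUA",
    "#=GC SS_cons   .....",
    "#=GC ELEMENTS  33...",
    "//"
  ), f)
  sto <- read_stockholm(f)
  expect_equal(unname(sto$alignment["seqA"]), "AC-GUAC--A")
  expect_equal(sto$ss_cons, "<<.>>.....")
  expect_equal(sto$gc$ELEMENTS, "11.2233...")
})

test_that("database TSVs round-trip field-for-field, including pathological text", {
  introns <- tibble::tibble(
    intron_id = c("X.1_1", "X.1_2"), genbank_id = "X.1",
    start_1based = c(201L, 1200L), end_1based = c(950L, 1900L),
    strand = c("+", "-"),
    intron_seq = c("TACGT", "TGGGA"), exon5_seq = c("AAA", "CCC"),
    exon3_seq = c("GGG", "TTT"),
    boundary_source = c("intron_feature", "compound_gap"),
    overlap_with_hit = c(750L, 700L),
    subtype = c("IC1", NA), subtype_score = c(85.2, NA),
    structural_elements = c("P1:1-45;P9:300-350", NA),
    organism = c("Weird\tname\nwith \\ escapes", "Normalus organismus"),
    taxid = c(562L, NA), organism_category = c("fungi", "other"),
    subcellular_location = c("mitochondria", "n/a"), n_hegs = c(1L, 0L)
  )
  hegs <- tibble::tibble(
    heg_id = "X.1_1_heg1", intron_id = "X.1_1",
    start_in_intron = 10L, end_in_intron = 400L, frame = 0L, strand = "+",
    genetic_code_id = 4L, code_provenance = "expected",
    evidence_source = "interproscan",
    evidence_annotation = "Homing endonuclease,\tLAGLIDADG",
    peptide_seq = "MKL"
  )
  fi <- withr::local_tempfile(fileext = ".tsv")
  fh <- withr::local_tempfile(fileext = ".tsv")
  write_database_tsv(introns, hegs, fi, fh)
  back <- read_database_tsv(fi, fh)
  expect_equal(back$introns, introns)
  expect_equal(back$hegs[, names(back$hegs)], hegs[, names(back$hegs)])
  # escaping keeps the physical files rectangular
  expect_true(all(lengths(strsplit(readLines(fi), "\t")) == ncol(introns)))
})

test_that("empty databases write header-only files that read back empty", {
  fi <- withr::local_tempfile(fileext = ".tsv")
  fh <- withr::local_tempfile(fileext = ".tsv")
  write_database_tsv(tibble::tibble(), tibble::tibble(), fi, fh)
  expect_length(readLines(fi), 1L)
  back <- read_database_tsv(fi, fh)
  expect_equal(nrow(back$introns), 0L)
  expect_equal(nrow(back$hegs), 0L)
})
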