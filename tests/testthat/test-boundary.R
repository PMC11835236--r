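# Boundary refinement: overlap arithmetic, candidate extraction, selection,
# validation, exonic context, and the full per-hit pipeline.

test_that("compute_overlap counts shared positions of closed ranges", {
  expect_equal(compute_overlap(1, 100, 1, 100), 100L)
  expect_equal(compute_overlap(1, 100, 101, 200), 0L) # adjacency
  # brute-force oracle: count integers in both sets
  brute <- length(intersect(seq(100, 300), seq(250, 400)))
  expect_equal(brute, 51L)
  expect_equal(compute_overlap(100, 300, 250, 400), brute)
  # symmetry on random ranges
  set.seed(11)
  for (k in 1:50) {
    a <- sort(sample.int(2000, 2))
    b <- sort(sample.int(2000, 2))
    expect_equal(
      compute_overlap(a[1], a[2], b[1], b[2]),
      compute_overlap(b[1], b[2], a[1], a[2])
    )
    expect_equal(
      compute_overlap(a[1], a[2], b[1], b[2]),
      length(intersect(seq(a[1], a[2]), seq(b[1], b[2])))
    )
  }
})

test_that("candidates come from intron features and compound-location gaps", {
  feats <- dplyr::bind_rows(
    make_feature("source", parts_tbl(1, 1500)),
    make_feature("intron", parts_tbl(201, 950)),
    make_feature("CDS", parts_tbl(c(1, 951), c(200, 1500)))
  )
  cands <- extract_candidates(feats, 180, 1000)
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$boundary_source, c("intron_feature", "compound_gap"))
  # both rules recover the same planted span 201..950 with overlap 750
  expect_true(all(cands$start == 201L & cands$end == 950L))
  expect_true(all(cands$overlap == 750L))
  expect_equal(cands$feature_index, c(2L, 3L))
})

test_that("the 50-position overlap rule is a sharp threshold", {
  feats <- make_feature("intron", parts_tbl(201, 950))
  # hit covering exactly 49 positions of the intron
  expect_equal(nrow(extract_candidates(feats, 902, 1400, min_overlap = 50)), 0L)
  # one more position crosses the threshold
  expect_equal(nrow(extract_candidates(feats, 901, 1400, min_overlap = 50)), 1L)
})

test_that("multi-gap compound locations yield one candidate per gap", {
  feats <- make_feature("CDS", parts_tbl(c(1, 301, 801), c(200, 600, 1200)))
  cands <- extract_candidates(feats, 1, 1200, min_overlap = 50)
  expect_equal(cands$start, c(201L, 601L))
  expect_equal(cands$end, c(300L, 800L))
  expect_equal(cands$boundary_source, rep("compound_gap", 2))
})

test_that("best-candidate selection is argmax with deterministic tie-break", {
  cands <- tibble::tibble(
    start = c(100L, 400L), end = c(900L, 520L), strand = "+",
    boundary_source = "intron_feature", overlap = c(750L, 120L),
    feature_index = c(3L, 1L)
  )
  expect_equal(select_best_candidate(cands)$overlap, 750L)
  ties <- tibble::tibble(
    start = c(10L, 20L), end = c(310L, 320L), strand = "+",
    boundary_source = "intron_feature", overlap = c(300L, 300L),
    feature_index = c(5L, 2L)
  )
  expect_equal(select_best_candidate(ties)$feature_index, 2L)
  expect_equal(nrow(select_best_candidate(ties[0, ])), 0L)
})

test_that("validation applies the three checks in order", {
  seq <- paste0("A", strrep("C", 98), "T") # length 100
  expect_equal(validate_candidate(seq, 1, 50)$reason, "at_entry_start")
  expect_equal(validate_candidate(seq, 2, 100)$reason, "at_entry_end")
  # position 2 is C, not T
  expect_equal(validate_candidate(seq, 2, 99)$reason, "no_initial_U")
  seq2 <- paste0("A", "T", strrep("C", 97), "G")
  expect_true(validate_candidate(seq2, 2, 99)$ok)
  # a candidate at the entry start fails that check before the U check
  expect_equal(validate_candidate(seq2, 1, 50)$reason, "at_entry_start")
})

test_that("the U check supports both readings and minus-strand orientation", {
  #           123456789
  seq <- "GGTACGTACG"
  # first_of_range: base at start must be T
  expect_true(validate_candidate(seq, 3, 8, "+", "first_of_range")$ok)
  expect_false(validate_candidate(seq, 4, 8, "+", "first_of_range")$ok)
  # before_range: base before start must be T (last nt of preceding exon)
  expect_true(validate_candidate(seq, 4, 8, "+", "before_range")$ok)
  # minus strand, first_of_range: complement of base at end must be T -> end base A
  seq_m <- "GGCATCGACG" # position 5 is T... complement A; end=4 is A -> revcomp starts T
  expect_true(validate_candidate(seq_m, 2, 4, "-", "first_of_range")$ok)
  expect_false(validate_candidate(seq_m, 2, 5, "-", "first_of_range")$ok)
})

test_that("ambiguity codes at the initial position fail the U check", {
  seq <- paste0("A", "N", strrep("C", 97), "G")
  expect_equal(validate_candidate(seq, 2, 50)$reason, "no_initial_U")
})

test_that("exonic context is truncated at record edges and strand-aware", {
  seq <- random_dna_str(1500)
  ctx <- extract_exonic_context(seq, 201, 949, "+", max_len = 150)
  expect_equal(ctx$exon5_seq, substr(seq, 51, 200))
  expect_equal(ctx$exon3_seq, substr(seq, 950, 1099))
  expect_equal(nchar(ctx$exon5_seq), 150L)
  # truncation near the start
  ctx2 <- extract_exonic_context(seq, 11, 500, "+")
  expect_equal(nchar(ctx2$exon5_seq), 10L)
  # truncation near the end
  ctx3 <- extract_exonic_context(seq, 200, 1497, "+")
  expect_equal(nchar(ctx3$exon3_seq), 3L)
  # minus strand: contexts swap and reverse-complement
  ctxm <- extract_exonic_context(seq, 201, 949, "-", max_len = 150)
  expect_equal(ctxm$exon5_seq, revcomp_dna(substr(seq, 950, 1099)))
  expect_equal(ctxm$exon3_seq, revcomp_dna(substr(seq, 51, 200)))
})

test_that("refine_hits recovers planted boundaries and accounts for every hit", {
  withr::local_seed(301)
  fx <- generate_fixtures(
    fixture_spec(seed = 301, n_records = 20, boundary_pathway = "both",
      fraction_minus = 0.3),
    withr::local_tempdir()
  )
  recs <- read_genbank(fx$files$genbank)
  hits <- read_tblout(fx$files$tblout)
  ref <- refine_hits(recs, hits)
  expect_equal(nrow(ref$introns) + nrow(ref$rejected), nrow(hits))
  truth <- fx$truth
  joined <- dplyr::inner_join(
    truth, ref$introns,
    by = c(entry_id = "genbank_id")
  )
  expect_equal(nrow(joined), 20L)
  expect_equal(joined$start_1based, joined$intron_start)
  expect_equal(joined$end_1based, joined$intron_end)
  expect_equal(joined$strand.y, joined$strand.x)
  # type invariants of accepted entries
  expect_true(all(substr(ref$introns$intron_seq, 1, 1) == "T"))
  expect_true(all(nchar(ref$introns$exon5_seq) >= 1 &
    nchar(ref$introns$exon5_seq) <= 150))
  expect_true(all(nchar(ref$introns$exon3_seq) >= 1 &
    nchar(ref$introns$exon3_seq) <= 150))
  expect_true(all(ref$introns$start_1based < ref$introns$end_1based))
  # sequence round trip against the record
  for (i in seq_len(nrow(ref$introns))) {
    r <- recs[recs$entry_id == ref$introns$genbank_id[i], ]
    sub <- substr(r$sequence, ref$introns$start_1based[i], ref$introns$end_1based[i])
    if (ref$introns$strand[i] == "-") sub <- revcomp_dna(sub)
    expect_equal(ref$introns$intron_seq[i], sub)
  }
})

test_that("refinement is deterministic and rejects missing records and non-U starts", {
  fx <- generate_fixtures(
    fixture_spec(seed = 77, n_records = 12, fraction_u_start = 0.5),
    withr::local_tempdir()
  )
  recs <- read_genbank(fx$files$genbank)
  hits <- read_tblout(fx$files$tblout)
  ref1 <- refine_hits(recs, hits)
  ref2 <- refine_hits(recs, hits)
  expect_identical(ref1$introns, ref2$introns)
  expect_identical(ref1$rejected, ref2$rejected)
  # non-U planted records are rejected for exactly that reason
  exp_rej <- fx$truth$entry_id[fx$truth$expected == "no_initial_U"]
  got_rej <- ref1$rejected$target_id[ref1$rejected$reason == "no_initial_U"]
  expect_setequal(got_rej, exp_rej)
  # a hit pointing at an absent record
  orphan <- hits[1, ]
  orphan$target_id <- "NOPE.1"
  ref3 <- refine_hits(recs, dplyr::bind_rows(hits, orphan))
  expect_equal(sum(ref3$rejected$reason == "missing_record"), 1L)
})

test_that("identical boundaries from multiple hits are deduplicated when enabled", {
  feats <- make_feature("intron", parts_tbl(201, 950))
  rec <- make_record("DUP.1", {
    s <- random_dna_str(1500)
    substr(s, 201, 201) <- "T"
    s
  }, feats)
  hits <- tibble::tibble(
    target_id = "DUP.1", model_name = "M",
    start = c(180L, 190L), end = c(1000L, 990L), strand = "+",
    score = c(50, 45), e_value = c(1e-10, 1e-8)
  )
  ref <- refine_hits(rec, hits)
  expect_equal(nrow(ref$introns), 1L)
  expect_equal(ref$rejected$reason, "duplicate_boundary")
  ref_keep <- refine_hits(rec, hits, dedupe_identical_boundaries = FALSE)
  expect_equal(nrow(ref_keep$introns), 2L)
  # ordinals are ascending-start within the entry
  expect_equal(ref_keep$introns$intron_id, c("DUP.1_1", "DUP.1_2"))
})
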