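# Translation, ORF finding (vs brute-force oracle) and nested pruning.

test_that("translation follows the NCBI tables codon by codon", {
  expect_equal(translate_dna("ATGAAATAG", 1), "MK*")
  expect_equal(translate_dna("TGA", 1), "*")
  expect_equal(translate_dna("TGA", 4), "W") # mold mitochondrial reassignment
  expect_equal(translate_dna("ATN", 1), "X") # resolutions disagree -> X
  expect_equal(translate_dna("CGN", 1), "R") # all resolutions agree -> translated
  expect_equal(translate_dna("GCU", 1), "A") # RNA accepted
  # full-table agreement with the curated Biostrings tables
  bases <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(
    as.vector(outer(bases, bases, paste0)), bases, paste0
  ))
  for (tid in c(1, 4, 11)) {
    ref <- Biostrings::getGeneticCode(as.character(tid), full.search = TRUE)
    got <- vapply(all64, function(cd) translate_dna(cd, tid), character(1))
    expect_equal(unname(got), unname(ref[all64]))
  }
})

test_that("a planted ORF is found exactly, on either strand", {
  withr::local_seed(21)
  gc1 <- genetic_code(1)
  body <- paste(
    sample(setdiff(names(gc1$codons), gc1$stop_codons), 129, replace = TRUE),
    collapse = ""
  )
  orf <- paste0("ATG", body, "TAA") # 130 aa + stop = 393 nt
  lead <- paste0(random_dna_str(10), "TAA") # in-frame stop guard
  seq <- paste0(lead, orf, random_dna_str(47))
  found <- find_orfs(seq, 1, min_aa = 120)
  planted <- found[found$strand == "+" & found$start == nchar(lead) + 1, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, nchar(lead) + nchar(orf))
  expect_equal(planted$aa_length, 130L)
  expect_equal(planted$frame, (nchar(lead)) %% 3L)
  expect_true(planted$has_stop)
  expect_equal(planted$peptide, translate_dna(paste0("ATG", body), 1))
  expect_false(grepl("*", planted$peptide, fixed = TRUE))
  # the same ORF on the reverse-complemented sequence appears mirrored
  rc <- find_orfs(revcomp_dna(seq), 1, min_aa = 120)
  mirrored <- rc[rc$strand == "-", ]
  expect_equal(nchar(seq) - mirrored$end + 1L, planted$start)
  expect_equal(nchar(seq) - mirrored$start + 1L, planted$end)
})

test_that("ORF intervals are codon-multiples and too-short sequences yield none", {
  expect_equal(nrow(find_orfs(random_dna_str(300), 1, min_aa = 120)), 0L)
  withr::local_seed(8)
  for (k in 1:10) {
    orfs <- find_orfs(random_dna_str(1500), 1, min_aa = 20)
    if (nrow(orfs) > 0) {
      expect_true(all((orfs$end - orfs$start + 1L) %% 3L == 0L))
      expect_true(all(orfs$aa_length >= 20L))
    }
  }
})

test_that("find_orfs agrees with the brute-force oracle on random sequences", {
  withr::local_seed(113)
  for (k in 1:30) {
    n <- sample(200:1200, 1)
    seq <- random_dna_str(n)
    tid <- sample(c(1, 4, 11), 1)
    min_aa <- sample(c(15, 40), 1)
    got <- orf_key_frame(find_orfs(seq, tid, min_aa))
    exp <- orf_key_frame(oracle_orfs(seq, tid, min_aa))
    expect_equal(got, exp, info = sprintf("seq %d, table %d", k, tid))
  }
})

test_that("reverse-complement symmetry holds as a property", {
  withr::local_seed(77)
  for (k in 1:10) {
    seq <- random_dna_str(900)
    a <- find_orfs(seq, 4, min_aa = 20)
    b <- find_orfs(revcomp_dna(seq), 4, min_aa = 20)
    n <- nchar(seq)
    b_mapped <- tibble::tibble(
      start = n - b$end + 1L, end = n - b$start + 1L,
      strand = ifelse(b$strand == "+", "-", "+"),
      aa_length = b$aa_length, has_stop = b$has_stop
    )
    a_cmp <- a[, c("start", "end", "strand", "aa_length", "has_stop")]
    ord <- function(d) d[order(d$start, d$end, d$strand), ]
    expect_equal(
      as.data.frame(ord(a_cmp)), as.data.frame(ord(b_mapped)),
      ignore_attr = TRUE
    )
  }
})

test_that("nested pruning drops contained same-strand ORFs only", {
  orfs <- tibble::tibble(
    start = c(1L, 31L), end = c(390L, 390L), strand = "+",
    frame = c(0L, 0L), table_id = 1L, aa_length = c(129L, 119L),
    has_stop = TRUE, peptide = c("A", "B")
  )
  kept <- prune_nested(orfs)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$start, 1L)

  # partial overlap in different frames: both retained (the overlapping
  # endonuclease-pair configuration)
  pair <- tibble::tibble(
    start = c(1L, 366L), end = c(390L, 800L), strand = "+",
    frame = c(0L, 2L), table_id = 1L, aa_length = c(129L, 144L),
    has_stop = TRUE, peptide = c("A", "B")
  )
  expect_equal(nrow(prune_nested(pair)), 2L)

  # identical interval on opposite strands: both kept
  both <- tibble::tibble(
    start = 1L, end = c(390L, 390L), strand = c("+", "-"),
    frame = 0L, table_id = 1L, aa_length = 129L, has_stop = TRUE,
    peptide = c("A", "B")
  )
  expect_equal(nrow(prune_nested(both)), 2L)
})

test_that("pruned output never contains a same-strand containment pair", {
  withr::local_seed(31)
  for (k in 1:20) {
    m <- sample(5:25, 1)
    orfs <- tibble::tibble(
      start = sample.int(500, m, replace = TRUE)
    ) |>
      dplyr::mutate(
        end = start + 3L * sample.int(100, m, replace = TRUE),
        strand = sample(c("+", "-"), m, replace = TRUE),
        frame = sample(0:2, m, replace = TRUE),
        table_id = 1L, aa_length = (end - start + 1L) %/% 3L,
        has_stop = TRUE, peptide = "M"
      )
    kept <- prune_nested(orfs)
    # quadratic scan
    for (i in seq_len(nrow(kept))) {
      for (j in seq_len(nrow(kept))) {
        if (i == j || kept$strand[i] != kept$strand[j]) next
        contained <- kept$start[i] <= kept$start[j] && kept$end[i] >= kept$end[j] &&
          (kept$start[i] < kept$start[j] || kept$end[i] > kept$end[j])
        expect_false(contained)
      }
    }
  }
})

test_that("ORF enumeration merges cross-code duplicates preferring the expected code", {
  withr::local_seed(55)
  ctx <- fungal_context()
  # an ORF with no TGA/AGA codons is identical under tables 1 and 4
  gc1 <- genetic_code(1)
  safe <- setdiff(names(gc1$codons), c(gc1$stop_codons, "TGA", "AGA", "AGG", "ATA", "CTG", "TTG", "GTG", "ATT", "ATC", "TTA"))
  body <- paste(sample(safe, 125, replace = TRUE), collapse = "")
  seq <- paste0("TAATAG", "ATG", body, "TAA", "TAGTAA")
  orfs <- enumerate_orfs(seq, "X_1", ctx, codes = c(1L, 4L), min_aa = 120)
  shared <- orfs[orfs$start == 7L, ]
  expect_equal(nrow(shared), 1L)
  # mitochondrial context prefers table 4 (the expected compartment code)
  expect_equal(shared$table_id, 4L)
  expect_match(orfs$orf_id, "^X_1_orf\\d+$")
})
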