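test_that("delimited count tables round-trip with labels, order and values intact", {
  cm <- read_count_table(extdata("tfbs_counts_synthetic.tsv"))
  expect_s3_class(cm, "edl_counts")
  expect_identical(position_labels(cm), as.character(1:6))
  expect_identical(alphabet(cm, "1"), c("A", "C", "G", "T"))
  expect_equal(sum(as.matrix(cm)), 600)

  again <- read_count_table(write_matrix(cm))
  expect_identical(again$positions, cm$positions)
  expect_identical(again$values, cm$values)

  # orientation transpose gives the same object
  tm <- t(as.matrix(cm))
  lines <- c(paste(c("position", colnames(tm)), collapse = "\t"),
             vapply(seq_len(nrow(tm)), function(i)
               paste(c(rownames(tm)[i], tm[i, ]), collapse = "\t"), character(1)))
  cm2 <- read_count_table(lines, orientation = "rows-are-positions")
  expect_identical(cm2$values, cm$values)
})

test_that("count table validation rejects malformed input", {
  expect_error(read_count_table(c("symbol\t1\t2", "A\t1\t2", "A\t3\t4")),
               class = "edl_validation_error")
  expect_error(read_count_table(c("symbol\t1\t2", "A\t1\t2", "C\t-3\t4")),
               class = "edl_validation_error")
  expect_error(read_count_table(c("symbol\t1\t2", "A\t1\t2", "C\t3")),
               class = "edl_format_error")
  expect_error(read_count_table(c("symbol\t1", "A\t1.5")),
               class = "edl_validation_error")
  # integral after rounding at 1e-9 is fine
  cm <- read_count_table(c("symbol\t1", "A\t2.0000000001", "C\t1"))
  expect_identical(unname(cm$values[[1]]), c(2, 1))
})

test_that("long-format tables support string symbols and per-position alphabets", {
  pm <- read_probability_table(extdata("mutsig_probs.tsv"))
  expect_identical(position_labels(pm), c("-2", "-1", "0", "1", "2"))
  expect_identical(alphabet(pm, "0"),
                   c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_identical(alphabet(pm, "-1"), c("A", "C", "G", "T"))
  expect_equal(position_values(pm, "0")[["C>T"]], 0.96, tolerance = 1e-12)
  rt <- read_probability_table(write_matrix(pm))
  expect_equal(rt$values, pm$values, tolerance = 1e-12)
})

test_that("JASPAR PFM parsing follows the dialect", {
  cm <- read_jaspar_pfm(c(">M1", "A [ 1 0 ]", "C [ 0 1 ]", "G [ 0 0 ]", "T [ 0 0 ]"))
  expect_identical(position_labels(cm), c("1", "2"))
  expect_identical(unname(cm$values[[1]]), c(1, 0, 0, 0))

  fixture <- read_jaspar_pfm(extdata("motif_synthetic.pfm"))
  expect_identical(position_labels(fixture), as.character(1:6))
  expect_identical(alphabet(fixture, "1"), c("A", "C", "G", "T"))

  expect_error(read_jaspar_pfm(c("A [ 1 0 ]", "C [ 0 1 ]")),
               class = "edl_format_error")
  expect_error(read_jaspar_pfm(c(">M1", "A [ 1 0 ]", "C [ 0 1 ]", "G [ 0 0 ]")),
               class = "edl_format_error")
  expect_error(read_jaspar_pfm(c(">M1", "A [ 1 0 ]", "C [ 0 1 ]",
                                 "G [ 0 0 ]", "T [ 0 ]")),
               class = "edl_format_error")
})

test_that("sequence tokenization counts per column in first-appearance order", {
  cm <- counts_from_sequences(c("NAS", "NGS", "NAT"))
  expect_identical(cm$values[[1]], c(N = 3))
  expect_identical(cm$values[[2]], c(A = 2, G = 1))
  expect_identical(cm$values[[3]], c(S = 2, T = 1))

  expect_error(counts_from_sequences(c("ABC", "ABCD")),
               class = "edl_validation_error")
  expect_error(counts_from_sequences(character(0)),
               class = "edl_validation_error")

  fa <- counts_from_sequences(extdata("seqs_synthetic.fasta"))
  expect_identical(fa$values[[1]], c(N = 5))
  expect_true(all(vapply(fa$values, sum, numeric(1)) == 5))

  # an all-identical center column keeps its full mass on one symbol
  big <- counts_from_sequences(rep("ANA", 5422))
  expect_identical(big$values[[2]], c(N = 5422))

  # delimiter tokenizer for string symbols
  sm <- counts_from_sequences(c("C>T,A", "C>T,G", "T>C,A"),
                              tokenizer = "delimiter")
  expect_identical(sm$values[[1]], c("C>T" = 2, "T>C" = 1))
})

test_that("normalize_counts is the ML estimate and records precision", {
  cm <- count_matrix(list(`1` = c(A = 33, C = 33, G = 33, T = 1)))
  pm <- normalize_counts(cm)
  expect_equal(unname(pm$values[[1]]), c(0.33, 0.33, 0.33, 0.01))
  expect_equal(pm$effective_count, 100)

  one <- normalize_counts(count_matrix(list(`0` = c(N = 5422, Q = 0))))
  expect_identical(unname(one$values[[1]]), c(1, 0))

  expect_error(normalize_counts(count_matrix(list(`1` = c(A = 1), `2` = c(A = 0)))),
               regexp = "position 2", class = "edl_validation_error")
  expect_equal(unname(normalize_counts(cm, effective_count = 50)$effective_count), 50)
})

test_that("normalization yields unit simplexes for random count matrices", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    L <- sample(1:5, 1)
    vals <- lapply(seq_len(L), function(j)
      stats::setNames(rpois(n, lambda = 8) + 1, paste0("S", seq_len(n))))
    pm <- normalize_counts(count_matrix(vals, as.character(seq_len(L))))
    sums <- vapply(pm$values, sum, numeric(1))
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("alphabet and probability invariants are enforced", {
  expect_error(count_matrix(list(`1` = c(A = 1, ` ` = 2))),
               class = "edl_validation_error")
  expect_error(probability_matrix(list(`1` = c(A = 0.6, C = 0.6))),
               class = "edl_validation_error")
  expect_error(background(c(A = 0.5, C = 0.6)), class = "edl_validation_error")
  expect_error(background("gc40"), class = "edl_validation_error")
  # U and T are distinct symbols: no aliasing
  b <- background(c(A = 0.25, C = 0.25, G = 0.25, U = 0.25))
  p <- one_pos_probs(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_error(log_ratios(p, b), class = "edl_validation_error")
})
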