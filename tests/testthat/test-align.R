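test_that("global alignment handles identity, substitution and gap cases", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$mismatches, 0L)
  expect_equal(al$gap_columns, 0L)
  expect_equal(al$identity, 1.0)
  expect_equal(al$score, 20)

  # one substitution; gaps prohibitively expensive at these lengths:
  # 3 * 5 - 4 = 11, confirmed by exhaustive enumeration of all alignments
  al <- global_align("ACGT", "ACTT")
  expect_equal(al$mismatches, 1L)
  expect_equal(al$score, 11)
  expect_equal(al$score, oracle_global_score("ACGT", "ACTT"))

  # single deletion
  al <- global_align("ACGTACGT", "ACGACGT")
  expect_equal(al$gap_columns, 1L)
  expect_equal(al$mismatches, 0L)
  expect_equal(al$score, oracle_global_score("ACGTACGT", "ACGACGT"))
})

test_that("aligned strings de-gap to the inputs and columns partition", {
  set.seed(11)
  for (t in 1:25) {
    a <- rand_dna(sample(3:12, 1))
    b <- rand_dna(sample(3:12, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", al$aligned_b, fixed = TRUE), b)
    expect_equal(al$matches + al$mismatches + al$gap_columns, al$length)
  }
})

test_that("global scores match exhaustive enumeration on short pairs", {
  set.seed(7)
  p <- align_params("global")
  for (t in 1:60) {
    a <- rand_dna(sample(2:8, 1))
    b <- rand_dna(sample(2:8, 1))
    expect_equal(global_align(a, b, p)$score, oracle_global_score(a, b, p),
                 info = paste(a, b))
  }
  # distinct terminal-gap pricing exercised explicitly
  p2 <- align_params("global", gap_open = 6, gap_extend = 2,
                     end_open = 1, end_extend = 1)
  for (t in 1:40) {
    a <- rand_dna(sample(2:7, 1))
    b <- rand_dna(sample(2:7, 1))
    expect_equal(global_align(a, b, p2)$score, oracle_global_score(a, b, p2),
                 info = paste(a, b))
  }
})

test_that("mutation counts are symmetric in the sequence order", {
  set.seed(12)
  for (t in 1:20) {
    a <- rand_dna(10); b <- rand_dna(sample(8:12, 1))
    al1 <- global_align(a, b)
    al2 <- global_align(b, a)
    expect_equal(al1$mismatches, al2$mismatches)
    expect_equal(al1$gap_columns, al2$gap_columns)
    expect_equal(al1$score, al2$score)
  }
})

test_that("local alignment finds embedded queries and respects seeding", {
  set.seed(3)
  q <- "ACGTACGTAC"
  subj <- paste0(strrep("T", 45), q, strrep("G", 45))
  h <- local_align(q, subj)
  expect_equal(h$score[1], 10)
  expect_equal(h$identity[1], 1.0)
  expect_equal(h$s_start[1], 46L)

  # one substitution at query position 6: 9 matches - 1 mismatch = 8
  q2 <- "ACGTATGTAC"
  h2 <- local_align(q2, paste0(strrep("T", 45), q, strrep("G", 45)),
                    min_score = 5)
  expect_equal(h2$score[1], 8)

  # no shared 5-mer: seeding precondition unmet
  h3 <- local_align("ACACACACAC", strrep("G", 60), min_score = 1)
  expect_equal(nrow(h3), 0L)
})

test_that("local scores match a plain affine Smith-Waterman oracle", {
  set.seed(8)
  p <- align_params("local", word_size = 0L)
  for (t in 1:60) {
    a <- rand_dna(sample(2:8, 1))
    b <- rand_dna(sample(2:8, 1))
    os <- oracle_local_score(a, b, p)
    h <- local_align(a, b, p, min_score = 1e-9)
    got <- if (nrow(h) == 0L) 0 else h$score[1]
    expect_equal(got, os, info = paste(a, b))
  }
})

test_that("empty sequences and bad alphabets are rejected", {
  expect_error(global_align("", "ACGT"), "non-empty")
  expect_error(global_align("ACGT", "ACXT"), "alphabet")
  expect_warning(align_params("global", gap_open = 1, gap_extend = 5),
                 "unusual")
})
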