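test_that("dereplication keeps one locus per exact repeat content", {
  set.seed(61)
  cons <- rand_dna(30)
  l1 <- make_locus(rand_dna(60), rep(cons, 3), id = "A")
  l2 <- make_locus(rand_dna(60), rep(cons, 3), id = "B")
  out <- dereplicate_arrays(list(l1, l2))
  expect_length(out, 1L)
  expect_equal(out[[1]]$id, "A")

  mut <- mutate_seq(cons, 5)
  l3 <- make_locus(rand_dna(60), c(mut, cons, cons), id = "C")
  expect_length(dereplicate_arrays(list(l1, l3)), 2L)
  expect_length(dereplicate_arrays(list()), 0L)
})

test_that("length-outlier repeats are excluded from counting", {
  set.seed(62)
  cons <- rand_dna(36)
  r35 <- substr(cons, 1, 35)
  r34 <- substr(cons, 1, 34)
  loc <- make_locus(rand_dna(60), c(cons, r35, r34, cons), consensus = cons)
  expect_equal(filter_length_outliers(loc), c(1L, 2L, 4L))
  loc2 <- make_locus(rand_dna(60), rep(cons, 4), consensus = cons)
  expect_equal(filter_length_outliers(loc2), 1:4)
})

test_that("mutation counting reports positions on consensus coordinates", {
  set.seed(63)
  cons <- rand_dna(36)
  expect_equal(count_mutations(cons, cons)$mutations, 0L)

  m <- mutate_seq(cons, c(2, 9))
  cm <- count_mutations(m, cons)
  expect_equal(cm$mutations, 2L)
  expect_equal(cm$positions, c(2L, 9L))

  # single 1-nt deletion
  del <- paste0(substr(cons, 1, 17), substr(cons, 19, 36))
  cm <- count_mutations(del, cons)
  expect_equal(cm$mutations, 1L)
  expect_equal(cm$gap_columns, 1L)

  # a 2-nt gap counts as 2 column mutations, or 1 with run merging
  del2 <- paste0(substr(cons, 1, 17), substr(cons, 20, 36))
  expect_equal(count_mutations(del2, cons)$mutations, 2L)
  expect_equal(count_mutations(del2, cons, gap_run_as_one = TRUE)$mutations, 1L)
})

test_that("cohort summary contrasts focus and non-focus repeats", {
  set.seed(64)
  loci <- lapply(1:10, function(i) {
    cons <- rand_dna(36)
    make_locus(rand_dna(60), c(mutate_seq(cons, sample(36, 1)),
                               rep(cons, 3)),
               id = paste0("L", i), consensus = cons)
  })
  ms <- mutation_summary(loci, focus = "first")
  expect_equal(ms$focus_fraction, 1.0)
  expect_equal(ms$nonfocus_fraction, 0.0)
  expect_equal(sum(ms$hist["focus", ]), 10)
  expect_equal(sum(ms$hist["other", ]), 30)

  # order invariance
  ms2 <- mutation_summary(rev(loci), focus = "first")
  expect_equal(ms2$focus_fraction, ms$focus_fraction)
  expect_equal(ms2$hist, ms$hist)
  expect_equal(ms2$pos_counts, ms$pos_counts)
})

test_that("an unmutated cohort yields exactly zero fractions", {
  set.seed(65)
  loci <- lapply(1:5, function(i)
    make_locus(rand_dna(60), rep(rand_dna(36), 4), id = paste0("Z", i)))
  ms <- mutation_summary(loci)
  expect_identical(ms$focus_fraction, 0)
  expect_identical(ms$nonfocus_fraction, 0)
})

test_that("planted mutation positions concentrate where planted", {
  set.seed(66)
  loci <- lapply(1:40, function(i) {
    cons <- rand_dna(36)
    make_locus(rand_dna(60), c(mutate_seq(cons, sample(15, 2)), rep(cons, 2)),
               id = paste0("P", i), consensus = cons)
  })
  ms <- mutation_summary(loci)
  pc <- ms$pos_counts$focus
  expect_gte(sum(pc[1:15]) / sum(pc), 0.95)
})
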