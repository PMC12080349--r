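plant_rescue_locus <- function(gap, n_subs, cons_len = 36L, up_len = 150L,
                               even = FALSE) {
  cons <- rand_dna(cons_len, gc = 0.5)
  pos <- if (even) round(seq(2, cons_len - 1, length.out = n_subs))
         else sample(cons_len, n_subs)
  degraded <- mutate_seq(cons, pos)
  pre <- rand_dna(up_len - gap - cons_len)
  up <- paste0(pre, degraded, rand_dna(gap))
  list(locus = make_locus(up, rep(cons, 4), consensus = cons), cons = cons)
}

test_that("a planted degraded repeat at rescue distance is promoted", {
  set.seed(51)
  pl <- plant_rescue_locus(gap = 30L, n_subs = 3L)
  n_rep <- nrow(pl$locus$repeats)
  r <- rescue_mutated_repeat(pl$locus, n_shuffles = 200L, seed = 1)
  expect_true(r$accepted)
  expect_lt(r$candidate$empirical_e, 0.01)
  expect_equal(nrow(r$locus$repeats), n_rep + 1L)
  expect_equal(nrow(r$locus$spacers), nrow(r$locus$repeats) - 1L)
  # the promoted repeat 1 still matches the consensus above the gate
  al <- global_align(repeat_seqs(r$locus)[1], pl$cons)
  expect_gt(al$identity, 0.70)
  # rescue is idempotent once nothing is left to find
  r2 <- rescue_mutated_repeat(r$locus, n_shuffles = 200L, seed = 2)
  expect_false(r2$accepted)
  r3 <- rescue_mutated_repeat(r2$locus, n_shuffles = 200L, seed = 3)
  expect_false(r3$accepted)
  expect_equal(nrow(r3$locus$repeats), nrow(r$locus$repeats))
})

test_that("candidates outside the distance or identity gates are rejected", {
  set.seed(52)
  # too far: implied spacer length 50 > 45
  pl <- plant_rescue_locus(gap = 50L, n_subs = 3L)
  r <- rescue_mutated_repeat(pl$locus, n_shuffles = 200L, seed = 1)
  expect_false(r$accepted)
  # too degraded: ~60% identity, evenly spread so no sub-segment of the
  # copy reaches the gates (scattered random substitutions can leave long
  # intact runs that are genuine local hits)
  pl <- plant_rescue_locus(gap = 30L, n_subs = 14L, even = TRUE)
  r <- rescue_mutated_repeat(pl$locus, n_shuffles = 200L, seed = 1)
  expect_false(r$accepted)
})

test_that("rescue works on the minus strand too", {
  set.seed(53)
  cons <- rand_dna(36)
  degraded <- mutate_seq(cons, sample(36, 2))
  up <- paste0(rand_dna(84), degraded, rand_dna(30))
  loc <- make_locus(up, rep(cons, 3), consensus = cons, strand = "-")
  r <- rescue_mutated_repeat(loc, n_shuffles = 200L, seed = 9)
  expect_true(r$accepted)
  al <- global_align(repeat_seqs(r$locus)[1], cons)
  expect_gte(al$matches, 34)
})

test_that("upstream trimming follows the nearest gene and the 30 nt floor", {
  set.seed(54)
  up <- rand_dna(400)
  loc <- make_locus(up, rep(rand_dna(30), 3))
  r1s <- loc$repeats$start[1]
  # gene ending 400 nt away: cap applies
  t1 <- trim_upstream(loc, data.frame(start = 1, end = r1s - 401))
  expect_equal(nchar(upstream_seq(t1)), 180L)
  # gene ending 100 nt away: shortened
  t2 <- trim_upstream(loc, data.frame(start = 1, end = r1s - 101))
  expect_equal(nchar(upstream_seq(t2)), 100L)
  expect_false(t2$rejected)
  # gene ending 20 nt away: discarded
  t3 <- trim_upstream(loc, data.frame(start = 1, end = r1s - 21))
  expect_true(t3$rejected)
})

test_that("null upstream regions are rescued at below the e-value gate rate", {
  set.seed(55)
  n <- 200L
  acc <- 0L
  for (t in seq_len(n)) {
    loc <- make_locus(rand_dna(150), rep(rand_dna(36), 3))
    r <- rescue_mutated_repeat(loc, n_shuffles = 200L, seed = t)
    if (r$accepted) acc <- acc + 1L
  }
  expect_lte(acc / n, 0.02)
})

test_that("qc_cohort reports actions per locus", {
  set.seed(56)
  loci <- list(make_locus(rand_dna(200), rep(rand_dna(30), 3), id = "A"),
               make_locus(rand_dna(60), rep(rand_dna(30), 3), id = "B"))
  genes <- data.frame(contig = c("ctg_A", "ctg_B"), start = c(1, 1),
                      end = c(1, 1))
  out <- qc_cohort(loci, genes, n_shuffles = 100L, seed = 1)
  expect_equal(out$report$locus, c("A", "B"))
  expect_true(all(out$report$action %in% c("kept", "trimmed", "rescued", "discarded")))
  expect_equal(out$report$upstream_len,
               vapply(out$loci, function(l) nchar(upstream_seq(l)), 0L))
})
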