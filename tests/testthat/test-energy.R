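test_that("longer perfect duplexes are more stable", {
  s20 <- "ACGUACGGUCCAGCAUGCAU"
  e20 <- interaction_energy(s20, revcomp(s20))
  e10 <- interaction_energy(substr(s20, 1, 10), revcomp(substr(s20, 1, 10)))
  expect_true(e20$interaction && e10$interaction)
  expect_lt(e20$energy, e10$energy)
  expect_equal(e20$n_pairs, 20L)
})

test_that("unpairable sequences report no interaction", {
  e <- interaction_energy(strrep("A", 12), strrep("A", 12))
  expect_false(e$interaction)
  expect_error(interaction_energy("ACGUNACGU", "ACGUACGU"), "N")
  expect_error(interaction_energy("ACGU", "ACGUACGU"), "8 nt")
})

test_that("the energy DP matches exhaustive duplex enumeration", {
  set.seed(91)
  for (t in 1:60) {
    a <- rand_dna(sample(8:12, 1), gc = runif(1, 0.3, 0.7))
    b <- rand_dna(sample(8:12, 1), gc = runif(1, 0.3, 0.7))
    o <- oracle_duplex_energy(a, b)
    r <- interaction_energy(a, b)
    if (is.na(o)) {
      expect_false(r$interaction, info = paste(a, b))
    } else {
      expect_true(r$interaction, info = paste(a, b))
      expect_equal(r$energy, o, tolerance = 1e-9, info = paste(a, b))
    }
  }
})

test_that("appending complementary sequence never raises the optimum", {
  set.seed(92)
  for (t in 1:20) {
    a <- rand_dna(10, 0.6)
    b <- revcomp(a)
    e1 <- interaction_energy(a, b)
    a2 <- paste0(a, "G")
    b2 <- paste0("C", b)
    e2 <- interaction_energy(a2, b2)
    expect_lte(e2$energy, e1$energy)
  }
})

test_that("tracrRNA redundancy filtering keeps one locus per cluster", {
  set.seed(93)
  tr <- rand_dna(60)
  l1 <- make_locus(rand_dna(60), rep(rand_dna(36), 3), id = "A", tracr = tr)
  l2 <- make_locus(rand_dna(60), rep(rand_dna(36), 3), id = "B", tracr = tr)
  l3 <- make_locus(rand_dna(60), rep(rand_dna(36), 3), id = "C",
                   tracr = rand_dna(60))
  l4 <- make_locus(rand_dna(60), rep(rand_dna(36), 3), id = "D")
  expect_message(out <- filter_redundant_tracrs(list(l1, l2, l3, l4)),
                 "without a tracrRNA")
  expect_setequal(vapply(out, `[[`, "", "id"), c("A", "C"))
  expect_length(filter_redundant_tracrs(list()), 0L)
})

test_that("Mann-Whitney U and p-values match enumeration and symmetry", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.05)

  x <- c(2, 4, 6, 8)
  mw2 <- mann_whitney_u(x, x)
  expect_equal(mw2$U, length(x)^2 / 2)

  set.seed(94)
  for (t in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    pool <- sample(seq_len(1000), nx + ny) / 1000 # distinct: exact p applies
    x <- pool[seq_len(nx)]; y <- pool[nx + seq_len(ny)]
    alt <- sample(c("two.sided", "less", "greater"), 1)
    mw <- mann_whitney_u(x, y, alt)
    u_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(mw$U, u_brute)
    expect_equal(mw$p_value, oracle_mw_exact(x, y, alt), tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("cohort comparison is neutral when extra repeats are unmutated", {
  set.seed(95)
  loci <- lapply(1:8, function(i) {
    cons <- rand_dna(36)
    tr <- paste0(revcomp(substr(cons, 1, 24)), rand_dna(40))
    make_locus(rand_dna(60), rep(cons, 3), id = paste0("E", i),
               tracr = tr, consensus = cons)
  })
  cmp <- compare_cohort(loci)
  expect_equal(cmp$median_extra, cmp$median_consensus)
  expect_equal(cmp$per_locus$energy_extra, cmp$per_locus$energy_consensus)
  expect_gt(cmp$p_value, 0.9)

  expect_warning(cmp1 <- compare_cohort(loci[1]), "single-locus")
  expect_true(is.na(cmp1$p_value))
})

test_that("anti-repeat-window mutations weaken the interaction", {
  set.seed(96)
  loci <- lapply(1:30, function(i) {
    cons <- rand_dna(36)
    tr <- paste0(revcomp(substr(cons, 1, 24)), rand_dna(40))
    extra <- mutate_seq(cons, sample(15, 3))
    make_locus(rand_dna(60), c(extra, rep(cons, 2)), id = paste0("W", i),
               tracr = tr, consensus = cons)
  })
  cmp <- compare_cohort(loci)
  expect_gt(cmp$median_extra, cmp$median_consensus) # less negative
})
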