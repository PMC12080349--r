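test_that("planted duplexes are found with the expected geometry", {
  set.seed(71)
  # perfect 12-nt stem, arms 20 nt apart
  arm <- "GACGGCATCGTC"
  up <- paste0(strrep("A", 15), arm, strrep("A", 20), revcomp(arm),
               strrep("A", 15))
  h <- find_helix(up, helix_params(12, 3, "intra"))
  expect_false(is.null(h))
  expect_gte(h$bp_count, 12L)
  expect_equal(h$unpaired_count, 0L)
  expect_equal(h$arm_a, c(16L, 27L))

  # guide mode: 8-nt reverse complement of guide positions embedded upstream
  up2 <- rand_dna(80, gc = 0.1) # A/T-poor pairing background
  g8 <- substr(up2, 60, 67) # inside the last-25 window of an 80-mer
  up2 <- paste0(substr(up2, 1, 19), revcomp(g8), substr(up2, 28, 80))
  h2 <- find_helix(up2, helix_params(8, 2, "guide"))
  expect_false(is.null(h2))
  expect_gte(h2$bp_count, 8L)
  expect_gte(h2$arm_b[2], 80L - 25L + 1L)
})

test_that("sub-threshold and unpairable inputs yield no helix", {
  set.seed(72)
  # only a 7-nt complement available
  bg <- strrep("A", 80)
  g7 <- "GCGGCCG"
  up <- paste0(substr(bg, 1, 19), revcomp(g7), substr(bg, 27, 55),
               strrep("A", 5), g7, strrep("A", 13))
  expect_null(find_helix(up, helix_params(8, 2, "guide")))
  expect_null(find_helix(strrep("A", 80), helix_params(8, 2, "intra")))
})

test_that("the helix finder agrees with the row-DP oracle on short inputs", {
  set.seed(73)
  for (t in 1:120) {
    n <- sample(20:60, 1)
    s <- rand_dna(n, gc = runif(1, 0.25, 0.6))
    mode <- if (t %% 2 == 0) "guide" else "intra"
    k <- sample(4:8, 1); m <- sample(0:3, 1)
    gs <- if (mode == "guide") n - 24L else NA
    o <- oracle_helix(s, m, 3L, gs)
    h <- find_helix(s, helix_params(k, m, mode))
    if (o$bp >= k) {
      expect_false(is.null(h), info = s)
      expect_equal(h$bp_count, o$bp, info = s)
      expect_equal(h$unpaired_count, o$unpaired, info = s)
    } else {
      expect_null(h, info = s)
    }
  }
})

test_that("relaxing parameters never loses a helix (monotonicity)", {
  set.seed(74)
  arm <- rand_dna(11, gc = 0.8)
  planted <- paste0(rand_lowpair(15), arm, rand_lowpair(12), revcomp(arm),
                    rand_lowpair(15))
  cases <- c(planted, replicate(40, rand_dna(70, gc = 0.5)))
  for (s in cases) {
    h_strict <- find_helix(s, helix_params(10, 1, "intra"))
    if (!is.null(h_strict)) {
      expect_false(is.null(find_helix(s, helix_params(9, 1, "intra"))))
      expect_false(is.null(find_helix(s, helix_params(10, 2, "intra"))))
    }
  }
})

test_that("null probabilities reflect composition, not arrangement", {
  gp <- helix_params(8, 2, "guide")
  expect_equal(system_null_prob(strrep("A", 60), gp, 100, seed = 1), 0)
  # alternating GC is self-complementary under any dinucleotide shuffle
  expect_equal(system_null_prob(strrep("GC", 30), gp, 100, seed = 1), 1)
  # a planted perfect duplex in an A-rich background is an arrangement
  # effect, mostly destroyed by shuffling
  set.seed(75)
  arm <- rand_dna(12, gc = 0.9)
  s <- paste0(rand_lowpair(20), arm, rand_lowpair(20), revcomp(arm),
              rand_lowpair(40))
  np <- system_null_prob(s, helix_params(12, 3, "intra"), 100, seed = 2)
  expect_lt(np, 0.2)
  expect_error(system_null_prob(s, gp, n_shuffles = 10), "n_shuffles")
})

test_that("Poisson-binomial tail matches closed forms and Monte Carlo", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 2), 0.25)
  expect_equal(poisson_binomial_tail(rep(0.1, 10), 0), 1.0)
  set.seed(76)
  probs <- runif(50)
  for (x in c(10, 25, 35)) {
    draws <- colSums(matrix(rbinom(50 * 20000, 1, probs), nrow = 50))
    mc <- mean(draws >= x)
    se <- sqrt(mc * (1 - mc) / 20000)
    expect_lt(abs(poisson_binomial_tail(probs, x) - mc), 3 * se + 1e-6)
  }
})

test_that("aggregation floors zero nulls and reports the observed count", {
  enr <- aggregate_enrichment(c(TRUE, TRUE, FALSE), c(0, 0.5, 0.2),
                              n_shuffles = 100)
  expect_equal(enr$n_with_helix, 2L)
  expect_equal(min(enr$null_probs), 1 / 101)
  expect_true(enr$aggregate_p >= 0 && enr$aggregate_p <= 1)
})

test_that("the pairing profile reflects which positions pair", {
  prof <- pairing_profile(list(10:17, 10:17, 10:17))
  expect_equal(prof$frequency[10:17], rep(1, 8))
  expect_equal(prof$frequency[c(1:9, 18:25)], rep(0, 17))
  prof0 <- pairing_profile(list(integer(0), integer(0)))
  expect_equal(prof0$frequency, rep(0, 25))
})

test_that("the parameter scan recovers planted helix geometry", {
  set.seed(77)
  loci <- lapply(1:30, function(i) {
    arm <- rand_dna(12, gc = 0.85)
    up <- paste0(rand_lowpair(30), arm, rand_lowpair(20), revcomp(arm),
                 rand_lowpair(38))
    make_locus(up, rep(rand_dna(36), 3), id = paste0("S", i))
  })
  sc <- parameter_scan(loci, k_range = c(8, 10, 12, 13), m_range = c(0, 2),
                       mode = "intra", n_shuffles = 50, seed = 5)
  expect_false(is.null(sc$chosen))
  expect_equal(sc$chosen$min_bp, 12L)

  # one-cell grid returns that cell
  sc1 <- parameter_scan(loci[1:5], k_range = 12, m_range = 0, mode = "intra",
                        n_shuffles = 50, seed = 6)
  expect_equal(nrow(sc1$grid), 1L)

  # pure-null cohort: no selection after Bonferroni
  set.seed(78)
  null_loci <- lapply(1:25, function(i)
    make_locus(rand_lowpair(100), rep(rand_dna(36), 3), id = paste0("N", i)))
  scn <- parameter_scan(null_loci, k_range = c(10, 12), m_range = c(0, 2),
                        mode = "intra", n_shuffles = 50, seed = 7)
  expect_null(scn$chosen)
})
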