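test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_loci = 6)
  c1 <- generate_cohort(cfg, seed = 7)
  c2 <- generate_cohort(cfg, seed = 7)
  expect_identical(lapply(c1$loci, `[[`, "contig"),
                   lapply(c2$loci, `[[`, "contig"))
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(c1$loci[[1]]$contig, c3$loci[[1]]$contig))
})

test_that("structural invariants hold for every generated locus", {
  cohort <- generate_cohort(synth_config(n_loci = 15, p_rescue = 0.3), seed = 3)
  for (l in cohort$loci) {
    expect_equal(nrow(l$repeats), nrow(l$spacers) + 1L)
    expect_gte(nchar(upstream_seq(l)), 30L)
    expect_lte(nchar(upstream_seq(l)), 180L)
    # tracrRNA starts with the exact reverse complement of the consensus 5' end
    expect_equal(substr(l$tracrRNA, 1, 24), revcomp(substr(l$consensus, 1, 24)))
  }
  # gene annotations bound each upstream region
  expect_equal(nrow(cohort$genes), 15L)
})

test_that("plant probabilities of zero give an all-negative ground truth", {
  cfg <- synth_config(n_loci = 8, p_mutation = 0, p_rit = 0, p_helix = 0,
                      p_nonextra_mutation = 0)
  cohort <- generate_cohort(cfg, seed = 5)
  expect_false(any(cohort$truth$planted_mutation))
  expect_false(any(cohort$truth$planted_rit))
  expect_false(any(cohort$truth$planted_helix))
  ms <- mutation_summary(cohort$loci)
  expect_identical(ms$focus_fraction, 0)
  expect_identical(ms$nonfocus_fraction, 0)
})

test_that("forced mutation plants touch exactly the configured positions", {
  cfg <- synth_config(n_loci = 10, p_mutation = 1,
                      mutation_count_probs = c(0, 1, 0), p_rit = 0,
                      p_helix = 0, p_nonextra_mutation = 0)
  cohort <- generate_cohort(cfg, seed = 9)
  for (i in seq_along(cohort$loci)) {
    l <- cohort$loci[[i]]
    rs <- repeat_seqs(l)
    diffs <- which(strsplit(rs[1], "")[[1]] != strsplit(l$consensus, "")[[1]])
    expect_length(diffs, 2L)
    expect_equal(paste(diffs, collapse = ";"),
                 cohort$truth$mutation_positions[i])
  }
})

test_that("planted features are where the ground truth says", {
  cohort <- generate_cohort(synth_config(n_loci = 30, p_rit = 1, p_helix = 1),
                            seed = 13)
  for (i in seq_along(cohort$loci)) {
    l <- cohort$loci[[i]]
    tr <- cohort$truth[i, ]
    up <- upstream_seq(l)
    # terminator: a call overlapping the planted interval
    calls <- call_terminators(up)
    expect_true(any(calls$start <= tr$rit_end & calls$end >= tr$rit_start),
                info = l$id)
    # helix: the planted arm is the reverse complement of the guide substring
    guide_sub <- substr(up, tr$helix_guide_start, tr$helix_guide_start + 9L)
    arm <- substr(up, tr$helix_arm_start, tr$helix_arm_start + 9L)
    expect_equal(arm, revcomp(guide_sub), info = l$id)
    expect_false(is.null(find_helix(up, helix_params(8, 2, "guide"))))
  }
})

test_that("rescue plants are recoverable by the QC stage", {
  cohort <- generate_cohort(synth_config(n_loci = 6, p_rescue = 1, p_rit = 0,
                                         p_helix = 0), seed = 21)
  rescued <- 0L
  for (l in cohort$loci) {
    r <- rescue_mutated_repeat(l, n_shuffles = 200, seed = 4)
    if (r$accepted) rescued <- rescued + 1L
  }
  expect_gte(rescued, 5L)
})

test_that("null genomes respect the gene-count bound and determinism", {
  g <- generate_null_genome(10, 20000, seed = 2)
  expect_lte(nrow(g$genes), 10L)
  ig <- enumerate_intergenic(g$genes, 20000)
  expect_lte(nrow(ig), nrow(g$genes) + 1L)
  g2 <- generate_null_genome(10, 20000, seed = 2)
  expect_identical(g, g2)
})

test_that("realized composition tracks the configured frequencies", {
  g <- generate_null_genome(0, 100000, gc = 0.40, seed = 6)
  ch <- strsplit(g$contig, "")[[1]]
  mono <- table(ch) / length(ch)
  expect_lt(abs(sum(mono[c("C", "G")]) - 0.40), 0.02)
  di <- table(paste0(ch[-length(ch)], ch[-1])) / (length(ch) - 1)
  exp_p <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  for (d in names(di)) {
    b <- strsplit(d, "")[[1]]
    expect_lt(abs(di[[d]] - exp_p[b[1]] * exp_p[b[2]]), 0.02)
  }
})
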