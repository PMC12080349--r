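plant_terminator <- function(bg_len = 150L, gc = 0.4) {
  stem <- rand_dna(9, gc = 0.85)
  term <- paste0(stem, rand_dna(4, gc = 0.3), revcomp(stem), strrep("T", 8))
  bg <- rand_dna(bg_len, gc)
  pos <- sample(seq_len(bg_len - 30L), 1)
  list(seq = paste0(substr(bg, 1, pos - 1), term, substr(bg, pos, bg_len)),
       start = pos, end = pos + nchar(term) - 1L)
}

test_that("a planted canonical terminator yields one spanning call", {
  set.seed(81)
  for (t in 1:30) {
    pl <- plant_terminator()
    calls <- call_terminators(pl$seq)
    expect_gte(nrow(calls), 1L)
    # some call overlaps the plant
    expect_true(any(calls$start <= pl$end & calls$end >= pl$start))
  }
})

test_that("both hairpin and U-tract are required", {
  set.seed(82)
  stem <- rand_dna(9, 0.85)
  no_tail <- paste0(strrep("A", 40), stem, "TTCA", revcomp(stem), strrep("A", 48))
  expect_equal(nrow(call_terminators(no_tail)), 0L)
  no_stem <- paste0(strrep("A", 40), strrep("T", 8), strrep("A", 60))
  expect_equal(nrow(call_terminators(no_stem)), 0L)
})

test_that("one interior mismatch is tolerated only for long stems", {
  # 10-bp stem with a central mismatch (>= stem_min + 2 pairs overall)
  stem <- "GGCGCCGCGG"
  rc <- revcomp(stem)
  substr(rc, 5, 5) <- "A" # break one pair
  # pairs: 4 before + 5 after the mismatch = 9 < 10 = stem_min + 2 -> reject
  s1 <- paste0(strrep("A", 30), stem, "TTCG", rc, strrep("T", 8), strrep("A", 30))
  cfg <- terminator_config(stem_min = 8)
  got <- call_terminators(s1, cfg)
  expect_true(nrow(got) == 0L || all(got$stem_bp >= 8))
  # 12-bp stem with a central mismatch: 11 pairs >= 10 -> accepted
  stem2 <- "GGCGCCGCGGCC"
  rc2 <- revcomp(stem2)
  substr(rc2, 6, 6) <- "A"
  s2 <- paste0(strrep("A", 30), stem2, "TTCG", rc2, strrep("T", 8), strrep("A", 30))
  expect_gte(nrow(call_terminators(s2, cfg)), 1L)
})

test_that("intergenic enumeration is the strict complement of merged genes", {
  ig <- enumerate_intergenic(data.frame(start = c(1, 201), end = c(100, 300)), 400)
  expect_equal(ig$start, c(101L, 301L))
  expect_equal(ig$end, c(200L, 400L))
  # a 20-nt gap is excluded
  ig2 <- enumerate_intergenic(data.frame(start = c(1, 121), end = c(100, 300)), 300)
  expect_equal(nrow(ig2), 0L)
  # no genes: whole contig
  ig3 <- enumerate_intergenic(data.frame(start = integer(), end = integer()), 500)
  expect_equal(ig3, data.frame(start = 1L, end = 500L))
  # complement property: intergenic + merged genes tile the contig
  set.seed(83)
  genes <- data.frame(start = sort(sample(1:900, 5)) * 2)
  genes$end <- genes$start + sample(50:200, 5)
  clen <- 2200L
  genes$end <- pmin(genes$end, clen)
  ig4 <- enumerate_intergenic(genes, clen, min_len = 0L)
  merged <- ecrmech:::.merge_intervals(genes$start, genes$end)
  covered <- sum(ig4$end - ig4$start + 1L) + sum(merged$end - merged$start + 1L)
  expect_equal(covered, clen)
})

test_that("observed/expected RIT ratios follow their definitions", {
  set.seed(84)
  # 10 loci, 3 with a planted upstream terminator
  loci <- lapply(1:10, function(i) {
    up <- if (i <= 3) plant_terminator(120)$seq else strrep("A", 150)
    make_locus(up, rep(rand_dna(36), 3), id = paste0("R", i))
  })
  rep1 <- rit_ratio_report(loci)
  expect_equal(rep1$observed_rits, 3L)
  expect_equal(rep1$observed_ratio, 0.3)
  expect_true(is.na(rep1$expected_ratio))
  # order invariance
  rep2 <- rit_ratio_report(rev(loci))
  expect_equal(rep2$observed_ratio, rep1$observed_ratio)

  # expected ratio is the mean of per-genome intergenic fractions
  g1 <- generate_null_genome(8, 8000, seed = 11)
  g2 <- generate_null_genome(8, 8000, seed = 12)
  rep3 <- rit_ratio_report(loci, genomes = list(g1, g2))
  expect_equal(rep3$expected_ratio, mean(rep3$per_genome))
  expect_true(rep3$expected_ratio >= 0 && rep3$expected_ratio <= 1)
})

test_that("imported terminator calls round-trip through the adapter", {
  tf <- tempfile(fileext = ".gff")
  writeLines(c("# comment",
               "ctg1\trnie\tterminator\t100\t130\t25.3\t+\t.\tid=t1",
               "ctg2\trnie\tterminator\t50\t80\t12.0\t-\t.\tid=t2"), tf)
  imp <- import_terminators(tf)
  expect_equal(nrow(imp), 2L)
  expect_equal(imp$start, c(100L, 50L))
  expect_equal(imp$source, rep("imported", 2))
  unlink(tf)
})
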