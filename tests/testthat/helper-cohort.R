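# quick constructors for hand-built loci

# build a locus whose upstream region is exactly `upstream` and whose
# array consists of the given repeat sequences separated by random spacers
make_locus <- function(upstream, repeats, id = "L1", spacer_len = 30L,
                       tracr = NULL, strand = "+", consensus = NULL,
                       subtype = "II-C", gene_gap = NULL) {
  n_rep <- length(repeats)
  spacers <- replicate(max(0L, n_rep - 1L), rand_dna(spacer_len))
  array_seq <- if (n_rep > 1L)
    paste0(paste0(repeats[-n_rep], spacers, collapse = ""), repeats[n_rep])
  else repeats
  gene <- rand_dna(120L)
  contig_fwd <- paste0(gene, upstream, array_seq, rand_dna(40L))
  rl <- nchar(repeats)
  starts <- integer(n_rep)
  pos <- nchar(gene) + nchar(upstream) + 1L
  for (t in seq_len(n_rep)) {
    starts[t] <- pos
    pos <- pos + rl[t] + if (t < n_rep) spacer_len else 0L
  }
  reps <- data.frame(start = starts, end = starts + rl - 1L)
  clen <- nchar(contig_fwd)
  if (strand == "-") {
    contig <- ecrmech::revcomp(contig_fwd)
    reps <- data.frame(start = clen - reps$end + 1L, end = clen - reps$start + 1L)
  } else contig <- contig_fwd
  crispr_locus(id = id, contig = contig, repeats = reps, strand = strand,
               subtype = subtype, tracrRNA = tracr, consensus = consensus,
               contig_id = paste0("ctg_", id),
               upstream_max = nchar(upstream))
}

# substitute k random positions of a sequence (different bases)
mutate_seq <- function(s, positions) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
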