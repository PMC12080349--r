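Synthetic example data (two loci) produced by `generate_cohort()` with
planted terminators and guide helices; regenerate with seed 99.

- example_contigs.fasta : contig sequences
- example_loci.json     : locus descriptors (1-based inclusive intervals)
- example_genes.gff3    : upstream gene annotations
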