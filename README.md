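# ecrmech

Screening type II-C CRISPR-Cas loci for mechanisms that suppress the
extraneous CRISPR RNA (ecrRNA).

## The problem

A CRISPR array always carries one more repeat than spacers.  The spare
("extra") repeat — in type II systems the first repeat in transcription
order — would be transcribed and processed into an *extraneous* crRNA whose
"guide" is simply the 25 nt of intergenic sequence upstream of the array.
Such ecrRNAs load Cas9 without directing immunity and so dilute the
defence.  Type II-A systems silence the ecrRNA with a leader:repeat
hairpin, but type II-C arrays are organised differently (each repeat has
its own promoter, spacers are acquired at the distal end), so other
mechanisms must act.  This package implements an in-silico screen for
three candidate mechanisms in II-C systems:

1. **Extra-repeat mutations** — the first repeat is also the oldest and
   accumulates mutations that are expected to disrupt the
   repeat:tracrRNA duplex needed for crRNA processing.
2. **Rho-independent terminators (RITs)** — an intrinsic terminator
   (hairpin + poly-U tract) in the upstream region insulates the array
   from read-through transcription.
3. **Guide-sequestering helices** — RNA helices pairing the 25-nt ecrRNA
   guide window with the upstream region can block processing or
   targeting.

## Methods at a glance

* **Array QC**: mutated repeats hidden in the upstream region are rescued
  by a seeded Smith-Waterman search (match +1 / mismatch −1, gap 2/1,
  word size 5) gated on distance (implied spacer length 20–45 nt),
  identity (> 70%) and an **empirical e-value**: the fraction of 1000
  dinucleotide-shuffled upstream regions containing a better-scoring hit
  must be below 0.01.  The upstream region is then trimmed at the nearest
  upstream gene (cap 180 nt; discard below 30 nt).
* **Mutation profiling**: each repeat is globally aligned to the array
  consensus (match +5 / mismatch −4, gap 10/4, end gaps 10/4); mutations
  are mismatch plus gap columns, reported on consensus coordinates.
* **Helix enrichment**: a qualifying helix has ≥ k Watson-Crick pairs
  with ≤ m unpaired (bulge/internal-loop) nucleotides — (12, 3) within
  the upstream region, (8, 2) for helices whose 3' arm overlaps the guide
  window.  Per system, a null probability is estimated from dinucleotide
  shuffles; cohort-level enrichment is the exact Poisson-binomial upper
  tail of the observed helix count, P(X ≥ X_obs).
* **RIT calling**: a native stem-loop + U-tract detector (stem ≥ 8 pairs
  WC+G·U, loop 3–10 nt, ≥ 6 T in an 8-nt window within 3 nt of the stem),
  with Table-1-style observed vs expected ratios over intergenic regions.
* **Duplex energies**: tracrRNA vs extra/consensus repeat minimum-free-
  energy hybridization under a nearest-neighbour model (Turner-style
  Watson-Crick stacks, initiation penalty, per-nucleotide loop penalty),
  compared with a Mann-Whitney U test.
* **Mechanism calling**: flags per locus — ≥ 2 extra-repeat mutations, ≥ 1
  upstream RIT, or a qualifying helix with occurrence probability > 75%
  (1 − shuffle-null probability) — plus the Venn decomposition.
* **Synthetic cohorts**: `generate_cohort()` builds loci with planted
  mutations, terminators, helices and rescuable repeats at configurable
  prevalences, with full ground truth, so every stage is testable.

## Worked example

```r
library(ecrmech)
cohort <- generate_cohort(synth_config(n_loci = 40), seed = 7)
run <- run_pipeline(cohort$loci, genes = cohort$genes, seed = 7)
print(run)
```

```
ecrRNA suppression screen: 40 loci in, 40 after QC, 40 after dereplication
Mutation summary over 40 arrays (243 repeats, focus = first repeat)
  focus repeats with >= 1 mutation: 65.0%
  other repeats with >= 1 mutation: 5.9%
  count histogram (focus / other):
        0  1 2 3+
focus  14 16 4  6
other 191 12 0  0
RIT report [II-C]: 4 / 40 systems with an upstream RIT (ratio 0.10, 10%)
  mean upstream length 180 nt; expected intergenic ratio n/a
Helix enrichment [intra 12 bp / 3 unpaired]: 22 / 40 systems (expected 15.0), P = 0.0159
Helix enrichment [guide 8 bp / 2 unpaired]: 38 / 40 systems (expected 35.8), P = 0.183
Helix enrichment [guide, RIT systems removed]: 34 / 36 systems (expected 32.2), P = 0.244
tracrRNA interaction energies over 40 loci
  median extra repeat:     -36.7 kcal/mol
  median consensus repeat: -41.8 kcal/mol
  Mann-Whitney U = 1097.0, two.sided P = 0.00433
Mechanism assignment over 40 systems (30% assigned)
  mutation             8
  ...
```

Reading the output: 65% of extra repeats carry at least one mutation
versus 5.9% of the other repeats (the generator plants them at 60% / 5%);
the upstream-internal 12-bp helix count (22 observed vs 15 expected under
the shuffle null) is enriched at P = 0.016; the energy comparison shows
the planted extra-repeat mutations weakening the tracrRNA interaction
(−36.7 vs −41.8 kcal/mol median).  Individual stages are exported too:
`rescue_mutated_repeat()`, `count_mutations()`, `find_helix()`,
`system_null_prob()`, `call_terminators()`, `interaction_energy()`,
`assign_mechanisms()`, and so on — see the help pages and the methods
vignette (`vignettes/ecrmech-methods.Rmd`).

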