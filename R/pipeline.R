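#' Deterministic train/test split of a cohort
#'
#' Loci are assigned to the training split by a deterministic hash of
#' their id, so the split is stable across runs and machines.
#'
#' @param loci list of `crispr_locus` objects.
#' @param train_fraction fraction assigned to training.
#' @param seed integer salt for the hash.
#' @return a list with `train` and `test` (disjoint lists of loci).
#' @export
split_cohort <- function(loci, train_fraction = 0.55, seed = 1L) {
  h <- vapply(loci, function(l) .child_seed(seed, l$id) / 2147483629, 0)
  train <- h < train_fraction
  list(train = loci[train], test = loci[!train])
}

#' Run the full ecrRNA-suppression screen on a cohort
#'
#' Stages, in order: quality control (mutated-repeat rescue and upstream
#' trimming), array dereplication, repeat mutation summary, terminator
#' calling and the observed/expected RIT ratio, helix enrichment (intra
#' and guide modes, the guide mode additionally rerun after excluding
#' systems with a predicted RIT), repeat:tracrRNA duplex-energy
#' comparison, and mechanism assignment with a Venn decomposition.
#' Deterministic given `seed`.
#'
#' @param loci list of `crispr_locus` objects (e.g. from
#'   [generate_cohort()] or [read_locus_json()]).
#' @param genes optional gene annotation data.frame (`contig`, `start`,
#'   `end`) used for upstream trimming.
#' @param genomes optional list of genomes (each `list(contig, genes)`)
#'   for the expected RIT ratio.
#' @param seed master seed (all stage seeds derive from it).
#' @param rescue run the mutated-repeat rescue stage.
#' @param rescue_shuffles shuffle-null size for the rescue e-value.
#' @param helix_shuffles per-system shuffle-null size for helix stages.
#' @param intra,guide [helix_params()] for the two helix modes.
#' @param term_config a [terminator_config()].
#' @param energy run the duplex-energy stage (needs tracrRNAs).
#' @param mechanisms run the mechanism caller (requires the other stages).
#' @param helix_occurrence occurrence-probability threshold for the helix
#'   mechanism (default 0.75).
#' @param focus focus repeat for the mutation summary (`"first"` for
#'   II-C).
#' @return an object of class `ecr_run`: stage outputs (`qc`, `mutation`,
#'   `rit`, `helix_intra`, `helix_guide`, `helix_guide_norit`, `energy`,
#'   `assignments`, `venn`) plus a `manifest`.
#' @export
run_pipeline <- function(loci, genes = NULL, genomes = NULL, seed = 1L,
                         rescue = TRUE, rescue_shuffles = 1000L,
                         helix_shuffles = 100L,
                         intra = helix_params(mode = "intra"),
                         guide = helix_params(mode = "guide"),
                         term_config = terminator_config(),
                         energy = TRUE, mechanisms = TRUE,
                         helix_occurrence = 0.75,
                         focus = c("first", "last")) {
  focus <- match.arg(focus)
  n_input <- length(loci)

  # stage 1: QC
  qc <- qc_cohort(loci, genes = genes, n_shuffles = rescue_shuffles,
                  seed = .child_seed(seed, "qc"), rescue = rescue)
  kept <- Filter(function(l) !l$rejected, qc$loci)

  # stage 2: dereplication + mutation summary
  dedup <- dereplicate_arrays(kept)
  mut <- mutation_summary(dedup, focus = focus)
  extra_mut <- setNames(rep(NA_integer_, length(dedup)),
                        vapply(dedup, `[[`, "", "id"))
  for (l in dedup) {
    rs <- repeat_seqs(l)
    i <- if (focus == "first") 1L else length(rs)
    extra_mut[l$id] <- count_mutations(rs[i], l$consensus)$mutations
  }

  # stage 4 (before helix, so the RIT-exclusion rerun can use it)
  rit <- rit_ratio_report(dedup, genomes = genomes, config = term_config,
                          label = dedup[[1]]$subtype)

  # stage 3: helix enrichment
  hseed <- .child_seed(seed, "helix")
  h_intra <- helix_enrichment(dedup, intra, n_shuffles = helix_shuffles,
                              seed = .child_seed(hseed, "intra"))
  h_guide <- helix_enrichment(dedup, guide, n_shuffles = helix_shuffles,
                              seed = .child_seed(hseed, "guide"))
  # guide-mode rerun with RIT systems removed (nulls are reusable: the
  # exclusion only drops systems)
  h_guide_norit <- NULL
  no_rit <- !rit$upstream_has_rit[h_guide$per_system$locus]
  if (sum(no_rit) >= 2L) {
    ps <- h_guide$per_system[no_rit, , drop = FALSE]
    h_guide_norit <- list(
      per_system = ps,
      enrichment = aggregate_enrichment(ps$has_helix, ps$null_prob,
                                        n_shuffles = helix_shuffles,
                                        label = "guide, RIT systems removed"))
  }

  # stage 5: duplex energies
  en <- NULL
  if (energy) {
    filt <- filter_redundant_tracrs(dedup)
    if (length(filt) >= 1L) en <- compare_cohort(filt)
  }

  # stage 6: mechanism assignment
  assignments <- NULL; venn <- NULL
  if (mechanisms) {
    ids <- vapply(dedup, `[[`, "", "id")
    stages <- data.frame(
      locus = ids,
      extra_mutations = as.integer(extra_mut[ids]),
      n_rit = as.integer(rit$upstream_has_rit[ids]),
      helix_intra = h_intra$per_system$has_helix[match(ids, h_intra$per_system$locus)],
      null_intra = h_intra$per_system$null_prob[match(ids, h_intra$per_system$locus)],
      helix_guide = h_guide$per_system$has_helix[match(ids, h_guide$per_system$locus)],
      null_guide = h_guide$per_system$null_prob[match(ids, h_guide$per_system$locus)],
      stringsAsFactors = FALSE)
    assignments <- assign_mechanisms(stages, occurrence = helix_occurrence)
    venn <- venn_summary(assignments)
  }

  manifest <- list(
    seed = seed, n_input = n_input, n_kept = length(kept),
    n_dereplicated = length(dedup),
    rescue = rescue, rescue_shuffles = rescue_shuffles,
    helix_shuffles = helix_shuffles,
    intra_params = unclass(intra), guide_params = unclass(guide),
    terminator = unclass(term_config),
    stages_run = c("qc", "mutation", "rit", "helix",
                   if (energy) "energy", if (mechanisms) "mechanisms"))

  structure(list(qc = qc, mutation = mut, extra_mutations = extra_mut,
                 rit = rit, helix_intra = h_intra, helix_guide = h_guide,
                 helix_guide_norit = h_guide_norit, energy = en,
                 assignments = assignments, venn = venn,
                 manifest = manifest),
            class = "ecr_run")
}

#' @export
print.ecr_run <- function(x, ...) {
  cat(sprintf("ecrRNA suppression screen: %d loci in, %d after QC, %d after dereplication\n",
              x$manifest$n_input, x$manifest$n_kept, x$manifest$n_dereplicated))
  print(x$mutation)
  print(x$rit)
  print(x$helix_intra$enrichment)
  print(x$helix_guide$enrichment)
  if (!is.null(x$helix_guide_norit)) print(x$helix_guide_norit$enrichment)
  if (!is.null(x$energy)) print(x$energy)
  if (!is.null(x$venn)) print(x$venn)
  invisible(x)
}

#' Consolidated summary report of a pipeline run
#'
#' Assembles the headline tables: the Table-1-style RIT ratios, the
#' mutation-summary fractions, the helix enrichment p-values per mode,
#' the energy comparison, and the mechanism Venn counts.  Ratios are
#' rounded to 2 decimals and percentages to integers in the tables;
#' machine-readable values are unrounded.
#'
#' @param run an `ecr_run` object.
#' @param outdir optional directory; when given, TSV/JSON artifacts are
#'   written there.
#' @return a list of data.frames (`rit`, `mutation`, `enrichment`,
#'   `energy`, `venn`) plus `values` (unrounded headline numbers).
#' @export
summary_report <- function(run, outdir = NULL) {
  rit_tab <- data.frame(
    cohort = run$rit$label,
    avg_intergenic_len = round(run$rit$avg_intergenic_len),
    observed_rit = run$rit$observed_rits,
    systems_analyzed = run$rit$systems_analyzed,
    ratio = round(run$rit$observed_ratio, 2),
    ratio_percent = sprintf("%.0f%%", 100 * run$rit$observed_ratio),
    expected_ratio = round(run$rit$expected_ratio, 2))
  mut_tab <- data.frame(
    class = c("extra", "non-extra"),
    fraction_mutated = round(c(run$mutation$focus_fraction,
                               run$mutation$nonfocus_fraction), 2),
    percent = sprintf("%.0f%%", 100 * c(run$mutation$focus_fraction,
                                        run$mutation$nonfocus_fraction)))
  enr_rows <- list(
    data.frame(mode = "intra", n_obs = run$helix_intra$enrichment$n_with_helix,
               expected = run$helix_intra$enrichment$expected,
               p = run$helix_intra$enrichment$aggregate_p),
    data.frame(mode = "guide", n_obs = run$helix_guide$enrichment$n_with_helix,
               expected = run$helix_guide$enrichment$expected,
               p = run$helix_guide$enrichment$aggregate_p))
  if (!is.null(run$helix_guide_norit))
    enr_rows <- c(enr_rows, list(
      data.frame(mode = "guide-noRIT",
                 n_obs = run$helix_guide_norit$enrichment$n_with_helix,
                 expected = run$helix_guide_norit$enrichment$expected,
                 p = run$helix_guide_norit$enrichment$aggregate_p)))
  enr_tab <- do.call(rbind, enr_rows)
  en_tab <- NULL
  if (!is.null(run$energy))
    en_tab <- data.frame(n = run$energy$n,
                         median_extra = run$energy$median_extra,
                         median_consensus = run$energy$median_consensus,
                         U = run$energy$U, p = run$energy$p_value)
  venn_tab <- NULL
  if (!is.null(run$venn))
    venn_tab <- data.frame(region = names(run$venn$counts),
                           count = as.integer(run$venn$counts))
  values <- list(
    observed_rit_ratio = run$rit$observed_ratio,
    expected_rit_ratio = run$rit$expected_ratio,
    extra_mutated_fraction = run$mutation$focus_fraction,
    nonextra_mutated_fraction = run$mutation$nonfocus_fraction,
    helix_intra_p = run$helix_intra$enrichment$aggregate_p,
    helix_guide_p = run$helix_guide$enrichment$aggregate_p,
    helix_guide_norit_p = if (is.null(run$helix_guide_norit)) NA_real_
                          else run$helix_guide_norit$enrichment$aggregate_p,
    energy_median_extra = if (is.null(run$energy)) NA_real_ else run$energy$median_extra,
    energy_median_consensus = if (is.null(run$energy)) NA_real_
                              else run$energy$median_consensus,
    energy_p = if (is.null(run$energy)) NA_real_ else run$energy$p_value,
    assigned_fraction = if (is.null(run$venn)) NA_real_ else run$venn$assigned_fraction)
  out <- list(rit = rit_tab, mutation = mut_tab, enrichment = enr_tab,
              energy = en_tab, venn = venn_tab, values = values)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(rit_tab, file.path(outdir, "rit_report.tsv"),
               "observed vs expected intrinsic terminators")
    .write_tsv(mut_tab, file.path(outdir, "mutation_summary.tsv"),
               "repeats with >= 1 mutation vs the array consensus")
    .write_tsv(enr_tab, file.path(outdir, "helix_enrichment.tsv"),
               "shuffle-null helix enrichment")
    .write_tsv(run$mutation$records, file.path(outdir, "repeat_mutations.tsv"),
               "per-repeat mutation records")
    if (!is.null(en_tab))
      .write_tsv(en_tab, file.path(outdir, "energy_comparison.tsv"),
                 "tracrRNA interaction energies, extra vs consensus repeat")
    if (!is.null(venn_tab))
      .write_tsv(venn_tab, file.path(outdir, "mechanism_venn.tsv"),
                 "mechanism assignment Venn counts")
    jsonlite::write_json(values, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
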