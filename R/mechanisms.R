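#' Assign candidate ecrRNA-suppression mechanisms per locus
#'
#' Flags each locus by the three thresholds: (1) mutation mechanism - the
#' extra repeat carries at least `min_mutations` mutations; (2) RIT
#' mechanism - at least one terminator call in the upstream region;
#' (3) helix mechanism - a qualifying helix (either upstream-internal or
#' overlapping the ecrRNA guide window) whose occurrence probability
#' exceeds `occurrence`, where the occurrence probability of an observed
#' helix is 1 minus its shuffle-null probability (the confidence that the
#' helix is not a composition artifact).
#'
#' @param stages data.frame with one row per locus and columns `locus`,
#'   `extra_mutations` (integer), `n_rit` (integer), `helix_intra`,
#'   `null_intra`, `helix_guide`, `null_guide` (logical / numeric; any of
#'   the helix columns may be omitted if that mode was not run).  Rows
#'   with `NA` in a required column are excluded with a message.
#' @param min_mutations mutation-count threshold (default 2).
#' @param occurrence helix occurrence-probability threshold (default 0.75).
#' @return data.frame: `locus`, `has_mutation_mechanism`,
#'   `has_rit_mechanism`, `has_helix_mechanism`, `assigned`.
#' @export
assign_mechanisms <- function(stages, min_mutations = 2L, occurrence = 0.75) {
  stopifnot(is.data.frame(stages),
            all(c("locus", "extra_mutations", "n_rit") %in% names(stages)))
  need <- c("extra_mutations", "n_rit")
  ok <- !Reduce(`|`, lapply(stages[need], is.na))
  if (any(!ok))
    message(sum(!ok), " locus/loci with missing stage output excluded")
  stages <- stages[ok, , drop = FALSE]
  helix_flag <- rep(FALSE, nrow(stages))
  for (mode in c("intra", "guide")) {
    hcol <- paste0("helix_", mode); ncol <- paste0("null_", mode)
    if (all(c(hcol, ncol) %in% names(stages))) {
      f <- !is.na(stages[[hcol]]) & stages[[hcol]] &
        (1 - stages[[ncol]]) > occurrence
      helix_flag <- helix_flag | f
    }
  }
  out <- data.frame(locus = stages$locus,
                    has_mutation_mechanism = stages$extra_mutations >= min_mutations,
                    has_rit_mechanism = stages$n_rit >= 1L,
                    has_helix_mechanism = helix_flag,
                    stringsAsFactors = FALSE)
  out$assigned <- out$has_mutation_mechanism | out$has_rit_mechanism |
    out$has_helix_mechanism
  out
}

#' Venn decomposition of mechanism assignments
#'
#' Counts the seven non-empty mechanism intersections plus the unassigned
#' class, and the assigned fraction.
#'
#' @param assignments data.frame as returned by [assign_mechanisms()].
#' @return an object of class `venn_summary` with `counts` (named:
#'   `mutation`, `rit`, `helix`, `mutation+rit`, `mutation+helix`,
#'   `rit+helix`, `mutation+rit+helix`, `none`), `total` and
#'   `assigned_fraction`.
#' @export
venn_summary <- function(assignments) {
  stopifnot(nrow(assignments) >= 1L)
  m <- assignments$has_mutation_mechanism
  r <- assignments$has_rit_mechanism
  h <- assignments$has_helix_mechanism
  counts <- c(
    "mutation" = sum(m & !r & !h),
    "rit" = sum(!m & r & !h),
    "helix" = sum(!m & !r & h),
    "mutation+rit" = sum(m & r & !h),
    "mutation+helix" = sum(m & !r & h),
    "rit+helix" = sum(!m & r & h),
    "mutation+rit+helix" = sum(m & r & h),
    "none" = sum(!m & !r & !h))
  structure(list(counts = counts, total = nrow(assignments),
                 assigned_fraction = 1 - counts[["none"]] / nrow(assignments)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("Mechanism assignment over %d systems (%.0f%% assigned)\n",
              x$total, 100 * x$assigned_fraction))
  for (nm in names(x$counts))
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
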