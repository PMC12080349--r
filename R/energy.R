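#' Intermolecular RNA-RNA interaction energy
#'
#' Minimum-free-energy hybridization duplex between two RNAs under a
#' nearest-neighbour model: Turner-style stack free energies for
#' Watson-Crick stacks (a simplified constant for wobble-containing
#' stacks), a duplex initiation penalty, and a fixed per-nucleotide
#' penalty for bulge/internal-loop nucleotides.  No intramolecular
#' accessibility term is included; the engine scores hybridization only.
#'
#' @param rna_a,rna_b sequences (>= 8 nt; T and U are equivalent).
#' @param init duplex initiation penalty in kcal/mol (default 4.1).
#' @param loop_penalty per-unpaired-nucleotide penalty in kcal/mol
#'   (default 1.0).
#' @param max_loop maximum total unpaired nucleotides between consecutive
#'   pairs (default 16).
#' @return an object of class `duplex_energy`: `interaction` (logical),
#'   and when an interaction exists `energy` (kcal/mol, < 0), `n_pairs`
#'   (paired nucleotides per strand) and `pairs` (two-column matrix of
#'   paired positions, 1-based: column 1 on `rna_a` 5'->3', column 2 on
#'   `rna_b`).
#' @export
#' @examples
#' interaction_energy("ACGUACGUACGUACGU", revcomp("ACGTACGTACGTACGT"))
interaction_energy <- function(rna_a, rna_b, init = 4.1, loop_penalty = 1.0,
                               max_loop = 16L) {
  a <- .norm_seq(rna_a, "rna_a"); b <- .norm_seq(rna_b, "rna_b")
  if (grepl("N", a, fixed = TRUE) || grepl("N", b, fixed = TRUE))
    stop("ambiguous residues (N) are not allowed in energy calculations")
  if (nchar(a) < 8L || nchar(b) < 8L)
    stop("both sequences must be at least 8 nt")
  r <- .duplex_energy_cpp(.enc(a), .enc(b), init, loop_penalty,
                          as.integer(max_loop))
  structure(r, class = "duplex_energy")
}

#' @export
print.duplex_energy <- function(x, ...) {
  if (!isTRUE(x$interaction)) cat("No favourable interaction (energy >= 0)\n")
  else cat(sprintf("Duplex: %.2f kcal/mol over %d base pairs\n",
                   x$energy, x$n_pairs))
  invisible(x)
}

#' Remove loci with redundant tracrRNAs
#'
#' Greedy identity clustering of the tracrRNA sequences at `threshold`
#' (CD-HIT-style identity); one representative locus per cluster is
#' retained.  Loci without a tracrRNA are excluded with a message.
#'
#' @param loci list of `crispr_locus` objects.
#' @param threshold identity threshold (default 0.70).
#' @return the filtered list.
#' @export
filter_redundant_tracrs <- function(loci, threshold = 0.70) {
  has <- vapply(loci, function(l) !is.null(l$tracrRNA), FALSE)
  if (any(!has))
    message(sum(!has), " locus/loci without a tracrRNA excluded")
  loci <- loci[has]
  if (length(loci) == 0L) return(loci)
  cl <- greedy_identity_cluster(vapply(loci, `[[`, "", "tracrRNA"), threshold)
  loci[cl$representatives]
}

#' Mann-Whitney U test
#'
#' U is computed by pair counting with half credit for ties.  The p-value
#' is exact (full permutation distribution) when the pooled sample size is
#' at most 20 and there are no ties, else a normal approximation with tie
#' and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @return a list with `U`, `p_value`, `alternative`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), "less")
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  U <- sum(cmp)
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 20L && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  list(U = U, p_value = wt$p.value, alternative = alternative)
}

#' Cohort energy comparison: extra repeat vs consensus repeat
#'
#' For each locus the interaction energy between the tracrRNA and (a) the
#' extra repeat (repeat 1) and (b) the consensus repeat is computed with
#' [interaction_energy()]; the two energy samples are compared with a
#' Mann-Whitney U test (two-sided by default).  Sequences with no
#' favourable interaction contribute 0 kcal/mol.
#'
#' @param loci redundancy-filtered list of `crispr_locus` objects with
#'   tracrRNAs (see [filter_redundant_tracrs()]).
#' @param alternative test sidedness (default two-sided).
#' @return an object of class `cohort_energy`: per-locus data.frame,
#'   medians, `U`, `p_value`.
#' @export
compare_cohort <- function(loci, alternative = "two.sided") {
  loci <- Filter(function(l) !l$rejected && !is.null(l$tracrRNA), loci)
  stopifnot(length(loci) >= 1L)
  rows <- lapply(loci, function(l) {
    rs <- repeat_seqs(l)
    e1 <- interaction_energy(l$tracrRNA, rs[1L])
    e2 <- interaction_energy(l$tracrRNA, l$consensus)
    data.frame(locus = l$id,
               energy_extra = if (isTRUE(e1$interaction)) e1$energy else 0,
               energy_consensus = if (isTRUE(e2$interaction)) e2$energy else 0,
               length_extra = if (isTRUE(e1$interaction)) e1$n_pairs else 0L,
               length_consensus = if (isTRUE(e2$interaction)) e2$n_pairs else 0L,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  U <- NA_real_; p <- NA_real_
  if (nrow(per_locus) >= 2L) {
    mw <- mann_whitney_u(per_locus$energy_extra, per_locus$energy_consensus,
                         alternative)
    U <- mw$U; p <- mw$p_value
  } else {
    warning("single-locus cohort: medians reported, test skipped")
  }
  structure(list(per_locus = per_locus, n = nrow(per_locus),
                 median_extra = median(per_locus$energy_extra),
                 median_consensus = median(per_locus$energy_consensus),
                 U = U, p_value = p, alternative = alternative),
            class = "cohort_energy")
}

#' @export
print.cohort_energy <- function(x, ...) {
  cat(sprintf("tracrRNA interaction energies over %d loci\n", x$n))
  cat(sprintf("  median extra repeat:     %.1f kcal/mol\n", x$median_extra))
  cat(sprintf("  median consensus repeat: %.1f kcal/mol\n", x$median_consensus))
  if (!is.na(x$p_value))
    cat(sprintf("  Mann-Whitney U = %.1f, %s P = %.3g\n", x$U, x$alternative,
                x$p_value))
  invisible(x)
}
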