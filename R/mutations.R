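#' Remove redundant arrays (exact duplicate repeat content)
#'
#' Arrays are dereplicated on the concatenation of all repeat sequences
#' (identity threshold 1): the first-seen locus of each class is retained.
#'
#' @param loci list of `crispr_locus` objects.
#' @return the dereplicated list.
#' @export
dereplicate_arrays <- function(loci) {
  if (length(loci) == 0L) return(loci)
  keys <- vapply(loci, function(l) paste(repeat_seqs(l), collapse = ""), "")
  loci[!duplicated(keys)]
}

#' Repeats retained for mutation counting (length filter)
#'
#' Repeats whose length differs from the consensus by two or more
#' nucleotides are excluded from mutation counting (they remain part of
#' the locus).
#'
#' @param locus a `crispr_locus`.
#' @return integer indices (transcription order) of retained repeats.
#' @export
filter_length_outliers <- function(locus) {
  rs <- repeat_seqs(locus)
  which(abs(nchar(rs) - nchar(locus$consensus)) < 2L)
}

#' Count mutations of one repeat against the consensus
#'
#' The repeat is globally aligned to the consensus (match +5 / mismatch -4,
#' gap 10/4, terminal gaps 10/4) and mutations are the mismatch columns
#' plus the gap columns.  Positions are reported in consensus coordinates
#' (1-based, 5'->3' in transcription orientation); an insertion column
#' takes the nearest 5' consensus position.
#'
#' @param repeat_seq repeat sequence (transcription orientation).
#' @param consensus consensus repeat sequence.
#' @param gap_run_as_one count a run of contiguous gap columns on the same
#'   strand as a single mutation (default FALSE: one per column).
#' @return a list with `mutations`, `positions`, `mismatches`,
#'   `gap_columns`.
#' @export
#' @examples
#' count_mutations("ACGTACGTA", "ACGAACGTA")
count_mutations <- function(repeat_seq, consensus, gap_run_as_one = FALSE) {
  al <- global_align(repeat_seq, consensus)
  ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
  pos <- 0L
  positions <- integer(0)
  prev_gap <- "" # strand of the previous column's gap, for run merging
  for (k in seq_along(ca)) {
    if (cb[k] != "-") pos <- pos + 1L
    if (ca[k] == "-") {            # deletion in the repeat
      if (!(gap_run_as_one && prev_gap == "a"))
        positions <- c(positions, pos)
      prev_gap <- "a"
    } else if (cb[k] == "-") {     # insertion in the repeat
      if (!(gap_run_as_one && prev_gap == "b"))
        positions <- c(positions, max(1L, pos))
      prev_gap <- "b"
    } else {
      if (ca[k] != cb[k]) positions <- c(positions, pos)
      prev_gap <- ""
    }
  }
  list(mutations = length(positions), positions = positions,
       mismatches = al$mismatches, gap_columns = al$gap_columns)
}

#' Cohort mutation summary: focus repeat vs other repeats
#'
#' Counts mutations per retained repeat against each array's consensus and
#' contrasts the focus class (the extra repeat: `focus = "first"` for
#' type II-C, where the extra repeat is the first and oldest repeat;
#' `focus = "last"` for the type II-A oldest-repeat comparison) with all
#' other repeats.
#'
#' @param loci list of `crispr_locus` objects (post QC; rejected loci are
#'   skipped).
#' @param focus `"first"` or `"last"`.
#' @param gap_run_as_one see [count_mutations()].
#' @return an object of class `mutation_summary`: per-repeat `records`,
#'   class fractions with >= 1 mutation, count histogram (0/1/2/3+), and
#'   per-position mutation counts per class.
#' @export
mutation_summary <- function(loci, focus = c("first", "last"),
                             gap_run_as_one = FALSE) {
  focus <- match.arg(focus)
  loci <- Filter(function(l) !l$rejected, loci)
  stopifnot(length(loci) >= 1L)
  recs <- list()
  maxlen <- max(vapply(loci, function(l) nchar(l$consensus), 0L))
  pos_counts <- list(focus = integer(maxlen), other = integer(maxlen))
  for (l in loci) {
    keep <- filter_length_outliers(l)
    rs <- repeat_seqs(l)
    focus_idx <- if (focus == "first") 1L else length(rs)
    for (i in keep) {
      cm <- count_mutations(rs[i], l$consensus, gap_run_as_one)
      is_f <- i == focus_idx
      recs[[length(recs) + 1L]] <- data.frame(
        locus = l$id, repeat_index = i, is_extra = is_f,
        mutations = cm$mutations,
        positions = paste(cm$positions, collapse = ";"),
        stringsAsFactors = FALSE)
      cls <- if (is_f) "focus" else "other"
      p <- cm$positions[cm$positions <= maxlen]
      for (pp in p) pos_counts[[cls]][pp] <- pos_counts[[cls]][pp] + 1L
    }
  }
  records <- do.call(rbind, recs)
  f <- records$mutations[records$is_extra]
  o <- records$mutations[!records$is_extra]
  histo <- function(v) c(`0` = sum(v == 0), `1` = sum(v == 1),
                         `2` = sum(v == 2), `3+` = sum(v >= 3))
  structure(list(records = records,
                 focus = focus,
                 n_arrays = length(loci),
                 n_repeats = nrow(records),
                 focus_fraction = if (length(f)) mean(f >= 1) else NA_real_,
                 nonfocus_fraction = if (length(o)) mean(o >= 1) else NA_real_,
                 hist = rbind(focus = histo(f), other = histo(o)),
                 pos_counts = pos_counts),
            class = "mutation_summary")
}

#' @export
print.mutation_summary <- function(x, ...) {
  cat(sprintf("Mutation summary over %d arrays (%d repeats, focus = %s repeat)\n",
              x$n_arrays, x$n_repeats, x$focus))
  cat(sprintf("  focus repeats with >= 1 mutation: %.1f%%\n", 100 * x$focus_fraction))
  cat(sprintf("  other repeats with >= 1 mutation: %.1f%%\n", 100 * x$nonfocus_fraction))
  cat("  count histogram (focus / other):\n")
  print(x$hist)
  invisible(x)
}
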