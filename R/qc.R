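#' Rescue a mutated repeat hidden in the upstream region
#'
#' Searches the upstream region for a degenerate copy of the consensus
#' repeat missed by array annotation.  A local-alignment hit is a candidate
#' when the implied spacer length (gap between the hit 3' end and repeat 1)
#' lies in `spacer_range`, its identity exceeds `min_identity`, and its raw
#' score reaches `min_score`.  For the best candidate an empirical e-value
#' is computed: the fraction of `n_shuffles` dinucleotide-shuffled upstream
#' regions containing any hit with a strictly better score.  When the
#' empirical e-value is below `e_threshold` the candidate is promoted to a
#' new repeat 1, the intervening sequence becomes a spacer, and the
#' upstream region is re-extracted.  At most one rescue per call.
#'
#' @param locus a `crispr_locus` with a consensus and non-empty upstream.
#' @param n_shuffles shuffle-null size (>= 100).
#' @param seed optional integer seed for the shuffle null.
#' @param e_threshold acceptance threshold on the empirical e-value.
#' @param min_identity identity gate (matching columns / alignment length).
#' @param spacer_range allowed implied spacer length, inclusive.
#' @param min_score raw-score floor for local hits.
#' @return a list with `locus` (possibly updated), `candidate` (one-row
#'   data.frame or `NULL`) and `accepted` (logical).
#' @export
rescue_mutated_repeat <- function(locus, n_shuffles = 1000L, seed = NULL,
                                  e_threshold = 0.01, min_identity = 0.70,
                                  spacer_range = c(20L, 45L), min_score = 10) {
  stopifnot(inherits(locus, "crispr_locus"))
  if (is.null(locus$consensus) || nchar(locus$consensus) == 0L)
    stop("locus has no consensus repeat")
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  up <- upstream_seq(locus)
  if (nchar(up) < nchar(locus$consensus))
    return(list(locus = locus, candidate = NULL, accepted = FALSE))

  params <- align_params("local")
  hits <- local_align(locus$consensus, up, params, min_score = min_score)
  if (nrow(hits) == 0L)
    return(list(locus = locus, candidate = NULL, accepted = FALSE))
  hits$implied_spacer_len <- nchar(up) - hits$s_end
  cand <- hits[hits$implied_spacer_len >= spacer_range[1] &
               hits$implied_spacer_len <= spacer_range[2] &
               hits$identity > min_identity, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(list(locus = locus, candidate = NULL, accepted = FALSE))
  cand <- cand[order(-cand$score, cand$implied_spacer_len, cand$s_start), , drop = FALSE]
  best <- cand[1L, , drop = FALSE]

  # empirical e-value over the dinucleotide-shuffle null
  count_better <- .with_seed(seed, {
    n_better <- 0L
    for (t in seq_len(n_shuffles)) {
      sh <- dinucleotide_shuffle(up)
      h <- local_align(locus$consensus, sh, params, min_score = best$score + 1)
      if (nrow(h) > 0L && any(h$score > best$score)) n_better <- n_better + 1L
    }
    n_better
  })
  empirical_e <- count_better / n_shuffles
  best$empirical_e <- empirical_e
  if (empirical_e >= e_threshold)
    return(list(locus = locus, candidate = best, accepted = FALSE))

  # promote: map the hit from upstream coordinates to contig coordinates
  n <- nchar(up)
  if (locus$strand == "+") {
    u_start <- locus$repeats$start[1L] - n
    new_rep <- c(start = u_start + best$s_start - 1L,
                 end = u_start + best$s_end - 1L)
  } else {
    r1e <- locus$repeats$end[1L]
    new_rep <- c(start = r1e + (n - best$s_end + 1L),
                 end = r1e + (n - best$s_start + 1L))
  }
  locus$repeats <- rbind(data.frame(start = new_rep[["start"]],
                                    end = new_rep[["end"]]),
                         locus$repeats)
  # new spacer between the promoted repeat and the old repeat 1
  old1 <- locus$repeats[2L, ]
  sp <- if (locus$strand == "+")
    data.frame(start = new_rep[["end"]] + 1L, end = old1$start - 1L)
  else
    data.frame(start = old1$end + 1L, end = new_rep[["start"]] - 1L)
  locus$spacers <- rbind(sp, locus$spacers)
  locus$rescued <- locus$rescued + 1L
  locus$upstream <- .extract_upstream(locus)
  list(locus = locus, candidate = best, accepted = TRUE)
}

#' Trim the upstream region at the nearest upstream gene
#'
#' The upstream region is shortened to the distance between repeat 1 and
#' the nearest gene boundary on its 5' side (either strand), capped at
#' `max_len`.  Loci whose trimmed upstream region is shorter than
#' `min_len` are flagged rejected and excluded from downstream stages.
#'
#' @param locus a `crispr_locus`.
#' @param genes data.frame with `start`, `end` (1-based inclusive) on the
#'   locus contig; gene strand is ignored.
#' @param max_len upstream cap (default 180).
#' @param min_len minimum retained upstream length (default 30).
#' @return the updated locus (check `$rejected`).
#' @export
trim_upstream <- function(locus, genes, max_len = 180L, min_len = 30L) {
  stopifnot(inherits(locus, "crispr_locus"))
  r1 <- locus$repeats[1L, ]
  if (locus$strand == "+") {
    avail <- r1$start - 1L
    gdist <- avail
    if (!is.null(genes) && nrow(genes) > 0L) {
      before <- genes[genes$start < r1$start, , drop = FALSE]
      if (nrow(before) > 0L)
        gdist <- max(0L, r1$start - max(pmin(before$end, r1$start - 1L)) - 1L)
    }
  } else {
    clen <- nchar(locus$contig)
    avail <- clen - r1$end
    gdist <- avail
    if (!is.null(genes) && nrow(genes) > 0L) {
      after <- genes[genes$end > r1$end, , drop = FALSE]
      if (nrow(after) > 0L)
        gdist <- max(0L, min(pmax(after$start, r1$end + 1L)) - r1$end - 1L)
    }
  }
  len <- min(max_len, gdist, avail)
  if (len < min_len) {
    locus$rejected <- TRUE
    locus$reject_reason <- sprintf("upstream region %d nt < %d nt", len, min_len)
    locus$upstream <- ""
    return(locus)
  }
  locus$upstream_max <- as.integer(len)
  locus$upstream <- .extract_upstream(locus, len)
  locus
}

#' Quality control for a cohort of loci
#'
#' Runs mutated-repeat rescue (iterated up to `max_iterations` acceptances)
#' followed by upstream trimming against gene annotations, and reports the
#' per-locus outcome.
#'
#' @param loci list of `crispr_locus` objects.
#' @param genes optional data.frame of gene intervals with a `contig`
#'   column matching each locus's `contig_id` (plus `start`, `end`).
#' @param n_shuffles shuffle-null size for the rescue empirical e-value.
#' @param seed master seed; per-locus seeds are derived from it and the
#'   locus id.
#' @param max_iterations maximum number of rescue acceptances per locus.
#' @param rescue run the rescue stage (TRUE by default).
#' @return a list with `loci` (updated; rejected loci retained and
#'   flagged) and `report` (data.frame: locus, action, upstream_len,
#'   empirical_e).
#' @export
qc_cohort <- function(loci, genes = NULL, n_shuffles = 1000L, seed = 1L,
                      max_iterations = 3L, rescue = TRUE) {
  report <- data.frame(locus = character(), action = character(),
                       upstream_len = integer(), empirical_e = numeric(),
                       stringsAsFactors = FALSE)
  out <- vector("list", length(loci))
  for (t in seq_along(loci)) {
    loc <- loci[[t]]
    action <- "kept"
    emp_e <- NA_real_
    if (rescue) {
      for (it in seq_len(max_iterations)) {
        r <- rescue_mutated_repeat(loc, n_shuffles = n_shuffles,
                                   seed = .child_seed(seed, paste0(loc$id, ":", it)))
        if (!is.null(r$candidate)) emp_e <- r$candidate$empirical_e
        loc <- r$locus
        if (!r$accepted) break
        action <- "rescued"
      }
    }
    g <- NULL
    if (!is.null(genes) && nrow(genes) > 0L)
      g <- genes[genes$contig == loc$contig_id, , drop = FALSE]
    loc <- trim_upstream(loc, g)
    if (loc$rejected) action <- "discarded"
    else if (action == "kept" && nchar(loc$upstream) < 180L) action <- "trimmed"
    report <- rbind(report, data.frame(locus = loc$id, action = action,
                                       upstream_len = nchar(loc$upstream),
                                       empirical_e = emp_e,
                                       stringsAsFactors = FALSE))
    out[[t]] <- loc
  }
  list(loci = out, report = report)
}
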