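#' Alignment parameter sets
#'
#' Bundles scoring parameters for the two alignment engines.  A gap of
#' length L costs `gap_open + L * gap_extend`; in global mode, terminal
#' gaps cost `end_open + L * end_extend` instead.  In local mode,
#' `word_size > 0` requires reported alignments to contain an exact match
#' run of at least that length (seed), a documented sensitivity trade-off;
#' end penalties are ignored.
#'
#' Defaults follow the two parameterizations used throughout the pipeline:
#' the repeat-vs-consensus global aligner (match +5 / mismatch -4,
#' gap 10/4, end gaps 10/4) and the repeat-rescue local search
#' (match +1 / mismatch -1, gap 2/1, word size 5).
#'
#' @param mode `"global"` or `"local"`.
#' @param match,mismatch integer match score and mismatch penalty.
#' @param gap_open,gap_extend non-negative affine gap costs.
#' @param end_open,end_extend non-negative terminal-gap costs (global only).
#' @param word_size seed length for local mode; 0 disables seeding.
#' @return an object of class `align_params`.
#' @export
#' @examples
#' align_params("local")
align_params <- function(mode = c("global", "local"),
                         match = if (mode == "global") 5L else 1L,
                         mismatch = if (mode == "global") -4L else -1L,
                         gap_open = if (mode == "global") 10 else 2,
                         gap_extend = if (mode == "global") 4 else 1,
                         end_open = 10, end_extend = 4,
                         word_size = if (mode == "global") 0L else 5L) {
  mode <- match.arg(mode)
  stopifnot(gap_open >= 0, gap_extend >= 0, end_open >= 0, end_extend >= 0,
            word_size >= 0)
  if (gap_extend > gap_open)
    warning("gap_extend larger than gap_open: unusual affine parameterization")
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 end_open = end_open, end_extend = end_extend,
                 word_size = as.integer(word_size)),
            class = "align_params")
}

# column statistics shared by both engines
.alignment_stats <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  gap <- ca == "-" | cb == "-"
  match <- !gap & ca == cb & ca != "N"
  list(length = length(ca), matches = sum(match),
       gap_columns = sum(gap), mismatches = sum(!gap & !match))
}

#' Global pairwise alignment with affine and terminal gap penalties
#'
#' Needleman-Wunsch/Gotoh alignment in which internal and terminal gaps are
#' priced separately, as in EMBOSS needle with end-gap weighting enabled.
#' The traceback tie-break prefers a substitution column over a gap in `a`
#' over a gap in `b`, making the reported alignment deterministic.
#'
#' @param a,b DNA strings (non-empty).
#' @param params an [align_params()] object with `mode = "global"`.
#' @return an object of class `pairwise_alignment`: aligned strings, score,
#'   and the column counts (`matches`, `mismatches`, `gap_columns`,
#'   `length`, `identity` = matches / length).
#' @export
#' @examples
#' global_align("ACGTACGT", "ACGACGT")
global_align <- function(a, b, params = align_params("global")) {
  stopifnot(inherits(params, "align_params"))
  if (params$mode != "global") stop("params$mode must be 'global'")
  a <- .norm_seq(a, "a"); b <- .norm_seq(b, "b")
  r <- .global_align_cpp(a, b, params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         params$end_open, params$end_extend)
  st <- .alignment_stats(r$aligned_a, r$aligned_b)
  structure(c(r, st, list(identity = st$matches / st$length)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment (score ", x$score, ")\n", sep = "")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  cat(sprintf(" length %d, matches %d, mismatches %d, gap columns %d, identity %.3f\n",
              x$length, x$matches, x$mismatches, x$gap_columns, x$identity))
  invisible(x)
}

#' Seeded local alignment (Smith-Waterman)
#'
#' Exhaustive Smith-Waterman under the same affine gap convention as
#' [global_align()].  Reported hits are maximal-scoring local alignments on
#' non-overlapping subject intervals, sorted by score; with
#' `params$word_size > 0` only alignments containing an exact match run of
#' at least `word_size` columns are reported (seeding).
#'
#' @param query,subject DNA strings.
#' @param params an [align_params()] object with `mode = "local"`.
#' @param min_score minimum raw score for a reported hit.
#' @param max_hits cap on the number of reported hits.
#' @return a data.frame with one row per hit: `s_start`, `s_end` (subject,
#'   1-based inclusive), `q_start`, `q_end`, `score`, `identity`
#'   (matching columns / alignment length), `matches`, `align_len`,
#'   `aligned_q`, `aligned_s`.
#' @export
#' @examples
#' local_align("ACGTACGTAC", paste0(strrep("T", 30), "ACGTACGTAC", strrep("G", 30)))
local_align <- function(query, subject, params = align_params("local"),
                        min_score = 10, max_hits = 10L) {
  stopifnot(inherits(params, "align_params"))
  if (params$mode != "local") stop("params$mode must be 'local'")
  query <- .norm_seq(query, "query"); subject <- .norm_seq(subject, "subject")

  hits <- list()
  scan_segment <- function(offset, seg) {
    if (length(hits) >= max_hits || nchar(seg) == 0L) return(invisible())
    r <- .local_align_cpp(query, seg, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
    if (r$score < min_score) return(invisible())
    st <- .alignment_stats(r$aligned_a, r$aligned_b)
    ok_seed <- TRUE
    if (params$word_size > 0L) {
      ca <- strsplit(r$aligned_a, "", fixed = TRUE)[[1L]]
      cb <- strsplit(r$aligned_b, "", fixed = TRUE)[[1L]]
      eq <- ca == cb & ca != "-" & ca != "N"
      runs <- rle(eq)
      ok_seed <- any(runs$values & runs$lengths >= params$word_size)
    }
    if (ok_seed) {
      hits[[length(hits) + 1L]] <<- data.frame(
        s_start = offset + r$b_start - 1L, s_end = offset + r$b_end - 1L,
        q_start = r$a_start, q_end = r$a_end,
        score = r$score, identity = st$matches / st$length,
        matches = st$matches, align_len = st$length,
        aligned_q = r$aligned_a, aligned_s = r$aligned_b,
        stringsAsFactors = FALSE)
      # recurse into the flanks outside the consumed subject interval
      scan_segment(offset, substr(seg, 1L, r$b_start - 1L))
      scan_segment(offset + r$b_end, substr(seg, r$b_end + 1L, nchar(seg)))
    }
    invisible()
  }
  scan_segment(1L, subject)
  if (length(hits) == 0L)
    return(data.frame(s_start = integer(), s_end = integer(),
                      q_start = integer(), q_end = integer(),
                      score = numeric(), identity = numeric(),
                      matches = integer(), align_len = integer(),
                      aligned_q = character(), aligned_s = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(-out$score, out$s_start), , drop = FALSE]
}

#' Exact dinucleotide-preserving shuffle
#'
#' Random permutation of a sequence preserving its exact dinucleotide count
#' multiset and both endpoint residues (Altschul-Erickson Eulerian-walk
#' construction).  Used to build composition-matched null sequences.
#'
#' @param s a DNA string of length >= 2.
#' @param seed optional integer seed; when `NULL`, the current RNG state is
#'   used (and advanced).
#' @return a shuffled string.
#' @export
#' @examples
#' dinucleotide_shuffle("ACGTACGTAAGG", seed = 1)
dinucleotide_shuffle <- function(s, seed = NULL) {
  s <- .norm_seq(s)
  if (nchar(s) < 2L) stop("sequence must have length >= 2")
  v <- .enc(s)
  r <- if (is.null(seed)) .dinuc_shuffle_cpp(v)
       else .with_seed(seed, .dinuc_shuffle_cpp(v))
  .dec(r)
}
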