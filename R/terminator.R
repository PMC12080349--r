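#' Configuration for the intrinsic-terminator detector
#'
#' A Rho-independent terminator (RIT) call is a hairpin with a stem of at
#' least `stem_min` consecutive WC/G.U pairs (one interior mismatch is
#' tolerated when the stem reaches `stem_min + 2`), a loop of
#' `loop_min`..`loop_max` nt, whose stem 3' side is followed within
#' `max_gap` nt by a `u_window`-nt window containing at least `u_min` T
#' (U) residues.  The call score is stem pairs + GC-pair count + U-tract
#' count.
#'
#' @param stem_min minimum stem pairs (default 8).
#' @param loop_min,loop_max loop length bounds (default 3..10).
#' @param u_min minimum T count in the tail window (default 6).
#' @param u_window tail window length (default 8).
#' @param max_gap maximum nt between stem 3' end and tail window (default 3).
#' @param max_mismatch interior mismatches tolerated (0 or 1; default 1).
#' @return an object of class `terminator_config`.
#' @export
terminator_config <- function(stem_min = 8L, loop_min = 3L, loop_max = 10L,
                              u_min = 6L, u_window = 8L, max_gap = 3L,
                              max_mismatch = 1L) {
  stopifnot(stem_min >= 3L, loop_min >= 1L, loop_max >= loop_min,
            u_min >= 1L, u_window >= u_min, max_gap >= 0L,
            max_mismatch %in% c(0L, 1L))
  structure(list(stem_min = as.integer(stem_min), loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max), u_min = as.integer(u_min),
                 u_window = as.integer(u_window), max_gap = as.integer(max_gap),
                 max_mismatch = as.integer(max_mismatch),
                 mismatch_min_stem = as.integer(stem_min + 2L)),
            class = "terminator_config")
}

#' Call intrinsic terminators in a sequence
#'
#' Scans one strand of `seq` (5'->3') with the heuristic stem-loop +
#' U-tract detector; overlapping candidate calls are merged to the
#' highest-scoring one.
#'
#' @param seq DNA string (>= 30 nt recommended).
#' @param config a [terminator_config()].
#' @return data.frame of calls: `start`, `end` (1-based inclusive on
#'   `seq`), `stem_bp`, `loop_len`, `u_count`, `score`, `source`.
#' @export
#' @examples
#' term <- paste0("GCCGGCGGC", "TTCA", "GCCGCCGGC", "TTTTTTTT")
#' call_terminators(paste0(strrep("A", 40), term, strrep("A", 40)))
call_terminators <- function(seq, config = terminator_config()) {
  s <- .norm_seq(seq)
  cand <- .terminator_scan_cpp(.enc(s), config$stem_min, config$loop_min,
                               config$loop_max, config$u_min, config$u_window,
                               config$max_gap, config$max_mismatch,
                               config$mismatch_min_stem)
  cand <- as.data.frame(cand)
  if (nrow(cand) == 0L) {
    cand$source <- character(0)
    return(cand)
  }
  cand <- cand[order(-cand$score, cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= ke & cand$end[i] >= ks)) {
      keep[i] <- TRUE
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$source <- "native"
  out
}

#' Import externally predicted terminator calls
#'
#' Adapter for terminator predictions produced by an external tool, given
#' as GFF3-like tab-separated lines (seqid, source, type, start, end,
#' score, strand, ...).
#'
#' @param path path to the GFF3-like file.
#' @return data.frame with `seqid`, `start`, `end`, `strand`, `score`,
#'   `source = "imported"`.
#' @export
import_terminators <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(seqid = vapply(f, `[`, "", 1L),
             start = as.integer(vapply(f, `[`, "", 4L)),
             end = as.integer(vapply(f, `[`, "", 5L)),
             strand = vapply(f, `[`, "", 7L),
             score = suppressWarnings(as.numeric(vapply(f, `[`, "", 6L))),
             source = "imported", stringsAsFactors = FALSE)
}

#' Intergenic regions of a contig
#'
#' Complement of the (merged) gene intervals, keeping regions strictly
#' longer than `min_len` nt; gaps at the contig ends are included.
#'
#' @param genes data.frame with `start`, `end` (1-based inclusive).
#' @param contig_len contig length.
#' @param min_len minimum retained region length (exclusive bound;
#'   default 30).
#' @return data.frame with `start`, `end` of intergenic regions.
#' @export
#' @examples
#' enumerate_intergenic(data.frame(start = c(1, 201), end = c(100, 300)), 400)
enumerate_intergenic <- function(genes, contig_len, min_len = 30L) {
  if (is.null(genes) || nrow(genes) == 0L) {
    out <- data.frame(start = 1L, end = as.integer(contig_len))
  } else {
    m <- .merge_intervals(genes$start, genes$end)
    starts <- c(1L, m$end + 1L)
    ends <- c(m$start - 1L, as.integer(contig_len))
    out <- data.frame(start = starts, end = ends)
    out <- out[out$start <= out$end, , drop = FALSE]
  }
  out <- out[out$end - out$start + 1L > min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# does a region (given as a forward-strand string) contain a call on
# either strand?
.region_has_terminator <- function(seq, config) {
  if (nchar(seq) < 2L * config$stem_min + config$loop_min) return(FALSE)
  nrow(call_terminators(seq, config)) > 0L ||
    nrow(call_terminators(revcomp(seq), config)) > 0L
}

#' Observed vs expected RIT occurrence (Table-1-style report)
#'
#' The observed ratio is the fraction of loci with at least one terminator
#' call in their upstream region (scanned in transcription orientation
#' only).  The expected ratio is the mean over genomes of the fraction of
#' intergenic regions (> 30 nt, both strands scanned, counted once) that
#' contain a call.
#'
#' @param loci list of `crispr_locus` objects (rejected loci skipped).
#' @param genomes optional list of genomes, each a list with `contig`
#'   (string) and `genes` (data.frame `start`/`end`); when `NULL` the
#'   expected ratio is `NA`.
#' @param config a [terminator_config()].
#' @param label cohort label.
#' @return an object of class `rit_ratio_report`.
#' @export
rit_ratio_report <- function(loci, genomes = NULL,
                             config = terminator_config(), label = "") {
  loci <- Filter(function(l) !l$rejected, loci)
  stopifnot(length(loci) >= 1L)
  upstream_calls <- vapply(loci, function(l) {
    up <- upstream_seq(l)
    nchar(up) >= 2L * config$stem_min + config$loop_min &&
      nrow(call_terminators(up, config)) > 0L
  }, FALSE)
  avg_len <- mean(vapply(loci, function(l) nchar(upstream_seq(l)), 0))
  expected <- NA_real_
  per_genome <- numeric(0)
  if (!is.null(genomes)) {
    for (g in genomes) {
      ig <- enumerate_intergenic(g$genes, nchar(g$contig))
      if (nrow(ig) == 0L) {
        message("genome with no intergenic regions > 30 nt skipped")
        next
      }
      has <- vapply(seq_len(nrow(ig)), function(i)
        .region_has_terminator(substr(g$contig, ig$start[i], ig$end[i]), config),
        FALSE)
      per_genome <- c(per_genome, mean(has))
    }
    if (length(per_genome) > 0L) expected <- mean(per_genome)
  }
  structure(list(label = label,
                 avg_intergenic_len = avg_len,
                 observed_rits = sum(upstream_calls),
                 systems_analyzed = length(loci),
                 observed_ratio = mean(upstream_calls),
                 expected_ratio = expected,
                 per_genome = per_genome,
                 upstream_has_rit = setNames(upstream_calls,
                                             vapply(loci, `[[`, "", "id"))),
            class = "rit_ratio_report")
}

#' @export
print.rit_ratio_report <- function(x, ...) {
  cat(sprintf("RIT report%s: %d / %d systems with an upstream RIT (ratio %.2f, %.0f%%)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$observed_rits, x$systems_analyzed, x$observed_ratio,
              100 * x$observed_ratio))
  cat(sprintf("  mean upstream length %.0f nt; expected intergenic ratio %s\n",
              x$avg_intergenic_len,
              if (is.na(x$expected_ratio)) "n/a" else sprintf("%.2f", x$expected_ratio)))
  invisible(x)
}
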