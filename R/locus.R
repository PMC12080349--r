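#' Construct a CRISPR locus record
#'
#' A locus is normalized to transcription orientation: repeat 1 is the
#' first repeat in transcription order (the extra repeat), the upstream
#' region is the intergenic sequence ending immediately 5' of repeat 1
#' (capped at `upstream_max` nt), and the guide window is the last 25 nt of
#' the upstream region (the putative ecrRNA guide).  Intervals are 1-based
#' inclusive on the forward strand of the contig.
#'
#' @param id locus identifier.
#' @param contig forward-strand contig sequence.
#' @param repeats data.frame with columns `start`, `end`: repeat intervals
#'   on the contig (any order; sorted into transcription order internally).
#' @param strand `"+"` or `"-"` (transcription strand of the array).
#' @param subtype `"II-A"`, `"II-C"` or `"other"`.
#' @param tracrRNA optional tracrRNA sequence (5'->3').
#' @param consensus optional consensus repeat; when `NULL` it is computed
#'   from the array itself by majority ([consensus_repeat()]) over the
#'   non-extra repeats when at least three exist, else over all repeats.
#' @param contig_id label for the contig.
#' @param upstream_max upstream cap in nt (180 by default).
#' @return an object of class `crispr_locus`.
#' @export
crispr_locus <- function(id, contig, repeats, strand = c("+", "-"),
                         subtype = c("II-C", "II-A", "other"),
                         tracrRNA = NULL, consensus = NULL,
                         contig_id = "contig", upstream_max = 180L) {
  strand <- match.arg(strand)
  subtype <- match.arg(subtype)
  contig <- .norm_seq(contig, "contig")
  stopifnot(is.data.frame(repeats), all(c("start", "end") %in% names(repeats)),
            nrow(repeats) >= 1L)
  stopifnot(all(repeats$start >= 1L), all(repeats$end <= nchar(contig)),
            all(repeats$start <= repeats$end))
  o <- if (strand == "+") order(repeats$start) else order(-repeats$start)
  repeats <- repeats[o, c("start", "end"), drop = FALSE]
  rownames(repeats) <- NULL

  # spacers: gaps between consecutive repeats, in transcription order
  spacers <- NULL
  if (nrow(repeats) > 1L) {
    a <- repeats[-nrow(repeats), , drop = FALSE]
    b <- repeats[-1L, , drop = FALSE]
    spacers <- if (strand == "+")
      data.frame(start = a$end + 1L, end = b$start - 1L)
    else
      data.frame(start = b$end + 1L, end = a$start - 1L)
    if (any(spacers$start > spacers$end)) stop("adjacent or overlapping repeats")
  } else {
    spacers <- data.frame(start = integer(), end = integer())
  }

  loc <- structure(list(id = id, subtype = subtype, contig_id = contig_id,
                        contig = contig, strand = strand,
                        repeats = repeats, spacers = spacers,
                        consensus = NULL, upstream = NULL,
                        tracrRNA = if (is.null(tracrRNA)) NULL else .norm_seq(tracrRNA, "tracrRNA"),
                        upstream_max = as.integer(upstream_max),
                        rejected = FALSE, reject_reason = NA_character_,
                        rescued = 0L),
                   class = "crispr_locus")
  loc$consensus <- if (is.null(consensus)) .locus_consensus(loc)
                   else .norm_seq(consensus, "consensus")
  loc$upstream <- .extract_upstream(loc, upstream_max)
  loc
}

# consensus from the array itself: majority over non-extra repeats when at
# least three exist, else over all repeats
.locus_consensus <- function(locus) {
  rs <- repeat_seqs(locus)
  if (length(rs) >= 4L) consensus_repeat(rs[-1L]) else consensus_repeat(rs)
}

# upstream region of length <= cap, bounded by the contig edge
.extract_upstream <- function(locus, cap = locus$upstream_max) {
  r1 <- locus$repeats[1L, ]
  if (locus$strand == "+") {
    avail <- r1$start - 1L
    len <- min(cap, avail)
    if (len <= 0L) return("")
    substr(locus$contig, r1$start - len, r1$start - 1L)
  } else {
    avail <- nchar(locus$contig) - r1$end
    len <- min(cap, avail)
    if (len <= 0L) return("")
    revcomp(substr(locus$contig, r1$end + 1L, r1$end + len))
  }
}

#' Repeat sequences of a locus in transcription orientation
#' @param locus a `crispr_locus`.
#' @return character vector, repeat 1 (the extra repeat) first.
#' @export
repeat_seqs <- function(locus) {
  vapply(seq_len(nrow(locus$repeats)), function(i)
    .oriented_subseq(locus$contig, locus$repeats$start[i], locus$repeats$end[i],
                     locus$strand), "")
}

#' Spacer sequences of a locus in transcription orientation
#' @param locus a `crispr_locus`.
#' @return character vector (one fewer than the repeats).
#' @export
spacer_seqs <- function(locus) {
  if (nrow(locus$spacers) == 0L) return(character(0))
  vapply(seq_len(nrow(locus$spacers)), function(i)
    .oriented_subseq(locus$contig, locus$spacers$start[i], locus$spacers$end[i],
                     locus$strand), "")
}

#' Upstream region of a locus (5'->3', ending just before repeat 1)
#' @param locus a `crispr_locus`.
#' @return the upstream string (possibly empty).
#' @export
upstream_seq <- function(locus) locus$upstream

#' Guide window: the last 25 nt of the upstream region
#'
#' The putative ecrRNA guide, i.e. the 25 nt of intergenic sequence
#' immediately 5' of the extra repeat (shorter if the upstream region is).
#' @param locus a `crispr_locus`.
#' @param guide_len window length (default 25).
#' @return the guide-window string.
#' @export
guide_window <- function(locus, guide_len = 25L) {
  up <- locus$upstream
  n <- nchar(up)
  substr(up, max(1L, n - guide_len + 1L), n)
}

#' @export
print.crispr_locus <- function(x, ...) {
  cat(sprintf("CRISPR locus %s [%s, strand %s]\n", x$id, x$subtype, x$strand))
  cat(sprintf("  %d repeats / %d spacers, consensus %d nt\n",
              nrow(x$repeats), nrow(x$spacers), nchar(x$consensus)))
  cat(sprintf("  upstream %d nt%s, tracrRNA %s\n", nchar(x$upstream),
              if (x$rescued > 0L) sprintf(" (%d repeat(s) rescued)", x$rescued) else "",
              if (is.null(x$tracrRNA)) "absent" else paste0(nchar(x$tracrRNA), " nt")))
  if (x$rejected) cat("  REJECTED:", x$reject_reason, "\n")
  invisible(x)
}
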