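#' Greedy identity clustering of sequences
#'
#' Longest-first greedy clustering: each sequence joins the first existing
#' cluster whose representative it matches at or above `threshold` identity,
#' else founds a new cluster.  Identity follows the CD-HIT convention:
#' matching columns of a semi-global alignment (terminal gaps free) divided
#' by the length of the shorter sequence.
#'
#' @param seqs character vector of DNA strings.
#' @param threshold identity threshold in (0, 1].
#' @return a list with `cluster` (integer cluster id per input sequence) and
#'   `representatives` (input indices of cluster representatives, in
#'   cluster-id order).
#' @export
#' @examples
#' greedy_identity_cluster(c("ACGTACGTAC", "ACGTACGTAC", "TTTTTTTTTT"), 0.9)
greedy_identity_cluster <- function(seqs, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  n <- length(seqs)
  if (n == 0L) return(list(cluster = integer(), representatives = integer()))
  seqs <- vapply(seqs, .norm_seq, "", USE.NAMES = FALSE)
  ord <- order(-nchar(seqs), seq_len(n)) # longest first, stable
  params <- align_params("global", end_open = 0, end_extend = 0)
  cluster <- integer(n)
  reps <- integer(0)
  for (i in ord) {
    assigned <- FALSE
    for (ci in seq_along(reps)) {
      rs <- seqs[reps[ci]]
      ident <- if (rs == seqs[i]) 1 else {
        al <- global_align(seqs[i], rs, params)
        al$matches / min(nchar(seqs[i]), nchar(rs))
      }
      if (ident >= threshold) { cluster[i] <- ci; assigned <- TRUE; break }
    }
    if (!assigned) {
      reps <- c(reps, i)
      cluster[i] <- length(reps)
    }
  }
  list(cluster = cluster, representatives = reps)
}

#' Consensus repeat from an array's repeats
#'
#' Column-wise majority over a star alignment anchored on the most frequent
#' exact repeat sequence (ties broken alphabetically).  Each repeat is
#' globally aligned to the anchor; per anchor column the majority residue is
#' taken (ties among bases alphabetical, a base beats a gap on ties) and
#' gap-majority columns are dropped.  Insertions relative to the anchor are
#' not propagated into the consensus.
#'
#' @param repeats character vector of repeat sequences (>= 1).
#' @return the consensus string.
#' @export
#' @examples
#' consensus_repeat(c("ACGT", "ACGT", "ACTT"))
consensus_repeat <- function(repeats) {
  stopifnot(length(repeats) >= 1L)
  repeats <- vapply(repeats, .norm_seq, "", USE.NAMES = FALSE)
  tab <- table(repeats)
  anchor <- names(tab)[tab == max(tab)]
  anchor <- sort(anchor)[1L]
  la <- nchar(anchor)
  prof <- matrix("-", nrow = length(repeats), ncol = la)
  params <- align_params("global")
  for (r in seq_along(repeats)) {
    if (repeats[r] == anchor) {
      prof[r, ] <- strsplit(anchor, "", fixed = TRUE)[[1L]]
      next
    }
    al <- global_align(repeats[r], anchor, params)
    ca <- strsplit(al$aligned_a, "", fixed = TRUE)[[1L]]
    cb <- strsplit(al$aligned_b, "", fixed = TRUE)[[1L]]
    pos <- 0L
    for (k in seq_along(cb)) {
      if (cb[k] != "-") { # column consumes an anchor residue
        pos <- pos + 1L
        prof[r, pos] <- ca[k]
      } # insertions relative to the anchor are skipped
    }
  }
  cons <- character(0)
  for (j in seq_len(la)) {
    counts <- table(prof[, j])
    top <- max(counts)
    winners <- sort(names(counts)[counts == top]) # '-' sorts before bases
    pick <- if (length(winners) > 1L && winners[1L] == "-") winners[2L] else winners[1L]
    if (pick != "-") cons <- c(cons, pick)
  }
  paste(cons, collapse = "")
}
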