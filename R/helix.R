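#' Helix search parameters
#'
#' Parameters for the qualifying-helix search: at least `min_bp`
#' Watson-Crick pairs (G.U only when `allow_GU`) with at most
#' `max_unpaired` interior unpaired (bulge / internal loop) nucleotides
#' and at least `min_loop` nt separating the two arms.  `mode = "intra"`
#' searches the whole upstream region; `mode = "guide"` additionally
#' requires the 3' arm to overlap the guide window (the last 25 nt of the
#' upstream region, i.e. the putative ecrRNA guide).
#'
#' When `min_bp`/`max_unpaired` are omitted, the mode defaults are used:
#' 12 bp / 3 unpaired (intra), 8 bp / 2 unpaired (guide).
#'
#' @param min_bp minimum base pairs (>= 4).
#' @param max_unpaired maximum unpaired nucleotides (>= 0).
#' @param mode `"intra"` or `"guide"`.
#' @param allow_GU score G.U wobble pairs (default FALSE).
#' @param min_loop minimum loop/arm separation in nt (default 3).
#' @return an object of class `helix_params`.
#' @export
#' @examples
#' helix_params(mode = "guide")
helix_params <- function(min_bp = NULL, max_unpaired = NULL,
                         mode = c("intra", "guide"),
                         allow_GU = FALSE, min_loop = 3L) {
  mode <- match.arg(mode)
  if (is.null(min_bp)) min_bp <- if (mode == "intra") 12L else 8L
  if (is.null(max_unpaired)) max_unpaired <- if (mode == "intra") 3L else 2L
  stopifnot(min_bp >= 4L, max_unpaired >= 0L, min_loop >= 0L)
  structure(list(min_bp = as.integer(min_bp),
                 max_unpaired = as.integer(max_unpaired),
                 mode = mode, allow_GU = isTRUE(allow_GU),
                 min_loop = as.integer(min_loop)),
            class = "helix_params")
}

.guide_start <- function(n, mode, guide_len) {
  if (mode == "guide") max(0L, n - as.integer(guide_len)) else -1L # 0-based
}

#' Find the best qualifying helix in an upstream region
#'
#' Searches all disjoint arm pairs for an antiparallel duplex with at
#' least `p$min_bp` pairs and at most `p$max_unpaired` interior unpaired
#' nucleotides (mismatched opposing pairs are never scored as pairs).
#' Returns the match maximizing (pair count, -unpaired, 5'-most arm_a),
#' or `NULL` when none qualifies.
#'
#' @param upstream upstream-region string (5'->3').
#' @param p a [helix_params()] object.
#' @param guide_len guide-window length for guide mode (default 25).
#' @return `NULL` or an object of class `helix_match` with `bp_count`,
#'   `unpaired_count`, `arm_a`, `arm_b` (1-based inclusive intervals on
#'   the upstream region) and `pairs` (two-column matrix of paired
#'   positions, outermost pair first).
#' @export
#' @examples
#' up <- paste0("GGGCCCGGGCCC", strrep("A", 20), "GGGCCCGGGCCC")
#' find_helix(up, helix_params(8, 0, "intra"))
find_helix <- function(upstream, p, guide_len = 25L) {
  stopifnot(inherits(p, "helix_params"))
  up <- .norm_seq(upstream)
  n <- nchar(up)
  if (n < 2L * p$min_bp + p$min_loop) return(NULL)
  r <- .helix_best_cpp(.enc(up), p$min_bp, p$max_unpaired, p$min_loop,
                       .guide_start(n, p$mode, guide_len), p$allow_GU)
  if (!isTRUE(r$found)) return(NULL)
  pr <- r$pairs
  structure(list(bp_count = r$bp, unpaired_count = r$unpaired,
                 arm_a = c(min(pr[, 1]), max(pr[, 1])),
                 arm_b = c(min(pr[, 2]), max(pr[, 2])),
                 pairs = pr, params = p),
            class = "helix_match")
}

#' @export
print.helix_match <- function(x, ...) {
  cat(sprintf("Helix: %d bp, %d unpaired; arm_a %d-%d, arm_b %d-%d\n",
              x$bp_count, x$unpaired_count, x$arm_a[1], x$arm_a[2],
              x$arm_b[1], x$arm_b[2]))
  invisible(x)
}

#' Per-system shuffle-null helix probability
#'
#' Fraction of dinucleotide-shuffled upstream regions (guide window
#' shuffled along with the rest) containing any qualifying helix.
#'
#' @param locus a `crispr_locus` or an upstream string.
#' @param p a [helix_params()] object.
#' @param n_shuffles null size (>= 20).
#' @param seed optional integer seed.
#' @param guide_len guide-window length (default 25).
#' @return the null probability (fraction in \[0, 1\]).
#' @export
system_null_prob <- function(locus, p, n_shuffles = 100L, seed = NULL,
                             guide_len = 25L) {
  stopifnot(inherits(p, "helix_params"))
  if (n_shuffles < 20L) stop("n_shuffles must be >= 20 (unstable estimate)")
  up <- if (inherits(locus, "crispr_locus")) upstream_seq(locus) else .norm_seq(locus)
  n <- nchar(up)
  if (n < 2L * p$min_bp + p$min_loop) return(0)
  cnt <- .with_seed(seed,
    .helix_null_count_cpp(.enc(up), p$min_bp, p$max_unpaired, p$min_loop,
                          .guide_start(n, p$mode, guide_len), p$allow_GU,
                          as.integer(n_shuffles)))
  cnt / n_shuffles
}

#' Exact Poisson-binomial upper tail
#'
#' P(X >= x_obs) where X is a sum of independent Bernoulli indicators with
#' the given success probabilities, by exact convolution.
#'
#' @param probs vector of per-trial probabilities.
#' @param x_obs observed count.
#' @return the tail probability.
#' @export
#' @examples
#' poisson_binomial_tail(c(0.5, 0.5), 2) # 0.25
poisson_binomial_tail <- function(probs, x_obs) {
  stopifnot(all(probs >= 0), all(probs <= 1))
  n <- length(probs)
  if (x_obs <= 0) return(1)
  if (x_obs > n) return(0)
  dp <- c(1, numeric(n))
  for (p in probs) dp <- dp * (1 - p) + c(0, dp[-(n + 1)]) * p
  sum(dp[(x_obs + 1L):(n + 1L)])
}

#' Cohort-level helix enrichment against the shuffle null
#'
#' Aggregates per-system helix presence against per-system shuffle-null
#' probabilities: the observed number of systems with a qualifying helix
#' is compared with the Poisson-binomial distribution implied by the null
#' probabilities (independence across systems), giving a one-sided upper
#' tail p-value.  Null probabilities of zero are floored at
#' 1/(n_shuffles + 1) to avoid a degenerate zero-variance null.
#'
#' @param has_helix logical vector: qualifying helix present per system.
#' @param null_prob numeric vector of per-system null probabilities.
#' @param n_shuffles the null size used to estimate `null_prob` (for the
#'   zero floor).
#' @param label cohort label carried into the result.
#' @return an object of class `enrichment_result`: `n_systems`,
#'   `n_with_helix`, `expected` (sum of null probabilities),
#'   `aggregate_p`.
#' @export
aggregate_enrichment <- function(has_helix, null_prob, n_shuffles = 100L,
                                 label = "") {
  stopifnot(length(has_helix) == length(null_prob), length(has_helix) >= 2L)
  p <- pmax(null_prob, 1 / (n_shuffles + 1))
  x_obs <- sum(has_helix)
  structure(list(label = label, n_systems = length(has_helix),
                 n_with_helix = x_obs, expected = sum(p),
                 aggregate_p = poisson_binomial_tail(p, x_obs),
                 null_probs = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Helix enrichment%s: %d / %d systems (expected %.1f), P = %.3g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$n_with_helix, x$n_systems, x$expected, x$aggregate_p))
  invisible(x)
}

#' Per-system helix search and enrichment over a cohort
#'
#' Runs [find_helix()] and [system_null_prob()] per locus (per-locus seeds
#' derived from `seed` and the locus id) and aggregates with
#' [aggregate_enrichment()].
#'
#' @param loci list of `crispr_locus` objects (rejected loci skipped).
#' @param p a [helix_params()] object.
#' @param n_shuffles per-system null size.
#' @param seed master seed.
#' @param exclude optional logical vector (or vector of locus ids) marking
#'   systems to drop, e.g. systems with a predicted terminator for the
#'   RIT-exclusion rerun.
#' @param guide_len guide-window length.
#' @return a list with `per_system` (data.frame: locus, has_helix,
#'   bp_count, unpaired_count, arm coordinates, null_prob,
#'   guide positions paired), `enrichment` (an `enrichment_result`) and
#'   `profile` (per-position pairing frequency, guide mode only).
#' @export
helix_enrichment <- function(loci, p, n_shuffles = 100L, seed = 1L,
                             exclude = NULL, guide_len = 25L) {
  loci <- Filter(function(l) !l$rejected, loci)
  if (!is.null(exclude)) {
    if (is.character(exclude))
      exclude <- vapply(loci, function(l) l$id %in% exclude, FALSE)
    loci <- loci[!exclude]
  }
  rows <- list()
  guide_pos <- vector("list", length(loci))
  for (t in seq_along(loci)) {
    l <- loci[[t]]
    up <- upstream_seq(l)
    hm <- find_helix(up, p, guide_len)
    np <- system_null_prob(up, p, n_shuffles,
                           seed = .child_seed(seed, paste0("null:", l$id)),
                           guide_len = guide_len)
    gp <- integer(0)
    if (!is.null(hm)) {
      w0 <- nchar(up) - guide_len # window = positions w0+1 .. n
      idx <- c(hm$pairs[, 1], hm$pairs[, 2])
      gp <- sort(unique(idx[idx > w0])) - w0
    }
    guide_pos[[t]] <- gp
    rows[[t]] <- data.frame(
      locus = l$id, has_helix = !is.null(hm),
      bp_count = if (is.null(hm)) NA_integer_ else hm$bp_count,
      unpaired_count = if (is.null(hm)) NA_integer_ else hm$unpaired_count,
      arm_a_start = if (is.null(hm)) NA_integer_ else hm$arm_a[1],
      arm_a_end = if (is.null(hm)) NA_integer_ else hm$arm_a[2],
      arm_b_start = if (is.null(hm)) NA_integer_ else hm$arm_b[1],
      arm_b_end = if (is.null(hm)) NA_integer_ else hm$arm_b[2],
      null_prob = np, stringsAsFactors = FALSE)
  }
  per_system <- do.call(rbind, rows)
  enr <- aggregate_enrichment(per_system$has_helix, per_system$null_prob,
                              n_shuffles = n_shuffles,
                              label = sprintf("%s %d bp / %d unpaired",
                                              p$mode, p$min_bp, p$max_unpaired))
  prof <- NULL
  if (p$mode == "guide")
    prof <- pairing_profile(guide_pos, guide_len = guide_len)
  list(per_system = per_system, enrichment = enr, profile = prof,
       guide_positions = guide_pos)
}

#' Per-position pairing-frequency profile over the guide window
#'
#' For each guide-window position (1 = 5'-most of the 25-nt window), the
#' fraction of systems whose best helix pairs that position.
#'
#' @param guide_positions list (one element per system) of paired
#'   guide-window positions, as produced by [helix_enrichment()].
#' @param guide_len window length (default 25).
#' @return data.frame with `position` and `frequency`.
#' @export
pairing_profile <- function(guide_positions, guide_len = 25L) {
  n <- length(guide_positions)
  counts <- integer(guide_len)
  for (gp in guide_positions)
    for (g in gp) if (g >= 1L && g <= guide_len) counts[g] <- counts[g] + 1L
  data.frame(position = seq_len(guide_len),
             frequency = if (n > 0) counts / n else rep(0, guide_len))
}

#' Training-set parameter scan for the helix statistic
#'
#' Computes the aggregate enrichment p-value over a (min_bp, max_unpaired)
#' grid on a training cohort, reusing one set of shuffles per locus across
#' the grid.  The minimum-p cell is selected (ties toward larger min_bp,
#' then smaller max_unpaired); if no cell is significant at `alpha` after
#' Bonferroni correction over the grid, no parameters are selected.
#'
#' @param training list of `crispr_locus` objects (training split).
#' @param k_range candidate `min_bp` values.
#' @param m_range candidate `max_unpaired` values.
#' @param mode `"intra"` or `"guide"`.
#' @param n_shuffles per-system null size.
#' @param seed master seed.
#' @param alpha familywise significance level for the no-selection gate.
#' @param guide_len guide-window length.
#' @param allow_GU score G.U pairs.
#' @return a list with `grid` (data.frame: min_bp, max_unpaired, n_obs,
#'   expected, p) and `chosen` (a [helix_params()] object or `NULL`).
#' @export
parameter_scan <- function(training, k_range, m_range,
                           mode = c("intra", "guide"), n_shuffles = 100L,
                           seed = 1L, alpha = 0.05, guide_len = 25L,
                           allow_GU = FALSE) {
  mode <- match.arg(mode)
  training <- Filter(function(l) !l$rejected, training)
  stopifnot(length(training) >= 2L)
  k_range <- sort(as.integer(k_range))
  m_range <- sort(as.integer(m_range))
  k_cap <- max(k_range)
  nsys <- length(training)
  # obs_bp[s, mi], null_ge[s, mi, ki] = null prob of >= k pairs
  obs_bp <- matrix(0L, nsys, length(m_range))
  null_ge <- array(0, c(nsys, length(m_range), length(k_range)))
  for (s in seq_len(nsys)) {
    up <- upstream_seq(training[[s]])
    x <- .enc(up)
    gs <- .guide_start(nchar(up), mode, guide_len)
    for (mi in seq_along(m_range))
      obs_bp[s, mi] <- .helix_maxbp_cpp(x, k_cap, m_range[mi], 3L, gs, allow_GU)
    shuf <- .with_seed(.child_seed(seed, paste0("scan:", training[[s]]$id)),
      .helix_shuffle_maxbp_cpp(x, k_cap, m_range, 3L, gs, allow_GU,
                               as.integer(n_shuffles)))
    for (mi in seq_along(m_range))
      for (ki in seq_along(k_range))
        null_ge[s, mi, ki] <- mean(shuf[, mi] >= k_range[ki])
  }
  grid <- expand.grid(min_bp = k_range, max_unpaired = m_range,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_obs <- NA_integer_; grid$expected <- NA_real_; grid$p <- NA_real_
  for (g in seq_len(nrow(grid))) {
    ki <- match(grid$min_bp[g], k_range)
    mi <- match(grid$max_unpaired[g], m_range)
    has <- obs_bp[, mi] >= grid$min_bp[g]
    enr <- aggregate_enrichment(has, null_ge[, mi, ki], n_shuffles)
    grid$n_obs[g] <- enr$n_with_helix
    grid$expected[g] <- enr$expected
    grid$p[g] <- enr$aggregate_p
  }
  o <- order(grid$p, -grid$min_bp, grid$max_unpaired)
  best <- grid[o[1L], ]
  chosen <- NULL
  if (best$p <= alpha / nrow(grid))
    chosen <- helix_params(best$min_bp, best$max_unpaired, mode,
                           allow_GU = allow_GU)
  list(grid = grid, chosen = chosen)
}
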