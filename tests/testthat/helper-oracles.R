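# Independent reference implementations used as oracles.  These are
# deliberately naive (exhaustive enumeration / plain-R dynamic programs)
# and share no code with the package internals.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# purine-skewed background with few self-complementary pairings, for
# planting helices that dominate their sequence's null
rand_lowpair <- function(n, p = c(0.85, 0.05, 0.02, 0.08)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# ---- global alignment: exhaustive enumeration over all alignments --------

# score an alignment given as a move string (D = residue column,
# A = gap column consuming a, B = gap column consuming b); gap runs
# touching either end of the alignment are priced with the end costs
oracle_score_moves <- function(moves, av, bv, p) {
  r <- rle(moves)
  i <- 0L; j <- 0L; s <- 0
  nr <- length(r$lengths)
  for (t in seq_len(nr)) {
    ty <- r$values[t]; L <- r$lengths[t]
    if (ty == "D") {
      for (q in seq_len(L)) {
        i <- i + 1L; j <- j + 1L
        s <- s + if (av[i] == bv[j] && av[i] != "N") p$match else p$mismatch
      }
    } else {
      terminal <- (t == 1L || t == nr)
      s <- s - if (terminal) p$end_open + L * p$end_extend
               else p$gap_open + L * p$gap_extend
      if (ty == "A") i <- i + L else j <- j + L
    }
  }
  s
}

oracle_global_score <- function(a, b, p = align_params("global")) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  buf <- character(n + m)
  rec <- function(i, j, d) {
    if (i == n && j == m) {
      s <- oracle_score_moves(buf[seq_len(d)], av, bv, p)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m) { buf[d + 1L] <<- "D"; rec(i + 1L, j + 1L, d + 1L) }
    if (i < n) { buf[d + 1L] <<- "A"; rec(i + 1L, j, d + 1L) }
    if (j < m) { buf[d + 1L] <<- "B"; rec(i, j + 1L, d + 1L) }
    invisible()
  }
  rec(0L, 0L, 0L)
  best
}

# ---- local alignment: plain-R affine DP (clamped at zero) ----------------

oracle_local_score <- function(q, s, p = align_params("local")) {
  qa <- strsplit(q, "", fixed = TRUE)[[1L]]
  sa <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(qa); m <- length(sa)
  open1 <- p$gap_open + p$gap_extend
  M <- matrix(0, n + 1, m + 1)
  GA <- matrix(-Inf, n + 1, m + 1)
  GB <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1 + seq_len(n)) {
    for (j in 1 + seq_len(m)) {
      sc <- if (qa[i - 1] == sa[j - 1] && qa[i - 1] != "N") p$match else p$mismatch
      M[i, j] <- max(0, sc + max(M[i - 1, j - 1], GA[i - 1, j - 1], GB[i - 1, j - 1]))
      GA[i, j] <- max(M[i - 1, j] - open1, GA[i - 1, j] - p$gap_extend,
                      GB[i - 1, j] - open1)
      GB[i, j] <- max(M[i, j - 1] - open1, GB[i, j - 1] - p$gap_extend,
                      GA[i, j - 1] - open1)
      best <- max(best, M[i, j])
    }
  }
  best
}

# ---- qualifying helix: row-vectorized chain DP ---------------------------

# returns list(bp = best qualifying pair count, unpaired = minimal total
# skips achieving it), counting chains of WC pairs with at most m interior
# skipped nucleotides, innermost separation >= min_loop, and (guide mode)
# outermost 3' position >= guide_start (1-based; NA = intra)
oracle_helix <- function(s, m, min_loop = 3L, guide_start = NA) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  x <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(x)
  P <- outer(x, x, function(a, b) comp[a] == b)
  NEG <- -1L
  g <- lapply(0:m, function(u) matrix(NEG, n, n))
  best_bp <- 0L; best_u <- NA_integer_
  for (i in seq_len(n)) {
    for (u in 0:m) {
      row <- rep(NEG, n)
      jok <- which(P[i, ]); jok <- jok[jok > i]
      if (length(jok)) {
        startok <- if (is.na(guide_start)) jok else jok[jok >= guide_start]
        if (u == 0 && length(startok)) row[startok] <- 1L
        for (a in 0:u) {
          ip <- i - 1L - a
          if (ip < 1L) next
          for (b in 0:(u - a)) {
            prev <- g[[u - a - b + 1L]][ip, ]
            sh <- b + 1L
            pr <- c(prev[(1L + sh):n], rep(NEG, sh))
            cand <- pr + 1L
            upd <- jok[cand[jok] > row[jok] & pr[jok] > 0L]
            row[upd] <- cand[upd]
          }
        }
      }
      g[[u + 1L]][i, ] <- row
      jq <- which(row > 0L)
      jq <- jq[jq - i - 1L >= min_loop]
      if (length(jq)) {
        mx <- max(row[jq])
        if (mx > best_bp || (mx == best_bp && (is.na(best_u) || u < best_u))) {
          if (mx > best_bp) { best_bp <- mx; best_u <- u }
        }
      }
    }
  }
  # minimal u achieving best_bp
  if (best_bp > 0L) {
    for (u in 0:m) {
      found <- FALSE
      for (i in seq_len(n)) {
        row <- g[[u + 1L]][i, ]
        jq <- which(row == best_bp); jq <- jq[jq - i - 1L >= min_loop]
        if (length(jq)) { found <- TRUE; break }
      }
      if (found) { best_u <- u; break }
    }
  }
  list(bp = best_bp, unpaired = best_u)
}

# ---- duplex hybridization energy: memoized top-down recursion ------------

oracle_duplex_energy <- function(a, b, init = 4.1, loop_pen = 1.0,
                                 max_loop = 16L) {
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L, T = 4L)
  av <- code[strsplit(toupper(a), "", fixed = TRUE)[[1L]]]
  bv <- code[strsplit(toupper(b), "", fixed = TRUE)[[1L]]]
  pc <- function(x, y) { # AU=1 UA=2 GC=3 CG=4 GU=5 UG=6, else 0
    if (x == 1L && y == 4L) 1L else if (x == 4L && y == 1L) 2L
    else if (x == 3L && y == 2L) 3L else if (x == 2L && y == 3L) 4L
    else if (x == 3L && y == 4L) 5L else if (x == 4L && y == 3L) 6L else 0L
  }
  wc <- matrix(c(-0.93, -1.10, -2.08, -2.24,
                 -1.33, -0.93, -2.11, -2.35,
                 -2.35, -2.24, -3.26, -3.42,
                 -2.11, -2.08, -2.36, -3.26), 4, 4, byrow = TRUE)
  stk <- function(p1, p2) {
    if (p1 <= 4L && p2 <= 4L) wc[p1, p2]
    else if (p1 >= 5L && p2 >= 5L) -0.5
    else -1.2
  }
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  suffix <- function(i, j) { # best added energy after last pair (i, j)
    key <- paste0(i, ",", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- 0 # stop here
    if (i < n && j > 1L) {
      for (i2 in (i + 1L):n) {
        la <- i2 - i - 1L
        if (la > max_loop) break
        for (j2 in (j - 1L):1L) {
          lb <- j - j2 - 1L
          if (la + lb > max_loop) break
          if (pc(av[i2], bv[j2]) == 0L) next
          cost <- if (la == 0L && lb == 0L) stk(pc(av[i], bv[j]), pc(av[i2], bv[j2]))
                  else loop_pen * (la + lb)
          v2 <- cost + suffix(i2, j2)
          if (v2 < best) best <- v2
        }
      }
    }
    memo[[key]] <- best
    best
  }
  best <- Inf
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (pc(av[i], bv[j]) == 0L) next
    v <- init + suffix(i, j)
    if (v < best) best <- v
  }
  if (!is.finite(best) || best >= -1e-9) NA_real_ else best
}

# ---- Mann-Whitney: full label enumeration --------------------------------

oracle_mw_exact <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">") + 0.5 * outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  idx <- utils::combn(length(pool), nx)
  us <- apply(idx, 2, function(k) u_of(pool[k], pool[-k]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}
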