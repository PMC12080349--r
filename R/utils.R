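# internal sequence helpers and seed plumbing

.BASES <- c("A", "C", "G", "T")
.base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# normalize to the internal DNA alphabet: upper case, U -> T
.norm_seq <- function(x, what = "sequence", allow_empty = FALSE) {
  if (length(x) != 1L || !is.character(x) || is.na(x))
    stop(what, " must be a single character string")
  s <- chartr("u", "T", toupper(x))
  s <- chartr("U", "T", s)
  if (!allow_empty && nchar(s) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGTN]", s))
    stop(what, " contains characters outside the A/C/G/T/N alphabet")
  s
}

.enc <- function(s) {
  v <- .base_codes[strsplit(s, "", fixed = TRUE)[[1L]]]
  v[is.na(v)] <- 4L
  unname(v)
}

.dec <- function(v) paste(c(.BASES, "N")[v + 1L], collapse = "")

#' Reverse complement of a DNA sequence
#'
#' @param x a single DNA string (A/C/G/T/N; U is accepted and mapped to T).
#' @return the reverse complement string.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  s <- .norm_seq(x)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# random DNA of length n with the given GC content
.rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  expr
}

# deterministic child seed from (master seed, string key); stays < 2^31
.child_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 1987654321
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# 1-based inclusive interval extraction in transcription orientation
.oriented_subseq <- function(contig, start, end, strand) {
  s <- substr(contig, start, end)
  if (strand == "-") revcomp(s) else s
}

# merge 1-based inclusive intervals given as a 2-column matrix/data.frame
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(data.frame(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (t in seq_along(start)[-1]) {
    if (start[t] <= me + 1L) me <- max(me, end[t])
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- start[t]; me <- end[t] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}
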