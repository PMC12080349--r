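#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic-locus generator.  Defaults emulate the
#' reported characteristics of type II-C systems: upstream intergenic
#' regions of mean 247 nt (68 nt for II-A), 60% of extra repeats carrying
#' at least one mutation versus 5% of other repeats, mutations biased to
#' the first 15 nt of the repeat, a 12% terminator prevalence, and a
#' tracrRNA whose anti-repeat is the exact reverse complement of the
#' consensus repeat 5' end.  Background composition is AT-rich
#' (GC = 0.40), typical of the intergenic regions of the AT-rich hosts of
#' II-C systems.
#'
#' @param n_loci number of loci.
#' @param subtype `"II-C"` or `"II-A"` (sets the upstream length
#'   distribution default).
#' @param repeat_length,spacer_length repeat and spacer lengths in nt.
#' @param spacers_range inclusive range of spacers per array.
#' @param upstream_mean,upstream_sd normal distribution of the intergenic
#'   distance to the upstream gene, truncated at `upstream_min`.
#' @param upstream_min minimum upstream length (30).
#' @param gc background GC content.
#' @param p_mutation probability that the extra repeat carries planted
#'   mutations.
#' @param mutation_count_probs probabilities of 1, 2, 3 planted mutations
#'   given a mutated extra repeat.
#' @param position_bias fraction of planted mutations falling in the
#'   first 15 nt of the repeat.
#' @param p_nonextra_mutation probability that a non-extra repeat carries
#'   one mutation.
#' @param p_rit probability of a planted intrinsic terminator in the
#'   upstream region.
#' @param p_helix probability of a planted guide-pairing helix.
#' @param helix_len planted helix length in bp.
#' @param p_rescue probability of a planted degraded repeat 20-45 nt
#'   upstream of repeat 1 (off by default).
#' @param rescue_subs substitutions in the planted degraded repeat.
#' @param anti_repeat_len tracrRNA anti-repeat length.
#' @param tracr_scaffold_len tracrRNA scaffold length.
#' @param upstream_cap analysis cap on the upstream region (180 nt).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_loci = 100L, subtype = c("II-C", "II-A"),
                         repeat_length = 36L, spacer_length = 30L,
                         spacers_range = c(3L, 8L),
                         upstream_mean = if (subtype == "II-C") 247 else 68,
                         upstream_sd = if (subtype == "II-C") 60 else 20,
                         upstream_min = 30L, gc = 0.40,
                         p_mutation = 0.6,
                         mutation_count_probs = c(0.5, 0.3, 0.2),
                         position_bias = 0.8,
                         p_nonextra_mutation = 0.05,
                         p_rit = 0.12, p_helix = 0.3, helix_len = 10L,
                         p_rescue = 0, rescue_subs = 3L,
                         anti_repeat_len = 24L, tracr_scaffold_len = 60L,
                         upstream_cap = 180L) {
  subtype <- match.arg(subtype)
  stopifnot(n_loci >= 1L, repeat_length >= 20L, spacer_length >= 15L,
            all(c(p_mutation, p_nonextra_mutation, p_rit, p_helix, p_rescue,
                  position_bias) >= 0),
            all(c(p_mutation, p_nonextra_mutation, p_rit, p_helix, p_rescue,
                  position_bias) <= 1),
            upstream_min >= 30L, gc > 0, gc < 1,
            abs(sum(mutation_count_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "synth_config")
}

# substitute positions in a sequence with different random bases
.plant_substitutions <- function(seq, positions) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in positions)
    ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
  paste(ch, collapse = "")
}

# place an interval of length len within [lo, hi] avoiding occupied
# intervals; returns start or NA
.place_interval <- function(len, lo, hi, occupied, tries = 50L) {
  if (hi - len + 1L < lo) return(NA_integer_)
  for (t in seq_len(tries)) {
    s <- sample(lo:(hi - len + 1L), 1L)
    e <- s + len - 1L
    clash <- any(vapply(occupied, function(iv) s <= iv[2] && e >= iv[1], FALSE))
    if (!clash) return(s)
  }
  NA_integer_
}

# one synthetic locus in "transcript" orientation; returns NULL when the
# geometry is infeasible under the drawn upstream length
.synth_locus <- function(cfg, id) {
  rl <- cfg$repeat_length
  consensus <- .rand_dna(rl, cfg$gc)
  n_spacers <- sample(cfg$spacers_range[1]:cfg$spacers_range[2], 1L)
  up_len <- max(cfg$upstream_min, round(rnorm(1, cfg$upstream_mean, cfg$upstream_sd)))
  upstream <- .rand_dna(up_len, cfg$gc)
  win_lo <- max(1L, up_len - cfg$upstream_cap + 1L) # analyzed window
  occupied <- list()
  truth <- list(planted_mutation = FALSE, mutation_count = 0L,
                mutation_positions = integer(0),
                planted_rit = FALSE, rit_start = NA_integer_, rit_end = NA_integer_,
                planted_helix = FALSE, helix_guide_start = NA_integer_,
                helix_arm_start = NA_integer_,
                planted_rescue = FALSE, rescue_gap = NA_integer_)

  # planted guide-pairing helix: reverse complement of a guide-window
  # substring embedded >= 3 nt 5' of it
  if (runif(1) < cfg$p_helix) {
    gs_lo <- max(win_lo, up_len - 24L)
    gs_hi <- up_len - cfg$helix_len + 1L
    if (gs_hi < gs_lo) return(NULL)
    gs <- sample(gs_lo:gs_hi, 1L)
    arm <- revcomp(substr(upstream, gs, gs + cfg$helix_len - 1L))
    as <- .place_interval(cfg$helix_len, win_lo, gs - 4L, occupied)
    if (is.na(as)) return(NULL)
    substr(upstream, as, as + cfg$helix_len - 1L) <- arm
    occupied <- c(occupied, list(c(as, as + cfg$helix_len - 1L),
                                 c(gs, gs + cfg$helix_len - 1L)))
    truth$planted_helix <- TRUE
    truth$helix_guide_start <- gs
    truth$helix_arm_start <- as
  }

  # planted canonical terminator: GC-rich 9-bp stem, 4-nt loop, 8-nt T tract
  if (runif(1) < cfg$p_rit) {
    stem <- .rand_dna(9L, 0.85)
    term <- paste0(stem, .rand_dna(4L, 0.3), revcomp(stem), strrep("T", 8L))
    ts <- .place_interval(nchar(term), win_lo, up_len - 2L, occupied)
    if (is.na(ts)) return(NULL)
    substr(upstream, ts, ts + nchar(term) - 1L) <- term
    occupied <- c(occupied, list(c(ts, ts + nchar(term) - 1L)))
    truth$planted_rit <- TRUE
    truth$rit_start <- ts
    truth$rit_end <- ts + nchar(term) - 1L
  }

  # planted degraded repeat (rescue target) ending 20-45 nt before repeat 1
  if (runif(1) < cfg$p_rescue) {
    gap <- sample(20:45, 1L)
    rs <- up_len - gap - rl + 1L
    if (rs < win_lo) return(NULL)
    clash <- any(vapply(occupied, function(iv) rs <= iv[2] && up_len - gap >= iv[1], FALSE))
    if (clash) return(NULL)
    degr <- .plant_substitutions(consensus, sample(rl, cfg$rescue_subs))
    substr(upstream, rs, rs + rl - 1L) <- degr
    truth$planted_rescue <- TRUE
    truth$rescue_gap <- gap
  }

  # repeats: repeat 1 is the extra repeat and receives the planted mutations
  reps <- rep(consensus, n_spacers + 1L)
  if (runif(1) < cfg$p_mutation) {
    k <- sample(seq_along(cfg$mutation_count_probs), 1L,
                prob = cfg$mutation_count_probs)
    in15 <- runif(k) < cfg$position_bias
    cap15 <- min(15L, rl)
    pos <- integer(0)
    for (b in in15) {
      avail <- setdiff(if (b) 1:cap15 else (cap15 + 1L):rl, pos)
      if (length(avail) == 0L) avail <- setdiff(1:rl, pos)
      pos <- c(pos, if (length(avail) == 1L) avail else sample(avail, 1L))
    }
    reps[1L] <- .plant_substitutions(consensus, pos)
    truth$planted_mutation <- TRUE
    truth$mutation_count <- k
    truth$mutation_positions <- sort(pos)
  }
  for (t in 2L:length(reps)) {
    if (runif(1) < cfg$p_nonextra_mutation)
      reps[t] <- .plant_substitutions(consensus, sample(rl, 1L))
  }

  spacers <- replicate(n_spacers, .rand_dna(cfg$spacer_length, cfg$gc))
  array_seq <- paste0(paste0(reps[-length(reps)], spacers, collapse = ""),
                      reps[length(reps)])

  tracr <- paste0(revcomp(substr(consensus, 1L, cfg$anti_repeat_len)),
                  .rand_dna(cfg$tracr_scaffold_len, cfg$gc))

  # contig: pad | gene | upstream | array | tail (transcript orientation)
  gene_len <- 300L
  pad <- 20L; tail_len <- 60L
  gene_seq <- .rand_dna(gene_len, cfg$gc + 0.05)
  contig_fwd <- paste0(.rand_dna(pad, cfg$gc), gene_seq, upstream, array_seq,
                       .rand_dna(tail_len, cfg$gc))
  array_off <- pad + gene_len + up_len # 0-based offset of the array
  rep_starts <- array_off + 1L +
    (seq_len(n_spacers + 1L) - 1L) * (rl + cfg$spacer_length)
  repeats <- data.frame(start = rep_starts, end = rep_starts + rl - 1L)
  genes <- data.frame(start = pad + 1L, end = pad + gene_len)

  strand <- sample(c("+", "-"), 1L)
  clen <- nchar(contig_fwd)
  if (strand == "-") {
    contig <- revcomp(contig_fwd)
    repeats <- data.frame(start = clen - repeats$end + 1L,
                          end = clen - repeats$start + 1L)
    genes <- data.frame(start = clen - genes$end + 1L,
                        end = clen - genes$start + 1L)
  } else {
    contig <- contig_fwd
  }

  locus <- crispr_locus(id = id, contig = contig, repeats = repeats,
                        strand = strand, subtype = cfg$subtype,
                        tracrRNA = tracr, consensus = consensus,
                        contig_id = paste0("ctg_", id),
                        upstream_max = min(cfg$upstream_cap, up_len))
  genes$contig <- locus$contig_id
  # report planted coordinates in the coordinates of the analyzed upstream
  # window (1 = its 5' end)
  for (f in c("rit_start", "rit_end", "helix_guide_start", "helix_arm_start"))
    if (!is.na(truth[[f]])) truth[[f]] <- truth[[f]] - win_lo + 1L
  list(locus = locus, genes = genes, truth = truth)
}

#' Generate a synthetic locus cohort with planted ground truth
#'
#' Builds `cfg$n_loci` CRISPR loci (one contig each, random strand) with
#' planted extra-repeat mutations, guide-pairing helices, intrinsic
#' terminators and optionally rescuable degraded repeats, at the
#' configured prevalences, plus gene annotations bounding each upstream
#' region and a tracrRNA with an exact anti-repeat.  Fully reproducible
#' from the seed (per-locus child seeds are derived from it).
#'
#' @param cfg a [synth_config()].
#' @param seed integer master seed.
#' @return a list with `loci` (list of `crispr_locus`), `genes`
#'   (data.frame with `contig`, `start`, `end`), `truth` (data.frame of
#'   planted flags and coordinates, one row per locus) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_config(n_loci = 3), seed = 1)
#' cohort$truth
generate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"))
  loci <- vector("list", cfg$n_loci)
  genes <- list()
  truth <- list()
  n_regen <- 0L
  for (i in seq_len(cfg$n_loci)) {
    id <- sprintf("L%04d", i)
    res <- NULL
    attempt <- 0L
    while (is.null(res)) {
      attempt <- attempt + 1L
      if (attempt > 50L) stop("infeasible synthetic geometry for locus ", id)
      res <- .with_seed(.child_seed(seed, paste0(id, "#", attempt)),
                        .synth_locus(cfg, id))
      if (is.null(res)) n_regen <- n_regen + 1L
    }
    loci[[i]] <- res$locus
    genes[[i]] <- res$genes
    truth[[i]] <- data.frame(locus = id,
                             planted_mutation = res$truth$planted_mutation,
                             mutation_count = res$truth$mutation_count,
                             mutation_positions = paste(res$truth$mutation_positions,
                                                        collapse = ";"),
                             planted_rit = res$truth$planted_rit,
                             rit_start = res$truth$rit_start,
                             rit_end = res$truth$rit_end,
                             planted_helix = res$truth$planted_helix,
                             helix_guide_start = res$truth$helix_guide_start,
                             helix_arm_start = res$truth$helix_arm_start,
                             planted_rescue = res$truth$planted_rescue,
                             rescue_gap = res$truth$rescue_gap,
                             stringsAsFactors = FALSE)
  }
  if (n_regen > 0L)
    message(n_regen, " locus draw(s) regenerated for infeasible geometry")
  list(loci = loci, genes = do.call(rbind, genes),
       truth = do.call(rbind, truth), config = cfg)
}

#' Generate a random annotated mini-genome
#'
#' Random genes (lengths uniform in `gene_len_range`) separated by
#' exponentially distributed intergenic gaps (mean `gap_mean`), on a
#' composition-controlled background; used for the expected-ratio
#' denominator of the terminator enrichment statistic.
#'
#' @param n_genes number of genes.
#' @param contig_len contig length in nt.
#' @param gc background GC content.
#' @param seed integer seed.
#' @param gene_len_range inclusive gene-length range.
#' @param gap_mean mean intergenic gap length.
#' @return a list with `contig` (string) and `genes` (data.frame
#'   `start`/`end`).
#' @export
generate_null_genome <- function(n_genes, contig_len, gc = 0.40, seed = 1L,
                                 gene_len_range = c(300L, 900L),
                                 gap_mean = 150) {
  .with_seed(seed, {
    contig <- .rand_dna(contig_len, gc)
    starts <- integer(0); ends <- integer(0)
    pos <- 1L + round(rexp(1, 1 / gap_mean))
    for (g in seq_len(n_genes)) {
      len <- sample(gene_len_range[1]:gene_len_range[2], 1L)
      if (pos + len - 1L > contig_len) break
      starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
      pos <- pos + len + round(rexp(1, 1 / gap_mean)) + 1L
    }
    list(contig = contig, genes = data.frame(start = starts, end = ends))
  })
}
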