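# Seeded synthetic transcriptomes and footprint libraries with known
# per-gene readthrough ground truth.
#
# The generator emulates the salient phenomena of termination-mutant
# ribo-seq libraries: 3-nt periodic CDS footprints, programmed per-gene
# frame-0 3'-UTR density (readthrough), partial frame fidelity beyond the
# stop, optional ribosome stall pile-ups at the penultimate codon and the
# first downstream in-frame stop, and the 20-23 / 27-32 nt read-length
# classes. Read placement is Poisson and positionally uniform within each
# region.

#' Synthetic dataset configuration
#'
#' Defaults describe a termination-competent yeast-like library: yeast-like
#' stop codon usage, mildly G/A-biased nt +4, a mean log2 readthrough
#' efficiency of -4 (sd 1), frame fidelity 0.7 beyond the stop codon, 5%
#' off-frame CDS noise, no stall pile-up (`stall_multiplier = 1`; raise it to
#' emulate termination/recycling mutants), and a read-length distribution
#' peaked at 28 nt over the 20-23 and 27-32 nt classes.
#'
#' @param n_genes Number of genes.
#' @param utr5_range,utr3_range Min/max UTR lengths (nt).
#' @param cds_codons Min/max CDS length in codons (start and stop included).
#' @param ext_codons Min/max extension length in codons (the first downstream
#'   in-frame stop codon included); capped by the 3'-UTR length.
#' @param lambda_cds Frame-0 CDS read density (reads per nt).
#' @param re_mean,re_sd Baseline and gene-level sd of true log2 readthrough
#'   efficiency.
#' @param effect_map Named list of per-feature log2 RE shifts, e.g.
#'   `list(stop_codon = c(UGA = 1.5), nt_p4 = c(C = 0.8))`.
#' @param stop_freq Named sampling frequencies of the canonical stop codon.
#' @param nt4_freq Named sampling frequencies of nt +4.
#' @param nt4_coupling Optional list `list(stop = , nt = , odds = )`
#'   multiplying the odds of nucleotide `nt` at +4 for genes carrying `stop`.
#' @param frame_fidelity Fraction of 3'-UTR reads in frame 0.
#' @param offframe_cds_noise Off-frame fraction of CDS reads.
#' @param stall_multiplier Pile-up factor at the penultimate codon and the
#'   first downstream in-frame stop (1 = no stall).
#' @param read_length_probs Named numeric vector of read-length
#'   probabilities.
#' @param offsets P-site offset table (`length`, `offset`).
#' @param rnaseq_depth Total expected RNA-seq read count.
#' @return An `rt_synth_config` list.
#' @export
synthetic_config <- function(
    n_genes = 1000L,
    utr5_range = c(30L, 120L),
    cds_codons = c(100L, 300L),
    ext_codons = c(3L, 20L),
    utr3_range = c(80L, 250L),
    lambda_cds = 0.5,
    re_mean = -4, re_sd = 1,
    effect_map = list(),
    stop_freq = c(UAA = 0.47, UAG = 0.23, UGA = 0.30),
    nt4_freq = c(A = 0.30, C = 0.20, G = 0.30, U = 0.20),
    nt4_coupling = NULL,
    frame_fidelity = 0.7,
    offframe_cds_noise = 0.05,
    stall_multiplier = 1,
    read_length_probs = c(`20` = 0.03, `21` = 0.04, `22` = 0.04, `23` = 0.04,
                          `27` = 0.06, `28` = 0.25, `29` = 0.20, `30` = 0.14,
                          `31` = 0.12, `32` = 0.08),
    offsets = tibble(length = c(20:23, 27:32),
                     offset = c(10L, 10L, 11L, 11L, 12L, 12L, 13L, 13L,
                                14L, 14L)),
    rnaseq_depth = 2e6) {
  stopifnot(frame_fidelity > 0, frame_fidelity <= 1,
            offframe_cds_noise >= 0, offframe_cds_noise < 1,
            lambda_cds > 0, stall_multiplier >= 1)
  if (3L * ext_codons[1] > utr3_range[1]) {
    abort("extension cannot be longer than the shortest 3'-UTR")
  }
  if (ext_codons[1] < 2L) {
    abort(paste0("ext_codons must be at least 2 (one sense codon carrying ",
                 "nt +4 plus the downstream stop)"))
  }
  validate_offset_table(offsets)
  structure(
    list(n_genes = n_genes, utr5_range = utr5_range,
         cds_codons = cds_codons, ext_codons = ext_codons,
         utr3_range = utr3_range, lambda_cds = lambda_cds,
         re_mean = re_mean, re_sd = re_sd, effect_map = effect_map,
         stop_freq = stop_freq, nt4_freq = nt4_freq,
         nt4_coupling = nt4_coupling, frame_fidelity = frame_fidelity,
         offframe_cds_noise = offframe_cds_noise,
         stall_multiplier = stall_multiplier,
         read_length_probs = read_length_probs, offsets = offsets,
         rnaseq_depth = rnaseq_depth),
    class = "rt_synth_config")
}

#' Generate a synthetic transcriptome with known context ground truth
#'
#' Each gene gets a random 5'-UTR, a CDS (AUG start, stop-free sense
#' interior, stop codon sampled from `stop_freq`), an nt +4 sampled from
#' `nt4_freq` (optionally odds-coupled to the stop codon), a guaranteed first
#' downstream in-frame stop at `ext_codons` codons, and a random distal
#' 3'-UTR. Reproducible under `seed`.
#'
#' @param config An [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `models` (valid transcript models, `utr3_annotated =
#'   TRUE`) and `truth` (per-gene assigned context and lengths).
#' @export
generate_transcriptome <- function(config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- config$n_genes
  nt <- c("A", "C", "G", "U")
  u5 <- sample(config$utr5_range[1]:config$utr5_range[2], n, replace = TRUE)
  ncod <- sample(config$cds_codons[1]:config$cds_codons[2], n, replace = TRUE)
  u3 <- sample(config$utr3_range[1]:config$utr3_range[2], n, replace = TRUE)
  ext_max <- pmin(config$ext_codons[2], u3 %/% 3L)
  ext <- config$ext_codons[1] +
    floor(runif(n) * (ext_max - config$ext_codons[1] + 1L))
  stops <- sample(names(config$stop_freq), n, replace = TRUE,
                  prob = config$stop_freq)
  nt4 <- character(n)
  for (i in seq_len(n)) {
    p <- config$nt4_freq
    cp <- config$nt4_coupling
    if (!is.null(cp) && stops[i] == cp$stop) {
      p[cp$nt] <- p[cp$nt] * cp$odds
    }
    nt4[i] <- sample(names(p), 1L, prob = p)
  }
  seqs <- character(n)
  p_site <- character(n)
  dstop <- character(n)
  for (i in seq_len(n)) {
    interior <- sample(SENSE_CODONS, ncod[i] - 2L, replace = TRUE)
    p_site[i] <- interior[length(interior)]
    cds <- paste0("AUG", paste(interior[-length(interior)], collapse = ""),
                  p_site[i], stops[i])
    # extension: first codon starts with nt+4, interior stop-free, then the
    # guaranteed first downstream in-frame stop
    first_pool <- SENSE_CODONS[substr(SENSE_CODONS, 1, 1) == nt4[i]]
    ext_cod <- c(sample(first_pool, 1L),
                 if (ext[i] > 2L) sample(SENSE_CODONS, ext[i] - 2L,
                                         replace = TRUE))
    dstop[i] <- sample(names(config$stop_freq), 1L,
                       prob = config$stop_freq)
    ext_seq <- paste0(paste(ext_cod, collapse = ""), dstop[i])
    distal <- paste(sample(nt, u3[i] - 3L * ext[i], replace = TRUE),
                    collapse = "")
    utr5_seq <- paste(sample(nt, u5[i], replace = TRUE), collapse = "")
    seqs[i] <- paste0(utr5_seq, cds, ext_seq, distal)
  }
  ids <- sprintf("g%04d", seq_len(n))
  models <- tibble(id = ids, seq = seqs, utr5_len = u5,
                   cds_len = 3L * ncod, utr3_len = u3,
                   utr3_annotated = TRUE)
  truth <- tibble(id = ids, stop_codon = stops, nt_p4 = nt4,
                  p_site_codon = p_site, first_utr3_stop = dstop,
                  ext_codons = ext, utr5_len = u5, cds_len = 3L * ncod,
                  utr3_len = u3)
  list(models = models, truth = truth)
}

#' Assign programmed readthrough efficiencies
#'
#' Additive model on the log2 scale: `true_log2_re = baseline + sum of
#' applicable feature effects + N(0, noise_sd)` per gene.
#'
#' @param truth Truth tibble from [generate_transcriptome()].
#' @param effect_map Named list of per-feature level shifts (see
#'   [synthetic_config()]).
#' @param noise_sd Gene-level noise sd (log2 units).
#' @param baseline Baseline log2 readthrough efficiency.
#' @param seed Integer seed.
#' @return The truth tibble with a `true_log2_re` column.
#' @export
assign_true_re <- function(truth, effect_map = list(), noise_sd = 1,
                           baseline = -4, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  re <- rep(baseline, nrow(truth))
  for (f in names(effect_map)) {
    eff <- effect_map[[f]]
    hit <- match(truth[[f]], names(eff))
    re <- re + ifelse(is.na(hit), 0, eff[hit])
  }
  truth$true_log2_re <- re + rnorm(nrow(truth), 0, noise_sd)
  truth
}

#' Simulate a footprint library with programmed readthrough
#'
#' Frame-0 CDS read counts are Poisson with density `lambda_cds`; frame-0
#' 3'-UTR counts are Poisson with density `lambda_cds * 2^true_log2_re` over
#' the adjusted 3'-UTR (stop codon included). Off-frame reads are added per
#' `offframe_cds_noise` (CDS) and `frame_fidelity` (3'-UTR); stall pile-ups
#' at the penultimate codon and at the first downstream in-frame stop are
#' scaled by `stall_multiplier` (the downstream-stop pile-up is frame 0 and
#' therefore enters the readthrough numerator, reproducing the known
#' overestimation when ribosomes queue there). Each read's 5' end is
#' back-computed from its P-site via the offset table.
#'
#' @param models,truth Output of [generate_transcriptome()]; `truth` must
#'   carry `true_log2_re` (see [assign_true_re()]).
#' @param config An [synthetic_config()].
#' @param seed Integer seed.
#' @return Tibble `transcript_id`, `five_prime` (0-based), `length`.
#' @export
simulate_footprints <- function(models, truth, config, seed) {
  stopifnot("true_log2_re" %in% names(truth))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lam <- config$lambda_cds
  stall <- config$stall_multiplier
  ff <- config$frame_fidelity
  offn <- config$offframe_cds_noise

  draw <- function(grid, n) grid[sample.int(length(grid), n, replace = TRUE)]
  per_gene <- purrr::map(seq_len(nrow(models)), function(i) {
    u5 <- models$utr5_len[i]
    cl <- models$cds_len[i]
    u3 <- models$utr3_len[i]
    tx_len <- u5 + cl + u3
    re <- truth$true_log2_re[match(models$id[i], truth$id)]
    lam3 <- lam * 2^re

    # frame-0 CDS (sense codon starts; stop codon handled on the 3'-UTR side)
    cds_grid <- u5 + 3L * (seq_len(cl %/% 3L - 1L) - 1L)
    n_cds <- rpois(1, lam * cl)
    pos <- draw(cds_grid, n_cds)
    # stall at the penultimate codon
    if (stall > 1) {
      pos <- c(pos, rep(u5 + cl - 6L, rpois(1, (stall - 1) * 3 * lam)))
    }
    # off-frame CDS noise
    n_off <- rpois(2, lam * cl * offn / 2)
    pos <- c(pos, draw(cds_grid + 1L, n_off[1]), draw(cds_grid + 2L, n_off[2]))

    # frame-0 adjusted 3'-UTR (stop codon start + downstream in-frame grid)
    utr3_grid <- (u5 + cl - 3L) + 3L * (seq_len((u3 + 3L) %/% 3L) - 1L)
    n_utr3 <- rpois(1, lam3 * (u3 + 3L))
    pos3 <- draw(utr3_grid, n_utr3)
    if (stall > 1) {
      ds_stop <- u5 + cl + 3L * truth$ext_codons[match(models$id[i],
                                                       truth$id)] - 3L
      pos3 <- c(pos3, rep(ds_stop, rpois(1, (stall - 1) * 3 * lam3)))
    }
    # off-frame 3'-UTR reads per frame fidelity
    if (ff < 1) {
      n_off3 <- rpois(2, lam3 * (u3 + 3L) * (1 - ff) / ff / 2)
      g1 <- utr3_grid[utr3_grid + 1L < tx_len] + 1L
      g2 <- utr3_grid[utr3_grid + 2L < tx_len] + 2L
      pos3 <- c(pos3, draw(g1, n_off3[1]), draw(g2, n_off3[2]))
    }
    tibble(transcript_id = models$id[i], psite = c(pos, pos3))
  })
  fp <- bind_rows(per_gene)
  lens <- as.integer(names(config$read_length_probs))
  fp$length <- sample(lens, nrow(fp), replace = TRUE,
                      prob = config$read_length_probs)
  off <- config$offsets$offset[match(fp$length, config$offsets$length)]
  fp %>%
    mutate(five_prime = .data$psite - off) %>%
    select("transcript_id", "five_prime", "length")
}

#' Simulate an RNA-seq abundance table
#'
#' Per-gene abundances are log-normal; counts are Poisson with expectation
#' proportional to abundance x transcript length, scaled to
#' `rnaseq_depth` total reads. Exported in a form compatible with
#' [correlation_matrix()] and [translation_efficiency()].
#'
#' @param models Model tibble.
#' @param config An [synthetic_config()].
#' @param seed Integer seed.
#' @return Tibble `id`, `count`, `expression` (RPKM-scale).
#' @export
simulate_rnaseq <- function(models, config, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  len <- nchar(models$seq)
  abund <- stats::rlnorm(nrow(models), log(10), 1)
  mu <- abund * len
  if (config$rnaseq_depth <= 0) {
    counts <- rep(0L, nrow(models))
  } else {
    counts <- rpois(nrow(models), config$rnaseq_depth * mu / sum(mu))
  }
  total <- max(sum(counts), 1L)
  tibble(id = models$id, count = counts,
         expression = counts / (len / 1e3) / (total / 1e6))
}
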