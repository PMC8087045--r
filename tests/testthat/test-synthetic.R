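# The seeded generator: transcriptomes, programmed RE, footprints, writers.

test_that("transcriptome generation is seed-reproducible and valid", {
  cfg <- synthetic_config(n_genes = 40)
  a <- generate_transcriptome(cfg, seed = 51)
  b <- generate_transcriptome(cfg, seed = 51)
  expect_identical(a, b)
  c_ <- generate_transcriptome(cfg, seed = 52)
  expect_false(identical(a$models$seq, c_$models$seq))
  expect_silent(validate_models(a$models))
  # the designated downstream stop is really the first in-frame one
  rm_ <- locate_extensions(a$models)
  expect_equal(rm_$ext_hi - rm_$ext_lo, 3L * a$truth$ext_codons)
  expect_true(all(rm_$has_downstream_stop))
})

test_that("requested stop-codon frequencies are matched empirically", {
  cfg <- synthetic_config(n_genes = 3000,
                          stop_freq = c(UAA = 0.5, UAG = 0.3, UGA = 0.2))
  sim <- generate_transcriptome(cfg, seed = 53)
  freq <- table(sim$truth$stop_codon) / 3000
  expect_equal(unname(freq["UAA"]), 0.5, tolerance = 0.04)
  expect_equal(unname(freq["UAG"]), 0.3, tolerance = 0.067)
  expect_equal(unname(freq["UGA"]), 0.2, tolerance = 0.1)
  # and the extracted features agree with the programmed truth
  ctx <- extract_sequence_context(sim$models, locate_extensions(sim$models))
  expect_equal(ctx$stop_codon, sim$truth$stop_codon)
  expect_equal(ctx$nt_p4, sim$truth$nt_p4)
  expect_equal(ctx$p_site_codon, sim$truth$p_site_codon)
})

test_that("nt4 coupling raises the joint frequency as an odds multiplier", {
  cfg <- synthetic_config(n_genes = 4000,
                          nt4_coupling = list(stop = "UAA", nt = "G",
                                              odds = 3))
  sim <- generate_transcriptome(cfg, seed = 54)
  t_ <- sim$truth
  p_g_uaa <- mean(t_$nt_p4[t_$stop_codon == "UAA"] == "G")
  p_g_other <- mean(t_$nt_p4[t_$stop_codon != "UAA"] == "G")
  expect_gt(p_g_uaa, p_g_other + 0.1)
})

test_that("programmed RE is additive with seeded noise", {
  cfg <- synthetic_config(n_genes = 2000)
  sim <- generate_transcriptome(cfg, seed = 55)
  t0 <- assign_true_re(sim$truth, noise_sd = 0, baseline = -4, seed = 1)
  expect_true(all(t0$true_log2_re == -4))
  emap <- list(stop_codon = c(UGA = 1), nt_p4 = c(C = 0.5))
  t1 <- assign_true_re(sim$truth, emap, noise_sd = 0, baseline = -4, seed = 1)
  uga_c <- t1$stop_codon == "UGA" & t1$nt_p4 == "C"
  expect_true(all(t1$true_log2_re[uga_c] == -4 + 1 + 0.5))
  t2 <- assign_true_re(sim$truth, emap, noise_sd = 1, baseline = -4, seed = 2)
  expect_equal(mean(t2$true_log2_re[t2$stop_codon == "UGA"]) -
                 mean(t2$true_log2_re[t2$stop_codon != "UGA"]),
               1, tolerance = 0.2)
})

test_that("simulation with no noise recovers RE nearly unbiased", {
  cfg <- synthetic_config(n_genes = 60, lambda_cds = 3, re_mean = 0,
                          utr3_range = c(150L, 250L),
                          frame_fidelity = 1, offframe_cds_noise = 0)
  sim <- generate_transcriptome(cfg, seed = 56)
  truth <- assign_true_re(sim$truth, noise_sd = 0, baseline = 0, seed = 3)
  fp <- simulate_footprints(sim$models, truth, cfg, seed = 57)
  fp <- assign_psites(filter_footprint_lengths(fp), cfg$offsets, sim$models)
  fp <- add_frames(fp, sim$models)
  rm_ <- locate_extensions(sim$models)
  est <- readthrough_efficiency(count_region_frames(fp, sim$models, rm_),
                                sim$models, rm_)
  expect_lt(abs(mean(est$log2_re)), 0.1)
  # frame fidelity 1: extension reads are exclusively frame 0
  ff <- frame_fractions(count_region_frames(fp, sim$models, rm_),
                        "extension")
  expect_equal(ff$fraction, c(1, 0, 0))
})

test_that("a stall pile-up appears at the penultimate codon in the metagene", {
  cfg <- synthetic_config(n_genes = 40, lambda_cds = 1, stall_multiplier = 20)
  sim <- generate_transcriptome(cfg, seed = 58)
  truth <- assign_true_re(sim$truth, noise_sd = 1, baseline = -4, seed = 4)
  fp <- simulate_footprints(sim$models, truth, cfg, seed = 59)
  fp <- assign_psites(filter_footprint_lengths(fp), cfg$offsets, sim$models)
  mg <- metagene_profile(fp, sim$models, anchor = "stop")
  expect_equal(mg$position[which.max(mg$fraction)], -3L)
})

test_that("stall reads leave the estimate nearly unchanged when they sit in the exclusion zone", {
  base_args <- list(n_genes = 80, lambda_cds = 3, re_mean = -2,
                    utr3_range = c(150L, 250L))
  run <- function(stall) {
    cfg <- do.call(synthetic_config, c(base_args,
                                       list(stall_multiplier = stall)))
    sim <- generate_transcriptome(cfg, seed = 60)
    truth <- assign_true_re(sim$truth, noise_sd = 0, baseline = -2, seed = 5)
    fp <- simulate_footprints(sim$models, truth, cfg, seed = 61)
    fp <- add_frames(assign_psites(filter_footprint_lengths(fp),
                                   cfg$offsets, sim$models), sim$models)
    rm_ <- locate_extensions(sim$models)
    readthrough_efficiency(count_region_frames(fp, sim$models, rm_),
                           sim$models, rm_)$log2_re
  }
  re1 <- run(1)
  re20 <- run(20)
  # the penultimate-codon pile-up is excluded by the CDS edge zones, but the
  # frame-0 pile-up at the downstream stop enters the numerator: the median
  # shifts upward by roughly the programmed pile-up mass
  delta <- median(re20) - median(re1)
  expect_gt(delta, 0)
  expect_lt(delta, 1.5)
})

test_that("rnaseq simulation is seeded, depth-scaled and length-proportional", {
  cfg <- synthetic_config(n_genes = 200)
  sim <- generate_transcriptome(cfg, seed = 62)
  a <- simulate_rnaseq(sim$models, cfg, seed = 63)
  b <- simulate_rnaseq(sim$models, cfg, seed = 63)
  expect_identical(a, b)
  expect_equal(sum(a$count), cfg$rnaseq_depth, tolerance = 0.05)
  cfg0 <- synthetic_config(n_genes = 200, rnaseq_depth = 0)
  z <- simulate_rnaseq(sim$models, cfg0, seed = 63)
  expect_true(all(z$count == 0))
})

test_that("writers round-trip through the corresponding readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_genes = 15)
  sim <- generate_transcriptome(cfg, seed = 64)
  truth <- assign_true_re(sim$truth, noise_sd = 1, seed = 6)
  fp <- simulate_footprints(sim$models, truth, cfg, seed = 65)

  # transcriptome: write -> load gives back the same models
  write_transcriptome(sim$models, file.path(dir, "t.fa"),
                      file.path(dir, "t.gff3"))
  models2 <- load_transcriptome(file.path(dir, "t.gff3"),
                                file.path(dir, "t.fa"))
  models2 <- models2[match(sim$models$id, models2$id), ]
  expect_equal(models2$seq, sim$models$seq)
  expect_equal(models2$utr5_len, sim$models$utr5_len)
  expect_equal(models2$cds_len, sim$models$cds_len)
  expect_equal(models2$utr3_len, sim$models$utr3_len)
  expect_true(all(models2$utr3_annotated))

  # footprints: TSV and SAM round-trips are lossless
  write_footprints_tsv(fp, file.path(dir, "fp.tsv"))
  fp_tsv <- read_footprints_tsv(file.path(dir, "fp.tsv"))
  expect_equal(as.data.frame(fp_tsv), as.data.frame(fp))
  sub <- fp[1:200, ]
  write_footprints_sam(sub, sim$models, file.path(dir, "fp.sam"))
  fp_sam <- read_footprints_sam(file.path(dir, "fp.sam"))
  expect_equal(dplyr::arrange(as.data.frame(fp_sam), transcript_id,
                              five_prime, length),
               dplyr::arrange(as.data.frame(sub), transcript_id,
                              five_prime, length))

  # offset table round-trip
  write_offset_table(cfg$offsets, file.path(dir, "off.tsv"))
  expect_equal(as.data.frame(read_offset_table(file.path(dir, "off.tsv"))),
               as.data.frame(cfg$offsets))

  # one-call dataset writer emits every artifact
  out <- write_synthetic_dataset(sim$models, truth, fp, cfg, seed = 64,
                                 dir = file.path(dir, "ds"),
                                 rnaseq = simulate_rnaseq(sim$models, cfg, 1))
  expect_true(all(file.exists(file.path(out, c(
    "transcriptome.fa", "transcriptome.gff3", "footprints.tsv",
    "truth.tsv", "offsets.tsv", "abundance.tsv", "MANIFEST.tsv")))))
})

test_that("infeasible configurations are rejected", {
  expect_error(synthetic_config(ext_codons = c(10L, 20L),
                                utr3_range = c(20L, 40L)),
               "extension")
  expect_error(synthetic_config(frame_fidelity = 0), "frame_fidelity")
})
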