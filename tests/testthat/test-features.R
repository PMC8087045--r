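# Stop-codon context features, exit-tunnel properties, tAI, controls.

test_that("sequence context reads the channel positions off the transcript", {
  m <- toy_model(utr5 = strrep("A", 10),
                 cds = paste0("AUG", strrep("AAG", 10), "GCUUAA"),
                 utr3 = "CAAAAAGGGG")
  rm_ <- locate_extensions(m)
  ctx <- extract_sequence_context(m, rm_)
  expect_equal(ctx$stop_codon, "UAA")
  expect_equal(ctx$nt_p4, "C")
  expect_equal(ctx$p_site_codon, "GCU")
  expect_equal(ctx$p_site_aa, "A")
  expect_equal(ctx$e_site_codon, "AAG")
  expect_equal(ctx$e_site_aa, "K")
  expect_equal(ctx$nt_m1, "U")
  expect_true(ctx$context_complete)
})

test_that("every channel position matches direct string slicing on a toy gene", {
  utr5 <- "GGGGG"
  cds <- "AUGCAUUCGAAGGAUUGCCCAGUCAAAGCUUAG"   # 33 nt, ends UAG
  utr3 <- "CGAUAGCCCC"
  m <- toy_model(utr5 = utr5, cds = cds, utr3 = utr3)
  ctx <- extract_sequence_context(m, locate_extensions(m))
  # upstream: nt -k is the k-th nt before the stop codon
  upstream <- substr(cds, nchar(cds) - 17, nchar(cds) - 3)  # nt -15..-1
  for (k in 1:15) {
    expect_equal(ctx[[paste0("nt_m", k)]], substr(upstream, 16 - k, 16 - k),
                 info = paste("nt -", k))
  }
  expect_equal(ctx$stop_codon, substr(cds, nchar(cds) - 2, nchar(cds)))
  for (k in 4:9) {
    expect_equal(ctx[[paste0("nt_p", k)]], substr(utr3, k - 3, k - 3),
                 info = paste("nt +", k))
  }
  # concatenated categorical features reproduce the transcript around the stop
  stitched <- paste0(
    paste(sapply(15:1, function(k) ctx[[paste0("nt_m", k)]]), collapse = ""),
    ctx$stop_codon,
    paste(sapply(4:9, function(k) ctx[[paste0("nt_p", k)]]), collapse = "")
  )
  expect_equal(stitched, substr(m$seq, m$utr5_len + m$cds_len - 17,
                                m$utr5_len + m$cds_len + 6))
  # first downstream in-frame stop: CGA UAG -> UAG
  expect_equal(ctx$first_utr3_stop, "UAG")
})

test_that("short 3'-UTRs and short CDSs produce NA positions with flags", {
  m <- toy_model(utr5 = strrep("A", 10),
                 cds = paste0("AUG", strrep("AAG", 10), "UAA"),
                 utr3 = "CGAU")
  ctx <- extract_sequence_context(m, locate_extensions(m))
  expect_equal(ctx$nt_p4, "C")
  expect_equal(ctx$nt_p7, "U")
  expect_true(is.na(ctx$nt_p8))
  expect_true(is.na(ctx$nt_p9))
  expect_false(ctx$context_complete)
  m2 <- toy_model(cds = "AUGGCUGAAUAA", utr3 = "CAAAAAGG")  # 12-nt CDS
  ctx2 <- extract_sequence_context(m2, locate_extensions(m2))
  expect_true(is.na(ctx2$nt_m15))
  expect_equal(ctx2$nt_m9, "A")  # first CDS nt (9 nt upstream of the stop)
})

test_that("C-terminal translation indexes residues from the stop codon", {
  m <- toy_model(cds = "AUGGCUUAA", utr3 = "CAAAAA")
  ct <- translate_c_terminus(m)
  expect_equal(ct$c_term, "AM")  # aa1 = Ala (GCU), aa2 = Met (AUG)
  expect_equal(ct$n_aa, 2L)
  expect_true(ct$truncated)
  # 40-codon gene: hand translation of the last 30 sense codons
  set.seed(406)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA"))
  cods <- sample(sense, 38, replace = TRUE)
  cds <- paste0("ATG", paste(cods, collapse = ""), "TAA")
  m2 <- toy_model(cds = chartr("T", "U", cds), utr3 = "CAAAAA")
  ct2 <- translate_c_terminus(m2)
  hand <- rev(as.character(Biostrings::GENETIC_CODE[cods]))[1:30]
  expect_equal(ct2$c_term, paste(hand, collapse = ""))
  expect_equal(ct2$n_aa, 30L)
  expect_false(ct2$truncated)
  # aa1 is the residue encoded by nt -3..-1
  ctx <- extract_sequence_context(m2, locate_extensions(m2))
  expect_equal(substr(ct2$c_term, 1, 1), ctx$p_site_aa)
})

test_that("internal in-frame stops are a validation error", {
  m <- toy_model(cds = "AUGUAAGCUUAA", utr3 = "CAAAAA")
  expect_error(translate_c_terminus(m), "internal stop")
})

test_that("tunnel fractions count residue classes per window", {
  fr <- tunnel_property_fractions("KKKKKKK")
  expect_equal(fr$charge_pos, 1)
  expect_equal(fr$charge_neg, 0)
  expect_equal(fr$charge_neutral, 0)
  fr2 <- tunnel_property_fractions("KDAAAGG")
  expect_equal(fr2$charge_pos, 1 / 7)
  expect_equal(fr2$charge_neg, 1 / 7)
  expect_equal(fr2$charge_neutral, 5 / 7)
  # each class group sums to 1
  expect_equal(fr2$charge_pos + fr2$charge_neutral + fr2$charge_neg, 1)
  expect_equal(fr2$polarity_polar + fr2$polarity_nonpolar, 1)
  expect_equal(fr2$hydrophobicity_hydrophilic + fr2$hydrophobicity_neutral +
                 fr2$hydrophobicity_hydrophobic +
                 fr2$hydrophobicity_very_hydrophobic, 1)
  # empty windows are NA
  expect_true(is.na(tunnel_property_fractions(NA_character_)$charge_pos))
  # property tables cover all 20 residues exactly once
  expect_equal(sort(residue_properties()$aa),
               sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
})

test_that("external features are copied verbatim, NA when absent, validated", {
  fm <- tibble::tibble(id = c("a", "b"))
  st <- tibble::tibble(id = "a", mfe = -12.3, struct_distance = 40)
  hx <- tibble::tibble(id = "a", helix_fraction = 0.25)
  out <- suppressMessages(attach_external_features(fm, st, hx))
  expect_equal(out$mfe[1], -12.3)
  expect_equal(out$struct_distance[1], 40)
  expect_equal(out$helix_fraction[1], 0.25)
  expect_true(is.na(out$mfe[2]))
  expect_error(
    attach_external_features(fm, st,
                             tibble::tibble(id = "a", helix_fraction = 1.2)),
    "\\[0, 1\\]")
  expect_error(
    attach_external_features(fm, tibble::tibble(id = "a", mfe = 3,
                                                struct_distance = 1), NULL),
    "<= 0")
})

test_that("negative controls are uniform, in range and seed-reproducible", {
  fm <- tibble::tibble(id = sprintf("g%05d", 1:10000))
  a <- add_negative_controls(fm, seed = 11)
  b <- add_negative_controls(fm, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$random_number >= 1 & a$random_number <= 100))
  expect_true(all(a$random_factor %in% c("A", "C", "G", "U")))
  expect_gt(chisq.test(table(a$random_factor))$p.value, 0.001)
  expect_gt(chisq.test(table(a$random_number))$p.value, 0.001)
})

test_that("gene tAI is the geometric mean over sense codons", {
  tai <- tibble::tibble(codon = c("AUG", "GCU", "AAG"),
                        tai = c(0.25, 1.0, 0.5))
  m <- toy_model(cds = "AUGGCUUAA", utr3 = "CAAAAA")
  expect_equal(gene_tai(m, tai)$tai, sqrt(0.25 * 1.0))
  m1 <- toy_model(cds = "AUGUAA", utr3 = "CAAAAA")  # single sense codon
  expect_equal(gene_tai(m1, tai)$tai, 0.25)
  m3 <- toy_model(cds = "AUGGCUGCUGCUUAA", utr3 = "CAAAAA")
  expect_equal(gene_tai(m3, tibble::tibble(codon = c("AUG", "GCU"),
                                           tai = c(0.7, 0.7)))$tai, 0.7)
  expect_error(gene_tai(toy_model(cds = "AUGCCCUAA", utr3 = "C"), tai),
               "absent")
  expect_equal(codon_tai(c("GCU", "AAG"), tai), c(1.0, 0.5))
})

test_that("the assembled matrix is pure, fixed-arity and schema-complete", {
  cfg <- synthetic_config(n_genes = 30)
  sim <- generate_transcriptome(cfg, seed = 21)
  rm_ <- locate_extensions(sim$models)
  fm1 <- build_feature_matrix(sim$models, rm_, seed = 5)
  fm2 <- build_feature_matrix(sim$models, rm_, seed = 5)
  expect_identical(fm1, fm2)
  sch <- feature_schema(fm1)
  expect_true(all(sch$feature %in% names(fm1)))
  # 24 channel nt features + first stop + 2 site residues + 1 control factor
  expect_equal(sum(sch$type == "categorical"), 26L)
  # 40 tunnel fractions + utr3_len + 3 external + random_number
  expect_equal(sum(sch$type == "numeric"), 45L)
  # context of the generator's truth matches the extracted features
  expect_equal(fm1$stop_codon, sim$truth$stop_codon)
  expect_equal(fm1$nt_p4, sim$truth$nt_p4)
  expect_equal(fm1$first_utr3_stop, sim$truth$first_utr3_stop)
})
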