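test_that("dilution mixes p/q tumor reads with 1 - p/q normal reads", {
  expect_equal(dilution_fraction(q = 0.8, p = 0.2),
               c(tumor = 0.25, normal = 0.75))
  expect_equal(dilution_fraction(q = 0.8, p = 0.8), c(tumor = 1, normal = 0))
  expect_error(dilution_fraction(q = 0.5, p = 0.6), "concentrate")
  expect_error(dilution_fraction(q = 0, p = 0), "source purity")
})

test_that("diluted variants follow the binomial read model", {
  model <- sequencing_model(mean_depth = 100)
  set.seed(1)
  # identity: p = q leaves the expected VAF unchanged
  obs <- dilute_variant(0.37, q = 0.8, p = 0.8, model)
  expect_equal(obs$expected_vaf, 0.37)
  # p = 0: no tumor reads at all
  obs <- dilute_variant(0.4, q = 0.8, p = 0, model)
  expect_equal(obs$expected_vaf, 0)
  expect_false(obs$detected)
  # binomial expectation oracle: q=0.8, p=0.4, vaf=0.4 -> E[alt] = depth * 0.2
  set.seed(2)
  alts <- replicate(10000, dilute_variant(0.4, 0.8, 0.4, model)$alt_count)
  expect_equal(dilute_variant(0.4, 0.8, 0.4, model)$expected_vaf, 0.2)
  expect_lt(abs(mean(alts) - 20) / 20, 0.01)
})

test_that("catalog dilution keeps exactly the detected records", {
  recs <- records_from_channels(rep(c("A[C>T]G", "T[C>A]T"), 10), vaf = 0.4)
  liberal <- sequencing_model(mean_depth = 10000, min_alt_reads = 1,
                              min_vaf = 0)
  set.seed(3)
  out <- dilute_catalog(recs, q = 0.8, p = 0.8, model = liberal)
  expect_equal(out$n_detected, 20L)
  expect_equal(compute_tmb(out$catalog), 20L)
  out0 <- dilute_catalog(recs, q = 0.8, p = 0, model = liberal)
  expect_equal(out0$n_detected, 0L)
  expect_equal(compute_tmb(out0$catalog), 0L)
  # a record without VAF is an error naming it
  recs$vaf[3] <- NA
  expect_error(dilute_catalog(recs, 0.8, 0.4), "3")
})

test_that("detection is channel-blind: f_deam survives dilution", {
  set.seed(4)
  prof <- make_class_profile(0.25)
  chans <- rep(channel96_labels(), as.integer(stats::rmultinom(1, 1000, prof)))
  recs <- records_from_channels(chans, vaf = 0.4)
  f_src <- compute_fdeam(build_catalog(recs, "S1"))
  f_dil <- replicate(200, {
    compute_fdeam(dilute_catalog(recs, q = 0.8, p = 0.1)$catalog)
  })
  # mean diluted f_deam within the 95% binomial CI of the source value
  p_src <- f_src / 100
  ci_half <- 1.96 * sqrt(p_src * (1 - p_src) / length(chans)) * 100
  expect_lt(abs(mean(f_dil) - f_src), ci_half)
})

test_that("the allele-fraction mixture formula matches hand evaluation", {
  expect_equal(observed_major_fraction(2, 0, p = 0.5), 0.75)
  expect_equal(observed_major_fraction(1, 1, p = 0.3), 0.5)
  expect_equal(observed_major_fraction(1, 1, p = 0.9), 0.5)
  expect_equal(observed_major_fraction(2, 1, p = 1), 2 / 3)
})

test_that("attenuation recovers states at full purity and collapses at low purity", {
  segs <- rbind(seg("chr1", 1, 30e6, 2, 0),
                seg("chr1", 30e6 + 1, 60e6, 2, 1),
                seg("chr1", 60e6 + 1, 100e6, 1, 1))
  set.seed(5)
  out <- attenuate_segments(segs, p = 1, noise_sd_at_unit_depth = 0)
  expect_equal(out$cn_major, segs$cn_major)
  expect_equal(out$cn_minor, segs$cn_minor)
  # at 10% purity every state is within the diploid calling band
  out_low <- attenuate_segments(segs, p = 0.1, noise_sd_at_unit_depth = 0)
  expect_true(all(out_low$cn_major == 1 & out_low$cn_minor == 1))
  expect_error(attenuate_segments(segs, p = 0), "positive")
})

test_that("the purity experiment is reproducible from its seed", {
  cfg <- generator_config(n_pos = 4, n_neg = 4, seed = 21)
  coh <- generate_cohort(cfg)
  a <- run_purity_experiment(coh, purities = c(0.4, 0.1), seed = 99)
  b <- run_purity_experiment(coh, purities = c(0.4, 0.1), seed = 99)
  expect_identical(a, b)
  # identity at the source purity with a liberal model: no dilution loss
  lib <- sequencing_model(mean_depth = 5000, min_alt_reads = 1, min_vaf = 0)
  res <- run_purity_experiment(coh, purities = 0.8, seed = 1, model = lib,
                               noise_sd_at_unit_depth = 0)
  sc <- score_cohort(coh)
  auc_f <- suppressMessages(roc_auc(sc$fdeam, sc$label,
                                    "lower_predicts_positive"))$auc
  expect_equal(res$auc[res$biomarker == "fdeam"], auc_f)
})

test_that("a single-class cohort cannot enter the purity experiment", {
  cfg <- generator_config(n_pos = 3, n_neg = 0, seed = 2)
  coh <- generate_cohort(cfg)
  expect_error(run_purity_experiment(coh, purities = 0.4, seed = 1),
               "both benchmark classes")
})
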