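test_that("AUC equals pairwise concordance with ties counted one half", {
  lab <- c("negative", "negative", "positive", "positive")
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), lab, "higher_predicts_positive")
  expect_equal(r$auc, 0.75)  # 3 of 4 pairs concordant
  # perfect separation and full ties
  expect_equal(roc_auc(c(1, 2, 3, 4), lab)$auc, 1)
  expect_equal(roc_auc(c(2, 2, 2, 2), lab)$auc, 0.5)
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")
})

test_that("roc_auc matches the brute-force concordance oracle on random instances", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    labels <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    dir <- sample(c("lower_predicts_positive", "higher_predicts_positive"), 1)
    expect_equal(roc_auc(scores, labels, dir)$auc,
                 auc_by_concordance(scores, labels, dir))
  }
})

test_that("flipping the direction reflects the AUC around one half", {
  set.seed(12)
  labels <- sample(c("positive", "negative"), 30, replace = TRUE)
  labels[1:2] <- c("positive", "negative")
  scores <- rnorm(30)
  a <- roc_auc(scores, labels, "higher_predicts_positive")$auc
  b <- roc_auc(scores, labels, "lower_predicts_positive")$auc
  expect_equal(a + b, 1)
})

test_that("NA scores are excluded pairwise with a message", {
  lab <- c("positive", "positive", "negative", "negative", "positive")
  expect_message(r <- roc_auc(c(1, NA, 2, 3, 4), lab), "1 sample")
  expect_equal(r$n_excluded, 1L)
})

test_that("the DeLong test is two-sided and degenerates correctly", {
  set.seed(13)
  lab <- rep(c("positive", "negative"), each = 25)
  s <- c(rnorm(25, 1), rnorm(25))
  same <- delong_paired(s, s, lab)
  expect_equal(same$p_value, 1)
  expect_equal(same$auc_a, same$auc_b)
  # perfectly separating vs random, n = 50 per class: overwhelming evidence
  lab2 <- rep(c("positive", "negative"), each = 50)
  sep <- c(rnorm(50, 10), rnorm(50))
  rnd <- rnorm(100)
  expect_lt(delong_paired(sep, rnd, lab2)$p_value, 0.001)
  expect_error(delong_paired(1:3, 1:4, rep("positive", 3)), "same samples")
})

test_that("DeLong p agrees with the paired bootstrap on moderate cohorts", {
  set.seed(14)
  lab <- rep(c("positive", "negative"), each = 30)
  a <- c(rnorm(30, 0.8), rnorm(30))
  b <- c(rnorm(30, 0.5), rnorm(30))
  dl <- delong_paired(a, b, lab)
  bs <- bootstrap_auc_test(a, b, lab, B = 2000, seed = 15)
  expect_lt(abs(dl$p_value - bs$p_value), 0.05)
})

test_that("cutpoint optimization performs exhaustive balanced-accuracy search", {
  # separable negative-predictor case: midpoint threshold, perfect accuracy
  lab <- c("positive", "positive", "negative", "negative")
  opt <- optimize_cutpoint(c(5, 8, 20, 30), lab, "lower_predicts_positive")
  expect_equal(opt$threshold, 14)
  expect_equal(opt$balanced_accuracy, 1)
  # degenerate: all scores tied
  opt2 <- optimize_cutpoint(rep(3, 4), lab, "lower_predicts_positive")
  expect_equal(opt2$balanced_accuracy, 0.5)
  expect_true(opt2$degenerate)
  # random instances: equal to an independent exhaustive grid search, and
  # never below the balanced accuracy at any tested threshold
  set.seed(16)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    labels <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("positive", "negative")
    scores <- round(runif(n, 0, 10), 1)
    dir <- sample(c("lower_predicts_positive", "higher_predicts_positive"), 1)
    opt <- optimize_cutpoint(scores, labels, dir)
    grid <- sort(unique(c(scores - 0.05, scores + 0.05)))
    oracle <- max(vapply(grid, function(thr) {
      evaluate_at_cutpoint(scores, labels, thr, dir)$balanced_accuracy
    }, numeric(1)))
    expect_equal(opt$balanced_accuracy, oracle)
    for (thr in sample(grid, 5)) {
      expect_gte(opt$balanced_accuracy,
                 evaluate_at_cutpoint(scores, labels, thr, dir)$balanced_accuracy)
    }
  }
})

test_that("fixed-cutpoint evaluation reproduces a hand confusion matrix", {
  lab <- c("positive", "positive", "negative", "negative")
  at14 <- evaluate_at_cutpoint(c(5, 8, 20, 30), lab, 14,
                               "lower_predicts_positive")
  expect_equal(at14$sensitivity, 1)
  expect_equal(at14$specificity, 1)
  # threshold below all scores of a negative predictor: nothing called
  at0 <- evaluate_at_cutpoint(c(5, 8, 20, 30), lab, 1,
                              "lower_predicts_positive")
  expect_equal(at0$sensitivity, 0)
  expect_equal(at0$specificity, 1)
  # hand-tabulated 10-sample instance, positive predictor, threshold 5:
  # predicted positive iff score >= 5
  scores <- c(7, 5, 3, 9, 1, 4, 6, 2, 8, 5)
  labs10 <- c("positive", "positive", "positive", "positive", "positive",
              "negative", "negative", "negative", "negative", "negative")
  # TP = 3 (7, 5, 9), FN = 2 (3, 1); TN = 3 (4, 2), FP = 2 (6, 8, 5 -> 3!)
  ev <- evaluate_at_cutpoint(scores, labs10, 5, "higher_predicts_positive")
  expect_equal(ev$sensitivity, 3 / 5)
  expect_equal(ev$specificity, 2 / 5)
  expect_equal(ev$balanced_accuracy, 0.5)
})

test_that("Spearman correlation handles ties and recovers a planted rank correlation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$R, 1)
  expect_equal(spearman_cor(x, rev(x))$R, -1)
  expect_error(spearman_cor(1:2, 1:2), "3 complete pairs")
  set.seed(17)
  rho <- 2 * sin(-0.6 * pi / 6)  # Gaussian copula for Spearman -0.6
  z1 <- rnorm(300)
  y <- rho * z1 + sqrt(1 - rho^2) * rnorm(300)
  expect_lt(abs(spearman_cor(z1, y)$R - (-0.6)), 0.1)
})

test_that("differential channel analysis flags planted CpG depletion", {
  set.seed(18)
  pos <- replicate(50, catalog_from_profile(make_class_profile(0.08), 60),
                   simplify = FALSE)
  neg <- replicate(50, catalog_from_profile(make_class_profile(0.25), 60),
                   simplify = FALSE)
  res <- differential_channels(pos, neg)
  expect_equal(nrow(res), 96)
  cpg <- res[res$channel %in% fdeam_channels(), ]
  expect_true(all(cpg$significant))
  expect_true(all(cpg$delta < 0))
  # BH adjustment is monotone in the raw-p ranks
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  # the significant set is a prefix of the raw-p rank order
  sig_ranks <- which(res$significant[ord])
  if (length(sig_ranks) > 0) {
    expect_equal(sig_ranks, seq_along(sig_ranks))
  }
  expect_error(differential_channels(pos[1], neg), "at least 2")
})

test_that("Cohen's kappa follows the marginal-product definition", {
  expect_equal(cohens_kappa(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)), 1)
  # 2x2 table a=40 b=10 c=10 d=40: p_o = 0.8, p_e = 0.5, kappa = 0.6
  a <- c(rep(TRUE, 50), rep(FALSE, 50))
  b <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  expect_equal(cohens_kappa(a, b), 0.6)
  # a constant rater gives kappa 0
  expect_equal(cohens_kappa(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)), 0)
  expect_error(cohens_kappa(c(TRUE, FALSE), TRUE), "length")
})

test_that("signature CG>TG content is the mass on the four f_deam channels", {
  expect_equal(signature_cgtg_fraction(rep(1 / 96, 96)), 100 * 4 / 96)
  one <- rep(0, 96)
  names(one) <- channel96_labels()
  one["A[C>T]G"] <- 1
  expect_equal(signature_cgtg_fraction(one), 100)
  expect_error(signature_cgtg_fraction(rep(1 / 95, 95)), "length 96")
  expect_warning(signature_cgtg_fraction(rep(1, 96)), "renormaliz")
})

test_that("signature matrices in the COSMIC layout are read and reordered by label", {
  labs <- channel96_labels()
  set.seed(19)
  sig <- runif(96)
  sig <- sig / sum(sig)
  df <- data.frame(Type = rev(labs), SBSX = rev(sig))  # scrambled row order
  tmp <- withr::local_tempfile(fileext = ".txt")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_signature_matrix(tmp)
  expect_equal(rownames(m), labs)
  expect_equal(unname(m[, "SBSX"]), sig)
  expect_equal(signature_cgtg_fraction(m[, "SBSX"]),
               100 * sum(sig[match(fdeam_channels(), labs)]))
})
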