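#' Orient scores so that larger means more likely HR-deficient
#'
#' @noRd
.oriented <- function(scores, direction) {
  direction <- match.arg(direction,
                         c("lower_predicts_positive", "higher_predicts_positive"))
  if (direction == "lower_predicts_positive") -scores else scores
}

.drop_na_pairs <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(sprintf("excluding %d sample(s) with NA score or label", n_excluded))
  }
  list(scores = scores[keep], labels = labels[keep], n_excluded = n_excluded)
}

.check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both classes (positive and negative) must be present", call. = FALSE)
  }
}

#' ROC curve and AUC for a biomarker
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2)
#' after orienting the score by `direction`. f_deam is a NEGATIVE predictor
#' of HRD (low values predict deficiency), so it uses
#' `direction = "lower_predicts_positive"`; HRDsum uses
#' `"higher_predicts_positive"`. Computation is delegated to
#' \pkg{pROC}.
#'
#' @param scores Numeric biomarker values; `NA` values (e.g. f_deam at very
#'   low TMB) are excluded pairwise with their labels.
#' @param labels `"positive"`/`"negative"` labels (character or factor).
#' @param direction `"lower_predicts_positive"` or
#'   `"higher_predicts_positive"`.
#' @return List of class `roc_result`: `auc`, `roc` (the pROC object on the
#'   oriented scores), `direction`, `n_excluded`.
#' @export
roc_auc <- function(scores, labels, direction = "higher_predicts_positive") {
  d <- .drop_na_pairs(scores, as.character(labels))
  .check_two_classes(d$labels)
  oriented <- .oriented(d$scores, direction)
  r <- pROC::roc(response = d$labels, predictor = oriented,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  structure(list(auc = as.numeric(pROC::auc(r)), roc = r,
                 direction = direction, n_excluded = d$n_excluded),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (%s, %d NA excluded)\n",
              x$auc, x$direction, x$n_excluded))
  invisible(x)
}

#' Paired DeLong test comparing two biomarkers
#'
#' Compares the AUCs of two biomarkers measured on the same samples using
#' DeLong's structural-components covariance estimator (two-sided), as
#' implemented in \pkg{pROC}. Samples with an NA in either score are
#' excluded pairwise.
#'
#' @param scores_a,scores_b Score vectors on identical samples.
#' @param labels Class labels.
#' @param direction_a,direction_b Orientation of each biomarker.
#' @return List with `auc_a`, `auc_b`, `p_value`, `n_excluded`.
#' @export
delong_paired <- function(scores_a, scores_b, labels,
                          direction_a = "higher_predicts_positive",
                          direction_b = "higher_predicts_positive") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must cover the same samples",
         call. = FALSE)
  }
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  labels <- as.character(labels)[keep]
  .check_two_classes(labels)
  a <- .oriented(scores_a[keep], direction_a)
  b <- .oriented(scores_b[keep], direction_b)
  ra <- pROC::roc(labels, a, levels = c("negative", "positive"),
                  direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, b, levels = c("negative", "positive"),
                  direction = "<", quiet = TRUE)
  if (isTRUE(all.equal(a, b))) {
    # identical curves: AUC difference is exactly 0, DeLong variance is 0
    return(list(auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)),
                p_value = 1, n_excluded = sum(!keep)))
  }
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       p_value = tst$p.value, n_excluded = sum(!keep))
}

.confusion_at <- function(scores, labels, threshold, direction) {
  direction <- match.arg(direction,
                         c("lower_predicts_positive", "higher_predicts_positive"))
  pred_pos <- if (direction == "lower_predicts_positive") {
    scores < threshold
  } else {
    scores >= threshold
  }
  is_pos <- labels == "positive"
  sens <- sum(pred_pos & is_pos) / sum(is_pos)
  spec <- sum(!pred_pos & !is_pos) / sum(!is_pos)
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

#' Evaluate a biomarker at a fixed cutpoint
#'
#' For a negative predictor (`lower_predicts_positive`) a sample is called
#' HR-deficient when its score is strictly below the threshold (f_deam
#' convention, default cutpoint 13.1); for a positive predictor the call is
#' score >= threshold (HRDsum convention, default cutpoint 42).
#'
#' @inheritParams roc_auc
#' @param threshold Finite cutpoint on the original score scale.
#' @return data.frame with `threshold`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `n_excluded`.
#' @export
evaluate_at_cutpoint <- function(scores, labels, threshold,
                                 direction = "higher_predicts_positive") {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  d <- .drop_na_pairs(scores, as.character(labels))
  .check_two_classes(d$labels)
  m <- .confusion_at(d$scores, d$labels, threshold, direction)
  data.frame(threshold = threshold, sensitivity = m[["sensitivity"]],
             specificity = m[["specificity"]],
             balanced_accuracy = m[["balanced_accuracy"]],
             n_excluded = d$n_excluded)
}

#' Find the cutpoint maximizing balanced accuracy
#'
#' Exhaustively evaluates the balanced accuracy (mean of sensitivity and
#' specificity) at every candidate threshold — the midpoints between
#' adjacent distinct sorted scores, plus one threshold below and one above
#' all scores — and returns the maximizer. Ties in balanced accuracy are
#' broken toward the threshold yielding the higher sensitivity.
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `degenerate` (TRUE when all scores are tied and
#'   no informative threshold exists), `n_excluded`.
#' @export
optimize_cutpoint <- function(scores, labels,
                              direction = "higher_predicts_positive") {
  d <- .drop_na_pairs(scores, as.character(labels))
  .check_two_classes(d$labels)
  u <- sort(unique(d$scores))
  degenerate <- length(u) < 2
  cand <- if (degenerate) {
    u[1]
  } else {
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  }
  best <- NULL
  for (thr in cand) {
    m <- .confusion_at(d$scores, d$labels, thr, direction)
    if (is.null(best) ||
        m[["balanced_accuracy"]] > best$balanced_accuracy + 1e-12 ||
        (abs(m[["balanced_accuracy"]] - best$balanced_accuracy) <= 1e-12 &&
         m[["sensitivity"]] > best$sensitivity)) {
      best <- data.frame(threshold = thr, sensitivity = m[["sensitivity"]],
                         specificity = m[["specificity"]],
                         balanced_accuracy = m[["balanced_accuracy"]])
    }
  }
  best$degenerate <- degenerate
  best$n_excluded <- d$n_excluded
  best
}

#' Spearman rank correlation between two biomarkers
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation via [stats::cor.test()]). Incomplete pairs
#' are dropped.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `R`, `p_value`, `n` (complete pairs used).
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep], method = "spearman",
                                         exact = FALSE))
  list(R = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Differential analysis of the 96 channels between two groups
#'
#' Per-sample channel counts are normalized by the sample's TMB; each
#' channel's normalized frequencies are compared between the groups with a
#' two-sided Wilcoxon rank-sum test (exact when the combined sample size is
#' at most 50 and there are no ties, normal approximation with continuity
#' correction otherwise). The difference of group means (delta =
#' mean(positive) - mean(negative)) is reported alongside
#' Benjamini-Hochberg adjusted p-values; significance is called at FDR 5%.
#'
#' @param catalogs_pos,catalogs_neg Lists of `mut_catalog` (at least 2 per
#'   group).
#' @param fdr Significance level on the adjusted p-values (default 0.05).
#' @return data.frame with one row per channel: `channel`, `delta`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
differential_channels <- function(catalogs_pos, catalogs_neg, fdr = 0.05) {
  if (length(catalogs_pos) < 2 || length(catalogs_neg) < 2) {
    stop("each group needs at least 2 catalogs", call. = FALSE)
  }
  freq <- function(cat) {
    tmb <- compute_tmb(cat)
    if (tmb == 0) rep(0, 96) else as.numeric(cat$counts) / tmb
  }
  fp <- do.call(rbind, lapply(catalogs_pos, freq))
  fn <- do.call(rbind, lapply(catalogs_neg, freq))
  n_comb <- nrow(fp) + nrow(fn)
  labs <- channel96_labels()
  p_raw <- numeric(96)
  delta <- numeric(96)
  for (j in seq_len(96)) {
    delta[j] <- mean(fp[, j]) - mean(fn[, j])
    p_raw[j] <- suppressWarnings(
      stats::wilcox.test(fp[, j], fn[, j], exact = n_comb <= 50,
                         correct = TRUE)$p.value)
  }
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  data.frame(channel = labs, delta = delta, p_raw = p_raw, p_adj = p_adj,
             significant = p_adj < fdr, stringsAsFactors = FALSE)
}

#' Cohen's kappa for two binary call vectors
#'
#' kappa = (p_o - p_e) / (1 - p_e), with the expected agreement p_e from
#' the marginal products. Returns 0 when either rater is constant (p_o
#' equals p_e algebraically and the statistic is defined as 0).
#'
#' @param calls_a,calls_b Paired logical (or two-level) call vectors.
#' @return Numeric kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) {
    stop("call vectors differ in length", call. = FALSE)
  }
  keep <- !is.na(calls_a) & !is.na(calls_b)
  a <- calls_a[keep]
  b <- calls_b[keep]
  n <- length(a)
  if (n == 0) stop("no complete pairs", call. = FALSE)
  p_o <- mean(a == b)
  lev <- unique(c(a, b))
  p_e <- sum(vapply(lev, function(l) mean(a == l) * mean(b == l), numeric(1)))
  if (abs(1 - p_e) < 1e-12) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Brute-force AUC by pairwise concordance
#'
#' Independent reference implementation of the Mann-Whitney AUC: iterates
#' over all positive-negative pairs, counting 1 for a concordant pair, 1/2
#' for a tie. Quadratic in the sample size; intended for validating the
#' ROC machinery on small instances, not for production use.
#'
#' @inheritParams roc_auc
#' @return Numeric AUC.
#' @export
auc_by_concordance <- function(scores, labels,
                               direction = "higher_predicts_positive") {
  d <- .drop_na_pairs(scores, as.character(labels))
  .check_two_classes(d$labels)
  s <- .oriented(d$scores, direction)
  pos <- s[d$labels == "positive"]
  neg <- s[d$labels == "negative"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

#' Paired bootstrap test for an AUC difference
#'
#' Stratified nonparametric bootstrap over samples: in each resample the
#' positive and negative strata are resampled with replacement and the AUC
#' difference recomputed; the two-sided p-value comes from the normal
#' approximation z = D / sd(D*). Serves as an independent check on the
#' DeLong test.
#'
#' @inheritParams delong_paired
#' @param B Number of bootstrap resamples (default 2000).
#' @param seed RNG seed for reproducibility.
#' @return List with `auc_a`, `auc_b`, `p_value`.
#' @export
bootstrap_auc_test <- function(scores_a, scores_b, labels, B = 2000,
                               direction_a = "higher_predicts_positive",
                               direction_b = "higher_predicts_positive",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  labels <- as.character(labels)[keep]
  .check_two_classes(labels)
  a <- .oriented(scores_a[keep], direction_a)
  b <- .oriented(scores_b[keep], direction_b)
  # rank-based AUC, fast enough for thousands of resamples
  fast_auc <- function(s, is_pos) {
    r <- rank(s)
    n1 <- sum(is_pos)
    n0 <- sum(!is_pos)
    (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  is_pos <- labels == "positive"
  d0 <- fast_auc(a, is_pos) - fast_auc(b, is_pos)
  ip <- which(is_pos)
  ineg <- which(!is_pos)
  dstar <- numeric(B)
  for (k in seq_len(B)) {
    idx <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
    pos_k <- c(rep(TRUE, length(ip)), rep(FALSE, length(ineg)))
    dstar[k] <- fast_auc(a[idx], pos_k) - fast_auc(b[idx], pos_k)
  }
  sd_d <- stats::sd(dstar)
  p <- if (sd_d < 1e-12) {
    if (abs(d0) < 1e-12) 1 else 0
  } else {
    2 * stats::pnorm(-abs(d0) / sd_d)
  }
  list(auc_a = fast_auc(a, is_pos), auc_b = fast_auc(b, is_pos), p_value = p)
}
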