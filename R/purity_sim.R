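#' Sequencing model for the purity dilution experiment
#'
#' Parameters of the variant-level read model used when diluting a tumor
#' to a lower purity: sequencing depth per site is Poisson (or negative
#' binomial when `depth_dispersion` is finite) around `mean_depth`; the
#' alt-read count is binomial in the expected VAF; a variant is detected
#' when it has at least `min_alt_reads` alt reads and an observed VAF of at
#' least `min_vaf`. The defaults (3 alt reads, VAF 0.02, depth 100) make
#' detection collapse near 5\% tumor purity but not at 10\%, mirroring how
#' limited coverage bounds mutation calling at very low purity.
#'
#' @param mean_depth Mean sequencing depth (default 100).
#' @param depth_dispersion Negative-binomial size parameter; `Inf` (the
#'   default) gives Poisson depths.
#' @param min_alt_reads Minimum alt reads for detection (default 3).
#' @param min_vaf Minimum observed VAF for detection (default 0.02).
#' @return List of class `seq_model`.
#' @export
sequencing_model <- function(mean_depth = 100, depth_dispersion = Inf,
                             min_alt_reads = 3, min_vaf = 0.02) {
  stopifnot(mean_depth > 0, min_alt_reads >= 0, min_vaf >= 0, min_vaf < 1)
  structure(list(mean_depth = mean_depth, depth_dispersion = depth_dispersion,
                 min_alt_reads = min_alt_reads, min_vaf = min_vaf),
            class = "seq_model")
}

.draw_depth <- function(n, model) {
  if (is.finite(model$depth_dispersion)) {
    stats::rnbinom(n, size = model$depth_dispersion, mu = model$mean_depth)
  } else {
    stats::rpois(n, model$mean_depth)
  }
}

#' Read-mixing fractions for a purity dilution
#'
#' Diluting a tumor of source purity `q` to target purity `p` corresponds
#' to combining a proportion p/q of tumor reads with a proportion 1 - p/q
#' of matched-normal reads.
#'
#' @param q Source tumor purity in (0, 1].
#' @param p Target tumor purity in \[0, q\]. A sample cannot be
#'   concentrated by admixing normal reads, so `p > q` is an error.
#' @return Named numeric vector `c(tumor, normal)` summing to 1.
#' @export
#' @examples
#' dilution_fraction(q = 0.8, p = 0.2)  # tumor 0.25, normal 0.75
dilution_fraction <- function(q, p) {
  if (q <= 0 || q > 1) stop("source purity q must be in (0, 1]", call. = FALSE)
  if (p < 0) stop("target purity p must be non-negative", call. = FALSE)
  if (p > q) stop("cannot concentrate a sample: target purity p exceeds source purity q",
                  call. = FALSE)
  c(tumor = p / q, normal = 1 - p / q)
}

#' Simulate the observation of one diluted variant
#'
#' The expected VAF after dilution is the source VAF scaled by p/q (normal
#' reads carry no somatic alt allele); the observed depth and alt count
#' are then drawn from the sequencing model and the detection rule applied.
#'
#' @param true_vaf_at_q VAF at the source purity, in \[0, 1\].
#' @param q,p Source and target purity (see [dilution_fraction()]).
#' @param model A [sequencing_model()].
#' @return List: `expected_vaf`, `depth`, `alt_count`, `detected`.
#' @export
dilute_variant <- function(true_vaf_at_q, q, p, model = sequencing_model()) {
  stopifnot(true_vaf_at_q >= 0, true_vaf_at_q <= 1)
  fr <- dilution_fraction(q, p)
  expected_vaf <- true_vaf_at_q * fr[["tumor"]]
  depth <- .draw_depth(1L, model)
  alt <- stats::rbinom(1L, depth, expected_vaf)
  detected <- alt >= model$min_alt_reads &&
    (depth > 0 && alt / depth >= model$min_vaf)
  list(expected_vaf = expected_vaf, depth = depth, alt_count = alt,
       detected = detected)
}

#' Dilute a sample's mutation set and rebuild its catalog
#'
#' Applies [dilute_variant()] to every record (vectorized) and keeps
#' exactly those whose diluted observation passes the detection rule.
#' Detection depends only on the VAF and depth — never on the channel — so
#' the expected channel spectrum, and hence the expected f_deam, is
#' invariant under dilution; only the effective TMB shrinks.
#'
#' @param records Mutation data.frame (layout of [read_maf()]) with a
#'   `vaf` column at source purity; a missing VAF is an error naming the
#'   record.
#' @param q,p Source and target purity.
#' @param model A [sequencing_model()].
#' @param sample_id Sample id for the rebuilt catalog; defaults to the
#'   records' sample.
#' @return List: `records` (the detected subset), `catalog`
#'   (`mut_catalog` of the detected records), `n_input`, `n_detected`.
#' @export
dilute_catalog <- function(records, q, p, model = sequencing_model(),
                           sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- unique(records$sample)[1]
  n <- nrow(records)
  if (n > 0 && anyNA(records$vaf)) {
    stop(sprintf("record(s) without VAF: %s",
                 paste(utils::head(which(is.na(records$vaf)), 5), collapse = ", ")),
         call. = FALSE)
  }
  if (n == 0) {
    return(list(records = records, catalog = build_catalog(records, sample_id),
                n_input = 0L, n_detected = 0L))
  }
  fr <- dilution_fraction(q, p)
  evaf <- records$vaf * fr[["tumor"]]
  depth <- .draw_depth(n, model)
  alt <- stats::rbinom(n, depth, evaf)
  detected <- alt >= model$min_alt_reads & depth > 0 &
    alt / pmax(depth, 1L) >= model$min_vaf
  kept <- records[detected, , drop = FALSE]
  kept$vaf <- (alt / pmax(depth, 1L))[detected]
  kept$depth <- depth[detected]
  list(records = kept, catalog = build_catalog(kept, sample_id),
       n_input = n, n_detected = sum(detected))
}

#' Observed major-allele fraction of a segment in an impure sample
#'
#' For allele copies (a, b) at tumor purity p, the bulk sample mixes p
#' tumor genomes with (1 - p) diploid normal genomes contributing one copy
#' of each allele, so the major-allele fraction observed in reads is
#' (p a + (1 - p)) / (p (a + b) + 2 (1 - p)). Balanced segments give
#' exactly 1/2 at any purity.
#'
#' @param a,b Major and minor allele copy numbers.
#' @param p Tumor purity in (0, 1\].
#' @return Numeric fraction in \[0, 1\].
#' @export
#' @examples
#' observed_major_fraction(2, 0, p = 0.5)  # 0.75
observed_major_fraction <- function(a, b, p) {
  stopifnot(all(p > 0), all(p <= 1))
  (p * a + (1 - p)) / (p * (a + b) + 2 * (1 - p))
}

#' Attenuate allele-specific copy-number segments at reduced purity
#'
#' Models why copy-number-based scar scores lose sensitivity at low tumor
#' purity. For a segment with allele copies (a, b) in a tumor of purity p,
#' the observed major-allele fraction in the mixed sample is
#' \deqn{m = (p a + (1 - p)) / (p (a + b) + 2 (1 - p))}
#' (the normal contributes one copy of each allele), plus Gaussian noise
#' with standard deviation `noise_sd_at_unit_depth / sqrt(mean_depth)`.
#' A segment is re-called to its integer allele state only when the
#' observed fraction deviates from 1/2 by more than `calling_threshold`;
#' otherwise it is indistinguishable from a balanced diploid state and
#' collapses to (1, 1). Adjacent identical states are merged afterwards.
#'
#' @param segments Segment data.frame (`chrom`, `start`, `end`,
#'   `cn_major`, `cn_minor`).
#' @param p Tumor purity in (0, 1].
#' @param noise_sd_at_unit_depth Noise scale; at depth d the sd is this
#'   value / sqrt(d). Default 0.5 (sd 0.05 at depth 100).
#' @param model A [sequencing_model()] supplying the mean depth.
#' @param calling_threshold Minimum |m - 0.5| to call a non-diploid state
#'   (default 0.08).
#' @return The observed segment data.frame, suitable for
#'   [compute_hrdsum()].
#' @export
attenuate_segments <- function(segments, p, noise_sd_at_unit_depth = 0.5,
                               model = sequencing_model(),
                               calling_threshold = 0.08) {
  if (p <= 0) stop("purity p must be positive (no tumor signal at p = 0)",
                   call. = FALSE)
  if (p > 1) stop("purity p must be at most 1", call. = FALSE)
  if (nrow(segments) == 0) return(segments)
  m <- observed_major_fraction(segments$cn_major, segments$cn_minor, p)
  sd_noise <- noise_sd_at_unit_depth / sqrt(model$mean_depth)
  m_obs <- m + stats::rnorm(length(m), 0, sd_noise)
  called <- abs(m_obs - 0.5) > calling_threshold
  out <- segments
  out$cn_major[!called] <- 1L
  out$cn_minor[!called] <- 1L
  # merge runs of identical adjacent states per chromosome
  merged <- NULL
  for (ch in unique(out$chrom)) {
    s <- out[out$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    keep <- s[1, , drop = FALSE]
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        j <- nrow(keep)
        if (s$cn_major[i] == keep$cn_major[j] &&
            s$cn_minor[i] == keep$cn_minor[j] &&
            s$start[i] == keep$end[j] + 1) {
          keep$end[j] <- s$end[i]
        } else {
          keep <- rbind(keep, s[i, , drop = FALSE])
        }
      }
    }
    merged <- rbind(merged, keep)
  }
  merged
}

#' Run the tumor-purity dilution experiment on a cohort
#'
#' For each target purity and replicate, every sample's mutation set is
#' diluted ([dilute_catalog()]) and its segments attenuated
#' ([attenuate_segments()]); f_deam and HRDsum are recomputed and both
#' biomarkers evaluated against the benchmark labels, by AUC and by
#' balanced accuracy at the fixed clinical cutpoints. Fully reproducible
#' from the seed.
#'
#' @param cohort A `synthetic_cohort` (see [generate_cohort()]) or any list
#'   with `samples` (each having `sample_id`, `label`, `variants`,
#'   `segments`, `purity`) and `annotation`.
#' @param purities Target purity levels, e.g. `c(0.6, 0.4, 0.2, 0.1, 0.05)`.
#' @param fdeam_cutpoint f_deam cutpoint (default 13.1; call positive below
#'   it).
#' @param hrdsum_cutpoint HRDsum cutpoint (default 42; call positive at or
#'   above it).
#' @param reps Replicate dilutions per purity (default 1).
#' @param seed RNG seed.
#' @param model A [sequencing_model()].
#' @param min_tmb Passed to [compute_fdeam()].
#' @param noise_sd_at_unit_depth,calling_threshold Passed to
#'   [attenuate_segments()].
#' @return Tidy data.frame: `purity`, `replicate`, `biomarker`, `auc`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`.
#' @export
run_purity_experiment <- function(cohort, purities = c(0.6, 0.4, 0.2, 0.1, 0.05),
                                  fdeam_cutpoint = 13.1, hrdsum_cutpoint = 42,
                                  reps = 1, seed = 1,
                                  model = sequencing_model(), min_tmb = 10,
                                  noise_sd_at_unit_depth = 0.5,
                                  calling_threshold = 0.08) {
  labels <- vapply(cohort$samples, function(s) s$label, character(1))
  if (length(unique(labels)) < 2) {
    stop("cohort must contain both benchmark classes", call. = FALSE)
  }
  set.seed(seed)
  res <- list()
  for (p in purities) {
    for (r in seq_len(reps)) {
      fdeam <- numeric(length(cohort$samples))
      hrds <- numeric(length(cohort$samples))
      for (i in seq_along(cohort$samples)) {
        smp <- cohort$samples[[i]]
        dil <- dilute_catalog(smp$variants, q = smp$purity, p = p,
                              model = model, sample_id = smp$sample_id)
        fdeam[i] <- compute_fdeam(dil$catalog, min_tmb = min_tmb)
        seg_obs <- attenuate_segments(smp$segments, p = p,
                                      noise_sd_at_unit_depth = noise_sd_at_unit_depth,
                                      model = model,
                                      calling_threshold = calling_threshold)
        hrds[i] <- compute_hrdsum(seg_obs, cohort$annotation)$hrdsum
      }
      res[[length(res) + 1]] <- rbind(
        .purity_row(p, r, "fdeam", fdeam, labels, fdeam_cutpoint,
                    "lower_predicts_positive"),
        .purity_row(p, r, "hrdsum", hrds, labels, hrdsum_cutpoint,
                    "higher_predicts_positive"))
    }
  }
  do.call(rbind, res)
}

.purity_row <- function(p, r, biomarker, scores, labels, cutpoint, direction) {
  keep <- !is.na(scores)
  auc <- NA_real_
  cp <- data.frame(sensitivity = NA_real_, specificity = NA_real_,
                   balanced_accuracy = NA_real_)
  if (length(unique(labels[keep])) == 2) {
    auc <- suppressMessages(roc_auc(scores, labels, direction))$auc
    cp <- suppressMessages(
      evaluate_at_cutpoint(scores, labels, cutpoint, direction))
  }
  data.frame(purity = p, replicate = r, biomarker = biomarker, auc = auc,
             balanced_accuracy = cp$balanced_accuracy,
             sensitivity = cp$sensitivity, specificity = cp$specificity,
             stringsAsFactors = FALSE)
}
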