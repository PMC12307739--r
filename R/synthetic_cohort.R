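#' Synthetic genome annotation (22 autosomes)
#'
#' A fixed annotation of 22 autosomes with chromosome lengths close to the
#' human autosomes and synthetic centromeres (a 5 Mb interval starting at
#' 40\% of the chromosome length). Ships with the package as a plain-text
#' fixture and is used by the cohort generator.
#'
#' @return data.frame with columns `chrom`, `length`, `cen_start`,
#'   `cen_end`.
#' @export
synthetic_genome_annotation <- function() {
  read_genome_annotation(system.file("extdata", "genome_annotation_synthetic.tsv",
                                     package = "deamHRD", mustWork = TRUE))
}

#' Class-dependent channel profile
#'
#' Builds a 96-channel probability vector placing `cpg_mass` on the four
#' CpG C>T channels (equally) and spreading the remainder uniformly over
#' the other 92 channels. The HR-proficient class uses a high CpG mass
#' (clock-like, SBS1-like spectrum); the HR-deficient class a low one
#' (flat, SBS3-like spectrum), reproducing the depletion of CpG C>T
#' mutations in HR-deficient tumors.
#'
#' @param cpg_mass Total probability mass on the f_deam channels, in
#'   \[0, 1\].
#' @return Named numeric vector over [channel96_labels()], summing to 1.
#' @export
make_class_profile <- function(cpg_mass) {
  stopifnot(cpg_mass >= 0, cpg_mass <= 1)
  labs <- channel96_labels()
  prof <- stats::setNames(rep((1 - cpg_mass) / 92, 96), labs)
  prof[fdeam_channels()] <- cpg_mass / 4
  prof
}

#' Generator configuration for synthetic HRD cohorts
#'
#' Defaults emulate the contrast between HR-deficient (positive, H1a*) and
#' HR-proficient (negative, H3) high-purity ovarian tumors: mean f_deam of
#' about 8\% vs 25\%, HRDsum centred near 55 vs 20 (the clinical cutpoint
#' being 42), log-normal TMB giving well over 90\% of samples a TMB of at
#' least 10, clonal VAFs around q/2 for source purity q = 0.8.
#'
#' @param n_pos,n_neg Samples per class (default 20 + 20).
#' @param cpg_mass_pos,cpg_mass_neg CpG C>T mass of the class profiles
#'   (defaults 0.08 and 0.25); overridden by explicit `profile_pos` /
#'   `profile_neg`.
#' @param profile_pos,profile_neg Optional full 96-channel probability
#'   vectors.
#' @param tmb_meanlog,tmb_sdlog Log-normal TMB parameters (defaults
#'   log(60), 0.5).
#' @param hrdsum_pos,hrdsum_neg `(mean, sd)` of the truncated-normal
#'   HRDsum target per class (defaults c(55, 15), c(20, 12)).
#' @param vaf_shape `(alpha, beta)` of the Beta VAF distribution (default
#'   c(8, 12), mean 0.4).
#' @param purity Source tumor purity q of every sample (default 0.8).
#' @param seed RNG seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_pos = 20, n_neg = 20,
                             cpg_mass_pos = 0.08, cpg_mass_neg = 0.25,
                             profile_pos = NULL, profile_neg = NULL,
                             tmb_meanlog = log(60), tmb_sdlog = 0.5,
                             hrdsum_pos = c(55, 15), hrdsum_neg = c(20, 12),
                             vaf_shape = c(8, 12), purity = 0.8, seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, purity > 0, purity <= 1)
  if (is.null(profile_pos)) profile_pos <- make_class_profile(cpg_mass_pos)
  if (is.null(profile_neg)) profile_neg <- make_class_profile(cpg_mass_neg)
  for (prof in list(profile_pos, profile_neg)) {
    if (length(prof) != 96 || any(prof < 0) || abs(sum(prof) - 1) > 1e-8) {
      stop("class profiles must be non-negative length-96 vectors summing to 1",
           call. = FALSE)
    }
  }
  structure(list(n_pos = n_pos, n_neg = n_neg,
                 profile_pos = profile_pos, profile_neg = profile_neg,
                 tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
                 hrdsum_pos = hrdsum_pos, hrdsum_neg = hrdsum_neg,
                 vaf_shape = vaf_shape, purity = purity, seed = seed),
            class = "generator_config")
}

# ---- scar-event planting -------------------------------------------------
#
# Segment layouts engineered so that each planted unit contributes exactly
# one qualifying event and nothing else, under the default scoring
# thresholds (LOH > 15 Mb; LST smoothing 3 Mb, flanks >= 10 Mb; TAI
# telomeric, centromere-respecting).  Flanks/buffers are 4-5 Mb - large
# enough to survive the 3 Mb smoothing, too small to count as an LST flank
# - with states chosen so that no pair of adjacent segments ever merges.
#
#   LOH unit (24 Mb, interior):  (2,1) 4 | (2,0) 16 | (2,1) 4
#   LST unit (28 Mb, interior):  (2,0) 4 | (2,1) 10 | (3,1) 10 | (2,0) 4
#   TAI unit (14 Mb, telomeric): (2,1) 10 at the telomere | (2,0) 4 inward
#
# Units are separated by >= 4 Mb of (1,1) background so smoothing never
# brings two units into contact.

.mb <- 1e6

.loh_unit <- function(chrom, at) {
  data.frame(chrom = chrom,
             start = at + c(0, 4, 20) * .mb,
             end = at + c(4, 20, 24) * .mb - 1,
             cn_major = c(2, 2, 2), cn_minor = c(1, 0, 1))
}

.lst_unit <- function(chrom, at) {
  data.frame(chrom = chrom,
             start = at + c(0, 4, 14, 24) * .mb,
             end = at + c(4, 14, 24, 28) * .mb - 1,
             cn_major = c(2, 2, 3, 2), cn_minor = c(0, 1, 1, 0))
}

.tai_unit <- function(chrom, arm_start, arm_end, side) {
  if (side == "start") {
    data.frame(chrom = chrom,
               start = c(arm_start, arm_start + 10 * .mb),
               end = c(arm_start + 10 * .mb - 1, arm_start + 14 * .mb - 1),
               cn_major = c(2, 2), cn_minor = c(1, 0))
  } else {
    data.frame(chrom = chrom,
               start = c(arm_end - 14 * .mb + 1, arm_end - 10 * .mb + 1),
               end = c(arm_end - 10 * .mb, arm_end),
               cn_major = c(2, 2), cn_minor = c(0, 1))
  }
}

#' Construct a segment profile containing exactly k scar events per type
#'
#' Builds a full allele-specific segment list over the synthetic genome in
#' which exactly `k_loh` LOH, `k_lst` LST and `k_tai` TAI events qualify
#' under the default scoring rules, and nothing else scores. TAI units are
#' placed at chromosome-arm telomeres (at most one per chromosome end);
#' LOH and LST units are packed into arm interiors separated by balanced
#' (1, 1) background. If the genome cannot host all requested events the
#' achievable number is planted; the actually planted counts are returned
#' in the `planted` attribute, which is the generator's ground truth.
#'
#' @param k_loh,k_lst,k_tai Requested event counts.
#' @param annotation Genome annotation (default
#'   [synthetic_genome_annotation()]).
#' @return Segment data.frame with attribute `planted` =
#'   `c(loh, lst, tai)`.
#' @export
plant_scar_genome <- function(k_loh, k_lst, k_tai,
                              annotation = synthetic_genome_annotation()) {
  stopifnot(k_loh >= 0, k_lst >= 0, k_tai >= 0)
  arms <- list()
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    arms[[length(arms) + 1]] <- list(chrom = a$chrom, start = 1,
                                     end = a$cen_start - 1, side = "start")
    arms[[length(arms) + 1]] <- list(chrom = a$chrom, start = a$cen_end + 1,
                                     end = a$length, side = "end")
  }
  segs <- list()
  planted <- c(loh = 0L, lst = 0L, tai = 0L)
  tai_used <- rep(FALSE, length(arms))
  # telomeric TAI units first
  for (j in seq_along(arms)) {
    if (planted[["tai"]] >= k_tai) break
    arm <- arms[[j]]
    if (arm$end - arm$start + 1 < 18 * .mb) next  # unit + clearance
    segs[[length(segs) + 1]] <- .tai_unit(arm$chrom, arm$start, arm$end,
                                          arm$side)
    tai_used[j] <- TRUE
    planted[["tai"]] <- planted[["tai"]] + 1L
  }
  # interior units, alternating LOH / LST, packed arm by arm
  queue <- c(rep("loh", k_loh), rep("lst", k_lst))
  if (length(queue) > 0) {
    queue <- queue[order(c(seq_len(k_loh), seq_len(k_lst)))]  # interleave types
    qi <- 1L
    for (j in seq_along(arms)) {
      if (qi > length(queue)) break
      arm <- arms[[j]]
      lo <- arm$start
      hi <- arm$end
      if (tai_used[j]) {
        if (arm$side == "start") lo <- lo + 14 * .mb else hi <- hi - 14 * .mb
      }
      cursor <- lo + 4 * .mb
      while (qi <= length(queue)) {
        type <- queue[qi]
        width <- if (type == "loh") 24 * .mb else 28 * .mb
        if (cursor + width + 4 * .mb - 1 > hi) break
        segs[[length(segs) + 1]] <- if (type == "loh") {
          .loh_unit(arm$chrom, cursor)
        } else {
          .lst_unit(arm$chrom, cursor)
        }
        planted[[type]] <- planted[[type]] + 1L
        cursor <- cursor + width + 4 * .mb
        qi <- qi + 1L
      }
    }
  }
  units <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               cn_major = numeric(0), cn_minor = numeric(0))
  # fill everything else with (1,1) background, chromosome by chromosome
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    u <- units[units$chrom == a$chrom, , drop = FALSE]
    u <- u[order(u$start), , drop = FALSE]
    cursor <- 1
    for (r in seq_len(nrow(u))) {
      if (u$start[r] > cursor) {
        out[[length(out) + 1]] <- data.frame(chrom = a$chrom, start = cursor,
                                             end = u$start[r] - 1,
                                             cn_major = 1, cn_minor = 1)
      }
      out[[length(out) + 1]] <- u[r, ]
      cursor <- u$end[r] + 1
    }
    if (cursor <= a$length) {
      out[[length(out) + 1]] <- data.frame(chrom = a$chrom, start = cursor,
                                           end = a$length,
                                           cn_major = 1, cn_minor = 1)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "planted") <- planted
  res
}

# ---- sample and cohort generation ---------------------------------------

.rtruncnorm_pos <- function(mean, sd) {
  max(0L, as.integer(round(stats::rnorm(1, mean, sd))))
}

.channel_to_record <- function(label) {
  # canonical label "A[C>T]G" -> pyrimidine-strand record bases
  up <- substr(label, 1, 1)
  ref <- substr(label, 3, 3)
  alt <- substr(label, 5, 5)
  down <- substr(label, 7, 7)
  c(up = up, ref = ref, alt = alt, down = down)
}

#' Generate one synthetic tumor sample
#'
#' TMB is drawn log-normal (rounded, floored at 0); channels are a
#' multinomial draw from the class profile; VAFs are Beta; the segment
#' profile is planted to contain exactly the drawn number of qualifying
#' LOH/LST/TAI events, whose total follows the class HRDsum distribution
#' (truncated normal, split over the three event types by a symmetric
#' multinomial). The planted ground truth is recorded per sample.
#'
#' Uses the current RNG state: seed at the cohort level (see
#' [generate_cohort()]).
#'
#' @param config A [generator_config()].
#' @param label `"positive"` (HR-deficient) or `"negative"`.
#' @param sample_id Sample identifier.
#' @param annotation Genome annotation.
#' @return List: `sample_id`, `label`, `variants` (MAF-like data.frame
#'   with context and VAF), `segments`, `purity`, `truth` (expected
#'   f_deam, planted event counts, drawn TMB).
#' @export
generate_sample <- function(config, label, sample_id,
                            annotation = synthetic_genome_annotation()) {
  profile <- if (label == "positive") config$profile_pos else config$profile_neg
  tmb <- max(0L, as.integer(round(stats::rlnorm(1, config$tmb_meanlog,
                                                config$tmb_sdlog))))
  labs <- channel96_labels()
  counts <- if (tmb > 0) {
    as.integer(stats::rmultinom(1, tmb, profile))
  } else {
    integer(96)
  }
  channels <- rep(labs, counts)
  n <- length(channels)
  variants <- data.frame(sample = character(0), chrom = character(0),
                         pos = integer(0), ref = character(0),
                         alt = character(0), up = character(0),
                         down = character(0), vaf = numeric(0),
                         depth = integer(0), stringsAsFactors = FALSE)
  if (n > 0) {
    bases <- t(vapply(channels, .channel_to_record, character(4)))
    chrom_idx <- sample.int(nrow(annotation), n, replace = TRUE)
    pos <- vapply(chrom_idx, function(i) {
      as.integer(stats::runif(1, 2, annotation$length[i] - 1))
    }, integer(1))
    variants <- data.frame(sample = sample_id,
                           chrom = annotation$chrom[chrom_idx],
                           pos = pos,
                           ref = unname(bases[, "ref"]),
                           alt = unname(bases[, "alt"]),
                           up = unname(bases[, "up"]),
                           down = unname(bases[, "down"]),
                           vaf = stats::rbeta(n, config$vaf_shape[1],
                                              config$vaf_shape[2]),
                           depth = NA_integer_, stringsAsFactors = FALSE)
  }
  hp <- if (label == "positive") config$hrdsum_pos else config$hrdsum_neg
  h_total <- .rtruncnorm_pos(hp[1], hp[2])
  k3 <- as.integer(stats::rmultinom(1, h_total, rep(1 / 3, 3)))
  segments <- plant_scar_genome(k3[1], k3[2], k3[3], annotation)
  planted <- attr(segments, "planted")
  list(sample_id = sample_id, label = label, variants = variants,
       segments = segments, purity = config$purity,
       truth = list(expected_fdeam = 100 * sum(profile[fdeam_channels()]),
                    tmb = tmb, planted = planted,
                    hrdsum = sum(planted)))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_pos` HR-deficient and `n_neg` HR-proficient samples from the
#' generator configuration (see [generate_sample()]) and attaches
#' benchmark-consistent cause-of-HRD inputs: positives carry either a
#' biallelic deleterious BRCA1/2 alteration (70\%) or BRCA1 promoter
#' hypermethylation (30\%); negatives carry neither. Identical
#' `(config, seed)` reproduce the cohort bitwise.
#'
#' @param config A [generator_config()].
#' @param annotation Genome annotation.
#' @return Object of class `synthetic_cohort`: list with `samples`,
#'   `alterations`, `methylation`, `annotation`, `config`, `summary`.
#' @export
generate_cohort <- function(config = generator_config(),
                            annotation = synthetic_genome_annotation()) {
  if (config$n_pos + config$n_neg == 0) {
    stop("empty cohort: n_pos + n_neg must be positive", call. = FALSE)
  }
  set.seed(config$seed)
  ids <- sprintf("S%03d", seq_len(config$n_pos + config$n_neg))
  labels <- c(rep("positive", config$n_pos), rep("negative", config$n_neg))
  samples <- vector("list", length(ids))
  alt_rows <- list()
  meth <- data.frame(sample = ids, brca1_promoter_hm = FALSE,
                     stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    samples[[i]] <- generate_sample(config, labels[i], ids[i], annotation)
    if (labels[i] == "positive") {
      if (stats::runif(1) < 0.7) {
        gene <- sample(c("BRCA1", "BRCA2"), 1)
        alt_rows[[length(alt_rows) + 1]] <-
          data.frame(sample = ids[i], gene = gene, effect = "deleterious",
                     allelic = "biallelic", stringsAsFactors = FALSE)
      } else {
        meth$brca1_promoter_hm[i] <- TRUE
      }
    }
  }
  alterations <- if (length(alt_rows)) do.call(rbind, alt_rows) else
    data.frame(sample = character(0), gene = character(0),
               effect = character(0), allelic = character(0),
               stringsAsFactors = FALSE)
  fdeam <- vapply(samples, function(s) {
    compute_fdeam(build_catalog(s$variants, s$sample_id))
  }, numeric(1))
  hrds <- vapply(samples, function(s) s$truth$hrdsum, numeric(1))
  summary <- data.frame(label = c("positive", "negative"),
                        mean_fdeam = c(mean(fdeam[labels == "positive"], na.rm = TRUE),
                                       mean(fdeam[labels == "negative"], na.rm = TRUE)),
                        mean_hrdsum = c(mean(hrds[labels == "positive"]),
                                        mean(hrds[labels == "negative"])))
  structure(list(samples = samples, alterations = alterations,
                 methylation = meth, annotation = annotation,
                 config = config, summary = summary),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%d positive / %d negative), seed %d\n",
              length(x$samples), x$config$n_pos, x$config$n_neg,
              x$config$seed))
  print(x$summary)
  invisible(x)
}

#' Score a cohort: f_deam, HRDsum and TMB per sample
#'
#' @param cohort A `synthetic_cohort` or compatible list.
#' @param min_tmb Passed to [compute_fdeam()].
#' @return data.frame `sample`, `label`, `fdeam`, `hrdsum`, `tmb`.
#' @export
score_cohort <- function(cohort, min_tmb = 10) {
  rows <- lapply(cohort$samples, function(s) {
    cat96 <- build_catalog(s$variants, s$sample_id)
    sc <- compute_hrdsum(s$segments, cohort$annotation)
    data.frame(sample = s$sample_id, label = s$label,
               fdeam = compute_fdeam(cat96, min_tmb = min_tmb),
               hrdsum = sc$hrdsum, tmb = compute_tmb(cat96),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a cohort as a plain-text fixture directory
#'
#' Emits `mutations.tsv` (MAF-like, with context and VAF columns),
#' `segments.tsv`, `labels.tsv`, `alterations.tsv`, `methylation.tsv`,
#' `genome.tsv` and `manifest.yaml` (config and seed). The files round-trip
#' losslessly through the package's readers ([read_cohort_dir()]).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  muts <- do.call(rbind, lapply(cohort$samples, function(s) s$variants))
  if (is.null(muts) || nrow(muts) == 0) {
    muts <- data.frame(sample = character(0), chrom = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0), up = character(0),
                       down = character(0), vaf = numeric(0),
                       depth = integer(0))
  }
  names(muts)[names(muts) == "up"] <- "context_up"
  names(muts)[names(muts) == "down"] <- "context_down"
  wt(muts, "mutations.tsv")
  segs <- do.call(rbind, lapply(cohort$samples, function(s) {
    cbind(sample = s$sample_id, s$segments)
  }))
  if (is.null(segs)) {
    segs <- data.frame(sample = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       cn_major = numeric(0), cn_minor = numeric(0))
  }
  wt(segs, "segments.tsv")
  wt(data.frame(sample = vapply(cohort$samples, function(s) s$sample_id, character(1)),
                label = vapply(cohort$samples, function(s) s$label, character(1)),
                purity = vapply(cohort$samples, function(s) s$purity, numeric(1))),
     "labels.tsv")
  wt(cohort$alterations, "alterations.tsv")
  wt(cohort$methylation, "methylation.tsv")
  wt(cohort$annotation, "genome.tsv")
  cfg <- cohort$config
  manifest <- list(seed = cfg$seed, n_pos = cfg$n_pos, n_neg = cfg$n_neg,
                   tmb_meanlog = cfg$tmb_meanlog, tmb_sdlog = cfg$tmb_sdlog,
                   hrdsum_pos = as.numeric(cfg$hrdsum_pos),
                   hrdsum_neg = as.numeric(cfg$hrdsum_neg),
                   vaf_shape = as.numeric(cfg$vaf_shape),
                   purity = cfg$purity,
                   cpg_mass_pos = sum(cfg$profile_pos[fdeam_channels()]),
                   cpg_mass_neg = sum(cfg$profile_neg[fdeam_channels()]))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort fixture directory back into memory
#'
#' Inverse of [write_fixture_files()]: reconstructs a cohort list usable
#' by [score_cohort()], [run_purity_experiment()] and [run_pipeline()].
#'
#' @param dir Directory written by [write_fixture_files()].
#' @return List with `samples`, `alterations`, `methylation`,
#'   `annotation`, `manifest`.
#' @export
read_cohort_dir <- function(dir) {
  need <- c("mutations.tsv", "segments.tsv", "labels.tsv", "genome.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("cohort directory lacks required files: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  muts <- read_maf(file.path(dir, "mutations.tsv"))
  segs <- read_segments(file.path(dir, "segments.tsv"))
  labels <- utils::read.delim(file.path(dir, "labels.tsv"),
                              stringsAsFactors = FALSE)
  annotation <- read_genome_annotation(file.path(dir, "genome.tsv"))
  alterations <- if (file.exists(file.path(dir, "alterations.tsv"))) {
    read_alterations(file.path(dir, "alterations.tsv"))
  } else NULL
  methylation <- if (file.exists(file.path(dir, "methylation.tsv"))) {
    read_methylation(file.path(dir, "methylation.tsv"))
  } else NULL
  manifest <- if (file.exists(file.path(dir, "manifest.yaml"))) {
    yaml::read_yaml(file.path(dir, "manifest.yaml"))
  } else NULL
  samples <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$sample[i]
    v <- muts[muts$sample == id, , drop = FALSE]
    s <- segs[segs$sample == id,
              c("chrom", "start", "end", "cn_major", "cn_minor"),
              drop = FALSE]
    rownames(v) <- rownames(s) <- NULL
    list(sample_id = id, label = labels$label[i], variants = v,
         segments = s,
         purity = if ("purity" %in% names(labels)) labels$purity[i] else NA_real_)
  })
  list(samples = samples, alterations = alterations,
       methylation = methylation, annotation = annotation,
       manifest = manifest)
}
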