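#' Genomic scar scores from allele-specific copy-number segments
#'
#' Implements the three classical HRD scar scores on allele-specific
#' copy-number segments and their sum:
#' \describe{
#'   \item{LOH}{count of loss-of-heterozygosity segments (minor copy 0,
#'     major copy > 0) longer than 15 Mb that do not span a whole
#'     chromosome.}
#'   \item{LST}{large-scale state transitions: per chromosome arm, after
#'     removing segments shorter than 3 Mb and merging identical adjacent
#'     states to a fixed point, the number of adjacent segment pairs with
#'     different allele-specific states where both segments are at least
#'     10 Mb.}
#'   \item{TAI}{telomeric allelic imbalance: allele-imbalanced segments
#'     (major != minor) that reach a telomere (segment start 1 or segment
#'     end at the chromosome length), do not cross the centromere, and do
#'     not span the whole chromosome.}
#' }
#' HRDsum = LOH + LST + TAI. "Mb" means 1e6 bp exactly; segment length is
#' `end - start + 1`. Sex chromosomes are excluded by default. A segment is
#' considered to cross the centromere when it spans the entire centromere
#' interval (reaching both arms); segments merely overlapping one edge stay
#' on their arm.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `cn_major`, `cn_minor`; 1-based inclusive coordinates, non-overlapping
#'   and sorted within each chromosome.
#' @param annotation data.frame with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`.
#' @param loh_min_length LOH segment length threshold (default 15 Mb,
#'   exclusive).
#' @param lst_smooth Segments shorter than this are removed before LST
#'   counting (default 3 Mb).
#' @param lst_min_flank Minimum length of both segments flanking a counted
#'   transition (default 10 Mb).
#' @param exclude_sex Drop chromosomes X/Y before scoring (default TRUE).
#' @return For `compute_hrdsum()`, an object of class `scar_scores`: a list
#'   with `loh`, `lst`, `tai`, `hrdsum`. The individual functions return a
#'   single integer.
#' @name scar_scores
NULL

.drop_sex <- function(segments) {
  sex <- c("X", "Y", "chrX", "chrY")
  segments[!segments$chrom %in% sex, , drop = FALSE]
}

.validate_segments <- function(segments) {
  if (nrow(segments) == 0) return(invisible(segments))
  stopifnot(all(c("chrom", "start", "end", "cn_major", "cn_minor") %in%
                  names(segments)))
  if (any(segments$start > segments$end)) {
    stop("segment with start > end", call. = FALSE)
  }
  if (any(segments$cn_major < segments$cn_minor) ||
      any(segments$cn_minor < 0)) {
    stop("segments must satisfy cn_major >= cn_minor >= 0", call. = FALSE)
  }
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop(sprintf("overlapping segments on chromosome %s", ch),
           call. = FALSE)
    }
  }
  invisible(segments)
}

.chrom_info <- function(annotation, ch) {
  i <- match(ch, annotation$chrom)
  if (is.na(i)) stop(sprintf("chromosome %s missing from genome annotation", ch),
                     call. = FALSE)
  annotation[i, ]
}

#' @rdname scar_scores
#' @export
compute_loh <- function(segments, annotation, loh_min_length = 15e6,
                        exclude_sex = TRUE) {
  if (exclude_sex) segments <- .drop_sex(segments)
  .validate_segments(segments)
  if (nrow(segments) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (s$cn_minor != 0 || s$cn_major <= 0) next
    len <- s$end - s$start + 1
    if (len <= loh_min_length) next
    info <- .chrom_info(annotation, s$chrom)
    whole <- s$start <= 1 && s$end >= info$length
    if (!whole) n <- n + 1L
  }
  n
}

# split segments into arm-restricted pieces; pieces are truncated at the
# centromere boundaries so arm-internal adjacency is well defined
.arm_pieces <- function(segments, info) {
  arms <- list(p = c(1, info$cen_start - 1),
               q = c(info$cen_end + 1, info$length))
  lapply(arms, function(a) {
    s <- segments[segments$end >= a[1] & segments$start <= a[2], , drop = FALSE]
    if (nrow(s) == 0) return(s)
    s$start <- pmax(s$start, a[1])
    s$end <- pmin(s$end, a[2])
    s[order(s$start), , drop = FALSE]
  })
}

# remove sub-threshold segments and merge identical adjacent states,
# iterated to a fixed point
.smooth_arm <- function(s, min_len) {
  repeat {
    if (nrow(s) == 0) return(s)
    keep <- (s$end - s$start + 1) >= min_len
    s <- s[keep, , drop = FALSE]
    if (nrow(s) <= 1) return(s)
    merged <- s[1, , drop = FALSE]
    changed <- FALSE
    for (i in 2:nrow(s)) {
      j <- nrow(merged)
      if (s$cn_major[i] == merged$cn_major[j] &&
          s$cn_minor[i] == merged$cn_minor[j]) {
        merged$end[j] <- s$end[i]
        changed <- TRUE
      } else {
        merged <- rbind(merged, s[i, , drop = FALSE])
      }
    }
    s <- merged
    if (!changed && all((s$end - s$start + 1) >= min_len)) return(s)
  }
}

#' @rdname scar_scores
#' @export
compute_lst <- function(segments, annotation, lst_smooth = 3e6,
                        lst_min_flank = 10e6, exclude_sex = TRUE) {
  if (exclude_sex) segments <- .drop_sex(segments)
  .validate_segments(segments)
  if (nrow(segments) == 0) return(0L)
  n <- 0L
  for (ch in unique(segments$chrom)) {
    info <- .chrom_info(annotation, ch)
    for (arm in .arm_pieces(segments[segments$chrom == ch, , drop = FALSE],
                            info)) {
      arm <- .smooth_arm(arm, lst_smooth)
      if (nrow(arm) < 2) next
      len <- arm$end - arm$start + 1
      for (i in 1:(nrow(arm) - 1)) {
        differs <- arm$cn_major[i] != arm$cn_major[i + 1] ||
          arm$cn_minor[i] != arm$cn_minor[i + 1]
        if (differs && len[i] >= lst_min_flank && len[i + 1] >= lst_min_flank) {
          n <- n + 1L
        }
      }
    }
  }
  n
}

#' @rdname scar_scores
#' @export
compute_tai <- function(segments, annotation, exclude_sex = TRUE) {
  if (exclude_sex) segments <- .drop_sex(segments)
  .validate_segments(segments)
  if (nrow(segments) == 0) return(0L)
  n <- 0L
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    if (s$cn_major == s$cn_minor) next
    info <- .chrom_info(annotation, s$chrom)
    telomeric <- s$start <= 1 || s$end >= info$length
    if (!telomeric) next
    whole <- s$start <= 1 && s$end >= info$length
    crosses_cen <- s$start < info$cen_start && s$end > info$cen_end
    if (!whole && !crosses_cen) n <- n + 1L
  }
  n
}

#' @rdname scar_scores
#' @export
compute_hrdsum <- function(segments, annotation, loh_min_length = 15e6,
                           lst_smooth = 3e6, lst_min_flank = 10e6,
                           exclude_sex = TRUE) {
  loh <- compute_loh(segments, annotation, loh_min_length, exclude_sex)
  lst <- compute_lst(segments, annotation, lst_smooth, lst_min_flank,
                     exclude_sex)
  tai <- compute_tai(segments, annotation, exclude_sex)
  structure(list(loh = loh, lst = lst, tai = tai, hrdsum = loh + lst + tai),
            class = "scar_scores")
}

#' @export
print.scar_scores <- function(x, ...) {
  cat(sprintf("<scar_scores> LOH=%d LST=%d TAI=%d HRDsum=%d\n",
              x$loh, x$lst, x$tai, x$hrdsum))
  invisible(x)
}

#' Read allele-specific copy-number segments
#'
#' @param path TSV with columns `sample`, `chrom`, `start`, `end`,
#'   `cn_major`, `cn_minor`.
#' @return data.frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  req <- c("sample", "chrom", "start", "end", "cn_major", "cn_minor")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("segment table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read a genome annotation (chromosome lengths and centromeres)
#'
#' @param path TSV with columns `chrom`, `length`, `cen_start`, `cen_end`.
#' @return data.frame.
#' @export
read_genome_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  req <- c("chrom", "length", "cen_start", "cen_end")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("genome annotation lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- df$cen_start <= 1 | df$cen_end >= df$length | df$cen_start > df$cen_end
  if (any(bad)) stop("centromere interval must lie strictly inside the chromosome",
                     call. = FALSE)
  df
}

#' Score every sample in a segment table
#'
#' @param segments data.frame as from [read_segments()] (with a `sample`
#'   column).
#' @param annotation Genome annotation data.frame.
#' @param ... Passed to [compute_hrdsum()].
#' @return data.frame with `sample`, `loh`, `lst`, `tai`, `hrdsum`.
#' @export
score_cohort_segments <- function(segments, annotation, ...) {
  ids <- unique(segments$sample)
  rows <- lapply(ids, function(s) {
    sc <- compute_hrdsum(segments[segments$sample == s,
                                  c("chrom", "start", "end", "cn_major", "cn_minor")],
                         annotation, ...)
    data.frame(sample = s, loh = sc$loh, lst = sc$lst, tai = sc$tai,
               hrdsum = sc$hrdsum, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
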