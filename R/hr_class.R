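#' Default HR pathway gene list
#'
#' Returns the gene list used to map gene symbols to the groups `BRCA12`,
#' `other_HR`, `non_HR`. The shipped list
#' (`inst/extdata/hr_genes_placeholder.tsv`) is a PLACEHOLDER covering
#' well-known HR pathway members; it is NOT the authoritative 142-gene
#' panel, which should be supplied by the user for real analyses.
#'
#' @param path Optional path to a TSV with columns `gene`, `group`
#'   (`BRCA12` or `other_HR`); defaults to the shipped placeholder.
#' @return data.frame with columns `gene`, `group`.
#' @export
hr_gene_list <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hr_genes_placeholder.tsv",
                        package = "deamHRD", mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Map a gene symbol to its HR gene group
#'
#' @param gene Character vector of gene symbols.
#' @param gene_list data.frame from [hr_gene_list()].
#' @return Character vector over `{"BRCA12", "other_HR", "non_HR"}`.
#' @export
hr_gene_group <- function(gene, gene_list = hr_gene_list()) {
  out <- rep("non_HR", length(gene))
  out[gene %in% gene_list$gene[gene_list$group == "other_HR"]] <- "other_HR"
  out[gene %in% gene_list$gene[gene_list$group == "BRCA12"]] <- "BRCA12"
  out
}

.h_class_levels <- c("H1a", "H1b", "H2a", "H2b", "H3")

#' Classify the cause of homologous recombination deficiency for one tumor
#'
#' Each tumor is assigned the highest of the classes supported by its
#' alterations: deleterious BRCA1/2 (H1a) > deleterious other-HR-gene (H1b)
#' > BRCA1/2 VUS (H2a) > other-HR-gene VUS (H2b) > none of these (H3).
#' The allelic suffix (BA/MA) is taken from the alterations of the winning
#' class (biallelic wins over monoallelic when both are present) and only
#' applies to the deleterious classes H1a/H1b. `allelic = "unknown"` is
#' treated as monoallelic. A tumor is flagged `h1a_star` — the benchmark
#' positive — when it carries a biallelic deleterious BRCA1/2 alteration or
#' BRCA1 promoter hypermethylation.
#'
#' @param alterations data.frame for ONE sample with columns `sample`,
#'   `gene`, `effect` (`deleterious`/`VUS`), `allelic`
#'   (`biallelic`/`monoallelic`/`unknown`). May have zero rows.
#' @param methylation BRCA1 promoter hypermethylation status: `TRUE`,
#'   `FALSE` or `"unknown"`. `"unknown"` is treated as `FALSE` for
#'   classification but recorded verbatim.
#' @param sample_id Sample identifier; required when `alterations` is empty.
#' @param gene_list HR gene list, see [hr_gene_list()].
#' @return A one-row data.frame: `sample`, `h_class`, `allelic_suffix`
#'   (`BA`/`MA`/`none`), `brca1_hypermethylated`, `h1a_star`.
#' @export
classify_hr_status <- function(alterations, methylation = FALSE,
                               sample_id = NULL, gene_list = hr_gene_list()) {
  if (!is.null(alterations) && nrow(alterations) > 0) {
    ids <- unique(alterations$sample)
    if (length(ids) > 1) {
      stop("alterations belong to multiple samples: ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    if (is.null(sample_id)) sample_id <- ids
  }
  if (is.null(sample_id)) stop("sample_id required for empty alteration sets",
                               call. = FALSE)
  meth_known <- !identical(methylation, "unknown")
  meth <- meth_known && isTRUE(methylation)

  h_class <- "H3"
  suffix <- "none"
  if (!is.null(alterations) && nrow(alterations) > 0) {
    grp <- hr_gene_group(alterations$gene, gene_list)
    cls <- rep(NA_character_, nrow(alterations))
    cls[alterations$effect == "deleterious" & grp == "BRCA12"] <- "H1a"
    cls[alterations$effect == "deleterious" & grp == "other_HR"] <- "H1b"
    cls[alterations$effect == "VUS" & grp == "BRCA12"] <- "H2a"
    cls[alterations$effect == "VUS" & grp == "other_HR"] <- "H2b"
    hit <- !is.na(cls)
    if (any(hit)) {
      ord <- match(cls[hit], .h_class_levels)
      h_class <- .h_class_levels[min(ord)]
      if (h_class %in% c("H1a", "H1b")) {
        top <- alterations[hit, ][cls[hit] == h_class, , drop = FALSE]
        suffix <- if (any(top$allelic == "biallelic")) "BA" else "MA"
      }
    }
  }
  h1a_star <- (h_class == "H1a" && suffix == "BA") || meth
  data.frame(sample = sample_id, h_class = h_class, allelic_suffix = suffix,
             brca1_hypermethylated = if (meth_known) meth else NA,
             h1a_star = h1a_star, stringsAsFactors = FALSE)
}

#' Classify every sample in an alteration table
#'
#' @param alterations data.frame over all samples (columns as in
#'   [classify_hr_status()]).
#' @param methylation data.frame with columns `sample`,
#'   `brca1_promoter_hm` (logical or `"unknown"`), or `NULL` when no
#'   methylation data exist.
#' @param sample_ids Samples to classify; defaults to the union of samples
#'   seen in `alterations` and `methylation` (samples without alterations
#'   are classified H3).
#' @param gene_list HR gene list.
#' @return data.frame with one classification row per sample.
#' @export
classify_hr_cohort <- function(alterations, methylation = NULL,
                               sample_ids = NULL, gene_list = hr_gene_list()) {
  if (is.null(sample_ids)) {
    sample_ids <- unique(c(alterations$sample,
                           if (!is.null(methylation)) methylation$sample))
  }
  rows <- lapply(sample_ids, function(s) {
    alt_s <- alterations[alterations$sample == s, , drop = FALSE]
    meth_s <- "unknown"
    if (!is.null(methylation) && s %in% methylation$sample) {
      v <- methylation$brca1_promoter_hm[methylation$sample == s][1]
      meth_s <- if (identical(v, "unknown")) "unknown" else as.logical(v)
    }
    classify_hr_status(alt_s, methylation = meth_s, sample_id = s,
                       gene_list = gene_list)
  })
  do.call(rbind, rows)
}

#' Derive benchmark labels (HR-deficient vs HR-proficient)
#'
#' Positives are H1a* tumors (biallelic deleterious BRCA1/2 or BRCA1
#' promoter hypermethylation); negatives are H3 tumors without
#' hypermethylation. All other tumors are excluded, with the reason
#' recorded, since their HR status is ambiguous (VUS carriers, monoallelic
#' or non-BRCA deleterious alterations).
#'
#' @param classifications data.frame from [classify_hr_cohort()], one row
#'   per sample.
#' @return data.frame `sample`, `label` (`"positive"`/`"negative"`/
#'   `"excluded"`), `reason`.
#' @export
build_benchmark_labels <- function(classifications) {
  if (nrow(classifications) == 0) {
    return(data.frame(sample = character(0), label = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  if (anyDuplicated(classifications$sample)) {
    stop("multiple classifications for one sample", call. = FALSE)
  }
  label <- rep("excluded", nrow(classifications))
  reason <- sprintf("class %s not benchmarkable", classifications$h_class)
  pos <- classifications$h1a_star
  neg <- classifications$h_class == "H3" & !pos
  label[pos] <- "positive"
  reason[pos] <- "H1a* (biallelic deleterious BRCA1/2 or BRCA1 hypermethylation)"
  label[neg] <- "negative"
  reason[neg] <- "H3, no HR pathway alteration"
  data.frame(sample = classifications$sample, label = label, reason = reason,
             stringsAsFactors = FALSE)
}

#' Read gene alteration and methylation tables
#'
#' @param path TSV with columns `sample`, `gene`, `effect`, `allelic`.
#' @return data.frame.
#' @export
read_alterations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "gene", "effect", "allelic")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("alteration table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_alterations
#' @param meth_path TSV with columns `sample`, `brca1_promoter_hm`.
#' @export
read_methylation <- function(meth_path) {
  df <- utils::read.delim(meth_path, stringsAsFactors = FALSE)
  req <- c("sample", "brca1_promoter_hm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("methylation table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}
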