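#' Read an SBS signature matrix in the COSMIC layout
#'
#' Expects a tab-separated file whose first column holds the 96 channel
#' labels (`"A[C>A]A"` style; the column is commonly named `Type`) and
#' whose remaining columns are signature probability vectors. Rows are
#' matched by label and reordered to the canonical channel order of
#' [channel96_labels()], so the row order of the input file does not
#' matter.
#'
#' @param path Path to the matrix file (e.g. `COSMIC_v3.3.1_SBS_GRCh38.txt`
#'   as distributed by COSMIC).
#' @return Numeric matrix, 96 rows (canonical order) by one column per
#'   signature.
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- channel96_labels()
  key <- df[[1]]
  if (!all(labs %in% key)) {
    stop("signature matrix does not contain all 96 channel labels in its first column",
         call. = FALSE)
  }
  m <- as.matrix(df[match(labs, key), -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labs
  m
}

#' CpG C>T content of a mutational signature
#'
#' The percentage of a signature's probability mass falling on the four
#' channels that define f_deam (`N[C>T]G`). Signatures dominated by these
#' channels (clock-like deamination, mismatch-repair deficiency, POLE)
#' confound the use of f_deam as an HRD biomarker in the corresponding
#' tumor entities.
#'
#' @param signature Numeric vector of length 96 over the canonical channel
#'   order, or a named vector matching [channel96_labels()]. Must be
#'   non-negative; if it does not sum to 1 within 1e-6 it is renormalized
#'   with a warning.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' sig <- rep(1 / 96, 96)
#' signature_cgtg_fraction(sig)  # 4/96 * 100
signature_cgtg_fraction <- function(signature) {
  if (length(signature) != 96) {
    stop("signature vector must have length 96", call. = FALSE)
  }
  if (any(signature < 0)) stop("signature mass must be non-negative",
                               call. = FALSE)
  labs <- channel96_labels()
  if (is.null(names(signature))) names(signature) <- labs
  total <- sum(signature)
  if (abs(total - 1) > 1e-6) {
    warning("signature does not sum to 1; renormalizing", call. = FALSE)
  }
  100 * sum(signature[fdeam_channels()]) / total
}

#' Locate the bundled COSMIC SBS matrix, if present
#'
#' The package does not redistribute the COSMIC signature matrix. Users who
#' want signature-composition analyses against COSMIC v3.3 should place the
#' official `COSMIC_v3.3.1_SBS.txt` (GRCh37 or GRCh38 build; record which)
#' under the package's `extdata` directory or pass an explicit path to
#' [read_signature_matrix()].
#'
#' @return The file path, or `NA_character_` when the file is not
#'   installed.
#' @export
cosmic_matrix_path <- function() {
  p <- system.file("extdata", "COSMIC_v3.3.1_SBS.txt", package = "deamHRD")
  if (identical(p, "")) NA_character_ else p
}
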