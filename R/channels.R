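#' The 96 trinucleotide substitution channels
#'
#' Single base substitutions are reduced to six pyrimidine-referenced
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G) and combined with the
#' 5' and 3' flanking bases, giving the standard 96 mutation-type channels
#' used for mutational spectra.
#'
#' The canonical order is substitution-major: the six substitution types in
#' the order above, within each type the 5' base in A, C, G, T order, and
#' within that the 3' base in A, C, G, T order. This matches the row layout
#' of COSMIC-style signature matrices once rows are matched by label.
#'
#' @return Character vector of the 96 channel labels, e.g. `"A[C>T]G"`,
#'   in canonical order.
#' @export
#' @examples
#' head(channel96_labels())
channel96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  labs <- character(0)
  for (s in subs) {
    for (up in bases) {
      for (down in bases) {
        labs <- c(labs, sprintf("%s[%s]%s", up, s, down))
      }
    }
  }
  labs
}

# channels whose counts form the f_deam numerator: C>T at CpG sites
#' Channels defining the CpG C>T (deamination) numerator
#'
#' The four channels N[C>T]G: a C>T transition whose 3' neighbour is G,
#' i.e. a CpG dinucleotide mutating to TpG. These mutations are attributed
#' to spontaneous deamination of 5-methylcytosine (the clock-like process
#' of signature SBS1).
#'
#' @return Character vector of length 4.
#' @export
fdeam_channels <- function() {
  c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")
}

.valid_bases <- c("A", "C", "G", "T")
.complement <- c(A = "T", C = "G", G = "C", T = "A")

.check_base <- function(x, field) {
  x <- toupper(x)
  if (length(x) != 1L || is.na(x) || !x %in% .valid_bases) {
    stop(sprintf("invalid base symbol '%s' in field '%s'", x, field),
         call. = FALSE)
  }
  x
}

#' Normalize a substitution to the pyrimidine strand
#'
#' When the reference base is a purine (A or G) the trinucleotide is
#' reverse-complemented so that the reference base of the reported
#' substitution is a pyrimidine (C or T); the flanking bases swap sides and
#' are complemented. Pyrimidine-referenced input passes through unchanged.
#'
#' @param ref,alt Reference and alternate base (single characters, A/C/G/T).
#' @param up,down 5' and 3' flanking bases.
#' @return A list with elements `substitution` (e.g. `"C>T"`), `up`, `down`.
#' @export
#' @examples
#' normalize_to_pyrimidine("G", "A", up = "C", down = "T")  # -> C>T, A, G
normalize_to_pyrimidine <- function(ref, alt, up, down) {
  ref <- .check_base(ref, "ref")
  alt <- .check_base(alt, "alt")
  up <- .check_base(up, "up")
  down <- .check_base(down, "down")
  if (ref == alt) stop("ref and alt must differ", call. = FALSE)
  if (ref %in% c("C", "T")) {
    list(substitution = paste0(ref, ">", alt), up = up, down = down)
  } else {
    list(substitution = paste0(.complement[[ref]], ">", .complement[[alt]]),
         up = .complement[[down]], down = .complement[[up]])
  }
}

#' Classify a mutation into its 96-channel label
#'
#' @param ref,alt Reference and alternate base.
#' @param up,down 5' and 3' flanking bases; both must be present (run
#'   context extraction first for calls lacking flanking context).
#' @return The canonical channel label, e.g. `"A[C>T]G"`.
#' @export
classify_channel <- function(ref, alt, up, down) {
  if (missing(up) || missing(down) || is.na(up) || is.na(down) ||
      !nzchar(up) || !nzchar(down)) {
    stop("flanking context is missing; run extract_context_from_reference() first",
         call. = FALSE)
  }
  n <- normalize_to_pyrimidine(ref, alt, up, down)
  sprintf("%s[%s]%s", n$up, n$substitution, n$down)
}
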