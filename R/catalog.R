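#' Build a 96-channel mutation catalog for one sample
#'
#' Counts single base substitutions over the 96 trinucleotide channels after
#' pyrimidine-strand normalization. Records that are not single-base
#' substitutions (multi-base ref or alt) are skipped and counted; records
#' containing ambiguity codes (N) in the substitution or context are skipped
#' with a warning. Invalid base symbols raise an error naming the record.
#'
#' @param records A data.frame with columns `ref`, `alt`, `up`, `down`
#'   (flanking bases) and optionally `chrom`, `pos`, `vaf`, `depth`.
#' @param sample_id Sample identifier stored in the catalog.
#' @return An object of class `mut_catalog`: a list with `sample_id`,
#'   `counts` (named integer vector over [channel96_labels()]) and
#'   `n_skipped` (non-SBS or ambiguous records).
#' @export
build_catalog <- function(records, sample_id) {
  labs <- channel96_labels()
  counts <- stats::setNames(integer(96), labs)
  n_skipped <- 0L
  n <- if (is.null(records)) 0L else nrow(records)
  if (n > 0L) {
    ref <- toupper(as.character(records$ref))
    alt <- toupper(as.character(records$alt))
    up <- toupper(as.character(records$up))
    down <- toupper(as.character(records$down))
    sbs <- nchar(ref) == 1L & nchar(alt) == 1L
    n_skipped <- sum(!sbs)
    idx <- which(sbs)
    if (length(idx)) {
      amb <- ref[idx] == "N" | alt[idx] == "N" | up[idx] == "N" |
        down[idx] == "N"
      if (any(amb)) {
        warning(sprintf("record %s skipped: ambiguous base (N)",
                        paste(idx[amb], collapse = ", ")), call. = FALSE)
        n_skipped <- n_skipped + sum(amb)
        idx <- idx[!amb]
      }
    }
    if (length(idx)) {
      bad <- !(ref[idx] %in% .valid_bases & alt[idx] %in% .valid_bases &
                 up[idx] %in% .valid_bases & down[idx] %in% .valid_bases)
      if (any(bad)) {
        i <- idx[which(bad)[1]]
        stop(sprintf("record %d: invalid base symbol (ref=%s alt=%s up=%s down=%s)",
                     i, ref[i], alt[i], up[i], down[i]), call. = FALSE)
      }
      same <- ref[idx] == alt[idx]
      if (any(same)) {
        i <- idx[which(same)[1]]
        stop(sprintf("record %d: ref equals alt (%s)", i, ref[i]),
             call. = FALSE)
      }
      # vectorized pyrimidine-strand normalization
      r <- ref[idx]
      a <- alt[idx]
      u <- up[idx]
      d <- down[idx]
      pur <- r %in% c("A", "G")
      r2 <- r; a2 <- a; u2 <- u; d2 <- d
      r2[pur] <- unname(.complement[r[pur]])
      a2[pur] <- unname(.complement[a[pur]])
      u2[pur] <- unname(.complement[d[pur]])
      d2[pur] <- unname(.complement[u[pur]])
      ch <- sprintf("%s[%s>%s]%s", u2, r2, a2, d2)
      tab <- table(factor(ch, levels = labs))
      counts <- stats::setNames(as.integer(tab), labs)
    }
  }
  structure(list(sample_id = sample_id, counts = counts,
                 n_skipped = n_skipped),
            class = "mut_catalog")
}

#' @export
print.mut_catalog <- function(x, ...) {
  cat(sprintf("<mut_catalog> sample %s: TMB = %d, f_deam = %s, skipped = %d\n",
              x$sample_id, compute_tmb(x),
              format(compute_fdeam(x), digits = 3), x$n_skipped))
  invisible(x)
}

#' Construct a catalog directly from channel counts
#'
#' Useful when counts come from an external tabulation (or a simulation)
#' rather than from raw mutation records. Channels absent from `counts`
#' are zero.
#'
#' @param counts Named non-negative integer vector; names must be channel
#'   labels from [channel96_labels()].
#' @param sample_id Sample identifier.
#' @return A `mut_catalog`.
#' @export
as_mut_catalog <- function(counts, sample_id) {
  labs <- channel96_labels()
  bad <- setdiff(names(counts), labs)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(utils::head(bad, 3), collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("channel counts must be non-negative", call. = FALSE)
  full <- stats::setNames(integer(96), labs)
  full[names(counts)] <- as.integer(counts)
  structure(list(sample_id = sample_id, counts = full, n_skipped = 0L),
            class = "mut_catalog")
}

#' Tumor mutational burden of a catalog
#'
#' TMB is defined here as the total number of single base substitutions,
#' i.e. the sum of the 96 channel counts.
#'
#' @param catalog A `mut_catalog`.
#' @return Non-negative integer.
#' @export
compute_tmb <- function(catalog) {
  stopifnot(inherits(catalog, "mut_catalog"))
  as.integer(sum(catalog$counts))
}

#' CpG deamination fraction f_deam
#'
#' The fraction of C>T transitions at CpG sites (channels
#' `A[C>T]G`, `C[C>T]G`, `G[C>T]G`, `T[C>T]G`) among all single base
#' substitutions, expressed as a percentage. Low values predict homologous
#' recombination deficiency. Samples whose TMB falls below `min_tmb` are
#' reported as `NA`: with very few mutations the fraction is dominated by
#' sampling noise (its standard error scales as 1/sqrt(TMB)).
#'
#' @param catalog A `mut_catalog`.
#' @param min_tmb Minimum TMB required to report a value (default 10).
#' @return Percentage in \[0, 100\], or `NA` when TMB < `min_tmb`.
#' @export
compute_fdeam <- function(catalog, min_tmb = 10) {
  stopifnot(inherits(catalog, "mut_catalog"))
  tmb <- compute_tmb(catalog)
  if (tmb < min_tmb) return(NA_real_)
  100 * sum(catalog$counts[fdeam_channels()]) / tmb
}

#' Extract trinucleotide context from a reference genome
#'
#' Returns the bases at `pos - 1`, `pos`, `pos + 1` (uppercased) of the
#' requested chromosome. Works on a named character vector of sequences or
#' a `Biostrings::DNAStringSet`.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `DNAStringSet`.
#' @param chrom Chromosome name.
#' @param pos 1-based position; must satisfy `2 <= pos <= length - 1`.
#' @param ref Optional expected reference base; a mismatch with the genome
#'   raises a reference-mismatch error.
#' @return A list with `up`, `ref`, `down`.
#' @export
extract_context_from_reference <- function(genome, chrom, pos, ref = NULL) {
  seq <- NULL
  if (methods::is(genome, "DNAStringSet") &&
      requireNamespace("Biostrings", quietly = TRUE)) {
    if (!chrom %in% names(genome)) {
      stop(sprintf("chromosome '%s' not found in genome", chrom), call. = FALSE)
    }
    len <- Biostrings::width(genome[chrom])
    if (pos < 2 || pos > len - 1) {
      stop(sprintf("position %d is at the edge of chromosome %s (length %d)",
                   pos, chrom, len), call. = FALSE)
    }
    seq <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                   pos - 1, pos + 1)))
  } else {
    if (!chrom %in% names(genome)) {
      stop(sprintf("chromosome '%s' not found in genome", chrom), call. = FALSE)
    }
    len <- nchar(genome[[chrom]])
    if (pos < 2 || pos > len - 1) {
      stop(sprintf("position %d is at the edge of chromosome %s (length %d)",
                   pos, chrom, len), call. = FALSE)
    }
    seq <- toupper(substr(genome[[chrom]], pos - 1, pos + 1))
  }
  tri <- strsplit(seq, "")[[1]]
  if (!is.null(ref) && tri[2] != toupper(ref)) {
    stop(sprintf("reference mismatch at %s:%d: genome has %s, record has %s",
                 chrom, pos, tri[2], ref), call. = FALSE)
  }
  list(up = tri[1], ref = tri[2], down = tri[3])
}

#' Read somatic mutations from a MAF-like TSV
#'
#' Required columns: `sample`, `chrom`, `pos`, `ref`, `alt`. Optional:
#' `context_up`, `context_down`, `vaf`, `depth`. Context columns are
#' renamed to `up`/`down` in the result; absent optional columns come back
#' as `NA` so the caller can fill them from a reference genome.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data.frame with columns `sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `up`, `down`, `vaf`, `depth`.
#' @export
read_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  req <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop(sprintf("MAF file %s lacks required columns: %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(sample = as.character(df$sample),
                    chrom = as.character(df$chrom),
                    pos = as.integer(df$pos),
                    ref = toupper(as.character(df$ref)),
                    alt = toupper(as.character(df$alt)),
                    stringsAsFactors = FALSE)
  out$up <- if ("context_up" %in% names(df)) toupper(as.character(df$context_up)) else NA_character_
  out$down <- if ("context_down" %in% names(df)) toupper(as.character(df$context_down)) else NA_character_
  out$vaf <- if ("vaf" %in% names(df)) as.numeric(df$vaf) else NA_real_
  out$depth <- if ("depth" %in% names(df)) as.integer(df$depth) else NA_integer_
  out
}

#' Read SNV records from a VCF and annotate trinucleotide context
#'
#' Keeps biallelic single-nucleotide records only; indels and multi-base
#' alleles are dropped. When a reference genome is supplied the 5'/3'
#' flanking bases are looked up (and the VCF REF checked against it).
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param sample_id Sample identifier to assign to the records.
#' @param genome Optional reference: named character vector of sequences or
#'   a `DNAStringSet` (see [extract_context_from_reference()]).
#' @return A data.frame in the same layout as [read_maf()].
#' @export
read_vcf_snvs <- function(path, sample_id, genome = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    toupper(fix$REF) %in% .valid_bases & toupper(fix$ALT) %in% .valid_bases
  fix <- fix[keep, , drop = FALSE]
  out <- data.frame(sample = rep(sample_id, nrow(fix)),
                    chrom = fix$CHROM,
                    pos = as.integer(fix$POS),
                    ref = toupper(fix$REF),
                    alt = toupper(fix$ALT),
                    up = NA_character_, down = NA_character_,
                    vaf = NA_real_, depth = NA_integer_,
                    stringsAsFactors = FALSE)
  if (!is.null(genome) && nrow(out) > 0L) {
    for (i in seq_len(nrow(out))) {
      ctx <- extract_context_from_reference(genome, out$chrom[i], out$pos[i],
                                            ref = out$ref[i])
      out$up[i] <- ctx$up
      out$down[i] <- ctx$down
    }
  }
  out
}

#' Build one catalog per sample from a mutation table
#'
#' @param records Mutation data.frame as returned by [read_maf()].
#' @param min_vaf,min_depth Optional filters applied before counting; by
#'   default no filter is applied.
#' @return Named list of `mut_catalog`, one per sample present.
#' @export
build_catalogs <- function(records, min_vaf = NULL, min_depth = NULL) {
  if (!is.null(min_vaf)) records <- records[!is.na(records$vaf) & records$vaf >= min_vaf, ]
  if (!is.null(min_depth)) records <- records[!is.na(records$depth) & records$depth >= min_depth, ]
  ids <- unique(records$sample)
  out <- lapply(ids, function(s) build_catalog(records[records$sample == s, ], s))
  stats::setNames(out, ids)
}

#' Tabulate catalogs as a sample-by-channel matrix
#'
#' @param catalogs List of `mut_catalog` objects.
#' @return Integer matrix, one row per sample, 96 columns in canonical
#'   channel order.
#' @export
catalogs_to_matrix <- function(catalogs) {
  m <- do.call(rbind, lapply(catalogs, function(cc) cc$counts))
  rownames(m) <- vapply(catalogs, function(cc) cc$sample_id, character(1))
  m
}

#' Write catalogs, TMB and f_deam to a TSV
#'
#' One row per sample: 96 channel-count columns in canonical order plus
#' `tmb` and `fdeam` columns.
#'
#' @param catalogs List of `mut_catalog`.
#' @param path Output path.
#' @param min_tmb Passed to [compute_fdeam()].
#' @return The written data.frame, invisibly.
#' @export
write_catalogs_tsv <- function(catalogs, path, min_tmb = 10) {
  m <- catalogs_to_matrix(catalogs)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$tmb <- vapply(catalogs, compute_tmb, integer(1))
  df$fdeam <- vapply(catalogs, compute_fdeam, numeric(1), min_tmb = min_tmb)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
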