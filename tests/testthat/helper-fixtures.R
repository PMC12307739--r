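# shared fixtures, built in code

# a mut_catalog with prescribed channel counts
catalog_from_counts <- function(counts, sample_id = "S1") {
  full <- stats::setNames(integer(96), channel96_labels())
  full[names(counts)] <- as.integer(counts)
  structure(list(sample_id = sample_id, counts = full, n_skipped = 0L),
            class = "mut_catalog")
}

# a mut_catalog drawn multinomially from a profile
catalog_from_profile <- function(profile, n, sample_id = "S1") {
  catalog_from_counts(
    stats::setNames(as.integer(stats::rmultinom(1, n, profile)),
                    channel96_labels()),
    sample_id)
}

# one-chromosome annotation: 100 Mb, centromere 60-65 Mb
tiny_annotation <- function(length = 100e6, cen = c(60e6, 65e6),
                            chrom = "chr1") {
  data.frame(chrom = chrom, length = length,
             cen_start = cen[1], cen_end = cen[2],
             stringsAsFactors = FALSE)
}

seg <- function(chrom, start, end, a, b) {
  data.frame(chrom = chrom, start = start, end = end,
             cn_major = a, cn_minor = b, stringsAsFactors = FALSE)
}

# mutation records whose channel is prescribed (pyrimidine-strand bases)
records_from_channels <- function(channels, sample_id = "S1", vaf = 0.4) {
  up <- substr(channels, 1, 1)
  ref <- substr(channels, 3, 3)
  alt <- substr(channels, 5, 5)
  down <- substr(channels, 7, 7)
  data.frame(sample = sample_id, chrom = "chr1",
             pos = seq_along(channels) * 1000L, ref = ref, alt = alt,
             up = up, down = down, vaf = vaf, depth = NA_integer_,
             stringsAsFactors = FALSE)
}

reverse_complement_record <- function(rec) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  data.frame(sample = rec$sample, chrom = rec$chrom, pos = rec$pos,
             ref = unname(comp[rec$ref]), alt = unname(comp[rec$alt]),
             up = unname(comp[rec$down]), down = unname(comp[rec$up]),
             vaf = rec$vaf, depth = rec$depth, stringsAsFactors = FALSE)
}
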