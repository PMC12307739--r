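test_that("catalog counting conserves SBS records and skips the rest", {
  expect_equal(compute_tmb(build_catalog(NULL, "empty")), 0L)
  recs <- records_from_channels(rep("A[C>T]G", 3))
  cat3 <- build_catalog(recs, "S1")
  expect_equal(unname(cat3$counts[["A[C>T]G"]]), 3L)
  expect_equal(compute_tmb(cat3), 3L)
  expect_equal(sum(cat3$counts), 3L)
  # a 2-bp deletion is skipped and reported
  recs2 <- rbind(recs,
                 data.frame(sample = "S1", chrom = "chr1", pos = 99L,
                            ref = "AT", alt = "A", up = "C", down = "G",
                            vaf = 0.4, depth = NA_integer_))
  cat4 <- build_catalog(recs2, "S1")
  expect_equal(compute_tmb(cat4), 3L)
  expect_equal(cat4$n_skipped, 1L)
  # conservation over a random record set
  set.seed(1)
  chans <- sample(channel96_labels(), 57, replace = TRUE)
  expect_equal(compute_tmb(build_catalog(records_from_channels(chans), "S1")),
               57L)
})

test_that("ambiguous bases are skipped with a warning, invalid bases error", {
  recs <- records_from_channels(c("A[C>T]G", "T[C>A]T"))
  recs$up[2] <- "N"
  expect_warning(cat2 <- build_catalog(recs, "S1"), "ambiguous")
  expect_equal(compute_tmb(cat2), 1L)
  recs$up[2] <- "Z"
  expect_error(build_catalog(recs, "S1"), "invalid base")
})

test_that("f_deam is the CpG C>T percentage, NA below the TMB floor", {
  cat10 <- catalog_from_counts(c("A[C>T]G" = 2, "C[C>T]G" = 1,
                                 "T[C>T]G" = 1, "T[C>A]T" = 6))
  expect_equal(compute_fdeam(cat10), 40)
  expect_true(is.na(compute_fdeam(catalog_from_counts(c()))))
  cat9 <- catalog_from_counts(c("A[C>T]G" = 9))
  expect_true(is.na(compute_fdeam(cat9, min_tmb = 10)))
  expect_equal(compute_fdeam(cat9, min_tmb = 5), 100)
})

test_that("f_deam recovers the generating CpG mass under multinomial sampling", {
  set.seed(101)
  prof <- make_class_profile(0.89)
  cat_big <- catalog_from_profile(prof, 2000)
  expect_lt(abs(compute_fdeam(cat_big) - 89), 3)
  # invariance under record permutation
  set.seed(5)
  chans <- sample(channel96_labels(), 40, replace = TRUE)
  f1 <- compute_fdeam(build_catalog(records_from_channels(chans), "a"))
  f2 <- compute_fdeam(build_catalog(records_from_channels(sample(chans)), "a"))
  expect_equal(f1, f2)
})

test_that("context extraction honours edges and reference mismatches", {
  genome <- c(chr1 = "ACGT")
  ctx <- extract_context_from_reference(genome, "chr1", 2)
  expect_identical(ctx, list(up = "A", ref = "C", down = "G"))
  expect_error(extract_context_from_reference(genome, "chr1", 1), "edge")
  expect_error(extract_context_from_reference(genome, "chr1", 4), "edge")
  expect_error(extract_context_from_reference(genome, "chr1", 2, ref = "T"),
               "mismatch")
  # soft-masked genome is uppercased
  ctx <- extract_context_from_reference(c(chr1 = "acgt"), "chr1", 3)
  expect_identical(ctx$ref, "G")
})

test_that("VCF input keeps SNVs only and pulls context from the genome", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=12>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t3\t.\tC\tT\t.\tPASS\t.",
               "chr1\t4\t.\tG\tA\t.\tPASS\t.",
               "chr1\t8\t.\tAT\tA\t.\tPASS\t."),  # indel: dropped
             tmp)
  genome <- c(chr1 = "AACGTGCATTAA")
  recs <- read_vcf_snvs(tmp, "S9", genome = genome)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$up, c("A", "C"))
  expect_equal(recs$down, c("G", "T"))
  cat2 <- build_catalog(recs, "S9")
  expect_equal(compute_tmb(cat2), 2L)
  # chr1:3 C>T in A_G; chr1:4 G>A in C_T reverse-complements to the same channel
  expect_equal(unname(cat2$counts[["A[C>T]G"]]), 2L)
})

test_that("MAF round trip preserves catalogs", {
  set.seed(9)
  chans <- sample(channel96_labels(), 30, replace = TRUE)
  recs <- records_from_channels(chans)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  out <- recs
  names(out)[names(out) == "up"] <- "context_up"
  names(out)[names(out) == "down"] <- "context_down"
  write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_maf(tmp)
  expect_equal(build_catalog(back, "S1")$counts,
               build_catalog(recs, "S1")$counts)
})
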