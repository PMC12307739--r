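ann1 <- tiny_annotation()  # 100 Mb, centromere 60-65 Mb

test_that("LOH counts long sub-chromosomal minor-allele losses only", {
  expect_equal(compute_loh(seg("chr1", 1e6, 21e6 - 1, 2, 0), ann1), 1L)
  # whole-chromosome LOH is excluded
  expect_equal(compute_loh(seg("chr1", 1, 100e6, 2, 0), ann1), 0L)
  # below the 15 Mb threshold
  expect_equal(compute_loh(seg("chr1", 1e6, 11e6 - 1, 2, 0), ann1), 0L)
  # threshold is exclusive: exactly 15 Mb does not count
  expect_equal(compute_loh(seg("chr1", 1e6, 16e6 - 1, 2, 0), ann1), 0L)
  # copy-neutral (1,1) and homozygous-deleted (0,0) segments never count
  expect_equal(compute_loh(seg("chr1", 1e6, 30e6, 1, 1), ann1), 0L)
  expect_equal(compute_loh(seg("chr1", 1e6, 30e6, 0, 0), ann1), 0L)
})

test_that("LST counts transitions between long segments after smoothing", {
  two <- rbind(seg("chr1", 1e6, 21e6 - 1, 2, 1),
               seg("chr1", 21e6, 36e6 - 1, 2, 0))
  expect_equal(compute_lst(two, ann1), 1L)
  # a 2 Mb interruption is smoothed away
  three <- rbind(seg("chr1", 1e6, 21e6 - 1, 2, 1),
                 seg("chr1", 21e6, 23e6 - 1, 3, 2),
                 seg("chr1", 23e6, 38e6 - 1, 2, 0))
  expect_equal(compute_lst(three, ann1), 1L)
  # uniform arm: no transition
  expect_equal(compute_lst(seg("chr1", 1e6, 50e6, 2, 1), ann1), 0L)
  # a short flank (< 10 Mb) does not support a transition
  short <- rbind(seg("chr1", 1e6, 9e6, 2, 1),
                 seg("chr1", 9e6 + 1, 30e6, 2, 0))
  expect_equal(compute_lst(short, ann1), 0L)
  # identical adjacent states merge before counting
  merged <- rbind(seg("chr1", 1e6, 15e6, 2, 0),
                  seg("chr1", 15e6 + 1, 30e6, 2, 0))
  expect_equal(compute_lst(merged, ann1), 0L)
})

test_that("TAI counts telomere-anchored imbalance that respects the centromere", {
  expect_equal(compute_tai(seg("chr1", 1, 30e6, 2, 1), ann1), 1L)
  # crossing the centromere disqualifies (chromosome of 70 Mb, cen 60-65)
  ann70 <- tiny_annotation(length = 70e6, cen = c(60e6, 65e6))
  expect_equal(compute_tai(seg("chr1", 50e6, 70e6, 2, 1), ann70), 0L)
  # balanced telomeric segment does not count
  expect_equal(compute_tai(seg("chr1", 1, 30e6, 1, 1), ann1), 0L)
  # interior imbalance does not count
  expect_equal(compute_tai(seg("chr1", 20e6, 40e6, 2, 1), ann1), 0L)
  # whole-chromosome imbalance does not count
  expect_equal(compute_tai(seg("chr1", 1, 100e6, 2, 1), ann1), 0L)
  # both telomeres can score on one chromosome
  both <- rbind(seg("chr1", 1, 20e6, 2, 1),
                seg("chr1", 80e6, 100e6, 3, 1))
  expect_equal(compute_tai(both, ann1), 2L)
})

test_that("HRDsum is additive across the three components", {
  ann3 <- rbind(tiny_annotation(chrom = "chr1"),
                tiny_annotation(chrom = "chr2"),
                tiny_annotation(chrom = "chr3"))
  segs <- rbind(seg("chr1", 1e6, 21e6 - 1, 2, 0),              # LOH
                rbind(seg("chr2", 1e6, 21e6 - 1, 2, 1),        # LST pair
                      seg("chr2", 21e6, 36e6 - 1, 2, 0)),
                seg("chr3", 1, 30e6, 2, 1))                    # TAI
  sc <- compute_hrdsum(segs, ann3)
  expect_equal(sc$loh, 1L)
  expect_equal(sc$lst, 1L)
  expect_equal(sc$tai, 1L)
  expect_equal(sc$hrdsum, sc$loh + sc$lst + sc$tai)
  # empty input scores zero everywhere
  sc0 <- compute_hrdsum(segs[0, ], ann3)
  expect_equal(unlist(sc0[c("loh", "lst", "tai", "hrdsum")]),
               c(loh = 0L, lst = 0L, tai = 0L, hrdsum = 0L))
})

test_that("overlapping segments are rejected and sex chromosomes dropped", {
  bad <- rbind(seg("chr1", 1e6, 30e6, 2, 1), seg("chr1", 25e6, 50e6, 2, 0))
  expect_error(compute_loh(bad, ann1), "overlap")
  annX <- rbind(ann1, tiny_annotation(chrom = "chrX"))
  sx <- seg("chrX", 1e6, 21e6 - 1, 2, 0)
  expect_equal(compute_loh(sx, annX), 0L)
  expect_equal(compute_loh(sx, annX, exclude_sex = FALSE), 1L)
})

test_that("scores are invariant under a coordinate translation", {
  off <- 7e6
  segs <- rbind(seg("chr1", 1e6, 21e6 - 1, 2, 0),
                seg("chr1", 21e6, 36e6 - 1, 2, 1))
  ann_shift <- tiny_annotation(length = 100e6 + off,
                               cen = c(60e6 + off, 65e6 + off))
  shifted <- segs
  shifted$start <- shifted$start + off
  shifted$end <- shifted$end + off
  a <- compute_hrdsum(segs, ann1)
  b <- compute_hrdsum(shifted, ann_shift)
  expect_equal(unlist(a), unlist(b))
})

test_that("planted genomes score exactly their planted event counts", {
  ann <- synthetic_genome_annotation()
  for (k in c(0L, 2L, 4L)) {
    segs <- plant_scar_genome(k, k + 1L, k + 2L, ann)
    sc <- compute_hrdsum(segs, ann)
    expect_equal(c(sc$loh, sc$lst, sc$tai), c(k, k + 1L, k + 2L))
    expect_equal(unname(attr(segs, "planted")), c(k, k + 1L, k + 2L))
  }
})
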