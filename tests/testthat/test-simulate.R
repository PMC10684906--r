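test_that("simulate_cross honors the class mix and ground-truth labels", {
  lay <- tiny_layout()
  cr <- simulate_cross(lay, sim_config(seed = 3), c(f1 = 3, self = 2))
  expect_length(cr$offspring, 5)
  cls <- vapply(cr$offspring, `[[`, "", "class")
  expect_equal(sum(cls == "f1"), 3)
  expect_equal(sum(cls == "self"), 2)
  eg <- vapply(cr$offspring, `[[`, "", "edited_genotype")
  expect_equal(sum(eg == "het"), 3)
  expect_equal(sum(eg == "hom_edited"), 2)

  elim <- simulate_cross(lay, sim_config(seed = 3),
                         c(eliminated_tetraploid = 1))$offspring[[1]]
  expect_true(all(elim$copy_number == 4))
  expect_true(all(unlist(elim$origin) == "B"))

  mono <- simulate_cross(lay, sim_config(seed = 3),
                         c(aneuploid_mono7 = 1))$offspring[[1]]
  expect_equal(mono$copy_number[["chr7"]], 1L)
  expect_true(all(mono$copy_number[names(mono$copy_number) != "chr7"] == 2))
  expect_equal(mono$origin[["chr7"]], "B")

  expect_error(simulate_cross(lay, sim_config(), c(triploid = 1)),
               "triploid")
  expect_error(simulate_cross(lay, sim_config(), c(f1 = -1)), ">= 0")
})

test_that("simulated outputs are byte-identical under a fixed seed", {
  lay <- tiny_layout(3)
  cfg <- sim_config(seed = 11)
  p1 <- tempfile(); p2 <- tempfile()
  for (p in c(p1, p2)) {
    cr <- simulate_cross(lay, cfg, c(f1 = 1))
    dir.create(p)
    write_alignments(cr$offspring[[1]], lay, cfg, file.path(p, "a.sam"))
    write_variant_calls(cr$offspring[[1]], cr$parents, lay, cfg,
                        file.path(p, "a.vcf"))
    write_fluorescence_tables(cr$offspring, cfg,
                              file.path(p, "pace.csv"),
                              file.path(p, "flow.csv"))
  }
  for (f in c("a.sam", "a.vcf", "pace.csv", "flow.csv"))
    expect_identical(readLines(file.path(p1, f)),
                     readLines(file.path(p2, f)))
})

test_that("retained read-pair counts follow the copy-number model", {
  lay <- tiny_layout(2)
  cfg <- sim_config(seed = 7, depth_per_copy = 30, decoy_fraction = 0)
  cr <- simulate_cross(lay, cfg, c(f1 = 1))
  p <- tempfile(fileext = ".sam")
  write_alignments(cr$offspring[[1]], lay, cfg, p)
  oc <- oracle_sam_bin_counts(p)
  # 2 chromosomes x 20 bins, diploid at depth 30/copy: mean 60 pairs
  # = 120 records per bin; all bins populated
  expect_equal(nrow(oc), 40)
  mean_pairs <- mean(oc$n) / 2
  expect_gt(mean_pairs, 60 * 0.9)
  expect_lt(mean_pairs, 60 * 1.1)

  # copy number 0 chromosome yields no retained reads there
  zero <- cr$offspring[[1]]
  zero$copy_number["chr2"] <- 0L
  p0 <- tempfile(fileext = ".sam")
  write_alignments(zero, lay, cfg, p0)
  oc0 <- oracle_sam_bin_counts(p0)
  expect_false("chr2" %in% oc0$chrom)
})

test_that("decoy records fail each filter criterion", {
  lay <- tiny_layout(3)
  cfg <- sim_config(seed = 5, depth_per_copy = 30, decoy_fraction = 0.1)
  cr <- simulate_cross(lay, cfg, c(f1 = 1))
  p <- tempfile(fileext = ".sam")
  write_alignments(cr$offspring[[1]], lay, cfg, p)
  d <- oracle_sam_decoys(p)
  expect_true(all(d >= 1))
  # and the package filter discards exactly what the oracle sees
  fr <- filter_reads(read_alignments(p))
  expect_equal(unname(attr(fr, "discarded")[c("bad_flag", "bad_mapq",
                                              "bad_mate")]),
               unname(d))
})

test_that("variant calls reflect the offspring's parental copies", {
  lay <- tiny_layout()
  cfg <- sim_config(seed = 9, error_rate = 0)
  cr <- simulate_cross(lay, cfg,
                       c(f1 = 1, eliminated_tetraploid = 1))
  f1_vcf <- tempfile(fileext = ".vcf")
  el_vcf <- tempfile(fileext = ".vcf")
  write_variant_calls(cr$offspring[[1]], cr$parents, lay, cfg, f1_vcf)
  write_variant_calls(cr$offspring[[2]], cr$parents, lay, cfg, el_vcf)
  f1r <- oracle_vcf_records(f1_vcf)
  elr <- oracle_vcf_records(el_vcf)
  # f1: heterozygous at every site where the parents differ (all sites)
  expect_true(all(f1r$zyg == "het"))
  # uniparental genome: zero heterozygous records at error rate 0
  expect_equal(sum(elr$zyg == "het"), 0)
  # shared site table across samples of the cross
  expect_equal(f1r$pos, elr$pos)
})

test_that("genotyping errors appear at the configured binomial rate", {
  lay <- tiny_layout()
  e <- 0.01
  cfg <- sim_config(seed = 21, error_rate = e)
  cr <- simulate_cross(lay, cfg, c(eliminated_tetraploid = 1))
  p <- tempfile(fileext = ".vcf")
  write_variant_calls(cr$offspring[[1]], cr$parents, lay, cfg, p)
  rec <- oracle_vcf_records(p)
  n <- nrow(rec)
  miscalls <- sum(rec$zyg == "het")   # truth is homozygous everywhere
  expect_true(abs(miscalls - n * e) < 4 * sqrt(n * e * (1 - e)))
})

test_that("fluorescence archetypes are exact at zero noise", {
  lay <- tiny_layout()
  cfg <- sim_config(seed = 2, fluor_cv = 0, n_nuclei = 500)
  cr <- simulate_cross(lay, cfg,
                       c(self = 1, f1 = 1, aneuploid_mono7 = 1,
                         eliminated_tetraploid = 1))
  ft <- write_fluorescence_tables(cr$offspring, cfg)
  pace <- ft$pace
  expect_equal(pace$fam[1], 0); expect_gt(pace$hex[1], 0)     # self
  expect_equal(pace$fam[2], pace$hex[2])                      # f1
  expect_gt(pace$fam[3], 0); expect_equal(pace$hex[3], 0)     # candidate
  # tetraploid flow location is exactly twice the diploid's at noise 0
  med <- tapply(ft$flow$fluorescence, ft$flow$sample_id, median)
  ids <- vapply(cr$offspring, `[[`, "", "id")
  expect_equal(unname(med[ids[4]] / med[ids[2]]), 2.0)
})

test_that("segment overrides change coverage only inside the segment", {
  lay <- tiny_layout(1)
  cfg <- sim_config(seed = 13, depth_per_copy = 40, decoy_fraction = 0)
  cr <- simulate_cross(lay, cfg, c(f1 = 1))
  o <- set_segment_copy(cr$offspring[[1]], "chr1", 2.5e6, 5e6, 3L)
  p <- tempfile(fileext = ".sam")
  write_alignments(o, lay, cfg, p)
  oc <- oracle_sam_bin_counts(p)
  inside <- oc$n[oc$bin >= 10] / 2
  outside <- oc$n[oc$bin < 10] / 2
  expect_gt(mean(inside), 3 * 40 * 0.9)
  expect_lt(mean(inside), 3 * 40 * 1.1)
  expect_gt(mean(outside), 2 * 40 * 0.9)
  expect_lt(mean(outside), 2 * 40 * 1.1)
})
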