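test_that("read filtering keeps exactly proper unique same-contig pairs", {
  p <- handmade_sam(tempfile(fileext = ".sam"))
  reads <- read_alignments(p)
  expect_equal(nrow(reads), 6)
  kept <- filter_reads(reads)
  expect_equal(kept$qname, c("r1", "r2", "r6"))
  d <- attr(kept, "discarded")
  expect_equal(unname(d["bad_mapq"]), 1L)  # r3
  expect_equal(unname(d["bad_flag"]), 1L)  # r4
  expect_equal(unname(d["bad_mate"]), 1L)  # r5
  expect_equal(unname(d["total"]), 3L)
  # order preserved
  expect_false(is.unsorted(match(kept$qname, reads$qname)))
})

test_that("malformed SAM lines are skipped with a warning, not fatal", {
  p <- tempfile(fileext = ".sam")
  lines <- readLines(handmade_sam(tempfile(fileext = ".sam")))
  writeLines(append(lines, "truncated\tline", after = 4), p)
  expect_warning(reads <- read_alignments(p), "malformed")
  expect_equal(nrow(reads), 6)
  expect_equal(attr(reads, "n_malformed"), 1L)
})

test_that("reads are binned by mid position and totals conserved", {
  p <- handmade_sam(tempfile(fileext = ".sam"))
  kept <- filter_reads(read_alignments(p))
  lay <- genome_layout(c(chr1 = 5e6, chr2 = 5e6))
  b <- bin_reads(kept, bin_grid(lay))
  expect_equal(sum(b$count), nrow(kept))
  # r1 mid 125000 -> chr1 bin 0; r2 mid 250000 -> chr1 bin 1 (half-open)
  expect_equal(b$count[b$chrom == "chr1" & b$bin == 0], 1L)
  expect_equal(b$count[b$chrom == "chr1" & b$bin == 1], 1L)
  expect_equal(sum(b$count[b$chrom == "chr2"]), 1L)
  bad <- kept; bad$chrom[1] <- "chrZ"
  expect_error(bin_reads(bad, bin_grid(lay)), "chrZ")
})

test_that("binned counts equal an independent per-line recount", {
  fam <- sim_family_sams(seed = 31, cls = "f1", n_controls = 1)
  for (p in c(fam$sample_sam, fam$control_sams)) {
    b <- bin_reads(filter_reads(read_alignments(p)),
                   bin_grid(fam$layout))
    expect_counts_match_oracle(b, oracle_sam_bin_counts(p))
  }
})

test_that("normalization is definitional and masks zero-control bins", {
  lay <- genome_layout(c(chr1 = 1e6), bin_size = 2.5e5)
  g <- bin_grid(lay)
  mk <- function(counts) { x <- g; x$count <- counts; x }
  s <- mk(c(100L, 50L, 100L, 0L))
  ctl <- list(mk(c(100L, 100L, 100L, 0L)), mk(c(100L, 100L, 100L, 0L)))
  pr <- normalize_dosage(s, ctl)
  # percent depths sum to one
  expect_equal(sum(pr$percent), 1, tolerance = 1e-12)
  # sample percent equal to control mean -> 2; half -> 1
  expect_equal(pr$normalized[1], 2 * (100 / 250) / (100 / 300))
  frac <- (pr$percent / (ctl[[1]]$count / 300))[1:3]
  expect_equal(pr$normalized[1:3], 2 * frac)
  # bin with zero control mean is masked, not divided
  expect_true(is.na(pr$normalized[4]))
  # a sample identical to the controls normalizes to exactly 2
  expect_equal(normalize_dosage(ctl[[1]], ctl)$normalized[1:3],
               rep(2, 3))
  expect_error(normalize_dosage(s, ctl[1]), "two control")
  g2 <- bin_grid(genome_layout(c(chrX = 1e6), bin_size = 2.5e5))
  bad <- g2; bad$count <- c(1L, 1L, 1L, 1L)
  expect_error(normalize_dosage(s, list(bad, bad)), "different grid")
  zero <- mk(rep(0L, 4))
  expect_error(normalize_dosage(s, list(zero, ctl[[1]])), "> 0 total")
})

test_that("dosage calling reads states off the bin medians", {
  lay <- tiny_layout(3)
  g <- bin_grid(lay)
  base <- as.data.frame(g)
  base$count <- 60L
  base$percent <- 1 / nrow(g)
  mkprof <- function(norm) {
    p <- base; p$normalized <- norm
    class(p) <- c("dosage_profile", "data.frame"); p
  }
  n <- nrow(g) / 3
  # chr1 ~1, chr2/chr3 ~2
  prof <- mkprof(c(rep(1, n), rep(2, 2 * n)) + rep(c(-.05, .05), 30))
  call <- call_dosage(prof)
  expect_equal(unname(call$states["chr1"]), "monosomic")
  expect_equal(unname(call$states["chr2"]), "disomic")
  expect_equal(nrow(call$segments), 0)

  # a >=8-bin run at 2.5 on an otherwise disomic chromosome is reported
  v <- rep(2, nrow(g)); v[21:30] <- 2.5
  call2 <- call_dosage(mkprof(v))
  expect_equal(unname(call2$states["chr2"]), "disomic")
  expect_equal(nrow(call2$segments), 1)
  expect_equal(call2$segments$chrom, "chr2")
  expect_equal(call2$segments$mean_normalized, 2.5)
  # shorter runs are not
  v[21:30] <- 2; v[31:37] <- 2.5
  expect_equal(nrow(call_dosage(mkprof(v))$segments), 0)

  # all-masked chromosome is "other" with a flag
  v2 <- rep(2, nrow(g)); v2[1:n] <- NA
  call3 <- call_dosage(mkprof(v2))
  expect_equal(unname(call3$states["chr1"]), "other")
  expect_equal(call3$uninformative, "chr1")
})

test_that("normalized dosage is invariant to uniform coverage scaling", {
  lay <- tiny_layout()
  cr <- simulate_cross(lay, sim_config(seed = 17), c(f1 = 3))
  ctl <- lapply(1:2, function(i)
    hapscreen:::simulate_bin_counts(cr$offspring[[i]], lay, 30, 100 + i))
  s1 <- hapscreen:::simulate_bin_counts(cr$offspring[[3]], lay, 30, 55)
  s4 <- hapscreen:::simulate_bin_counts(cr$offspring[[3]], lay, 120, 56)
  p1 <- normalize_dosage(s1, ctl)
  p4 <- normalize_dosage(s4, ctl)
  # 4x coverage, same genome: normalized values agree in expectation
  expect_equal(median(p1$normalized), median(p4$normalized),
               tolerance = 0.05)
  expect_equal(mean(p4$normalized) / mean(p1$normalized), 1,
               tolerance = 0.05)
})

test_that("controls normalized against their own set sit at two", {
  lay <- tiny_layout()
  cr <- simulate_cross(lay, sim_config(seed = 23), c(f1 = 4))
  counts <- lapply(1:4, function(i)
    hapscreen:::simulate_bin_counts(cr$offspring[[i]], lay, 30, 200 + i))
  for (i in 1:4) {
    pr <- normalize_dosage(counts[[i]], counts)
    expect_gt(median(pr$normalized), 1.9)
    expect_lt(median(pr$normalized), 2.1)
  }
})

test_that("dosage recovers simulated karyotypes through the full pipeline", {
  seeds <- 1:6
  for (s in seeds) {
    cls <- c("f1", "aneuploid_mono7")[s %% 2 + 1]
    fam <- sim_family_sams(seed = 300 + s, cls = cls)
    res <- dosage_pipeline(fam$sample_sam, fam$control_sams, fam$layout)
    truth <- fam$cross$offspring[[5]]$copy_number
    want <- ifelse(truth == 1, "monosomic",
                   ifelse(truth == 2, "disomic", "trisomic"))
    expect_equal(res$call$states, want)
  }
  # segmental three-copy state on an otherwise disomic chromosome;
  # high depth so per-bin noise cannot break the deviation run
  fam <- sim_family_sams(seed = 451, cls = "f1", depth = 100)
  lay <- fam$layout; cfg <- fam$config
  seg <- set_segment_copy(fam$cross$offspring[[5]], "chr3", 0, 2e6, 3L)
  p <- tempfile(fileext = ".sam")
  write_alignments(seg, lay, cfg, p)
  res <- dosage_pipeline(p, fam$control_sams, lay)
  expect_equal(unname(res$call$states["chr3"]), "disomic")
  expect_true("chr3" %in% res$call$segments$chrom)
  seg_row <- res$call$segments[res$call$segments$chrom == "chr3", ]
  expect_gt(seg_row$mean_normalized[1], 2.5)
})

test_that("whole-genome duplication is invisible to relative dosage", {
  fam <- sim_family_sams(seed = 77, cls = "eliminated_tetraploid")
  res <- dosage_pipeline(fam$sample_sam, fam$control_sams, fam$layout)
  expect_true(all(res$call$states == "disomic"))
  expect_equal(unname(median(res$profile$normalized, na.rm = TRUE)), 2,
               tolerance = 0.05)
})

test_that("per-chromosome normalization option erases chromosome signal", {
  fam <- sim_family_sams(seed = 88, cls = "aneuploid_mono7")
  grid <- bin_grid(fam$layout)
  binned <- function(p) bin_reads(filter_reads(read_alignments(p)), grid)
  s <- binned(fam$sample_sam)
  ctl <- lapply(fam$control_sams, binned)
  per_sample <- normalize_dosage(s, ctl)
  per_chrom <- normalize_dosage(s, ctl, per_chromosome = TRUE)
  m7 <- function(p) median(p$normalized[p$chrom == "chr7"], na.rm = TRUE)
  expect_lt(m7(per_sample), 1.2)    # monosomy visible
  expect_gt(m7(per_chrom), 1.8)     # audit mode: signal normalized away
})
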