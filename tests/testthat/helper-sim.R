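# shared small-genome fixtures built in code

tiny_layout <- function(nchrom = 9, len = 5e6)
  genome_layout(stats::setNames(rep(len, nchrom), paste0("chr", 1:nchrom)))

# simulate one offspring of `cls` plus n_controls f1 controls and write
# all SAMs; returns list of paths + truth objects
sim_family_sams <- function(seed, cls = "aneuploid_mono7",
                            n_controls = 4, depth = 30, dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  lay <- tiny_layout()
  cfg <- sim_config(seed = seed, depth_per_copy = depth)
  mix <- stats::setNames(c(n_controls, 1), c("f1", cls))
  cr <- simulate_cross(lay, cfg, mix)
  ctl <- file.path(dir, sprintf("ctl%d.sam", seq_len(n_controls)))
  for (i in seq_len(n_controls))
    write_alignments(cr$offspring[[i]], lay, cfg, ctl[i])
  smp <- file.path(dir, "sample.sam")
  write_alignments(cr$offspring[[n_controls + 1]], lay, cfg, smp)
  list(layout = lay, config = cfg, cross = cr,
       sample_sam = smp, control_sams = ctl)
}

# a handwritten six-record SAM exercising every filter branch
handmade_sam <- function(path) {
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:5000000",
    "@SQ\tSN:chr2\tLN:5000000",
    "r1\t99\tchr1\t124925\t60\t150M\t=\t125100\t0\t*\t*",
    "r2\t99\tchr1\t249925\t60\t150M\t=\t250100\t0\t*\t*",
    "r3\t99\tchr1\t1000\t30\t150M\t=\t1200\t0\t*\t*",
    "r4\t77\tchr1\t2000\t60\t150M\t=\t2200\t0\t*\t*",
    "r5\t83\tchr1\t3000\t60\t150M\tchr2\t3200\t0\t*\t*",
    "r6\t147\tchr2\t4000\t60\t150M\t=\t4200\t0\t*\t*"),
    path)
  path
}
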