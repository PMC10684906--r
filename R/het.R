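#' Read variant records from a VCF file
#'
#' Loads a single-sample VCF (via \pkg{vcfR}) into the flat record
#' table the heterozygosity scan operates on: position, site QUAL,
#' INFO/DP, INFO/SCBZ and the sample genotype reduced to its
#' zygosity.  Genotype classification uses the GT field only — the two
#' alleles equal and reference is \code{hom_ref}, equal and non-reference
#' \code{hom_alt}, different \code{het}, absent \code{missing} — so
#' multi-allelic records need no special handling.
#'
#' @param path Path to a VCF (4.x) file.
#' @return Data.frame with columns \code{chrom, pos, qual, dp, scbz,
#'   genotype}.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  dp <- suppressWarnings(vcfR::extract.info(v, "DP", as.numeric = TRUE))
  scbz <- suppressWarnings(vcfR::extract.info(v, "SCBZ", as.numeric = TRUE))
  gt_raw <- if (ncol(v@gt) >= 2) v@gt[, 2] else rep(NA_character_, nrow(fix))
  # strip any trailing FORMAT subfields, keep GT
  gt_raw <- sub(":.*$", "", gt_raw)
  genotype <- gt_zygosity(gt_raw)
  data.frame(chrom = fix[, "CHROM"],
             pos = as.integer(fix[, "POS"]),
             qual = as.numeric(fix[, "QUAL"]),
             dp = dp,
             scbz = scbz,
             genotype = genotype,
             stringsAsFactors = FALSE)
}

# zygosity from a GT string ("0/1", "1|1", ...)
gt_zygosity <- function(gt) {
  out <- rep("missing", length(gt))
  known <- !is.na(gt) & !grepl("\\.", gt)
  al <- strsplit(gt[known], "[/|]")
  z <- vapply(al, function(a) {
    u <- unique(a)
    if (length(u) > 1L) "het"
    else if (identical(u, "0")) "hom_ref"
    else "hom_alt"
  }, character(1))
  out[known] <- z
  out
}

#' Apply variant post-filters and retain heterozygous calls
#'
#' Retains exactly the records with QUAL > 140, DP <= 50, SCBZ <= 0
#' and a heterozygous genotype — the complement of the exclusion
#' expression \code{QUAL <= 140 || DP > 50 || SCBZ > 0} followed by
#' removal of homozygous calls.  Records discarded by each clause are
#' tallied in the \code{discarded} attribute.  A record with no SCBZ
#' annotation passes that clause by default (counted under
#' \code{scbz_missing}) so the scan runs on third-party call sets;
#' \code{strict_scbz = TRUE} drops such records instead.  The filter
#' is idempotent: filtering its own output changes nothing.
#'
#' @param records Data.frame from \code{\link{read_variants}}.
#' @param strict_scbz Drop records with missing SCBZ (default FALSE).
#' @return The retained heterozygous subset, with attribute
#'   \code{discarded} (named counts per clause) and
#'   \code{scbz_missing} (count of records lacking SCBZ).
#' @export
filter_variants <- function(records, strict_scbz = FALSE) {
  fail_qual <- is.na(records$qual) | records$qual <= 140
  fail_dp <- is.na(records$dp) | records$dp > 50
  scbz_na <- is.na(records$scbz)
  fail_scbz <- (!scbz_na & records$scbz > 0) | (scbz_na & strict_scbz)
  not_het <- records$genotype != "het"
  keep <- !(fail_qual | fail_dp | fail_scbz | not_het)
  out <- records[keep, , drop = FALSE]
  attr(out, "discarded") <- c(qual = sum(fail_qual), dp = sum(fail_dp),
                              scbz = sum(fail_scbz),
                              not_het = sum(not_het),
                              total = sum(!keep))
  attr(out, "scbz_missing") <- sum(scbz_na)
  if (sum(scbz_na) > 0 && !strict_scbz)
    warning(sum(scbz_na), " record(s) lack SCBZ; passed that clause")
  out
}

#' Count heterozygous SNPs in genome bins
#'
#' Each retained heterozygous SNP increments exactly one bin by its
#' mapped position under the half-open convention shared with the
#' dosage module; totals are conserved.
#'
#' @param het Filtered data.frame (needs \code{chrom}, \code{pos}).
#' @param grid A \code{bin_grid}.
#' @param sample_id Sample label.
#' @return A \code{het_profile}: the grid plus integer
#'   \code{het_count}.
#' @export
bin_het_snps <- function(het, grid, sample_id = "sample") {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- integer(nrow(grid))
  if (nrow(het)) {
    idx <- assign_bin(het$chrom, het$pos, grid)
    tab <- table(paste(het$chrom, idx, sep = ":"))
    m <- match(names(tab), grid_key(grid))
    counts[m] <- as.integer(tab)
  }
  out <- as.data.frame(grid)
  out$het_count <- counts
  attr(out, "sample_id") <- sample_id
  attr(out, "bin_size") <- attr(grid, "bin_size")
  class(out) <- c("het_profile", "data.frame")
  out
}

#' Detect chromosome- or genome-wide heterozygosity loss
#'
#' A chromosome is called \code{reduced} when the median of its per-bin
#' heterozygous-SNP counts falls below \code{threshold} times the
#' median of the pooled control bins for that chromosome; a genome-wide
#' reduction is reported when every chromosome is reduced.  A
#' chromosome whose control median is zero carries no information and
#' is called \code{normal} with a flag.
#'
#' @param sample A \code{het_profile}.
#' @param controls List of at least two \code{het_profile}s on the same
#'   grid.
#' @param threshold Fraction of the control median below which a
#'   chromosome is reduced (default 0.10, chosen so Poisson
#'   fluctuation in an outbred control never trips it at realistic SNP
#'   densities).
#' @return A list of class \code{het_loss_call}: \code{per_chrom}
#'   (named character over normal/reduced), \code{genome_wide}
#'   (\code{"normal"} or \code{"genome_wide_reduction"}),
#'   \code{sample_medians}, \code{control_medians} and
#'   \code{uninformative} chromosomes.
#' @export
detect_het_loss <- function(sample, controls, threshold = 0.10) {
  stopifnot(inherits(sample, "het_profile"))
  if (length(controls) < 2)
    stop("at least two control profiles are required")
  key <- paste(sample$chrom, sample$bin, sep = ":")
  for (ctl in controls)
    if (!identical(paste(ctl$chrom, ctl$bin, sep = ":"), key))
      stop("control binned on a different grid than the sample")
  chroms <- unique(sample$chrom)
  verdict <- character(0); sm <- numeric(0); cm <- numeric(0)
  uninf <- character(0)
  for (ch in chroms) {
    s_med <- stats::median(sample$het_count[sample$chrom == ch])
    pooled <- unlist(lapply(controls, function(x)
      x$het_count[x$chrom == ch]))
    c_med <- stats::median(pooled)
    sm[ch] <- s_med; cm[ch] <- c_med
    if (c_med == 0) {
      verdict[ch] <- "normal"
      uninf <- c(uninf, ch)
    } else {
      verdict[ch] <- if (s_med < threshold * c_med) "reduced" else "normal"
    }
  }
  gw <- if (all(verdict == "reduced")) "genome_wide_reduction" else "normal"
  structure(list(per_chrom = verdict, genome_wide = gw,
                 sample_medians = sm, control_medians = cm,
                 uninformative = uninf),
            class = "het_loss_call")
}

#' @export
print.het_loss_call <- function(x, ...) {
  cat("<het_loss_call> genome-wide:", x$genome_wide, "\n")
  for (ch in names(x$per_chrom))
    cat(sprintf("  %-6s %-8s (sample median %.0f, control median %.0f)\n",
                ch, x$per_chrom[ch], x$sample_medians[ch],
                x$control_medians[ch]))
  invisible(x)
}

#' Run the full heterozygosity pipeline on VCF files
#'
#' @param sample_vcf Path to the sample VCF.
#' @param control_vcfs Character vector (>= 2) of control VCF paths.
#' @param layout A \code{genome_layout}.
#' @param threshold Passed to \code{\link{detect_het_loss}}.
#' @return List with \code{profile} (\code{het_profile}) and
#'   \code{call} (\code{het_loss_call}).
#' @export
het_pipeline <- function(sample_vcf, control_vcfs, layout,
                         threshold = 0.10) {
  grid <- bin_grid(layout)
  prof <- function(p, id) bin_het_snps(filter_variants(read_variants(p)),
                                       grid, sample_id = id)
  sp <- prof(sample_vcf, basename(sample_vcf))
  cps <- lapply(control_vcfs, function(p) prof(p, basename(p)))
  list(profile = sp, call = detect_het_loss(sp, cps, threshold))
}

#' Write a heterozygosity profile as TSV
#'
#' Per-bin table (chromosome, bin start, het count) from which
#' heterozygosity tracks are plotted.
#'
#' @param profile A \code{het_profile}.
#' @param path Output TSV path.
#' @export
write_het_tsv <- function(profile, path) {
  utils::write.table(profile[, c("chrom", "start", "het_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
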