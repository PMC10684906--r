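# Independent brute-force oracles.  These deliberately re-derive every
# quantity from the raw file text through a different code path
# (read.table on whole lines, per-record arithmetic) than the package
# uses, so agreement is evidence, not tautology.

# per-bin retained-read recount straight off a SAM file
oracle_sam_bin_counts <- function(path, bin_size = 250000) {
  lines <- readLines(path)
  body <- lines[!grepl("^@", lines)]
  if (!length(body))
    return(data.frame(chrom = character(0), bin = integer(0),
                      n = integer(0)))
  df <- utils::read.table(text = body, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:11))
  keep <- df$V2 %in% c(83, 99, 147, 163) & df$V5 == 60 & df$V7 == "="
  df <- df[keep, ]
  reflen <- ifelse(grepl("^[0-9]+M$", df$V6),
                   as.integer(sub("M$", "", df$V6)), 0L)
  mid <- df$V4 + reflen %/% 2
  agg <- stats::aggregate(list(n = mid),
                          by = list(chrom = df$V3,
                                    bin = mid %/% bin_size),
                          FUN = length)
  agg[order(agg$chrom, agg$bin), ]
}

# tally of filter-failing records by category, straight off a SAM file
oracle_sam_decoys <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^@", lines)]
  df <- utils::read.table(text = body, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = paste0("V", 1:11))
  c(bad_flag = sum(!(df$V2 %in% c(83, 99, 147, 163))),
    bad_mapq = sum(df$V5 != 60),
    bad_mate = sum(df$V7 != "="))
}

# flat record table straight off a VCF file
oracle_vcf_records <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "id", "ref",
                                        "alt", "qual", "filter", "info",
                                        "format", "gt"))
  getinfo <- function(key) {
    m <- regmatches(df$info,
                    regexpr(paste0("(?<=", key, "=)[-0-9.]+"),
                            df$info, perl = TRUE))
    out <- rep(NA_real_, nrow(df))
    hit <- grepl(paste0(key, "="), df$info)
    out[hit] <- as.numeric(m)
    out
  }
  df$dp <- getinfo("DP")
  df$scbz <- getinfo("SCBZ")
  a1 <- substr(df$gt, 1, 1); a2 <- substr(df$gt, 3, 3)
  df$zyg <- ifelse(a1 != a2, "het",
                   ifelse(a1 == "0", "hom_ref", "hom_alt"))
  df
}

# post-filter heterozygous-SNP recount per bin, straight off a VCF
oracle_vcf_het_bins <- function(path, bin_size = 250000) {
  df <- oracle_vcf_records(path)
  keep <- df$qual > 140 & df$dp <= 50 & df$scbz <= 0 & df$zyg == "het"
  df <- df[keep, ]
  if (!nrow(df))
    return(data.frame(chrom = character(0), bin = integer(0),
                      n = integer(0)))
  agg <- stats::aggregate(list(n = df$pos),
                          by = list(chrom = df$chrom,
                                    bin = df$pos %/% bin_size),
                          FUN = length)
  agg[order(agg$chrom, agg$bin), ]
}

# compare a package binned-count table against an oracle recount
expect_counts_match_oracle <- function(binned, oracle) {
  pk <- binned[binned$count > 0, c("chrom", "bin", "count")]
  pk <- pk[order(pk$chrom, pk$bin), ]
  expect_equal(pk$chrom, oracle$chrom)
  expect_equal(pk$bin, oracle$bin)
  expect_equal(pk$count, oracle$n)
}
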