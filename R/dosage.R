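#' Read alignment records from a SAM file
#'
#' Loads the fields of a SAM file that the dosage filters operate on
#' (FLAG, RNAME, POS, MAPQ, RNEXT) plus the read's mid position,
#' computed as POS + floor(aligned_length / 2) with the aligned length
#' taken from the CIGAR reference-consuming operations (M/D/N/=/X; a
#' \code{*} CIGAR contributes 0).  The filter semantics are defined on
#' the raw SAM columns — notably the literal \code{"="} mate-reference
#' marker — so the text fields are consumed directly; a line with fewer
#' than 11 tab-separated fields is skipped and tallied, never fatal.
#'
#' @param path Path to a headered SAM file.
#' @return Data.frame with columns \code{qname, flag, chrom, pos, mapq,
#'   rnext, mid}; attribute \code{n_malformed} counts skipped lines.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 11L
  n_bad <- sum(!ok)
  if (n_bad > 0)
    warning(n_bad, " malformed SAM line(s) skipped")
  fields <- fields[ok]
  # flat extraction of the i-th field of every record (records vary in
  # field count past 11, so offsets rather than a matrix)
  flat <- unlist(fields, use.names = FALSE)
  starts <- cumsum(c(1L, lengths(fields)[-length(fields)]))
  get <- function(i) flat[starts + (i - 1L)]
  cigar <- get(6)
  out <- data.frame(qname = get(1),
                    flag = as.integer(get(2)),
                    chrom = get(3),
                    pos = as.integer(get(4)),
                    mapq = as.integer(get(5)),
                    rnext = get(7),
                    stringsAsFactors = FALSE)
  out$mid <- out$pos + cigar_ref_len(cigar) %/% 2L
  attr(out, "n_malformed") <- n_bad
  out
}

# reference-consuming length of CIGAR strings (M, D, N, =, X);
# vectorized fast path for the ubiquitous single-M form
cigar_ref_len <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  rest <- which(!simple & cigar != "*")
  out[rest] <- vapply(cigar[rest], function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  out
}

# FLAG values of a properly paired, mapped mate in either orientation
PROPER_PAIR_FLAGS <- c(83L, 99L, 147L, 163L)

#' Filter alignment records for dosage analysis
#'
#' Retains exactly the records that are properly paired and uniquely
#' mapped with the mate on the same contig: FLAG in \{83, 99, 147,
#' 163\}, RNEXT \code{"="}, MAPQ exactly 60 (the aligner's
#' unique-mapping value).  Input order is preserved; the number of
#' records discarded by each criterion is attached as an attribute
#' (a record failing several criteria is tallied under each).
#'
#' @param reads Data.frame from \code{\link{read_alignments}}.
#' @return The retained subset, with attribute \code{discarded}: a
#'   named integer vector (bad_flag, bad_mapq, bad_mate, total).
#' @examples
#' \dontrun{filter_reads(read_alignments("sample.sam"))}
#' @export
filter_reads <- function(reads) {
  bad_flag <- !(reads$flag %in% PROPER_PAIR_FLAGS)
  bad_mapq <- reads$mapq != 60L
  bad_mate <- reads$rnext != "="
  keep <- !(bad_flag | bad_mapq | bad_mate)
  out <- reads[keep, , drop = FALSE]
  attr(out, "discarded") <- c(bad_flag = sum(bad_flag),
                              bad_mapq = sum(bad_mapq),
                              bad_mate = sum(bad_mate),
                              total = sum(!keep))
  out
}

#' Count retained reads in genome bins
#'
#' Each retained record increments exactly one bin, chosen by its mid
#' position under the shared half-open convention (see
#' \code{\link{bin_grid}}).  Totals are conserved: the bin counts sum
#' to the number of input records.
#'
#' @param reads Filtered data.frame (needs \code{chrom} and \code{mid}).
#' @param grid A \code{bin_grid}.
#' @return The grid with an integer \code{count} column appended.
#' @export
bin_reads <- function(reads, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- integer(nrow(grid))
  if (nrow(reads)) {
    idx <- assign_bin(reads$chrom, reads$mid, grid)
    key <- paste(reads$chrom, idx, sep = ":")
    tab <- table(key)
    m <- match(names(tab), grid_key(grid))
    counts[m] <- as.integer(tab)
  }
  out <- grid
  out$count <- counts
  out
}

#' Normalize binned read depth against euploid controls
#'
#' Converts raw per-bin counts to percent depth (bin count divided by
#' the sample's total retained reads) and normalizes each bin by the
#' mean percent depth of the control samples in that bin, times two, so
#' that a value of 2 represents the diploid copy number.  Bins where
#' the control mean is zero are masked (NA), not divided, so bin
#' indices stay aligned across samples.  The method is relative:
#' whole-genome duplication or haploidy leaves every normalized value
#' at 2 and is invisible by design.
#'
#' @param sample_counts Binned counts for the sample
#'   (\code{\link{bin_reads}} output).
#' @param control_counts List of at least two binned-count data.frames
#'   for euploid controls, on the identical grid.
#' @param sample_id Sample label.
#' @param per_chromosome If TRUE, percent depth is computed within each
#'   chromosome (an alternative normalization retained for audit);
#'   default FALSE, per-sample, which preserves whole-chromosome dosage
#'   signal.
#' @return A \code{dosage_profile}: the grid plus \code{count},
#'   \code{percent} and \code{normalized} columns.
#' @export
normalize_dosage <- function(sample_counts, control_counts,
                             sample_id = "sample",
                             per_chromosome = FALSE) {
  if (!is.list(control_counts) || inherits(control_counts, "data.frame"))
    stop("control_counts must be a list of binned-count data.frames")
  if (length(control_counts) < 2)
    stop("at least two control profiles are required")
  key <- grid_key(sample_counts)
  for (ctl in control_counts)
    if (!identical(grid_key(ctl), key))
      stop("control binned on a different grid than the sample")
  if (any(vapply(control_counts, function(x) sum(x$count), 0) == 0))
    stop("every control must have > 0 total reads")

  pct <- function(x) {
    if (per_chromosome) {
      tot <- stats::ave(x$count, x$chrom, FUN = sum)
      ifelse(tot > 0, x$count / tot, 0)
    } else x$count / sum(x$count)
  }
  sp <- pct(sample_counts)
  cp <- rowMeans(vapply(control_counts, pct, numeric(nrow(sample_counts))))
  out <- as.data.frame(sample_counts)
  out$percent <- sp
  out$normalized <- ifelse(cp > 0, 2 * sp / cp, NA_real_)
  attr(out, "sample_id") <- sample_id
  attr(out, "bin_size") <- attr(sample_counts, "bin_size")
  class(out) <- c("dosage_profile", "data.frame")
  out
}

#' Call chromosome and segmental dosage states
#'
#' Assigns each chromosome a copy state from the median of its
#' normalized bin values (defaults: < 1.5 monosomic, [1.5, 2.5)
#' disomic, [2.5, 3.5) trisomic, else other) and reports segmental
#' anomalies as maximal runs of at least \code{min_run} consecutive
#' unmasked bins deviating from the chromosome's state value by more
#' than \code{deviation}.  A chromosome whose bins are all masked is
#' called \code{other} and flagged uninformative.
#'
#' @param profile A \code{dosage_profile}.
#' @param thresholds Numeric length 3: monosomic/disomic,
#'   disomic/trisomic and trisomic/other boundaries.
#' @param min_run Minimum run length for a segmental anomaly (default 8
#'   bins, i.e. 2 Mb at 250-kb bins).
#' @param deviation Minimum absolute deviation of a bin from the
#'   chromosome state value to count toward a run (default 0.4).
#' @return A list of class \code{dosage_call}: \code{states} (named
#'   character vector per chromosome), \code{chrom_medians},
#'   \code{segments} (data.frame chrom/start_bin/end_bin/start/end/
#'   mean_normalized) and \code{uninformative} (character vector).
#' @export
call_dosage <- function(profile, thresholds = c(1.5, 2.5, 3.5),
                        min_run = 8L, deviation = 0.4) {
  stopifnot(inherits(profile, "dosage_profile"),
            length(thresholds) == 3, !is.unsorted(thresholds))
  chroms <- unique(profile$chrom)
  states <- character(0); meds <- numeric(0); uninf <- character(0)
  segs <- list()
  state_value <- c(monosomic = 1, disomic = 2, trisomic = 3)
  for (ch in chroms) {
    v <- profile$normalized[profile$chrom == ch]
    g <- profile[profile$chrom == ch, ]
    if (all(is.na(v))) {
      states[ch] <- "other"; meds[ch] <- NA_real_
      uninf <- c(uninf, ch)
      next
    }
    med <- stats::median(v, na.rm = TRUE)
    st <- if (med < thresholds[1]) "monosomic"
          else if (med < thresholds[2]) "disomic"
          else if (med < thresholds[3]) "trisomic"
          else "other"
    states[ch] <- st; meds[ch] <- med
    ref <- if (st %in% names(state_value)) state_value[[st]] else med
    dev <- !is.na(v) & abs(v - ref) > deviation
    r <- rle(dev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_run)
    for (j in hit) {
      i1 <- starts[j]; i2 <- ends[j]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_bin = g$bin[i1], end_bin = g$bin[i2],
        start = g$start[i1], end = g$end[i2],
        mean_normalized = mean(v[i1:i2], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start_bin = integer(0),
               end_bin = integer(0), start = integer(0),
               end = integer(0), mean_normalized = numeric(0))
  structure(list(states = states, chrom_medians = meds,
                 segments = segments, uninformative = uninf),
            class = "dosage_call")
}

#' @export
print.dosage_call <- function(x, ...) {
  cat("<dosage_call>\n")
  for (ch in names(x$states))
    cat(sprintf("  %-6s %-10s (median %.2f)\n", ch, x$states[ch],
                x$chrom_medians[ch]))
  if (nrow(x$segments)) {
    cat("  segmental anomalies:\n")
    print(x$segments)
  } else cat("  no segmental anomalies\n")
  invisible(x)
}

#' Run the full dosage pipeline on SAM files
#'
#' Convenience wrapper: read, filter and bin the sample and each
#' control SAM, normalize, and call dosage states.
#'
#' @param sample_sam Path to the sample SAM.
#' @param control_sams Character vector (>= 2) of control SAM paths.
#' @param layout A \code{genome_layout}.
#' @param ... Passed to \code{\link{call_dosage}}.
#' @return List with \code{profile} (\code{dosage_profile}) and
#'   \code{call} (\code{dosage_call}).
#' @export
dosage_pipeline <- function(sample_sam, control_sams, layout, ...) {
  grid <- bin_grid(layout)
  binned <- function(p) bin_reads(filter_reads(read_alignments(p)), grid)
  prof <- normalize_dosage(binned(sample_sam),
                           lapply(control_sams, binned),
                           sample_id = basename(sample_sam))
  list(profile = prof, call = call_dosage(prof, ...))
}

#' Write a dosage profile as TSV
#'
#' Emits the per-bin table (chromosome, bin start, bin end, raw count,
#' percent depth, normalized value) that karyotype plots are drawn
#' from.
#'
#' @param profile A \code{dosage_profile}.
#' @param path Output TSV path.
#' @export
write_dosage_tsv <- function(profile, path) {
  utils::write.table(
    profile[, c("chrom", "start", "end", "count", "percent", "normalized")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
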