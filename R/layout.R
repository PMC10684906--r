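#' Genome layout for binned analyses
#'
#' Describes the chromosome complement over which reads, variants and
#' copy-number states are binned.  The default is a nine-chromosome toy
#' genome of 5 Mb per chromosome (20 bins of 250 kb each), small enough
#' that full simulated pipelines run in seconds; the binning arithmetic
#' is identical at real genome sizes.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in
#'   base pairs.  Names are the chromosome identifiers used in SAM/VCF
#'   output.  Default: \code{chr1}..\code{chr9}, 5 Mb each.
#' @param bin_size Bin width in base pairs (default 250000, the window
#'   size used throughout the dosage and heterozygosity analyses).
#' @return An object of class \code{genome_layout}: a list with
#'   \code{chrom_names}, \code{chrom_lengths} and \code{bin_size}.
#' @examples
#' lay <- genome_layout()
#' length(lay$chrom_names)  # 9
#' @export
genome_layout <- function(chrom_lengths = stats::setNames(rep(5e6, 9),
                                                          paste0("chr", 1:9)),
                          bin_size = 250000L) {
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)))
    stop("chrom_lengths must have unique names")
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L) stop("bin_size must be > 0")
  if (any(chrom_lengths < 2 * bin_size))
    stop("every chromosome must span at least two bins")
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 bin_size = bin_size),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom_names), " chromosomes, ",
      "bin size ", x$bin_size, " bp\n", sep = "")
  invisible(x)
}

#' Bin grid over a genome layout
#'
#' Tiles each chromosome with half-open bins \code{[start, start + bin_size)}
#' in 0-based coordinates; the last bin of each chromosome is truncated at
#' the chromosome end.  The same grid object is shared by the dosage and
#' heterozygosity modules so bin boundaries can never drift between them.
#'
#' @param layout A \code{genome_layout}.
#' @return A \code{bin_grid}: a data.frame with columns \code{chrom},
#'   \code{bin} (0-based index within chromosome), \code{start} (0-based,
#'   inclusive) and \code{end} (exclusive).
#' @examples
#' head(bin_grid(genome_layout()))
#' @export
bin_grid <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  b <- layout$bin_size
  rows <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = b)
    data.frame(chrom = ch,
               bin = seq_along(starts) - 1L,
               start = starts,
               end = pmin(starts + b, len),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  attr(g, "bin_size") <- b
  attr(g, "chrom_lengths") <- layout$chrom_lengths
  class(g) <- c("bin_grid", "data.frame")
  g
}

#' Assign 1-based positions to grid bins
#'
#' Maps a genomic coordinate to its bin index under the shared half-open
#' convention \code{floor(pos / bin_size)}: bin 0 holds positions
#' 0..249999, so position 125,000 is interior to bin 0 and position
#' 250,000 is the first position of bin 1 when bins are 250 kb wide.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of positions.
#' @param grid A \code{bin_grid}.
#' @return Integer vector of 0-based bin indices within each chromosome.
#' @keywords internal
assign_bin <- function(chrom, pos, grid) {
  lens <- attr(grid, "chrom_lengths")
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown))
    stop("chromosome(s) absent from bin grid: ",
         paste(unknown, collapse = ", "))
  b <- attr(grid, "bin_size")
  idx <- as.numeric(pos) %/% b
  # clamp positions at/past the chromosome end into the final (truncated) bin
  nbins <- (as.numeric(lens[chrom]) - 1) %/% b
  as.integer(pmin(pmax(idx, 0), nbins))
}

# key of one grid row, used for joins between profiles
grid_key <- function(g) paste(g$chrom, g$bin, sep = ":")
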