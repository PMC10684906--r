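#' Locate fluorescence peaks in a flow-cytometry sample
#'
#' Nuclei stained with a stoichiometric DNA dye (e.g. propidium
#' iodide) fluoresce in proportion to DNA content, so a population of
#' G1 nuclei forms a peak whose position tracks ploidy.  The events
#' are first debris-gated (values below \code{gate_fraction} of the
#' global mode position are dropped), then histogrammed on
#' \code{n_bins} log-spaced bins, smoothed with a moving average of
#' window \code{smooth}, and local maxima extracted.  The requested
#' number of highest modes is returned in ascending position; each
#' peak's median is computed over the events within ±20\% of its mode.
#' If fewer separable modes than requested are found, the found peaks
#' are returned with a \code{merged} flag — the signature of two
#' samples of equal DNA content mixed in one tube.
#'
#' @param values Positive per-nucleus fluorescence intensities
#'   (>= 200 events after gating).
#' @param expected_peaks 1 (single sample) or 2 (mixed preparation).
#' @param n_bins Histogram bins (default 64, log-spaced; instrument
#'   intensities span decades).
#' @param smooth Moving-average window (default 3 bins).
#' @param gate_fraction Debris gate as a fraction of the global mode
#'   position (default 0.10).
#' @param min_separation Minimum fold-difference in position between
#'   two reported modes (default 1.25).  Local maxima closer than this
#'   are histogram noise on one peak's flank and are merged into the
#'   higher mode; distinct ploidy classes differ by at least 4/3.
#' @return A data.frame of class \code{peak_estimates} with one row
#'   per peak: \code{mode}, \code{median}, \code{lower}, \code{upper},
#'   \code{n_events}; attribute \code{merged} is TRUE when fewer peaks
#'   than requested were separable.
#' @export
find_peaks <- function(values, expected_peaks = 1L, n_bins = 64L,
                       smooth = 3L, gate_fraction = 0.10,
                       min_separation = 1.25) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("zero events")
  if (any(values <= 0)) stop("fluorescence values must be positive")
  if (length(values) < 200)
    stop("need at least 200 events, got ", length(values))
  stopifnot(expected_peaks %in% c(1L, 2L))

  hist_modes <- function(v) {
    br <- exp(seq(log(min(v)) - 1e-9, log(max(v)) + 1e-9,
                  length.out = n_bins + 1L))
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    k <- smooth
    sm <- stats::filter(h$counts, rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    sm <- as.numeric(sm)
    # local maxima (plateaus count once, at their first bin)
    n <- length(sm)
    left <- c(Inf, sm[-n]); right <- c(sm[-1], -Inf)
    peaks <- which(sm > left & sm >= right & sm > 0)
    centers <- sqrt(h$breaks[-length(h$breaks)] * h$breaks[-1])
    list(pos = centers[peaks], height = sm[peaks])
  }

  # debris gate against the pre-gate global mode
  m0 <- hist_modes(values)
  global_mode <- m0$pos[which.max(m0$height)]
  gated <- values[values >= gate_fraction * global_mode]
  if (length(gated) == 0) stop("zero events after gating")

  m <- hist_modes(gated)
  ord <- order(m$height, decreasing = TRUE)
  # greedily accept modes, highest first, requiring positional separation
  take <- numeric(0)
  for (p in m$pos[ord]) {
    if (length(take) == expected_peaks) break
    if (all(pmax(p / take, take / p) >= min_separation))
      take <- c(take, p)
  }
  merged <- length(take) < expected_peaks
  take <- sort(take)
  rows <- lapply(take, function(p) {
    inpk <- gated[gated >= 0.8 * p & gated <= 1.2 * p]
    data.frame(mode = p, median = stats::median(inpk),
               lower = 0.8 * p, upper = 1.2 * p,
               n_events = length(inpk))
  })
  out <- do.call(rbind, rows)
  attr(out, "merged") <- merged
  attr(out, "n_gated") <- length(gated)
  class(out) <- c("peak_estimates", "data.frame")
  out
}

#' Estimate ploidy from peak medians
#'
#' Relative nuclear DNA content is the ratio of the sample's peak
#' median to the diploid reference's peak median; the nominal ploidy
#' is that ratio times the reference ploidy, rounded to the nearest
#' integer.  In \code{mixed} mode both genotypes were prepared and
#' stained in one tube and \code{sample_peaks} holds both peaks of the
#' mixture, the lower one taken as the reference (the diploid
#' standard); no separate reference is used, which cancels
#' preparation-dependent staining differences.
#'
#' @param sample_peaks \code{peak_estimates} for the sample (in mixed
#'   mode: the two-peak estimate of the mixture).
#' @param reference_peaks \code{peak_estimates} for the diploid
#'   reference (ignored in mixed mode).
#' @param reference_ploidy Ploidy of the reference standard
#'   (default 2).
#' @param mode \code{"separate"} or \code{"mixed"}.
#' @return A list of class \code{ploidy_call}: \code{ratio},
#'   \code{nominal_ploidy}, \code{mode}, \code{sample_median},
#'   \code{reference_median}.
#' @examples
#' \dontrun{estimate_ploidy(find_peaks(s), find_peaks(ref))}
#' @export
estimate_ploidy <- function(sample_peaks, reference_peaks = NULL,
                            reference_ploidy = 2,
                            mode = c("separate", "mixed")) {
  mode <- match.arg(mode)
  if (mode == "separate") {
    if (is.null(reference_peaks) || nrow(reference_peaks) < 1)
      stop("reference peak missing")
    s_med <- sample_peaks$median[which.max(sample_peaks$n_events)]
    r_med <- reference_peaks$median[which.max(reference_peaks$n_events)]
  } else {
    if (nrow(sample_peaks) < 2)
      stop("mixed mode requires two peaks in the mixture ",
           "(merged peaks mean equal DNA content)")
    r_med <- sample_peaks$median[1]   # peaks are in ascending position
    s_med <- sample_peaks$median[2]
  }
  if (!isTRUE(r_med > 0)) stop("reference median is zero or missing")
  ratio <- s_med / r_med
  structure(list(ratio = ratio,
                 nominal_ploidy = max(1L, as.integer(round(
                   ratio * reference_ploidy))),
                 mode = mode,
                 sample_median = s_med, reference_median = r_med),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> ratio %.3f -> nominal ploidy %d (%s prep)\n",
              x$ratio, x$nominal_ploidy, x$mode))
  invisible(x)
}

#' Read a flow-cytometry event table
#'
#' @param path CSV with header \code{sample_id,fluorescence}, one
#'   event per row.
#' @return Data.frame with those columns.
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fluorescence")
  if (!all(need %in% names(df)))
    stop("flow CSV must have columns: ", paste(need, collapse = ", "))
  df
}
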