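#' Classify seedlings from PACE endpoint fluorescence
#'
#' A PACE (PCR allele-competitive extension) assay reads the edited
#' CENH3 locus through two allele-specific primers carrying distinct
#' fluorophores: FAM reports the wild-type allele, HEX the cenh3-edited
#' allele.  Classification uses the allele fraction
#' \code{r = fam / (fam + hex)}:
#' \itemize{
#'   \item \code{r >= t_high}: FAM-only — homozygous wild type, a
#'     \emph{candidate} for genome elimination;
#'   \item \code{r <= t_low}: HEX-only — homozygous edited, a
#'     \emph{self}-pollination;
#'   \item \code{r} inside the F1 band: both fluorophores in roughly
#'     equal amounts — an \emph{f1};
#'   \item anywhere else (the gaps between bands): \emph{no_call}.
#' }
#' A seedling with no signal in either channel is a no_call flagged
#' \code{signal_absent} rather than an error, so plate-scale input is
#' never aborted by one failed well.
#'
#' @param fam,hex Non-negative endpoint intensities (vectorized).
#' @param thresholds List with \code{t_low}, \code{t_high} and
#'   \code{f1_band} (length-2).  Defaults 0.15 / 0.85 / c(0.30, 0.70).
#' @return Character vector over \{self, f1, candidate, no_call\} with
#'   attribute \code{signal_absent}, a logical vector marking wells
#'   with fam = hex = 0.
#' @examples
#' classify_pace(c(0.95, 0.5, 0), c(0.02, 0.5, 1))
#' @export
classify_pace <- function(fam, hex, thresholds = pace_thresholds()) {
  t_low <- thresholds$t_low; t_high <- thresholds$t_high
  band <- thresholds$f1_band
  if (!(0 < t_low && t_low < 0.5 && 0.5 < t_high && t_high < 1))
    stop("thresholds must satisfy 0 < t_low < 0.5 < t_high < 1")
  if (!(band[1] > t_low && band[2] < t_high && band[1] < 0.5 &&
        band[2] > 0.5))
    stop("f1_band must lie strictly between t_low and t_high around 0.5")
  if (any(fam < 0) || any(hex < 0))
    stop("fluorescence intensities must be non-negative")
  n <- max(length(fam), length(hex))
  fam <- rep_len(fam, n); hex <- rep_len(hex, n)
  absent <- fam == 0 & hex == 0
  r <- ifelse(absent, NA_real_, fam / (fam + hex))
  out <- rep("no_call", n)
  out[!absent & r >= t_high] <- "candidate"
  out[!absent & r <= t_low] <- "self"
  out[!absent & r >= band[1] & r <= band[2]] <- "f1"
  attr(out, "signal_absent") <- absent
  out
}

#' Default PACE classification thresholds
#'
#' Symmetric allele-fraction bands with explicit no-call gaps: "only"
#' one fluorophore means an allele fraction beyond 0.85 (or below
#' 0.15), "approximately equal" means within [0.30, 0.70].
#'
#' @param t_low,t_high Homozygote cutoffs.
#' @param f1_band Length-2 heterozygote band.
#' @return A list usable as the \code{thresholds} argument of
#'   \code{\link{classify_pace}}.
#' @export
pace_thresholds <- function(t_low = 0.15, t_high = 0.85,
                            f1_band = c(0.30, 0.70)) {
  list(t_low = t_low, t_high = t_high, f1_band = f1_band)
}

#' Classify seedlings from Sanger genotype calls
#'
#' Maps the manually read genotype at the edited-locus target window to
#' the progeny class: homozygous edited is a self-pollination,
#' heterozygous an F1, homozygous wild type a genome-elimination
#' candidate, and an ambiguous chromatogram a no_call.
#'
#' @param genotype Character vector over \{hom_edited, het,
#'   hom_wildtype, ambiguous\}.
#' @return Character vector over \{self, f1, candidate, no_call\}.
#' @examples
#' classify_sanger(c("hom_wildtype", "het", "ambiguous"))
#' @export
classify_sanger <- function(genotype) {
  map <- c(hom_edited = "self", het = "f1",
           hom_wildtype = "candidate", ambiguous = "no_call")
  bad <- setdiff(unique(genotype), names(map))
  if (length(bad))
    stop("unknown Sanger genotype: ", paste(bad, collapse = ", "))
  unname(map[genotype])
}

# round half-up (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize one cross's progeny screen
#'
#' Tallies the class labels of a cross's seedlings and computes the
#' self-pollination rate as 100 * self / (surveyed - no-calls), rounded
#' half-up to one decimal.  If seed counts are supplied, the
#' germination rate 100 * germinated / sown is reported the same way.
#'
#' @param classes Character vector of per-seedling labels over
#'   \{self, f1, candidate, no_call\}.
#' @param cross_id Cross identifier.
#' @param seeds_sown,seeds_germinated Optional seed counts for the
#'   germination rate.
#' @return A one-row data.frame of class \code{cross_summary} with
#'   columns cross_id, total, f1, candidate, self, no_call,
#'   self_rate and germination_rate (NA when seed counts absent).
#' @examples
#' summarize_cross(rep(c("f1", "self"), c(142, 8)), "RP71")
#' @export
summarize_cross <- function(classes, cross_id,
                            seeds_sown = NULL, seeds_germinated = NULL) {
  if (!length(classes)) stop("no progeny")
  bad <- setdiff(unique(classes), c("self", "f1", "candidate", "no_call"))
  if (length(bad))
    stop("unknown progeny class: ", paste(bad, collapse = ", "))
  n <- length(classes)
  cnt <- function(k) sum(classes == k)
  callable <- n - cnt("no_call")
  self_rate <- if (callable > 0)
    round_half_up(100 * cnt("self") / callable, 1) else NA_real_
  germ <- if (!is.null(seeds_sown) && !is.null(seeds_germinated)) {
    stopifnot(seeds_sown > 0, seeds_germinated >= 0,
              seeds_germinated <= seeds_sown)
    round_half_up(100 * seeds_germinated / seeds_sown, 1)
  } else NA_real_
  out <- data.frame(cross_id = cross_id, total = n,
                    f1 = cnt("f1"), candidate = cnt("candidate"),
                    self = cnt("self"), no_call = cnt("no_call"),
                    self_rate = self_rate, germination_rate = germ,
                    stringsAsFactors = FALSE)
  class(out) <- c("cross_summary", "data.frame")
  out
}

#' Aggregate several cross summaries into screen totals
#'
#' @param summaries List of \code{cross_summary} rows (or a data.frame
#'   of them).  Cross ids must be unique.
#' @return A one-row data.frame with total surveyed, total f1, total
#'   candidates, total self and total no-calls across the screen.
#' @export
aggregate_screen <- function(summaries) {
  if (inherits(summaries, "data.frame")) summaries <- list(summaries)
  if (!length(summaries)) stop("no summaries")
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  if (anyDuplicated(tab$cross_id))
    stop("duplicate cross ids: ",
         paste(unique(tab$cross_id[duplicated(tab$cross_id)]),
               collapse = ", "))
  data.frame(crosses = nrow(tab),
             total = sum(tab$total), f1 = sum(tab$f1),
             candidate = sum(tab$candidate), self = sum(tab$self),
             no_call = sum(tab$no_call))
}

#' Read a PACE signal table
#'
#' @param path CSV with header \code{seedling_id,fam,hex}.
#' @return Data.frame with those columns.
#' @export
read_pace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seedling_id", "fam", "hex")
  if (!all(need %in% names(df)))
    stop("PACE CSV must have columns: ", paste(need, collapse = ", "))
  df
}
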