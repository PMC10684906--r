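#' Call the parental origin of one diagnostic marker locus
#'
#' Parents are genotyped at diagnostic loci where each is homozygous;
#' the progeny call is presence-based: homozygous for parent A's allele
#' is \code{A_only}, homozygous for parent B's \code{B_only}, carrying
#' both \code{both}, any allele matching neither parent
#' \code{inconsistent}, and a locus where the parents share an allele
#' set is \code{uninformative}.  Genotypes are allele strings such as
#' \code{"G/G"}, \code{"G/T"} or \code{"G"} (separator \code{/} or
#' \code{|}; order irrelevant).
#'
#' @param parentA_gt,parentB_gt,progeny_gt Character vectors of
#'   genotypes (recycled to common length).
#' @return Character vector over \{A_only, B_only, both, inconsistent,
#'   uninformative\}.
#' @examples
#' call_marker_origin("G/G", "T/T", c("T/T", "G/T", "C/C"))
#' @export
call_marker_origin <- function(parentA_gt, parentB_gt, progeny_gt) {
  n <- max(length(parentA_gt), length(parentB_gt), length(progeny_gt))
  parentA_gt <- rep_len(parentA_gt, n)
  parentB_gt <- rep_len(parentB_gt, n)
  progeny_gt <- rep_len(progeny_gt, n)
  al <- function(gt) lapply(strsplit(gt, "[/|]"), unique)
  aA <- al(parentA_gt); aB <- al(parentB_gt); aP <- al(progeny_gt)
  vapply(seq_len(n), function(i) {
    if (setequal(aA[[i]], aB[[i]])) return("uninformative")
    inA <- aP[[i]] %in% aA[[i]]
    inB <- aP[[i]] %in% aB[[i]]
    if (any(!inA & !inB)) return("inconsistent")
    hasA <- any(inA); hasB <- any(inB)
    if (hasA && hasB) "both" else if (hasA) "A_only" else "B_only"
  }, character(1))
}

#' Infer nuclear lineage from per-locus origin calls
#'
#' All informative loci assigned exclusively to one parent gives a
#' uniparental verdict for that parent; any locus carrying both
#' parental alleles gives \code{biparental}; conflicting exclusive
#' calls, or any inconsistent call, withholds a verdict
#' (\code{mixed}).  One discordant locus suffices to withhold a
#' uniparental verdict — the conclusion rests on full concordance
#' across the marker panel.
#'
#' @param calls Character vector of per-locus calls from
#'   \code{\link{call_marker_origin}}.
#' @return A list of class \code{lineage_verdict}: \code{verdict} over
#'   \{uniparental_A, uniparental_B, biparental, mixed\} and
#'   \code{counts}, the tally per call category.
#' @examples
#' infer_nuclear_lineage(rep("B_only", 18))
#' @export
infer_nuclear_lineage <- function(calls) {
  valid <- c("A_only", "B_only", "both", "inconsistent", "uninformative")
  bad <- setdiff(unique(calls), valid)
  if (length(bad))
    stop("unknown origin call: ", paste(bad, collapse = ", "))
  counts <- vapply(valid, function(k) sum(calls == k), integer(1))
  informative <- calls[calls != "uninformative"]
  if (!length(informative)) stop("no informative markers")
  verdict <-
    if (any(informative == "inconsistent")) "mixed"
    else if (any(informative == "both")) "biparental"
    else if (all(informative == "A_only")) "uniparental_A"
    else if (all(informative == "B_only")) "uniparental_B"
    else "mixed"   # exclusive calls for both parents at different loci
  structure(list(verdict = verdict, counts = counts),
            class = "lineage_verdict")
}

#' @export
print.lineage_verdict <- function(x, ...) {
  cat("<lineage_verdict>", x$verdict, "\n")
  print(x$counts)
  invisible(x)
}

#' Identify the maternal parent from an organellar haplotype
#'
#' Organellar (mitochondrial) inheritance is uniparental-maternal, so
#' the parent whose haplotype exactly matches the progeny at the
#' diagnostic region is the maternal parent.  The parents must differ
#' at the region, and the progeny must match exactly one of them.
#'
#' @param progeny_hap Progeny haplotype string.
#' @param parent_haps Named character vector of length 2: the parental
#'   haplotypes.
#' @return Name of the maternal parent.
#' @examples
#' infer_maternal_parent("ATCG", c(mut = "ATCG", wt = "ATCA"))
#' @export
infer_maternal_parent <- function(progeny_hap, parent_haps) {
  if (length(parent_haps) != 2 || is.null(names(parent_haps)))
    stop("parent_haps must be a named vector of two haplotypes")
  if (parent_haps[[1]] == parent_haps[[2]])
    stop("uninformative organellar marker: parental haplotypes identical")
  hit <- names(parent_haps)[parent_haps == progeny_hap]
  if (length(hit) != 1)
    stop("maternity indeterminate: progeny matches neither parent")
  hit
}

#' Read a nuclear marker genotype table
#'
#' @param path CSV with header
#'   \code{locus_id,chrom,parentA_gt,parentB_gt,progeny_gt}.
#' @return Data.frame with those columns.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "chrom", "parentA_gt", "parentB_gt", "progeny_gt")
  if (!all(need %in% names(df)))
    stop("marker CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Run the full lineage assignment on a marker table
#'
#' @param markers Data.frame as from \code{\link{read_marker_csv}} or
#'   \code{\link{marker_genotypes}}.
#' @return List with per-locus \code{calls} (data.frame locus_id,
#'   chrom, origin) and the \code{verdict}
#'   (\code{lineage_verdict}).
#' @export
lineage_pipeline <- function(markers) {
  origin <- call_marker_origin(markers$parentA_gt, markers$parentB_gt,
                               markers$progeny_gt)
  list(calls = data.frame(locus_id = markers$locus_id,
                          chrom = markers$chrom, origin = origin,
                          stringsAsFactors = FALSE),
       verdict = infer_nuclear_lineage(origin))
}
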