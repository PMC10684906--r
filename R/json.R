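#' Write an analysis call as JSON
#'
#' Serializes a \code{dosage_call}, \code{het_loss_call},
#' \code{lineage_verdict} or \code{ploidy_call} to a JSON file, the
#' machine-readable counterpart of the per-bin TSV substrates.
#'
#' @param call One of the call objects above.
#' @param path Output path.
#' @export
write_call_json <- function(call, path) {
  stopifnot(inherits(call, c("dosage_call", "het_loss_call",
                             "lineage_verdict", "ploidy_call")))
  x <- lapply(unclass(call), function(el) {
    if (is.data.frame(el)) el else as.list(el)
  })
  x$call_type <- class(call)[1]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
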