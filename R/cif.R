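#' Clinical Impact Factors
#'
#' The five Clinical Impact Factor (CIF) categories into which audit and
#' inspection findings are mapped. Two belong to the human-subject-protection
#' area (informed consent, safety) and three to reliability of trial results
#' (data integrity, protecting primary endpoints, sponsor oversight).
#'
#' @return Character vector of the five CIF identifiers, in a fixed order.
#' @export
#' @examples
#' cif_names()
cif_names <- function() {
  c("consent", "data_integrity", "protecting_primary_endpoints",
    "safety", "sponsor_oversight")
}

#' @keywords internal
finding_cols <- function() paste0("findings_", cif_names())

`%||%` <- function(a, b) if (is.null(a)) b else a
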