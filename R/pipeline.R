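# Cross-module pipeline recipes.

find_sample <- function(samples, patient, compartment) {
  hit <- Filter(function(s) s$patient_id == patient &&
                  s$compartment == compartment, samples)
  if (length(hit) == 0) NULL else hit[[1]]
}

#' Tissue-enriched sub-repertoire for one patient
#'
#' Convenience recipe: calls clones enriched in `compartment` versus
#' `versus` ([call_enriched()]) for one patient and returns the enriched
#' restriction of the `compartment` sample ([enriched_subrepertoire()]).
#' With `compartment = "ADJACENT_LUNG"`, `versus = "PBMC"` this is the
#' "lung-enriched repertoire (versus paired PBMC)"; with `versus = "TUMOR"`
#' it is the lung repertoire enriched compared to the tumor, the variable
#' used for survival stratification.
#'
#' @param samples named list of [tcr_sample()] objects.
#' @param patient patient identifier.
#' @param compartment compartment to restrict.
#' @param versus comparison compartment.
#' @param min_total,alpha passed to [call_enriched()].
#' @return A `tcr_sample` (possibly empty), or `NULL` when either sample is
#'   missing for this patient.
#' @export
tissue_enriched_sample <- function(samples, patient,
                                   compartment = "ADJACENT_LUNG",
                                   versus = "PBMC",
                                   min_total = 5, alpha = 0.1) {
  a <- find_sample(samples, patient, compartment)
  b <- find_sample(samples, patient, versus)
  if (is.null(a) || is.null(b)) return(NULL)
  enr <- call_enriched(a, b, min_total = min_total, alpha = alpha)
  suppressWarnings(enriched_subrepertoire(a, enr, side = "A"))
}

#' Per-patient clonality of a tissue-enriched repertoire
#'
#' @inheritParams tissue_enriched_sample
#' @return Data frame `patient_id`, `clonality` (NA where either sample is
#'   missing or the enriched restriction is empty).
#' @export
enriched_clonality_table <- function(samples, compartment = "ADJACENT_LUNG",
                                     versus = "TUMOR", min_total = 5,
                                     alpha = 0.1) {
  pts <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  rows <- lapply(pts, function(p) {
    s <- tissue_enriched_sample(samples, p, compartment, versus,
                                min_total, alpha)
    val <- if (is.null(s) || nrow(s$clones) == 0) NA_real_ else clonality(s)
    data.frame(patient_id = p, clonality = val, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
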