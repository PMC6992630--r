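#' TCR repertoire sample container
#'
#' A `tcr_sample` holds the set of unique TCR-beta rearrangements (clones)
#' observed in one tissue sample, plus the normalization metadata needed for
#' the per-sample repertoire attributes. Clones are stored as a data frame
#' with one row per unique rearrangement.
#'
#' @param clones data frame with columns `cdr3_aa` (uppercase amino-acid
#'   CDR3), `cdr3_nt` (nucleotide sequence or `NA`), `v_gene`, `j_gene`
#'   (normalized labels), `templates` (positive integer count) and
#'   `productive` (logical).
#' @param sample_id,patient_id identifiers.
#' @param compartment one of `"PBMC"`, `"ADJACENT_LUNG"`, `"TUMOR"`,
#'   `"HEALTHY_LUNG"`, `"COPD_LUNG"`.
#' @param usable_input positive number: total nucleated-cell equivalents (or
#'   DNA mass) usable for TCR sequencing, the denominator of T cell density.
#'   `NA` if unknown.
#' @param parse_report optional list attached by [read_rearrangements()].
#' @return An object of class `tcr_sample`: a list with elements `sample_id`,
#'   `patient_id`, `compartment`, `clones`, `total_templates` (recomputed as
#'   the sum of clone templates, never trusted from file), `usable_input`
#'   and `parse_report`.
#' @export
tcr_sample <- function(clones, sample_id, patient_id = NA_character_,
                       compartment = c("PBMC", "ADJACENT_LUNG", "TUMOR",
                                       "HEALTHY_LUNG", "COPD_LUNG"),
                       usable_input = NA_real_, parse_report = NULL) {
  compartment <- match.arg(compartment)
  required <- c("cdr3_aa", "v_gene", "j_gene", "templates", "productive")
  missing_cols <- setdiff(required, names(clones))
  if (length(missing_cols) > 0)
    stop("clones table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"cdr3_nt" %in% names(clones)) clones$cdr3_nt <- NA_character_
  clones$templates <- as.integer(clones$templates)
  if (nrow(clones) > 0 && any(clones$templates < 1))
    stop("retained clones must have templates >= 1")
  bad_aa <- clones$productive &
    (is.na(clones$cdr3_aa) | clones$cdr3_aa == "" | grepl("\\*", clones$cdr3_aa))
  if (any(bad_aa))
    stop("productive clones must have a non-empty CDR3 without stop codons")
  rownames(clones) <- NULL
  structure(
    list(sample_id = sample_id,
         patient_id = patient_id,
         compartment = compartment,
         clones = clones[, c("cdr3_aa", "cdr3_nt", "v_gene", "j_gene",
                             "templates", "productive")],
         total_templates = sum(clones$templates),
         usable_input = usable_input,
         parse_report = parse_report),
    class = "tcr_sample")
}

#' @export
print.tcr_sample <- function(x, ...) {
  cat(sprintf("<tcr_sample> %s  [%s, patient %s]\n",
              x$sample_id, x$compartment, x$patient_id))
  cat(sprintf("  %d clones, %d templates (%d productive clones)\n",
              nrow(x$clones), x$total_templates, sum(x$clones$productive)))
  if (!is.na(x$usable_input))
    cat(sprintf("  usable input: %s nucleated-cell equivalents\n",
                format(x$usable_input, big.mark = ",")))
  invisible(x)
}

#' @export
summary.tcr_sample <- function(object, ...) {
  p <- productive_filter(object)
  cat(sprintf("Sample %s (%s):\n", object$sample_id, object$compartment))
  cat(sprintf("  clones: %d total, %d productive\n",
              nrow(object$clones), nrow(p$clones)))
  cat(sprintf("  templates: %d total, %d productive\n",
              object$total_templates, p$total_templates))
  if (nrow(p$clones) >= 1)
    cat(sprintf("  clonality (productive): %.4f\n", clonality(p)))
  invisible(object)
}

#' Restrict a sample to productive rearrangements
#'
#' Keeps only clones with `productive = TRUE` and recomputes the template
#' total. All downstream repertoire attributes in this package are computed
#' on productive-only repertoires (the assay's out-of-frame and stop-codon
#' rearrangements carry no antigen-receptor information).
#'
#' @param sample a [tcr_sample()].
#' @return A `tcr_sample` with non-productive clones removed. If no clone is
#'   productive, an empty repertoire is returned with a warning; downstream
#'   operations decide how to treat it.
#' @export
productive_filter <- function(sample) {
  stopifnot(inherits(sample, "tcr_sample"))
  keep <- sample$clones[sample$clones$productive, , drop = FALSE]
  if (nrow(keep) == 0 && nrow(sample$clones) > 0)
    warning("no productive clones in sample ", sample$sample_id)
  out <- sample
  out$clones <- keep
  rownames(out$clones) <- NULL
  out$total_templates <- sum(keep$templates)
  out
}

#' Clone identity keys for a sample
#'
#' The pipeline supports two clone-identity conventions: amino-acid-only
#' (`"aa"`, collapsing convergent recombination; the default used by the
#' overlap and differential-abundance stages) and amino acid plus V/J gene
#' (`"aa_vj"`).
#'
#' @param sample a [tcr_sample()], or a clone data frame.
#' @param key `"aa"` or `"aa_vj"`.
#' @return Character vector of clone keys, one per clone row.
#' @export
clone_keys <- function(sample, key = c("aa", "aa_vj")) {
  key <- match.arg(key)
  cl <- if (inherits(sample, "tcr_sample")) sample$clones else sample
  if (key == "aa") cl$cdr3_aa
  else paste(cl$cdr3_aa, cl$v_gene, cl$j_gene, sep = "|")
}

#' Aggregate clone counts by identity key
#'
#' @param sample a [tcr_sample()].
#' @param key identity convention, see [clone_keys()].
#' @param productive_only restrict to productive clones first (default TRUE).
#' @return Named integer vector of template counts per unique clone key.
#' @export
clone_counts <- function(sample, key = c("aa", "aa_vj"), productive_only = TRUE) {
  key <- match.arg(key)
  s <- if (productive_only) suppressWarnings(productive_filter(sample)) else sample
  if (nrow(s$clones) == 0) return(integer(0))
  k <- clone_keys(s, key)
  counts <- tapply(s$clones$templates, k, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
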