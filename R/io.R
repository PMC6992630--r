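# Reading/writing rearrangement tables and the cohort manifest.

the_dialects <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- yaml::read_yaml(system.file("extdata", "dialects.yaml",
                                            package = "tcrep"))
    cache
  }
})

the_gene_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- utils::read.delim(
        system.file("extdata", "trb_gene_synonyms.tsv", package = "tcrep"),
        stringsAsFactors = FALSE)
    cache
  }
})

#' Normalize a TCR-beta V/J gene name
#'
#' Maps immunoSEQ-style names (`"TCRBV09-01"`) and IMGT-style names
#' (`"TRBV9"`, optionally with an allele suffix such as `"*01"`) onto a single
#' canonical IMGT-style label, so that V-gene usage can be compared across
#' vendor dialects. Resolution is table-driven (a bundled synonym table) with
#' a rule-based fallback (strip the `TCRB` prefix to `TRB`, drop zero padding,
#' drop the allele). Names that cannot be interpreted map to the sentinel
#' `"unresolved"` and are never dropped silently.
#'
#' The function is idempotent: canonical labels map to themselves.
#'
#' @param raw character vector of gene names.
#' @return Character vector of canonical labels (or `"unresolved"`).
#' @export
#' @examples
#' normalize_gene_name(c("TCRBV09-01", "TRBV9", "TCRBJ02-07", "garbage##"))
normalize_gene_name <- function(raw) {
  tab <- the_gene_table()
  vapply(raw, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return("unresolved")
    up <- toupper(trimws(x))
    up <- sub("\\*[0-9]+$", "", up)          # strip allele
    hit <- tab$canonical[match(up, tab$raw)]
    if (!is.na(hit)) return(hit)
    if (grepl("^TRB[VJ][0-9]+(-[0-9]+)?$", up)) return(up)  # already canonical
    if (grepl("^TCRB[VJ][0-9]+(-[0-9]+)?$", up)) {
      type <- substr(up, 5, 5)
      body <- substr(up, 6, nchar(up))
      parts <- strsplit(body, "-", fixed = TRUE)[[1]]
      fam <- as.integer(parts[1])
      cand <- paste0("TRB", type, fam)
      if (length(parts) > 1) cand <- paste0(cand, "-", as.integer(parts[2]))
      hit <- tab$canonical[match(cand, tab$raw)]
      if (!is.na(hit)) return(hit)
      if (cand %in% tab$canonical) return(cand)
      # single-member family written with a gene part the table lacks
      nodash <- paste0("TRB", type, fam)
      if (nodash %in% tab$canonical) return(nodash)
      return(cand)
    }
    "unresolved"
  }, character(1), USE.NAMES = FALSE)
}

#' Read a rearrangement table into a repertoire sample
#'
#' Parses one sample's rearrangement TSV (one row per unique rearrangement)
#' in either the immunoSEQ dialect (`nucleotide`, `aminoAcid`,
#' `count (templates)`, `vGeneName`, `jGeneName`, `sequenceStatus`) or the
#' AIRR-style dialect (`junction`, `junction_aa`, `duplicate_count`,
#' `v_call`, `j_call`, `productive`). Gene names are normalized via
#' [normalize_gene_name()]; rows with zero templates are dropped; duplicate
#' `(cdr3_aa, v_gene, j_gene)` rows are merged by summing templates. A parse
#' report (rows read / dropped / merged / failed) is attached to the sample.
#'
#' @param path file path.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @param sample_id identifier (defaults to the file name without extension).
#' @param patient_id,compartment,usable_input metadata passed to
#'   [tcr_sample()].
#' @return A validated [tcr_sample()].
#' @export
read_rearrangements <- function(path, dialect = c("immunoseq", "airr"),
                                sample_id = NULL, patient_id = NA_character_,
                                compartment = "PBMC", usable_input = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- the_dialects()[[dialect]]
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- unlist(spec$columns, use.names = FALSE)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0)
    stop("format error: required column(s) missing for dialect '", dialect,
         "': ", paste(absent, collapse = ", "))
  if (nrow(raw) == 0) stop("no rearrangements in ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]+$", "", basename(path))

  n_read <- nrow(raw)
  counts <- suppressWarnings(as.numeric(raw[[spec$columns$templates]]))
  bad <- is.na(counts) | counts != floor(counts) | counts < 0
  if (sum(bad) > 0.01 * n_read)
    stop("file rejected: ", sum(bad), "/", n_read,
         " rows have unparseable template counts")
  prod_raw <- raw[[spec$columns$productive]]
  productive <- prod_raw %in% unlist(spec$productive_true)

  cl <- data.frame(
    cdr3_aa = toupper(raw[[spec$columns$cdr3_aa]]),
    cdr3_nt = raw[[spec$columns$cdr3_nt]],
    v_gene = normalize_gene_name(raw[[spec$columns$v_gene]]),
    j_gene = normalize_gene_name(raw[[spec$columns$j_gene]]),
    templates = counts,
    productive = productive,
    stringsAsFactors = FALSE)
  cl <- cl[!bad, , drop = FALSE]
  n_zero <- sum(cl$templates == 0)
  cl <- cl[cl$templates > 0, , drop = FALSE]
  if (nrow(cl) == 0) stop("no rearrangements with positive counts in ", path)

  key <- paste(cl$cdr3_aa, cl$v_gene, cl$j_gene, sep = "|")
  n_before <- nrow(cl)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    merged <- cl[first, , drop = FALSE]
    merged$templates <- as.integer(tapply(cl$templates, key, sum)[key[first]])
    # a merged clone is productive if any of its rows was
    merged$productive <- as.logical(tapply(cl$productive, key, any)[key[first]])
    cl <- merged
  }
  cl <- cl[order(-cl$templates, cl$cdr3_aa, cl$v_gene, cl$j_gene), ,
           drop = FALSE]
  report <- list(rows_read = n_read, rows_failed = sum(bad),
                 rows_zero_count = n_zero, rows_merged = n_before - nrow(cl))
  tcr_sample(cl, sample_id = sample_id, patient_id = patient_id,
             compartment = compartment, usable_input = usable_input,
             parse_report = report)
}

#' Write a repertoire sample as a rearrangement table
#'
#' Writes the sample's clone table in the requested dialect with that
#' dialect's fixed column order, so write-then-read round-trips the clone
#' multiset exactly.
#'
#' @param sample a [tcr_sample()].
#' @param path output file path.
#' @param dialect `"immunoseq"` or `"airr"`.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(sample, path,
                                 dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  spec <- the_dialects()[[dialect]]
  cl <- sample$clones
  out <- data.frame(a = cl$cdr3_nt, b = cl$cdr3_aa, c = cl$templates,
                    d = cl$v_gene, e = cl$j_gene, stringsAsFactors = FALSE)
  names(out) <- unlist(spec$columns[c("cdr3_nt", "cdr3_aa", "templates",
                                      "v_gene", "j_gene")], use.names = FALSE)
  ptrue <- unlist(spec$productive_true)[1]
  pfalse <- unlist(spec$productive_false)[1]
  out[[spec$columns$productive]] <- ifelse(cl$productive, ptrue, pfalse)
  out <- out[, unlist(spec$order), drop = FALSE]
  out[is.na(out)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest has one row per patient with clinical covariates (`age`,
#' `sex`, `histology`, `stage`, `smoking`, `tumor_size`, `os_time`,
#' `os_event`, `relapse`) plus one column per compartment holding the path of
#' that patient's rearrangement file (empty if the compartment was not
#' sampled) and optionally `usable_input_<compartment>` columns.
#'
#' @param path manifest CSV/TSV path (separator inferred from extension).
#' @param check_files verify that every referenced rearrangement file exists.
#' @return Data frame of class `tcr_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"patient_id" %in% names(m)) stop("manifest lacks 'patient_id'")
  if (anyDuplicated(m$patient_id))
    stop("duplicate patient_id rows in manifest")
  if ("os_time" %in% names(m) && any(m$os_time < 0, na.rm = TRUE))
    stop("negative os_time in manifest")
  comp_cols <- intersect(c("PBMC", "ADJACENT_LUNG", "TUMOR",
                           "HEALTHY_LUNG", "COPD_LUNG"), names(m))
  if (check_files) {
    base <- dirname(path)
    for (cc in comp_cols) {
      f <- m[[cc]]
      f <- f[!is.na(f) & nzchar(f)]
      f <- ifelse(file.exists(f), f, file.path(base, f))
      miss <- f[!file.exists(f)]
      if (length(miss) > 0)
        stop("manifest references missing file(s): ",
             paste(utils::head(miss, 3), collapse = ", "))
    }
  }
  class(m) <- c("tcr_manifest", "data.frame")
  m
}

#' Load every sample referenced by a manifest
#'
#' @param manifest a [read_manifest()] result.
#' @param dir directory paths in the manifest are relative to.
#' @param dialect rearrangement dialect.
#' @return A named list of [tcr_sample()] objects keyed by
#'   `<patient>_<compartment>`.
#' @export
load_cohort <- function(manifest, dir = ".", dialect = "immunoseq") {
  comp_cols <- intersect(c("PBMC", "ADJACENT_LUNG", "TUMOR",
                           "HEALTHY_LUNG", "COPD_LUNG"), names(manifest))
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    for (cc in comp_cols) {
      f <- manifest[[cc]][i]
      if (is.na(f) || !nzchar(f)) next
      if (!file.exists(f)) f <- file.path(dir, f)
      ui_col <- paste0("usable_input_", cc)
      ui <- if (ui_col %in% names(manifest)) manifest[[ui_col]][i] else NA_real_
      sid <- paste0(manifest$patient_id[i], "_", cc)
      out[[sid]] <- read_rearrangements(
        f, dialect = dialect, sample_id = sid,
        patient_id = manifest$patient_id[i], compartment = cc,
        usable_input = ui)
    }
  }
  out
}
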