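# Repertoire homology: Jaccard, Morisita-Horn, top-N sharing, public clones.

overlap_counts <- function(a, b, key = "aa") {
  ca <- if (inherits(a, "tcr_sample")) clone_counts(a, key) else a
  cb <- if (inherits(b, "tcr_sample")) clone_counts(b, key) else b
  list(a = ca, b = cb)
}

#' Jaccard index between two repertoires
#'
#' Shared unique clones over the union of unique clones,
#' \eqn{|A \cap B| / |A \cup B|}, on the pipeline clone-identity key
#' (amino-acid CDR3 by default). Abundance is ignored.
#'
#' @param a,b [tcr_sample()] objects (or named count vectors).
#' @param key clone identity convention (see [clone_keys()]).
#' @return Jaccard index in `[0, 1]`; `NA` with a warning if either
#'   repertoire is empty.
#' @export
jaccard_index <- function(a, b, key = "aa") {
  oc <- overlap_counts(a, b, key)
  if (length(oc$a) == 0 || length(oc$b) == 0) {
    warning("empty repertoire: Jaccard index absent")
    return(NA_real_)
  }
  ka <- names(oc$a); kb <- names(oc$b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Morisita-Horn overlap index between two repertoires
#'
#' The abundance-weighted homology score
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{(d_x + d_y)\, X\, Y}, \quad
#'       d_x = \sum_i x_i^2 / X^2,\; d_y = \sum_i y_i^2 / Y^2,}
#' summing over the union of clone keys (a clone absent from one sample
#' counts 0 there). The Morisita-Horn form is used because it is bounded in
#' `[0, 1]` and invariant to scaling either count vector.
#'
#' @inheritParams jaccard_index
#' @return Overlap in `[0, 1]`; `NA` with a warning on an empty repertoire.
#' @export
morisita_index <- function(a, b, key = "aa") {
  oc <- overlap_counts(a, b, key)
  if (length(oc$a) == 0 || length(oc$b) == 0) {
    warning("empty repertoire: Morisita index absent")
    return(NA_real_)
  }
  keys <- union(names(oc$a), names(oc$b))
  x <- rep(0, length(keys)); names(x) <- keys
  y <- x
  x[names(oc$a)] <- oc$a
  y[names(oc$b)] <- oc$b
  X <- sum(x); Y <- sum(y)
  dx <- sum(x^2) / X^2
  dy <- sum(y^2) / Y^2
  2 * sum(x * y) / ((dx + dy) * X * Y)
}

#' Sharing of the top-N most prevalent clones
#'
#' Ranks the source repertoire's clones by template count (ties broken by
#' higher count then lexicographic clone key, so results are deterministic),
#' takes the top `n`, and reports how many are detected anywhere in the
#' partner repertoire and how many of those are also within the partner's
#' own top `n` under the same ranking.
#'
#' @param source,partner [tcr_sample()] objects (or named count vectors).
#' @param n number of top clones (default 100).
#' @param key clone identity convention.
#' @return List with `n`, `detected_in_partner`, `in_partner_top_n`.
#' @export
top_n_sharing <- function(source, partner, n = 100, key = "aa") {
  stopifnot(n >= 1)
  oc <- overlap_counts(source, partner, key)
  top_keys <- function(cnt) {
    ord <- order(-cnt, names(cnt))
    names(cnt)[ord][seq_len(min(n, length(cnt)))]
  }
  ts <- top_keys(oc$a)
  tp <- top_keys(oc$b)
  detected <- sum(ts %in% names(oc$b))
  in_top <- sum(ts %in% tp)
  list(n = as.integer(n), detected_in_partner = as.integer(detected),
       in_partner_top_n = as.integer(in_top))
}

#' Public clones across patients
#'
#' Tabulates clone keys observed in at least `k` distinct patients, with
#' per-compartment patient-occurrence counts.
#'
#' @param samples list of [tcr_sample()] objects covering >= 2 patients.
#' @param k minimum number of patients (default 2; `k = 1` lists every
#'   observed clone).
#' @param key clone identity convention.
#' @return Data frame: `clone`, `n_patients`, then one column per
#'   compartment with the number of distinct patients carrying the clone
#'   there.
#' @export
public_clones <- function(samples, k = 2, key = "aa") {
  pts <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  if (length(pts) < 2) stop("public_clones requires samples from >= 2 patients")
  recs <- do.call(rbind, lapply(samples, function(s) {
    kk <- unique(clone_keys(suppressWarnings(productive_filter(s)), key))
    if (length(kk) == 0) return(NULL)
    data.frame(clone = kk, patient = s$patient_id,
               compartment = s$compartment, stringsAsFactors = FALSE)
  }))
  recs <- unique(recs)
  by_clone <- tapply(recs$patient, recs$clone,
                     function(p) length(unique(p)))
  keep <- names(by_clone)[by_clone >= k]
  if (length(keep) == 0)
    return(data.frame(clone = character(0), n_patients = integer(0)))
  out <- data.frame(clone = keep,
                    n_patients = as.integer(by_clone[keep]),
                    stringsAsFactors = FALSE)
  for (cc in unique(recs$compartment)) {
    sub <- recs[recs$compartment == cc, ]
    cnt <- tapply(sub$patient, sub$clone, function(p) length(unique(p)))
    out[[cc]] <- as.integer(ifelse(is.na(cnt[keep]), 0, cnt[keep]))
  }
  out <- out[order(-out$n_patients, out$clone), ]
  rownames(out) <- NULL
  out
}

#' Exclusive and shared fractions of two identifier sets
#'
#' Generic set-sharing utility (e.g. for per-tissue mutation identifier
#' sets): fractions of the union found only in `a`, only in `b`, and shared.
#'
#' @param a,b character vectors of identifiers (duplicates ignored).
#' @return Named numeric vector `(frac_only_a, frac_only_b, frac_shared)`
#'   summing to 1; all-`NA` with a warning when both sets are empty.
#' @export
set_sharing <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    warning("both sets empty: sharing fractions absent")
    return(c(frac_only_a = NA_real_, frac_only_b = NA_real_,
             frac_shared = NA_real_))
  }
  shared <- length(intersect(a, b))
  c(frac_only_a = (length(a) - shared) / length(u),
    frac_only_b = (length(b) - shared) / length(u),
    frac_shared = shared / length(u))
}

#' Pairwise overlap table for a cohort
#'
#' Computes Jaccard and Morisita-Horn indices plus top-N sharing for a given
#' compartment pair in every patient that has both samples.
#'
#' @param samples named list of [tcr_sample()] objects.
#' @param pair character vector of two compartments, e.g.
#'   `c("ADJACENT_LUNG", "TUMOR")` (the first is the top-N source).
#' @param n top-N size (default 100).
#' @param key clone identity convention.
#' @return Data frame with one row per patient with both compartments.
#' @export
cohort_overlap <- function(samples, pair, n = 100, key = "aa") {
  pts <- unique(vapply(samples, `[[`, character(1), "patient_id"))
  rows <- lapply(pts, function(p) {
    sa <- Filter(function(s) s$patient_id == p && s$compartment == pair[1],
                 samples)
    sb <- Filter(function(s) s$patient_id == p && s$compartment == pair[2],
                 samples)
    if (length(sa) == 0 || length(sb) == 0) return(NULL)
    a <- sa[[1]]; b <- sb[[1]]
    tn <- top_n_sharing(a, b, n = n, key = key)
    data.frame(patient_id = p,
               jaccard = jaccard_index(a, b, key),
               morisita = morisita_index(a, b, key),
               top_n = tn$n, detected_in_partner = tn$detected_in_partner,
               in_partner_top_n = tn$in_partner_top_n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
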