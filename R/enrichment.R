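# Differential clone abundance between paired samples.

#' Exact test p-value for one clone's 2x2 count table
#'
#' Fisher's exact test on the table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`,
#' computed by direct hypergeometric enumeration over the conditional
#' support (the same two-sided rule as [stats::fisher.test()]: sum the
#' probabilities of all tables no more likely than the observed one).
#' Vectorized over clones.
#'
#' @param count_a,count_b clone template counts in samples A and B.
#' @param total_a,total_b total productive templates of samples A and B.
#' @param alternative `"two.sided"` (default), `"greater"` (enriched in A)
#'   or `"less"`.
#' @return Numeric vector of p-values.
#' @export
test_clone <- function(count_a, total_a, count_b, total_b,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  total_a <- rep_len(total_a, n); total_b <- rep_len(total_b, n)
  stopifnot(all(total_a > 0), all(total_b > 0),
            all(count_a >= 0), all(count_b >= 0),
            all(count_a <= total_a), all(count_b <= total_b))
  vapply(seq_len(n), function(i) {
    k <- count_a[i] + count_b[i]            # conditioned row margin
    A <- total_a[i]; N <- total_a[i] + total_b[i]
    lo <- max(0, k - total_b[i]); hi <- min(k, A)
    x <- lo:hi
    dens <- stats::dhyper(x, k, N - k, A)
    dobs <- stats::dhyper(count_a[i], k, N - k, A)
    p <- switch(alternative,
      two.sided = sum(dens[dens <= dobs * (1 + 1e-7)]),
      greater = sum(dens[x >= count_a[i]]),
      less = sum(dens[x <= count_a[i]]))
    min(1, p)
  }, numeric(1))
}

#' Call clones differentially abundant between two paired samples
#'
#' Applies the paired differential-abundance screen: productive repertoires,
#' amino-acid clone identity, every clone with combined count
#' `>= min_total` tested by a two-sided exact test ([test_clone()]) against
#' the two samples' productive template totals, Benjamini-Hochberg
#' adjustment across the clones tested within this pair, and a direction
#' label (`enriched_in`) for clones with `q <= alpha`. Clones absent from
#' one sample count 0 there. All tested clones are returned, called or not.
#'
#' @param a,b paired [tcr_sample()] objects from one patient.
#' @param min_total minimum combined count for a clone to be tested
#'   (default 5).
#' @param alpha FDR threshold for the enrichment call (default 0.1).
#' @return Data frame of class `tcr_enrichment`: `clone`, `count_a`,
#'   `count_b`, `total_a`, `total_b`, `p_value`, `q_value`, `enriched_in`
#'   (`"A"`, `"B"` or `"neither"`). Empty (zero rows) if no clone passes
#'   `min_total`.
#' @export
call_enriched <- function(a, b, min_total = 5, alpha = 0.1) {
  ca <- clone_counts(a, key = "aa")
  cb <- clone_counts(b, key = "aa")
  ta <- sum(ca); tb <- sum(cb)
  keys <- union(names(ca), names(cb))
  xa <- ifelse(is.na(ca[keys]), 0L, ca[keys])
  xb <- ifelse(is.na(cb[keys]), 0L, cb[keys])
  keep <- (xa + xb) >= min_total
  out <- data.frame(clone = keys[keep],
                    count_a = as.integer(xa[keep]),
                    count_b = as.integer(xb[keep]),
                    total_a = rep(as.integer(ta), sum(keep)),
                    total_b = rep(as.integer(tb), sum(keep)),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0) {
    out$p_value <- numeric(0); out$q_value <- numeric(0)
    out$enriched_in <- character(0)
    class(out) <- c("tcr_enrichment", "data.frame")
    return(out)
  }
  out$p_value <- test_clone(out$count_a, ta, out$count_b, tb)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  fa <- out$count_a / ta
  fb <- out$count_b / tb
  out$enriched_in <- ifelse(out$q_value <= alpha & fa > fb, "A",
                     ifelse(out$q_value <= alpha & fb > fa, "B", "neither"))
  out <- out[order(out$p_value, out$clone), ]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "min_total") <- min_total
  attr(out, "sample_a") <- a$sample_id
  attr(out, "sample_b") <- b$sample_id
  class(out) <- c("tcr_enrichment", "data.frame")
  out
}

#' Restrict a sample to its enriched sub-repertoire
#'
#' Keeps only the clones labeled enriched on the requested side of a
#' [call_enriched()] result (e.g. the "lung-enriched" repertoire versus
#' paired PBMC, on which clonality and homology are then recomputed).
#'
#' @param sample the [tcr_sample()] the restriction applies to.
#' @param results a [call_enriched()] result computed on a pair that
#'   includes `sample`.
#' @param side `"A"` or `"B"`: which side's enriched clones to keep
#'   (`"A"` = first argument of [call_enriched()]).
#' @return A `tcr_sample` restricted to the enriched clones (amino-acid
#'   identity); empty with a warning if nothing was enriched on that side.
#' @export
enriched_subrepertoire <- function(sample, results, side = c("A", "B")) {
  side <- match.arg(side)
  stopifnot(inherits(results, "tcr_enrichment"))
  keep_keys <- results$clone[results$enriched_in == side]
  s <- suppressWarnings(productive_filter(sample))
  keep <- clone_keys(s) %in% keep_keys
  out <- s
  out$clones <- s$clones[keep, , drop = FALSE]
  rownames(out$clones) <- NULL
  out$total_templates <- sum(out$clones$templates)
  if (nrow(out$clones) == 0)
    warning("empty enriched sub-repertoire for sample ", sample$sample_id)
  out
}
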