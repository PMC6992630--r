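# Motif-based antigen-specificity grouping of CDR3s, with viral
# classification and per-patient tissue-location proportions.

#' Trim a CDR3 to its motif-analysis window
#'
#' Removes the 3 N-terminal and 2 C-terminal residues (the germline-encoded
#' ends contribute little paratope diversity); sequences shorter than 7
#' residues are excluded from motif analysis (`NA`).
#'
#' @param cdr3 character vector of CDR3 amino-acid sequences.
#' @return Character vector of trimmed analysis substrings (`NA` for
#'   sequences shorter than 7).
#' @export
trim_cdr3 <- function(cdr3) {
  len <- nchar(cdr3)
  out <- ifelse(len >= 7, substr(cdr3, 4, len - 2), NA_character_)
  out
}

all_kmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  }), use.names = FALSE)
}

contains_motif <- function(seqs, motif) {
  grepl(motif, seqs, fixed = TRUE)
}

#' Locally enriched CDR3 motifs
#'
#' Finds k-mers (k in `k_values`) over-represented in an analysis CDR3 set
#' relative to a reference repertoire. Sequences are first trimmed with
#' [trim_cdr3()]. A k-mer present in at least 2 distinct analysis CDR3s is a
#' candidate; its fold enrichment is the fraction of analysis CDR3s
#' containing it over the fraction of reference CDR3s containing it (the
#' reference rate is floored at `0.5 / n_reference` when zero), and its
#' resampling p-value is the probability that at least the observed number
#' of `|analysis|` CDR3s drawn from the reference contain the motif,
#' estimated over `resamples` draws. Motifs with fold `>= fold_min` and
#' p `<= p_max` are returned.
#'
#' @param cdr3_set character vector of analysis CDR3s (untrimmed).
#' @param reference character vector of reference CDR3s (untrimmed); should
#'   be at least 10x the analysis set (warning otherwise).
#' @param k_values k-mer sizes (default `2:4`).
#' @param fold_min minimum fold enrichment (default 10).
#' @param p_max maximum resampling p-value (default 0.001).
#' @param resamples number of reference resamples (default 1000).
#' @param seed RNG seed for the resampling null.
#' @return Data frame of class `motif_hits`: `motif`, `k`, `observed_count`,
#'   `reference_rate`, `fold_enrichment`, `resample_p`.
#' @export
enriched_motifs <- function(cdr3_set, reference, k_values = 2:4,
                            fold_min = 10, p_max = 0.001, resamples = 1000,
                            seed = 1) {
  if (length(reference) == 0) stop("empty reference repertoire")
  an <- unique(trim_cdr3(unique(cdr3_set)))
  an <- an[!is.na(an)]
  ref <- trim_cdr3(unique(reference))
  ref <- ref[!is.na(ref)]
  if (length(ref) < 10 * length(an))
    warning("reference set is smaller than 10x the analysis set")
  n_an <- length(an); n_ref <- length(ref)

  # one tabulation pass per corpus: per-sequence-unique k-mers, so the count
  # is the number of CDR3s containing each k-mer
  an_tab <- ref_tab <- NULL
  for (k in k_values) {
    an_tab <- c(an_tab, table(all_kmers(an, k)))
    ref_tab <- c(ref_tab, table(all_kmers(ref, k)))
  }
  cand <- names(an_tab)[an_tab >= 2]
  if (length(cand) == 0)
    return(empty_motif_hits())

  obs <- as.integer(an_tab[cand])
  ref_n <- ref_tab[cand]
  ref_n[is.na(ref_n)] <- 0
  ref_rate <- pmax(as.numeric(ref_n) / n_ref, 0.5 / n_ref)
  fold <- (obs / n_an) / ref_rate
  pass_fold <- fold >= fold_min
  if (!any(pass_fold)) return(empty_motif_hits())

  cand <- cand[pass_fold]; obs <- obs[pass_fold]
  ref_rate <- ref_rate[pass_fold]; fold <- fold[pass_fold]

  # resampling null: draw analysis-sized sets from the reference
  M <- vapply(cand, function(m) contains_motif(ref, m), logical(n_ref))
  M <- matrix(as.numeric(M), nrow = n_ref)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  exceed <- numeric(length(cand))
  for (r in seq_len(resamples)) {
    idx <- sample.int(n_ref, n_an, replace = TRUE)
    cnt <- colSums(M[idx, , drop = FALSE])
    exceed <- exceed + (cnt >= obs)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  p <- exceed / resamples

  out <- data.frame(motif = cand, k = nchar(cand),
                    observed_count = as.integer(obs),
                    reference_rate = ref_rate,
                    fold_enrichment = fold, resample_p = p,
                    stringsAsFactors = FALSE)
  out <- out[out$resample_p <= p_max, , drop = FALSE]
  out <- out[order(-out$fold_enrichment, out$motif), ]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

empty_motif_hits <- function() {
  out <- data.frame(motif = character(0), k = integer(0),
                    observed_count = integer(0), reference_rate = numeric(0),
                    fold_enrichment = numeric(0), resample_p = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("motif_hits", "data.frame")
  out
}

# union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Build antigen-specificity groups
#'
#' Groups CDR3s predicted to share antigen specificity: two CDR3s are
#' related if they share an enriched local motif (from [enriched_motifs()],
#' matched within the trimmed sequence) or are globally similar (equal
#' trimmed length, Hamming distance <= 1). Groups are the connected
#' components of that relation; singletons are discarded.
#'
#' @param cdr3_table data frame with columns `cdr3_aa` and optionally
#'   `patient_id`, `sample_id`, `compartment` (member provenance, carried
#'   through).
#' @param motifs a [enriched_motifs()] result (or a character vector of
#'   motifs).
#' @return A `specificity_groups` object: list with `groups` (data frame
#'   `group_id`, `cdr3_aa`, unique per group member sequence), `members`
#'   (`cdr3_table` rows annotated with `group_id`), and `motifs_by_group`
#'   (named list of the enriched motifs occurring in each group).
#' @export
build_groups <- function(cdr3_table, motifs) {
  if (is.character(motifs)) motif_strings <- motifs
  else motif_strings <- motifs$motif
  tab <- cdr3_table
  tab$.trim <- trim_cdr3(tab$cdr3_aa)
  tab <- tab[!is.na(tab$.trim), , drop = FALSE]
  seqs <- sort(unique(tab$.trim))
  ns <- length(seqs)
  if (ns == 0) return(empty_groups(cdr3_table))
  parent <- seq_len(ns)
  union_ <- function(i, j) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
    invisible(NULL)
  }
  # local rule: same enriched motif
  linked <- logical(ns)
  for (m in motif_strings) {
    hit <- which(contains_motif(seqs, m))
    if (length(hit) >= 2) {
      linked[hit] <- TRUE
      for (h in hit[-1]) union_(hit[1], h)
    }
  }
  # global rule: equal length, Hamming distance <= 1
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) < 2) next
    mat <- do.call(rbind, strsplit(seqs[idx], ""))
    for (i in seq_len(length(idx) - 1)) {
      diffs <- colSums(t(mat[(i + 1):length(idx), , drop = FALSE]) != mat[i, ])
      near <- which(diffs <= 1)
      for (j in near) {
        union_(idx[i], idx[i + j])
        linked[idx[i]] <- TRUE; linked[idx[i + j]] <- TRUE
      }
    }
  }
  root <- vapply(seq_len(ns), function(i) uf_find(parent, i), integer(1))
  comp_size <- table(root)
  keep <- comp_size[as.character(root)] >= 2
  if (!any(keep)) return(empty_groups(cdr3_table))
  root_kept <- root[keep]
  gid <- match(root_kept, sort(unique(root_kept)))
  groups <- data.frame(group_id = sprintf("G%04d", gid),
                       trimmed = seqs[keep], stringsAsFactors = FALSE)
  tab$group_id <- groups$group_id[match(tab$.trim, groups$trimmed)]
  members <- tab[!is.na(tab$group_id), , drop = FALSE]
  members$.trim <- NULL
  rownames(members) <- NULL
  member_seq <- unique(members[, c("group_id", "cdr3_aa")])
  rownames(member_seq) <- NULL
  motifs_by_group <- lapply(split(groups$trimmed, groups$group_id), function(ss)
    motif_strings[vapply(motif_strings, function(m)
      any(contains_motif(ss, m)), logical(1))])
  structure(list(groups = member_seq[order(member_seq$group_id,
                                           member_seq$cdr3_aa), ],
                 members = members,
                 motifs_by_group = motifs_by_group),
            class = "specificity_groups")
}

empty_groups <- function(cdr3_table) {
  structure(list(groups = data.frame(group_id = character(0),
                                     cdr3_aa = character(0)),
                 members = cbind(cdr3_table[0, , drop = FALSE],
                                 group_id = character(0)),
                 motifs_by_group = list()),
            class = "specificity_groups")
}

#' @export
print.specificity_groups <- function(x, ...) {
  cat(sprintf("<specificity_groups> %d groups, %d member sequences\n",
              length(unique(x$groups$group_id)), nrow(x$groups)))
  invisible(x)
}

#' Classify specificity groups as viral or non-viral
#'
#' A group is viral when (a) at least `min_viral_members` of its member
#' CDR3s exactly match a CDR3 in the tetramer-defined viral reference and
#' (b) some V gene is enriched among the group's members relative to
#' cohort-wide V usage (one-sided Fisher's exact test p < `v_p_max`).
#'
#' @param groups a [build_groups()] result whose `members` carry a `v_gene`
#'   column.
#' @param viral_reference data frame with column `cdr3_aa` (e.g.
#'   [make_viral_reference()]).
#' @param cohort_v_usage named integer vector: clone counts per V gene over
#'   the analysis universe. `"unresolved"` entries are excluded from the
#'   Fisher table.
#' @param min_viral_members minimum exact reference matches (default 3).
#' @param v_p_max V-gene Fisher threshold (default 0.05).
#' @return Data frame, one row per group: `group_id`, `n_members`,
#'   `n_viral_members`, `v_gene_top`, `v_gene_fisher_p`, `is_viral`.
#' @export
classify_viral <- function(groups, viral_reference, cohort_v_usage,
                           min_viral_members = 3, v_p_max = 0.05) {
  stopifnot(inherits(groups, "specificity_groups"))
  mem <- groups$members
  if (nrow(mem) == 0)
    return(data.frame(group_id = character(0), n_members = integer(0),
                      n_viral_members = integer(0),
                      v_gene_top = character(0),
                      v_gene_fisher_p = numeric(0), is_viral = logical(0)))
  cohort_v_usage <- cohort_v_usage[names(cohort_v_usage) != "unresolved"]
  Nv <- sum(cohort_v_usage)
  ref_set <- unique(viral_reference$cdr3_aa)
  rows <- lapply(split(mem, mem$group_id), function(g) {
    seqs <- unique(g$cdr3_aa)
    n_viral <- sum(seqs %in% ref_set)
    gv <- g[!duplicated(g$cdr3_aa) & g$v_gene != "unresolved", , drop = FALSE]
    n_g <- nrow(gv)
    p_best <- 1; v_best <- NA_character_
    if (n_g > 0 && Nv > 0) {
      for (v in unique(gv$v_gene)) {
        if (!v %in% names(cohort_v_usage)) next
        x <- sum(gv$v_gene == v)
        Xv <- cohort_v_usage[[v]]
        p <- test_clone(x, n_g, max(Xv - x, 0), max(Nv - n_g, 1),
                        alternative = "greater")
        if (p < p_best) { p_best <- p; v_best <- v }
      }
    }
    data.frame(group_id = g$group_id[1],
               n_members = length(seqs),
               n_viral_members = as.integer(n_viral),
               v_gene_top = v_best, v_gene_fisher_p = p_best,
               is_viral = n_viral >= min_viral_members && p_best < v_p_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient tissue-location proportions of viral and non-viral motifs
#'
#' For one patient, each specificity group with patient-matched members in
#' the tumor and/or adjacent lung is categorized as `TUMOR_ONLY`,
#' `LUNG_ONLY` or `SHARED` (members in both). Because public databases are
#' skewed towards non-viral specificities, viral and non-viral groups are
#' normalized separately: each label's proportions over the three categories
#' sum to 1. `fold_shared` is the viral shared proportion over the
#' non-viral shared proportion (absent when the denominator is 0).
#'
#' @param groups a [build_groups()] result whose `members` carry
#'   `patient_id` and `compartment`.
#' @param viral_calls a [classify_viral()] result.
#' @param patient patient identifier.
#' @return List with `viral` and `nonviral` proportion vectors (or `NULL`
#'   when a label has no groups for this patient) and `fold_shared`.
#' @export
location_proportions <- function(groups, viral_calls, patient) {
  mem <- groups$members[groups$members$patient_id == patient, , drop = FALSE]
  mem <- mem[mem$compartment %in% c("TUMOR", "ADJACENT_LUNG"), , drop = FALSE]
  if (nrow(mem) == 0)
    return(list(viral = NULL, nonviral = NULL, fold_shared = NA_real_))
  loc <- vapply(split(mem, mem$group_id), function(g) {
    has_t <- any(g$compartment == "TUMOR")
    has_l <- any(g$compartment == "ADJACENT_LUNG")
    if (has_t && has_l) "SHARED" else if (has_t) "TUMOR_ONLY" else "LUNG_ONLY"
  }, character(1))
  is_viral <- stats::setNames(viral_calls$is_viral, viral_calls$group_id)
  lab <- is_viral[names(loc)]
  prop3 <- function(locs) {
    if (length(locs) == 0) return(NULL)
    cats <- c("TUMOR_ONLY", "LUNG_ONLY", "SHARED")
    tab <- table(factor(locs, levels = cats))
    stats::setNames(as.numeric(tab) / length(locs), cats)
  }
  pv <- prop3(loc[!is.na(lab) & lab])
  pn <- prop3(loc[!is.na(lab) & !lab])
  fold <- if (is.null(pv) || is.null(pn) || pn[["SHARED"]] == 0) NA_real_
          else pv[["SHARED"]] / pn[["SHARED"]]
  list(viral = pv, nonviral = pn, fold_shared = fold)
}
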