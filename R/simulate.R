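# Synthetic multi-compartment cohort generator with known ground truth.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

TRBV_UNIVERSE <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV5-4", "TRBV6-1",
                   "TRBV6-5", "TRBV7-2", "TRBV7-9", "TRBV9", "TRBV10-3",
                   "TRBV11-2", "TRBV12-3", "TRBV13", "TRBV14", "TRBV15",
                   "TRBV18", "TRBV19", "TRBV20-1", "TRBV24-1", "TRBV25-1",
                   "TRBV27", "TRBV28", "TRBV29-1", "TRBV30")
TRBJ_UNIVERSE <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

#' Random CDR3 amino-acid sequences
#'
#' Draws valid-looking TCR-beta CDR3s: uniform length between `min_len` and
#' `max_len`, fixed C/F terminal framing, interior residues uniform over the
#' 20-letter alphabet. Sequences containing any `exclude` substring are
#' rejected and redrawn (used to build motif-free decoys and references).
#'
#' @param n number of sequences.
#' @param min_len,max_len total CDR3 length range (default 8-20).
#' @param exclude character vector of forbidden substrings.
#' @return Character vector of length `n`.
#' @export
random_cdr3s <- function(n, min_len = 8, max_len = 20, exclude = character(0)) {
  draw <- function(k) {
    len <- sample(min_len:max_len, k, replace = TRUE)
    chars <- sample(AA20, sum(len - 2), replace = TRUE)
    grp <- rep.int(seq_len(k), len - 2)
    mids <- vapply(split(chars, grp), paste, character(1), collapse = "")
    paste0("C", mids, "F")
  }
  out <- draw(n)
  if (length(exclude) > 0) {
    for (iter in 1:50) {
      bad <- vapply(out, function(s) any(vapply(exclude, grepl, logical(1),
                                                x = s, fixed = TRUE)), logical(1))
      if (!any(bad)) break
      out[bad] <- draw(sum(bad))
    }
  }
  out
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: heavy-tailed latent
#' clone-size distributions per compartment, configurable clone sharing
#' between compartment pairs, planted viral-specific public clones carrying
#' known motifs and a biased V-gene usage, multinomial template sampling at a
#' configurable depth, and survival times whose hazard is log-linear in
#' standardized latent repertoire features.
#'
#' @param n_patients number of patients.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   output files.
#' @param compartments compartments simulated per patient.
#' @param clones_per_compartment named integer vector of latent clone counts.
#' @param clone_size list: `dist` (`"lognormal"` or `"power_law"`) and
#'   `sigma` (lognormal sd of log-weights) or `exponent` (Pareto tail).
#' @param sharing_fractions named vector over `"A:B"` compartment pairs in
#'   `[0, 1]`: the fraction of the smaller member's clones planted into both.
#' @param depth named vector: templates sequenced per compartment.
#' @param clonality_shift named list/vector per compartment: fraction of
#'   latent mass moved onto the top clone; an entry may be a length-2 range,
#'   drawn per patient (creates between-patient clonality heterogeneity).
#' @param shared_expansion weight multiplier applied to clones shared
#'   between adjacent lung and tumor (antigen-driven clones expanded on both
#'   sides of the tumor margin are more abundant than bystanders).
#' @param n_viral_public_clones number of public viral clones planted into
#'   every patient's lung and tumor.
#' @param n_viral_motifs number of distinct 4-mer motifs the viral clones
#'   carry (round-robin assignment).
#' @param viral_v_bias named probability vector over V genes for viral clones.
#' @param viral_reference_size rows of the synthetic tetramer-defined viral
#'   reference (planted clones + decoys).
#' @param latent_density mean of the per-sample latent T cell fraction
#'   (Beta-distributed with concentration `density_concentration`).
#' @param density_concentration Beta concentration of the latent density.
#' @param nonproductive_fraction extra non-productive clones added per
#'   sample, as a fraction of observed productive clones.
#' @param survival_model list: `baseline` hazard (per day), `coefs` named
#'   vector over latent features (`"<COMPARTMENT>_clonality"`,
#'   `"<COMPARTMENT>_density"`), `censor_range` days.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 50,
                       seed = 1,
                       compartments = c("PBMC", "ADJACENT_LUNG", "TUMOR"),
                       clones_per_compartment = c(PBMC = 400,
                                                  ADJACENT_LUNG = 250,
                                                  TUMOR = 300),
                       clone_size = list(dist = "lognormal", sigma = 1),
                       sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0.30,
                                             "PBMC:ADJACENT_LUNG" = 0.05,
                                             "PBMC:TUMOR" = 0.05),
                       depth = c(PBMC = 12000, ADJACENT_LUNG = 6000,
                                 TUMOR = 8000),
                       clonality_shift = list(PBMC = 0.02,
                                              ADJACENT_LUNG = c(0.05, 0.30),
                                              TUMOR = 0.05),
                       shared_expansion = 3,
                       n_viral_public_clones = 25,
                       n_viral_motifs = 5,
                       viral_v_bias = c(TRBV9 = 0.75, TRBV19 = 0.15,
                                        TRBV28 = 0.10),
                       viral_reference_size = 500,
                       latent_density = 0.24,
                       density_concentration = 12,
                       nonproductive_fraction = 0.05,
                       survival_model = list(
                         baseline = 2e-4,
                         coefs = c(ADJACENT_LUNG_clonality = 0.5,
                                   PBMC_density = -0.3),
                         censor_range = c(365, 3650))) {
  cfg <- list(n_patients = n_patients, seed = as.integer(seed),
              compartments = compartments,
              clones_per_compartment = clones_per_compartment,
              clone_size = clone_size,
              sharing_fractions = sharing_fractions,
              depth = depth, clonality_shift = clonality_shift,
              shared_expansion = shared_expansion,
              n_viral_public_clones = n_viral_public_clones,
              n_viral_motifs = n_viral_motifs,
              viral_v_bias = viral_v_bias,
              viral_reference_size = viral_reference_size,
              latent_density = latent_density,
              density_concentration = density_concentration,
              nonproductive_fraction = nonproductive_fraction,
              survival_model = survival_model)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  comps <- cfg$compartments
  if (!all(comps %in% names(cfg$clones_per_compartment)))
    stop("clones_per_compartment must cover every compartment")
  if (!all(comps %in% names(cfg$depth)))
    stop("depth must cover every compartment")
  if (any(cfg$depth[comps] < 1)) stop("depth must be >= 1")
  if (any(cfg$sharing_fractions < 0 | cfg$sharing_fractions > 1))
    stop("sharing_fractions must lie in [0, 1]")
  if (cfg$n_viral_public_clones > 0 &&
      cfg$viral_reference_size < cfg$n_viral_public_clones)
    stop("viral_reference_size must be >= n_viral_public_clones")
  # feasibility: shared blocks cannot exceed a compartment's clone budget
  share_load <- stats::setNames(numeric(length(comps)), comps)
  for (pair in names(cfg$sharing_fractions)) {
    ab <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (!all(ab %in% comps)) next
    n_sh <- round(cfg$sharing_fractions[[pair]] *
                    min(cfg$clones_per_compartment[ab]))
    share_load[ab] <- share_load[ab] + n_sh
  }
  over <- share_load > cfg$clones_per_compartment[comps]
  if (any(over))
    stop("infeasible config: shared clones exceed clone budget in ",
         paste(comps[over], collapse = ", "))
  invisible(TRUE)
}

# Latent weights for one compartment of one patient.
draw_weights <- function(n, clone_size) {
  if (identical(clone_size$dist, "lognormal")) {
    sigma <- clone_size$sigma
    exp(stats::rnorm(n, 0, sigma))
  } else if (identical(clone_size$dist, "power_law")) {
    a <- clone_size$exponent
    stats::runif(n)^(-1 / (a - 1))
  } else stop("unknown clone_size dist: ", clone_size$dist)
}

shift_value <- function(spec) {
  if (length(spec) == 2) stats::runif(1, spec[1], spec[2]) else spec[1]
}

# Deterministic generation of the planted viral public clones; driven by its
# own derived seed so make_viral_reference() reproduces the same set.
viral_clone_table <- function(cfg) {
  if (cfg$n_viral_public_clones == 0)
    return(data.frame(cdr3_aa = character(0), v_gene = character(0),
                      motif = character(0), stringsAsFactors = FALSE))
  set.seed((cfg$seed + 7919L) %% .Machine$integer.max)
  motifs <- character(0)
  while (length(motifs) < cfg$n_viral_motifs) {
    m <- paste(sample(AA20, 4, replace = TRUE), collapse = "")
    if (!m %in% motifs) motifs <- c(motifs, m)
  }
  n <- cfg$n_viral_public_clones
  cdr3 <- character(n)
  motif_of <- motifs[((seq_len(n) - 1) %% cfg$n_viral_motifs) + 1]
  for (i in seq_len(n)) {
    len <- sample(12:16, 1)
    pre_n <- sample(3:(len - 7), 1)      # leaves >= 2 post residues
    post_n <- len - 2 - pre_n - 4
    cdr3[i] <- paste0("C", paste(sample(AA20, pre_n, replace = TRUE),
                                 collapse = ""),
                      motif_of[i],
                      paste(sample(AA20, post_n, replace = TRUE),
                            collapse = ""), "F")
  }
  # clones of one motif family share a dominant V gene (the V-gene
  # restriction of same-specificity TCRs that motif clustering relies on)
  v_of_motif <- stats::setNames(
    sample(names(cfg$viral_v_bias), cfg$n_viral_motifs, replace = TRUE,
           prob = cfg$viral_v_bias), motifs)
  data.frame(cdr3_aa = cdr3, v_gene = unname(v_of_motif[motif_of]),
             motif = motif_of, stringsAsFactors = FALSE)
}

#' Synthetic tetramer-defined viral CDR3 reference
#'
#' Builds the viral reference table used by the motif-classification stage:
#' every planted viral public clone (with its V gene and a nominal epitope
#' label derived from its motif) plus motif-free decoy CDR3s up to
#' `viral_reference_size` rows. With `n_viral_public_clones = 0` the table
#' contains only decoys. This is a synthetic stand-in for a public
#' tetramer-sorted CDR3 database; real analyses may supply any table with
#' columns `cdr3_aa`, `v_gene`, `epitope`.
#'
#' @param config a [sim_config()].
#' @return Data frame with columns `cdr3_aa`, `v_gene`, `epitope`.
#' @export
make_viral_reference <- function(config) {
  vt <- viral_clone_table(config)
  motifs <- unique(vt$motif)
  n_decoy <- config$viral_reference_size - nrow(vt)
  set.seed((config$seed + 104729L) %% .Machine$integer.max)
  decoys <- random_cdr3s(n_decoy, exclude = motifs)
  out <- rbind(
    if (nrow(vt) > 0)
      data.frame(cdr3_aa = vt$cdr3_aa, v_gene = vt$v_gene,
                 epitope = paste0("EPI_", match(vt$motif, motifs)),
                 stringsAsFactors = FALSE),
    data.frame(cdr3_aa = decoys,
               v_gene = sample(TRBV_UNIVERSE, n_decoy, replace = TRUE),
               epitope = "DECOY", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate a multi-compartment TCR repertoire cohort
#'
#' For each patient, latent clone populations are drawn per compartment
#' (lognormal or power-law weights, with a configurable fraction of mass
#' shifted onto the top clone); clones are shared between compartment pairs
#' according to `sharing_fractions`; planted viral public clones (identical
#' across patients, motif-bearing, V-biased) are added to lung and tumor;
#' observed counts are multinomial draws of `depth` templates from the
#' latent frequencies; survival times are exponential with a log-linear
#' hazard in standardized latent repertoire features, with uniform censoring.
#'
#' @param config a [sim_config()].
#' @return A `tcr_cohort` list: `samples` (named [tcr_sample()] list),
#'   `manifest` (clinical covariates, one row per patient), `truth` (ground
#'   truth: latent frequencies, shared and viral clone identities, latent
#'   features, survival coefficients), `viral_reference`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  viral <- viral_clone_table(cfg)
  viral_ref <- make_viral_reference(cfg)
  set.seed(cfg$seed)
  comps <- cfg$compartments
  pairs <- names(cfg$sharing_fractions)
  pairs <- pairs[vapply(pairs, function(p)
    all(strsplit(p, ":", fixed = TRUE)[[1]] %in% comps), logical(1))]

  samples <- list()
  truth_latent <- list()
  truth_shared <- list()
  feats <- list()
  manifest_rows <- list()

  for (pi in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", pi)
    # clone identity sets with pairwise-shared blocks
    shared_ids <- list()
    for (pair in pairs) {
      ab <- strsplit(pair, ":", fixed = TRUE)[[1]]
      n_sh <- round(cfg$sharing_fractions[[pair]] *
                      min(cfg$clones_per_compartment[ab]))
      shared_ids[[pair]] <- if (n_sh > 0) random_cdr3s(n_sh) else character(0)
    }
    comp_ids <- list()
    for (cc in comps) {
      ids <- unlist(shared_ids[grepl(cc, names(shared_ids), fixed = TRUE)],
                    use.names = FALSE)
      n_priv <- cfg$clones_per_compartment[[cc]] - length(ids)
      ids <- c(ids, random_cdr3s(n_priv))
      if (nrow(viral) > 0 && cc %in% c("ADJACENT_LUNG", "TUMOR"))
        ids <- c(ids, viral$cdr3_aa)
      comp_ids[[cc]] <- unique(ids)
    }
    truth_shared[[pid]] <- lapply(stats::setNames(pairs, pairs), function(p) {
      ab <- strsplit(p, ":", fixed = TRUE)[[1]]
      extra <- if (nrow(viral) > 0 && all(ab %in% c("ADJACENT_LUNG", "TUMOR")))
        viral$cdr3_aa else character(0)
      unique(c(shared_ids[[p]], extra))
    })

    # per-clone gene assignments (consistent within patient)
    all_ids <- unique(unlist(comp_ids, use.names = FALSE))
    vmap <- stats::setNames(sample(TRBV_UNIVERSE, length(all_ids),
                                   replace = TRUE), all_ids)
    jmap <- stats::setNames(sample(TRBJ_UNIVERSE, length(all_ids),
                                   replace = TRUE), all_ids)
    if (nrow(viral) > 0) vmap[viral$cdr3_aa] <- viral$v_gene

    # clone abundances are correlated across compartments: one patient-level
    # base weight per clone, times compartment-level lognormal noise (an
    # expanded clone shared by lung and tumor is expanded in both)
    base_w <- stats::setNames(draw_weights(length(all_ids), cfg$clone_size),
                              all_ids)
    noise_sd <- if (identical(cfg$clone_size$dist, "lognormal"))
      0.5 * cfg$clone_size$sigma else 0.5
    lt_shared <- truth_shared[[pid]][["ADJACENT_LUNG:TUMOR"]]
    if (!is.null(lt_shared) && length(lt_shared) > 0)
      base_w[lt_shared] <- base_w[lt_shared] * cfg$shared_expansion

    truth_latent[[pid]] <- list()
    pfeat <- c()
    for (cc in comps) {
      ids <- comp_ids[[cc]]
      w <- base_w[ids] * exp(stats::rnorm(length(ids), 0, noise_sd))
      p <- unname(w / sum(w))
      sh <- shift_value(cfg$clonality_shift[[cc]])
      if (sh > 0) {
        top <- which.max(p)
        p <- (1 - sh) * p
        p[top] <- p[top] + sh
      }
      names(p) <- ids
      truth_latent[[pid]][[cc]] <- p

      d_latent <- stats::rbeta(1, cfg$latent_density * cfg$density_concentration,
                               (1 - cfg$latent_density) * cfg$density_concentration)
      depth <- cfg$depth[[cc]]
      counts <- as.integer(stats::rmultinom(1, depth, p))
      obs <- counts > 0
      cl <- data.frame(cdr3_aa = ids[obs], cdr3_nt = NA_character_,
                       v_gene = unname(vmap[ids[obs]]),
                       j_gene = unname(jmap[ids[obs]]),
                       templates = counts[obs], productive = TRUE,
                       stringsAsFactors = FALSE)
      n_np <- round(cfg$nonproductive_fraction * nrow(cl))
      if (n_np > 0) {
        npseq <- random_cdr3s(n_np)
        npseq <- paste0(substr(npseq, 1, 4), "*",
                        substr(npseq, 5, nchar(npseq)))
        cl <- rbind(cl, data.frame(
          cdr3_aa = npseq, cdr3_nt = NA_character_,
          v_gene = sample(TRBV_UNIVERSE, n_np, replace = TRUE),
          j_gene = sample(TRBJ_UNIVERSE, n_np, replace = TRUE),
          templates = sample(1:3, n_np, replace = TRUE),
          productive = FALSE, stringsAsFactors = FALSE))
      }
      cl <- cl[order(-cl$templates, cl$cdr3_aa), ]
      sid <- paste0(pid, "_", cc)
      samples[[sid]] <- tcr_sample(
        cl, sample_id = sid, patient_id = pid, compartment = cc,
        usable_input = round(sum(cl$templates) / d_latent))
      pfeat[paste0(cc, "_clonality")] <- 1 - shannon_entropy(p) / log(length(p))
      pfeat[paste0(cc, "_density")] <- d_latent
      pfeat[paste0(cc, "_richness")] <- length(p)
    }
    feats[[pid]] <- pfeat

    manifest_rows[[pid]] <- data.frame(
      patient_id = pid,
      age = round(stats::rnorm(1, 66, 10)),
      sex = sample(c("F", "M"), 1),
      histology = sample(c("ADCA", "SCCA"), 1, prob = c(0.62, 0.38)),
      stage = sample(c("I", "II", "III"), 1, prob = c(0.48, 0.33, 0.19)),
      smoking = sample(c("current", "former", "never"), 1,
                       prob = c(0.43, 0.48, 0.09)),
      tumor_size = round(stats::runif(1, 1, 8), 1),
      stringsAsFactors = FALSE)
  }

  # survival: log-linear hazard in standardized latent features
  fm <- do.call(rbind, feats)
  sm <- cfg$survival_model
  lp <- rep(0, cfg$n_patients)
  for (nm in names(sm$coefs)) {
    if (!nm %in% colnames(fm)) stop("unknown survival feature: ", nm)
    z <- as.numeric(scale(fm[, nm]))
    if (all(is.finite(z))) lp <- lp + sm$coefs[[nm]] * z
  }
  t_event <- stats::rexp(cfg$n_patients, rate = sm$baseline * exp(lp))
  t_cens <- stats::runif(cfg$n_patients, sm$censor_range[1], sm$censor_range[2])
  manifest <- do.call(rbind, manifest_rows)
  manifest$os_time <- round(pmin(t_event, t_cens), 1)
  manifest$os_event <- as.integer(t_event <= t_cens)
  manifest$relapse <- stats::rbinom(cfg$n_patients, 1, 0.35)
  rownames(manifest) <- NULL

  structure(list(samples = samples, manifest = manifest,
                 truth = list(latent = truth_latent, shared = truth_shared,
                              viral = viral, features = fm,
                              survival_coefs = sm$coefs),
                 viral_reference = viral_ref, config = cfg),
            class = "tcr_cohort")
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("<tcr_cohort> %d patients, %d samples (%s)\n",
              x$config$n_patients, length(x$samples),
              paste(x$config$compartments, collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one immunoSEQ-dialect rearrangement TSV per sample, a cohort
#' manifest (`manifest.tsv`) with file paths and usable-input columns, the
#' viral reference (`viral_reference.tsv`) and the ground truth
#' (`ground_truth.json`). Output is deterministic: identical cohort objects
#' produce byte-identical files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param dialect rearrangement dialect to write.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = "immunoseq") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  comps <- cohort$config$compartments
  for (cc in comps) {
    man[[cc]] <- ""
    man[[paste0("usable_input_", cc)]] <- NA_real_
  }
  for (s in cohort$samples) {
    f <- paste0(s$sample_id, ".tsv")
    write_rearrangements(s, file.path(dir, f), dialect = dialect)
    i <- match(s$patient_id, man$patient_id)
    man[[s$compartment]][i] <- f
    man[[paste0("usable_input_", s$compartment)]][i] <- s$usable_input
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$viral_reference,
                     file.path(dir, "viral_reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- list(
    shared = cohort$truth$shared,
    viral = cohort$truth$viral,
    features = as.data.frame(cohort$truth$features),
    survival_coefs = as.list(cohort$truth$survival_coefs),
    latent = lapply(cohort$truth$latent, function(pp)
      lapply(pp, function(p) as.list(stats::setNames(unname(p), names(p)))))
  )
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
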