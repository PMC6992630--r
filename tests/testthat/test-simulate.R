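test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_sim_config(seed = 17, n_patients = 3)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_equal(h1, h2)
})

test_that("zero sharing yields disjoint true clone sets", {
  cfg <- small_sim_config(seed = 5, n_patients = 3,
                          sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0,
                                                "PBMC:ADJACENT_LUNG" = 0,
                                                "PBMC:TUMOR" = 0),
                          n_viral_public_clones = 0)
  co <- simulate_cohort(cfg)
  for (pid in names(co$truth$latent)) {
    lat <- co$truth$latent[[pid]]
    expect_equal(length(intersect(names(lat$ADJACENT_LUNG),
                                  names(lat$TUMOR))), 0)
    expect_equal(length(intersect(names(lat$PBMC), names(lat$TUMOR))), 0)
  }
})

test_that("planted sharing matches the configured true-set overlap", {
  s <- 0.3
  cfg <- small_sim_config(seed = 9, n_patients = 4,
                          sharing_fractions = c("ADJACENT_LUNG:TUMOR" = s,
                                                "PBMC:ADJACENT_LUNG" = 0,
                                                "PBMC:TUMOR" = 0),
                          n_viral_public_clones = 0)
  co <- simulate_cohort(cfg)
  n_l <- cfg$clones_per_compartment[["ADJACENT_LUNG"]]
  n_t <- cfg$clones_per_compartment[["TUMOR"]]
  n_sh <- round(s * min(n_l, n_t))
  for (pid in names(co$truth$latent)) {
    lat <- co$truth$latent[[pid]]
    shared <- intersect(names(lat$ADJACENT_LUNG), names(lat$TUMOR))
    expect_equal(length(shared), n_sh)
    expect_setequal(shared, co$truth$shared[[pid]][["ADJACENT_LUNG:TUMOR"]])
    jac_true <- length(shared) /
      length(union(names(lat$ADJACENT_LUNG), names(lat$TUMOR)))
    expect_equal(jac_true, n_sh / (n_l + n_t - n_sh), tolerance = 1e-12)
  }
})

test_that("a deep uniform repertoire has near-zero clonality", {
  cfg <- sim_config(n_patients = 1, seed = 2, compartments = "TUMOR",
                    clones_per_compartment = c(TUMOR = 100),
                    clone_size = list(dist = "lognormal", sigma = 0),
                    sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0),
                    depth = c(TUMOR = 1e6),
                    clonality_shift = list(TUMOR = 0),
                    n_viral_public_clones = 0,
                    survival_model = list(baseline = 2e-4, coefs = c(),
                                          censor_range = c(365, 3650)))
  co <- simulate_cohort(cfg)
  expect_lt(clonality(co$samples[[1]]), 0.01)
})

test_that("observed frequencies recover latent frequencies at high depth", {
  cfg <- sim_config(n_patients = 1, seed = 21, compartments = "TUMOR",
                    clones_per_compartment = c(TUMOR = 200),
                    depth = c(TUMOR = 20000),   # 100x the clone count
                    sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0),
                    clonality_shift = list(TUMOR = 0.1),
                    n_viral_public_clones = 0,
                    survival_model = list(baseline = 2e-4, coefs = c(),
                                          censor_range = c(365, 3650)))
  co <- simulate_cohort(cfg)
  lat <- co$truth$latent$P001$TUMOR
  cnt <- clone_counts(co$samples[[1]])
  obs <- stats::setNames(rep(0, length(lat)), names(lat))
  obs[names(cnt)] <- cnt
  expect_gt(stats::cor(obs, lat, method = "spearman"), 0.9)
})

test_that("every planted viral clone embeds its motif and reaches the reference", {
  cfg <- small_sim_config(seed = 33, n_patients = 2)
  co <- simulate_cohort(cfg)
  vt <- co$truth$viral
  expect_equal(nrow(vt), cfg$n_viral_public_clones)
  expect_true(all(mapply(grepl, vt$motif, vt$cdr3_aa, fixed = TRUE)))
  ref <- co$viral_reference
  expect_true(all(vt$cdr3_aa %in% ref$cdr3_aa))
  # each motif is carried by >= 3 reference sequences
  per_motif <- table(vt$motif)
  expect_true(all(per_motif >= 3))
  # decoys never contain a planted motif
  decoys <- ref$cdr3_aa[ref$epitope == "DECOY"]
  for (m in unique(vt$motif))
    expect_false(any(grepl(m, decoys, fixed = TRUE)))
})

test_that("a motif-free reference is produced when no virals are planted", {
  cfg <- small_sim_config(seed = 3, n_patients = 2, n_viral_public_clones = 0)
  ref <- make_viral_reference(cfg)
  expect_true(all(ref$epitope == "DECOY"))
  expect_equal(nrow(ref), cfg$viral_reference_size)
})

test_that("infeasible or invalid configs are rejected before simulation", {
  expect_error(small_sim_config(sharing_fractions =
    c("ADJACENT_LUNG:TUMOR" = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(clones_per_compartment = c(PBMC = 10,
                            ADJACENT_LUNG = 10, TUMOR = 10),
                          sharing_fractions = c("ADJACENT_LUNG:TUMOR" = 0.9,
                                                "PBMC:ADJACENT_LUNG" = 0.9,
                                                "PBMC:TUMOR" = 0.9)),
               "infeasible")
  expect_error(small_sim_config(n_viral_public_clones = 50,
                                viral_reference_size = 10), "reference_size")
})

test_that("simulated survival covariates and times are complete", {
  co <- simulate_cohort(small_sim_config(seed = 10, n_patients = 5))
  m <- co$manifest
  expect_equal(nrow(m), 5)
  expect_true(all(m$os_time >= 0))
  expect_true(all(m$os_event %in% c(0, 1)))
  expect_true(all(c("age", "sex", "histology", "stage", "smoking",
                    "tumor_size") %in% names(m)))
})
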