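test_that("declared association tests run with unadjusted and BH p-values", {
  set.seed(51)
  d <- data.frame(x = 1:20, y = 2 * (1:20) + 0,
                  g2 = rep(c("a", "b"), each = 10),
                  g3 = rep(c("a", "b", "c"), length.out = 20))
  d$z <- c(rnorm(10), rnorm(10, 4))   # separates g2
  plan <- list(
    list(method = "spearman", x = "x", y = "y"),
    list(method = "mann_whitney", x = "z", group = "g2"),
    list(method = "kruskal_wallis", x = "x", group = "g3"),
    list(method = "wilcoxon_paired", x = "x", y = "y"))
  r <- associate(d, plan)
  expect_equal(nrow(r$results), 4)
  # monotone transform: Spearman rho exactly 1
  expect_equal(r$results$statistic[1], 1)
  expect_true(all(c("p_value", "p_adjusted_bh") %in% names(r$results)))
  expect_true(all(r$results$p_adjusted_bh >= r$results$p_value - 1e-12,
                  na.rm = TRUE))
  # matches the classical routines directly
  expect_equal(r$results$p_value[2],
               suppressWarnings(stats::wilcox.test(z ~ g2, d))$p.value)
  expect_equal(r$results$p_value[3],
               stats::kruskal.test(d$x, factor(d$g3))$p.value)
})

test_that("small groups are skipped with a recorded reason", {
  d <- data.frame(x = c(1, 2, 3, 4, 10), g = c("a", "a", "a", "a", "b"))
  r <- associate(d, list(list(method = "mann_whitney", x = "x", group = "g")))
  expect_true(is.na(r$results$p_value))
  expect_match(r$results$note, "skipped")
})

test_that("Dunn's test follows only a significant Kruskal-Wallis", {
  set.seed(52)
  d <- data.frame(x = c(rnorm(15), rnorm(15, 5), rnorm(15, 10)),
                  g = rep(c("a", "b", "c"), each = 15))
  r <- associate(d, list(list(method = "kruskal_wallis", x = "x", group = "g")))
  expect_equal(length(r$posthoc), 1)
  ph <- r$posthoc[[1]]
  expect_equal(nrow(ph), 3)
  expect_lt(ph$p_value[ph$group1 == "a" & ph$group2 == "c"], 0.001)
  dnull <- data.frame(x = rnorm(60), g = rep(c("a", "b", "c"), each = 20))
  # an insignificant omnibus (overwhelmingly likely under this null) gates
  # the post hoc; re-draw deterministically to a null with p > 0.05
  rn <- associate(dnull, list(list(method = "kruskal_wallis",
                                   x = "x", group = "g")))
  if (rn$results$p_value > 0.05) expect_equal(length(rn$posthoc), 0)
})

test_that("with two groups Dunn's z-square equals the Kruskal statistic", {
  set.seed(53)
  x <- c(rnorm(12), rnorm(14, 1)); g <- rep(c("a", "b"), c(12, 14))
  ph <- dunn_test(x, g)
  kw <- stats::kruskal.test(x, factor(g))
  expect_equal(ph$z^2, unname(kw$statistic), tolerance = 1e-10)
})

test_that("median-split survival recovers a strong planted effect", {
  set.seed(54)
  n <- 120
  x <- runif(n)
  lp <- 1.5 * scale(x)
  t_ev <- rexp(n, rate = 2e-4 * exp(lp))
  t_c <- runif(n, 365, 3650)
  d <- data.frame(v = x, os_time = pmin(t_ev, t_c),
                  os_event = as.integer(t_ev <= t_c),
                  age = rnorm(n, 65, 8), sex = sample(c("F", "M"), n, TRUE),
                  histology = sample(c("ADCA", "SCCA"), n, TRUE),
                  stage = sample(c("I", "II", "III"), n, TRUE),
                  smoking = sample(c("current", "former", "never"), n, TRUE),
                  tumor_size = runif(n, 1, 8))
  r <- survival_analysis(d, "v")
  expect_false(r$underpowered)
  expect_gt(r$hazard_ratio, 1)
  expect_lt(r$logrank_p, 0.05)
  expect_true(r$hr_ci[1] < r$hazard_ratio && r$hazard_ratio < r$hr_ci[2])
  expect_lt(r$multivariate_p, 0.05)
  # median split sizes differ by at most the tie count (none here)
  med <- stats::median(d$v)
  expect_lte(abs(sum(d$v > med) - sum(d$v <= med)), 1)
})

test_that("at-median handling and alternate event columns behave", {
  d <- data.frame(v = c(1, 1, 1, 2, 3, 4), os_time = c(100, 200, 300, 400,
                  500, 600), os_event = c(1, 1, 0, 1, 0, 1))
  r_lo <- suppressWarnings(survival_analysis(d, "v", min_events = 1,
                                             at_median = "low"))
  # median 1.5; ties below: low group keeps at-median values
  d2 <- data.frame(v = c(1, 2, 2, 3), os_time = 1:4 * 100,
                   os_event = c(1, 1, 1, 1),
                   dss_time = 1:4 * 50, dss_event = c(0, 0, 0, 0))
  r_hi <- suppressWarnings(survival_analysis(d2, "v", min_events = 1,
                                             at_median = "high"))
  expect_true(!is.na(r_lo$logrank_p) && !is.na(r_hi$logrank_p))
  # all-censored alternate endpoint: underpowered, no hazard ratio
  r_dss <- survival_analysis(d2, "v", time_col = "dss_time",
                             event_col = "dss_event")
  expect_true(r_dss$underpowered)
  expect_true(is.na(r_dss$hazard_ratio))
  expect_error(survival_analysis(data.frame(v = c(1, 1), os_time = c(1, 2),
                                            os_event = c(1, 1)), "v"),
               "constant")
})

test_that("enriched-clonality pipeline handles missing compartments", {
  co <- simulate_cohort(small_sim_config(seed = 19, n_patients = 3))
  expect_null(tissue_enriched_sample(co$samples, "P001",
                                     compartment = "HEALTHY_LUNG"))
  ec <- enriched_clonality_table(co$samples, "ADJACENT_LUNG", "TUMOR")
  expect_equal(nrow(ec), 3)
  expect_true(all(is.na(ec$clonality) | (ec$clonality >= 0 &
                                           ec$clonality <= 1)))
})
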