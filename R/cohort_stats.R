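# Cohort-level association and survival analyses.

#' Dunn's post hoc test
#'
#' Pairwise rank-based comparisons following a Kruskal-Wallis test: for
#' groups i, j the statistic is the difference of mean ranks scaled by the
#' tie-corrected variance,
#' \eqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{T = \sum (t^3 - t) / (12(N-1))}. Two-sided
#' unadjusted p-values plus Benjamini-Hochberg adjusted values are reported.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return Data frame: `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(x, g) {
  ok <- stats::complete.cases(x, g)
  x <- x[ok]; g <- factor(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- table(g)
  lv <- levels(g)
  out <- list()
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1):length(lv)) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    out[[length(out) + 1]] <- data.frame(
      group1 = lv[i], group2 = lv[j], z = z,
      p_value = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Run a declared plan of cohort association tests
#'
#' Executes a list of declared comparisons against a merged metrics +
#' manifest table, mirroring a nonparametric analysis battery: Spearman rank
#' correlation, Mann-Whitney, Wilcoxon matched pairs, Kruskal-Wallis (with
#' Dunn's post hoc only after a significant omnibus test). Unadjusted
#' p-values are the primary output (an exploratory-screen convention);
#' BH-adjusted values are added as a clearly separated extra column.
#'
#' @param data data frame holding all referenced columns.
#' @param plan list of comparisons; each a list with `method` (one of
#'   `"spearman"`, `"mann_whitney"`, `"wilcoxon_paired"`,
#'   `"kruskal_wallis"`), `x` (response column) and `y` (second variable
#'   for `spearman`/`wilcoxon_paired`) or `group` (factor column for the
#'   group tests).
#' @param kw_alpha omnibus threshold gating Dunn's test (default 0.05).
#' @param min_group_n groups smaller than this cause the comparison to be
#'   skipped with a recorded reason (default 3).
#' @return List: `results` data frame (`comparison`, `method`, `statistic`,
#'   `p_value`, `p_adjusted_bh`, `n`, `note`) and `posthoc` (named list of
#'   [dunn_test()] tables for significant Kruskal-Wallis comparisons).
#' @export
associate <- function(data, plan, kw_alpha = 0.05, min_group_n = 3) {
  rows <- list(); posthoc <- list()
  for (cmp in plan) {
    nm <- paste0(cmp$x, " ~ ", if (!is.null(cmp$y)) cmp$y else cmp$group)
    method <- cmp$method
    note <- ""
    stat <- NA_real_; p <- NA_real_; n <- NA_integer_
    if (method == "spearman") {
      ok <- stats::complete.cases(data[[cmp$x]], data[[cmp$y]])
      n <- sum(ok)
      if (n >= 3) {
        ct <- suppressWarnings(stats::cor.test(data[[cmp$x]][ok],
                                               data[[cmp$y]][ok],
                                               method = "spearman"))
        stat <- unname(ct$estimate); p <- ct$p.value
      } else note <- "skipped: n < 3"
    } else if (method == "mann_whitney") {
      ok <- stats::complete.cases(data[[cmp$x]], data[[cmp$group]])
      x <- data[[cmp$x]][ok]; g <- factor(data[[cmp$group]][ok])
      n <- length(x)
      if (nlevels(g) == 2 && min(table(g)) >= min_group_n) {
        wt <- suppressWarnings(stats::wilcox.test(x ~ g))
        stat <- unname(wt$statistic); p <- wt$p.value
      } else note <- "skipped: needs 2 groups with n >= min_group_n"
    } else if (method == "wilcoxon_paired") {
      ok <- stats::complete.cases(data[[cmp$x]], data[[cmp$y]])
      n <- sum(ok)
      if (n >= min_group_n) {
        wt <- suppressWarnings(stats::wilcox.test(data[[cmp$x]][ok],
                                                  data[[cmp$y]][ok],
                                                  paired = TRUE))
        stat <- unname(wt$statistic); p <- wt$p.value
      } else note <- "skipped: n < min_group_n"
    } else if (method == "kruskal_wallis") {
      ok <- stats::complete.cases(data[[cmp$x]], data[[cmp$group]])
      x <- data[[cmp$x]][ok]; g <- factor(data[[cmp$group]][ok])
      n <- length(x)
      if (nlevels(g) >= 2 && min(table(g)) >= min_group_n) {
        kt <- stats::kruskal.test(x, g)
        stat <- unname(kt$statistic); p <- kt$p.value
        if (!is.na(p) && p < kw_alpha) posthoc[[nm]] <- dunn_test(x, g)
      } else note <- "skipped: group n < min_group_n"
    } else stop("unknown method: ", method)
    rows[[length(rows) + 1]] <- data.frame(
      comparison = nm, method = method, statistic = stat, p_value = p,
      n = n, note = note, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$p_adjusted_bh <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[, c("comparison", "method", "statistic", "p_value",
                 "p_adjusted_bh", "n", "note")]
  rownames(res) <- NULL
  list(results = res, posthoc = posthoc)
}

#' Median-split survival analysis of a repertoire variable
#'
#' Dichotomizes the variable at its sample median (high = strictly above the
#' median; at-median observations go to the low group, flippable via
#' `at_median`), then reports the log-rank test, the univariate Cox hazard
#' ratio (high vs low) with confidence interval, and the same variable's
#' p-value from a multivariate Cox model adjusted for age, sex, histology,
#' stage, smoking and tumor size (covariates absent from `data` or constant
#' are dropped).
#'
#' @param data data frame with `os_time`, `os_event`, the variable and
#'   covariate columns (e.g. merged [repertoire_metrics()] + manifest).
#' @param variable column name of the repertoire variable.
#' @param time_col,event_col survival columns (defaults `os_time`,
#'   `os_event`; point `event_col` at an alternate cause-specific event
#'   column for disease-specific survival).
#' @param at_median `"low"` (default) or `"high"`: group receiving
#'   at-median observations.
#' @param min_events fewer events than this flags the result underpowered
#'   and suppresses the hazard ratio (default 10).
#' @return List of class `tcr_survival`: `variable`, `n`, `n_events`,
#'   `logrank_p`, `hazard_ratio`, `hr_ci` (95%), `univariate_p`,
#'   `multivariate_p`, `underpowered`.
#' @export
survival_analysis <- function(data, variable, time_col = "os_time",
                              event_col = "os_event",
                              at_median = c("low", "high"),
                              min_events = 10) {
  at_median <- match.arg(at_median)
  x <- data[[variable]]
  if (is.null(x)) stop("variable not found: ", variable)
  ok <- stats::complete.cases(x, data[[time_col]], data[[event_col]])
  d <- data[ok, , drop = FALSE]
  x <- x[ok]
  if (length(unique(x)) < 2) stop("variable is constant")
  med <- stats::median(x)
  high <- if (at_median == "low") x > med else x >= med
  d$.high <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  n_events <- sum(d[[event_col]])
  res <- list(variable = variable, n = nrow(d), n_events = n_events,
              logrank_p = NA_real_, hazard_ratio = NA_real_,
              hr_ci = c(NA_real_, NA_real_), univariate_p = NA_real_,
              multivariate_p = NA_real_,
              underpowered = n_events < min_events)
  surv <- survival::Surv(d[[time_col]], d[[event_col]])
  if (n_events > 0) {
    sd <- survival::survdiff(surv ~ .high, data = d)
    res$logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  if (!res$underpowered) {
    uni <- survival::coxph(surv ~ .high, data = d)
    s <- summary(uni)
    res$hazard_ratio <- unname(s$conf.int[1, "exp(coef)"])
    res$hr_ci <- unname(s$conf.int[1, c("lower .95", "upper .95")])
    res$univariate_p <- unname(s$coefficients[1, "Pr(>|z|)"])
    covs <- c("age", "sex", "histology", "stage", "smoking", "tumor_size")
    covs <- covs[covs %in% names(d)]
    covs <- covs[vapply(covs, function(cc) {
      v <- d[[cc]][stats::complete.cases(d[[cc]])]
      length(unique(v)) >= 2
    }, logical(1))]
    if (length(covs) > 0) {
      fml <- stats::as.formula(paste("surv ~ .high +",
                                     paste(covs, collapse = " + ")))
      multi <- tryCatch(survival::coxph(fml, data = d),
                        error = function(e) NULL)
      if (!is.null(multi))
        res$multivariate_p <-
          unname(summary(multi)$coefficients[".highhigh", "Pr(>|z|)"])
    }
  }
  class(res) <- "tcr_survival"
  res
}

#' @export
print.tcr_survival <- function(x, ...) {
  cat(sprintf("Survival (median split) for '%s': n = %d, events = %d\n",
              x$variable, x$n, x$n_events))
  cat(sprintf("  log-rank p = %.4g\n", x$logrank_p))
  if (!x$underpowered)
    cat(sprintf("  HR (high vs low) = %.3f [%.3f, %.3f], univariate p = %.4g, multivariate p = %.4g\n",
                x$hazard_ratio, x$hr_ci[1], x$hr_ci[2],
                x$univariate_p, x$multivariate_p))
  else cat("  underpowered: fewer events than the configured minimum; no HR\n")
  invisible(x)
}
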