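# ---- inferential layer: mixed models, Wilcoxon, Bonferroni -------------

# tidy a fitted nlme::lme into the reporting contract shared by all
# mixed-model wrappers
tidy_lme <- function(fit, converged = TRUE) {
  tab <- summary(fit)$tTable
  vc <- nlme::VarCorr(fit)
  fixed <- data.frame(term = rownames(tab),
                      estimate = tab[, "Value"],
                      se = tab[, "Std.Error"],
                      df = tab[, "DF"],
                      t = tab[, "t-value"],
                      p = tab[, "p-value"],
                      row.names = NULL)
  fixed$ci_low <- fixed$estimate - stats::qt(0.975, fixed$df) * fixed$se
  fixed$ci_high <- fixed$estimate + stats::qt(0.975, fixed$df) * fixed$se
  list(fixed = fixed,
       var_intercept = as.numeric(vc["(Intercept)", "Variance"]),
       var_residual = as.numeric(vc["Residual", "Variance"]),
       n_obs = fit$dims$N, n_groups = unname(fit$dims$ngrps[1]),
       converged = converged)
}

#' Proximo-distal fat-fraction gradient (random-intercept model)
#'
#' Fits `FF = b0 + b1 * segment` with segment position (1 = distal, 5 =
#' proximal) as a numeric fixed covariate and a random intercept per
#' patient, by REML with a variance-components covariance structure
#' (muscles are level 1, patients level 2). A negative `b1` quantifies the
#' distal-to-proximal decline in percent per segment. Fixed-effect p-values
#' use the containment degrees of freedom of the nested model.
#'
#' @param segments data.frame with columns `patient`, `segment` (1..5),
#'   `ff`, and optionally `mercuri` for subsetting.
#' @param subset optional Mercuri class label (`"<10"`, `"10-30"`,
#'   `"30-60"`, `">60"`) restricting the fit to one severity group.
#' @return list with `fixed` (term, estimate, se, df, t, p, 95% CI),
#'   variance components, `n_obs`, `n_groups`, `converged`.
#' @export
fit_segment_gradient <- function(segments, subset = NULL) {
  d <- segments
  if (!is.null(subset)) d <- d[d$mercuri == subset, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("patient", "segment", "ff")]), ,
         drop = FALSE]
  if (length(unique(d$patient)) < 2L) {
    stop("segment-gradient model needs at least 2 patients", call. = FALSE)
  }
  if (length(unique(d$segment)) < 2L) {
    stop("segment-gradient model needs at least 2 distinct segments",
         call. = FALSE)
  }
  d$patient <- factor(d$patient)
  fit <- tryCatch(
    nlme::lme(ff ~ segment, random = ~ 1 | patient, data = d,
              method = "REML"),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("mixed model did not converge (", conditionMessage(fit),
            "); falling back to the pooled OLS slope", call. = FALSE)
    ols <- stats::lm(ff ~ segment, data = d)
    sm <- summary(ols)$coefficients
    fixed <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        se = sm[, 2], df = ols$df.residual, t = sm[, 3],
                        p = sm[, 4], row.names = NULL)
    fixed$ci_low <- fixed$estimate - stats::qt(0.975, fixed$df) * fixed$se
    fixed$ci_high <- fixed$estimate + stats::qt(0.975, fixed$df) * fixed$se
    return(list(fixed = fixed, var_intercept = NA_real_,
                var_residual = summary(ols)$sigma^2, n_obs = nrow(d),
                n_groups = length(unique(d$patient)), converged = FALSE))
  }
  tidy_lme(fit)
}

#' Baseline-bin contrasts of annualized change
#'
#' Random-intercept model of `change_per_year` with the baseline
#' fat-fraction bin as a fixed factor (reference bin `0-10`) and patient as
#' the random grouping, fitted by REML. Each non-reference bin's
#' coefficient estimates the difference in mean annual change relative to
#' the `0-10` bin; raw p-values are Bonferroni-adjusted for `m` tests
#' (default 8, one per non-reference bin).
#'
#' @param records longitudinal-record data.frame (needs `change_per_year`,
#'   `baseline_bin`, `patient`).
#' @param m number of tests for the Bonferroni correction.
#' @return data.frame: `bin`, `estimate`, `se`, `df`, `p_raw`,
#'   `p_adj = min(1, m * p_raw)`.
#' @export
fit_bin_contrasts <- function(records, m = 8) {
  d <- records[!is.na(records$change_per_year), , drop = FALSE]
  d$baseline_bin <- droplevels(d$baseline_bin)
  if (!"0-10" %in% levels(d$baseline_bin) ||
      !sum(d$baseline_bin == "0-10")) {
    stop("reference bin 0-10 is empty", call. = FALSE)
  }
  if (length(unique(d$patient)) < 2L) {
    stop("bin-contrast model needs at least 2 patients", call. = FALSE)
  }
  d$patient <- factor(d$patient)
  d$baseline_bin <- stats::relevel(d$baseline_bin, ref = "0-10")
  fit <- nlme::lme(change_per_year ~ baseline_bin, random = ~ 1 | patient,
                   data = d, method = "REML")
  tab <- summary(fit)$tTable
  keep <- grepl("^baseline_bin", rownames(tab))
  out <- data.frame(bin = sub("^baseline_bin", "", rownames(tab)[keep]),
                    estimate = tab[keep, "Value"],
                    se = tab[keep, "Std.Error"],
                    df = tab[keep, "DF"],
                    p_raw = tab[keep, "p-value"],
                    row.names = NULL)
  out$p_adj <- pmin(1, m * out$p_raw)
  out
}

#' Wilcoxon signed-rank test with an exact small-sample null
#'
#' Two-sided one-sample (paired-difference) signed-rank test. Zero
#' differences are dropped (Wilcoxon convention) and ties in the absolute
#' differences receive midranks. For `n <= exact_max` non-zero differences
#' the p-value is exact, computed from the full null distribution of the
#' positive-rank sum (every one of the `2^n` sign assignments equally
#' likely under the symmetric null, enumerated by dynamic programming over
#' doubled midranks so tied ranks stay exact); above that a normal
#' approximation with continuity and tie correction is used.
#'
#' @param x numeric differences (or first sample when `y` is given).
#' @param y optional second sample; the test is applied to `x - y`.
#' @param exact_max largest n for the exact null (default 25).
#' @return list: `statistic` (V, the positive-rank sum), `p`, `n` (non-zero
#'   differences), `exact` flag.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) < 5L) {
    stop("need at least 5 non-zero differences", call. = FALSE)
  }
  n <- length(nz)
  r <- rank(abs(nz))
  v <- sum(r[nz > 0])
  if (n <= exact_max) {
    # null distribution of 2*V over doubled midranks (integers even with
    # ties); counts[s + 1] = number of sign patterns with doubled sum s
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
      counts <- counts + shifted
    }
    counts <- counts / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(counts[seq_len(v2 + 1L)])
    p_ge <- sum(counts[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = v, p = p, n = n, exact = TRUE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       exact = FALSE)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`; monotone in `p` and capped at 1.
#'
#' @param p raw p-values.
#' @param m number of tests (may exceed `length(p)`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  pmin(1, m * p)
}
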