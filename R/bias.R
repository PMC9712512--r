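# ---- localized-sampling bias audit -------------------------------------

#' Per-muscle sampling errors of reduced slice schemes
#'
#' For every muscle and scheme, the error is the value obtained from five
#' slices minus the value obtained over the whole muscle; the absolute
#' error is its absolute value. Two quantities are audited: the baseline
#' fat fraction, and the annualized fat-fraction change, where the
#' subsampled change re-selects the five slices independently at each
#' timepoint (using that timepoint's own slice count), as repeat scans are
#' planned in practice. Errors are computed per muscle-side, without
#' left/right averaging.
#'
#' @param baseline list of [muscle_profile()] objects (baseline).
#' @param followup optional list of follow-up profiles paired on
#'   (muscle, side); when given, change errors are computed for paired
#'   muscles, and unpaired ones are skipped with a warning.
#' @param interval_years follow-up interval, required with `followup`.
#' @param schemes character vector of reduced schemes to audit.
#' @param patient patient identifier stored on the records.
#' @return data.frame of bias records: `patient`, `muscle`, `side`,
#'   `scheme`, `quantity` (`baseline_ff` or `change_per_year`),
#'   `whole_value`, `sub_value`, `error`, `abs_error`, `baseline_bin`.
#' @export
bias_records <- function(baseline, followup = NULL, interval_years = NULL,
                         schemes = c("central5", "spread5"),
                         patient = "P1") {
  rows <- list()
  keyof <- function(p) paste(p$muscle, p$side, sep = "|")
  bkeys <- vapply(baseline, keyof, "")
  for (i in seq_along(baseline)) {
    pb <- baseline[[i]]
    whole_b <- whole_muscle_ff(pb)
    for (sc in schemes) {
      # the whole scheme retains full volume context: voxel-weighted, so
      # its error is identically zero
      sub_b <- if (sc == "whole") whole_b else subsampled_ff(pb, sc)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = patient, muscle = pb$muscle, side = pb$side, scheme = sc,
        quantity = "baseline_ff", whole_value = whole_b, sub_value = sub_b,
        error = sub_b - whole_b, abs_error = abs(sub_b - whole_b),
        baseline_bin = baseline_bin(whole_b))
    }
  }
  if (!is.null(followup)) {
    if (is.null(interval_years) || interval_years <= 0) {
      stop("interval_years must be positive when followup is given",
           call. = FALSE)
    }
    fkeys <- vapply(followup, keyof, "")
    unpaired <- union(setdiff(bkeys, fkeys), setdiff(fkeys, bkeys))
    if (length(unpaired)) {
      warning(sprintf("change errors: skipping %d unpaired muscle(s)",
                      length(unpaired)), call. = FALSE)
    }
    for (k in intersect(bkeys, fkeys)) {
      pb <- baseline[[match(k, bkeys)]]
      pf <- followup[[match(k, fkeys)]]
      whole_b <- whole_muscle_ff(pb)
      whole_rate <- (whole_muscle_ff(pf) - whole_b) / interval_years
      for (sc in schemes) {
        sub_rate <- if (sc == "whole") whole_rate else {
          (subsampled_ff(pf, sc) - subsampled_ff(pb, sc)) / interval_years
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient = patient, muscle = pb$muscle, side = pb$side,
          scheme = sc, quantity = "change_per_year",
          whole_value = whole_rate, sub_value = sub_rate,
          error = sub_rate - whole_rate,
          abs_error = abs(sub_rate - whole_rate),
          baseline_bin = baseline_bin(whole_b))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman agreement summary
#'
#' Mean error, sample SD and limits of agreement `mean +/- k * SD` over a
#' set of per-muscle errors (default `k = 1.96`, the conventional 95%
#' multiplier).
#'
#' @param errors numeric vector of signed errors (or a bias-record
#'   data.frame, in which case its `error` column is used).
#' @param k limits-of-agreement multiplier.
#' @return list: `mean_error`, `sd_error`, `loa_low`, `loa_high`, `k`, `n`.
#' @export
bland_altman <- function(errors, k = 1.96) {
  if (is.data.frame(errors)) errors <- errors$error
  errors <- errors[!is.na(errors)]
  n <- length(errors)
  if (n < 2L) stop("Bland-Altman needs at least 2 records", call. = FALSE)
  m <- mean(errors)
  s <- stats::sd(errors)
  list(mean_error = m, sd_error = s,
       loa_low = m - k * s, loa_high = m + k * s, k = k, n = n)
}

#' Test whether the absolute sampling error differs from zero
#'
#' Intercept-only random-intercept model on the absolute errors, with
#' patient as the grouping level (muscles within patients are not
#' independent), fitted by REML. With a single patient the model is not
#' identifiable and a one-sample t-test is used instead, with a warning.
#'
#' @param records bias-record data.frame (needs `abs_error`, `patient`).
#' @return list: `estimate` (mean absolute error, percentage points), `se`,
#'   `p`, `df`, `method`, `n_obs`, `n_patients`.
#' @export
abs_error_model <- function(records) {
  if (!nrow(records)) stop("no bias records", call. = FALSE)
  np <- length(unique(records$patient))
  if (np < 2L) {
    warning("single patient: falling back to a one-sample t-test",
            call. = FALSE)
    tt <- stats::t.test(records$abs_error)
    return(list(estimate = unname(tt$estimate), se = unname(tt$stderr),
                p = tt$p.value, df = unname(tt$parameter),
                method = "t", n_obs = nrow(records), n_patients = np))
  }
  d <- data.frame(abs_error = records$abs_error,
                  patient = factor(records$patient))
  fit <- nlme::lme(abs_error ~ 1, random = ~ 1 | patient, data = d,
                   method = "REML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
  tab <- summary(fit)$tTable
  list(estimate = unname(tab[1, "Value"]), se = unname(tab[1, "Std.Error"]),
       p = unname(tab[1, "p-value"]), df = unname(tab[1, "DF"]),
       method = "lme", n_obs = nrow(d), n_patients = np)
}
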