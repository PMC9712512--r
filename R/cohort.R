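# ---- whole-muscle records, composites, longitudinal change -------------

#' Whole-muscle summary record
#'
#' @param muscle,side,patient,timepoint identifiers.
#' @param ff_whole whole-muscle fat fraction (percent).
#' @param volume muscle volume in ml (labeled voxel count times voxel
#'   volume).
#' @param n_slices number of profile slices.
#' @return one-row data.frame with an added `mercuri` severity class
#'   (`<10`, `10-30`, `30-60`, `>60`; half-open bands, lower bound
#'   included).
#' @export
muscle_record <- function(muscle, side, patient, timepoint, ff_whole,
                          volume, n_slices = NA_integer_) {
  if (!is.finite(volume) || volume <= 0) {
    stop("muscle volume must be positive", call. = FALSE)
  }
  data.frame(muscle = muscle, side = side, patient = patient,
             timepoint = timepoint, ff_whole = ff_whole, volume = volume,
             n_slices = n_slices, mercuri = mercuri_class(ff_whole))
}

#' Mercuri-style severity class of a fat fraction
#'
#' @param ff fat fraction (percent), vectorized.
#' @return factor with levels `<10`, `10-30`, `30-60`, `>60` (half-open
#'   bands: 10 falls in `10-30`, 60 in `>60`).
#' @export
mercuri_class <- function(ff) {
  cut(ff, breaks = c(-Inf, 10, 30, 60, Inf),
      labels = c("<10", "10-30", "30-60", ">60"), right = FALSE)
}

#' Baseline fat-fraction decile bin
#'
#' Assigns 10-percentage-point half-open bins `0-10`, `10-20`, ..., `80-90`.
#' Fat fractions of 90% or more are folded into `80-90` with a warning:
#' muscles that saturated the top bin are too few to carry their own group.
#'
#' @param ff baseline fat fraction (percent), vectorized.
#' @return factor with the nine ordered bin labels.
#' @export
baseline_bin <- function(ff) {
  lab <- paste0(seq(0, 80, 10), "-", seq(10, 90, 10))
  if (any(ff >= 90, na.rm = TRUE)) {
    warning(sprintf("%d fat fraction(s) >= 90%% folded into bin 80-90",
                    sum(ff >= 90, na.rm = TRUE)), call. = FALSE)
  }
  idx <- pmin(floor(ff / 10), 8)
  factor(lab[idx + 1], levels = lab)
}

#' Volume-weighted composite fat fraction
#'
#' Weighted average of whole-muscle fat fractions over a set of muscles,
#' each weighted by its volume, so larger muscles count more:
#' `sum(FF_m * V_m) / sum(V_m)`. Applied per leg region, compartment or the
#' whole lower extremity of a participant (both legs pooled into one
#' weighted set).
#'
#' @param records data.frame of muscle records (needs `ff_whole`,
#'   `volume`).
#' @param scope optional logical vector or predicate selecting records.
#' @return list with `ff` (percent) and `total_volume` (ml).
#' @export
composite_ff <- function(records, scope = NULL) {
  if (!is.null(scope)) {
    keep <- if (is.function(scope)) scope(records) else scope
    records <- records[keep, , drop = FALSE]
  }
  if (!nrow(records)) stop("no muscles in scope", call. = FALSE)
  list(ff = sum(records$ff_whole * records$volume) / sum(records$volume),
       total_volume = sum(records$volume))
}

#' Average left and right legs per muscle
#'
#' Volume-weighted mean over sides when both are present; a single side
#' passes through unchanged.
#'
#' @param records data.frame of muscle records (needs `muscle`, `side`,
#'   `patient`, `ff_whole`, `volume`).
#' @return data.frame with one row per patient x muscle: `ff_whole` the
#'   volume-weighted mean over available sides, `volume` their sum,
#'   `n_sides` the count.
#' @export
left_right_average <- function(records) {
  key <- interaction(records$patient, records$muscle, drop = TRUE)
  out <- lapply(split(records, key), function(g) {
    data.frame(patient = g$patient[1], muscle = g$muscle[1],
               ff_whole = sum(g$ff_whole * g$volume) / sum(g$volume),
               volume = sum(g$volume), n_sides = nrow(g))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Longitudinal change record for one muscle
#'
#' Change is `follow-up FF - baseline FF`; the annualized rate divides by
#' the follow-up interval in years. The record carries the muscle's
#' baseline 10-point bin for the progression-by-severity analyses.
#'
#' @param baseline,followup one-row muscle records (same muscle, side and
#'   patient).
#' @param interval_years follow-up interval, `> 0`.
#' @return one-row data.frame: identifiers, `ff_baseline`, `ff_followup`,
#'   `interval_years`, `change`, `change_per_year`, `baseline_bin`.
#' @export
longitudinal_change <- function(baseline, followup, interval_years) {
  if (!identical(unname(c(baseline$muscle, baseline$side, baseline$patient)),
                 unname(c(followup$muscle, followup$side, followup$patient)))) {
    stop("baseline and follow-up records identify different muscles",
         call. = FALSE)
  }
  if (!is.finite(interval_years) || interval_years <= 0) {
    stop("interval_years must be positive", call. = FALSE)
  }
  ch <- followup$ff_whole - baseline$ff_whole
  data.frame(muscle = baseline$muscle, side = baseline$side,
             patient = baseline$patient,
             ff_baseline = baseline$ff_whole,
             ff_followup = followup$ff_whole,
             interval_years = interval_years,
             change = ch, change_per_year = ch / interval_years,
             baseline_bin = baseline_bin(baseline$ff_whole))
}

#' Annualized change summarised per baseline bin
#'
#' @param records data.frame of longitudinal records (needs
#'   `change_per_year`, `baseline_bin`).
#' @return data.frame with one row per bin: `baseline_bin`, `n`, `mean`,
#'   `sd` (sample SD), `empty` flag for bins with no muscles (reported as
#'   missing, never as zero change).
#' @export
change_by_baseline_bin <- function(records) {
  if (!nrow(records)) stop("no longitudinal records", call. = FALSE)
  bins <- levels(records$baseline_bin)
  out <- data.frame(baseline_bin = factor(bins, levels = bins),
                    n = 0L, mean = NA_real_, sd = NA_real_, empty = TRUE)
  for (i in seq_along(bins)) {
    v <- records$change_per_year[records$baseline_bin == bins[i]]
    v <- v[!is.na(v)]
    if (length(v)) {
      out$n[i] <- length(v)
      out$mean[i] <- mean(v)
      out$sd[i] <- if (length(v) > 1) stats::sd(v) else NA_real_
      out$empty[i] <- FALSE
    }
  }
  out
}

#' Segment-wise change matrix (the wave analysis)
#'
#' For each muscle present at both timepoints, computes the change of each
#' of the five segment means (follow-up minus baseline, each timepoint on
#' its own relative-length axis), annualized, and aggregates mean, SD and n
#' per baseline whole-muscle bin x segment cell. This is the quantity whose
#' per-bin maximum moves proximally with severity — the wave signature of
#' the infiltrating front.
#'
#' @param baseline,followup lists of [muscle_profile()] objects; muscles are
#'   paired on (muscle, side).
#' @param interval_years follow-up interval, `> 0`.
#' @return data.frame in long format: `baseline_bin`, `segment`, `n`,
#'   `mean`, `sd`, `empty`.
#' @export
segment_change_matrix <- function(baseline, followup, interval_years) {
  if (!is.finite(interval_years) || interval_years <= 0) {
    stop("interval_years must be positive", call. = FALSE)
  }
  keyof <- function(p) paste(p$muscle, p$side, sep = "|")
  bkeys <- vapply(baseline, keyof, "")
  fkeys <- vapply(followup, keyof, "")
  unpaired <- union(setdiff(bkeys, fkeys), setdiff(fkeys, bkeys))
  if (length(unpaired)) {
    warning(sprintf("skipping %d unpaired muscle(s): %s", length(unpaired),
                    paste(utils::head(unpaired, 5), collapse = ", ")),
            call. = FALSE)
  }
  shared <- intersect(bkeys, fkeys)
  rows <- list()
  for (k in shared) {
    pb <- baseline[[match(k, bkeys)]]
    pf <- followup[[match(k, fkeys)]]
    sb <- segment_means(pb)
    sf <- segment_means(pf)
    rows[[k]] <- data.frame(
      baseline_bin = baseline_bin(whole_muscle_ff(pb)),
      segment = 1:5,
      dff_per_year = (sf$ff - sb$ff) / interval_years)
  }
  long <- do.call(rbind, rows)
  bins <- levels(long$baseline_bin)
  out <- expand.grid(baseline_bin = factor(bins, levels = bins),
                     segment = 1:5, KEEP.OUT.ATTRS = FALSE)
  out$n <- 0L; out$mean <- NA_real_; out$sd <- NA_real_; out$empty <- TRUE
  for (i in seq_len(nrow(out))) {
    v <- long$dff_per_year[long$baseline_bin == out$baseline_bin[i] &
                             long$segment == out$segment[i]]
    if (length(v)) {
      out$n[i] <- length(v)
      out$mean[i] <- mean(v)
      out$sd[i] <- if (length(v) > 1) stats::sd(v) else NA_real_
      out$empty[i] <- FALSE
    }
  }
  out[order(out$baseline_bin, out$segment), ]
}
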