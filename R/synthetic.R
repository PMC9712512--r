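# ---- synthetic phantom legs and cohorts --------------------------------

#' Configuration for one synthetic phantom leg
#'
#' Describes a phantom lower extremity: tubular muscles with elliptical
#' cross-sections laid out on a disjoint in-plane grid, each carrying a
#' reversed-sigmoid fat-front profile along its length, embedded in a
#' subcutaneous fat shell, acquired as overlapping axial Dixon stacks.
#' Front parameters are drawn per muscle: plateaus and width uniformly
#' within the stated ranges, and the front position solved so the
#' whole-muscle fat fraction hits a target drawn uniformly over
#' `target_ff`, which spreads muscles evenly over the severity bins the
#' way a mixed-severity patient cohort does.
#'
#' @param n_muscles number of muscles in the leg.
#' @param n_slices leg length in slices.
#' @param spacing voxel spacing in mm (default in-plane 1.36 mm, slice
#'   thickness 5 mm).
#' @param radius_mm range of elliptical cross-section radii.
#' @param span_slices range of muscle lengths in slices; default 55-85% of
#'   the leg length.
#' @param pi_top,pi_base,w_range uniform draw ranges for the front
#'   parameters.
#' @param target_ff range of whole-muscle fat-fraction targets (percent).
#' @param noise_sd voxelwise fat-fraction noise SD in percentage points.
#' @param shell_ff fat fraction of the subcutaneous shell (percent).
#' @param n_stacks,overlap_slices stack split; 9 overlapping slices at
#'   5 mm reproduce a 45 mm stack overlap.
#' @param side leg side label.
#' @param seed integer seed (mandatory: all draws are reproducible).
#' @return list of class `synthetic_leg_config`.
#' @export
synthetic_leg_config <- function(n_muscles = 12, n_slices = 80,
                                 spacing = c(1.36, 1.36, 5),
                                 radius_mm = c(6, 10),
                                 span_slices = NULL,
                                 pi_top = c(60, 95), pi_base = c(0, 6),
                                 w_range = c(0.04, 0.12),
                                 target_ff = c(3, 87),
                                 noise_sd = 2, shell_ff = 90,
                                 n_stacks = 2, overlap_slices = 9,
                                 side = "R", seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (is.null(span_slices)) {
    span_slices <- c(ceiling(0.55 * n_slices), floor(0.85 * n_slices))
  }
  stopifnot(n_muscles >= 1, n_slices >= 10, noise_sd >= 0,
            span_slices[2] <= n_slices, n_stacks >= 1)
  structure(as.list(environment()), class = "synthetic_leg_config")
}

# solve the front position so the whole-muscle mean hits `target`;
# front_coverage is increasing in x0, so uniroot on [-0.5, 1.5]
solve_front_x0 <- function(pi_top, pi_base, w, target) {
  c_lo <- front_coverage(-0.5, w)
  c_hi <- front_coverage(1.5, w)
  cv <- (target - pi_base) / (pi_top - pi_base)
  cv <- min(max(cv, c_lo + 1e-6), c_hi - 1e-6)
  stats::uniroot(function(x0) front_coverage(x0, w) - cv,
                 interval = c(-0.5, 1.5), tol = 1e-10)$root
}

# draw per-muscle front parameters; whole-muscle targets spread uniformly
draw_front_params <- function(config) {
  n <- config$n_muscles
  pt <- stats::runif(n, config$pi_top[1], config$pi_top[2])
  pb <- stats::runif(n, config$pi_base[1], config$pi_base[2])
  w <- stats::runif(n, config$w_range[1], config$w_range[2])
  tgt <- stats::runif(n, pmax(config$target_ff[1], pb + 1),
                      pmin(config$target_ff[2], pt - 1))
  lapply(seq_len(n), function(i) {
    front_params(pt[i], pb[i], solve_front_x0(pt[i], pb[i], w[i], tgt[i]),
                 w[i])
  })
}

# in-plane layout: elliptical cylinders on a grid with guaranteed clearance
draw_geometry <- function(config) {
  n <- config$n_muscles
  rmax_vox <- config$radius_mm[2] / config$spacing[1]
  pitch <- ceiling(2 * rmax_vox + 4)
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  nx <- ncol * pitch + pitch %/% 2
  ny <- nrow * pitch + pitch %/% 2
  centers <- expand.grid(cx = pitch %/% 2 + pitch * (seq_len(ncol) - 0.5),
                         cy = pitch %/% 2 + pitch * (seq_len(nrow) - 0.5))
  centers <- centers[seq_len(n), ]
  len <- round(stats::runif(n, config$span_slices[1], config$span_slices[2]))
  s0 <- vapply(len, function(l) {
    sample.int(config$n_slices - l + 1L, 1L)
  }, 0L)
  list(nx = nx, ny = ny,
       geometry = data.frame(
         label = seq_len(n),
         cx = centers$cx, cy = centers$cy,
         rx = stats::runif(n, config$radius_mm[1], config$radius_mm[2]) /
           config$spacing[1],
         ry = stats::runif(n, config$radius_mm[1], config$radius_mm[2]) /
           config$spacing[2],
         slice_start = s0, slice_end = s0 + len - 1L))
}

# rasterize labels and the noiseless per-voxel fat fraction for one leg
build_leg_arrays <- function(config, geom, params_list) {
  nx <- geom$nx; ny <- geom$ny; nz <- config$n_slices
  g <- geom$geometry
  labels <- array(0L, c(nx, ny, nz))
  ffmean <- array(NA_real_, c(nx, ny, nz))
  xi <- matrix(rep(seq_len(nx), ny), nx, ny)
  yi <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  for (m in seq_len(nrow(g))) {
    disk <- ((xi - g$cx[m]) / g$rx[m])^2 + ((yi - g$cy[m]) / g$ry[m])^2 <= 1
    span <- g$slice_start[m]:g$slice_end[m]
    xrel <- (span - g$slice_start[m]) / (length(span) - 1)
    ffslice <- eval_front(params_list[[m]], xrel)
    for (k in seq_along(span)) {
      sl <- labels[, , span[k]]
      if (any(sl[disk] != 0L)) {
        stop("overlapping muscle geometry in synthetic leg", call. = FALSE)
      }
      sl[disk] <- g$label[m]
      labels[, , span[k]] <- sl
      fs <- ffmean[, , span[k]]
      fs[disk] <- ffslice[k]
      ffmean[, , span[k]] <- fs
    }
  }
  # subcutaneous fat shell: 2-voxel frame around the in-plane border
  shell <- xi <= 2 | xi >= nx - 1 | yi <= 2 | yi >= ny - 1
  for (k in seq_len(nz)) {
    fs <- ffmean[, , k]
    fs[shell] <- config$shell_ff
    ffmean[, , k] <- fs
  }
  list(labels = labels, ffmean = ffmean)
}

#' Generate one synthetic phantom leg
#'
#' Builds the label map and noiseless front-model fat fractions, adds
#' voxelwise Gaussian noise in fat-fraction space (clipped to \[0, 100\]),
#' converts to Dixon fat/water intensity pairs `F = FF * I`,
#' `W = (100 - FF) * I` with constant total intensity, and splits the leg
#' into overlapping acquisition stacks. Voxels outside muscles and shell
#' have zero signal and come out as missing in the fat-fraction map.
#'
#' @param config a [synthetic_leg_config()].
#' @param params_list optional list of [front_params()] (one per muscle)
#'   overriding the random draw — used to regenerate a leg at a later
#'   timepoint from propagated fronts.
#' @param geom optional geometry (from a previous call) so longitudinal
#'   timepoints share anatomy.
#' @return list: `stacks` (list of [dixon_stack()]), `labels`
#'   ([muscle_label_map()]), `truth` (per-muscle front parameters and
#'   implied whole-muscle FF), `geom`, `params` (list of [front_params()]).
#' @export
generate_leg <- function(config, params_list = NULL, geom = NULL) {
  stopifnot(inherits(config, "synthetic_leg_config"))
  set.seed(as.integer(config$seed))
  if (is.null(params_list)) params_list <- draw_front_params(config)
  if (is.null(geom)) geom <- draw_geometry(config)
  arr <- build_leg_arrays(config, geom, params_list)

  ff <- arr$ffmean
  defined <- !is.na(ff)
  if (config$noise_sd > 0) {
    ff[defined] <- ff[defined] +
      stats::rnorm(sum(defined), 0, config$noise_sd)
  }
  ff[defined] <- pmin(pmax(ff[defined], 0), 100)
  intensity <- 1
  fat <- ifelse(defined, ff * intensity, 0)
  water <- ifelse(defined, (100 - ff) * intensity, 0)
  dim(fat) <- dim(water) <- dim(ff)

  dz <- config$spacing[3]
  nz <- config$n_slices
  ns <- config$n_stacks
  ov <- if (ns > 1) config$overlap_slices else 0L
  len <- ceiling((nz + (ns - 1) * ov) / ns)
  stacks <- vector("list", ns)
  for (i in seq_len(ns)) {
    a <- min(1L + (i - 1L) * (len - ov), nz - len + 1L)
    b <- min(a + len - 1L, nz)
    stacks[[i]] <- dixon_stack(fat[, , a:b, drop = FALSE],
                               water[, , a:b, drop = FALSE],
                               spacing = config$spacing,
                               axis_offset_mm = (a - 1L) * dz)
  }

  g <- geom$geometry
  tab <- data.frame(label = g$label,
                    muscle = sprintf("muscle%02d", g$label),
                    side = config$side,
                    region = ifelse(g$slice_start > nz / 2, "upper", "lower"),
                    compartment = "phantom")
  truth <- data.frame(
    label = g$label, muscle = tab$muscle, side = config$side,
    pi_top = vapply(params_list, `[[`, 0, "pi_top"),
    pi_base = vapply(params_list, `[[`, 0, "pi_base"),
    x0 = vapply(params_list, `[[`, 0, "x0"),
    w = vapply(params_list, `[[`, 0, "w"),
    ff_whole = vapply(params_list, front_mean_ff, 0),
    n_slices = g$slice_end - g$slice_start + 1L)

  list(stacks = stacks,
       labels = muscle_label_map(arr$labels, tab),
       truth = truth, geom = geom, params = params_list)
}

#' Configuration for a synthetic longitudinal cohort
#'
#' @param n_patients number of phantom patients.
#' @param follow_up_years interval between the two scans (default 3.67,
#'   i.e. 3 years and 8 months).
#' @param progression a [progression_config()] describing the front's
#'   FF-dependent velocity.
#' @param severity_range per-patient multiplier range applied to the peak
#'   velocity, modelling between-patient progression-rate heterogeneity.
#' @param leg a [synthetic_leg_config()] template (its seed is re-derived
#'   per patient).
#' @param seed master seed.
#' @return list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 9, follow_up_years = 3.67,
                                    progression = progression_config(),
                                    severity_range = c(0.6, 1.4),
                                    leg = NULL, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(follow_up_years > 0, n_patients >= 1)
  if (is.null(leg)) leg <- synthetic_leg_config(seed = seed)
  structure(list(n_patients = n_patients,
                 follow_up_years = follow_up_years,
                 progression = progression,
                 severity_range = severity_range,
                 leg = leg, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic longitudinal cohort
#'
#' One phantom leg per patient at baseline; the follow-up leg shares the
#' anatomy and regenerates the voxel data from fronts advanced with
#' [propagate_front()], using a per-patient severity multiplier on the peak
#' velocity. Per-leg seeds are derived from the master seed by fixed
#' offsets, so the whole cohort is reproducible from one integer.
#'
#' @param config a [synthetic_cohort_config()].
#' @return list with one element per patient: `patient` id, `baseline` and
#'   `followup` legs (as from [generate_leg()]), `interval_years`,
#'   `severity`, and `truth` — the per-muscle table with true baseline and
#'   follow-up whole-muscle FF and true change per year.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  set.seed(config$seed)
  sev <- stats::runif(config$n_patients, config$severity_range[1],
                      config$severity_range[2])
  out <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    legcfg <- config$leg
    legcfg$seed <- (config$seed + 1009L * p) %% .Machine$integer.max
    bl <- generate_leg(legcfg)
    law <- config$progression
    law$v_max <- law$v_max * sev[p]
    fu_params <- lapply(bl$params, propagate_front,
                        years = config$follow_up_years, rate_law = law)
    legcfg$seed <- (legcfg$seed + 499L) %% .Machine$integer.max
    fu <- generate_leg(legcfg, params_list = fu_params, geom = bl$geom)
    truth <- bl$truth
    truth$ff_whole_followup <- fu$truth$ff_whole
    truth$true_change_per_year <-
      (fu$truth$ff_whole - bl$truth$ff_whole) / config$follow_up_years
    out[[p]] <- list(patient = sprintf("P%02d", p), baseline = bl,
                     followup = fu,
                     interval_years = config$follow_up_years,
                     severity = sev[p], truth = truth)
  }
  out
}

#' Fast profile-level synthetic cohort
#'
#' Generates muscle profiles directly from the front model, bypassing
#' voxel rasterization: slice fat fractions are the front evaluated on the
#' relative-length grid plus Gaussian slice-mean noise, with a constant
#' voxel count per slice. Used for large sampling-bias and wave studies
#' where hundreds of muscles are needed and voxel-level detail adds nothing
#' but runtime; the voxel path is exercised by [generate_leg()].
#'
#' @param n_muscles number of muscles.
#' @param n_slices slices per muscle (scalar or range to draw from).
#' @param target_ff whole-muscle FF target range (percent).
#' @param noise_sd slice-mean noise SD in percentage points.
#' @param years follow-up interval; when `> 0` follow-up profiles are
#'   generated from propagated fronts.
#' @param progression a [progression_config()].
#' @param n_patients muscles are assigned to patients round-robin.
#' @param pi_top,pi_base,w_range front parameter draw ranges.
#' @param n_voxels_per_slice constant slice voxel count.
#' @param seed integer seed.
#' @return list: `baseline` and (when `years > 0`) `followup` lists of
#'   [muscle_profile()], `patients` assignment, `truth` data.frame.
#' @export
simulate_profile_cohort <- function(n_muscles = 200, n_slices = c(40, 70),
                                    target_ff = c(3, 87), noise_sd = 0.8,
                                    years = 0,
                                    progression = progression_config(),
                                    n_patients = 9,
                                    pi_top = c(60, 95), pi_base = c(0, 6),
                                    w_range = c(0.04, 0.12),
                                    n_voxels_per_slice = 120, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(as.integer(seed))
  if (length(n_slices) == 1L) n_slices <- rep(n_slices, 2)
  pt <- stats::runif(n_muscles, pi_top[1], pi_top[2])
  pb <- stats::runif(n_muscles, pi_base[1], pi_base[2])
  w <- stats::runif(n_muscles, w_range[1], w_range[2])
  tgt <- stats::runif(n_muscles, pmax(target_ff[1], pb + 1),
                      pmin(target_ff[2], pt - 1))
  ns <- round(stats::runif(n_muscles, n_slices[1], n_slices[2]))
  patients <- sprintf("P%02d", rep_len(seq_len(n_patients), n_muscles))

  mk_profile <- function(par, n, muscle, tp) {
    x <- (seq_len(n) - 1) / (n - 1)
    ffv <- eval_front(par, x) + stats::rnorm(n, 0, noise_sd)
    ffv <- pmin(pmax(ffv, 0), 100)
    muscle_profile(muscle, "R", tp, seq_len(n), ffv,
                   rep(n_voxels_per_slice, n))
  }

  params <- lapply(seq_len(n_muscles), function(i) {
    front_params(pt[i], pb[i], solve_front_x0(pt[i], pb[i], w[i], tgt[i]),
                 w[i])
  })
  names <- sprintf("muscle%03d", seq_len(n_muscles))
  base <- lapply(seq_len(n_muscles), function(i) {
    mk_profile(params[[i]], ns[i], names[i], "baseline")
  })
  truth <- data.frame(
    muscle = names, patient = patients,
    pi_top = pt, pi_base = pb, w = w,
    x0 = vapply(params, `[[`, 0, "x0"),
    ff_whole = vapply(params, front_mean_ff, 0),
    n_slices = ns)
  out <- list(baseline = base, patients = patients, truth = truth,
              params = params)
  if (years > 0) {
    fu_params <- lapply(params, propagate_front, years = years,
                        rate_law = progression)
    out$followup <- lapply(seq_len(n_muscles), function(i) {
      mk_profile(fu_params[[i]], ns[i], names[i], "followup")
    })
    out$truth$ff_whole_followup <- vapply(fu_params, front_mean_ff, 0)
    out$truth$true_change_per_year <-
      (out$truth$ff_whole_followup - out$truth$ff_whole) / years
    out$fu_params <- fu_params
  }
  out
}
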