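# ---- domain containers -------------------------------------------------

#' Dixon acquisition stack
#'
#' Bundles co-registered fat and water magnitude volumes from a 2-point
#' Dixon acquisition, together with the grid geometry needed to place the
#' stack along the leg axis. Slice index runs along the third array axis;
#' with `distal_first = TRUE` slice 1 is the most distal slice.
#'
#' @param fat,water 3D non-negative intensity arrays of identical dimension.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param axis_offset_mm position (mm) of the stack's first slice along the
#'   distal-to-proximal leg axis.
#' @param distal_first logical; `TRUE` when slice 1 is most distal.
#' @return An object of class `dixon_stack`.
#' @export
dixon_stack <- function(fat, water, spacing = c(1.36, 1.36, 5),
                        axis_offset_mm = 0, distal_first = TRUE) {
  if (!identical(dim(fat), dim(water)) || length(dim(fat)) != 3L) {
    stop("fat and water volumes must be 3D arrays of identical dimension",
         call. = FALSE)
  }
  if (any(fat < 0, na.rm = TRUE) || any(water < 0, na.rm = TRUE)) {
    stop("Dixon intensities must be non-negative", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be three strictly positive values (mm)",
         call. = FALSE)
  }
  structure(
    list(fat = fat, water = water, spacing = spacing,
         axis_offset_mm = as.numeric(axis_offset_mm),
         distal_first = isTRUE(distal_first)),
    class = "dixon_stack"
  )
}

#' Fat-fraction volume
#'
#' Voxelwise fat fraction (percent, 0-100) on a 3D grid. Voxels where the
#' total Dixon signal was at or below the noise threshold carry `NA` and are
#' excluded from every downstream mean.
#'
#' @param ff 3D array of percent values with `NA` as the missing marker.
#' @param spacing voxel spacing `(dx, dy, dz)` in mm.
#' @param axis_offset_mm leg-axis position (mm) of slice 1.
#' @param distal_first logical orientation flag (slice 1 most distal).
#' @return An object of class `ff_volume`.
#' @export
ff_volume <- function(ff, spacing = c(1.36, 1.36, 5), axis_offset_mm = 0,
                      distal_first = TRUE) {
  if (length(dim(ff)) != 3L) stop("ff must be a 3D array", call. = FALSE)
  rng <- if (all(is.na(ff))) c(NA_real_, NA_real_) else range(ff, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < -1e-9 || rng[2] > 100 + 1e-9)) {
    stop("defined fat-fraction values must lie in [0, 100]", call. = FALSE)
  }
  structure(
    list(ff = ff, spacing = as.numeric(spacing),
         axis_offset_mm = as.numeric(axis_offset_mm),
         distal_first = isTRUE(distal_first)),
    class = "ff_volume"
  )
}

#' Scanner-upgrade harmonization model
#'
#' Linear voxelwise correction mapping pre-upgrade baseline fat fractions
#' onto the post-upgrade scale, `FF' = clip(slope * FF + intercept, 0, 100)`.
#' The default coefficients are the cross-calibration fitted on patients
#' scanned just before and after a reconstruction-software upgrade.
#'
#' @param slope unitless gain; must be positive (monotone correction).
#' @param intercept offset in percentage points.
#' @param clip_low,clip_high output clipping bounds (percent).
#' @return An object of class `harmonization_model`.
#' @export
harmonization_model <- function(slope = 1.1864, intercept = -2.7878,
                                clip_low = 0, clip_high = 100) {
  if (!is.finite(slope) || slope <= 0) {
    stop("harmonization slope must be positive", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 clip_low = clip_low, clip_high = clip_high),
            class = "harmonization_model")
}

#' Muscle label map
#'
#' Integer label volume (0 = background) plus the table mapping label ids to
#' muscle name, side, leg region and compartment, and an optional exclusion
#' list of (muscle, side, timepoint) rows for muscles unusable at a given
#' timepoint (e.g. fat-water swaps, which are excluded manually and never
#' detected automatically).
#'
#' @param labels 3D integer array, same grid as the fat-fraction volume.
#' @param label_table data.frame with columns `label`, `muscle`, `side`,
#'   `region`, `compartment`.
#' @param exclusions optional data.frame with columns `muscle`, `side`,
#'   `timepoint`.
#' @return An object of class `muscle_label_map`.
#' @export
muscle_label_map <- function(labels, label_table, exclusions = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array", call. = FALSE)
  needed <- c("label", "muscle", "side", "region", "compartment")
  if (!all(needed %in% names(label_table))) {
    stop("label_table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  missing <- setdiff(present, label_table$label)
  if (length(missing)) {
    stop("label id(s) absent from label table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, label_table = label_table,
                 exclusions = exclusions),
            class = "muscle_label_map")
}

# ---- operations --------------------------------------------------------

#' Compute a fat-fraction map from a Dixon stack
#'
#' `FF = 100 * F / (F + W)` per voxel. Voxels with total signal
#' `F + W <= epsilon` get `NA`: dividing the noise floor by itself would
#' otherwise paint the background with meaningless fractions.
#'
#' @param stack a [dixon_stack()].
#' @param epsilon non-negative intensity threshold; default 0 masks only
#'   exact zero-signal voxels.
#' @return An [ff_volume()] on the same grid.
#' @examples
#' st <- dixon_stack(array(60, c(2, 2, 3)), array(40, c(2, 2, 3)))
#' compute_ff_map(st)$ff[1, 1, 1]  # 60
#' @export
compute_ff_map <- function(stack, epsilon = 0) {
  stopifnot(inherits(stack, "dixon_stack"))
  if (!is.finite(epsilon) || epsilon < 0) {
    stop("epsilon must be a non-negative intensity", call. = FALSE)
  }
  tot <- stack$fat + stack$water
  ff <- ifelse(tot > epsilon, 100 * stack$fat / tot, NA_real_)
  dim(ff) <- dim(stack$fat)
  ff_volume(ff, spacing = stack$spacing,
            axis_offset_mm = stack$axis_offset_mm,
            distal_first = stack$distal_first)
}

#' Apply the scanner-upgrade harmonization to a fat-fraction volume
#'
#' Maps every defined voxel through the linear model and clips to
#' `[clip_low, clip_high]`; the raw line sends fat fractions below the zero
#' crossing (about 2.35%) negative and very high fractions above 100, so
#' clipping preserves the fat-fraction range invariant. Missing voxels pass
#' through unchanged. Intended for baseline maps only.
#'
#' @param ff an [ff_volume()].
#' @param model a [harmonization_model()].
#' @return The harmonized [ff_volume()].
#' @export
harmonize_ff <- function(ff, model = harmonization_model()) {
  stopifnot(inherits(ff, "ff_volume"), inherits(model, "harmonization_model"))
  v <- model$slope * ff$ff + model$intercept
  v <- pmin(pmax(v, model$clip_low), model$clip_high)
  out <- ff
  out$ff <- v
  dim(out$ff) <- dim(ff$ff)
  out
}

#' Stitch overlapping acquisition stacks into one volume
#'
#' Lower-extremity coverage from hip to ankle is acquired as several axial
#' stacks with a fixed overlap (typically 45 mm = 9 slices at 5 mm). This
#' concatenates them into a single distal-to-proximal volume. In overlap
#' regions the default `"distance"` policy takes each output slice from the
#' stack in which that slice lies farther from the stack edge, because coil
#' sensitivity (and hence Dixon quality) degrades towards stack edges;
#' `"average"` averages the contributing stacks voxelwise instead.
#'
#' @param stacks list of [ff_volume()] objects with identical in-plane grids
#'   and slice spacing, each carrying its `axis_offset_mm`.
#' @param blend `"distance"` (default) or `"average"`.
#' @return A single [ff_volume()] spanning the union extent.
#' @export
stitch_stacks <- function(stacks, blend = c("distance", "average")) {
  blend <- match.arg(blend)
  if (!length(stacks)) stop("need at least one stack", call. = FALSE)
  stopifnot(all(vapply(stacks, inherits, TRUE, "ff_volume")))
  if (length(stacks) == 1L) return(stacks[[1]])

  d1 <- dim(stacks[[1]]$ff)[1:2]
  sp <- stacks[[1]]$spacing
  for (s in stacks[-1]) {
    if (!identical(dim(s$ff)[1:2], d1)) {
      stop("in-plane grid mismatch between stacks", call. = FALSE)
    }
    if (abs(s$spacing[3] - sp[3]) > 1e-9) {
      stop("slice spacing differs between stacks", call. = FALSE)
    }
  }
  dz <- sp[3]
  ord <- order(vapply(stacks, function(s) s$axis_offset_mm, 0))
  stacks <- stacks[ord]
  start <- vapply(stacks, function(s) s$axis_offset_mm, 0) / dz
  if (any(abs(start - round(start)) > 1e-6)) {
    stop("stack offsets must be integer multiples of the slice thickness",
         call. = FALSE)
  }
  start <- as.integer(round(start))          # global index of slice 1, 0-based
  nsl <- vapply(stacks, function(s) dim(s$ff)[3], 0L)
  end <- start + nsl - 1L
  for (i in seq_along(stacks)[-1]) {
    if (start[i] > end[i - 1L] + 1L) {
      stop(sprintf("gap of %d slice(s) between stacks %d and %d",
                   start[i] - end[i - 1L] - 1L, i - 1L, i), call. = FALSE)
    }
  }
  g0 <- start[1]
  ntot <- max(end) - g0 + 1L
  out <- array(NA_real_, c(d1, ntot))
  if (blend == "average") {
    acc <- array(0, c(d1, ntot)); cnt <- array(0, c(d1, ntot))
    for (i in seq_along(stacks)) {
      idx <- (start[i] - g0 + 1L):(end[i] - g0 + 1L)
      v <- stacks[[i]]$ff
      ok <- !is.na(v)
      acc[, , idx][ok] <- acc[, , idx][ok] + v[ok]
      cnt[, , idx][ok] <- cnt[, , idx][ok] + 1
    }
    out <- ifelse(cnt > 0, acc / cnt, NA_real_)
    dim(out) <- c(d1, ntot)
  } else {
    for (g in seq_len(ntot) - 1L + g0) {      # global slice index, 0-based
      covers <- which(start <= g & g <= end)
      # distance of slice g to the nearest edge of each covering stack
      edge <- pmin(g - start[covers], end[covers] - g)
      pick <- covers[which.max(edge)]          # ties -> most distal stack
      out[, , g - g0 + 1L] <- stacks[[pick]]$ff[, , g - start[pick] + 1L]
    }
  }
  ff_volume(out, spacing = sp, axis_offset_mm = g0 * dz,
            distal_first = stacks[[1]]$distal_first)
}

#' Align baseline and follow-up volumes to shared coverage
#'
#' Longitudinal comparisons require both scans to cover the same
#' proximo-distal extent in the feet-to-head direction. Both volumes (and
#' their label maps, when given) are cropped along the slice axis to the
#' intersection of their coverage. Voxelwise registration is deliberately
#' not performed: all per-muscle analyses use each timepoint's own
#' relative-length axis, so only consistent coverage matters.
#'
#' @param baseline,followup [ff_volume()] objects, both distal-first.
#' @param baseline_labels,followup_labels optional matching label arrays.
#' @return list with cropped `baseline`, `followup` and, when supplied,
#'   `baseline_labels`, `followup_labels`.
#' @export
align_timepoints <- function(baseline, followup,
                             baseline_labels = NULL, followup_labels = NULL) {
  stopifnot(inherits(baseline, "ff_volume"), inherits(followup, "ff_volume"))
  if (!baseline$distal_first || !followup$distal_first) {
    stop("volumes must be normalized distal-first before alignment",
         call. = FALSE)
  }
  dz <- baseline$spacing[3]
  if (abs(dz - followup$spacing[3]) > 1e-9) {
    stop("slice spacing differs between timepoints", call. = FALSE)
  }
  span <- function(v) c(v$axis_offset_mm,
                        v$axis_offset_mm + (dim(v$ff)[3] - 1L) * dz)
  sb <- span(baseline); sf <- span(followup)
  lo <- max(sb[1], sf[1]); hi <- min(sb[2], sf[2])
  if (lo > hi + 1e-9) {
    stop("baseline and follow-up coverage do not overlap", call. = FALSE)
  }
  crop <- function(v, lab) {
    i0 <- as.integer(round((lo - v$axis_offset_mm) / dz)) + 1L
    i1 <- as.integer(round((hi - v$axis_offset_mm) / dz)) + 1L
    v$ff <- v$ff[, , i0:i1, drop = FALSE]
    v$axis_offset_mm <- lo
    if (!is.null(lab)) lab <- lab[, , i0:i1, drop = FALSE]
    list(vol = v, lab = lab)
  }
  b <- crop(baseline, baseline_labels)
  f <- crop(followup, followup_labels)
  out <- list(baseline = b$vol, followup = f$vol)
  if (!is.null(baseline_labels)) out$baseline_labels <- b$lab
  if (!is.null(followup_labels)) out$followup_labels <- f$lab
  out
}
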