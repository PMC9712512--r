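# fixture builders shared across the suite; everything is generated in
# code under a caller-supplied seed

# a profile with given per-slice fat fractions and voxel counts
mk_profile <- function(ff, n_voxels = rep(100, length(ff)),
                       muscle = "m", side = "R", tp = "baseline") {
  muscle_profile(muscle, side, tp, seq_along(ff), ff, n_voxels)
}

# random profile: slice count, fat fractions and voxel counts all drawn
rand_profile <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:60, 1)
  mk_profile(runif(n, 0, 100), n_voxels = sample(20:300, n, replace = TRUE))
}

# tiny voxel-level fixture: one muscle whose slice k holds `per_slice[k]`
# everywhere, with per-slice voxel counts controlled by the mask width
mk_voxel_fixture <- function(per_slice, widths = NULL) {
  nz <- length(per_slice)
  nx <- 12L
  if (is.null(widths)) widths <- sample(2:10, nz, replace = TRUE)
  ff <- array(NA_real_, c(nx, nx, nz))
  lab <- array(0L, c(nx, nx, nz))
  for (k in seq_len(nz)) {
    wdt <- widths[k]
    ff[seq_len(wdt), seq_len(wdt), k] <- per_slice[k]
    lab[seq_len(wdt), seq_len(wdt), k] <- 1L
  }
  list(
    ff = ff_volume(ff),
    labels = muscle_label_map(
      lab, data.frame(label = 1L, muscle = "m1", side = "R",
                      region = "lower", compartment = "c")),
    widths = widths)
}

# profile evaluated from a noiseless front model on an even grid
front_profile <- function(params, n, n_voxels = 100, tp = "baseline",
                          muscle = "m", side = "R") {
  x <- (seq_len(n) - 1) / (n - 1)
  mk_profile(eval_front(params, x), n_voxels = rep(n_voxels, n),
             muscle = muscle, side = side, tp = tp)
}
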