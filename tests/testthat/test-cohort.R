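# whole-muscle records, composites, longitudinal change, wave matrix

test_that("composite FF is the volume-weighted mean, bounded and order-invariant", {
  rec <- rbind(
    muscle_record("a", "R", "P1", "baseline", 30, 200),
    muscle_record("b", "R", "P1", "baseline", 60, 100))
  expect_equal(composite_ff(rec)$ff, 40)
  expect_equal(composite_ff(rec[1, ])$ff, 30)
  expect_equal(composite_ff(rec[2:1, ])$ff, composite_ff(rec)$ff)
  set.seed(9)
  many <- do.call(rbind, lapply(1:12, function(i) {
    muscle_record(paste0("m", i), "R", "P1", "baseline",
                  runif(1, 0, 100), runif(1, 20, 500))
  }))
  cmp <- composite_ff(many)$ff
  expect_true(cmp >= min(many$ff_whole) && cmp <= max(many$ff_whole))
  expect_error(composite_ff(many, scope = rep(FALSE, 12)), "no muscles")
})

test_that("composite equals the voxel-level fat-signal fraction on a shared grid", {
  # muscles as voxel sets: volume-weighted mean of voxel-mean FFs equals
  # the pooled voxel mean
  set.seed(21)
  voxels <- lapply(1:5, function(i) runif(sample(50:200, 1), 0, 100))
  rec <- do.call(rbind, lapply(seq_along(voxels), function(i) {
    muscle_record(paste0("m", i), "R", "P1", "baseline",
                  mean(voxels[[i]]), length(voxels[[i]]))
  }))
  expect_equal(composite_ff(rec)$ff, mean(unlist(voxels)), tolerance = 1e-12)
})

test_that("left/right averaging is volume-weighted with single-side passthrough", {
  rec <- rbind(
    muscle_record("ta", "L", "P1", "baseline", 30, 100),
    muscle_record("ta", "R", "P1", "baseline", 50, 100),
    muscle_record("sol", "L", "P1", "baseline", 12, 80),
    muscle_record("gm", "L", "P1", "baseline", 20, 100),
    muscle_record("gm", "R", "P1", "baseline", 40, 300))
  avg <- left_right_average(rec)
  expect_equal(avg$ff_whole[avg$muscle == "ta"], 40)
  expect_equal(avg$ff_whole[avg$muscle == "sol"], 12)
  expect_equal(avg$ff_whole[avg$muscle == "gm"], (20 * 100 + 40 * 300) / 400)
  expect_equal(avg$n_sides[avg$muscle == "sol"], 1)
})

test_that("longitudinal change and annualized rate follow their definitions", {
  b <- muscle_record("gm", "R", "P1", "baseline", 20, 100)
  f <- muscle_record("gm", "R", "P1", "followup", 30, 95)
  lc <- longitudinal_change(b, f, 2.5)
  expect_equal(lc$change, 10)
  expect_equal(lc$change_per_year, 4)
  expect_equal(lc$change, lc$change_per_year * lc$interval_years)
  same <- longitudinal_change(b, b, 2.5)
  expect_equal(same$change, 0)
  expect_equal(same$change_per_year, 0)
  # half-open bin convention at the boundary
  b30 <- muscle_record("gm", "R", "P1", "baseline", 30, 100)
  expect_equal(as.character(longitudinal_change(b30, f, 1)$baseline_bin),
               "30-40")
  other <- muscle_record("vl", "R", "P1", "followup", 30, 95)
  expect_error(longitudinal_change(b, other, 2.5), "different muscles")
  expect_error(longitudinal_change(b, f, 0), "positive")
  expect_warning(baseline_bin(93), "folded")
})

test_that("per-bin change summaries report sample SD and flag empty bins", {
  rec <- do.call(rbind, lapply(1:3, function(i) {
    b <- muscle_record(paste0("m", i), "R", "P1", "baseline", 15, 100)
    f <- muscle_record(paste0("m", i), "R", "P1", "followup", 15 + i, 100)
    longitudinal_change(b, f, 1)
  }))
  out <- change_by_baseline_bin(rec)
  row <- out[out$baseline_bin == "10-20", ]
  expect_equal(row$mean, 2)
  expect_equal(row$sd, 1)
  expect_equal(row$n, 3L)
  expect_true(all(out$empty[out$baseline_bin != "10-20"]))
  expect_true(all(is.na(out$mean[out$empty])))
})

test_that("segment change matrix is zero for identical timepoints and localizes front advance", {
  p <- front_profile(front_params(80, 5, 0.5, 0.08), 40)
  m0 <- segment_change_matrix(list(p), list(p), 2)
  expect_true(all(abs(m0$mean[!m0$empty]) < 1e-12))

  # noiseless front advanced from x0 = 0.2 to 0.4: analytic per-segment
  # change computed directly from the model concentrates in segments 1-2
  pb <- front_profile(front_params(80, 0, 0.2, 0.05), 60)
  pf <- front_profile(front_params(80, 0, 0.4, 0.05), 60, tp = "followup")
  m <- segment_change_matrix(list(pb), list(pf), 1)
  m <- m[!m$empty, ]
  x <- (0:59) / 59
  seg <- pmin(floor((100 * x) / 20) + 1, 5)
  dff <- eval_front(front_params(80, 0, 0.4, 0.05), x) -
    eval_front(front_params(80, 0, 0.2, 0.05), x)
  oracle <- as.numeric(tapply(dff, seg, mean))
  expect_equal(m$mean, oracle, tolerance = 1e-12)
  # the front sweeps [0.2, 0.4]: segment 2 carries the bulk of the change,
  # its shoulders spill into segments 1 and 3, the proximal muscle is quiet
  expect_equal(which.max(m$mean), 2L)
  expect_true(all(m$mean[4:5] < 0.05 * m$mean[2]))

  # fully infiltrated at both timepoints: nothing changes
  full <- front_profile(front_params(85, 5, 1.4, 0.05), 40)
  mfull <- segment_change_matrix(list(full), list(full), 3)
  expect_true(all(abs(mfull$mean[!mfull$empty]) < 1e-9))

  # unpaired muscles are skipped with a warning
  q <- front_profile(front_params(50, 0, 0.5, 0.1), 40, muscle = "other")
  expect_warning(segment_change_matrix(list(pb, q), list(pf), 1),
                 "unpaired")
})
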