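# per-slice profiles, length normalization, segments, slice schemes

test_that("extract_profile returns distal-first slice means on the relative axis", {
  fix <- mk_voxel_fixture(rep(40, 20), widths = rep(5, 20))
  p <- extract_profile(fix$ff, fix$labels, 1L)
  expect_equal(p$n_slices, 20)
  expect_equal(p$ff, rep(40, 20))
  expect_equal(p$n_voxels, rep(25, 20))
  # positions: 100 * i / (N - 1), endpoints exactly 0 and 100
  expect_equal(p$relative_pos, 100 * (0:19) / 19)
  expect_error(extract_profile(fix$ff, fix$labels, 99L), "absent")
})

test_that("single-slice muscles are rejected and interior holes dropped with warning", {
  fix <- mk_voxel_fixture(c(10), widths = 3)
  expect_error(extract_profile(fix$ff, fix$labels, 1L), "single-slice")
  set.seed(5)
  fix2 <- mk_voxel_fixture(seq(10, 55, by = 5))
  fix2$labels$labels[, , 4] <- 0L    # segmentation hole inside the span
  expect_warning(p <- extract_profile(fix2$ff, fix2$labels, 1L),
                 "dropped 1 empty slice")
  expect_equal(p$n_slices, 9)
  expect_false(4L %in% p$slice_index)
})

test_that("whole-muscle FF is voxel-weighted and equals the voxelwise mean", {
  p <- mk_profile(c(10, 30), n_voxels = c(100, 300))
  expect_equal(whole_muscle_ff(p), 25)
  expect_equal(whole_muscle_ff(mk_profile(rep(7.5, 9))), 7.5)
  # brute-force voxel oracle on randomized fixtures
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    vals <- runif(n, 0, 100)
    fix <- mk_voxel_fixture(vals)
    p <- extract_profile(fix$ff, fix$labels, 1L)
    oracle <- mean(fix$ff$ff[fix$labels$labels == 1L], na.rm = TRUE)
    expect_equal(whole_muscle_ff(p), oracle, tolerance = 1e-9)
  }
})

test_that("segment means follow the half-open 20% bins", {
  # hand enumeration at pos_i = 100 i / 9: slices pair up 2-per-segment
  p <- mk_profile(c(50, 50, 40, 40, 30, 30, 20, 20, 10, 10))
  expect_equal(segment_means(p)$ff, c(50, 40, 30, 20, 10))
  # n = 5: positions 0, 25, 50, 75, 100 fall one per bin
  p5 <- mk_profile(c(9, 7, 5, 3, 1))
  s5 <- segment_means(p5)
  expect_equal(s5$ff, c(9, 7, 5, 3, 1))
  expect_equal(s5$n_slices, rep(1L, 5))
  const <- segment_means(mk_profile(rep(42, 17)))
  expect_equal(const$ff, rep(42, 5))
  expect_error(segment_means(mk_profile(c(1, 2, 3, 4))), ">= 5 slices")
})

test_that("segment means reproduce a brute-force bin-assignment oracle", {
  set.seed(77)
  for (i in 1:50) {
    p <- rand_profile()
    got <- segment_means(p)
    bins <- pmin(floor(p$relative_pos / 20) + 1, 5)
    for (s in 1:5) {
      idx <- bins == s
      expect_equal(got$ff[s],
                   weighted.mean(p$ff[idx], p$n_voxels[idx]),
                   tolerance = 1e-12)
    }
  }
})

test_that("slice-selection schemes match their stated index rules", {
  expect_equal(select_slices("central5", 11), 4:8)       # floor((11-5)/2)=3
  expect_equal(select_slices("central5", 5), 1:5)
  expect_equal(select_slices("spread5", 21), c(3, 7, 11, 15, 19))
  expect_equal(select_slices("whole", 7), 1:7)
  expect_error(select_slices("spread5", 4), "at least 5")
  # property: spread5 indices non-decreasing and in range for all N
  for (n in 5:200) {
    idx <- select_slices("spread5", n)
    expect_false(is.unsorted(idx))
    expect_true(all(idx >= 1 & idx <= n))
    expect_length(idx, 5)
  }
})

test_that("subsampled FF realizes the reduced acquisition means", {
  const <- mk_profile(rep(33, 20))
  expect_equal(subsampled_ff(const, "central5"), 33)
  expect_equal(subsampled_ff(const, "spread5"), 33)
  # central window of an odd-length linear profile hits the midpoint value
  lin <- mk_profile(seq(90, 10, length.out = 11))
  expect_equal(subsampled_ff(lin, "central5"), lin$ff[6])
  # step profile, N = 20: rounded spread positions put 2 of 5 slices in the
  # high distal half -> 2/5 * 80 = 32
  step <- mk_profile(c(rep(80, 10), rep(0, 10)))
  expect_equal(subsampled_ff(step, "spread5"), 32)
})

test_that("profile-shape heuristic follows its fixed rule order", {
  expect_equal(classify_profile_shape(c(50, 40, 30, 20, 10)), "decreasing")
  expect_equal(classify_profile_shape(c(10, 10, 10, 10, 10)), "homogeneous")
  expect_equal(classify_profile_shape(c(40, 20, 10, 20, 40)), "u_shape")
  expect_equal(classify_profile_shape(c(10, 20, 30, 40, 50)), "reversed")
  expect_equal(classify_profile_shape(c(10, 40, 20, 5, 12)), "other")
})

test_that("profile tables round-trip through their CSV shape", {
  set.seed(12)
  profs <- list(rand_profile(12), rand_profile(8))
  profs[[2]]$muscle <- "m2"
  tab <- profile_table(profs)
  expect_equal(names(tab), c("muscle", "side", "timepoint", "slice_index",
                             "relative_pos", "ff", "n_voxels"))
  back <- profiles_from_table(tab)
  key <- vapply(back, function(p) p$muscle, "")
  for (p in profs) {
    q <- back[[which(key == p$muscle)]]
    expect_equal(q$ff, p$ff)
    expect_equal(q$n_voxels, p$n_voxels)
  }
})
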