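test_that("roi_mask matches the brute-force discrete-disc oracle", {
  grid <- c(30, 30)
  for (d in c(1, 2, 3, 4, 5, 7)) {
    roi <- roi_mask(c(15, 15), d, grid)
    oracle <- brute_force_disc(c(15, 15), d, grid)
    expect_equal(unname(roi$mask), unname(oracle),
                 info = paste("diameter", d))
  }
  expect_equal(nrow(roi_mask(c(10, 10), 1, grid)$mask), 1L)
  expect_equal(unname(roi_mask(c(10, 10), 1, grid)$mask[1, ]), c(10, 10))
})

test_that("roi_mask clips at grid edges and rejects out-of-grid centers", {
  roi <- roi_mask(c(1, 1), 4, c(20, 20))
  expect_true(all(roi$mask >= 1))
  interior <- roi_mask(c(10, 10), 4, c(20, 20))
  expect_lt(nrow(roi$mask), nrow(interior$mask))
  expect_error(roi_mask(c(0, 5), 4, c(20, 20)), "outside")
  expect_error(roi_mask(c(5, 25), 4, c(20, 20)), "outside")
})

test_that("roi_mask is translation-equivariant away from grid edges", {
  grid <- c(40, 40)
  base <- roi_mask(c(20, 20), 4, grid)
  for (shift in list(c(3, 0), c(0, -4), c(5, 7), c(-6, 2))) {
    moved <- roi_mask(c(20, 20) + shift, 4, grid)
    expect_equal(unname(moved$mask),
                 unname(sweep(base$mask, 2, -shift)))
  }
})

test_that("dynamic series validates counts and timebase", {
  arr <- array(1, dim = c(5, 8, 8))
  expect_s3_class(dynamic_planar_series(arr, 1), "dynamic_planar_series")
  bad <- arr; bad[1, 1, 1] <- -1
  expect_error(dynamic_planar_series(bad, 1), "non-negative")
  expect_error(dynamic_planar_series(arr, 0), "positive")
  expect_equal(frame_times(dynamic_planar_series(arr, 2)),
               c(1, 3, 5, 7, 9))
})

test_that("dynamic series round-trips through NIfTI + sidecar losslessly", {
  set.seed(42)
  arr <- array(rpois(10 * 16 * 16, 50), dim = c(10, 16, 16))
  series <- dynamic_planar_series(arr, 1, pixel_size_mm = 4)
  path <- tempfile(fileext = ".nii.gz")
  write_dynamic_series(series, path)
  back <- read_dynamic_series(path)
  expect_equal(back$frames, series$frames + 0)  # numeric but identical values
  expect_equal(back$frame_duration_s, 1)
  expect_equal(back$pixel_size_mm, 4)
  unlink(c(path, sub("\\.nii\\.gz$", ".yaml", path)))
})

test_that("read_dynamic_series rejects non-4D input", {
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(8, 8, 8))), path)
  expect_error(read_dynamic_series(path), "expected 4D")
  expect_error(read_dynamic_series(tempfile(fileext = ".nii")), "not found")
  unlink(path)
})

test_that("volume + template reader verifies grids and segment coverage", {
  tpl <- make_srt_template(c(16, 16, 16))
  vol <- spect_volume(array(5, dim = c(16, 16, 16)))
  vp <- tempfile(fileext = ".nii.gz"); tp <- tempfile(fileext = ".nii.gz")
  write_volume(vol, vp); write_volume(tpl, tp)
  got <- read_volume_and_template(vp, tp)
  expect_equal(nrow(got$template$segments), 24L)
  expect_equal(dim(got$volume$voxels), c(16L, 16L, 16L))

  ## grid mismatch
  vp2 <- tempfile(fileext = ".nii.gz")
  write_volume(spect_volume(array(1, dim = c(8, 8, 8))), vp2)
  expect_error(read_volume_and_template(vp2, tp), "does not match")

  ## undeclared label
  bad <- tpl$labels; bad[1, 1, 1] <- 25L
  tp2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), tp2)
  expect_error(read_volume_and_template(vp, tp2), "do not map")

  ## one hemisphere absent
  half <- tpl$labels; half[half > 12L] <- 0L
  tp3 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(half), tp3)
  expect_error(read_volume_and_template(vp, tp3), "right_")
  unlink(c(vp, tp, vp2, tp2, tp3))
})

test_that("analysis config validates and round-trips through YAML", {
  cfg <- analysis_config(lassen_alpha = 2, ccf = 0.8, normal_side = "right",
                         pp_hemisphere_roi = c(12, 32))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$lassen_alpha, 2)
  expect_equal(back$ccf, 0.8)
  expect_equal(back$normal_side, "right")
  expect_equal(back$pp_hemisphere_roi, c(12, 32))
  expect_error(analysis_config(lassen_alpha = -1), "lassen_alpha")
  expect_error(analysis_config(ccf = 0), "ccf")
  expect_error(analysis_config(basal_ganglia_segments = character(0)),
               "nonempty")
  yaml::write_yaml(list(not_a_field = 1), path)
  expect_error(read_config(path), "unknown config fields")
  unlink(path)
})

test_that("TAC CSV export round-trips", {
  tac <- time_activity_curve(1:10, (1:10)^2)
  path <- tempfile(fileext = ".csv")
  write_tac_csv(tac, path)
  back <- read_tac_csv(path)
  expect_equal(back$times_s, tac$times_s)
  expect_equal(back$counts, tac$counts)
  unlink(path)
})

test_that("TAC constructor enforces its invariants", {
  expect_error(time_activity_curve(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(time_activity_curve(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(time_activity_curve(1:3, c(1, -2, 3)), "non-negative")
})
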