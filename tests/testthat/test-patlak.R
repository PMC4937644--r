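test_that("Patlak transform is exact under a constant input", {
  t <- seq(0.5, 50, by = 1)
  ca <- rep(10, length(t))
  ku <- 0.03
  cb <- ku * 10 * t  # exact integral of the constant input
  pl <- patlak_transform(time_activity_curve(t, cb),
                         time_activity_curve(t, ca))
  expect_equal(pl$points$x, t)         # x_i = t_i for constant input
  expect_equal(pl$points$y, ku * t)    # exactly the line through 0

  zero <- patlak_transform(time_activity_curve(t, rep(0, length(t))),
                           time_activity_curve(t, ca))
  expect_true(all(zero$points$y == 0))

  expect_error(patlak_transform(time_activity_curve(t[-1], cb[-1]),
                                time_activity_curve(t, ca)), "timebase")
})

test_that("Patlak slope estimation is exact on a line and guards degeneracy", {
  x <- seq(2, 40, by = 2)
  pl <- structure(list(points = data.frame(time_s = x, x = x,
                                           y = 0.02 * x + 0.1),
                       input_peak_index = 1L),
                  class = "patlak_plot")
  kf <- estimate_ku(pl)
  expect_equal(kf$ku, 0.02)
  expect_equal(kf$intercept, 0.1)
  expect_equal(kf$r2, 1)

  degen <- structure(list(points = data.frame(time_s = 1:5,
                                              x = rep(3, 5),
                                              y = 1:5),
                          input_peak_index = 1L),
                     class = "patlak_plot")
  expect_error(estimate_ku(degen), "degenerate abscissa")
  expect_error(estimate_ku(pl, fit_window = c(1, 2)), "at least 3")
})

test_that("simulator curves give a collinear Patlak plot with slope ku_true", {
  s <- fixture_subject()
  grid <- dim(s$series$frames)[2:3]
  input <- extract_tac(s$series, roi_mask(s$truth$aorta_center, 4, grid))
  brain <- extract_tac_mean(
    s$series, roi_mask(s$truth$brain_center,
                       s$config$pp_hemisphere_diameter_px, grid))
  pl <- patlak_transform(brain, input)
  kf <- estimate_ku(pl)
  expect_gt(kf$r2, 0.9999)
  expect_equal(kf$ku, s$truth$ku_true, tolerance = 0.01)
})

test_that("ku scaling laws: joint rescale invariant, input-only inverse", {
  s <- fixture_subject()
  grid <- dim(s$series$frames)[2:3]
  input <- extract_tac(s$series, roi_mask(s$truth$aorta_center, 4, grid))
  brain <- extract_tac_mean(
    s$series, roi_mask(s$truth$brain_center, 8, grid))
  ku0 <- estimate_ku(patlak_transform(brain, input))$ku
  scale_tac <- function(tac, c)
    time_activity_curve(tac$times_s, tac$counts * c, kind = tac$kind)
  ku_joint <- estimate_ku(patlak_transform(scale_tac(brain, 5),
                                           scale_tac(input, 5)))$ku
  expect_equal(ku_joint, ku0, tolerance = 1e-10)
  ku_inp <- estimate_ku(patlak_transform(brain, scale_tac(input, 4)))$ku
  expect_equal(ku_inp, ku0 / 4, tolerance = 1e-10)
})

test_that("BPI and the PP calibration line behave as documented", {
  expect_equal(ku_to_bpi(0, 100)$bpi, 0)
  expect_equal(ku_to_bpi(0.05, 100)$bpi, 5)
  expect_equal(ku_to_bpi(0.02, 50)$bpi, 2 * ku_to_bpi(0.01, 50)$bpi)
  expect_error(ku_to_bpi(0.01, 0), "scale")

  expect_identical(bpi_to_mcbf(0), 19.8)
  expect_equal(bpi_to_mcbf(10), 45.8)
  expect_true(all(diff(bpi_to_mcbf(seq(0, 12, 0.5))) > 0))
  expect_error(bpi_to_mcbf(-1), ">= 0")
})

test_that("regional distribution anchors the basal ganglia at mCBF", {
  tpl <- make_srt_template(c(16, 16, 16))
  cfg <- analysis_config()
  uni <- setNames(rep(120, 24), srt_segment_names())
  rc <- distribute_rcbf_pp(uni, 42, cfg, tpl)
  expect_equal(unname(rc$per_segment), rep(42, 24))

  ## single-segment anchor maps to mcbf exactly even with varying counts
  cfg1 <- analysis_config(basal_ganglia_segments = "thalamus")
  varied <- setNames(seq(80, 195, by = 5), srt_segment_names())
  rc1 <- distribute_rcbf_pp(varied, 37.5, cfg1, tpl)
  expect_equal(rc1$per_segment[["left_thalamus"]], 37.5)
  expect_equal(rc1$mcbf, 37.5)
})

test_that("PP pipeline recovers flow ordering and correlates with truth", {
  s <- fixture_subject()
  pp <- patlak_pipeline(s$series, s$volume, s$template, s$config)
  expect_equal(pp$mcbf, s$truth$true_mcbf, tolerance = 0.01)
  expect_gt(cor(pp$per_segment[names(s$truth$segment_flow)],
                s$truth$segment_flow), 0.999)

  ## PP and IBUR rank segments identically on the noiseless simulator
  ib <- ibur_pipeline(s$series, s$volume, s$template, s$config)
  expect_equal(cor(pp$per_segment, ib$per_segment[names(pp$per_segment)],
                   method = "spearman"), 1)
})
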