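test_that("automatic aorta detection finds the simulator's aorta pixel", {
  s <- fixture_subject()
  roi <- detect_aorta_roi(s$series)
  expect_equal(roi$center, as.numeric(s$truth$aorta_center))

  ## invariant to a constant background offset
  shifted <- dynamic_planar_series(s$series$frames + 7,
                                   s$series$frame_duration_s)
  expect_equal(detect_aorta_roi(shifted)$center, roi$center)
})

test_that("detection tie-breaks are deterministic (frame, then row-major)", {
  arr <- array(0, dim = c(3, 10, 10))
  arr[2, 4, 4] <- 100  # earlier frame
  arr[3, 8, 8] <- 100
  s <- dynamic_planar_series(arr, 1)
  expect_equal(detect_aorta_roi(s)$center, c(4, 4))

  arr2 <- array(0, dim = c(2, 10, 10))
  arr2[1, 6, 2] <- 50  # same frame: smaller (row, col) wins
  arr2[1, 6, 9] <- 50
  arr2[1, 9, 1] <- 50
  s2 <- dynamic_planar_series(arr2, 1)
  expect_equal(detect_aorta_roi(s2)$center, c(6, 2))

  expect_error(detect_aorta_roi(dynamic_planar_series(array(0, c(3, 5, 5)), 1)),
               "no signal")
})

test_that("detection is equivariant to spatial translation of the scene", {
  arr <- array(0, dim = c(4, 20, 20))
  arr[3, 8, 9] <- 30; arr[2, 7, 9] <- 12
  s <- dynamic_planar_series(arr, 1)
  moved <- array(0, dim = c(4, 20, 20))
  moved[3, 13, 6] <- 30; moved[2, 12, 6] <- 12
  sm <- dynamic_planar_series(moved, 1)
  expect_equal(detect_aorta_roi(sm)$center,
               detect_aorta_roi(s)$center + c(5, -3))
})

test_that("TAC extraction sums the ROI and samples at frame midpoints", {
  arr <- array(0, dim = c(5, 12, 12))
  for (f in 1:5) arr[f, 6, 7] <- f
  s <- dynamic_planar_series(arr, 1)
  roi1 <- roi_mask(c(6, 7), 1, c(12, 12))
  tac <- extract_tac(s, roi1)
  expect_equal(tac$counts, as.numeric(1:5))
  expect_equal(tac$times_s, (1:5) - 0.5)

  const <- dynamic_planar_series(array(3, dim = c(4, 12, 12)), 2)
  roi4 <- roi_mask(c(6, 6), 4, c(12, 12))
  tac4 <- extract_tac(const, roi4)
  expect_equal(tac4$counts, rep(3 * nrow(roi4$mask), 4))
  mean4 <- extract_tac_mean(const, roi4)
  expect_equal(mean4$counts, rep(3, 4))
})

test_that("the simulated aorta TAC matches its generating model curves", {
  s <- fixture_subject()
  grid <- dim(s$series$frames)[2:3]
  tac <- extract_tac(s$series, roi_mask(s$truth$aorta_center, 4, grid))
  model <- gamma_value(s$truth$input_params, tac$times_s) +
    gamma_value(s$truth$pulmonary_params, tac$times_s)
  expect_equal(tac$counts, model, tolerance = 1e-10)
})

test_that("split_peaks brackets the two bolus peaks and handles edge cases", {
  times <- seq(0.5, 120, by = 1)
  p1 <- gamma_params(50, 3, 1.1, 2)    # pulmonary-like
  p2 <- gamma_params(90, 3, 2, 14)     # aortic-like
  tac <- time_activity_curve(times, gamma_value(p1, times) +
                               gamma_value(p2, times))
  sp <- split_peaks(tac)
  peak1_t <- times[sp$peak_indices[1]]
  peak2_t <- times[sp$peak_indices[2]]
  expect_lt(abs(peak1_t - (2 + 3 * 1.1)), 2)
  expect_lt(abs(peak2_t - (14 + 3 * 2)), 2)
  expect_true(sp$first_peak_window[2] < sp$second_peak_window[1])
  expect_true(sp$second_peak_window[1] <= sp$peak_indices[2])
  expect_true(sp$second_peak_window[2] > sp$peak_indices[2])
  ## truncation: curve at window end has fallen to ~30% of the second peak
  y_end <- tac$counts[sp$second_peak_window[2] + 1]
  expect_lt(y_end, 0.35 * tac$counts[sp$peak_indices[2]])

  mono <- time_activity_curve(1:30, (1:30)^1.5)
  expect_error(split_peaks(mono), "fewer than two peaks")

  ## heavily overlapped peaks: valley above 90% of the first peak
  y <- c(1, 2, 5, 20, 60, 90, 100, 98, 95, 97, 105, 100, 80, 60, 40,
         25, 15, 8, 4, 2, 1, 1, 1, 1)
  over <- time_activity_curve(seq_along(y), y)
  expect_warning(sp2 <- split_peaks(over, smooth_window = 1),
                 "overlapped")
  expect_equal(sp2$valley_index, 9L)
})

test_that("gamma fit recovers exact parameters from noiseless samples", {
  times <- seq(0.5, 60, by = 1)
  truth <- gamma_params(5, 2, 3, 4)
  tac <- gamma_curve(truth, times)
  fit <- fit_gamma(tac, c(5, 45))
  expect_true(fit$converged)
  expect_equal(fit$params$k_scale, 5, tolerance = 1e-4)
  expect_equal(fit$params$alpha_shape, 2, tolerance = 1e-4)
  expect_equal(fit$params$beta_scale_s, 3, tolerance = 1e-4)
  expect_equal(fit$params$t0_s, 4, tolerance = 1e-3)
  expect_equal(fit$integral_counts, gamma_integral(truth), tolerance = 1e-5)
  expect_error(fit_gamma(tac, c(1, 4)), "at least 5")
})

test_that("input integral is robust to Poisson noise at bolus count scale", {
  times <- seq(0.5, 60, by = 1)
  truth <- gamma_params(1000 / (6^2 * exp(-2)), 2, 3, 4)  # peak ~1000
  clean <- gamma_value(truth, times)
  true_int <- gamma_integral(truth)
  rel <- vapply(1:100, function(sd) {
    set.seed(sd)
    noisy <- time_activity_curve(times, rpois(length(times), clean))
    f <- fit_gamma(noisy, c(5, 45))
    abs(f$integral_counts - true_int) / true_int
  }, numeric(1))
  expect_lt(median(rel), 0.05)
})

test_that("input_counts is the analytic integral with its closed forms", {
  times <- seq(0.25, 30, by = 0.5)
  fit11 <- fit_gamma(gamma_curve(gamma_params(1, 1, 1, 3), times), c(4, 40))
  expect_equal(input_counts(fit11), 1.0, tolerance = 1e-5)  # Gamma(2) = 1

  fit_half <- fit_gamma(gamma_curve(gamma_params(1, 0.5, 1, 2), times),
                        c(3, 40))
  expect_equal(input_counts(fit_half), gamma(1.5), tolerance = 1e-4)

  ## linear in amplitude; scale-equivariance of the whole extraction
  fit2 <- fit_gamma(gamma_curve(gamma_params(2, 1, 1, 3), times), c(4, 40))
  expect_equal(input_counts(fit2), 2 * input_counts(fit11), tolerance = 1e-4)

  bad <- structure(list(converged = FALSE), class = "gamma_fit")
  expect_error(input_counts(bad), "did not converge")
})

test_that("analytic integral dominates the finite-window trapezoid", {
  times <- seq(0.5, 60, by = 1)
  tac <- gamma_curve(gamma_params(8, 2.5, 2, 6), times)
  fit <- fit_gamma(tac, c(7, 40))
  w <- seq(7, 40)
  fitted_vals <- gamma_value(fit$params, times[w])
  trap <- sum((fitted_vals[-1] + fitted_vals[-length(w)]) / 2 *
                diff(times[w]))
  expect_gte(fit$integral_counts, trap)
})
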