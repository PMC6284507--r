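test_that("medMax follows the stated order-statistic rules", {
  expect_equal(med_max(rep(7, 100)), 7)
  expect_equal(med_max(1:25), 15.5)  # median of {6..25}
  expect_warning(v <- med_max(1:10), "only 10 values")
  expect_equal(v, 5.5)
  expect_error(med_max(numeric(0)), "empty")
})

test_that("medMax agrees exactly with the full-sort oracle", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:400, 1)
    v <- stats::rnorm(n, sd = sample(1:50, 1))
    got <- suppressWarnings(med_max(v))
    expect_identical(got, oracle_medmax(v))
  }
})

test_that("smoothing averages three points with two-term endpoints", {
  expect_equal(smooth3(c(0, 3, 0)), c(1.5, 1.0, 1.5))
  expect_equal(smooth3(rep(4.2, 10)), rep(4.2, 10))
  expect_equal(smooth3(c(0, 1, 2, 3))[2:3], c(1, 2))  # linear invariance
  expect_equal(smooth3(5), 5)
  expect_equal(smooth3(c(1, 3)), c(2, 2))
  # mean shift bounded by the boundary terms
  set.seed(1)
  for (i in 1:20) {
    s <- stats::rnorm(50)
    bound <- (abs(s[2] - s[1]) + abs(s[50] - s[49])) / (3 * 50)
    expect_lte(abs(mean(smooth3(s)) - mean(s)), bound + 1e-12)
  }
})

test_that("bleach correction cancels a common temporal factor", {
  meta <- acq_meta(0.5, 0.11, 3)
  b <- exp(-0.01 * (0:49))
  tr <- structure(list(time_s = frame_times(meta, 50),
                       raw_medmax = 3.7 * b, nucleus_mean = b,
                       i0_raw = 3.7, meta = meta, channel_label = "g",
                       use_dog = FALSE), class = "intensity_trace")
  expect_equal(bleach_correct(tr), rep(3.7, 50))
  tr$nucleus_mean[10] <- 0
  expect_error(bleach_correct(tr), "non-positive")
})

test_that("RFI and delta-I normalizations are mutually consistent", {
  meta <- acq_meta(0.5, 0.11, 5)
  corrected <- c(rep(100, 5), 120, 150, 140, 130, 125)
  r <- rfi_curve(corrected, meta)
  expect_equal(r$i0, 100)
  expect_equal(mean(r$rfi[1:5]), 1)      # pre-damage mean is 1 exactly
  expect_equal(r$rfi[7], 1.5)
  d <- delta_intensity(corrected, meta)
  expect_equal(d[7], 50)
  expect_equal(d, r$i0 * (r$rfi - 1), tolerance = 1e-12)
  expect_equal(rfi_curve(rep(100, 10), meta)$rfi, rep(1, 10))
  expect_error(rfi_curve(c(rep(0, 5), 1, 2, 3, 4, 5), meta), "i0")
})

test_that("FMR rescales RFI to [0, 1] with its stated conventions", {
  meta <- acq_meta(0.5, 0.11, 1)
  fm <- fmr_curve(c(1, 1.5, 2.0, 1.75), meta)
  expect_true(fm$defined)
  expect_equal(fm$fmr, c(0, 0.5, 1.0, 0.75))
  expect_equal(fm$max_rfi, 2.0)
  # degenerate: no recruitment
  flat <- fmr_curve(rep(1, 8), meta)
  expect_false(flat$defined)
  expect_match(flat$reason, "no recruitment")
  expect_null(flat$fmr)
  # affine invariance: doubling the excess leaves FMR unchanged
  rfi <- c(1, 1.2, 1.8, 1.5)
  expect_equal(fmr_curve(1 + 2 * (rfi - 1), meta)$fmr,
               fmr_curve(rfi, meta)$fmr)
})

test_that("t50 is the first post-damage half-max crossing", {
  meta <- acq_meta(0.5, 0.11, 1)
  # one pre-damage frame, then FMR rising 0 -> 0.2 -> 0.6 -> 1.0:
  # the first crossing is the third post-damage frame, 1.0 s after damage
  fmr <- c(0, 0, 0.2, 0.6, 1.0)
  expect_equal(time_to_half_max(fmr, meta), 1.0)
  expect_true(is.na(time_to_half_max(c(0, 0.1, 0.2, 0.3), meta)))
  expect_true(is.na(time_to_half_max(NULL, meta)))
  # interpolation places the crossing between the bracketing frames
  expect_equal(time_to_half_max(fmr, meta, interpolate = TRUE),
               0.5 + 0.5 * (0.5 - 0.2) / 0.4)
})

test_that("curve statistics report maxima with earliest-frame tie-breaks", {
  meta <- acq_meta(0.5, 0.11, 1)
  st <- curve_stats(c(1, 2, 1.5), c(0, 1, 0.5), meta)
  expect_equal(st$max_rfi, 2)
  expect_equal(st$t_max, 0)       # first post-damage frame
  expect_equal(st$final_fmr, 0.5)
  mono <- curve_stats(c(1, 1.2, 1.4, 1.6), c(0, 0.33, 0.67, 1), meta)
  expect_equal(mono$t_max, 1.0)   # last frame
  tie <- curve_stats(c(1, 2, 2), c(0, 1, 1), meta)
  expect_equal(tie$t_max, 0)      # earliest of the tied frames
})

test_that("extraction recovers the noiseless model trace", {
  kin <- kinetic_params(1, 0.2, 0.01)
  cfg <- test_cfg(n_frames = 80L, dark_offset = 0, bleedthrough = 0,
                  green = list(I0 = 150, kinetics = kin, bleach = 0.002,
                               noise_sd = 0))
  s <- simulate_movie(cfg, seed = 2)
  tr <- extract_trace(s$green, test_damage_roi(), s$masks$nucleus$mask,
                      use_dog = FALSE)
  # raw medMax sits on stripe pixels: I0 * (1 + f) * bleach decay
  expect_equal(tr$raw_medmax, s$truth$green$stripe_trace, tolerance = 1e-10)
  # with A = 1 and slow dissociation the stripe approaches twice the
  # bleached baseline near its maximum
  tmax_idx <- which.max(tr$raw_medmax)
  expect_equal(tr$raw_medmax[tmax_idx],
               2 * 150 * exp(-0.002 * (tmax_idx - 1)),
               tolerance = 0.2)
  # an ROI with no stripe content follows the plain nucleus baseline
  off_roi <- rect_roi(18L, 8L, 30L, 6L)  # pokes above the nuclear boundary
  expect_warning(
    flat <- extract_trace(s$green, off_roi, s$masks$nucleus$mask,
                          use_dog = FALSE),
    "not fully contained")
  expect_equal(flat$raw_medmax, s$truth$green$nucleus_trace,
               tolerance = 1e-10)
  expect_error(extract_trace(s$green, test_damage_roi(),
                             matrix(FALSE, 64, 96)),
               "empty")
})

test_that("full-pipeline t50 tracks ground truth on a clean simulation", {
  kin <- kinetic_params(1.2, 0.15, 0.01)
  cfg <- test_cfg(n_frames = 120L, bleedthrough = 0,
                  green = list(I0 = 170, kinetics = kin, bleach = 0.001,
                               noise_sd = 0))
  s <- simulate_movie(cfg, seed = 4)
  tr <- extract_trace(s$green, test_damage_roi(), s$masks$nucleus$mask)
  cv <- recruitment_curve(tr, smooth = TRUE)
  expect_true(cv$defined)
  expect_lt(abs(cv$t50 - s$truth$green$t50), 1.0)
})

test_that("FMR is invariant to a positive gain on the raw movie", {
  kin <- kinetic_params(1, 0.25, 0.02)
  cfg <- test_cfg(n_frames = 60L,
                  green = list(I0 = 170, kinetics = kin, bleach = 0.001,
                               noise_sd = 12))
  s <- simulate_movie(cfg, seed = 8)
  damage <- test_damage_roi(); nuc <- s$masks$nucleus$mask
  curve_of <- function(movie) {
    recruitment_curve(extract_trace(movie, damage, nuc), smooth = TRUE)
  }
  base <- curve_of(s$green)
  gained <- curve_of(timelapse_movie(4 * s$green$frames, s$green$meta))
  expect_identical(gained$fmr, base$fmr)   # power-of-two gain: bit-identical
  odd <- curve_of(timelapse_movie(3.7 * s$green$frames, s$green$meta))
  expect_equal(odd$fmr, base$fmr, tolerance = 1e-10)
})
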