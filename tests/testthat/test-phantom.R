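test_that("covariate generation handles edge cases and is reproducible", {
  empty <- generate_covariates(0)
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("subject_id", "age", "sex", "hypertensive",
                        "wmh_fraction", "svd_score", "lacunar"))
  expect_error(generate_covariates(-1), "non-negative")
  a <- generate_covariates(30, seed = 4)
  b <- generate_covariates(30, seed = 4)
  expect_identical(a, b)
})

test_that("covariate marginals match the configured cohort proportions", {
  cv <- generate_covariates(10000, seed = 17)
  expect_lt(abs(mean(cv$sex == "male") - 30 / 42), 0.02)
  expect_lt(abs(mean(cv$hypertensive) - 33 / 42), 0.02)
  expect_true(all(cv$wmh_fraction >= 0 & cv$wmh_fraction <= 10))
  expect_true(all(cv$svd_score %in% 0:4))
  svd_props <- as.numeric(table(factor(cv$svd_score, levels = 0:4))) / 10000
  expect_lt(max(abs(svd_props - c(8, 10, 12, 7, 5) / 42)), 0.02)
  # WMH burden and SVD score are rank-correlated as configured
  rho <- cor(cv$wmh_fraction, cv$svd_score, method = "spearman")
  expect_gt(rho, 0.4)
})

test_that("default protocol yields 21 frames at 73 s spacing", {
  g <- phantom_geometry()
  expect_identical(g$n_frames, 21L)
  expect_equal(g$frame_interval, 73)
  cv <- generate_covariates(1, seed = 1)
  ph <- generate_series(subject_truth(cv, seed = 2), g, seed = 3)
  expect_identical(dim(ph$series$data)[4], 21L)
  expect_error(acquisition_geometry(n_rows = 0), "positive")
})

test_that("frame 0 is pre-contrast and noise-free series show no early enhancement", {
  kin <- kinetics_model(noise_sd = 0, gain_jitter = 0)
  cv <- generate_covariates(1, seed = 5)
  tr <- subject_truth(cv, kin, seed = 6)
  ph <- generate_series(tr, phantom_geometry(), kin, seed = 7)
  # onset at 73 s = frame 1; frames 0 and 1 carry zero enhancement
  expect_equal(ph$enhancement[, 1], setNames(rep(0, 5), names(TISSUES)))
  expect_equal(ph$enhancement[, 2], setNames(rep(0, 5), names(TISSUES)))
  expect_identical(ph$series$data[, , , 1], ph$series$data[, , , 2])
})

test_that("without leakage a gamma-variate bolus washes out by the last frame", {
  kin <- kinetics_model(noise_sd = 0, gain_jitter = 0,
                        leakage_base = setNames(rep(0, 5), names(TISSUES)),
                        leakage_link = 0)
  cv <- generate_covariates(1, seed = 8)
  tr <- subject_truth(cv, kin, seed = 9)
  ph <- generate_series(tr, phantom_geometry(), kin, seed = 10)
  for (ts in names(TISSUES)) {
    e <- ph$enhancement[ts, ]
    expect_lt(e[length(e)], 0.01 * max(e))
  }
})

test_that("ROI-mean enhancement tracks the programmed per-tissue curve within noise", {
  kin <- kinetics_model(noise_sd = 0.02, gain_jitter = 0)
  cv <- generate_covariates(1, seed = 11)
  tr <- subject_truth(cv, kin, seed = 12)
  ph <- generate_series(tr, phantom_geometry(), kin, seed = 13)
  tpl <- test_template()
  stack <- extract_region_stack(ph$series, tpl, "middle-high", "WM")
  curve <- enhancement_curve(stack)
  prog <- ph$enhancement["WM", ]
  n_vox <- nrow(stack$values)
  # error propagation: both the frame mean and the baseline mean are
  # noisy, so per-frame deviations have sd about
  # (noise_sd/sqrt(n)) * sqrt(1 + (1 + E)^2)
  sd_frame <- (kin$noise_sd / sqrt(n_vox)) * sqrt(1 + (1 + prog)^2)
  z <- abs(as.numeric(curve) - prog) / sd_frame
  expect_gte(mean(z[-1] < 3), 20 / 21)   # ~99.7% expected within 3 sd
  expect_true(all(z[-1] < 5))
  # and exactly recovered without noise
  kin0 <- kinetics_model(noise_sd = 0, gain_jitter = 0)
  tr0 <- subject_truth(cv, kin0, seed = 12)
  ph0 <- generate_series(tr0, phantom_geometry(), kin0, seed = 13)
  st0 <- extract_region_stack(ph0$series, tpl, "middle-high", "WM")
  expect_equal(as.numeric(enhancement_curve(st0)),
               unname(ph0$enhancement["WM", ]), tolerance = 1e-10)
})

test_that("series generation is deterministic and label map covers all tissues", {
  cv <- generate_covariates(1, seed = 20)
  tr <- subject_truth(cv, seed = 21)
  a <- generate_series(tr, phantom_geometry(), seed = 22)
  b <- generate_series(tr, phantom_geometry(), seed = 22)
  expect_identical(a$series$data, b$series$data)
  expect_setequal(setdiff(unique(as.vector(a$labels)), 0L),
                  unname(TISSUES))
})

test_that("simulated AUEC recovers the programmed WMH-leakage link sign", {
  # regression of AUEC on WMH fraction over a 60-subject cohort has the
  # sign of the programmed (positive) link
  cfg <- pipeline_config(n_subjects = 60, seed = 31,
                         descriptors = "Enh", units = "WM@middle-high",
                         run_stats = FALSE)
  res <- run_pipeline(cfg)
  au <- res$score_table[res$score_table$descriptor == "AUEC", ]
  cv <- res$covariates[match(au$subject_id, res$covariates$subject_id), ]
  expect_gt(coef(lm(au$score ~ cv$wmh_fraction))[2], 0)
})

test_that("phantom NIfTI round-trip preserves data and geometry", {
  cv <- generate_covariates(1, seed = 41)
  tr <- subject_truth(cv, seed = 42)
  g <- phantom_geometry(n_frames = 4L)
  ph <- generate_series(tr, g, seed = 43)
  dir <- withr::local_tempdir()
  write_phantom(ph, dir, id = "T01", seed = 43)
  back <- read_phantom(dir, "T01")
  expect_equal(back$series$data, ph$series$data, tolerance = 1e-6)
  expect_identical(back$labels, ph$labels)
  expect_identical(back$series$geometry$n_frames, 4L)
})
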