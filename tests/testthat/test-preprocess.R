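make_clean_run <- function(seed = 1, n = 116L) {
  truth <- make_ground_truth(small_truth_params(), 1L, seed = 1)[[1L]]
  ev <- make_design(small_design(1L), seed = seed)[[1L]]
  simulate_run(ev, truth, quiet_noise(), seed = seed)
}

test_that("constant run with zero motion yields no artifact flags", {
  run <- bold_run(array(1000, c(4, 4, 4, 20)), tr = 3)
  rep <- detect_artifacts(run, matrix(0, 20, 6))
  expect_equal(nrow(rep$flags), 0L)
})

test_that("injected global artifacts are recovered with their reason", {
  truth <- make_ground_truth(small_truth_params(), 1L, seed = 1)[[1L]]
  ev <- make_design(small_design(1L), seed = 1)[[1L]]
  # global-only injection at a rate giving ~5 artifact volumes
  nz <- noise_spec(artifact_rate = 5 / 116, motion_spike_mm = 0)
  found <- 0L; injected <- 0L
  for (seed in 1:6) {
    sr <- simulate_run(ev, truth, nz, seed = seed)
    rep <- detect_artifacts(sr$bold, sr$motion)
    injected <- injected + nrow(sr$artifacts)
    hit <- sr$artifacts$volume %in% rep$flags$volume[rep$flags$reason == "global_z"]
    found <- found + sum(hit)
  }
  expect_gt(injected, 10L)
  expect_gte(found / injected, 0.95)
})

test_that("motion-spike artifacts are recovered and clean runs stay clean", {
  truth <- make_ground_truth(small_truth_params(), 1L, seed = 1)[[1L]]
  ev <- make_design(small_design(1L), seed = 1)[[1L]]
  nz <- noise_spec(artifact_rate = 5 / 116, artifact_global_z = 0)
  sr <- simulate_run(ev, truth, nz, seed = 4)
  rep <- detect_artifacts(sr$bold, sr$motion)
  expect_true(all(sr$artifacts$volume %in% rep$flags$volume))
  # false positives on clean runs < 1%
  fp <- 0L; tot <- 0L
  for (seed in 11:16) {
    sr <- make_clean_run(seed)
    rep <- detect_artifacts(sr$bold, sr$motion)
    fp <- fp + nrow(rep$flags); tot <- tot + 116L
  }
  expect_lt(fp / tot, 0.01)
})

test_that("a 1.0 mm translation step is flagged as translation", {
  run <- bold_run(array(1000, c(4, 4, 4, 20)), tr = 3)
  motion <- matrix(0, 20, 6)
  motion[10:20, 1L] <- 1.0                      # one step of 1.0 mm in x
  rep <- detect_artifacts(run, motion)
  expect_equal(rep$flags$volume, 10L)
  expect_equal(rep$flags$reason, "translation")
  # rotation rule
  motion2 <- matrix(0, 20, 6)
  motion2[5:20, 5L] <- 0.02
  rep2 <- detect_artifacts(run, motion2)
  expect_equal(rep2$flags$volume, 5L)
  expect_equal(rep2$flags$reason, "rotation")
  expect_error(detect_artifacts(run, matrix(0, 19, 6)), "one row per")
})

test_that("run exclusion applies the 46/116 rule and subject rule", {
  fake_report <- function(n_flagged, n = 116L) {
    structure(list(flags = data.frame(volume = seq_len(n_flagged),
                                      reason = rep("global_z", n_flagged)),
                   n_volumes = n), class = "artifact_report")
  }
  r <- exclude_runs(list(fake_report(46L), fake_report(45L), fake_report(0L)))
  expect_equal(r$excluded, c(TRUE, FALSE, FALSE))
  expect_false(attr(r, "subject_excluded"))
  # the excluded participant's profile: every run at or over threshold
  r2 <- exclude_runs(list(fake_report(46L), fake_report(60L),
                          fake_report(58L), fake_report(56L)))
  expect_true(all(r2$excluded))
  expect_true(attr(r2, "subject_excluded"))
  expect_error(exclude_runs(list(fake_report(0L)), threshold_fraction = 0),
               "\\(0, 1\\]")
})

test_that("DCT high-pass removes slow drift, preserves the task band", {
  n <- 116L; tr <- 3; tt <- (0:(n - 1)) * tr
  expect_equal(dct_highpass(rep(7, n), tr)$filtered, rep(0, n))
  slow <- cos(2 * pi * tt / 300 + 0.4)
  out <- dct_highpass(slow, tr)$filtered
  expect_lt(stats::sd(out), 0.1 * stats::sd(slow))   # >= 10x RMS attenuation
  task <- sin(2 * pi * 0.125 * tt)
  kept <- dct_highpass(task, tr)$filtered
  expect_gt(stats::cor(kept, task), 0.99)
  expect_equal(dct_highpass(task, tr)$k, floor(2 * n * tr / 128))
  expect_error(dct_highpass(task, tr, cutoff_s = 5), "cutoff")
})

test_that("running-line filter removes lines exactly and passes the task band", {
  n <- 116L; tr <- 3; tt <- (0:(n - 1)) * tr
  line <- 5 + 0.03 * tt
  expect_lt(max(abs(gaussian_runline_detrend(line, tr))), 1e-8 * max(abs(line)))
  expect_equal(gaussian_runline_detrend(rep(3, n), tr), rep(0, n),
               tolerance = 1e-12)
  # spectral comparison on a slow + task mixture: power at the drift
  # frequency attenuated >= 10x, task frequency preserved within 10%
  slow <- cos(2 * pi * tt / 600)
  task <- sin(2 * pi * 0.125 * tt)
  out <- gaussian_runline_detrend(slow + task, tr)
  pw <- function(x, f) Mod(sum(x * exp(-2i * pi * f * tt)))^2
  expect_lt(pw(out, 1 / 600), pw(slow + task, 1 / 600) / 10)
  expect_gt(pw(out, 0.125), 0.81 * pw(slow + task, 0.125))
  # drifts well below 0.01 Hz attenuated >= 10x in amplitude
  vslow <- cos(2 * pi * tt / 1200 + 0.3)
  expect_lt(stats::sd(gaussian_runline_detrend(vslow, tr)),
            stats::sd(vslow) / 10)
})

test_that("both high-pass filters are linear operators", {
  n <- 116L; tr <- 3
  set.seed(8)
  x <- stats::rnorm(n); y <- stats::rnorm(n)
  a <- 2.5; b <- -1.3
  expect_equal(gaussian_runline_detrend(a * x + b * y, tr),
               a * gaussian_runline_detrend(x, tr) +
                 b * gaussian_runline_detrend(y, tr), tolerance = 1e-10)
  expect_equal(dct_highpass(a * x + b * y, tr)$filtered,
               a * dct_highpass(x, tr)$filtered +
                 b * dct_highpass(y, tr)$filtered, tolerance = 1e-10)
})

test_that("linear detrend removes slope, keeps mean", {
  t0 <- 1:50
  y <- 2 * t0 + 5
  out <- linear_detrend(y)
  expect_equal(out, rep(mean(y), 50))
  set.seed(1)
  w <- stats::rnorm(200)
  d <- linear_detrend(w)
  slope <- stats::coef(stats::lm(d ~ seq_along(d)))[2L]
  expect_lt(abs(slope), 1e-10)
})

test_that("detrending protects PSC estimates against drift", {
  # same run with and without drift: block PSC must differ < 0.2 pp
  tp <- small_truth_params(amp_common = 1, subject_jitter_sd = 0)
  truth <- make_ground_truth(tp, 1L, seed = 1)[[1L]]
  ev <- make_design(small_design(1L), seed = 1)[[1L]]
  clean <- simulate_run(ev, truth, quiet_noise(white_sd = 0, drift_amp = 0),
                        seed = 1)
  mask <- truth$amp_ext > 0
  p_clean <- psc_maps(clean, active_mask = mask)
  # default slow drift at 1% of baseline: PSC error below 0.2 pp at
  # every voxel (all drift phases are present across voxels)
  drifty <- simulate_run(ev, truth, quiet_noise(white_sd = 0, drift_amp = 10),
                         seed = 2)
  dd <- abs(p_clean$psc_ext - psc_maps(drifty, active_mask = mask)$psc_ext)
  expect_lt(max(dd, na.rm = TRUE), 0.2)
  # a fast 300-s drift defeats a straight-line fit partially; bounded
  drifty3 <- simulate_run(ev, truth,
                          quiet_noise(white_sd = 0, drift_amp = 10,
                                      drift_period = 300), seed = 2)
  dd3 <- abs(p_clean$psc_ext - psc_maps(drifty3, active_mask = mask)$psc_ext)
  expect_lt(max(dd3, na.rm = TRUE), 0.8)
})

test_that("spatial smoothing conserves mass, is linear, identity at fwhm 0", {
  vol <- array(0, c(15, 15, 15))
  vol[8, 8, 8] <- 1
  sm <- smooth_spatial(vol, fwhm_mm = 6, voxel_size = 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_lt(max(sm), 1)
  expect_identical(smooth_spatial(vol, fwhm_mm = 0), vol)
  # superposition of two distant deltas
  v2 <- array(0, c(30, 8, 8)); v2[5, 4, 4] <- 1
  v3 <- array(0, c(30, 8, 8)); v3[25, 4, 4] <- 1
  both <- smooth_spatial(v2 + v3, 6, 3)
  expect_equal(both, smooth_spatial(v2, 6, 3) + smooth_spatial(v3, 6, 3),
               tolerance = 1e-12)
  # edge content: reflection keeps the volume sum
  v4 <- array(0, c(10, 10, 10)); v4[1, 1, 1] <- 2
  expect_equal(sum(smooth_spatial(v4, 6, 3)), 2, tolerance = 1e-6)
})
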