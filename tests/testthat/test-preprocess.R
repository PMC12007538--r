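test_that("slice-timing correction is exact on linear signals", {
  tr <- 2.4
  tt <- (0:99) * tr
  v <- array(0, c(1, 1, 2, 100))
  v[1, 1, 1, ] <- 3 + 2 * tt              # onset 0: untouched
  v[1, 1, 2, ] <- 3 + 2 * (tt + 1.2)      # acquired 1.2 s late
  vol <- pd_volume(v, tr, slice_onsets = c(0, 1.2))
  out <- slice_timing_correct(vol)
  expect_identical(out$values[1, 1, 1, ], v[1, 1, 1, ])
  # interior samples recovered exactly; first point is edge-held
  expect_equal(out$values[1, 1, 2, 2:100], 3 + 2 * tt[2:100])
  expect_equal(out$slice_onsets, c(0, 0))
})

test_that("slice-timing correction reduces the phase error of a sinusoid", {
  sched <- fixture_schedule()
  tr <- sched$tr
  tt <- (0:299) * tr
  latent <- function(t) sin(2 * pi * 0.05 * t)
  v <- array(0, c(1, 1, 2, 300))
  v[1, 1, 1, ] <- latent(tt)
  v[1, 1, 2, ] <- latent(tt + 1.2)
  vol <- pd_volume(v, tr, slice_onsets = c(0, 1.2))
  out <- slice_timing_correct(vol)
  err_before <- mean(abs(v[1, 1, 2, ] - latent(tt)))
  err_after <- mean(abs(out$values[1, 1, 2, ] - latent(tt)))
  expect_lt(err_after, err_before / 3)
})

test_that("degree-3 detrending annihilates cubic drift, keeps oscillation", {
  tr <- 2.4
  n <- 500                                   # 1200 s
  tt <- seq_len(n)
  cubic <- 5 + 0.1 * tt - 1e-3 * tt^2 + 1e-5 * tt^3
  v <- array(rep(cubic, each = 4), c(2, 2, 1, n))
  out <- detrend(pd_volume(v, tr), 3)
  expect_lt(max(abs(out$values)) / max(abs(cubic)), 1e-8)
  # constant input -> zero
  vc <- array(7, c(2, 2, 1, 50))
  expect_lt(max(abs(detrend(pd_volume(vc, tr), 3)$values)), 1e-10)
  # a 0.05 Hz sinusoid survives with < 5% amplitude loss
  sine <- sin(2 * pi * 0.05 * (tt - 1) * tr)
  v2 <- array(rep(cubic + sine, each = 1), c(1, 1, 1, n))
  out2 <- detrend(pd_volume(v2, tr), 3)
  amp <- sqrt(2 * mean(out2$values[1, 1, 1, ]^2))
  expect_gt(amp, 0.95)
  expect_error(detrend(pd_volume(array(1, c(1, 1, 1, 4)), tr), 3))
})

test_that("calm detector reproduces the rolling-std oracle segmentation", {
  tr <- 2.4
  n1 <- round(300 / tr); n2 <- round(120 / tr)
  gs <- c(rep(100, n1),
          100 + 10 * sin(2 * pi * 0.5 * (1:n2) * tr),
          rep(100, n1))
  got <- detect_calm_periods(gs, tr)
  want <- oracle_calm(gs, tr)
  expect_equal(nrow(got$segments), 2)
  expect_equal(got$segments, want$segments)
  expect_equal(got$calm_score, want$score)
  # constant GS: one segment covering the whole scan
  const <- detect_calm_periods(rep(50, 300), tr)
  expect_equal(const$segments, data.frame(start = 1L, end = 301L))
  expect_equal(const$calm_score, 720)
  expect_false(const$excluded)
  # everywhere-noisy GS: nothing calm
  set.seed(1)
  noisy <- detect_calm_periods(100 + rnorm(300, sd = 20), tr)
  expect_equal(nrow(noisy$segments), 0)
  expect_equal(noisy$calm_score, 0)
  expect_true(noisy$excluded)
})

test_that("calm detection is invariant to affine rescaling of the GS", {
  tr <- 2.4
  set.seed(4)
  gs <- 100 + c(rep(0, 150), rnorm(50, sd = 12), rep(0, 150)) +
    rnorm(350, sd = 1)
  a <- detect_calm_periods(gs, tr)
  b <- detect_calm_periods(3.7 * gs, tr)
  expect_equal(a$segments, b$segments)
  expect_equal(a$calm_score, b$calm_score)
})

test_that("band-pass keeps 0.01-0.1 Hz and rejects out-of-band power", {
  fs <- 2                                     # 0.5 s sampling
  t <- (0:2399) / fs
  pass <- sin(2 * pi * 0.05 * t)
  stopb <- sin(2 * pi * 0.5 * t)
  g_pass <- max(abs(smsfus:::bandpass_zero_phase(pass, fs)[400:2000]))
  g_stop <- max(abs(smsfus:::bandpass_zero_phase(stopb, fs)[400:2000]))
  expect_gte(g_pass, 0.9)
  expect_lte(g_pass, 1.0 + 1e-3)   # forward-backward edge transient
  expect_lt(20 * log10(g_stop), -20)
  # zero-phase: no lag of the filtered sinusoid
  filt <- smsfus:::bandpass_zero_phase(pass, fs)
  cc <- stats::ccf(filt[400:2000], pass[400:2000], lag.max = 10,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("standardize + band-pass + concatenation has the stated shape", {
  tr <- 2.4
  set.seed(6)
  n <- 400
  v <- array(rnorm(2 * 2 * 1 * n), c(2, 2, 1, n))
  vol <- pd_volume(v, tr)
  segs <- structure(list(segments = data.frame(start = c(1L, 201L),
                                               end = c(151L, 401L))),
                    class = "calm_segments")
  out <- bandpass_standardize_concat(vol, segs)
  expect_equal(dim(out$values)[4], 350)
  # per-voxel mean ~ 0 and >90% of power inside the band for white input
  x <- out$values[1, 1, 1, 1:150]
  expect_lt(abs(mean(x)), 0.05)
  sp <- stats::spec.pgram(stats::ts(x, deltat = tr), plot = FALSE, taper = 0)
  inb <- sp$freq >= 0.005 & sp$freq <= 0.12
  expect_gt(sum(sp$spec[inb]) / sum(sp$spec), 0.9)
  # empty segments are an error
  empty <- structure(list(segments = data.frame(start = integer(),
                                                end = integer())),
                     class = "calm_segments")
  expect_error(bandpass_standardize_concat(vol, empty), "calm")
})

test_that("global-signal regression projects out the mean time course", {
  tr <- 2.4
  # identical voxels -> all zero
  v <- array(rep(sin(1:100), each = 8), c(2, 2, 2, 100))
  out <- global_signal_regress(pd_volume(v, tr))
  expect_lt(max(abs(out$values)), 1e-10)
  # GS of the output is ~0 and GS-orthogonal signals are untouched
  set.seed(8)
  common <- rnorm(100)
  ortho <- sin(2 * pi * (1:100) / 25)
  ortho <- unname(resid(lm(ortho ~ common)))  # orthogonal to {1, GS}
  v2 <- array(0, c(2, 1, 1, 100))
  v2[1, 1, 1, ] <- common + ortho
  v2[2, 1, 1, ] <- common - ortho
  out2 <- global_signal_regress(pd_volume(v2, tr))
  expect_lt(max(abs(global_signal(out2))), 1e-10)
  expect_equal(out2$values[1, 1, 1, ], ortho, tolerance = 1e-8)
})

test_that("GSR induces the documented spurious anticorrelation", {
  set.seed(9)
  n <- 300
  common <- 10 * sin(2 * pi * (1:n) / 40) + rnorm(n)
  a <- rnorm(n); b <- rnorm(n)
  v <- array(0, c(2, 1, 1, n))
  v[1, 1, 1, ] <- common + a
  v[2, 1, 1, ] <- common + b
  vol <- pd_volume(v, 2.4)
  pre <- cor(v[1, 1, 1, ], v[2, 1, 1, ])
  post_v <- global_signal_regress(vol)$values
  post <- cor(post_v[1, 1, 1, ], post_v[2, 1, 1, ])
  expect_lt(post, pre)
  expect_lt(post, 0)
})

test_that("full pipeline excludes scans with under 10 min of calm time", {
  sched <- fixture_schedule()
  lab <- fixture_labels()
  nreg <- nrow(lab$table)
  motion <- data.frame(onset_s = seq(50, 1100, by = 100),
                       duration_s = 70, amplitude_ratio = 1.4)
  spec <- simulation_spec(sched, 1200, lab$labels, diag(nreg),
                          motion_episodes = motion, noise_sigma = 0.2,
                          seed = 12)
  pd <- simulate_pd_series(spec)
  res <- preprocess(pd)
  expect_true(res$excluded)
  expect_lt(res$calm$calm_score, 600)
})
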