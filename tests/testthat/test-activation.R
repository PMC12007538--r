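test_that("HRF kernel starts and ends at zero with unit peak", {
  h <- hrf_model()
  t <- seq(0, h$duration + 1, by = 0.05)
  k <- hrf_kernel(h, t)
  expect_equal(k[1], 0)
  expect_equal(k[length(k)], 0)
  expect_equal(max(k), 1, tolerance = 1e-3)
  expect_true(all(k >= -1e-12))            # undershoot disabled by default
  expect_error(hrf_model(rise = -1))
})

test_that("stimulus regressor honors the 0/1 rescaling contract", {
  # all-zero stimulus
  expect_equal(build_regressor(rep(0, 50), tr = 1), rep(0, 50))
  # one long block: plateau 1, baseline 0
  x <- c(rep(0, 30), rep(1, 60), rep(0, 30))
  r <- build_regressor(x, hrf_model(), tr = 1)
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)
  expect_equal(r[seq_len(25)], rep(0, 25))
  expect_gt(mean(r[60:85]), 0.99)          # sustained plateau
  # 8-trial train: 8 lobes returning toward 0 between stimuli
  stim <- make_stimulus(60, 8, 30, 90, tr = 2.4)
  rr <- build_regressor(stim)
  # independent direct convolution oracle at TR resolution
  k <- hrf_kernel(hrf_model(), seq(0, hrf_model()$duration, by = 2.4))
  oracle <- stats::filter(c(stim$x, rep(0, length(k))), k, sides = 1)
  oracle <- oracle[seq_along(stim$x)]
  oracle[is.na(oracle)] <- 0
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(rr, as.numeric(oracle), tolerance = 1e-10)
  # 8 response lobes: count excursions above half maximum
  lobes <- rle(rr > 0.5)
  expect_equal(sum(lobes$values), 8)
  # regressor returns toward 0 between stimuli
  between <- rr[which(diff(stim$x) == 1)[-1] - 2]
  expect_true(all(between < 0.35))
})

test_that("GLM matches closed-form simple regression and stats::lm", {
  x <- seq(0, 1, length.out = 50)
  f <- glm_fit(2 + 3 * x, matrix(x))
  expect_equal(f$beta, c(2, 3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(f$baseline, 2, tolerance = 1e-8)
  set.seed(2)
  y <- rnorm(40); X <- matrix(rnorm(40))
  f2 <- glm_fit(y, X)
  s <- summary(lm(y ~ X))
  expect_equal(f2$t, s$coefficients[2, 3], tolerance = 1e-10)
  expect_equal(f2$p, s$coefficients[2, 4], tolerance = 1e-10)
  expect_equal(f2$df, 38)
  # closed-form simple-regression formulas
  b1 <- sum((x - mean(x)) * (x * 3 + 2 - mean(2 + 3 * x))) /
    sum((x - mean(x))^2)
  expect_equal(f$beta[2], b1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(glm_fit(y, cbind(X, X)), "rank")
})

test_that("GLM voxelwise type-I error is calibrated at 5%", {
  set.seed(101)
  n <- 60; reps <- 1000
  X <- matrix(rnorm(n))
  Y <- matrix(rnorm(n * reps), nrow = reps, byrow = TRUE)
  f <- glm_fit(Y, X)
  rate <- mean(f$p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})

test_that("planted-response GLM estimates are unbiased", {
  set.seed(11)
  stim <- make_stimulus(60, 8, 30, 90, 2.4)
  reg <- build_regressor(stim)
  betas <- vapply(1:200, function(i) {
    glm_fit(5 + 0.8 * reg + rnorm(length(reg), sd = 1), matrix(reg))$beta[2]
  }, numeric(1))
  expect_equal(mean(betas), 0.8, tolerance = 3 * sd(betas) / sqrt(200))
})

test_that("Bonferroni mask thresholds at alpha / n", {
  p <- rep(0.5, 100)
  p[1] <- 0.0004; p[2] <- 0.0006
  m <- bonferroni_mask(p, 0.05)
  expect_true(m[1])
  expect_false(m[2])
  expect_equal(sum(m), 1)
})

test_that("Bonferroni controls FWER under the global null", {
  set.seed(303)
  n <- 40; nvox <- 50; reps <- 500
  fw <- vapply(seq_len(reps), function(i) {
    f <- glm_fit(matrix(rnorm(n * nvox), nrow = nvox, byrow = TRUE),
                 matrix(rnorm(n)))
    any(bonferroni_mask(f$p, 0.05))
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(fw), 0.05 + 2 * se)
})

test_that("rCBV conversion and trial averaging behave as stated", {
  expect_equal(rcbv(100, 100), 0)
  expect_equal(rcbv(112, 100), 12)
  expect_error(rcbv(1, 0), "baseline")
  # identical trials average to any single trial
  x <- rep(c(0, 5, 3, 1), 4)
  expect_equal(trial_average(x, c(1, 5, 9, 13), 4), c(0, 5, 3, 1))
  expect_equal(trial_average(x, 1, 4), c(0, 5, 3, 1))  # single trial
  expect_error(trial_average(x, 15, 4), "exceeds")
  # noise shrinks by sqrt(8)
  set.seed(5)
  sds <- vapply(1:300, function(i) {
    y <- rnorm(8 * 20)
    sd(trial_average(y, seq(1, 160, by = 20), 20))
  }, numeric(1))
  expect_equal(mean(sds), 1 / sqrt(8), tolerance = 0.05)
})

test_that("planted 12% rCBV response is recovered by the closed loop", {
  sched <- fixture_schedule()
  lab <- fixture_labels()
  stim <- make_stimulus(60, 8, 30, 90, sched$tr)
  spec <- simulation_spec(sched, 780, lab$labels, diag(nrow(lab$table)),
                          response_regions = c("1" = 12), latent_sd = 0,
                          seed = 3)
  pd <- simulate_pd_series(spec, stim)
  fit <- activation_glm(pd, build_regressor(stim))
  sel <- lab$labels == 1
  amp <- mean(100 * fit$beta[sel] / fit$baseline[sel])
  expect_equal(amp, 12, tolerance = 1 / 12)   # within +/- 1 % rCBV
  # non-response regions stay silent
  expect_lt(max(abs(fit$beta[lab$labels == 3])), 1e-8)
})

test_that("TFCE matches hand-computed and brute-force values", {
  m <- array(0, c(3, 3, 3)); m[2, 2, 2] <- 2
  v <- tfce(m, dh = 0.1)
  expect_equal(v[2, 2, 2], 0.1 * sum(seq(0.1, 2, by = 0.1)^2))  # 2.87
  expect_equal(v[2, 2, 2], 2.87, tolerance = 1e-12)
  expect_equal(tfce(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))
  # cluster member beats an isolated voxel of the same height
  m2 <- array(0, c(5, 1, 1)); m2[1] <- 1; m2[3] <- 1; m2[4] <- 1
  v2 <- tfce(m2, dh = 0.1)
  expect_gt(v2[3], v2[1])
  # brute-force sweep oracle on a random map, both tails
  set.seed(7)
  m3 <- array(rnorm(24), c(4, 3, 2))
  expect_equal(tfce(m3, dh = 0.25), oracle_tfce(m3, dh = 0.25),
               tolerance = 1e-12)
})

test_that("TFCE is monotone under scaling and invariant to relabeling", {
  set.seed(8)
  m <- array(rnorm(18), c(3, 3, 2))
  e1 <- tfce(m, dh = 0.2)
  e2 <- tfce(2 * m, dh = 0.2)
  nz <- m > 0.3                # clear of the integration step
  expect_true(all(e2[nz] > e1[nz]))
  # mirroring the array mirrors the enhancement
  mm <- m[3:1, , ]
  expect_equal(tfce(mm, dh = 0.2), e1[3:1, , ])
})

test_that("exhaustive sign-flip permutation p-values are multiples of 1/64", {
  set.seed(5)
  subj <- lapply(1:6, function(i) array(rnorm(27), c(3, 3, 3)))
  g <- group_permutation_test(subj, alpha = 0.05, dh = 0.5)
  expect_true(g$exhaustive)
  expect_equal(g$n_perm_used, 64)
  expect_true(all(abs(g$p * 64 - round(g$p * 64)) < 1e-12))
  expect_true(all(g$p >= 1 / 64))
})

test_that("TFCE permutation controls FWER under the global null", {
  set.seed(404)
  reps <- 500
  fw <- vapply(seq_len(reps), function(i) {
    subj <- lapply(1:5, function(s) array(rnorm(18), c(3, 3, 2)))
    any(group_permutation_test(subj, alpha = 0.05, dh = 0.5)$mask)
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(fw), 0.05 + 2 * se)
})

test_that("a strong planted bilateral effect survives group inference", {
  set.seed(15)
  effect <- array(0, c(4, 4, 2))
  effect[1:2, 1:2, ] <- 6                  # "left"
  effect[3:4, 1:2, ] <- 6                  # "right" homolog
  subj <- lapply(1:6, function(i) effect + array(rnorm(32, sd = 0.8),
                                                 c(4, 4, 2)))
  g <- group_permutation_test(subj, alpha = 0.05, dh = 0.5)
  expect_true(all(g$mask[1:4, 1:2, ]))
  expect_false(any(g$mask[, 3:4, ]))
})
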