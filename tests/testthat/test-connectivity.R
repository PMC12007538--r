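make_vol <- function(series_by_region, labels, tr = 2.4) {
  # paint each region's series onto its voxels
  d <- c(dim(labels), ncol(series_by_region))
  v <- array(0, d)
  ids <- sort(unique(labels[labels > 0]))
  for (i in seq_along(ids)) {
    sel <- which(labels == ids[i])
    for (ti in seq_len(d[4])) {
      plane <- v[, , , ti]
      plane[sel] <- series_by_region[i, ti]
      v[, , , ti] <- plane
    }
  }
  pd_volume(v, tr)
}

test_that("region extraction averages voxels and flags absent regions", {
  lab <- fixture_labels()
  nreg <- nrow(lab$table)
  set.seed(1)
  S <- matrix(rnorm(nreg * 50), nreg)
  vol <- make_vol(S, lab$labels)
  ts <- extract_regions(vol, lab$labels, lab$table)
  expect_equal(unname(ts$series), S, tolerance = 1e-12)
  # single-voxel region returns that voxel's series exactly
  lab1 <- lab$labels
  lab1[1, 1, 1] <- 99L
  tab <- rbind(lab$table,
               data.frame(id = 99L, acronym = "X", hemisphere = "L",
                          mirror_id = NA))
  ts2 <- extract_regions(vol, lab1, tab)
  expect_equal(unname(ts2$series["X", ]), vol$values[1, 1, 1, ])
  # an id with no voxels is reported absent, not zero-filled
  tab2 <- rbind(tab, data.frame(id = 100L, acronym = "GONE",
                                hemisphere = "R", mirror_id = NA))
  ts3 <- extract_regions(vol, lab1, tab2)
  expect_equal(ts3$absent, 100L)
  expect_false("GONE" %in% rownames(ts3$series))
  expect_error(extract_regions(vol, lab$labels[, , 1, drop = FALSE]), "grid")
})

test_that("fc_matrix equals brute-force pairwise Pearson", {
  set.seed(2)
  m <- matrix(rnorm(8 * 120), 8)
  fc <- fc_matrix(m)
  brute <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    a <- m[i, ] - mean(m[i, ]); b <- m[j, ] - mean(m[j, ])
    brute[i, j] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  expect_equal(fc$r, brute, tolerance = 1e-12)
  expect_true(isSymmetric(fc$r))
  expect_equal(diag(fc$r), rep(1, 8))
  # identical and anti-correlated regions
  m2 <- rbind(m[1, ], m[1, ], -m[1, ])
  fc2 <- fc_matrix(m2)
  expect_equal(fc2$r[1, 2], 1)
  expect_equal(fc2$r[1, 3], -1)
  # constant series masked, not imputed
  m3 <- rbind(m[1, ], rep(5, 120))
  fc3 <- fc_matrix(m3)
  expect_true(is.na(fc3$r[1, 2]))
  expect_false(fc3$defined[1, 2])
})

test_that("Fisher group averaging matches the closed form", {
  r1 <- matrix(c(1, 0.3, 0.3, 1), 2)
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  g <- group_average_fc(list(r1, r2))
  expect_equal(g$r[1, 2], tanh((atanh(0.3) + atanh(0.9)) / 2),
               tolerance = 1e-12)
  expect_equal(g$r[1, 2], 0.712, tolerance = 1e-3)
  expect_equal(diag(g$r), c(1, 1))
  # identity on identical inputs, n = 1 passthrough
  expect_equal(group_average_fc(list(r1, r1))$r, r1)
  expect_equal(group_average_fc(list(r1))$r, r1)
  # odd symmetry
  gz <- group_average_fc(list(matrix(c(1, 0.5, 0.5, 1), 2),
                              matrix(c(1, -0.5, -0.5, 1), 2)))
  expect_equal(gz$r[1, 2], 0)
  # |r| = 1 off-diagonal is clipped with a warning, output stays in (-1, 1)
  expect_warning(gc <- group_average_fc(list(matrix(c(1, 1, 1, 1), 2), r1)),
                 "clipped")
  expect_lt(abs(gc$r[1, 2]), 1)
})

test_that("FC significance detects one true pair and controls FDR", {
  set.seed(3)
  k <- 6; n_subj <- 6
  mats <- lapply(seq_len(n_subj), function(s) {
    m <- matrix(rnorm(k * 200), k)
    m[2, ] <- 0.8 * m[1, ] + sqrt(1 - 0.64) * rnorm(200)
    fc_matrix(m)$r
  })
  sig <- fc_significance(mats, alpha = 0.05)
  expect_true(sig$mask[1, 2])
  expect_true(isSymmetric(sig$mask))
  # all-zero z across subjects: nothing significant
  null_mats <- replicate(4, diag(k), simplify = FALSE)
  expect_false(any(fc_significance(null_mats)$mask))
})

test_that("FC FDR stays controlled under the global null", {
  set.seed(42)
  k <- 8; n_subj <- 6; reps <- 500
  n_pairs <- k * (k - 1) / 2
  fdp <- vapply(seq_len(reps), function(i) {
    mats <- lapply(seq_len(n_subj), function(s)
      fc_matrix(matrix(rnorm(k * 60), k))$r)
    sig <- fc_significance(mats, alpha = 0.05)
    n_disc <- sum(sig$mask[upper.tri(sig$mask)])
    if (n_disc == 0) 0 else 1              # all discoveries are false here
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(fdp), 0.05 + 2 * se)
})

test_that("seed maps reuse the GLM and match region-level FC ordering", {
  lab <- fixture_labels()
  nreg <- nrow(lab$table)
  set.seed(4)
  S <- matrix(rnorm(nreg * 100), nreg)
  S[2, ] <- 0.9 * S[1, ] + sqrt(1 - 0.81) * rnorm(100)
  vol <- make_vol(S, lab$labels)
  sm <- seed_map(vol, S[1, ])
  # the seed's own voxels carry the maximal t
  expect_true(which.max(sm$t) %in% which(lab$labels == lab$table$id[1]))
  # region-pure voxels reproduce the FC column ordering by t
  fc <- fc_matrix(S)
  t_by_region <- vapply(seq_len(nreg), function(i) {
    mean(sm$t[lab$labels == lab$table$id[i]])
  }, numeric(1))
  expect_equal(order(t_by_region[-1]), order(fc$r[1, -1]))
  expect_error(seed_map(vol, rep(1, 100)), "constant")
})

test_that("bilateral planted network reaches the contralateral homolog", {
  sched <- fixture_schedule()
  lab <- fixture_labels()
  nreg <- nrow(lab$table)
  cov <- diag(nreg); cov[1, 2] <- cov[2, 1] <- 0.8
  tmaps <- lapply(1:6, function(s) {
    spec <- simulation_spec(sched, 600, lab$labels, cov, noise_sigma = 0.3,
                            seed = 400 + s)
    pd <- simulate_pd_series(spec)
    ts <- extract_regions(pd, lab$labels, lab$table)
    seed_map(pd, ts$series[1, ])$t        # seed in region 1 ("left")
  })
  g <- group_permutation_test(tmaps, alpha = 0.05, tail = "greater",
                              dh = 2)
  homolog <- lab$labels == 2
  other <- lab$labels == 3 | lab$labels == 4
  expect_true(all(g$mask[homolog]))
  expect_false(any(g$mask[other]))
})

test_that("specificity metric separates bilateral signal from global", {
  lab <- fixture_labels()
  nreg <- nrow(lab$table)
  set.seed(6)
  n <- 300
  shared <- rnorm(n)
  S <- matrix(rnorm(nreg * n, sd = 1), nreg)
  S[1, ] <- shared + 0.3 * rnorm(n)        # SS left
  S[2, ] <- shared + 0.3 * rnorm(n)        # SS right
  vol <- make_vol(S, lab$labels)
  ts <- extract_regions(vol, lab$labels, lab$table)
  sp <- fc_specificity(ts, "R1-L", "R1-R", "R2-L")
  expect_gt(sp$r_specific, 0.8)
  expect_lt(abs(sp$r_unspecific), 0.2)
  # global common signal: both high (the failure mode)
  Sg <- matrix(rep(shared, nreg), nreg, byrow = TRUE) +
    0.1 * matrix(rnorm(nreg * n), nreg)
  tsg <- extract_regions(make_vol(Sg, lab$labels), lab$labels, lab$table)
  spg <- fc_specificity(tsg, "R1-L", "R1-R", "R2-L")
  expect_gt(spg$r_specific, 0.9)
  expect_gt(spg$r_unspecific, 0.9)
  # independent noise: both ~ 0
  Sn <- matrix(rnorm(nreg * n), nreg)
  tsn <- extract_regions(make_vol(Sn, lab$labels), lab$labels, lab$table)
  spn <- fc_specificity(tsn, "R1-L", "R1-R", "R2-L")
  expect_lt(abs(spn$r_specific), 0.2)
  expect_lt(abs(spn$r_unspecific), 0.2)
  expect_error(fc_specificity(ts, "NOPE", "R1-R", "R2-L"), "not found")
})
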