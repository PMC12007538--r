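#' Four half-cosine canonical hemodynamic response function
#'
#' Piecewise kernel built from four half-cosine segments: an onset delay at
#' zero, a rising half-cosine to the peak, a falling half-cosine to an
#' (optional) undershoot, and a recovering half-cosine back to zero. The peak
#' is normalized to 1. Segment durations are configuration; defaults give a
#' ~8 s kernel with no undershoot, a conventional shape for rodent CBV
#' responses.
#'
#' @param onset_delay Dead time before the response starts, s.
#' @param rise Duration of the rising half-cosine, s.
#' @param fall Duration of the falling half-cosine, s.
#' @param recover Duration of the recovery half-cosine, s.
#' @param undershoot Depth of the undershoot as a fraction of the peak
#'   (0 disables it).
#' @return Object of class `hrf_model`.
#' @export
hrf_model <- function(onset_delay = 0.5, rise = 1.0, fall = 3.0,
                      recover = 3.5, undershoot = 0) {
  if (any(c(onset_delay, rise, fall, recover) <= 0)) {
    stop("all segment durations must be positive")
  }
  structure(list(onset_delay = onset_delay, rise = rise, fall = fall,
                 recover = recover, undershoot = undershoot,
                 duration = onset_delay + rise + fall + recover),
            class = "hrf_model")
}

#' Evaluate an HRF kernel on a time grid
#' @param hrf An [hrf_model()].
#' @param t Time points, s (from 0).
#' @return Kernel values; starts and ends at 0, peak 1.
#' @export
hrf_kernel <- function(hrf, t) {
  stopifnot(inherits(hrf, "hrf_model"))
  k <- numeric(length(t))
  t1 <- hrf$onset_delay
  t2 <- t1 + hrf$rise
  t3 <- t2 + hrf$fall
  t4 <- t3 + hrf$recover
  u <- hrf$undershoot
  seg <- t >= t1 & t < t2
  k[seg] <- (1 - cos(pi * (t[seg] - t1) / hrf$rise)) / 2
  seg <- t >= t2 & t < t3   # falling half-cosine from 1 down to -u
  k[seg] <- -u + (1 + u) * (1 + cos(pi * (t[seg] - t2) / hrf$fall)) / 2
  seg <- t >= t3 & t < t4
  k[seg] <- -u * (1 + cos(pi * (t[seg] - t3) / hrf$recover)) / 2
  k
}

# Causal convolution of a sampled stimulus with the HRF kernel, truncated to
# the input length.
convolve_hrf <- function(x, hrf, dt) {
  kt <- seq(0, hrf$duration, by = dt)
  k <- hrf_kernel(hrf, kt)
  full <- stats::convolve(x, rev(k), type = "open")
  full[seq_along(x)]
}

#' Build the GLM stimulus regressor
#'
#' Convolves the 0/1 stimulus timeline with the canonical HRF and rescales
#' the result so it is 0 with no stimulus and 1 during sustained stimulation
#' (peak-normalized).
#'
#' @param stimulus A [make_stimulus()] timeline (or a 0/1 vector with
#'   attribute-free sampling at `tr`).
#' @param hrf An [hrf_model()].
#' @param tr Sampling interval, s.
#' @return Numeric regressor, same length as the stimulus.
#' @export
build_regressor <- function(stimulus, hrf = hrf_model(), tr = NULL) {
  if (inherits(stimulus, "stimulus_timeline")) {
    x <- stimulus$x
    if (is.null(tr)) tr <- stimulus$tr
  } else {
    x <- as.numeric(stimulus)
    if (is.null(tr)) stop("tr must be given for a bare stimulus vector")
  }
  if (!any(x != 0)) return(numeric(length(x)))
  r <- convolve_hrf(x, hrf, tr)
  r <- r - min(r)
  r / max(r)
}

#' Voxelwise ordinary-least-squares GLM
#'
#' Fits `y = X beta + e` and returns the contrast t-statistic with its
#' two-sided p-value from the Student t distribution with `n - p` degrees of
#' freedom. The intercept estimate is the modeled baseline.
#'
#' @param y Response vector, or a voxels x time matrix (one fit per row).
#' @param X Design matrix without intercept column unless
#'   `add_intercept = FALSE`.
#' @param contrast Contrast vector over the columns of the full design
#'   (default: the first non-intercept regressor).
#' @param add_intercept Prepend an intercept column (default TRUE).
#' @return For vector `y`: list `beta`, `t`, `p`, `df`, `baseline`, `se`.
#'   For matrix `y`: list of vectors of the same names (one entry per row).
#' @export
glm_fit <- function(y, X, contrast = NULL, add_intercept = TRUE) {
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(intercept = 1, X)
  n <- nrow(X); p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  if (n <= p) stop("need more observations than regressors")
  if (is.null(contrast)) {
    contrast <- numeric(p)
    contrast[if (add_intercept) 2L else 1L] <- 1
  }
  ym <- if (is.matrix(y)) t(y) else matrix(y, ncol = 1)   # time x voxels
  xtx_inv <- solve(crossprod(X))
  beta <- xtx_inv %*% crossprod(X, ym)                    # p x voxels
  resid <- ym - X %*% beta
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  c_var <- drop(t(contrast) %*% xtx_inv %*% contrast)
  se <- sqrt(sigma2 * c_var)
  est <- drop(t(contrast) %*% beta)
  tstat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  out <- list(beta = if (is.matrix(y)) t(beta) else drop(beta),
              t = unname(tstat), p = unname(pval), df = df,
              baseline = if (add_intercept) unname(drop(beta[1, ])) else NULL,
              se = unname(se))
  out
}

#' Bonferroni significance mask
#'
#' Controls the familywise error rate at `alpha` by declaring a voxel
#' significant iff its p-value is below `alpha / n`, with `n` the number of
#' tested (in-mask) voxels.
#'
#' @param pmap Numeric p-value array or vector.
#' @param alpha FWER level (default 0.05).
#' @param mask Optional logical array restricting the tested voxels.
#' @return Logical mask of the same shape as `pmap`.
#' @export
bonferroni_mask <- function(pmap, alpha = 0.05, mask = NULL) {
  tested <- if (is.null(mask)) is.finite(pmap) else as.logical(mask)
  n <- sum(tested)
  out <- array(FALSE, dim = if (is.null(dim(pmap))) length(pmap) else dim(pmap))
  out[tested] <- pmap[tested] < alpha / n
  if (is.null(dim(pmap))) dim(out) <- NULL
  out
}

#' Relative CBV change
#'
#' `100 * (y - baseline) / baseline`: the Power Doppler signal expressed as a
#' percent change from its baseline (PD is proportional to CBV).
#'
#' @param series Numeric series or array.
#' @param baseline Positive baseline level (scalar or conformable).
#' @return rCBV in percent.
#' @export
rcbv <- function(series, baseline) {
  if (any(baseline <= 0)) stop("baseline must be positive")
  100 * (series - baseline) / baseline
}

#' Trial averaging of peristimulus responses
#'
#' Cuts equal-length windows starting at each trial onset out of a series (or
#' each row of a region x time matrix) and averages them, shrinking
#' trial-independent noise by sqrt(n_trials).
#'
#' @param x Numeric vector, or matrix with time in columns.
#' @param trial_onsets Trial start indices (1-based samples).
#' @param window Window length in samples.
#' @return Averaged window(s): vector, or matrix regions x window.
#' @export
trial_average <- function(x, trial_onsets, window) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (any(trial_onsets + window - 1 > ncol(m))) {
    stop("trial window exceeds the scan")
  }
  acc <- matrix(0, nrow(m), window)
  for (o in trial_onsets) acc <- acc + m[, o:(o + window - 1), drop = FALSE]
  acc <- acc / length(trial_onsets)
  if (is.matrix(x)) acc else drop(acc)
}

# Connected-component labeling of a logical 3D array under 6-connectivity
# (faces only). Iterative flood fill; returns an integer array of labels.
label_components_6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  coords <- arrayInd(idx_all, d)
  pos_of <- array(0L, d); pos_of[idx_all] <- seq_along(idx_all)
  visited <- logical(length(idx_all))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(idx_all)) {
    if (visited[s]) next
    nxt <- nxt + 1L
    stack <- s
    visited[s] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      lab[idx_all[cur]] <- nxt
      cc <- coords[cur, ]
      for (k in 1:6) {
        nb <- cc + offs[k, ]
        if (any(nb < 1L) || any(nb > d)) next
        if (!mask[nb[1], nb[2], nb[3]]) next
        p <- pos_of[nb[1], nb[2], nb[3]]
        if (!visited[p]) {
          visited[p] <- TRUE
          stack <- c(stack, p)
        }
      }
    }
  }
  lab
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster support over all thresholds: for each voxel,
#' `sum_h e(h)^E * h^H * dh` where `e(h)` is the extent of the cluster
#' containing the voxel when the map is thresholded at height `h`. Positive
#' and negative tails are enhanced separately (the negative tail on the
#' negated map) and recombined with their signs. 6-connectivity.
#'
#' @param statmap Numeric 3D array (a 1D/2D array is treated as a degenerate
#'   3D volume).
#' @param E Extent exponent (default 0.5).
#' @param H Height exponent (default 2).
#' @param dh Threshold step; default `max(abs(statmap)) / 100`.
#' @return Enhanced map, same shape as the input.
#' @export
tfce <- function(statmap, E = 0.5, H = 2, dh = NULL) {
  d0 <- dim(statmap)
  x <- as.array(statmap)
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  enhance_tail <- function(m, dh) {
    out <- array(0, dim(m))
    top <- max(m, 0)
    if (top < dh) return(out)
    hs <- seq(dh, top, by = dh)
    for (h in hs) {
      sup <- m >= h
      if (!any(sup)) break
      lab <- label_components_6(sup)
      sizes <- tabulate(lab[sup])
      out[sup] <- out[sup] + sizes[lab[sup]]^E * h^H * dh
    }
    out
  }
  if (is.null(dh)) {
    top <- max(abs(x))
    if (top == 0) return(statmap)
    dh <- top / 100
  }
  res <- enhance_tail(x, dh) - enhance_tail(-x, dh)
  if (is.null(d0)) as.numeric(res) else array(res, d0)
}

#' Group-level one-sample test with TFCE and max-statistic permutations
#'
#' Tests whether the mean of per-subject statistic maps differs from zero.
#' The observed one-sample t map is TFCE-enhanced; the null distribution is
#' the image-wise maximum of |TFCE| over random (or, for <= 12 subjects,
#' exhaustive) sign flips of the subjects, giving familywise error control.
#' Two-tailed by default; `tail = "greater"` gives the one-tailed variant
#' used for seed maps.
#'
#' @param subject_maps List of same-shaped numeric arrays (one per subject).
#' @param n_perm Number of permutations when not exhaustive (default 1000;
#'   values below 100 trigger a warning).
#' @param alpha FWER level.
#' @param tail `"two.sided"` or `"greater"`.
#' @param E,H,dh TFCE parameters.
#' @param seed Optional RNG seed for the sign flips.
#' @return Object of class `stat_map`: `t` (group t map), `tfce` (enhanced),
#'   `p` (permutation p per voxel), `mask` (significant voxels),
#'   `threshold` (the (1-alpha) max-null quantile), `method`, `df`,
#'   `n_perm_used`, `exhaustive`.
#' @export
group_permutation_test <- function(subject_maps, n_perm = 1000, alpha = 0.05,
                                   tail = c("two.sided", "greater"),
                                   E = 0.5, H = 2, dh = NULL, seed = NULL) {
  tail <- match.arg(tail)
  n <- length(subject_maps)
  if (n < 2L) stop("need at least 2 subjects")
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  d <- dim(subject_maps[[1]])
  stack <- vapply(subject_maps, as.numeric, numeric(prod(d)))

  one_sample_t <- function(s) {
    mu <- rowMeans(s)
    sdv <- sqrt(rowSums((s - mu)^2) / (n - 1))
    t <- mu / (sdv / sqrt(n))
    t[!is.finite(t)] <- 0
    t
  }
  score <- function(t_map) {
    e <- tfce(array(t_map, d), E = E, H = H, dh = dh)
    if (tail == "greater") as.numeric(e) else abs(as.numeric(e))
  }

  t_obs <- one_sample_t(stack)
  tfce_signed <- tfce(array(t_obs, d), E = E, H = H, dh = dh)
  obs <- if (tail == "greater") as.numeric(tfce_signed) else
    abs(as.numeric(tfce_signed))

  exhaustive <- n <= 12L
  flips <- if (exhaustive) {
    g <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    g
  } else {
    matrix(sample(c(1, -1), n_perm * n, replace = TRUE), ncol = n)
  }
  max_null <- apply(flips, 1, function(sgn) {
    max(score(one_sample_t(sweep(stack, 2, sgn, `*`))))
  })
  n_used <- length(max_null)
  thresh <- stats::quantile(max_null, 1 - alpha, type = 1, names = FALSE)
  # FWER-corrected p-value: fraction of the max-statistic null at or above
  # the observed enhancement; reject at p <= alpha (valid under the
  # discreteness of exhaustive sign-flipping)
  pvox <- vapply(obs, function(o) mean(max_null >= o), numeric(1))
  structure(list(t = array(t_obs, d),
                 tfce = tfce_signed,
                 p = array(pvox, d),
                 mask = array(pvox <= alpha, d),
                 threshold = thresh, method = "tfce_permutation",
                 df = n - 1L, n_perm_used = n_used,
                 exhaustive = exhaustive),
            class = "stat_map")
}

#' Voxelwise activation GLM over a 4D volume
#'
#' Applies [glm_fit()] with a stimulus regressor to every voxel of a
#' [pd_volume()] and assembles t/p/baseline maps with an optional
#' Bonferroni mask.
#'
#' @param vol A [pd_volume()].
#' @param regressor Stimulus regressor (length = volumes).
#' @param alpha FWER level for the Bonferroni mask.
#' @param mask Optional in-brain mask.
#' @return Object of class `stat_map` with `t`, `p`, `beta`, `baseline`,
#'   `mask`, `method = "bonferroni"`, `df`.
#' @export
activation_glm <- function(vol, regressor, alpha = 0.05, mask = NULL) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  fit <- glm_fit(m, matrix(regressor, ncol = 1))
  pm <- array(fit$p, d[1:3])
  structure(list(t = array(fit$t, d[1:3]), p = pm,
                 beta = array(fit$beta[, 2], d[1:3]),
                 baseline = array(fit$baseline, d[1:3]),
                 mask = bonferroni_mask(pm, alpha, mask),
                 method = "bonferroni", df = fit$df),
            class = "stat_map")
}
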