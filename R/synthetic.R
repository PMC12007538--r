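#' IQ phantom specification
#'
#' Desk-scale phantom emulating the component structure of ultrafast Doppler
#' blocks: a few high-energy low-rank tissue modes with slow phase modulation,
#' Doppler-shifted blood scatterers confined to a vessel mask, and circular
#' white complex noise.
#'
#' @param nx,nz Grid dimensions.
#' @param n_frames Frames per block (default 200).
#' @param frame_rate Frame rate, Hz (default 500).
#' @param tissue_amplitude,blood_amplitude,noise_sigma Component amplitudes
#'   (arbitrary units).
#' @param vessel_mask Logical nx x z matrix of vessel voxels; default a
#'   horizontal stripe through the middle.
#' @param blood_doppler_freq Doppler shift of blood, Hz (< frame_rate / 2).
#' @param tissue_motion_freq Slow tissue phase-modulation frequency, Hz.
#' @param tissue_rank Number of tissue modes (<= 3).
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(nx = 32, nz = 32, n_frames = 200, frame_rate = 500,
                         tissue_amplitude = 100, blood_amplitude = 1,
                         noise_sigma = 0.1, vessel_mask = NULL,
                         blood_doppler_freq = 150, tissue_motion_freq = 2,
                         tissue_rank = 2, seed = 1L) {
  if (blood_doppler_freq >= frame_rate / 2) {
    stop("blood_doppler_freq must be below the Nyquist rate")
  }
  if (any(c(tissue_amplitude, blood_amplitude, noise_sigma) < 0)) {
    stop("amplitudes must be non-negative")
  }
  if (tissue_rank < 1 || tissue_rank > 3) stop("tissue_rank must be 1..3")
  if (is.null(vessel_mask)) {
    vessel_mask <- matrix(FALSE, nx, nz)
    rows <- seq(max(1, floor(nz / 2) - 1), min(nz, floor(nz / 2) + 1))
    vessel_mask[, rows] <- TRUE
  }
  stopifnot(identical(dim(vessel_mask), c(as.integer(nx), as.integer(nz))))
  structure(list(nx = as.integer(nx), nz = as.integer(nz),
                 n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 tissue_amplitude = tissue_amplitude,
                 blood_amplitude = blood_amplitude, noise_sigma = noise_sigma,
                 vessel_mask = vessel_mask,
                 blood_doppler_freq = blood_doppler_freq,
                 tissue_motion_freq = tissue_motion_freq,
                 tissue_rank = tissue_rank, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic IQ block from a phantom specification
#'
#' Tissue is `tissue_rank` smooth spatial patterns, each with a slow
#' small-amplitude phase modulation at `tissue_motion_freq`; blood is a set of
#' scatterers inside the vessel mask whose phase advances at
#' `blood_doppler_freq` with mild amplitude decorrelation; noise is circular
#' complex white Gaussian. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return An [iq_block()] with attribute `"spec"` echoing the spec.
#' @export
make_iq_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  nx <- spec$nx; nz <- spec$nz; nt <- spec$n_frames
  t <- (seq_len(nt) - 1) / spec$frame_rate
  frames <- array(0 + 0i, c(nx, nz, nt))

  # tissue: unit-magnitude mutually near-orthogonal phase patterns (clutter
  # covers vessel and background alike) x slowly phase-modulated time
  # courses, one distinct motion harmonic per mode so the planted modes stay
  # separate spatiotemporal SVD modes
  gx <- seq(-1, 1, length.out = nx); gz <- seq(-1, 1, length.out = nz)
  for (k in seq_len(spec$tissue_rank)) {
    pat <- exp(1i * k * pi * gx) %o% exp(1i * k * pi * gz / 2)
    tc <- exp(1i * 1.2 * sin(2 * pi * k * spec$tissue_motion_freq * t + k))
    frames <- frames + spec$tissue_amplitude / k * outer(pat, tc)
  }

  # blood: fast-decorrelating flow speckle inside the vessel mask — per-voxel
  # independent circular Gaussian amplitude (scatterers crossing the voxel
  # between frames) carried on the Doppler phase ramp
  if (spec$blood_amplitude > 0 && any(spec$vessel_mask)) {
    idx <- which(spec$vessel_mask)
    nvx <- length(idx)
    doppler <- exp(1i * 2 * pi * spec$blood_doppler_freq * t)
    speckle <- (matrix(stats::rnorm(nvx * nt), nvx, nt) +
                  1i * matrix(stats::rnorm(nvx * nt), nvx, nt)) / sqrt(2)
    blood <- spec$blood_amplitude * speckle *
      matrix(doppler, nvx, nt, byrow = TRUE)
    plane <- matrix(0 + 0i, nx * nz, nt)
    plane[idx, ] <- blood
    frames <- frames + array(plane, c(nx, nz, nt))
  }

  if (spec$noise_sigma > 0) {
    frames <- frames + spec$noise_sigma / sqrt(2) *
      (array(stats::rnorm(nx * nz * nt), c(nx, nz, nt)) +
         1i * array(stats::rnorm(nx * nz * nt), c(nx, nz, nt)))
  }
  blk <- iq_block(frames, spec$frame_rate)
  attr(blk, "spec") <- spec
  blk
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Boxcar stimulus timeline
#'
#' After `baseline` seconds of rest, `n_stimuli` stimulation blocks of
#' `on_duration` seconds each are repeated every `period` seconds. The default
#' visual protocol (60, 8, 30, 90) lasts 780 s.
#'
#' @param baseline Initial rest, s.
#' @param n_stimuli Number of stimulation blocks.
#' @param on_duration ON time per block, s (`<= period`).
#' @param period Block repetition period, s.
#' @param tr Sampling interval (volume TR), s.
#' @return Object of class `stimulus_timeline`: 0/1 vector `x` sampled at
#'   volume onsets `(0, tr, 2 tr, ...)`, plus `tr`, `total_duration`,
#'   `onsets` (stimulus start times, s).
#' @examples
#' stim <- make_stimulus(60, 8, 30, 90, tr = 2.4)
#' stim$total_duration  # 780
#' length(stim$x)       # 325 volumes
#' @export
make_stimulus <- function(baseline = 60, n_stimuli = 8, on_duration = 30,
                          period = 90, tr = 2.4) {
  if (on_duration > period) stop("on_duration must not exceed period")
  total <- baseline + n_stimuli * period
  # volumes whose onset falls in [0, total)
  times <- seq(0, total - 1e-9, by = tr)
  onsets <- baseline + (seq_len(n_stimuli) - 1) * period
  x <- numeric(length(times))
  for (o in onsets) x[times >= o & times < o + on_duration] <- 1
  structure(list(x = x, tr = tr, total_duration = total, onsets = onsets,
                 on_duration = on_duration),
            class = "stimulus_timeline")
}

#' Resting-state / task simulation specification
#'
#' Defines a desk-scale 4D Power Doppler simulation: per-region latent
#' signals drawn from a network covariance and band-limited to the
#' resting-state band, optional HRF-convolved stimulus responses in chosen
#' regions (scaled as % of baseline), degree-3 polynomial drift, episodic
#' multiplicative motion, and voxel noise. Slices sample the latent process
#' at their true within-TR onsets so slice-timing correction is testable.
#'
#' @param schedule A [build_schedule()] result giving TR and slice onsets.
#' @param duration Scan duration, s.
#' @param labels Integer label array (x, y, z); 0 = outside any region.
#' @param network_cov Region covariance (correlation) matrix, symmetric PSD,
#'   regions in label order `sort(unique(labels[labels > 0]))`.
#' @param response_regions Named numeric vector: label id -> response
#'   amplitude in % of baseline (rCBV). NULL for resting state.
#' @param baseline Baseline PD level, arbitrary units (default 100 so %
#'   rCBV reads directly).
#' @param latent_sd Standard deviation of the latent fluctuations, in the
#'   same units as `baseline`.
#' @param drift_amplitude Peak amplitude of the random degree-3 drift, units.
#' @param motion_episodes Data frame (onset_s, duration_s, amplitude_ratio)
#'   of episodes multiplying the global level; NULL for none.
#' @param noise_sigma Voxelwise white-noise sd, units.
#' @param band Latent pass band, Hz.
#' @param seed Integer RNG seed.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(schedule, duration = 780, labels, network_cov,
                            response_regions = NULL, baseline = 100,
                            latent_sd = 1, drift_amplitude = 0,
                            motion_episodes = NULL, noise_sigma = 0,
                            band = c(0.01, 0.1), seed = 1L) {
  stopifnot(inherits(schedule, "scan_schedule"))
  ids <- sort(unique(labels[labels > 0]))
  if (nrow(network_cov) != length(ids)) {
    stop("network_cov dimension does not match the number of labels")
  }
  if (max(abs(network_cov - t(network_cov))) > 1e-8) {
    stop("network_cov must be symmetric")
  }
  ev <- eigen(network_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("network_cov must be positive semi-definite")
  if (!is.null(response_regions)) {
    if (any(response_regions < 0)) stop("effect sizes must be >= 0")
    if (!all(as.integer(names(response_regions)) %in% ids)) {
      stop("response_regions names must be label ids")
    }
  }
  if (!is.null(motion_episodes) && any(motion_episodes$amplitude_ratio <= 0)) {
    stop("motion amplitude ratios must be positive")
  }
  structure(list(schedule = schedule, duration = duration, labels = labels,
                 region_ids = ids, network_cov = network_cov,
                 response_regions = response_regions, baseline = baseline,
                 latent_sd = latent_sd, drift_amplitude = drift_amplitude,
                 motion_episodes = motion_episodes, noise_sigma = noise_sigma,
                 band = band, seed = as.integer(seed)),
            class = "simulation_spec")
}

# Band-limited unit-variance Gaussian latents with covariance `cov`:
# white noise filtered with the same zero-phase Butterworth design as the
# preprocessing band-pass (shared code path), then mixed by chol(cov).
simulate_latents <- function(n_regions, n_t, fs, cov, band) {
  pad <- min(n_t, 200L)
  w <- matrix(stats::rnorm((n_t + 2 * pad) * n_regions), ncol = n_regions)
  f <- apply(w, 2, bandpass_zero_phase, fs = fs, band = band)
  f <- f[pad + seq_len(n_t), , drop = FALSE]
  f <- scale(f, scale = FALSE)
  # empirically whiten the realized series so the sample correlation of the
  # mixed latents equals `cov` exactly (band-limited noise has few effective
  # degrees of freedom; raw mixing would leave visible sampling error)
  cs <- crossprod(f) / (n_t - 1)
  e <- eigen(cs, symmetric = TRUE)
  f <- f %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                n_regions) %*% t(e$vectors)
  L <- chol_psd(cov)
  f %*% t(L)
}

# Cholesky tolerant of PSD (rank-deficient) matrices via eigendecomposition.
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v))
}

#' Simulate a 4D Power Doppler series
#'
#' Voxel signal = baseline + latent-region fluctuation + stimulus response
#' (HRF-convolved boxcar scaled to the planted % rCBV) + degree-3 drift +
#' voxel noise, all multiplied by motion episodes when they are active.
#' Slices are sampled at `volume onset + slice onset` so the acquisition
#' staggering of the motorized schedule is present in the data.
#'
#' @param spec A [simulation_spec()].
#' @param stimulus A [make_stimulus()] timeline or NULL.
#' @param hrf An [hrf_model()]; default model used when NULL.
#' @return A [pd_volume()] (x, y, z, t) with TR and slice-onset metadata and
#'   a `provenance` attribute echoing the spec parameters and seed.
#' @export
simulate_pd_series <- function(spec, stimulus = NULL, hrf = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  sched <- spec$schedule
  tr <- sched$tr
  n_t <- floor(spec$duration / tr + 1e-9)
  d <- dim(spec$labels)
  nz <- d[3]
  onsets <- sched$slice_onsets
  if (length(onsets) < nz) onsets <- rep_len(onsets, nz)

  # latent processes on a fine grid so staggered slice onsets can sample them
  fine_dt <- min(c(diff(sort(unique(onsets))), tr / 4))
  fine_dt <- max(fine_dt, tr / 16)
  fine_t <- seq(0, spec$duration + tr, by = fine_dt)
  lat_fine <- simulate_latents(length(spec$region_ids), length(fine_t),
                               1 / fine_dt, spec$network_cov, spec$band) *
    spec$latent_sd

  # stimulus response regressor on the fine grid, peak-normalized to 1
  resp_fine <- NULL
  if (!is.null(stimulus) && !is.null(spec$response_regions)) {
    if (is.null(hrf)) hrf <- hrf_model()
    stim_fine <- numeric(length(fine_t))
    for (o in stimulus$onsets) {
      stim_fine[fine_t >= o & fine_t < o + stimulus$on_duration] <- 1
    }
    resp_fine <- convolve_hrf(stim_fine, hrf, fine_dt)
    resp_fine <- resp_fine - min(resp_fine)
    resp_fine <- resp_fine / max(resp_fine)   # 0 at rest, 1 sustained ON
  }

  drift_coef <- NULL
  if (spec$drift_amplitude > 0) {
    drift_coef <- matrix(stats::rnorm(prod(d) * 4, sd = spec$drift_amplitude /
                                        c(1, 1, 2, 6)), nrow = 4, byrow = FALSE)
    dim(drift_coef) <- c(4, d)
  }

  vol <- array(0, c(d, n_t))
  vol_onsets <- (seq_len(n_t) - 1) * tr
  region_of_voxel <- array(match(spec$labels, spec$region_ids), d)  # NA outside
  tn <- (vol_onsets - spec$duration / 2) / spec$duration    # centred time

  for (iz in seq_len(nz)) {
    t_slice <- vol_onsets + onsets[iz]
    fi <- pmin(pmax((t_slice / fine_dt) + 1, 1), length(fine_t))
    lo <- floor(fi); fr <- fi - lo
    hi <- pmin(lo + 1, length(fine_t))
    lat_s <- lat_fine[lo, , drop = FALSE] * (1 - fr) +
      lat_fine[hi, , drop = FALSE] * fr                    # n_t x regions
    resp_s <- if (!is.null(resp_fine)) {
      resp_fine[lo] * (1 - fr) + resp_fine[hi] * fr
    } else NULL
    for (iy in seq_len(d[2])) for (ix in seq_len(d[1])) {
      r <- region_of_voxel[ix, iy, iz]
      sig <- rep(spec$baseline, n_t)
      if (!is.na(r)) {
        sig <- sig + lat_s[, r]
        id <- spec$region_ids[r]
        if (!is.null(resp_s) &&
            as.character(id) %in% names(spec$response_regions)) {
          amp <- spec$response_regions[[as.character(id)]]
          sig <- sig + spec$baseline * amp / 100 * resp_s
        }
      }
      if (!is.null(drift_coef)) {
        co <- drift_coef[, ix, iy, iz]
        sig <- sig + co[1] + co[2] * tn + co[3] * tn^2 + co[4] * tn^3
      }
      if (spec$noise_sigma > 0) {
        sig <- sig + stats::rnorm(n_t, sd = spec$noise_sigma)
      }
      vol[ix, iy, iz, ] <- sig
    }
  }

  if (!is.null(spec$motion_episodes)) {
    for (m in seq_len(nrow(spec$motion_episodes))) {
      ep <- spec$motion_episodes[m, ]
      hit <- vol_onsets >= ep$onset_s & vol_onsets < ep$onset_s + ep$duration_s
      vol[, , , hit] <- vol[, , , hit, drop = FALSE] * ep$amplitude_ratio
    }
  }

  out <- pd_volume(vol, tr = tr, slice_onsets = onsets[seq_len(nz)])
  attr(out, "provenance") <- list(
    seed = spec$seed, duration = spec$duration, tr = tr,
    baseline = spec$baseline, latent_sd = spec$latent_sd,
    noise_sigma = spec$noise_sigma, band = spec$band,
    response_regions = as.list(spec$response_regions))
  out
}

#' Toy bilateral region label volume
#'
#' A small label array with left/right homologous region pairs plus a midline
#' region, standing in for an atlas segmentation at desk scale.
#'
#' @param nx,ny,nz Array dims.
#' @param n_pairs Number of bilateral pairs.
#' @return List: `labels` (integer array) and `table` (data.frame: id,
#'   acronym, hemisphere, mirror_id).
#' @export
toy_labels <- function(nx = 10, ny = 6, nz = 4, n_pairs = 3) {
  labels <- array(0L, c(nx, ny, nz))
  half <- floor(nx / 2)
  rows_per <- max(1, floor(ny / n_pairs))
  tab <- NULL
  id <- 0L
  for (p in seq_len(n_pairs)) {
    ys <- ((p - 1) * rows_per + 1):min(p * rows_per, ny)
    id_l <- id + 1L; id_r <- id + 2L; id <- id + 2L
    labels[1:half, ys, ] <- id_l
    labels[(half + 1):nx, ys, ] <- id_r
    tab <- rbind(tab,
                 data.frame(id = id_l, acronym = paste0("R", p, "-L"),
                            hemisphere = "L", mirror_id = id_r),
                 data.frame(id = id_r, acronym = paste0("R", p, "-R"),
                            hemisphere = "R", mirror_id = id_l))
  }
  list(labels = labels, table = tab)
}
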