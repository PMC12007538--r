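#' Tilted plane-wave set for coherent compounding
#'
#' @param n_angles Number of angles, evenly spaced and symmetric about 0.
#' @param theta_max Maximum steering angle, degrees.
#' @param prf Pulse repetition frequency, Hz.
#' @param speed_of_sound Speed of sound, m/s.
#' @return Object of class `plane_wave_set` with the angle list in degrees.
#' @examples
#' pw <- plane_wave_set()      # 8 angles from -12 to 12 degrees
#' round(pw$angles_deg, 2)
#' @export
plane_wave_set <- function(n_angles = 8L, theta_max = 12, prf = 4000,
                           speed_of_sound = 1540) {
  n_angles <- as.integer(n_angles)
  if (n_angles < 1L) stop("n_angles must be >= 1")
  angles <- if (n_angles == 1L) 0 else seq(-theta_max, theta_max,
                                           length.out = n_angles)
  structure(list(angles_deg = angles, theta_max = theta_max, prf = prf,
                 speed_of_sound = speed_of_sound,
                 frame_rate = compound_frame_rate(prf, n_angles)),
            class = "plane_wave_set")
}

#' Trapezoidal beamforming grid
#'
#' A reconstruction grid whose lateral extent widens linearly with depth at
#' the maximum steering angle, so regions beyond the physical aperture can
#' still be reconstructed from tilted transmissions. At depth z the half-width
#' is `aperture/2 + z * tan(theta_max)`.
#'
#' @param aperture_mm Physical aperture width, mm.
#' @param z_min,z_max Depth range, mm.
#' @param dx,dz Grid spacing, mm (default 0.1 x 0.1).
#' @param theta_max Maximum steering angle, degrees.
#' @return Object of class `trapezoidal_grid`: vectors `x` and `z` of the
#'   bounding rectangle plus a logical matrix `inside` (x by z) marking voxels
#'   inside the trapezoid.
#' @export
trapezoidal_grid <- function(aperture_mm, z_min = 0, z_max = 10,
                             dx = 0.1, dz = 0.1, theta_max = 12) {
  if (z_max <= z_min) stop("z_max must exceed z_min")
  half_top <- aperture_mm / 2
  slope <- tan(theta_max * pi / 180)
  half_bottom <- half_top + z_max * slope
  x <- seq(-half_bottom, half_bottom, by = dx)
  z <- seq(z_min, z_max, by = dz)
  inside <- outer(x, z, function(xx, zz) abs(xx) <= half_top + zz * slope + 1e-12)
  structure(list(x = x, z = z, dx = dx, dz = dz, theta_max = theta_max,
                 aperture_mm = aperture_mm, inside = inside),
            class = "trapezoidal_grid")
}

#' Lateral width of a trapezoidal grid at a given depth
#' @param grid A [trapezoidal_grid()].
#' @param z_mm Depth, mm.
#' @return Width in mm of the region reconstructed at that depth.
#' @export
grid_width_at_depth <- function(grid, z_mm) {
  stopifnot(inherits(grid, "trapezoidal_grid"))
  grid$aperture_mm + 2 * z_mm * tan(grid$theta_max * pi / 180)
}

#' Channel data container
#'
#' Complex baseband (IQ) element samples for one transmit event on one array.
#'
#' @param samples Complex matrix, elements x time samples.
#' @param element_x_mm Lateral element positions, mm (length = rows).
#' @param sample_rate Temporal sample rate, Hz.
#' @param t0 Time of the first sample, s (default 0).
#' @return Object of class `channel_data`.
#' @export
channel_data <- function(samples, element_x_mm, sample_rate, t0 = 0) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(element_x_mm)) {
    stop("element count mismatch between samples and element_x_mm")
  }
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples)))) {
    stop("channel samples must be finite")
  }
  structure(list(samples = samples, element_x_mm = element_x_mm,
                 sample_rate = sample_rate, t0 = t0),
            class = "channel_data")
}

# Linear interpolation of one element's complex record at arbitrary times.
# Delays falling outside the recording contribute zero.
interp_channel <- function(record, sample_rate, t0, t) {
  idx <- (t - t0) * sample_rate + 1
  lo <- floor(idx)
  frac <- idx - lo
  n <- length(record)
  ok <- lo >= 1 & lo < n
  out <- complex(length(t))
  if (any(ok)) {
    out[ok] <- record[lo[ok]] * (1 - frac[ok]) + record[lo[ok] + 1L] * frac[ok]
  }
  edge <- lo == n & frac == 0
  out[edge] <- record[n]
  out
}

#' Delay-and-sum beamforming of one plane-wave transmit
#'
#' For each grid voxel inside the trapezoid, sums the linearly interpolated
#' element samples at the two-way travel time
#' `tau = (z cos(theta) + x sin(theta)) / c + sqrt(z^2 + (x - xe)^2) / c`,
#' with a rectangular receive apodization accepting elements within the
#' f-number cone (`|x - xe| <= z / (2 f_number)`). Voxels outside the
#' trapezoid are set to NA; delays beyond the recording contribute zero.
#'
#' @param channels A [channel_data()].
#' @param angle_deg Transmit plane-wave angle, degrees.
#' @param grid A [trapezoidal_grid()].
#' @param speed_of_sound Speed of sound, m/s.
#' @param f_number Receive f-number for the rectangular apodization; `Inf`
#'   accepts all elements.
#' @return Complex matrix (length(grid$x) by length(grid$z)).
#' @export
das_beamform <- function(channels, angle_deg, grid, speed_of_sound = 1540,
                         f_number = 1.0) {
  stopifnot(inherits(channels, "channel_data"),
            inherits(grid, "trapezoidal_grid"))
  if (abs(angle_deg) > grid$theta_max + 1e-9) {
    stop("angle exceeds the grid's theta_max")
  }
  c_mm <- speed_of_sound * 1e3             # mm/s
  th <- angle_deg * pi / 180
  xe <- channels$element_x_mm
  img <- matrix(NA_complex_, length(grid$x), length(grid$z))
  for (iz in seq_along(grid$z)) {
    z <- grid$z[iz]
    half_acc <- if (is.finite(f_number)) z / (2 * f_number) else Inf
    ix_in <- which(grid$inside[, iz])
    if (!length(ix_in)) next
    xs <- grid$x[ix_in]
    tx_delay <- (z * cos(th) + xs * sin(th)) / c_mm
    acc <- complex(length(xs))
    for (e in seq_along(xe)) {
      use <- abs(xs - xe[e]) <= half_acc
      if (!any(use)) next
      rx_delay <- sqrt(z^2 + (xs[use] - xe[e])^2) / c_mm
      acc[use] <- acc[use] +
        interp_channel(channels$samples[e, ], channels$sample_rate,
                       channels$t0, tx_delay[use] + rx_delay)
    }
    img[ix_in, iz] <- acc
  }
  img
}

#' Coherent compounding of beamformed angle images
#'
#' @param images List of complex images on identical grids.
#' @return Complex image: the coherent (complex) mean across angles.
#' @export
compound <- function(images) {
  if (!length(images)) stop("no images to compound")
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("mismatched grids: images have different dimensions")
  }
  Reduce(`+`, images) / length(images)
}

#' Simulate plane-wave channel data from point scatterers
#'
#' Travel-time echo model used as the beamforming oracle and phantom source:
#' each scatterer returns a baseband Gaussian-windowed complex pulse at its
#' two-way travel time to each element.
#'
#' @param scatterers Data frame with columns `x_mm`, `z_mm`, `amp`.
#' @param element_x_mm Element lateral positions, mm.
#' @param angle_deg Transmit plane-wave angle, degrees.
#' @param sample_rate Sampling rate, Hz.
#' @param n_samples Record length per element.
#' @param speed_of_sound Speed of sound, m/s.
#' @param pulse_sigma Envelope width of the echo pulse, s.
#' @param carrier_freq Carrier frequency of the analytic echo pulse, Hz. The
#'   carrier phase is what makes delay-and-sum focus and coherent compounding
#'   cancel side lobes; 0 gives a phaseless envelope-only echo.
#' @return A [channel_data()] object.
#' @export
simulate_channels <- function(scatterers, element_x_mm, angle_deg,
                              sample_rate = 2e7, n_samples = 512,
                              speed_of_sound = 1540, pulse_sigma = 5e-8,
                              carrier_freq = 4e6) {
  c_mm <- speed_of_sound * 1e3
  th <- angle_deg * pi / 180
  t <- (seq_len(n_samples) - 1) / sample_rate
  samples <- matrix(0 + 0i, length(element_x_mm), n_samples)
  for (s in seq_len(nrow(scatterers))) {
    x0 <- scatterers$x_mm[s]; z0 <- scatterers$z_mm[s]
    a <- scatterers$amp[s]
    tau <- (z0 * cos(th) + x0 * sin(th)) / c_mm +
      sqrt(z0^2 + (element_x_mm - x0)^2) / c_mm
    for (e in seq_along(element_x_mm)) {
      samples[e, ] <- samples[e, ] +
        a * exp(-((t - tau[e])^2) / (2 * pulse_sigma^2)) *
        exp(2i * pi * carrier_freq * (t - tau[e]))
    }
  }
  channel_data(samples, element_x_mm, sample_rate)
}
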