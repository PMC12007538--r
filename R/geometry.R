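#' Probe geometry for a multi-array fUS probe
#'
#' Describes a probe made of several compact linear arrays mounted side by
#' side, each focused in elevation by an acoustic lens. Defaults correspond to
#' a 15 MHz four-array probe with 64 elements per array at 110 um pitch and
#' 2.1 mm between neighbouring arrays.
#'
#' @param n_arrays Number of linear arrays (>= 1).
#' @param elements_per_array Elements per array.
#' @param pitch_mm Element pitch in mm.
#' @param inter_array_mm Centre-to-centre spacing between arrays in mm.
#' @param elevation_fwhm_mm Elevation full-width half-maximum of each slice, mm.
#' @param center_frequency_mhz Centre frequency in MHz.
#' @return An object of class `probe_geometry`.
#' @examples
#' geom <- probe_geometry()
#' n_channels(geom)  # 256
#' @export
probe_geometry <- function(n_arrays = 4L, elements_per_array = 64L,
                           pitch_mm = 0.110, inter_array_mm = 2.1,
                           elevation_fwhm_mm = 0.5,
                           center_frequency_mhz = 15) {
  n_arrays <- as.integer(n_arrays)
  elements_per_array <- as.integer(elements_per_array)
  if (n_arrays < 1L) stop("n_arrays must be >= 1")
  if (elements_per_array < 1L) stop("elements_per_array must be >= 1")
  if (inter_array_mm <= 0) stop("inter_array_mm must be positive")
  if (pitch_mm <= 0) stop("pitch_mm must be positive")
  structure(list(
    n_arrays = n_arrays,
    elements_per_array = elements_per_array,
    pitch_mm = pitch_mm,
    inter_array_mm = inter_array_mm,
    elevation_fwhm_mm = elevation_fwhm_mm,
    center_frequency_mhz = center_frequency_mhz
  ), class = "probe_geometry")
}

#' Total addressable channel count of a probe
#' @param geometry A [probe_geometry()].
#' @return Integer, `n_arrays * elements_per_array`.
#' @export
n_channels <- function(geometry) {
  stopifnot(inherits(geometry, "probe_geometry"))
  geometry$n_arrays * geometry$elements_per_array
}

#' Volume repetition time of a scanned multi-slice acquisition
#'
#' One volume is completed after the probe has visited every motor position,
#' spending the Doppler integration time at each and a fixed translation dead
#' time between positions: `TR = n_positions * (t_integration + t_translation)`.
#'
#' @param n_positions Number of motor positions per volume.
#' @param t_integration Doppler integration time per position, seconds.
#' @param t_translation Translation dead time per move, seconds.
#' @return Repetition time in seconds.
#' @examples
#' repetition_time(4, 0.4, 0.2)  # 2.4 s
#' @export
repetition_time <- function(n_positions, t_integration, t_translation) {
  if (any(c(n_positions, t_integration, t_translation) <= 0)) {
    stop("all arguments must be positive")
  }
  n_positions * (t_integration + t_translation)
}

#' Compounded frame rate from plane-wave transmission
#'
#' Tilted plane waves fired at the pulse repetition frequency are coherently
#' compounded into one frame per angle sweep, so the frame rate is
#' `prf / n_angles`.
#'
#' @param prf Pulse repetition frequency, Hz.
#' @param n_angles Number of tilted plane-wave angles per compound frame.
#' @return Compound frame rate in Hz.
#' @examples
#' compound_frame_rate(4000, 8)  # 500 Hz
#' @export
compound_frame_rate <- function(prf, n_angles) {
  if (prf <= 0) stop("prf must be positive")
  if (n_angles < 1) stop("n_angles must be >= 1")
  prf / n_angles
}

# Interleaved visiting order: odd-indexed positions ascending, then
# even-indexed ascending. For n = 4 the order is hard-wired to 1-3-4-2
# (the even pair reversed), which caps the cyclic displacement at two steps.
interleaved_order <- function(n_positions) {
  n <- as.integer(n_positions)
  if (n == 1L) return(1L)
  if (n == 4L) return(c(1L, 3L, 4L, 2L))
  c(seq(1L, n, by = 2L), seq(2L, n, by = 2L))
}

#' Build the interleaved motorized scan schedule
#'
#' The probe is stepped through `n_positions` motor positions spaced by
#' `inter_array_mm / n_positions` so that the `n_arrays` slices acquired at
#' each position tile the elevation axis contiguously with no gaps. Positions
#' are visited in an interleaved order (1-3-4-2 for four positions) that
#' limits the maximum move, including the wrap back to position 1, to two
#' steps. Each slice records the within-TR onset time at which its position is
#' visited, used later by slice-timing correction.
#'
#' @param geometry A [probe_geometry()].
#' @param n_positions Motor positions per volume (>= 1).
#' @param t_integration Integration time per position, seconds.
#' @param t_translation Translation dead time, seconds. The motor move is
#'   modeled as a constant dead time regardless of distance.
#' @param origin_mm Elevation (Bregma-relative, anterior positive) of the most
#'   anterior slice, mm. Slice index 1 is the most anterior.
#' @return An object of class `scan_schedule` with fields `n_positions`,
#'   `step_mm`, `order`, `tr`, `slices` (data.frame: slice_index,
#'   elevation_mm, position, array, onset_s) and `slice_onsets`.
#' @examples
#' sched <- build_schedule(probe_geometry(), 4, 0.4, 0.2)
#' sched$tr          # 2.4
#' nrow(sched$slices) # 16
#' @export
build_schedule <- function(geometry, n_positions = 4L, t_integration = 0.4,
                           t_translation = 0.2, origin_mm = 3.0) {
  stopifnot(inherits(geometry, "probe_geometry"))
  n_positions <- as.integer(n_positions)
  if (n_positions < 1L) stop("n_positions must be >= 1")
  step <- geometry$inter_array_mm / n_positions
  order <- interleaved_order(n_positions)
  tr <- repetition_time(n_positions, t_integration, t_translation)
  dwell <- t_integration + t_translation
  # onset of a position = its rank in the visiting order (0-based) * dwell
  onset_of_position <- numeric(n_positions)
  onset_of_position[order] <- (seq_len(n_positions) - 1) * dwell

  # slice (array a, position p) sits at array offset + position offset along
  # elevation; anterior positive, slice 1 most anterior
  slices <- expand.grid(position = seq_len(n_positions),
                        array = seq_len(geometry$n_arrays))
  slices$elevation_mm <- origin_mm -
    (slices$array - 1L) * geometry$inter_array_mm -
    (slices$position - 1L) * step
  slices$onset_s <- onset_of_position[slices$position]
  slices <- slices[order(-slices$elevation_mm), ]
  slices$slice_index <- seq_len(nrow(slices))
  rownames(slices) <- NULL
  slices <- slices[, c("slice_index", "elevation_mm", "position", "array",
                       "onset_s")]
  if (anyDuplicated(round(slices$elevation_mm, 9)) > 0) {
    stop("degenerate geometry: duplicated slice elevations")
  }
  structure(list(
    geometry = geometry,
    n_positions = n_positions,
    step_mm = step,
    order = order,
    t_integration = t_integration,
    t_translation = t_translation,
    tr = tr,
    slices = slices,
    slice_onsets = slices$onset_s
  ), class = "scan_schedule")
}

#' @export
print.scan_schedule <- function(x, ...) {
  cat(sprintf(
    "scan_schedule: %d slices (%d arrays x %d positions), step %.3f mm, TR %.3f s\n",
    nrow(x$slices), x$geometry$n_arrays, x$n_positions, x$step_mm, x$tr))
  cat("order:", paste(x$order, collapse = "-"), "\n")
  invisible(x)
}

#' Maximum cyclic motor displacement of a schedule
#'
#' The largest move, in mm, between consecutively visited positions, including
#' the wrap-around move from the last position of one volume back to the first
#' position of the next.
#'
#' @param schedule A [build_schedule()] result.
#' @return Maximum displacement in mm.
#' @examples
#' max_cyclic_displacement(build_schedule(probe_geometry(), 4, 0.4, 0.2)) # 1.05
#' @export
max_cyclic_displacement <- function(schedule) {
  stopifnot(inherits(schedule, "scan_schedule"))
  ord <- schedule$order
  if (length(ord) < 2L) return(0)
  cyc <- c(ord, ord[1L])
  max(abs(diff(cyc))) * schedule$step_mm
}

#' Export a scan schedule as CSV
#' @param schedule A `scan_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "scan_schedule"))
  utils::write.csv(schedule$slices, path, row.names = FALSE)
  invisible(path)
}
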