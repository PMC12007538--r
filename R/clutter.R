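#' IQ block container
#'
#' A stack of complex baseband frames for one slice over one integration
#' window. The default block is 200 frames at 500 Hz (0.4 s).
#'
#' @param frames Complex 3D array (x, z, t).
#' @param frame_rate Frame rate, Hz.
#' @return Object of class `iq_block`.
#' @export
iq_block <- function(frames, frame_rate = 500) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be a 3D (x, z, t) array")
  if (d[3] < 2L) stop("an IQ block needs at least 2 frames")
  if (!all(is.finite(Re(frames))) || !all(is.finite(Im(frames)))) {
    stop("IQ values must be finite")
  }
  structure(list(frames = frames, frame_rate = frame_rate,
                 n_frames = d[3]), class = "iq_block")
}

#' Casorati (space x time) matrix of an IQ block
#'
#' Rows are voxels in a fixed raster order — voxel (ix, iz) maps to row
#' `(iz - 1) * Nx + ix`, i.e. R's native column-major order of the (x, z)
#' plane — and columns are frames. [uncasorati()] inverts the reshape.
#'
#' @param block An [iq_block()].
#' @return Complex matrix, (Nx * Nz) x Nt.
#' @export
casorati <- function(block) {
  stopifnot(inherits(block, "iq_block"))
  d <- dim(block$frames)
  dim(block$frames) <- c(d[1] * d[2], d[3])
  block$frames
}

#' Reshape a Casorati matrix back to an IQ block
#' @param mat Casorati matrix.
#' @param dims Original (Nx, Nz, Nt) dims.
#' @param frame_rate Frame rate, Hz.
#' @return An [iq_block()].
#' @export
uncasorati <- function(mat, dims, frame_rate = 500) {
  stopifnot(prod(dims[1:2]) == nrow(mat), dims[3] == ncol(mat))
  dim(mat) <- dims
  iq_block(mat, frame_rate)
}

#' SVD of the Casorati matrix of an IQ block
#'
#' Decomposes the space x time matrix as `Mc = U S V*`, with singular values
#' ordered non-increasing; the leading spatiotemporal modes carry the
#' high-energy tissue clutter and the tail carries blood and noise. Computed
#' on the raw (not mean-removed) matrix: a static tissue mean is itself
#' captured by mode 1.
#'
#' @param block An [iq_block()].
#' @return Object of class `svd_decomposition`: `u`, `d` (singular values),
#'   `v`, plus the block dims and frame rate.
#' @export
svd_decompose <- function(block) {
  stopifnot(inherits(block, "iq_block"))
  mc <- casorati(block)
  s <- svd(mc)
  structure(list(u = s$u, d = s$d, v = s$v, dims = dim(block$frames),
                 frame_rate = block$frame_rate),
            class = "svd_decomposition")
}

#' SVD clutter filtering of an IQ block
#'
#' Removes the first `n_cut` spatiotemporal modes (tissue) and returns the
#' remainder `sum_{i > n_cut} U_i lambda_i V_i*` reshaped to the block: the
#' blood signal. `n_cut = 0` returns the input unchanged (to numerical
#' tolerance). The fixed default for motion-free (anesthetized) data is
#' `n_cut = 60` of a 200-frame block; for awake data use [adaptive_ncut()].
#'
#' @param block An [iq_block()].
#' @param n_cut Number of leading modes to discard, `0 <= n_cut < n_frames`.
#' @return Filtered [iq_block()].
#' @export
svd_filter <- function(block, n_cut = 60L) {
  stopifnot(inherits(block, "iq_block"))
  n_cut <- as.integer(n_cut)
  if (n_cut < 0L || n_cut >= block$n_frames) {
    stop("n_cut must satisfy 0 <= n_cut < n_frames")
  }
  if (n_cut == 0L) return(block)
  s <- svd_decompose(block)
  keep <- seq(n_cut + 1L, length(s$d))
  mc <- s$u[, keep, drop = FALSE] %*%
    (s$d[keep] * Conj(t(s$v[, keep, drop = FALSE])))
  uncasorati(mc, s$dims, block$frame_rate)
}

#' Adaptive tissue-mode count from a fixed energy threshold
#'
#' Returns the smallest `n` whose leading modes hold at least
#' `energy_fraction` of the total energy `sum(lambda_i^2)`; at least one mode
#' is always removed. Used as the per-block `n_cut` for awake data with
#' episodic motion, where a fixed cut is not appropriate.
#'
#' @param decomp An [svd_decompose()] result (or anything with a `d` field of
#'   ordered singular values).
#' @param energy_fraction Fraction of total energy assigned to tissue,
#'   in (0, 1). Default 0.95.
#' @return Integer mode count.
#' @export
adaptive_ncut <- function(decomp, energy_fraction = 0.95) {
  if (energy_fraction <= 0 || energy_fraction >= 1) {
    stop("energy_fraction must be in (0, 1)")
  }
  e <- decomp$d^2
  cum <- cumsum(e) / sum(e)
  max(1L, which(cum >= energy_fraction - 1e-12)[1L])
}

#' Power Doppler image of a filtered IQ block
#'
#' Per-voxel mean over time of the squared signal magnitude. Proportional to
#' cerebral blood volume once tissue clutter has been removed.
#'
#' @param block An [iq_block()] (normally the output of [svd_filter()]).
#' @return Non-negative numeric matrix (x by z).
#' @export
power_doppler <- function(block) {
  stopifnot(inherits(block, "iq_block"))
  apply(Mod(block$frames)^2, c(1, 2), mean)
}

#' Total energy of an IQ block
#' @param block An [iq_block()].
#' @return `sum(|signal|^2)`.
#' @export
block_energy <- function(block) sum(Mod(block$frames)^2)
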