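# Independent oracles used across the suite. These deliberately re-derive
# results by brute force, never through the code paths they check.

# Brute-force per-voxel delay-and-sum: loops over voxels and elements with
# its own linear interpolation.
oracle_das <- function(channels, angle_deg, grid, speed_of_sound = 1540,
                       f_number = Inf) {
  c_mm <- speed_of_sound * 1e3
  th <- angle_deg * pi / 180
  img <- matrix(NA_complex_, length(grid$x), length(grid$z))
  for (ix in seq_along(grid$x)) for (iz in seq_along(grid$z)) {
    if (!grid$inside[ix, iz]) next
    x <- grid$x[ix]; z <- grid$z[iz]
    acc <- 0 + 0i
    for (e in seq_along(channels$element_x_mm)) {
      xe <- channels$element_x_mm[e]
      if (is.finite(f_number) && abs(x - xe) > z / (2 * f_number)) next
      tau <- (z * cos(th) + x * sin(th)) / c_mm +
        sqrt(z^2 + (x - xe)^2) / c_mm
      idx <- (tau - channels$t0) * channels$sample_rate + 1
      lo <- floor(idx); fr <- idx - lo
      n <- ncol(channels$samples)
      if (lo >= 1 && lo < n) {
        acc <- acc + channels$samples[e, lo] * (1 - fr) +
          channels$samples[e, lo + 1] * fr
      } else if (lo == n && fr == 0) {
        acc <- acc + channels$samples[e, n]
      }
    }
    img[ix, iz] <- acc
  }
  img
}

# Direct rolling-std calm segmentation (re-deriving the 5% / 60 s rule).
oracle_calm <- function(gs, tr, threshold_ratio = 0.05, min_duration = 60,
                        window = 24) {
  n <- length(gs)
  fit <- stats::lm(gs ~ seq_len(n))
  base <- stats::fitted(fit)
  half <- max(1, floor((window / tr) / 2))
  calm <- logical(n)
  for (i in seq_len(n)) {
    w <- max(1, i - half):min(n, i + half)
    calm[i] <- stats::sd(gs[w]) < threshold_ratio * abs(base[i])
  }
  r <- rle(calm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths * tr >= min_duration
  list(segments = data.frame(start = starts[keep], end = ends[keep] + 1),
       score = sum(r$lengths[keep]) * tr)
}

# Brute-force TFCE by explicit threshold sweep with its own component search
# (breadth-first over a neighbour list).
oracle_tfce <- function(m, E = 0.5, H = 2, dh) {
  d <- dim(m)
  nb_list <- function(mask) {
    idx <- which(mask)
    lab <- integer(length(mask)); nxt <- 0
    for (s in idx) {
      if (lab[s] > 0) next
      nxt <- nxt + 1
      q <- s
      while (length(q)) {
        cur <- q[1]; q <- q[-1]
        if (lab[cur] > 0) next
        lab[cur] <- nxt
        cc <- arrayInd(cur, d)
        for (dim_i in 1:3) for (sgn in c(-1, 1)) {
          nb <- cc; nb[dim_i] <- nb[dim_i] + sgn
          if (nb[dim_i] < 1 || nb[dim_i] > d[dim_i]) next
          li <- nb[1] + (nb[2] - 1) * d[1] + (nb[3] - 1) * d[1] * d[2]
          if (mask[li] && lab[li] == 0) q <- c(q, li)
        }
      }
    }
    lab
  }
  one_tail <- function(mm) {
    out <- array(0, d)
    top <- max(mm, 0)
    if (top <= 0) return(out)
    for (h in seq(dh, top, by = dh)) {
      sup <- mm >= h
      if (!any(sup)) break
      lab <- nb_list(sup)
      sizes <- table(lab[lab > 0])
      for (v in which(sup)) {
        out[v] <- out[v] + as.numeric(sizes[as.character(lab[v])])^E * h^H * dh
      }
    }
    out
  }
  one_tail(m) - one_tail(-m)
}

# Shared small fixtures
fixture_schedule <- function() build_schedule(probe_geometry(), 4, 0.4, 0.2)

fixture_labels <- function() toy_labels(nx = 6, ny = 4, nz = 2, n_pairs = 2)
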