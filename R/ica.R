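#' One fixed-point spatial ICA run
#'
#' PCA-whitens the voxels x time data to `n_components` dimensions, then runs
#' symmetric fixed-point ICA with the log-cosh non-Gaussianity contrast.
#' Spatial orientation: the recovered sources are spatial maps (voxel
#' loadings); mixing happens over time. Deterministic given `seed`.
#'
#' @param data Numeric matrix, voxels x time.
#' @param n_components Number of components (<= min(dim)).
#' @param seed Integer seed for the random unmixing initialization.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the unmixing update.
#' @return Object of class `ica_run`: `maps` (voxels x components, unit
#'   variance), `time_courses` (components x time), `converged`, `seed`,
#'   `n_iter`.
#' @export
run_ica <- function(data, n_components, seed = 1L, max_iter = 500,
                    tol = 1e-7) {
  data <- as.matrix(data)
  nv <- nrow(data); nt <- ncol(data)
  if (n_components > min(nv, nt)) {
    stop("n_components exceeds the data dimensionality")
  }
  # spatial ICA: each time point's image is one observed mixture, with voxels
  # as samples — centre every image over voxels
  x <- sweep(data, 2, colMeans(data))
  # PCA whitening across time: rows of xw are uncorrelated unit-variance
  # linear combinations of time points
  cv <- crossprod(x) / nv                    # time x time
  e <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(n_components)
  wh <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(pmax(e$values[keep], 1e-12)), n_components)
  xw <- x %*% wh                             # voxels x n_components, white
  xw <- t(xw)                                # comps' mixture: k x voxels

  old_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(old_seed))
  set.seed(seed)
  W <- matrix(stats::rnorm(n_components^2), n_components)
  sym_orth <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    wx <- W %*% xw                           # k x voxels: source estimates
    g <- tanh(wx)
    gp <- 1 - g^2
    W1 <- g %*% t(xw) / nv -
      diag(rowMeans(gp), nrow = n_components) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  s_maps <- t(W %*% xw)                      # voxels x k
  # unit-variance maps with a deterministic sign (largest |loading| positive)
  s_maps <- apply(s_maps, 2, function(v) {
    v <- v / stats::sd(v)
    if (v[which.max(abs(v))] < 0) -v else v
  })
  tc <- ls_time_courses(data, s_maps)
  structure(list(maps = s_maps, time_courses = tc, converged = converged,
                 seed = seed, n_iter = it), class = "ica_run")
}

# least-squares time courses for given spatial maps: tc = (S^T S)^-1 S^T X
ls_time_courses <- function(data, maps) {
  solve(crossprod(maps), crossprod(maps, data))
}

#' Icasso-style clustering of repeated ICA runs
#'
#' Pools the components of all converged runs, measures pairwise similarity
#' as the absolute Pearson correlation of spatial maps (sign-flip invariant),
#' clusters them by average-linkage agglomeration into `n_components`
#' clusters, and for each cluster reports the centrotype (the member with the
#' highest total intra-cluster similarity) and the stability index
#' `Iq = mean intra-cluster similarity - mean extra-cluster similarity`.
#'
#' @param runs List of [run_ica()] results.
#' @param n_components Number of clusters (normally the ICA dimensionality).
#' @return List of `stabilized_component` objects, ordered by decreasing Iq:
#'   each has `map` (centrotype spatial map), `iq`, `n_members`, `members`
#'   (run/component indices).
#' @export
icasso_cluster <- function(runs, n_components) {
  conv <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
  if (sum(conv) < 2L) {
    stop(sprintf("need >= 2 converged runs; %d of %d converged",
                 sum(conv), length(runs)))
  }
  runs <- runs[conv]
  maps <- do.call(cbind, lapply(runs, function(r) r$maps))
  origin <- do.call(rbind, lapply(seq_along(runs), function(i) {
    data.frame(run = i, comp = seq_len(ncol(runs[[i]]$maps)))
  }))
  m <- ncol(maps)
  sim <- abs(stats::cor(maps))
  cl <- stats::cutree(stats::hclust(stats::as.dist(1 - sim),
                                    method = "average"), k = n_components)
  comps <- lapply(seq_len(n_components), function(k) {
    idx <- which(cl == k)
    sim_in <- sim[idx, idx, drop = FALSE]
    centro <- idx[which.max(rowSums(sim_in))]
    intra <- if (length(idx) > 1) {
      mean(sim_in[upper.tri(sim_in)])
    } else 1
    extra <- if (length(idx) < m) mean(sim[idx, -idx]) else 0
    structure(list(map = maps[, centro], iq = intra - extra,
                   n_members = length(idx),
                   members = origin[idx, , drop = FALSE]),
              class = "stabilized_component")
  })
  comps[order(-vapply(comps, `[[`, numeric(1), "iq"))]
}

#' Z-scale a spatial map and threshold at |Z| > 3
#'
#' Standardizes the map to zero mean and unit variance over in-brain voxels
#' and masks voxels with `|Z| > z_thresh`. Under a standard-normal map the
#' masked fraction is `2 * pnorm(-3)` (about 0.27%) at the default threshold.
#'
#' @param map Numeric spatial map (vector or array), non-constant.
#' @param z_thresh Threshold on |Z| (default 3).
#' @param mask Optional logical in-brain mask (same shape).
#' @return List: `z` (Z-scored map; NA outside the mask), `mask` (logical,
#'   TRUE where |Z| > threshold), `fraction` (masked fraction of in-brain
#'   voxels).
#' @export
zscale_threshold <- function(map, z_thresh = 3.0, mask = NULL) {
  v <- as.numeric(map)
  inb <- if (is.null(mask)) rep(TRUE, length(v)) else as.logical(mask)
  sdv <- stats::sd(v[inb])
  if (is.na(sdv) || sdv == 0) stop("map is constant; cannot Z-scale")
  z <- (v - mean(v[inb])) / sdv
  z[!inb] <- NA_real_
  sig <- !is.na(z) & abs(z) > z_thresh
  out_z <- map; out_z[] <- z
  out_m <- map; out_m[] <- sig
  list(z = if (is.null(dim(map))) z else array(z, dim(map)),
       mask = if (is.null(dim(map))) sig else array(sig, dim(map)),
       fraction = sum(sig) / sum(inb))
}

#' Stabilized group spatial ICA
#'
#' Convenience wrapper: runs [run_ica()] `n_runs` times with different seeds
#' on temporally concatenated data, clusters the components with
#' [icasso_cluster()], and Z-scales/thresholds each centrotype map.
#'
#' @param data Voxels x time matrix (subjects concatenated in time).
#' @param n_components Dimensionality (candidate values in the field:
#'   15, 25, 35).
#' @param n_runs Number of randomized runs (production default 100;
#'   desk-scale analyses use 20).
#' @param seed Base seed; run i uses `seed + i`.
#' @param z_thresh |Z| threshold for the component masks.
#' @return List: `components` (stabilized components with `z`, `mask` and
#'   `fraction` added), `iq` (named vector of stability indices),
#'   `n_converged`.
#' @export
stabilized_ica <- function(data, n_components = 25, n_runs = 100,
                           seed = 1L, z_thresh = 3.0) {
  runs <- lapply(seq_len(n_runs), function(i) {
    run_ica(data, n_components, seed = seed + i)
  })
  comps <- icasso_cluster(runs, n_components)
  comps <- lapply(comps, function(cmp) {
    zt <- zscale_threshold(cmp$map, z_thresh)
    cmp$z <- zt$z; cmp$mask <- zt$mask; cmp$fraction <- zt$fraction
    cmp
  })
  list(components = comps,
       iq = vapply(comps, `[[`, numeric(1), "iq"),
       n_converged = sum(vapply(runs, `[[`, logical(1), "converged")))
}

#' Region overlap table for a component mask
#'
#' Counts, for each labeled region, how many of its voxels fall inside a
#' component's suprathreshold mask — the evidence a human uses to classify
#' components into networks (classification itself is left to the analyst).
#'
#' @param mask Logical spatial mask (same grid as `labels`).
#' @param labels Integer label array.
#' @param region_table Optional region table with `id`, `acronym`.
#' @return Data frame: id, acronym, n_voxels, n_overlap, fraction.
#' @export
region_overlap <- function(mask, labels, region_table = NULL) {
  ids <- sort(unique(labels[labels > 0]))
  out <- do.call(rbind, lapply(ids, function(id) {
    nv <- sum(labels == id)
    ov <- sum(mask[labels == id])
    data.frame(id = id,
               acronym = if (!is.null(region_table))
                 region_table$acronym[match(id, region_table$id)] else
                   as.character(id),
               n_voxels = nv, n_overlap = ov, fraction = ov / nv)
  }))
  out[order(-out$fraction), ]
}
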