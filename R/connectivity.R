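#' Extract region-averaged time series from a labeled volume
#'
#' Averages the voxel time courses of every labeled region. Regions present
#' in `region_table` (or in the label set) but empty on this grid are
#' reported in `absent`, never zero-filled.
#'
#' @param vol A [pd_volume()].
#' @param labels Integer label array matching the volume's spatial grid
#'   (0 = unlabeled).
#' @param region_table Optional data.frame (id, acronym, hemisphere,
#'   mirror_id) as produced by [toy_labels()].
#' @return Object of class `region_ts`: matrix `series` (region x time, rows
#'   named by region id or acronym), `table`, `absent` (ids with no voxels).
#' @export
extract_regions <- function(vol, labels, region_table = NULL) {
  stopifnot(inherits(vol, "pd_volume"))
  d <- dim(vol$values)
  if (!identical(dim(labels), d[1:3])) {
    stop("label volume is not on the same grid as the data")
  }
  ids <- if (is.null(region_table)) sort(unique(labels[labels > 0])) else
    region_table$id
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  lab_v <- as.integer(labels)
  present <- ids[ids %in% lab_v]
  series <- t(vapply(present, function(id) {
    colMeans(m[lab_v == id, , drop = FALSE])
  }, numeric(d[4])))
  rownames(series) <- if (!is.null(region_table)) {
    region_table$acronym[match(present, region_table$id)]
  } else as.character(present)
  structure(list(series = series, ids = present, table = region_table,
                 absent = setdiff(ids, present), tr = vol$tr),
            class = "region_ts")
}

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation between region time series; exactly
#' symmetric with unit diagonal. Constant series yield NA entries, which are
#' masked rather than imputed.
#'
#' @param ts A [extract_regions()] result or a region x time matrix.
#' @return Object of class `fc_matrix`: `r` (correlations), `defined`
#'   (logical mask of computable entries).
#' @export
fc_matrix <- function(ts) {
  m <- if (inherits(ts, "region_ts")) ts$series else as.matrix(ts)
  if (ncol(m) < 3L) stop("need at least 3 time points")
  if (nrow(m) < 2L) stop("need more than one region")
  sdv <- apply(m, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(m)))
  r <- (r + t(r)) / 2                       # enforce exact symmetry
  diag(r) <- 1
  defined <- outer(sdv > 0, sdv > 0, `&`)
  diag(defined) <- TRUE
  r[!defined] <- NA_real_
  structure(list(r = r, defined = defined), class = "fc_matrix")
}

#' Fisher-averaged group functional connectivity
#'
#' Per entry: Fisher z-transform (`atanh`) of every subject's correlation,
#' arithmetic mean across subjects, back-transform (`tanh`). Off-diagonal
#' entries at exactly +/-1 are clipped to 1 - 1e-7 with a warning before the
#' transform. The diagonal is forced to 1.
#'
#' @param matrices List of [fc_matrix()] objects (or plain correlation
#'   matrices) over the same region set.
#' @return An [fc_matrix()] holding the group-average correlations.
#' @export
group_average_fc <- function(matrices) {
  rs <- lapply(matrices, function(m) if (inherits(m, "fc_matrix")) m$r else m)
  dm <- dim(rs[[1]])
  if (!all(vapply(rs, function(r) identical(dim(r), dm), logical(1)))) {
    stop("matrices must share one region set")
  }
  zs <- lapply(rs, function(r) {
    off <- row(r) != col(r)
    if (any(abs(r[off]) >= 1, na.rm = TRUE)) {
      warning("off-diagonal |r| = 1 clipped before Fisher transform")
      r[off] <- pmin(pmax(r[off], -1 + 1e-7), 1 - 1e-7)
    }
    atanh(r)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  r <- tanh(zbar)
  diag(r) <- 1
  structure(list(r = r, defined = is.finite(r)), class = "fc_matrix")
}

#' FDR-controlled group significance of FC entries
#'
#' One-sample t-test of the Fisher-z correlations across subjects against
#' zero, per unique off-diagonal entry, with Benjamini-Hochberg correction
#' over the upper triangle at level `alpha` (two-tailed).
#'
#' @param matrices List of subject [fc_matrix()] objects or matrices.
#' @param alpha FDR level (default 0.05).
#' @return List: `mask` (symmetric logical, TRUE = significant), `p_raw`,
#'   `p_adj` (symmetric matrices; NA diagonal), `t` (group t values).
#' @export
fc_significance <- function(matrices, alpha = 0.05) {
  rs <- lapply(matrices, function(m) if (inherits(m, "fc_matrix")) m$r else m)
  n <- length(rs)
  if (n < 2L) stop("need at least 2 subjects")
  k <- nrow(rs[[1]])
  ut <- which(upper.tri(diag(k)))
  z <- vapply(rs, function(r) atanh(pmin(pmax(r[ut], -1 + 1e-7), 1 - 1e-7)),
              numeric(length(ut)))
  mu <- rowMeans(z)
  sdv <- sqrt(rowSums((z - mu)^2) / (n - 1))
  tval <- mu / (sdv / sqrt(n))
  tval[!is.finite(tval)] <- 0
  p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  mk <- function(v) {
    m <- matrix(NA_real_, k, k)
    m[ut] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  mask <- mk(as.numeric(padj < alpha)) == 1
  mask[is.na(mask)] <- FALSE
  list(mask = mask, p_raw = mk(p), p_adj = mk(padj), t = mk(tval))
}

#' Seed-based correlation map via the GLM
#'
#' Uses the seed region's average time course as the regressor of a voxelwise
#' GLM ([glm_fit()]) and returns subject-level t/p maps. Group-level seed
#' maps are obtained by passing per-subject t maps to
#' [group_permutation_test()] with `tail = "greater"` (one-tailed).
#'
#' @param vol A [pd_volume()].
#' @param seed_series Seed time course (length = volumes), non-constant.
#' @return Object of class `stat_map`: `t`, `p`, `beta`, `method = "none"`.
#' @export
seed_map <- function(vol, seed_series) {
  stopifnot(inherits(vol, "pd_volume"))
  if (stats::sd(seed_series) == 0) stop("seed series is constant")
  d <- dim(vol$values)
  m <- matrix(vol$values, prod(d[1:3]), d[4])
  fit <- glm_fit(m, matrix(seed_series, ncol = 1))
  structure(list(t = array(fit$t, d[1:3]), p = array(fit$p, d[1:3]),
                 beta = array(fit$beta[, 2], d[1:3]),
                 mask = NULL, method = "none", df = fit$df),
            class = "stat_map")
}

#' Functional-connectivity specificity quality metric
#'
#' Reports the correlation between homotopic somatosensory regions
#' (`r_specific`; expected high when FC is neuronal and bilateral) and
#' between somatosensory and anterior cingulate cortex (`r_unspecific`;
#' expected near zero — both high flags a global, unspecific signal).
#'
#' @param ts A [extract_regions()] result.
#' @param ss_left,ss_right,aca Region names (row names of the series) or ids.
#' @return List `r_specific`, `r_unspecific`.
#' @export
fc_specificity <- function(ts, ss_left, ss_right, aca) {
  stopifnot(inherits(ts, "region_ts"))
  get_row <- function(key) {
    i <- if (is.character(key)) match(key, rownames(ts$series)) else
      match(key, ts$ids)
    if (is.na(i)) stop("region not found: ", key)
    ts$series[i, ]
  }
  sl <- get_row(ss_left); sr <- get_row(ss_right); ac <- get_row(aca)
  list(r_specific = stats::cor(sl, sr),
       r_unspecific = stats::cor((sl + sr) / 2, ac))
}
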