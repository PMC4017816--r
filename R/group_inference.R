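#' Fisher's z transform of a correlation coefficient
#'
#' `z = atanh(r)`, giving an approximately normal variate suitable for
#' cross-subject t-tests on correlations.
#'
#' @param r correlation value(s) with `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z: |r| must be < 1")
  atanh(r)
}

#' Inverse Fisher z transform
#' @param z Fisher-z value(s).
#' @return correlation value(s), `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

#' One-sample t-test
#'
#' @param values numeric vector of per-subject statistics, length >= 2 with
#'   nonzero variance.
#' @param mu0 null mean (default 0).
#' @return list with `t`, `df = n - 1`, `p` (two-sided), `mean`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  if (n < 2L) stop("one_sample_t: need at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("one_sample_t: zero sample variance, t undefined")
  tval <- (mean(values) - mu0) / (s / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1L),
       mean = mean(values))
}

#' Bonferroni per-test threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests, >= 1.
#' @return the per-test p threshold `alpha / m`. Significance against this
#'   threshold is decided with a strict inequality (`p < alpha/m`).
#' @examples
#' bonferroni_threshold(0.05, 60)  # 8.33e-04
#' bonferroni_threshold(0.05, 15)  # 0.00333
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("bonferroni_threshold: alpha must lie in (0, 1)")
  if (!is.finite(m) || m < 1)
    stop("bonferroni_threshold: m must be >= 1")
  alpha / m
}

#' Group correlation table over network pairs
#'
#' For every unordered network pair, computes each subject's Pearson
#' correlation, transforms to Fisher's z, and tests the z values against
#' zero with a cross-subject one-sample t-test. Significance is Bonferroni
#' controlled over the number of pairs.
#'
#' @param cohort_series list (one element per subject) of numeric matrices
#'   or data.frames, volumes in rows and one named column per network.
#' @param alpha family-wise alpha for the Bonferroni threshold
#'   (default 0.05).
#' @return data.frame with one row per pair: `pair`, `n1`, `n2`, `mean_z`,
#'   `t`, `df`, `p_raw`, `p_threshold`, `significant`.
#' @export
correlation_table <- function(cohort_series, alpha = 0.05) {
  if (length(cohort_series) < 3L)
    stop("correlation_table: need at least 3 subjects")
  mats <- lapply(cohort_series, function(s) {
    m <- if (is.data.frame(s)) as.matrix(s) else
      if (is.list(s) && !is.matrix(s)) sapply(s, ts_values) else as.matrix(s)
    m
  })
  labels <- colnames(mats[[1]])
  if (is.null(labels)) labels <- paste0("N", seq_len(ncol(mats[[1]])))
  m <- length(labels)
  pairs <- utils::combn(m, 2)
  thr <- bonferroni_threshold(alpha, ncol(pairs))
  rows <- apply(pairs, 2, function(pr) {
    zs <- vapply(seq_along(mats), function(s) {
      a <- mats[[s]][, pr[1]]; b <- mats[[s]][, pr[2]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("correlation_table: constant series for subject ", s,
             ", pair ", labels[pr[1]], "-", labels[pr[2]])
      fisher_z(stats::cor(a, b))
    }, numeric(1))
    tt <- one_sample_t(zs)
    data.frame(pair = paste0(labels[pr[1]], "x", labels[pr[2]]),
               n1 = labels[pr[1]], n2 = labels[pr[2]],
               mean_z = tt$mean, t = tt$t, df = tt$df, p_raw = tt$p,
               p_threshold = thr, significant = tt$p < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group one-sample t-tests on an effect table
#'
#' Aggregates per-subject network-wise PPI effect tables (rows of
#' [run_networkwise_all()]) into one group row per (pair, target) effect,
#' with a Bonferroni threshold over the number of effects.
#'
#' @param effect_tables list of per-subject data.frames as returned by
#'   [run_networkwise_all()].
#' @param alpha family-wise alpha (default 0.05).
#' @return data.frame with `pair`, `target`, `mean_beta`, `t`, `df`,
#'   `p_raw`, `p_threshold`, `significant`.
#' @export
group_networkwise <- function(effect_tables, alpha = 0.05) {
  if (length(effect_tables) < 3L)
    stop("group_networkwise: need at least 3 subjects")
  key <- paste(effect_tables[[1]]$pair, effect_tables[[1]]$target, sep = "|")
  betas <- sapply(effect_tables, function(tab) {
    k <- paste(tab$pair, tab$target, sep = "|")
    if (!identical(k, key))
      stop("group_networkwise: effect tables are not aligned across subjects")
    tab$beta
  })
  thr <- bonferroni_threshold(alpha, length(key))
  rows <- lapply(seq_along(key), function(i) {
    tt <- one_sample_t(betas[i, ])
    data.frame(pair = effect_tables[[1]]$pair[i],
               target = effect_tables[[1]]$target[i],
               mean_beta = tt$mean, t = tt$t, df = tt$df, p_raw = tt$p,
               p_threshold = thr, significant = tt$p < thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Voxel-wise group t map
#'
#' One-sample t across subjects at every voxel of the supplied beta maps,
#' after multiplying by a +1/-1 contrast.
#'
#' @param beta_maps list of 3-D arrays on identical grids (NA outside each
#'   subject's mask).
#' @param contrast `+1` for positive effects, `-1` for negative.
#' @return list with `t` (3-D array), `df = n - 1`, `n`, `mask` (voxels with
#'   complete data).
#' @export
group_t_map <- function(beta_maps, contrast = 1) {
  if (length(beta_maps) < 3L) stop("group_t_map: need at least 3 subjects")
  if (!contrast %in% c(1, -1)) stop("group_t_map: contrast must be +1 or -1")
  d <- dim(beta_maps[[1]])
  for (b in beta_maps)
    if (!identical(dim(b), d)) stop("group_t_map: grid mismatch across subjects")
  n <- length(beta_maps)
  stack <- vapply(beta_maps, function(b) as.numeric(b) * contrast,
                  numeric(prod(d)))
  mu <- rowMeans(stack)
  sdv <- sqrt(rowSums((stack - mu)^2) / (n - 1))
  tval <- ifelse(is.finite(sdv) & sdv > 0, mu / (sdv / sqrt(n)), 0)
  mask <- array(apply(is.finite(stack), 1, all), dim = d)
  tval[!mask] <- NA_real_
  list(t = array(tval, dim = d), df = n - 1L, n = n, mask = mask)
}

#' Estimate spatial smoothness (FWHM) from standardized residuals
#'
#' The classical residuals-based estimator: within the mask the variance of
#' the spatial partial derivatives of unit-variance standardized residual
#' images gives, per axis, `FWHM_i = sqrt(4 log 2 / lambda_i)` mm, where
#' `lambda_i` is the derivative variance per mm^2. This is the smoothness
#' input that random-field-theory cluster inference requires.
#'
#' @param resid_frames list of 3-D standardized residual arrays (e.g. from
#'   [voxelwise_ppi()]), all on the same grid.
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param mask logical 3-D array; the estimate uses in-mask voxel pairs
#'   only. Must contain at least 27 voxels.
#' @return numeric length-3 FWHM in mm, one per axis.
#' @export
estimate_smoothness <- function(resid_frames, voxel_mm, mask) {
  if (length(resid_frames) < 2L)
    stop("estimate_smoothness: need at least 2 residual maps")
  mask <- array(as.logical(mask), dim = dim(resid_frames[[1]]))
  if (sum(mask) < 27L)
    stop("estimate_smoothness: mask smaller than 27 voxels, estimate unreliable")
  d <- dim(mask)
  num <- c(0, 0, 0); den <- c(0, 0, 0); var_tot <- 0; n_tot <- 0
  shift_pair <- function(a, m, axis) {
    # values at voxel pairs (v, v+1 along axis) with both voxels in mask
    idx1 <- switch(axis,
      list(1:(d[1] - 1), 1:d[2], 1:d[3]),
      list(1:d[1], 1:(d[2] - 1), 1:d[3]),
      list(1:d[1], 1:d[2], 1:(d[3] - 1)))
    idx2 <- switch(axis,
      list(2:d[1], 1:d[2], 1:d[3]),
      list(1:d[1], 2:d[2], 1:d[3]),
      list(1:d[1], 1:d[2], 2:d[3]))
    a1 <- a[idx1[[1]], idx1[[2]], idx1[[3]]]
    a2 <- a[idx2[[1]], idx2[[2]], idx2[[3]]]
    ok <- m[idx1[[1]], idx1[[2]], idx1[[3]]] & m[idx2[[1]], idx2[[2]], idx2[[3]]]
    list(d = (a2 - a1)[ok])
  }
  for (r in resid_frames) {
    v <- r[mask]
    v <- v[is.finite(v)]
    var_tot <- var_tot + sum(v^2); n_tot <- n_tot + length(v)
    for (axis in 1:3) {
      sp <- shift_pair(r, mask, axis)
      dd <- sp$d[is.finite(sp$d)]
      num[axis] <- num[axis] + sum(dd^2)
      den[axis] <- den[axis] + length(dd)
    }
  }
  v0 <- var_tot / n_tot
  if (!is.finite(v0) || v0 <= 0)
    stop("estimate_smoothness: residuals have zero variance, estimate unreliable")
  lambda <- (num / den) / v0 / voxel_mm^2    # derivative variance per mm^2
  if (any(!is.finite(lambda) | lambda <= 0))
    stop("estimate_smoothness: degenerate derivative variance")
  sqrt(4 * log(2) / lambda)
}

# Neighbor offsets for 6 (faces), 18 (faces+edges) or 26 (all) connectivity.
connectivity_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  nrm <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = nrm == 1, "18" = nrm <= 2, "26" = rep(TRUE, nrow(off)),
                 stop("connectivity must be 6, 18 or 26"))
  as.matrix(off[keep, ])
}

#' Label connected components of a binary 3-D volume
#'
#' Breadth-first labeling of the foreground voxels of a 3-D logical array
#' under 6-, 18- or 26-neighbor connectivity (default 18: faces + edges, the
#' convention of the major fMRI packages).
#'
#' @param volume logical (or 0/1) 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer array of the same shape: 0 for background, 1..K for the
#'   K components.
#' @export
label_components <- function(volume, connectivity = 18) {
  d <- dim(volume)
  if (length(d) != 3L) stop("label_components: volume must be 3-D")
  fg <- which(as.logical(volume))
  labels <- array(0L, dim = d)
  if (length(fg) == 0L) return(labels)
  off <- connectivity_offsets(connectivity)
  nb_lin <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  is_fg <- array(FALSE, dim = d); is_fg[fg] <- TRUE
  pos <- integer(prod(d)); pos[fg] <- seq_along(fg)
  visited <- logical(length(fg))
  lab <- 0L
  for (s in seq_along(fg)) {
    if (visited[s]) next
    lab <- lab + 1L
    queue <- fg[s]; visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue
      labels[cur] <- lab
      nxt <- integer(0)
      cur_coord <- arrayInd(cur, d)
      for (o in seq_len(nrow(off))) {
        cc <- cur_coord + matrix(off[o, ], nrow(cur_coord), 3, byrow = TRUE)
        ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] &
              cc[, 2] >= 1 & cc[, 2] <= d[2] &
              cc[, 3] >= 1 & cc[, 3] <= d[3]
        if (!any(ok)) next
        lin <- cc[ok, 1] + (cc[ok, 2] - 1L) * d[1] +
               (cc[ok, 3] - 1L) * d[1] * d[2]
        lin <- lin[is_fg[lin]]
        lin <- lin[!visited[pos[lin]]]
        if (length(lin)) {
          visited[pos[lin]] <- TRUE
          nxt <- c(nxt, lin)
        }
      }
      queue <- unique(nxt)
    }
  }
  labels
}

# Gaussian-RFT expected number of clusters and expected suprathreshold
# volume for a 3-D field; u is the Gaussian height threshold.
rft_expectations <- function(u, resels, n_voxels) {
  ec3 <- resels * (4 * log(2))^1.5 / (2 * pi)^2 * (u^2 - 1) * exp(-u^2 / 2)
  e_m <- max(ec3, 1e-12)                       # expected cluster count
  e_n <- n_voxels * stats::pnorm(u, lower.tail = FALSE)  # voxels above u
  list(e_m = e_m, e_n = e_n)
}

#' Cluster-level inference on a t map
#'
#' Height-thresholds a group t map at the `height_p` quantile of the t
#' distribution (one-sided, per contrast), labels the supra-threshold
#' connected components, and assigns each cluster an uncorrected
#' cluster-level p value from the Gaussian random-field approximation to the
#' cluster-extent distribution, `P(extent >= k) = exp(-beta k^(2/3))` with
#' `beta` set by the expected cluster size implied by the field's resel
#' count. Benjamini--Hochberg FDR is then applied across the clusters of
#' the map.
#'
#' The t field is mapped to a Gaussian field through the height threshold
#' (`u = qnorm(1 - height_p)`); exactness is not claimed for low df or
#' near-voxel smoothness, and the null behaviour is bounded by simulation in
#' the package tests.
#'
#' @param tmap 3-D t array (NA allowed outside the mask).
#' @param df degrees of freedom of the t map.
#' @param height_p voxel height threshold as an upper-tail p (default 0.001,
#'   must lie in (0, 0.05]).
#' @param fwhm_mm numeric length-3 smoothness estimate in mm
#'   (see [estimate_smoothness()]).
#' @param mask logical 3-D array of analyzed voxels.
#' @param voxel_mm numeric length-3 voxel size in mm.
#' @param q FDR level across clusters (default 0.0033).
#' @param connectivity cluster connectivity, 6/18/26 (default 18).
#' @return data.frame with one row per cluster: `label` (its id in the
#'   attached label array), `extent`, `peak_i/j/k`
#'   (0-based voxel indices), `peak_t`, `p_cluster`, `q_fdr`,
#'   `significant`; empty when nothing survives the height threshold.
#'   The label array is attached as attribute `"labels"`.
#' @export
cluster_inference <- function(tmap, df, height_p = 0.001, fwhm_mm, mask,
                              voxel_mm = c(3, 3, 3), q = 0.0033,
                              connectivity = 18) {
  if (height_p <= 0 || height_p > 0.05)
    stop("cluster_inference: height_p must lie in (0, 0.05]")
  mask <- array(as.logical(mask), dim = dim(tmap))
  t_thr <- stats::qt(height_p, df, lower.tail = FALSE)
  supra <- !is.na(tmap) & mask & tmap > t_thr
  empty <- data.frame(label = integer(0), extent = integer(0),
                      peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0),
                      peak_t = numeric(0), p_cluster = numeric(0),
                      q_fdr = numeric(0), significant = logical(0))
  labels <- label_components(supra, connectivity)
  k_max <- max(labels)
  if (k_max == 0L) { attr(empty, "labels") <- labels; return(empty) }

  u <- stats::qnorm(height_p, lower.tail = FALSE)
  n_voxels <- sum(mask)
  resels <- n_voxels * prod(voxel_mm) / prod(fwhm_mm)
  ex <- rft_expectations(u, resels, n_voxels)
  n_bar <- max(ex$e_n / ex$e_m, .Machine$double.eps)  # expected extent, voxels
  beta <- (gamma(5 / 2) / n_bar)^(2 / 3)

  rows <- lapply(seq_len(k_max), function(lb) {
    vox <- which(labels == lb)
    extent <- length(vox)
    pk <- vox[which.max(tmap[vox])]
    pc <- arrayInd(pk, dim(tmap))
    data.frame(label = lb, extent = extent,
               peak_i = pc[1] - 1L, peak_j = pc[2] - 1L, peak_k = pc[3] - 1L,
               peak_t = tmap[pk],
               p_cluster = min(exp(-beta * extent^(2 / 3)), 1))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_cluster), , drop = FALSE]
  out$q_fdr <- stats::p.adjust(out$p_cluster, method = "BH")
  out$significant <- out$q_fdr < q
  rownames(out) <- NULL
  attr(out, "labels") <- labels
  out
}
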