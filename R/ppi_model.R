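#' Build a physiophysiological interaction regressor
#'
#' The interaction between two BOLD network series is formed at the neural
#' level, following the deconvolve--detrend--multiply--reconvolve recipe:
#' both series are deconvolved to the neural level, linearly detrended,
#' multiplied element-wise, and the product is convolved back with the HRF.
#' Computing the product at the neural rather than hemodynamic level avoids
#' the spurious interaction terms that the nonlinearity of hemodynamic
#' convolution would otherwise introduce.
#'
#' @param s1,s2 cleaned `netppi_ts` (level `"bold"`) of equal length and tr.
#' @param k a `netppi_hrf` at the series' tr.
#' @param reg deconvolution ridge penalty, `NULL` for GCV
#'   (see [deconvolve_neural()]).
#' @param center subtract the mean of the reconvolved regressor (default
#'   TRUE, so the interaction column is orthogonal to the constant).
#' @return a `netppi_ts` (level `"bold"`) of the same length as the inputs.
#' @export
build_ppi_regressor <- function(s1, s2, k, reg = NULL, center = TRUE) {
  assert_level(s1, "bold", "build_ppi_regressor")
  assert_level(s2, "bold", "build_ppi_regressor")
  if (length(s1$values) != length(s2$values) || abs(s1$tr - s2$tr) > 1e-9)
    stop("build_ppi_regressor: s1 and s2 must share length and tr")
  n1 <- detrend_linear(deconvolve_neural(s1, k, reg))
  n2 <- detrend_linear(deconvolve_neural(s2, k, reg))
  prod_ts <- time_series(n1$values * n2$values, s1$tr, level = "neural",
                         label = paste0(s1$label, ":", s2$label))
  out <- convolve_bold(prod_ts, k)
  if (center) out <- ts_with_values(out, out$values - mean(out$values))
  out
}

#' Ordinary-least-squares fit of a linear model
#'
#' Plain OLS with the usual classical-statistics output: coefficient
#' estimates, standard errors, t statistics, residual degrees of freedom
#' `n - rank`, residual variance, and two-sided p values.
#'
#' @param design numeric matrix, one column per regressor (include your own
#'   constant). Column names are used to label coefficients.
#' @param y a `netppi_ts` or numeric vector of responses.
#' @return an object of class `netppi_glm` with fields `beta`, `se`, `t`,
#'   `p`, `df`, `sigma2`, `residuals`, `labels`.
#' @export
fit_glm <- function(design, y) {
  X <- as.matrix(design)
  v <- ts_values(y)
  if (nrow(X) != length(v))
    stop("fit_glm: design rows (", nrow(X), ") do not match response length (",
         length(v), ")")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("fit_glm: design is rank deficient; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, v)
  res <- qr.resid(qx, v)
  df <- length(v) - qx$rank
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  names(se) <- colnames(X)
  tval <- ifelse(se > 0, beta / se, 0)
  names(tval) <- colnames(X)
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(beta = beta, se = se, t = tval, p = pval, df = df,
                 sigma2 = sigma2, residuals = res, labels = colnames(X)),
            class = "netppi_glm")
}

#' @export
print.netppi_glm <- function(x, ...) {
  cat(sprintf("<netppi_glm: %d coefficients, df = %d>\n",
              length(x$beta), x$df))
  print(data.frame(beta = x$beta, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

#' Network-wise PPI model for one network triple
#'
#' Fits the interaction model
#' \deqn{y = \beta_0 + \beta_{N1} x_{N1} + \beta_{N2} x_{N2} +
#'       \beta_{PPI}\, x_{PPI} + \varepsilon}
#' where `y` is the target network's cleaned series, `x_N1`, `x_N2` are the
#' two source networks' cleaned series and `x_PPI` is the neural-level
#' interaction regressor from [build_ppi_regressor()]. A positive
#' `beta_PPI` means the coupling between the target and one source grows
#' with the activity of the other source. All inputs are assumed already
#' cleaned; the network-wise design carries no further nuisance columns.
#'
#' @param target `netppi_ts`, the dependent network series; must differ from
#'   both sources.
#' @param s1,s2 source network series.
#' @param k HRF kernel at the common tr.
#' @param reg deconvolution penalty (NULL = GCV).
#' @param scale scale `target`, `s1`, `s2` to unit variance first (default
#'   TRUE) so betas are comparable across network pairs.
#' @param center mean-center the non-constant design columns (default TRUE).
#' @return a `netppi_glm`; the coefficient of interest is labelled `"ppi"`.
#' @export
networkwise_ppi <- function(target, s1, s2, k, reg = NULL, scale = TRUE,
                            center = TRUE) {
  assert_level(target, "bold", "networkwise_ppi")
  if (isTRUE(all.equal(target$values, s1$values)) ||
      isTRUE(all.equal(target$values, s2$values)))
    stop("networkwise_ppi: target series is identical to a predictor")
  if (scale) {
    target <- scale_unit_variance(target)
    s1 <- scale_unit_variance(s1)
    s2 <- scale_unit_variance(s2)
  }
  ppi <- build_ppi_regressor(s1, s2, k, reg, center = center)
  cols <- cbind(constant = 1, n1 = s1$values, n2 = s2$values,
                ppi = ppi$values)
  if (center) cols[, -1] <- sweep(cols[, -1], 2, colMeans(cols[, -1]))
  colnames(cols) <- c("constant", "n1", "n2", "ppi")
  fit_glm(cols, target)
}

#' All network-wise PPI effects for one subject
#'
#' Enumerates every unordered pair of networks and, for each pair, fits the
#' network-wise PPI model with each non-member network as the target. With
#' six networks this yields 15 pairs and 15 x 4 = 60 effect rows.
#'
#' @param networks named list of cleaned `netppi_ts`, one per network;
#'   names (or series labels) must be distinct.
#' @param k HRF kernel.
#' @param reg deconvolution penalty (NULL = GCV).
#' @param scale,center passed to [networkwise_ppi()].
#' @return data.frame with columns `pair`, `n1`, `n2`, `target`, `beta`,
#'   `t`, `p`.
#' @export
run_networkwise_all <- function(networks, k, reg = NULL, scale = TRUE,
                                center = TRUE) {
  labels <- names(networks)
  if (is.null(labels))
    labels <- vapply(networks, function(s) s$label, character(1))
  if (anyDuplicated(labels))
    stop("run_networkwise_all: duplicate network labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- length(networks)
  if (m < 3L) stop("run_networkwise_all: need at least 3 networks")
  if (scale) networks <- lapply(networks, scale_unit_variance)
  # deconvolve each network once; each pair's regressor serves all targets
  neural <- lapply(networks, function(s)
    detrend_linear(deconvolve_neural(s, k, reg)))
  rows <- list()
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    prod_ts <- time_series(neural[[i]]$values * neural[[j]]$values,
                           networks[[i]]$tr, "neural")
    ppi <- convolve_bold(prod_ts, k)$values
    x1 <- networks[[i]]$values; x2 <- networks[[j]]$values
    cols <- cbind(constant = 1, n1 = x1, n2 = x2, ppi = ppi)
    if (center) cols[, -1] <- sweep(cols[, -1], 2, colMeans(cols[, -1]))
    colnames(cols) <- c("constant", "n1", "n2", "ppi")
    for (t_idx in setdiff(seq_len(m), c(i, j))) {
      fit <- fit_glm(cols, networks[[t_idx]])
      rows[[length(rows) + 1L]] <- data.frame(
        pair = paste0(labels[i], "x", labels[j]),
        n1 = labels[i], n2 = labels[j], target = labels[t_idx],
        beta = unname(fit$beta["ppi"]), t = unname(fit$t["ppi"]),
        p = unname(fit$p["ppi"]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Voxel-wise PPI model for one network pair
#'
#' Fits, at every in-mask voxel, an OLS model with eleven columns: constant,
#' the two network main effects, the PPI interaction regressor, the WM and
#' CSF compartment signals, and the six motion parameters. An implicit
#' high-pass filter is applied by residualizing both the data and every
#' non-constant design column against the same low-frequency DCT set
#' (cutoff `1/highpass_s` Hz).
#'
#' @param bold4d 4-D numeric array (x, y, z, time).
#' @param s1,s2 cleaned network series (level `"bold"`).
#' @param k HRF kernel.
#' @param nuisance a `netppi_nuisance` with motion + wm_pc1 + csf_pc1.
#' @param mask logical 3-D array; `NULL` derives one as voxels whose mean
#'   signal exceeds `mask_rel_threshold` times the global mean signal.
#' @param highpass_s high-pass period in seconds (default 100).
#' @param reg deconvolution penalty (NULL = GCV).
#' @param mask_rel_threshold relative mean-signal threshold for the default
#'   mask (default 0.2).
#' @param n_resid_frames number of standardized residual frames returned for
#'   smoothness estimation (evenly spaced over the scan; default 32).
#' @return list with `beta_ppi` (3-D array, NA outside the mask), `t_ppi`,
#'   `mask`, `df`, and `resid_frames` (list of 3-D standardized residual
#'   arrays).
#' @export
voxelwise_ppi <- function(bold4d, s1, s2, k, nuisance, mask = NULL,
                          highpass_s = 100, reg = NULL,
                          mask_rel_threshold = 0.2, n_resid_frames = 32L) {
  dims <- dim(bold4d)
  if (length(dims) != 4L) stop("voxelwise_ppi: bold4d must be 4-D")
  nt <- dims[4]
  if (nt != length(s1$values))
    stop("voxelwise_ppi: time dimension (", nt,
         ") does not match network series length (", length(s1$values), ")")
  vox <- prod(dims[1:3])
  Y <- matrix(bold4d, nrow = vox, ncol = nt)
  if (is.null(mask)) {
    mv <- rowMeans(Y)
    mask <- array(mv > mask_rel_threshold * mean(mv), dim = dims[1:3])
  } else {
    if (!identical(dim(mask), as.integer(dims[1:3])) &&
        !identical(dim(mask), dims[1:3]))
      stop("voxelwise_ppi: mask grid does not match the BOLD grid")
    mask <- array(as.logical(mask), dim = dims[1:3])
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("voxelwise_ppi: empty analysis mask")
  Y <- Y[idx, , drop = FALSE]

  ppi <- build_ppi_regressor(s1, s2, k, reg)
  X <- cbind(n1 = s1$values, n2 = s2$values, ppi = ppi$values,
             nuisance$matrix)
  # shared implicit high-pass: residualize data and design on one DCT set
  tr <- s1$tr
  n_low <- sum((seq_len(nt) - 1L) / (2 * nt * tr) < 1 / highpass_s)
  B <- dct_basis(nt, n_low)
  X <- X - B %*% crossprod(B, X)
  Y <- Y - tcrossprod(Y %*% B, B)
  X <- cbind(constant = 1, X)

  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("voxelwise_ppi: design is rank deficient; dependent columns: ",
         paste(bad, collapse = ", "))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  Bhat <- XtXinv %*% crossprod(X, t(Y))        # p x nvox
  E <- t(Y) - X %*% Bhat                        # nt x nvox residuals
  df <- nt - qx$rank
  sigma2 <- colSums(E^2) / df
  ppi_col <- which(colnames(X) == "ppi")
  beta <- Bhat[ppi_col, ]
  se <- sqrt(XtXinv[ppi_col, ppi_col] * sigma2)
  tval <- ifelse(se > 0, beta / se, 0)

  to_map <- function(v) {
    a <- array(NA_real_, dim = dims[1:3]); a[idx] <- v; a
  }
  sd_e <- sqrt(pmax(sigma2, .Machine$double.eps))
  frames <- unique(round(seq(1, nt, length.out = min(n_resid_frames, nt))))
  resid_frames <- lapply(frames, function(f) {
    a <- array(NA_real_, dim = dims[1:3]); a[idx] <- E[f, ] / sd_e; a
  })
  list(beta_ppi = to_map(beta), t_ppi = to_map(tval), mask = mask, df = df,
       resid_frames = resid_frames)
}
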