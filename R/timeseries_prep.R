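#' First-principal-component time series of a voxel matrix
#'
#' Extracts the dominant temporal mode of a compartment (e.g. white matter or
#' CSF) voxel-by-time matrix: each voxel's series is mean-centered, the first
#' right singular vector is taken as the component time series and scaled to
#' unit variance. The sign is fixed so that the voxel loading with the
#' largest magnitude is positive.
#'
#' @param voxel_matrix numeric matrix, voxels in rows, volumes in columns
#'   (>= 2 voxels, >= 3 volumes).
#' @param tr sampling interval in seconds for the returned series.
#' @param label label for the returned series.
#' @return a `netppi_ts` (level `"bold"`) of length `ncol(voxel_matrix)`.
#' @export
extract_first_pc <- function(voxel_matrix, tr = 1, label = "pc1") {
  m <- as.matrix(voxel_matrix)
  if (nrow(m) < 2L || ncol(m) < 3L)
    stop("extract_first_pc: need >= 2 voxels and >= 3 volumes")
  m <- m - rowMeans(m)
  if (all(abs(m) < 1e-12))
    stop("extract_first_pc: degenerate input, zero variance in every voxel")
  sv <- svd(m, nu = 1, nv = 1)
  score <- sv$v[, 1]
  loading <- sv$u[, 1]
  if (loading[which.max(abs(loading))] < 0) score <- -score
  time_series(score / stats::sd(score), tr, level = "bold", label = label)
}

#' Binary compartment mask from a tissue-probability map
#'
#' Voxels strictly above the threshold are retained. The default threshold
#' of 0.99 is deliberately severe so that partial-volume gray-matter voxels
#' are excluded from white-matter and CSF compartments.
#'
#' @param prob_map numeric array with values in `[0, 1]`.
#' @param threshold probability threshold in `[0, 1)`; strict comparison.
#' @return a logical array of the same shape.
#' @export
build_compartment_mask <- function(prob_map, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("build_compartment_mask: threshold must lie in [0, 1)")
  p <- as.array(prob_map)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("build_compartment_mask: probability map has values outside [0, 1]")
  p > threshold
}

#' Assemble a nuisance regressor set
#'
#' @param motion numeric matrix with 6 columns (3 translations in mm, 3
#'   rotations in radians), one row per volume.
#' @param wm_pc1,csf_pc1 `netppi_ts` (or numeric vectors) holding the first
#'   principal component of the white-matter and CSF compartments; rescaled
#'   to unit variance here if they are not already.
#' @return an object of class `netppi_nuisance` with a combined matrix.
#' @export
nuisance_set <- function(motion, wm_pc1 = NULL, csf_pc1 = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("nuisance_set: motion must have 6 columns, got ", ncol(motion))
  n <- nrow(motion)
  cols <- motion
  colnames(cols) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
  add1 <- function(cols, s, nm) {
    v <- ts_values(s)
    if (length(v) != n)
      stop("nuisance_set: ", nm, " length (", length(v),
           ") does not match motion rows (", n, ")")
    sdv <- stats::sd(v)
    if (sdv > 0) v <- v / sdv
    cbind(cols, structure(matrix(v, ncol = 1), dimnames = list(NULL, nm)))
  }
  if (!is.null(wm_pc1)) cols <- add1(cols, wm_pc1, "wm_pc1")
  if (!is.null(csf_pc1)) cols <- add1(cols, csf_pc1, "csf_pc1")
  structure(list(matrix = cols, n = n), class = "netppi_nuisance")
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary-least-squares residualization of `y` against the nuisance
#' columns plus an always-included constant (residualizing without an
#' intercept would bias the mean). The residual is orthogonal to every
#' nuisance column.
#'
#' @param y a `netppi_ts` or numeric vector.
#' @param nuisance a `netppi_nuisance` (see [nuisance_set()]) or a plain
#'   numeric matrix of regressors (constant added internally).
#' @return residual series, same type as `y`.
#' @export
regress_out <- function(y, nuisance) {
  v <- ts_values(y)
  nm <- if (inherits(nuisance, "netppi_nuisance")) nuisance$matrix
        else as.matrix(nuisance)
  if (nrow(nm) != length(v))
    stop("regress_out: series length (", length(v),
         ") does not match nuisance rows (", nrow(nm), ")")
  X <- cbind(constant = 1, nm)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("regress_out: nuisance matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- qr.resid(qx, v)
  if (is_time_series(y)) ts_with_values(y, res) else res
}

#' Discrete-cosine high-pass filter
#'
#' Removes the projection of the series onto the discrete-cosine components
#' with frequency below `cutoff_hz`, plus the constant. This is the standard
#' fMRI drift filter; with the default 0.01 Hz cutoff (100 s period) it
#' suppresses slow scanner drift while leaving resting-state fluctuations
#' above the cutoff essentially untouched.
#'
#' @param y a `netppi_ts` or numeric vector.
#' @param cutoff_hz cutoff frequency in Hz; must be below Nyquist
#'   `1/(2 tr)`.
#' @param tr sampling interval in seconds (taken from `y` when it is a
#'   `netppi_ts`).
#' @return filtered series, same type as `y`.
#' @export
dct_highpass <- function(y, cutoff_hz = 0.01, tr = NULL) {
  v <- ts_values(y)
  if (is_time_series(y)) tr <- y$tr
  if (is.null(tr)) stop("dct_highpass: tr required for a bare numeric vector")
  nyq <- 1 / (2 * tr)
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("dct_highpass: cutoff_hz must lie in (0, Nyquist = ", nyq, ")")
  n <- length(v)
  # column j (0-based) of the DCT basis has frequency j / (2 n tr)
  n_low <- sum((seq_len(n) - 1L) / (2 * n * tr) < cutoff_hz)
  B <- dct_basis(n, n_low)
  res <- v - B %*% crossprod(B, v)
  res <- drop(res)
  if (is_time_series(y)) ts_with_values(y, res) else res
}

#' Remove mean and linear trend
#'
#' Least-squares removal of an intercept and linear slope; the result has
#' zero mean and zero fitted slope and the operation is idempotent.
#'
#' @param y a `netppi_ts` or numeric vector of length >= 3.
#' @return detrended series, same type as `y`.
#' @export
detrend_linear <- function(y) {
  v <- ts_values(y)
  if (length(v) < 3L) stop("detrend_linear: need at least 3 samples")
  t <- seq_along(v)
  res <- stats::lm.fit(cbind(1, t), v)$residuals
  if (is_time_series(y)) ts_with_values(y, res) else res
}

#' Drop initial volumes from a series or matrix
#'
#' fMRI acquisitions discard the first few volumes so that longitudinal
#' magnetization reaches steady state; the emulated acquisition discards 2
#' of 230 volumes, retaining 228.
#'
#' @param x a `netppi_ts`, numeric vector, matrix (volumes in rows) or 4-D
#'   array (volumes along the 4th dimension).
#' @param n_discard number of initial volumes to drop (default 2).
#' @return `x` with the first `n_discard` volumes removed.
#' @export
discard_initial_volumes <- function(x, n_discard = 2L) {
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L) stop("discard_initial_volumes: n_discard must be >= 0")
  if (n_discard == 0L) return(x)
  if (is_time_series(x)) {
    return(ts_with_values(x, x$values[-seq_len(n_discard)]))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    nt <- dim(x)[4]
    if (n_discard >= nt) stop("discard_initial_volumes: nothing left")
    return(x[, , , seq.int(n_discard + 1L, nt), drop = FALSE])
  }
  if (is.matrix(x)) return(x[-seq_len(n_discard), , drop = FALSE])
  x[-seq_len(n_discard)]
}

#' Clean a set of network time series
#'
#' Applies the fixed cleaning order used throughout the pipeline: nuisance
#' regression (6 motion parameters + WM and CSF first principal components +
#' constant) followed by discrete-cosine high-pass filtering.
#'
#' @param series a list of `netppi_ts` (level `"bold"`).
#' @param nuisance a `netppi_nuisance`.
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01).
#' @return list of cleaned `netppi_ts` with the input names.
#' @export
clean_network_series <- function(series, nuisance, cutoff_hz = 0.01) {
  lapply(series, function(s) dct_highpass(regress_out(s, nuisance), cutoff_hz))
}
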