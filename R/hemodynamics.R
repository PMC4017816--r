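#' Canonical double-gamma hemodynamic response function
#'
#' Builds the canonical HRF as the difference of two gamma densities: a
#' positive response peaking around 5 s minus a delayed undershoot, scaled so
#' the peak amplitude is 1. The parameterization (response delay 6 s,
#' undershoot delay 16 s, unit dispersions, undershoot ratio 1/6, 32 s
#' support) is the de-facto standard of the major fMRI analysis packages.
#' Delay d and dispersion s map to a gamma density with shape d/s and scale
#' s, so the density vanishes at lag 0 whenever d > s.
#'
#' @param dt sampling interval of the kernel in seconds (use the TR for
#'   design-matrix work), 0 < dt <= duration.
#' @param duration kernel support in seconds; the kernel has
#'   `floor(duration/dt) + 1` samples covering lags 0..duration.
#' @param params named list overriding any of `response_delay_s`,
#'   `undershoot_delay_s`, `response_dispersion_s`,
#'   `undershoot_dispersion_s`, `undershoot_ratio`.
#' @return an object of class `netppi_hrf` with fields `dt`, `samples`
#'   (amplitudes from lag 0), `duration`, `params`.
#' @examples
#' k <- canonical_hrf(dt = 2, duration = 32)
#' length(k$samples)  # 17
#' @export
canonical_hrf <- function(dt, duration = 32, params = list()) {
  if (!is.finite(dt) || dt <= 0) stop("canonical_hrf: dt must be > 0")
  if (!is.finite(duration) || duration <= 0)
    stop("canonical_hrf: duration must be > 0")
  if (dt > duration) stop("canonical_hrf: dt must not exceed duration")
  p <- list(response_delay_s = 6, undershoot_delay_s = 16,
            response_dispersion_s = 1, undershoot_dispersion_s = 1,
            undershoot_ratio = 1 / 6)
  p[names(params)] <- params
  lag <- seq(0, by = dt, length.out = floor(duration / dt) + 1L)
  h <- stats::dgamma(lag, shape = p$response_delay_s / p$response_dispersion_s,
                     scale = p$response_dispersion_s) -
    p$undershoot_ratio *
      stats::dgamma(lag, shape = p$undershoot_delay_s / p$undershoot_dispersion_s,
                    scale = p$undershoot_dispersion_s)
  h <- h / max(h)
  structure(list(dt = dt, samples = h, duration = duration, params = p),
            class = "netppi_hrf")
}

#' @export
print.netppi_hrf <- function(x, ...) {
  cat(sprintf("<netppi_hrf: dt = %gs, %d samples over %gs, peak at %gs>\n",
              x$dt, length(x$samples), x$duration,
              (which.max(x$samples) - 1L) * x$dt))
  invisible(x)
}

#' Export an HRF kernel as a two-column TSV (lag_s, amplitude)
#' @param k a `netppi_hrf`.
#' @param path output file path.
#' @export
write_hrf_tsv <- function(k, path) {
  stopifnot(inherits(k, "netppi_hrf"))
  d <- data.frame(lag_s = seq(0, by = k$dt, length.out = length(k$samples)),
                  amplitude = k$samples)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Causal discrete convolution of x with kernel k, truncated to length(x).
# Zero-padded history: sample t of the output depends on x[1..t] only.
causal_convolve <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
  # convolve() works through FFTs; clip tiny imaginary-roundoff residue
  out[abs(out) < 1e-300] <- 0
  out
}

#' Convolve a neural-level series with an HRF kernel
#'
#' Causal, zero-padded discrete convolution truncated to the input length
#' (the standard fMRI design-matrix convention). The output is a BOLD-level
#' series on the same sampling grid.
#'
#' @param x a `netppi_ts` with level `"neural"`; `x$tr` must equal `k$dt`.
#' @param k a `netppi_hrf`.
#' @return a `netppi_ts` with level `"bold"`.
#' @export
convolve_bold <- function(x, k) {
  assert_level(x, "neural", "convolve_bold")
  stopifnot(inherits(k, "netppi_hrf"))
  if (abs(x$tr - k$dt) > 1e-9 * max(x$tr, k$dt))
    stop("convolve_bold: series tr (", x$tr, ") does not match kernel dt (",
         k$dt, "); resample the kernel with canonical_hrf(dt = tr)")
  ts_with_values(x, causal_convolve(x$values, k$samples), level = "bold")
}

# ---- deconvolution -------------------------------------------------------

# Orthonormal DCT-II basis, n samples, first n_col columns (column 1 is the
# constant). Column j (0-based) has frequency j / (2 * n * tr) Hz.
dct_basis <- function(n, n_col = n) {
  t <- seq_len(n) - 1L
  j <- seq_len(n_col) - 1L
  B <- cos(outer(2 * t + 1, j) * (pi / (2 * n)))
  B[, 1] <- B[, 1] / sqrt(2)
  B * sqrt(2 / n)
}

# The deconvolution operator (convolution matrix x DCT basis, SVD'ed) depends
# only on (kernel, n); cache it so repeated per-subject deconvolutions with a
# shared kernel cost O(n^2) instead of a fresh SVD each time.
.netppi_cache <- new.env(parent = emptyenv())

deconv_operator <- function(k, n, prior_corner_hz = 0.05) {
  key <- paste("deconv", n, format(k$dt, digits = 12),
               length(k$samples),
               format(sum(k$samples) + sum(k$samples^2), digits = 12),
               format(prior_corner_hz, digits = 12),
               sep = "_")
  op <- .netppi_cache[[key]]
  if (!is.null(op)) return(op)
  kern <- k$samples
  m <- min(length(kern), n)
  # lower-triangular Toeplitz convolution matrix
  K <- matrix(0, n, n)
  for (lag in seq_len(m)) {
    idx <- seq_len(n - lag + 1L)
    K[cbind(idx + lag - 1L, idx)] <- kern[lag]
  }
  X <- dct_basis(n)
  # frequency-weighted ridge: basis column j carries penalty weight
  # 1 + (f_j / f0)^4 (a curvature-type smoothness prior), so the shrinkage
  # bears on frequencies above the resting-state fluctuation band
  freq <- (seq_len(n) - 1L) / (2 * n * k$dt)
  w <- 1 + (freq / prior_corner_hz)^4
  scale_w <- 1 / sqrt(w)
  A <- sweep(K %*% X, 2, scale_w, `*`)
  sv <- svd(A)
  op <- list(X = X, u = sv$u, d = sv$d, v = sv$v, n = n, scale_w = scale_w)
  .netppi_cache[[key]] <- op
  op
}

# Generalized cross-validation for the ridge parameter on the SVD path.
gcv_lambda <- function(d, uty, y2, n, grid = 10^seq(-8, 6, length.out = 57)) {
  r0 <- max(y2 - sum(uty^2), 0)  # energy outside the column space
  scores <- vapply(grid, function(lam) {
    shrink <- lam / (d^2 + lam)
    rss <- sum((shrink * uty)^2) + r0
    df <- sum(d^2 / (d^2 + lam))
    n * rss / (n - df)^2
  }, numeric(1))
  grid[which.min(scores)]
}

#' Deconvolve a BOLD series to the neural level
#'
#' Estimates the neural-level signal whose HRF convolution best reproduces
#' the observed BOLD series. The neural signal is expanded in an orthonormal
#' discrete-cosine basis spanning frequencies up to Nyquist and its basis
#' coefficients are obtained by ridge-penalized least squares against the
#' convolution operator; the ridge prior on the coefficients plays the role
#' of the shrinkage prior in empirical-Bayes deconvolution schemes. The
#' penalty on basis column `j` is weighted by `1 + (f_j/f0)^4` (a
#' curvature-type smoothness prior with corner frequency
#' `prior_corner_hz`), so shrinkage bears on frequencies above the
#' resting-state fluctuation band and the weakly determined final samples
#' are extrapolated smoothly rather than fit with high-frequency
#' components. By default the overall ridge strength is chosen by
#' generalized cross-validation over a log-spaced grid; pass `reg` for a
#' fixed penalty (`reg = 0` gives the truncated-SVD pseudoinverse).
#'
#' Deconvolution runs at the series' own sampling interval (no microtime
#' upsampling), which is adequate at resting-state TRs of ~2 s.
#'
#' @param y a `netppi_ts` with level `"bold"`.
#' @param k a `netppi_hrf` with `dt` equal to `y$tr`.
#' @param reg ridge penalty on the DCT coefficients; `NULL` (default) selects
#'   it by GCV; must be >= 0 when given.
#' @param prior_corner_hz corner frequency of the smoothness prior in Hz
#'   (default 0.05).
#' @return a `netppi_ts` with level `"neural"`, same length as `y`.
#' @export
deconvolve_neural <- function(y, k, reg = NULL, prior_corner_hz = 0.05) {
  assert_level(y, "bold", "deconvolve_neural")
  stopifnot(inherits(k, "netppi_hrf"))
  if (abs(y$tr - k$dt) > 1e-9 * max(y$tr, k$dt))
    stop("deconvolve_neural: series tr does not match kernel dt")
  n <- length(y$values)
  if (n < length(k$samples))
    stop("deconvolve_neural: series (", n, " samples) shorter than kernel (",
         length(k$samples), " samples)")
  if (!is.null(reg) && (!is.finite(reg) || reg < 0))
    stop("deconvolve_neural: reg must be >= 0")
  op <- deconv_operator(k, n, prior_corner_hz)
  uty <- drop(crossprod(op$u, y$values))
  d <- op$d
  if (is.null(reg))
    reg <- gcv_lambda(d, uty, sum(y$values^2), n)
  if (reg == 0) {
    tol <- max(d) * n * .Machine$double.eps
    filt <- ifelse(d > tol, 1 / d, 0)
  } else {
    filt <- d / (d^2 + reg)
  }
  coefs <- op$scale_w * drop(op$v %*% (filt * uty))
  ts_with_values(y, drop(op$X %*% coefs), level = "neural")
}
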