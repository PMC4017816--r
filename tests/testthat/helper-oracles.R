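# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: pseudoinverse via base svd, flood fill via igraph (or
# a recursive stack fill when igraph is unavailable), OLS via explicit
# normal equations, Gaussian smoothing via separable kernels.

# Moore-Penrose pseudoinverse solve (oracle for OLS and deconvolution).
pinv_solve <- function(A, b, tol = NULL) {
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, b))
}

# Brute-force OLS via normal equations (oracle for fit_glm).
normal_equations_fit <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  list(beta = drop(beta), se = se, t = drop(beta) / se, df = df,
       sigma2 = sigma2)
}

# Connected-component labeling oracle built on igraph.
flood_fill_components <- function(volume, connectivity = 18) {
  d <- dim(volume)
  fg <- which(as.logical(volume))
  out <- array(0L, dim = d)
  if (length(fg) == 0L) return(out)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- off[!(off$dx == 0 & off$dy == 0 & off$dz == 0), ]
  nrm <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- as.matrix(off[switch(as.character(connectivity),
                              "6" = nrm == 1, "18" = nrm <= 2,
                              "26" = rep(TRUE, nrow(off))), ])
  pos <- integer(prod(d)); pos[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  edges <- list()
  for (o in seq_len(nrow(off))) {
    cc <- coords + matrix(off[o, ], nrow(coords), 3, byrow = TRUE)
    ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] & cc[, 2] >= 1 & cc[, 2] <= d[2] &
          cc[, 3] >= 1 & cc[, 3] <= d[3]
    lin <- cc[ok, 1] + (cc[ok, 2] - 1L) * d[1] + (cc[ok, 3] - 1L) * d[1] * d[2]
    src <- fg[ok]
    keep <- pos[lin] > 0
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(pos[src[keep]], pos[lin[keep]])
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[fg] <- as.integer(comp)
  out
}

# Relabel a component map into canonical form (labels ordered by first
# occurrence) so two labelings can be compared up to label permutation.
canonical_labels <- function(lab) {
  fg <- which(lab != 0L)
  m <- lab[fg]
  first <- match(unique(m), m)
  remap <- integer(max(m)); remap[m[first]] <- seq_along(first)
  lab[fg] <- remap[m]
  lab
}

# Separable 3-D Gaussian smoothing (oracle input for smoothness estimation).
gaussian_smooth_3d <- function(vol, fwhm_vox) {
  sigma <- fwhm_vox / sqrt(8 * log(2))
  half <- ceiling(4 * sigma)
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    ms <- apply(m, 2, function(col) {
      padded <- c(rep(col[1], half), col, rep(col[n], half))
      stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
    })
    inv <- order(perm)
    aperm(array(ms, dim = d[perm]), inv)
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

# Shared small fixtures.
tiny_hrf <- function(tr = 2) canonical_hrf(tr, 32)

band_limited_signal <- function(n, tr, freqs, phases = NULL) {
  if (is.null(phases)) phases <- stats::runif(length(freqs), 0, 2 * pi)
  t <- (seq_len(n) - 1L) * tr
  rowSums(mapply(function(f, ph) cos(2 * pi * f * t + ph), freqs, phases))
}
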