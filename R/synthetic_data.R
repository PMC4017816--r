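#' Configuration of a synthetic resting-state cohort
#'
#' Describes the full data-generating model for a simulated cohort: six
#' neural-level network time series per subject, with optional additive
#' (main-effect) and multiplicative (modulatory) couplings, hemodynamic
#' convolution, low-frequency drift, motion-correlated noise and WM/CSF
#' compartment signals. The defaults emulate the acquisition the pipeline
#' targets: 64 subjects, 228 retained volumes at TR = 2 s, six networks.
#'
#' Source networks are unit-variance Gaussian processes with a
#' squared-exponential autocovariance (length scale 4 s), giving slow
#' resting-state-like dynamics. A coupling target is built as
#' `sum(b * source) + sum(c * source_a * source_b) + noise_sd * innovation`,
#' where the innovation is white Gaussian; targets may not feed back into
#' other couplings (no cycles).
#'
#' @param n_subjects cohort size (default 64).
#' @param n_volumes retained volumes per subject (default 228, >= 32).
#' @param tr_s repetition time in seconds (default 2).
#' @param networks character vector of network labels (default the six
#'   canonical resting-state networks).
#' @param couplings data.frame with columns `source_a`, `source_b`,
#'   `target`, `c`: neural-level multiplicative couplings.
#' @param main_effects data.frame with columns `source`, `target`, `b`:
#'   additive neural couplings.
#' @param noise_sd sd of the white neural innovation of target networks
#'   (default 1).
#' @param bold_noise_sd sd of BOLD-level measurement noise; a fraction of it
#'   is carried by the motion regressors (default 0.5).
#' @param motion_noise_mix fraction (in sd) of BOLD noise aligned with the
#'   motion trace (default 0.3).
#' @param drift_amplitude amplitude of the low-frequency drift (default 1).
#' @param drift_periods_s cosine drift periods in seconds, all >= 100 s so
#'   the drift sits below the 0.01 Hz cutoff (default 128, 205, 342).
#' @param motion_sd per-step sd of the random-walk motion parameters
#'   (default 0.02; mm for translations, radians for rotations).
#' @param compartment_signal_sd amplitude with which WM/CSF compartment
#'   signals leak into network BOLD (default 0.5).
#' @param gp_length_scale_s squared-exponential length scale in seconds
#'   (default 4).
#' @param seed base RNG seed; fixes the whole cohort bit-for-bit.
#' @return object of class `netppi_syncfg`.
#' @export
synthetic_config <- function(n_subjects = 64, n_volumes = 228, tr_s = 2,
                             networks = c("aDMN", "pDMN", "SAL", "DAN",
                                          "LECN", "RECN"),
                             couplings = NULL, main_effects = NULL,
                             noise_sd = 1, bold_noise_sd = 0.5,
                             motion_noise_mix = 0.3,
                             drift_amplitude = 1,
                             drift_periods_s = c(128, 205, 342),
                             motion_sd = 0.02,
                             compartment_signal_sd = 0.5,
                             gp_length_scale_s = 4, seed = 1) {
  if (n_volumes < 32) stop("synthetic_config: n_volumes must be >= 32")
  if (anyDuplicated(networks)) stop("synthetic_config: duplicate network labels")
  empty_c <- data.frame(source_a = character(0), source_b = character(0),
                        target = character(0), c = numeric(0))
  empty_b <- data.frame(source = character(0), target = character(0),
                        b = numeric(0))
  couplings <- if (is.null(couplings)) empty_c else as.data.frame(couplings)
  main_effects <- if (is.null(main_effects)) empty_b else
    as.data.frame(main_effects)
  if (nrow(couplings)) {
    bad <- couplings$target == couplings$source_a |
           couplings$target == couplings$source_b
    if (any(bad))
      stop("synthetic_config: a coupling target cannot be its own source")
    if (!all(is.finite(couplings$c)))
      stop("synthetic_config: non-finite coupling coefficient")
  }
  if (nrow(main_effects) && !all(is.finite(main_effects$b)))
    stop("synthetic_config: non-finite main-effect coefficient")
  targets <- unique(c(couplings$target, main_effects$target))
  sources <- unique(c(couplings$source_a, couplings$source_b,
                      main_effects$source))
  unknown <- setdiff(c(targets, sources), networks)
  if (length(unknown))
    stop("synthetic_config: unknown network(s) in couplings: ",
         paste(unknown, collapse = ", "))
  if (length(intersect(targets, sources)))
    stop("synthetic_config: cyclic coupling specification; network(s) ",
         paste(intersect(targets, sources), collapse = ", "),
         " appear as both source and target")
  if (any(!is.finite(c(noise_sd, bold_noise_sd, drift_amplitude, motion_sd,
                       compartment_signal_sd))) ||
      any(c(noise_sd, bold_noise_sd, drift_amplitude, motion_sd,
            compartment_signal_sd) < 0))
    stop("synthetic_config: amplitudes must be finite and >= 0")
  if (any(1 / drift_periods_s >= 0.01 + 1e-12))
    stop("synthetic_config: drift periods must be >= 100 s (below 0.01 Hz)")
  structure(list(n_subjects = n_subjects, n_volumes = n_volumes, tr_s = tr_s,
                 networks = networks, couplings = couplings,
                 main_effects = main_effects, noise_sd = noise_sd,
                 bold_noise_sd = bold_noise_sd,
                 motion_noise_mix = motion_noise_mix,
                 drift_amplitude = drift_amplitude,
                 drift_periods_s = drift_periods_s, motion_sd = motion_sd,
                 compartment_signal_sd = compartment_signal_sd,
                 gp_length_scale_s = gp_length_scale_s, seed = seed),
            class = "netppi_syncfg")
}

# Deterministic per-subject seed derived from the base seed; kept < 2^31.
subject_seed <- function(seed, subject_index, salt = 0L) {
  as.integer((abs(seed) * 7919 + subject_index * 104729 + salt * 15485863) %%
               2147483629)
}

# Cholesky factor of the squared-exponential GP covariance; cached on
# (n, length_scale / tr) since it is identical across subjects.
gp_chol <- function(n, tr, length_scale) {
  key <- paste("gpchol", n, format(tr, digits = 12),
               format(length_scale, digits = 12), sep = "_")
  L <- .netppi_cache[[key]]
  if (!is.null(L)) return(L)
  tau <- outer(seq_len(n), seq_len(n), function(i, j) (i - j) * tr)
  C <- exp(-tau^2 / (2 * length_scale^2)) + diag(1e-8, n)
  L <- chol(C)
  .netppi_cache[[key]] <- L
  L
}

gp_draw <- function(n, tr, length_scale) {
  v <- drop(crossprod(gp_chol(n, tr, length_scale), stats::rnorm(n)))
  v / stats::sd(v)
}

#' Simulate one subject's neural-level network series
#'
#' Source networks are unit-variance smoothed Gaussian processes; target
#' networks are assembled from their declared additive and multiplicative
#' couplings plus white Gaussian innovation (`noise_sd`). Deterministic
#' given `(cfg$seed, subject_index)`.
#'
#' @param cfg a `netppi_syncfg`.
#' @param subject_index integer >= 1.
#' @return named list of `netppi_ts` (level `"neural"`), one per network.
#' @export
simulate_neural_networks <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "netppi_syncfg"))
  set.seed(subject_seed(cfg$seed, subject_index, salt = 1L))
  n <- cfg$n_volumes
  targets <- unique(c(cfg$couplings$target, cfg$main_effects$target))
  out <- list()
  for (nw in cfg$networks) {
    if (nw %in% targets) {
      out[[nw]] <- NA  # placeholder; filled after sources exist
    } else {
      out[[nw]] <- gp_draw(n, cfg$tr_s, cfg$gp_length_scale_s)
    }
  }
  for (nw in targets) {
    v <- cfg$noise_sd * stats::rnorm(n)
    me <- cfg$main_effects[cfg$main_effects$target == nw, , drop = FALSE]
    if (nrow(me)) for (r in seq_len(nrow(me)))
      v <- v + me$b[r] * out[[me$source[r]]]
    cp <- cfg$couplings[cfg$couplings$target == nw, , drop = FALSE]
    if (nrow(cp)) for (r in seq_len(nrow(cp)))
      v <- v + cp$c[r] * out[[cp$source_a[r]]] * out[[cp$source_b[r]]]
    out[[nw]] <- v
  }
  mapply(function(v, nm) time_series(v, cfg$tr_s, "neural", nm),
         out, names(out), SIMPLIFY = FALSE)
}

#' Simulate one subject's BOLD series and nuisance structure
#'
#' Convolves each neural series with the HRF and adds (i) a slow cosine
#' drift (periods >= 100 s, random phases), (ii) BOLD measurement noise, a
#' configurable fraction of which is aligned with the subject's random-walk
#' motion trace, and (iii) WM/CSF compartment leakage. The motion matrix
#' and the unit-variance WM/CSF compartment series are returned as the
#' subject's nuisance set, together with the complete ground truth.
#'
#' @param neural named list from [simulate_neural_networks()].
#' @param cfg a `netppi_syncfg`.
#' @param k a `netppi_hrf` at `cfg$tr_s`.
#' @param subject_index integer >= 1 (drives the nuisance RNG stream).
#' @return object of class `netppi_subject` with fields `neural`, `bold`
#'   (named lists of `netppi_ts`), `nuisance` (`netppi_nuisance`), `truth`.
#' @export
simulate_subject_bold <- function(neural, cfg, k, subject_index = 1L) {
  stopifnot(inherits(cfg, "netppi_syncfg"), inherits(k, "netppi_hrf"))
  set.seed(subject_seed(cfg$seed, subject_index, salt = 2L))
  n <- cfg$n_volumes
  t_s <- (seq_len(n) - 1L) * cfg$tr_s

  motion <- sapply(1:6, function(i) cumsum(stats::rnorm(n, 0, cfg$motion_sd)))
  wm <- gp_draw(n, cfg$tr_s, cfg$gp_length_scale_s)
  csf <- gp_draw(n, cfg$tr_s, cfg$gp_length_scale_s)

  motion_dir <- if (cfg$motion_sd > 0) {
    md <- rowSums(motion)
    sdm <- stats::sd(md)
    if (sdm > 0) (md - mean(md)) / sdm else rep(0, n)
  } else rep(0, n)

  bold <- list()
  for (nw in names(neural)) {
    b <- causal_convolve(neural[[nw]]$values, k$samples)
    if (cfg$drift_amplitude > 0) {
      drift <- rowSums(sapply(cfg$drift_periods_s, function(p)
        cos(2 * pi * t_s / p + stats::runif(1, 0, 2 * pi))))
      b <- b + cfg$drift_amplitude * drift
    }
    if (cfg$bold_noise_sd > 0) {
      mix <- cfg$motion_noise_mix
      eps <- mix * motion_dir + sqrt(max(1 - mix^2, 0)) * stats::rnorm(n)
      b <- b + cfg$bold_noise_sd * eps
    }
    if (cfg$compartment_signal_sd > 0)
      b <- b + cfg$compartment_signal_sd * (0.6 * wm + 0.4 * csf)
    bold[[nw]] <- time_series(b, cfg$tr_s, "bold", nw)
  }
  nuis <- nuisance_set(motion,
                       time_series(wm, cfg$tr_s, "bold", "wm_pc1"),
                       time_series(csf, cfg$tr_s, "bold", "csf_pc1"))
  structure(list(neural = neural, bold = bold, nuisance = nuis,
                 truth = list(couplings = cfg$couplings,
                              main_effects = cfg$main_effects,
                              seed = cfg$seed,
                              subject_index = subject_index)),
            class = "netppi_subject")
}

#' Simulate a full cohort
#'
#' @param cfg a `netppi_syncfg`.
#' @param k HRF kernel; defaults to `canonical_hrf(cfg$tr_s)`.
#' @param out_dir optional directory: writes per-subject network TSVs
#'   (`sub-XX_networks.tsv`), rp-style motion files (`sub-XX_rp.txt`),
#'   WM/CSF compartment TSVs and a `ground_truth.json`.
#' @return list of `netppi_subject`, invisibly annotated with `out_dir`.
#' @export
simulate_cohort <- function(cfg, k = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "netppi_syncfg"))
  if (is.null(k)) k <- canonical_hrf(cfg$tr_s)
  subjects <- lapply(seq_len(cfg$n_subjects), function(i)
    simulate_subject_bold(simulate_neural_networks(cfg, i), cfg, k, i))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(subjects)) {
      su <- subjects[[i]]
      tag <- sprintf("sub-%02d", i)
      net <- sapply(su$bold, ts_values)
      utils::write.table(round(net, 10),
                         file.path(out_dir, paste0(tag, "_networks.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(format(round(su$nuisance$matrix[, 1:6], 10),
                                scientific = FALSE, trim = TRUE),
                         file.path(out_dir, paste0(tag, "_rp.txt")),
                         sep = "  ", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      comp <- data.frame(wm_pc1 = su$nuisance$matrix[, "wm_pc1"],
                         csf_pc1 = su$nuisance$matrix[, "csf_pc1"])
      utils::write.table(round(comp, 10),
                         file.path(out_dir, paste0(tag, "_compartments.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    truth <- list(n_subjects = cfg$n_subjects, n_volumes = cfg$n_volumes,
                  tr_s = cfg$tr_s, networks = cfg$networks,
                  couplings = cfg$couplings, main_effects = cfg$main_effects,
                  noise_sd = cfg$noise_sd, seed = cfg$seed)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(subjects, "out_dir") <- out_dir
  subjects
}

# Spherical blob weight map centered at `center` (voxel coords) with the
# given radius; smooth quadratic falloff to 0 at the radius.
blob_map <- function(grid, center, radius) {
  d2 <- outer(outer((seq_len(grid[1]) - center[1])^2,
                    (seq_len(grid[2]) - center[2])^2, "+"),
              (seq_len(grid[3]) - center[3])^2, "+")
  w <- pmax(1 - d2 / radius^2, 0)
  array(w, dim = grid)
}

default_scene_layout <- function(grid, n_networks) {
  # non-overlapping blob centers on two depth layers + interaction region +
  # WM/CSF compartments, scaled to the grid
  fx <- function(f) round(f * grid[1]); fy <- function(f) round(f * grid[2])
  fz <- function(f) pmax(round(f * grid[3]), 1)
  centers <- rbind(
    c(fx(0.25), fy(0.25), fz(0.3)), c(fx(0.75), fy(0.25), fz(0.3)),
    c(fx(0.25), fy(0.75), fz(0.3)), c(fx(0.75), fy(0.75), fz(0.3)),
    c(fx(0.25), fy(0.50), fz(0.75)), c(fx(0.75), fy(0.50), fz(0.75)))
  list(network_centers = centers[seq_len(n_networks), , drop = FALSE],
       radius = max(3, round(min(grid) / 8)),
       interaction_center = c(fx(0.5), fy(0.5), fz(0.5)),
       interaction_radius = max(3, round(min(grid) / 9)),
       wm_center = c(fx(0.5), fy(0.12), fz(0.4)),
       csf_center = c(fx(0.5), fy(0.88), fz(0.6)))
}

#' Simulate a 4-D volume scene with a planted interaction region
#'
#' Builds a small-brain phantom for voxel-wise PPI: each network occupies a
#' smooth spherical blob whose voxels carry that network's BOLD series; a
#' designated interaction region additionally carries the HRF-convolved
#' product of two chosen neural series scaled by `interaction_c`; WM and CSF
#' compartments carry their synthesized signals; every voxel receives white
#' Gaussian noise of sd `voxel_noise_sd` on top of a baseline offset.
#'
#' @param cfg a `netppi_syncfg`.
#' @param subject_index subject to simulate.
#' @param grid integer length-3 grid size, every dimension >= 20
#'   (default 40 x 40 x 24).
#' @param voxel_mm voxel size in mm (default 3).
#' @param pair character length-2: the networks whose neural product drives
#'   the interaction region (default SAL, RECN).
#' @param interaction_c interaction amplitude in the region (default 1).
#' @param voxel_noise_sd white voxel noise sd (default 1).
#' @param k HRF kernel; defaults to `canonical_hrf(cfg$tr_s)`.
#' @return list with `img` (4-D array), `mask` (analysis mask), `wm_mask`,
#'   `csf_mask`, `interaction_mask`, `voxel_mm`, `subject`
#'   (the `netppi_subject` driving the scene), `pair`.
#' @export
simulate_volume_scene <- function(cfg, subject_index = 1L,
                                  grid = c(40, 40, 24), voxel_mm = c(3, 3, 3),
                                  pair = c("SAL", "RECN"),
                                  interaction_c = 1, voxel_noise_sd = 1,
                                  k = NULL) {
  stopifnot(inherits(cfg, "netppi_syncfg"))
  if (length(grid) != 3L || any(grid < 20))
    stop("simulate_volume_scene: every grid dimension must be >= 20")
  if (!all(pair %in% cfg$networks))
    stop("simulate_volume_scene: unknown pair networks")
  if (is.null(k)) k <- canonical_hrf(cfg$tr_s)
  su <- simulate_subject_bold(simulate_neural_networks(cfg, subject_index),
                              cfg, k, subject_index)
  lay <- default_scene_layout(grid, length(cfg$networks))
  maps <- lapply(seq_along(cfg$networks), function(i)
    blob_map(grid, lay$network_centers[i, ], lay$radius))
  names(maps) <- cfg$networks
  imask <- blob_map(grid, lay$interaction_center, lay$interaction_radius) > 0
  overlap <- vapply(maps, function(m) any(m[imask] > 0.05), logical(1))
  if (any(overlap))
    stop("simulate_volume_scene: interaction region overlaps source map(s): ",
         paste(names(maps)[overlap], collapse = ", "))
  wm_mask <- blob_map(grid, lay$wm_center, lay$radius) > 0
  csf_mask <- blob_map(grid, lay$csf_center, lay$radius) > 0

  n <- cfg$n_volumes
  vox <- prod(grid)
  W <- cbind(sapply(maps, as.numeric))                 # vox x networks
  S <- t(sapply(su$bold, ts_values))                   # networks x time
  Y <- W %*% S
  # planted neural-level interaction, forward-modelled exactly as assumed
  n1 <- detrend_linear(su$neural[[pair[1]]])$values
  n2 <- detrend_linear(su$neural[[pair[2]]])$values
  inter_bold <- causal_convolve(n1 * n2, k$samples)
  Y[as.numeric(imask) > 0, ] <-
    Y[as.numeric(imask) > 0, , drop = FALSE] +
    matrix(interaction_c * inter_bold, sum(imask), n, byrow = TRUE)
  wm_sig <- su$nuisance$matrix[, "wm_pc1"]
  csf_sig <- su$nuisance$matrix[, "csf_pc1"]
  Y[as.numeric(wm_mask) > 0, ] <-
    Y[as.numeric(wm_mask) > 0, , drop = FALSE] +
    matrix(wm_sig, sum(wm_mask), n, byrow = TRUE)
  Y[as.numeric(csf_mask) > 0, ] <-
    Y[as.numeric(csf_mask) > 0, , drop = FALSE] +
    matrix(csf_sig, sum(csf_mask), n, byrow = TRUE)

  set.seed(subject_seed(cfg$seed, subject_index, salt = 3L))
  Y <- Y + 100 + matrix(stats::rnorm(vox * n, 0, voxel_noise_sd), vox, n)
  mask <- array(Reduce(`+`, maps) > 0 | imask | wm_mask | csf_mask,
                dim = grid)
  list(img = array(Y, dim = c(grid, n)), mask = mask, wm_mask = wm_mask,
       csf_mask = csf_mask, interaction_mask = imask, voxel_mm = voxel_mm,
       subject = su, pair = pair)
}
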