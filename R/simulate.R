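#' Configuration for the synthetic multi-observer volume generator
#'
#' Defaults emulate the design of a multi-observer vestibular-schwannoma
#' volumetry test set: 100 subjects, 5 observers, lognormal tumor
#' volumes with median 903 mm^3 and a log-SD reproducing an
#' interquartile range of roughly 190-3,100 mm^3, and multiplicative
#' (log-normal) observer error split into a systematic per-observer
#' component and a residual component. Observer error being
#' multiplicative makes percent deviations volume-free by default;
#' volume-dependent error, the phenomenon the sliding-window band
#' exists to detect, is switched on explicitly via
#' `volume_dependent_noise`.
#'
#' @param n_subjects,m_observers design size (defaults 100 x 5).
#' @param median_volume median true volume, mm^3 (default 903).
#' @param log_volume_sd SD of log true volumes (default 2.06, matching
#'   the target interquartile range under a lognormal).
#' @param sigma_obs SD of the systematic per-observer log effect
#'   (default 0.03, i.e. ~3% multiplicative).
#' @param sigma_res SD of the residual log error (default 0.05).
#' @param observer_biases optional fixed per-observer log offsets
#'   (length m); default all zero, i.e. effects drawn from
#'   `N(0, sigma_obs^2)` only.
#' @param candidate_bias candidate annotator's systematic bias in
#'   percent (default 0).
#' @param candidate_sd SD of the candidate's log error; default
#'   `sqrt(sigma_obs^2 + sigma_res^2)`, which makes the candidate's
#'   marginal error distribution match a human observer's.
#' @param volume_dependent_noise factor multiplying `sigma_res` for
#'   subjects with true volume below `noise_threshold` (default 1 =
#'   homoscedastic).
#' @param noise_threshold volume threshold (mm^3) for the factor;
#'   default `median_volume`.
#' @param z normal quantile used for the closed-form true LOAM.
#' @param seed integer seed recorded in all outputs.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 100, m_observers = 5,
                              median_volume = 903, log_volume_sd = 2.06,
                              sigma_obs = 0.03, sigma_res = 0.05,
                              observer_biases = NULL,
                              candidate_bias = 0, candidate_sd = NULL,
                              volume_dependent_noise = 1,
                              noise_threshold = median_volume,
                              z = 1.96, seed = 1L) {
  if (is.null(observer_biases)) observer_biases <- rep(0, m_observers)
  if (is.null(candidate_sd)) candidate_sd <- sqrt(sigma_obs^2 + sigma_res^2)
  cfg <- list(n_subjects = as.integer(n_subjects),
              m_observers = as.integer(m_observers),
              median_volume = median_volume, log_volume_sd = log_volume_sd,
              sigma_obs = sigma_obs, sigma_res = sigma_res,
              observer_biases = observer_biases,
              candidate_bias = candidate_bias, candidate_sd = candidate_sd,
              volume_dependent_noise = volume_dependent_noise,
              noise_threshold = noise_threshold, z = z,
              seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 2 || m_observers < 2)
      stop("configuration error: need >= 2 subjects and >= 2 observers")
    if (median_volume <= 0 || log_volume_sd < 0)
      stop("configuration error: invalid volume distribution")
    if (sigma_obs < 0 || sigma_res < 0 || candidate_sd < 0)
      stop("configuration error: SDs must be >= 0")
    if (length(observer_biases) != m_observers)
      stop("configuration error: observer_biases must have length m_observers")
    if (volume_dependent_noise <= 0)
      stop("configuration error: volume_dependent_noise must be > 0")
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-observer volume matrix with known truth
#'
#' True volumes `T_i` are lognormal; observed volumes are
#' `V_ij = T_i * exp(b_j + e_ij)` with systematic observer effects
#' `b_j ~ N(bias_j, sigma_obs^2)` and residuals `e_ij ~ N(0, s_i^2)`,
#' where `s_i = sigma_res * volume_dependent_noise` below the volume
#' threshold and `sigma_res` above it. The returned truth record
#' includes the drawn effects and the closed-form (small-sigma,
#' homoscedastic) true LOAM in percent,
#' `100 * z * sqrt(((m-1)/m) * (sigma_obs^2 + sigma_res^2))`.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `"sim_volumes"`: `volumes` (a
#'   [volume_matrix()]), `true_volumes`, `observer_effects`,
#'   `true_loam_pct`, and `config`.
#' @export
simulate_volume_matrix <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  out <- with_seed(cfg$seed, {
    n <- cfg$n_subjects; m <- cfg$m_observers
    Ti <- exp(rnorm(n, log(cfg$median_volume), cfg$log_volume_sd))
    b <- rnorm(m, cfg$observer_biases, cfg$sigma_obs)
    s_i <- ifelse(Ti < cfg$noise_threshold,
                  cfg$sigma_res * cfg$volume_dependent_noise, cfg$sigma_res)
    E <- matrix(rnorm(n * m, 0, rep(s_i, m)), n, m)
    V <- Ti * exp(sweep(E, 2, b, "+"))
    list(Ti = Ti, b = b, V = V)
  })
  vm <- volume_matrix(out$V,
                      subject_ids = sprintf("S%03d", seq_len(cfg$n_subjects)),
                      observer_ids = paste0("O", seq_len(cfg$m_observers)))
  structure(
    list(volumes = vm,
         true_volumes = setNames(out$Ti, rownames(vm)),
         observer_effects = setNames(out$b, colnames(vm)),
         true_loam_pct = 100 * cfg$z *
           sqrt(((cfg$m_observers - 1) / cfg$m_observers) *
                  (cfg$sigma_obs^2 + cfg$sigma_res^2)),
         config = cfg),
    class = "sim_volumes")
}

#' @export
print.sim_volumes <- function(x, ...) {
  cat(sprintf(
    "<sim_volumes> %d x %d synthetic volumes, median truth %.4g mm^3, true LOAM %.4g%% (seed %d)\n",
    nrow(x$volumes), ncol(x$volumes), median(x$true_volumes),
    x$true_loam_pct, x$config$seed))
  invisible(x)
}

#' Simulate a candidate (AI) annotator's volumes
#'
#' The candidate measures `V_i = T_i * exp(log(1 + bias/100) + u_i)`
#' with `u_i ~ N(0, candidate_sd^2)`, built on the same true volumes as
#' the human matrix. With `bias = 0` and the default `candidate_sd` the
#' candidate is statistically indistinguishable from one more human
#' observer. `bias_small_factor` multiplies `(1 + bias/100) - 1` for
#' subjects below the config's volume threshold, emulating the larger
#' relative errors automated annotators show on small structures.
#'
#' @param sim a [simulate_volume_matrix()] result.
#' @param bias,candidate_sd override the config's candidate settings.
#' @param bias_small_factor bias inflation factor below the threshold
#'   (default 1 = none).
#' @param seed defaults to `config seed + 1` so candidate draws are
#'   reproducible yet independent of the human matrix draws.
#' @return Named numeric vector of candidate volumes (mm^3) per subject.
#' @export
simulate_candidate <- function(sim, bias = NULL, candidate_sd = NULL,
                               bias_small_factor = 1, seed = NULL) {
  stopifnot(inherits(sim, "sim_volumes"))
  cfg <- sim$config
  bias <- bias %||% cfg$candidate_bias
  candidate_sd <- candidate_sd %||% cfg$candidate_sd
  seed <- seed %||% ((cfg$seed + 1L) %% .Machine$integer.max)
  Ti <- sim$true_volumes
  eff_bias <- ifelse(Ti < cfg$noise_threshold,
                     bias * bias_small_factor, bias)
  with_seed(seed, {
    u <- rnorm(length(Ti), 0, candidate_sd)
    setNames(Ti * exp(log(1 + eff_bias / 100) + u), names(Ti))
  })
}

#' Configuration for 3D ellipsoid phantom masks
#'
#' @param dim lattice dimensions (voxels), length 3.
#' @param spacing voxel spacing, mm.
#' @param semi_axes_range range (mm) from which each subject's three
#'   ellipsoid semi-axes are drawn uniformly; every axis must exceed
#'   the voxel spacing.
#' @param semi_axes optional fixed semi-axes (mm, length 3) used for
#'   every subject instead of sampling.
#' @param boundary_noise_sd SD (mm) of the smooth radial boundary
#'   perturbation applied per observer.
#' @param smoothness angular correlation scale (radians) of the
#'   perturbation field (default 0.4).
#' @param seed integer seed.
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(dim = c(32, 32, 32), spacing = c(1, 1, 1),
                           semi_axes_range = c(4, 9), semi_axes = NULL,
                           boundary_noise_sd = 0.5, smoothness = 0.4,
                           seed = 1L) {
  if (!is.null(semi_axes)) {
    stopifnot(length(semi_axes) == 3)
    semi_axes_range <- range(semi_axes)
  }
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              semi_axes_range = as.numeric(semi_axes_range),
              semi_axes = semi_axes,
              boundary_noise_sd = boundary_noise_sd,
              smoothness = smoothness, seed = as.integer(seed))
  if (length(cfg$dim) != 3 || any(cfg$dim < 1))
    stop("configuration error: dim must be 3 positive integers")
  if (any(cfg$spacing <= 0))
    stop("configuration error: spacing must be positive")
  if (cfg$semi_axes_range[1] <= max(cfg$spacing))
    stop("configuration error: semi-axes must exceed the voxel spacing")
  if (cfg$boundary_noise_sd < 0 || cfg$smoothness <= 0)
    stop("configuration error: invalid perturbation parameters")
  half_extent <- (cfg$dim - 1) * cfg$spacing / 2
  margin <- cfg$semi_axes_range[2] + 4 * cfg$boundary_noise_sd
  if (any(margin > half_extent))
    stop("configuration error: ellipsoid (plus noise) can exceed the lattice")
  structure(cfg, class = "phantom_config")
}

# Smooth random field on the (theta, phi) angular grid: iid normal noise
# convolved with a separable Gaussian kernel (phi wraps), rescaled to
# unit SD.
smooth_sphere_field <- function(nt = 24, np = 48, scale = 0.4) {
  z <- matrix(rnorm(nt * np), nt, np)
  gk <- function(delta, s) exp(-0.5 * (delta / s)^2)
  # theta smoothing (truncated at the poles, renormalised)
  ktv <- gk((-6:6) * (pi / nt), scale)
  zs <- apply(z, 2, function(col) {
    vapply(seq_len(nt), function(i) {
      j <- (i - 6):(i + 6); ok <- j >= 1 & j <= nt
      sum(col[j[ok]] * ktv[ok]) / sum(ktv[ok])
    }, numeric(1))
  })
  # phi smoothing (periodic)
  off <- -12:12
  kpv <- gk(off * (2 * pi / np), scale)
  zs <- t(apply(zs, 1, function(row) {
    vapply(seq_len(np), function(i) {
      sum(row[((i + off - 1) %% np) + 1] * kpv) / sum(kpv)
    }, numeric(1))
  }))
  zs / sd(zs)
}

# Voxelize an ellipsoid (semi-axes `axes` mm, centered in the lattice)
# with a radial boundary displacement delta(theta, phi) in mm; a voxel
# center is foreground when its signed radial distance beyond the
# unperturbed boundary is <= the local displacement.
voxelize_perturbed_ellipsoid <- function(dim, spacing, axes, delta_field) {
  ctr <- (dim - 1) * spacing / 2
  x <- ((seq_len(dim[1]) - 1) * spacing[1]) - ctr[1]
  y <- ((seq_len(dim[2]) - 1) * spacing[2]) - ctr[2]
  z <- ((seq_len(dim[3]) - 1) * spacing[3]) - ctr[3]
  X <- array(rep(x, times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(y, each = dim[1]), times = dim[3]), dim)
  Z <- array(rep(z, each = dim[1] * dim[2]), dim)
  r <- sqrt(X^2 + Y^2 + Z^2)
  g <- sqrt((X / axes[1])^2 + (Y / axes[2])^2 + (Z / axes[3])^2)
  excess <- ifelse(g > 0, r * (1 - 1 / g), -max(axes))  # signed mm outside
  if (is.null(delta_field)) return(array(as.integer(excess <= 0), dim))
  nt <- nrow(delta_field); np <- ncol(delta_field)
  theta <- acos(pmin(1, pmax(-1, ifelse(r > 0, Z / r, 1))))
  phi <- atan2(Y, X) %% (2 * pi)
  it <- pmin(nt, pmax(1L, ceiling(theta / pi * nt)))
  ip <- pmin(np, 1L + floor(phi / (2 * pi) * np))
  delta <- array(delta_field[cbind(as.vector(it), as.vector(ip))], dim)
  array(as.integer(excess <= delta), dim)
}

#' Simulate ground-truth and observer phantom masks
#'
#' Each subject's ground truth is a voxelized ellipsoid with randomly
#' drawn semi-axes; each observer's mask is the same ellipsoid with a
#' smooth random radial displacement of the boundary (Gaussian-smoothed
#' angular noise, SD `boundary_noise_sd` mm), emulating inter-observer
#' contouring differences. All masks of a subject share the lattice and
#' spacing.
#'
#' @param cfg a [phantom_config()].
#' @param n_subjects,m_observers how many subjects/observers.
#' @return A list of class `"sim_phantoms"`: per subject a list with
#'   `truth` ([label_map()]), `observers` (list of m label maps), and
#'   `volumes` (named achieved volumes, mm^3, truth first); plus the
#'   config.
#' @export
simulate_observer_masks <- function(cfg = phantom_config(), n_subjects = 1,
                                    m_observers = 5) {
  stopifnot(inherits(cfg, "phantom_config"))
  subjects <- with_seed(cfg$seed, {
    lapply(seq_len(n_subjects), function(s) {
      sid <- sprintf("P%03d", s)
      axes <- cfg$semi_axes %||%
        runif(3, cfg$semi_axes_range[1], cfg$semi_axes_range[2])
      truth <- label_map(
        voxelize_perturbed_ellipsoid(cfg$dim, cfg$spacing, axes, NULL),
        cfg$spacing, subject_id = sid, observer_id = "truth")
      obs <- lapply(seq_len(m_observers), function(j) {
        fld <- if (cfg$boundary_noise_sd > 0)
          cfg$boundary_noise_sd * smooth_sphere_field(scale = cfg$smoothness)
        else NULL
        label_map(
          voxelize_perturbed_ellipsoid(cfg$dim, cfg$spacing, axes, fld),
          cfg$spacing, subject_id = sid, observer_id = paste0("O", j))
      })
      vols <- c(truth = volume_mm3(truth),
                setNames(vapply(obs, volume_mm3, numeric(1)),
                         paste0("O", seq_len(m_observers))))
      list(subject_id = sid, semi_axes = axes, truth = truth,
           observers = obs, volumes = vols)
    })
  })
  structure(list(subjects = subjects, config = cfg), class = "sim_phantoms")
}

#' @export
print.sim_phantoms <- function(x, ...) {
  cat(sprintf(
    "<sim_phantoms> %d subjects x %d observers on a %dx%dx%d lattice (seed %d)\n",
    length(x$subjects), length(x$subjects[[1]]$observers),
    x$config$dim[1], x$config$dim[2], x$config$dim[3], x$config$seed))
  invisible(x)
}
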