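#' Dice overlap between two label maps, in percent
#'
#' `100 * 2|A n B| / (|A| + |B|)`. Two empty masks are defined as perfect
#' agreement (100); one empty mask against a nonempty one gives 0.
#'
#' @param a,b [label_map()]s on the same lattice with the same spacing.
#' @return Dice score in percent, in \[0, 100\].
#' @export
dice <- function(a, b) {
  check_same_lattice(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(100)
  100 * 2 * sum(a$voxels * b$voxels) / (na + nb)
}

#' Relative volume error, in percent
#'
#' `100 * |v_pred - v_ref| / v_ref`. The absolute value is used; signed
#' deviation from a consensus lives in [delta_v_percent()] instead.
#'
#' @param v_pred predicted volume, mm^3.
#' @param v_ref reference volume, mm^3; must be > 0.
#' @return RVE in percent (>= 0).
#' @export
rve <- function(v_pred, v_ref) {
  if (!is.finite(v_ref) || v_ref <= 0)
    stop("invalid input: reference volume must be > 0")
  100 * abs(v_pred - v_ref) / v_ref
}

#' Surface voxel centers of a label map
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-connected neighbours is background or lies outside the lattice
#' (the array border counts as background). Coordinates are voxel centers
#' in physical mm: (index - 1) * spacing per axis.
#'
#' @param mask a nonempty [label_map()].
#' @return Numeric matrix with one row per surface voxel, columns x/y/z mm.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "label_map"))
  v <- mask$voxels
  if (sum(v) == 0) stop("empty mask: no surface exists")
  d <- dim(v)
  # padded array: border background makes boundary handling uniform
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
        p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
        p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
        p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
        p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
        p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(core == 1L & nb < 6L, arr.ind = TRUE)
  sweep(idx - 1, 2, mask$spacing, "*")
}

# Pooled symmetric surface distances: directed min-distances from every
# surface voxel of `a` to surface(b) and vice versa, concatenated.
surface_distances <- function(a, b) {
  check_same_lattice(a, b)
  if (sum(a$voxels) == 0 || sum(b$voxels) == 0)
    stop("undefined metric: surface distance requires two nonempty masks")
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  c(.directed_min_dists(sa, sb), .directed_min_dists(sb, sa))
}

#' Average symmetric surface distance (ASSD), in mm
#'
#' Mean of the pooled directed surface distances between the two masks'
#' 6-connectivity boundaries, Euclidean in physical mm between voxel
#' centers. Undefined (error) when either mask is empty: an empty
#' prediction is a detection failure and must surface, never score 0.
#'
#' @inheritParams dice
#' @return ASSD in mm (>= 0).
#' @export
assd <- function(a, b) mean(surface_distances(a, b))

#' 95th-percentile Hausdorff distance (HD95), in mm
#'
#' The 95th percentile (linear interpolation between order statistics) of
#' the same pooled directed surface-distance set used by [assd()]. Pooling
#' over both directions, rather than taking the maximum of two directed
#' percentiles, keeps the convention aligned with the pooled ASSD.
#'
#' @inheritParams dice
#' @return HD95 in mm (>= 0).
#' @export
hd95 <- function(a, b)
  quantile(surface_distances(a, b), 0.95, type = 7, names = FALSE)

check_same_lattice <- function(a, b) {
  stopifnot(inherits(a, "label_map"), inherits(b, "label_map"))
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("invalid input: masks are on different lattices (dim mismatch)")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("invalid input: masks have different voxel spacing")
  invisible(TRUE)
}

#' Pairwise segmentation metrics for one subject
#'
#' With only human observer masks, every unordered observer pair is
#' evaluated (the inter-observer table). With a `candidate` mask (e.g. an
#' automated annotator), the candidate is evaluated against each human
#' observer individually, with the human as the reference for RVE.
#' An empty mask makes ASSD/HD95 (and RVE when the reference is empty)
#' undefined; those cells are recorded as `NA`, never as 0.
#'
#' @param masks list of [label_map()]s for one subject, one per observer,
#'   all on the same lattice; at least 2.
#' @param candidate optional [label_map()] for the candidate annotator.
#' @return A data.frame with one row per evaluated pair and columns
#'   `subject_id`, `observer_a`, `observer_b`, `dice_pct`, `assd_mm`,
#'   `hd95_mm`, `rve_pct`, `volume_a_mm3`, `volume_b_mm3`.
#' @export
pairwise_metrics <- function(masks, candidate = NULL) {
  if (length(masks) < 2L) stop("invalid input: need at least 2 observer masks")
  for (m in masks[-1]) check_same_lattice(masks[[1]], m)
  if (!is.null(candidate)) check_same_lattice(masks[[1]], candidate)
  pair_row <- function(x, y) {
    va <- volume_mm3(x); vb <- volume_mm3(y)
    data.frame(
      subject_id = x$subject_id,
      observer_a = x$observer_id, observer_b = y$observer_id,
      dice_pct = dice(x, y),
      assd_mm = tryCatch(assd(x, y), error = function(e) NA_real_),
      hd95_mm = tryCatch(hd95(x, y), error = function(e) NA_real_),
      rve_pct = tryCatch(rve(va, vb), error = function(e) NA_real_),
      volume_a_mm3 = va, volume_b_mm3 = vb,
      stringsAsFactors = FALSE)
  }
  rows <- if (is.null(candidate)) {
    pairs <- utils::combn(length(masks), 2, simplify = FALSE)
    lapply(pairs, function(p) pair_row(masks[[p[1]]], masks[[p[2]]]))
  } else {
    lapply(masks, function(m) pair_row(candidate, m))
  }
  do.call(rbind, rows)
}
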