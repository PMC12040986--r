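#' Relative volumetric deviation from the human consensus, in percent
#'
#' Signed percent deviation of a candidate annotator's volume from the
#' mean volume of the human observers for the same subject.
#'
#' @param candidate_volume candidate volume(s), mm^3.
#' @param mean_human_volume mean human observer volume(s), mm^3 (> 0).
#' @return `100 * (candidate - mean) / mean`, signed percent.
#' @export
delta_v_percent <- function(candidate_volume, mean_human_volume) {
  if (any(!is.finite(mean_human_volume)) || any(mean_human_volume <= 0))
    stop("invalid input: mean human volume must be > 0")
  100 * (candidate_volume - mean_human_volume) / mean_human_volume
}

align_candidate <- function(candidate_volumes, subject_ids) {
  if (is.data.frame(candidate_volumes)) {
    if (!all(c("subject_id", "volume_mm3") %in% names(candidate_volumes)))
      stop("invalid input: candidate data.frame needs subject_id and volume_mm3")
    candidate_volumes <- setNames(candidate_volumes$volume_mm3,
                                  candidate_volumes$subject_id)
  }
  if (!is.null(names(candidate_volumes)) && any(nzchar(names(candidate_volumes)))) {
    missing_ids <- setdiff(subject_ids, names(candidate_volumes))
    if (length(missing_ids))
      stop("alignment error: candidate volumes missing for subjects: ",
           paste(missing_ids, collapse = ", "))
    candidate_volumes <- candidate_volumes[subject_ids]
  } else if (length(candidate_volumes) != length(subject_ids)) {
    stop("alignment error: unnamed candidate volumes must match subject count")
  }
  unname(candidate_volumes)
}

#' Classify a candidate annotator against the human agreement band
#'
#' Each subject's candidate volume is expressed as a signed percent
#' deviation from the mean of the human observers and compared with the
#' upper agreement limit evaluated at that subject's mean volume. Under
#' the default one-sided rule the candidate is comparable to the human
#' observers when the signed deviation lies below the upper limit; the
#' `two_sided` option compares the absolute deviation instead, guarding
#' against gross under-segmentation which the one-sided rule never flags.
#'
#' @param candidate_volumes per-subject candidate volumes: named numeric
#'   vector, unnamed vector in `vm_human`'s subject order, or a
#'   data.frame with `subject_id` and `volume_mm3`.
#' @param vm_human the human [volume_matrix()].
#' @param band the human [sliding_window_loam()] band.
#' @param rule `"one_sided"` (default) or `"two_sided"`.
#' @return A data.frame of class `"candidate_eval"` with one row per
#'   subject: `subject_id`, `mean_human_volume`, `candidate_volume`,
#'   `delta_v_pct`, `upper_limit_pct`, `comparable`, and `exceedance_pp`
#'   (the deviation minus the upper limit, in percentage points; `NA`
#'   for comparable subjects).
#' @export
classify_candidate <- function(candidate_volumes, vm_human, band,
                               rule = c("one_sided", "two_sided")) {
  rule <- match.arg(rule)
  if (!inherits(vm_human, "volume_matrix")) vm_human <- volume_matrix(vm_human)
  cand <- align_candidate(candidate_volumes, rownames(vm_human))
  vbar <- rowMeans(vm_human)
  dv <- delta_v_percent(cand, vbar)
  lim <- upper_agreement_limit(band, vbar)
  eff <- if (rule == "one_sided") dv else abs(dv)
  comparable <- eff < lim
  out <- data.frame(
    subject_id = rownames(vm_human),
    mean_human_volume = unname(vbar),
    candidate_volume = cand,
    delta_v_pct = unname(dv),
    upper_limit_pct = unname(lim),
    comparable = unname(comparable),
    exceedance_pp = ifelse(comparable, NA_real_, unname(eff - lim)),
    stringsAsFactors = FALSE)
  attr(out, "rule") <- rule
  class(out) <- c("candidate_eval", "data.frame")
  out
}

#' @export
print.candidate_eval <- function(x, digits = 3, ...) {
  n <- nrow(x); nc <- sum(x$comparable)
  cat(sprintf(
    "<candidate_eval> %d subjects (%s rule): %d comparable (%.0f%%), %d exceed the upper agreement limit\n",
    n, attr(x, "rule"), nc, 100 * nc / n, n - nc))
  if (nc < n) {
    ex <- x$exceedance_pp[!x$comparable]
    q <- quantile(ex, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    cat(sprintf("  exceedance: median %.*g pp (IQR %.*g-%.*g)\n",
                digits, q[2], digits, q[1], digits, q[3]))
  }
  invisible(x)
}

#' @export
summary.candidate_eval <- function(object, ...) quartile_summary(object)

#' Quartile-stratified comparability summary
#'
#' Splits subjects into quartiles of the mean human volume (boundaries =
#' 25/50/75% quantiles, linear interpolation; subjects exactly on a
#' boundary fall in the lower quartile) and reports, per quartile and
#' overall, the number and fraction of comparable subjects and the
#' median (IQR) exceedance over the upper agreement limit among the
#' incomparable ones.
#'
#' @param results a [classify_candidate()] table (>= 4 subjects).
#' @return A data.frame of class `"quartile_summary"` with rows
#'   Q1..Q4 and All; attribute `"boundaries"` holds the quartile
#'   boundary volumes (mm^3).
#' @export
quartile_summary <- function(results) {
  stopifnot(inherits(results, "data.frame"))
  if (nrow(results) < 4L)
    stop("insufficient data: quartile summary needs at least 4 subjects")
  v <- results$mean_human_volume
  qb <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  qi <- 1L + (v > qb[1]) + (v > qb[2]) + (v > qb[3])
  one <- function(rows, label) {
    k <- nrow(rows); nc <- sum(rows$comparable)
    ex <- rows$exceedance_pp[!rows$comparable]
    qs <- if (length(ex)) quantile(ex, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
          else rep(NA_real_, 3)
    data.frame(quartile = label, n = k, n_comparable = nc,
               n_incomparable = k - nc,
               pct_comparable = if (k) 100 * nc / k else NA_real_,
               exceedance_median_pp = qs[2],
               exceedance_q1_pp = qs[1], exceedance_q3_pp = qs[3],
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(1:4, function(q) one(results[qi == q, , drop = FALSE],
                                paste0("Q", q))),
    list(one(results, "All"))))
  rownames(out) <- NULL
  attr(out, "boundaries") <- qb
  class(out) <- c("quartile_summary", "data.frame")
  out
}

#' @export
print.quartile_summary <- function(x, digits = 3, ...) {
  cat("Comparability by tumor volume quartile\n")
  b <- attr(x, "boundaries")
  cat(sprintf("  boundaries: %.4g / %.4g / %.4g mm^3\n", b[1], b[2], b[3]))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Re-estimate the agreement band with the candidate as an observer
#'
#' Appends the candidate's volumes as an (m+1)-th observer column, so
#' per-subject consensus means are recomputed over all m+1 annotators,
#' and refits the sliding-window LOAM band on the enlarged matrix. If
#' the candidate behaves like one more human observer the band changes
#' little and its CI narrows; a systematically deviating candidate
#' inflates the observer variance component and raises the band.
#'
#' @inheritParams classify_candidate
#' @param candidate_id observer id for the new column.
#' @param ... passed to [sliding_window_loam()] (window size, step, CI
#'   settings, seed).
#' @return An [sliding_window_loam()] band for the m+1 observers.
#' @export
refit_with_candidate <- function(vm_human, candidate_volumes,
                                 candidate_id = "candidate", ...) {
  if (!inherits(vm_human, "volume_matrix")) vm_human <- volume_matrix(vm_human)
  cand <- align_candidate(candidate_volumes, rownames(vm_human))
  if (any(!is.finite(cand)) || any(cand <= 0))
    stop("invalid input: candidate volumes must be positive")
  aug <- cbind(unclass(vm_human), cand)
  colnames(aug) <- c(colnames(vm_human), candidate_id)
  sliding_window_loam(relative_deviations(volume_matrix(aug)), ...)
}

#' Compare two agreement bands' confidence intervals
#'
#' Evaluates both bands' LOAM 95% CIs on a shared log-spaced volume grid
#' over the intersection of their covered ranges and flags, per grid
#' point, whether the two intervals intersect. This is a descriptive
#' comparison of uncertainty bands, not a hypothesis test: full overlap
#' means the re-estimated limits are statistically indistinguishable
#' from the originals, while little or no overlap signals a real change
#' in inter-observer variability.
#'
#' @param a,b [sliding_window_loam()] bands fitted with CIs.
#' @param grid_size number of grid points (default 100).
#' @return An object of class `"band_comparison"`: data.frame `grid`
#'   with both bands' curves and an `overlap` flag, plus
#'   `overlap_fraction` in \[0, 1\].
#' @export
compare_bands <- function(a, b, grid_size = 100) {
  stopifnot(inherits(a, "agreement_band"), inherits(b, "agreement_band"))
  lo <- max(a$volume_range[1], b$volume_range[1])
  hi <- min(a$volume_range[2], b$volume_range[2])
  if (lo > hi)
    stop("invalid input: bands cover disjoint volume ranges")
  grid <- exp(seq(log(lo), log(hi), length.out = grid_size))
  ga <- data.frame(loam_a = predict(a, grid, "loam"),
                   lower_a = predict(a, grid, "lower"),
                   upper_a = predict(a, grid, "upper"))
  gb <- data.frame(loam_b = predict(b, grid, "loam"),
                   lower_b = predict(b, grid, "lower"),
                   upper_b = predict(b, grid, "upper"))
  overlap <- pmax(ga$lower_a, gb$lower_b) <= pmin(ga$upper_a, gb$upper_b)
  structure(
    list(grid = cbind(data.frame(volume_mm3 = grid), ga, gb,
                      data.frame(overlap = overlap)),
         overlap_fraction = mean(overlap)),
    class = "band_comparison")
}

#' @export
print.band_comparison <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<band_comparison> %d grid points over %.4g-%.4g mm^3: CI overlap on %.0f%% of the volume spectrum\n",
    nrow(g), min(g$volume_mm3), max(g$volume_mm3), 100 * x$overlap_fraction))
  invisible(x)
}
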