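#' Volume-dependent agreement band via a sliding window
#'
#' Inter-observer variability in tumor volumetry is typically larger for
#' small structures. The band captures this by sorting subjects by their
#' mean volume, fitting [loam()] on each contiguous window of
#' `window_size` subjects (advancing by `step`), and anchoring each fit
#' at the median mean-volume within its window. Between anchors the LOAM
#' and its CI bounds are interpolated linearly on the log-volume axis;
#' beyond the outermost anchors they are extrapolated as constants.
#'
#' @param dev a [relative_deviations()] table (or a [volume_matrix()]).
#' @param window_size subjects per window (>= 10, <= n; default 40).
#' @param step window advance in subjects (default 1).
#' @inheritParams loam
#' @return An object of class `"agreement_band"`: anchor table
#'   (`volume_mm3`, `loam_pct`, `ci_lower_pct`, `ci_upper_pct`), the
#'   per-window [loam()] fits, the covered volume range, and the
#'   configuration.
#' @seealso [upper_agreement_limit()], [classify_candidate()]
#' @export
sliding_window_loam <- function(dev, window_size = 40, step = 1,
                                z = 1.96, ci = c("gpq", "bootstrap", "none"),
                                n_draws = 2000, seed = NULL) {
  ci <- match.arg(ci)
  if (inherits(dev, "volume_matrix") || (is.matrix(dev) && !inherits(dev, "deviation_table")))
    dev <- relative_deviations(dev)
  stopifnot(inherits(dev, "deviation_table"))
  n <- length(dev$mean_volume)
  if (window_size > n)
    stop("invalid configuration: window_size exceeds the number of subjects")
  if (window_size < 10)
    stop("invalid configuration: window_size must be at least 10")
  ord <- order(dev$mean_volume)
  dev <- subset_deviations(dev, ord)
  starts <- seq(1L, n - window_size + 1L, by = as.integer(step))
  fits <- vector("list", length(starts))
  anchors <- numeric(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + window_size - 1L)
    wseed <- if (is.null(seed)) NULL else (seed + k - 1L) %% .Machine$integer.max
    fits[[k]] <- loam(subset_deviations(dev, idx), z = z, ci = ci,
                      n_draws = n_draws, seed = wseed)
    anchors[k] <- median(dev$mean_volume[idx])
  }
  tab <- data.frame(
    volume_mm3 = anchors,
    loam_pct = vapply(fits, `[[`, numeric(1), "estimate"),
    ci_lower_pct = vapply(fits, `[[`, numeric(1), "ci_lower"),
    ci_upper_pct = vapply(fits, `[[`, numeric(1), "ci_upper"))
  ord_a <- order(tab$volume_mm3)
  structure(
    list(anchors = tab[ord_a, ], fits = fits[ord_a],
         volume_range = range(dev$mean_volume),
         deviations = dev,
         config = list(window_size = window_size, step = step, z = z,
                       ci = ci, n_draws = n_draws, seed = seed)),
    class = "agreement_band")
}

#' @export
print.agreement_band <- function(x, digits = 4, ...) {
  a <- x$anchors
  cat(sprintf(
    "<agreement_band> %d windows of %d subjects (step %d) over %.4g-%.4g mm^3\n",
    nrow(a), x$config$window_size, x$config$step,
    x$volume_range[1], x$volume_range[2]))
  cat(sprintf("  LOAM %.*g-%.*g %%, upper agreement limit %.*g-%.*g %%\n",
              digits, min(a$loam_pct), digits, max(a$loam_pct),
              digits, min(a$ci_upper_pct), digits, max(a$ci_upper_pct)))
  invisible(x)
}

#' Evaluate an agreement band at arbitrary volumes
#'
#' @param object an [sliding_window_loam()] band.
#' @param volume numeric vector of volumes in mm^3 (> 0).
#' @param what which curve: the upper agreement limit (`"upper"`, the
#'   upper 95% CI bound of the LOAM), the LOAM point estimate
#'   (`"loam"`), or the lower CI bound (`"lower"`).
#' @param ... unused.
#' @return Numeric vector of percent values at `volume`.
#' @export
predict.agreement_band <- function(object, volume,
                                   what = c("upper", "loam", "lower"), ...) {
  what <- match.arg(what)
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("invalid input: volumes must be positive")
  a <- object$anchors
  y <- switch(what, upper = a$ci_upper_pct, loam = a$loam_pct,
              lower = a$ci_lower_pct)
  if (what != "loam" && any(is.na(y)))
    stop("band was fitted with ci = \"none\"; CI curves are unavailable")
  if (nrow(a) == 1L) return(rep(y, length(volume)))
  approx(log(a$volume_mm3), y, xout = log(volume), rule = 2, ties = mean)$y
}

#' Upper agreement limit at a given volume
#'
#' The upper bound of the 95% CI of the volume-dependent LOAM: the
#' ostensible maximum percent deviation from the observer mean that can
#' still be attributed to inter-observer variability. Deviations above
#' it indicate annotation error beyond observer disagreement.
#'
#' @param band an [sliding_window_loam()] band.
#' @param volume volume(s) in mm^3.
#' @return Upper agreement limit(s) in percent.
#' @export
upper_agreement_limit <- function(band, volume)
  predict(band, volume, what = "upper")

#' Write an agreement band's curves to CSV
#'
#' @param band an [sliding_window_loam()] band.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_agreement_band <- function(band, file) {
  write.csv(band$anchors[, c("volume_mm3", "loam_pct",
                             "ci_lower_pct", "ci_upper_pct")],
            file, row.names = FALSE)
  invisible(file)
}

#' Agreement plot
#'
#' Mirrors the standard volumetric agreement figure: percent deviation
#' from the observer mean against mean volume on a log axis, one point
#' per subject-observer pair, with the symmetric LOAM band and shaded
#' 95% CI. A second band (e.g. after adding a candidate observer) and
#' candidate deviations can be overlaid.
#'
#' @param x an [sliding_window_loam()] band.
#' @param overlay optional second band drawn in `overlay_col`.
#' @param candidate optional [classify_candidate()] result whose
#'   `delta_v_pct` points are overlaid.
#' @param col,overlay_col band colors.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_band <- function(x, overlay = NULL, candidate = NULL,
                                col = "#2166ac", overlay_col = "#1b7837", ...) {
  dev <- x$deviations
  v <- rep(dev$mean_volume, ncol(dev$deviations))
  d <- as.vector(dev$deviations)
  grid <- exp(seq(log(x$volume_range[1]), log(x$volume_range[2]),
                  length.out = 200))
  has_ci <- !any(is.na(x$anchors$ci_upper_pct))
  up <- predict(x, grid, "loam")
  ylim <- range(d, up, -up,
                if (has_ci) c(predict(x, grid, "upper"), -predict(x, grid, "upper")),
                if (!is.null(candidate)) candidate$delta_v_pct)
  graphics::plot(v, d, log = "x", pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("grey30", 0.6), ylim = ylim,
                 xlab = expression(paste("Mean volume [", mm^3, "]")),
                 ylab = "Deviation from observer mean [%]", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  draw_band <- function(b, bc) {
    lo <- predict(b, grid, "loam")
    graphics::lines(grid, lo, col = bc, lwd = 2)
    graphics::lines(grid, -lo, col = bc, lwd = 2)
    if (!any(is.na(b$anchors$ci_upper_pct))) {
      u <- predict(b, grid, "upper"); l <- predict(b, grid, "lower")
      shade <- grDevices::adjustcolor(bc, 0.2)
      graphics::polygon(c(grid, rev(grid)), c(u, rev(l)), col = shade, border = NA)
      graphics::polygon(c(grid, rev(grid)), c(-u, rev(-l)), col = shade, border = NA)
    }
  }
  draw_band(x, col)
  if (!is.null(overlay)) draw_band(overlay, overlay_col)
  if (!is.null(candidate))
    graphics::points(candidate$mean_human_volume, candidate$delta_v_pct,
                     pch = 17, col = "#b2182b")
  invisible(x)
}
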