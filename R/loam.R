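#' Fit limits of agreement with the mean (LOAM)
#'
#' Estimates the symmetric limit within which a single observer's
#' percent deviation from the observers' mean volume is expected to lie
#' with ~95% probability, generalising Bland-Altman limits of agreement
#' to m >= 2 observers. The deviations `d_ij` (percent, per-subject sum
#' zero) are decomposed as a two-way model `d_ij = b_j + e_ij` with a
#' systematic observer effect `b_j` and residual `e_ij`; variance
#' components are estimated by the ANOVA method of moments (negative
#' estimates truncated at zero) and
#' \deqn{LOAM = z \sqrt{\frac{m-1}{m}(\sigma_{obs}^2 + \sigma_{res}^2)}.}
#' The factor (m-1)/m reflects that a deviation from the mean of m
#' observers, the observer itself included, carries only (m-1)/m of the
#' total observer-plus-residual variance.
#'
#' The 95% confidence interval is computed by a seeded Monte Carlo
#' method. The default, `ci_method = "gpq"`, resamples the two ANOVA
#' mean squares from their scaled chi-square distributions (a
#' generalized-pivotal-quantity construction), which propagates the
#' large sampling error of the observer variance component when m is
#' small. `ci_method = "bootstrap"` is a plug-in parametric bootstrap
#' (percentile interval); it is faster to reason about but undercovers
#' at small m because it treats the estimated components as known.
#'
#' @param x a [relative_deviations()] table, a [volume_matrix()], or a
#'   plain positive matrix of volumes (subjects x observers).
#' @param z normal quantile for the limit (default 1.96, the two-sided
#'   95% level).
#' @param ci one of `"gpq"`, `"bootstrap"`, `"none"`.
#' @param n_draws Monte Carlo draws for the CI (default 2000).
#' @param seed optional integer; fixes the CI draws without disturbing
#'   the caller's RNG stream.
#' @param ... passed between methods.
#' @return An object of class `"loam"` with components `estimate`
#'   (percent), `sigma_obs2`, `sigma_res2`, `ms_obs`, `ms_res`, `m`, `n`,
#'   `z`, `ci_lower`, `ci_upper`, `ci_method`, `n_draws`, `seed`,
#'   `observer_effects`, and the deviation table used.
#' @examples
#' vm <- simulate_volume_matrix(simulation_config(n_subjects = 40, seed = 1))
#' fit <- loam(vm$volumes, seed = 1)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
loam <- function(x, ...) UseMethod("loam")

#' @rdname loam
#' @export
loam.deviation_table <- function(x, z = 1.96, ci = c("gpq", "bootstrap", "none"),
                                 n_draws = 2000, seed = NULL, ...) {
  ci <- match.arg(ci)
  D <- x$deviations
  n <- nrow(D); m <- ncol(D)
  if (is.null(n) || n < 2L || m < 2L)
    stop("insufficient data: LOAM needs at least 2 subjects and 2 observers")
  est <- loam_moments(D, z)
  fit <- structure(
    c(est,
      list(m = m, n = n, z = z, ci_method = ci,
           n_draws = if (ci == "none") 0L else as.integer(n_draws),
           seed = seed, deviations = x,
           ci_lower = NA_real_, ci_upper = NA_real_)),
    class = "loam")
  if (ci != "none" && est$estimate == 0 && est$sigma_obs2 == 0 &&
      est$sigma_res2 == 0) {
    fit$ci_lower <- fit$ci_upper <- 0   # degenerate: no variability at all
  } else if (ci != "none") {
    cib <- with_seed(seed, loam_ci(fit, method = ci, n_draws = n_draws))
    fit$ci_lower <- cib[1]; fit$ci_upper <- cib[2]
  }
  fit
}

#' @rdname loam
#' @export
loam.volume_matrix <- function(x, ...) loam(relative_deviations(x), ...)

#' @rdname loam
#' @export
loam.matrix <- function(x, ...) loam(relative_deviations(volume_matrix(x)), ...)

# ANOVA method-of-moments variance components on an n x m percent
# deviation matrix whose rows sum to zero (subject effect already removed
# by the deviation construction).
loam_moments <- function(D, z) {
  n <- nrow(D); m <- ncol(D)
  dbar_j <- colMeans(D)
  ms_obs <- n * sum((dbar_j - mean(dbar_j))^2) / (m - 1)
  ms_res <- sum(sweep(D, 2, dbar_j)^2) / ((n - 1) * (m - 1))
  sigma_res2 <- ms_res
  sigma_obs2 <- max(0, (ms_obs - ms_res) / n)
  list(estimate = z * sqrt(((m - 1) / m) * (sigma_obs2 + sigma_res2)),
       sigma_obs2 = sigma_obs2, sigma_res2 = sigma_res2,
       ms_obs = ms_obs, ms_res = ms_res,
       observer_effects = dbar_j)
}

loam_ci <- function(fit, method, n_draws) {
  n <- fit$n; m <- fit$m; z <- fit$z
  df_obs <- m - 1; df_res <- (n - 1) * (m - 1)
  draws <- if (method == "gpq") {
    # Resample the mean squares from their sampling distributions
    # (balanced two-way normal model): MS ~ E[MS] * chisq(df) / df,
    # inverted at the observed values.
    e2 <- df_res * fit$ms_res / rchisq(n_draws, df_res)
    eo <- df_obs * fit$ms_obs / rchisq(n_draws, df_obs)
    b2 <- pmax(0, (eo - e2) / n)
    z * sqrt(((m - 1) / m) * (b2 + e2))
  } else {
    so <- sqrt(fit$sigma_obs2); se <- sqrt(fit$sigma_res2)
    vapply(seq_len(n_draws), function(i) {
      Ds <- sweep(matrix(rnorm(n * m, 0, se), n, m), 2, rnorm(m, 0, so), "+")
      Ds <- Ds - rowMeans(Ds)
      loam_moments(Ds, z)$estimate
    }, numeric(1))
  }
  quantile(draws, c(0.025, 0.975), type = 7, names = FALSE)
}

#' @export
print.loam <- function(x, digits = 4, ...) {
  cat("Limits of agreement with the mean\n")
  cat(sprintf("  n = %d subjects, m = %d observers, z = %g\n", x$n, x$m, x$z))
  cat(sprintf("  LOAM: +/- %.*g %%", digits, x$estimate))
  if (!is.na(x$ci_lower))
    cat(sprintf("  (95%% CI %.*g - %.*g, %s, %d draws)",
                digits, x$ci_lower, digits, x$ci_upper, x$ci_method, x$n_draws))
  cat("\n")
  invisible(x)
}

#' @export
summary.loam <- function(object, ...) {
  structure(list(fit = object), class = "summary.loam")
}

#' @export
print.summary.loam <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("  variance components (pct^2): observer %.*g, residual %.*g\n",
              digits, f$sigma_obs2, digits, f$sigma_res2))
  cat("  systematic observer effects (pct):\n")
  print(round(f$observer_effects, digits))
  invisible(x)
}

#' @export
coef.loam <- function(object, ...) {
  c(loam = object$estimate,
    sigma_obs = sqrt(object$sigma_obs2),
    sigma_res = sqrt(object$sigma_res2))
}

#' @export
confint.loam <- function(object, parm = "loam", level = 0.95, ...) {
  if (!isTRUE(all.equal(level, 0.95)))
    stop("only the 95% interval is computed at fit time")
  out <- matrix(c(object$ci_lower, object$ci_upper), 1,
                dimnames = list("loam", c("2.5 %", "97.5 %")))
  out
}

#' @export
residuals.loam <- function(object, ...) {
  sweep(object$deviations$deviations, 2, object$observer_effects)
}

#' Simulate deviation matrices from a fitted LOAM model
#'
#' Draws new observer effects and residuals from the fitted normal
#' components and row-centers them, mimicking the deviation-from-mean
#' construction.
#'
#' @param object a fitted [loam()] object.
#' @param nsim number of matrices.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` deviation matrices (percent, n x m).
#' @export
simulate.loam <- function(object, nsim = 1, seed = NULL, ...) {
  n <- object$n; m <- object$m
  so <- sqrt(object$sigma_obs2); se <- sqrt(object$sigma_res2)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    Ds <- sweep(matrix(rnorm(n * m, 0, se), n, m), 2, rnorm(m, 0, so), "+")
    Ds - rowMeans(Ds)
  }))
}
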