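# Fixture builders and independent brute-force oracles for the
# geometric metrics. The oracles deliberately use naive element-wise
# loops and a hand-written percentile formula so they share no code
# path with the package implementation.

mask_from_indices <- function(dim, idx, spacing = c(1, 1, 1), ...) {
  v <- array(0L, dim)
  if (length(idx)) v[idx] <- 1L
  label_map(v, spacing, ...)
}

cube_mask <- function(dim, from, to, spacing = c(1, 1, 1)) {
  v <- array(0L, dim)
  v[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- 1L
  label_map(v, spacing)
}

# random blob: threshold of iid uniforms, retried until nonempty
random_mask <- function(dim, spacing = c(1, 1, 1), p = 0.2) {
  repeat {
    v <- array(as.integer(runif(prod(dim)) < p), dim)
    if (sum(v) > 0) return(label_map(v, spacing))
  }
}

# brute-force surface voxels: check all 6 face neighbours of every
# foreground voxel explicitly
oracle_surface <- function(mask) {
  v <- mask$voxels; d <- dim(v); sp <- mask$spacing
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (v[i, j, k] != 1L) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_surface <- FALSE
    for (q in nb) {
      if (any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3] ||
          v[q[1], q[2], q[3]] == 0L) { on_surface <- TRUE; break }
    }
    if (on_surface)
      out <- rbind(out, (c(i, j, k) - 1) * sp)
  }
  out
}

# exhaustive pooled directed surface distances
oracle_pooled_distances <- function(a, b) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  d_ab <- apply(sa, 1, function(p)
    sqrt(min(colSums((t(sb) - p)^2))))
  d_ba <- apply(sb, 1, function(p)
    sqrt(min(colSums((t(sa) - p)^2))))
  c(d_ab, d_ba)
}

# percentile with linear interpolation between order statistics,
# written out from the definition: h = (n-1)p + 1
oracle_pctl <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ANOVA mean squares via stats::aov on the long-format deviations; an
# independent route to the variance components used by loam()
oracle_loam <- function(D, z = 1.96) {
  n <- nrow(D); m <- ncol(D)
  long <- data.frame(d = as.vector(D),
                     subject = factor(rep(seq_len(n), m)),
                     observer = factor(rep(seq_len(m), each = n)))
  ms <- summary(stats::aov(d ~ subject + observer, data = long))[[1]]
  ms_obs <- ms["observer", "Mean Sq"]
  ms_res <- ms["Residuals", "Mean Sq"]
  s_res2 <- ms_res
  s_obs2 <- max(0, (ms_obs - ms_res) / n)
  z * sqrt(((m - 1) / m) * (s_obs2 + s_res2))
}
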