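test_that("generators are seed-deterministic and leave the RNG alone", {
  cfg <- simulation_config(n_subjects = 20, seed = 11)
  s1 <- simulate_volume_matrix(cfg)
  s2 <- simulate_volume_matrix(cfg)
  expect_identical(unclass(s1$volumes), unclass(s2$volumes))
  expect_identical(simulate_candidate(s1), simulate_candidate(s2))
  s3 <- simulate_volume_matrix(simulation_config(n_subjects = 20, seed = 12))
  expect_false(identical(unclass(s1$volumes), unclass(s3$volumes)))
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_volume_matrix(cfg))
  expect_identical(rnorm(1), before)
})

test_that("zero observer noise collapses to identical columns and zero LOAM", {
  sim <- simulate_volume_matrix(
    simulation_config(n_subjects = 15, sigma_obs = 0, sigma_res = 0, seed = 1))
  expect_equal(apply(sim$volumes, 1, function(r) diff(range(r))),
               rep(0, 15), ignore_attr = TRUE)
  expect_equal(loam(sim$volumes)$estimate, 0)
  expect_equal(sim$true_loam_pct, 0)
})

test_that("default volume distribution matches the emulated test set", {
  # median tumor volume 903 mm^3 with IQR 193-3,101: the sample median
  # of a default draw must fall inside that IQR
  for (s in 1:3) {
    sim <- simulate_volume_matrix(simulation_config(seed = s))
    expect_gt(median(sim$true_volumes), 193)
    expect_lt(median(sim$true_volumes), 3101)
  }
})

test_that("empirical spreads converge to the configured values at large n", {
  sim <- simulate_volume_matrix(
    simulation_config(n_subjects = 10000, seed = 21))
  expect_equal(sd(log(sim$true_volumes)), 2.06, tolerance = 0.05)
  # residual spread on the percent scale ~ 100 * sigma_res
  fit <- loam(sim$volumes, ci = "none")
  expect_equal(sqrt(fit$sigma_res2), 100 * 0.05, tolerance = 0.05)
  expect_equal(sim$true_loam_pct, 10.222, tolerance = 1e-3)
})

test_that("candidate bias translates into the expected mean deviation", {
  # pure +25% bias, no candidate noise: mean delta_v over subjects is
  # ~ 100*(1.25 * E[1/mean_j exp(b_j+e_ij)] - 1), i.e. just under 25%
  devs <- sapply(1:20, function(s) {
    sim <- simulate_volume_matrix(simulation_config(n_subjects = 200, seed = s))
    cand <- simulate_candidate(sim, bias = 25, candidate_sd = 0)
    mean(delta_v_percent(cand, rowMeans(sim$volumes)))
  })
  expect_equal(mean(devs), 24.9, tolerance = 0.04)  # +/- ~1 pp
  # truth as candidate: deviations reflect minus the mean observer
  # error, centering near zero
  # (the shared observer-mean shift exp(-bbar) varies between panels,
  # so average over panels)
  d0 <- sapply(1:10, function(s) {
    sim <- simulate_volume_matrix(simulation_config(n_subjects = 500, seed = s))
    cand0 <- simulate_candidate(sim, bias = 0, candidate_sd = 0)
    expect_identical(unname(cand0), unname(sim$true_volumes))
    mean(delta_v_percent(cand0, rowMeans(sim$volumes)))
  })
  expect_lt(abs(mean(d0)), 1.5)
})

test_that("phantom masks honour the noise-free and analytic-volume cases", {
  cfg0 <- phantom_config(dim = c(24, 24, 24), semi_axes = c(6, 5, 4),
                         boundary_noise_sd = 0, seed = 2)
  ph <- simulate_observer_masks(cfg0, n_subjects = 1, m_observers = 3)
  s <- ph$subjects[[1]]
  for (o in s$observers) {
    expect_identical(o$voxels, s$truth$voxels)
    expect_equal(dice(s$truth, o), 100)
    expect_equal(assd(s$truth, o), 0)
  }
  vol_analytic <- 4 / 3 * pi * 6 * 5 * 4
  expect_lt(abs(volume_mm3(s$truth) - vol_analytic) / vol_analytic, 0.15)
  # recorded volumes agree exactly with the mask-derived count
  expect_equal(s$volumes[["truth"]], volume_mm3(s$truth))
  expect_equal(s$volumes[["O1"]], volume_mm3(s$observers[[1]]))
})

test_that("stronger boundary noise increases mean pairwise surface distance", {
  mean_assd <- function(noise_sd) {
    out <- numeric(5)
    for (r in 1:5) {
      cfg <- phantom_config(dim = c(28, 28, 28), semi_axes = c(6, 5, 5),
                            boundary_noise_sd = noise_sd, seed = 100 + r)
      ph <- simulate_observer_masks(cfg, n_subjects = 1, m_observers = 3)
      pm <- pairwise_metrics(ph$subjects[[1]]$observers)
      out[r] <- mean(pm$assd_mm)
    }
    mean(out)
  }
  a0 <- mean_assd(0.2); a1 <- mean_assd(0.8); a2 <- mean_assd(1.6)
  expect_lt(a0, a1)
  expect_lt(a1, a2)
})

test_that("configuration errors are caught up front", {
  expect_error(simulation_config(n_subjects = 1), "configuration")
  expect_error(simulation_config(sigma_obs = -1), "configuration")
  expect_error(simulation_config(median_volume = 0), "configuration")
  expect_error(simulation_config(observer_biases = c(0, 0)), "configuration")
  expect_error(phantom_config(dim = c(16, 16, 16), semi_axes_range = c(5, 30)),
               "exceed")
  expect_error(phantom_config(spacing = c(0, 1, 1)), "configuration")
  expect_error(phantom_config(semi_axes_range = c(0.5, 3)), "exceed")
})
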