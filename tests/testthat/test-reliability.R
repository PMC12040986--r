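test_that("delta_v is the signed percent deviation from the consensus", {
  expect_equal(delta_v_percent(1000, 1000), 0)
  expect_equal(delta_v_percent(1100, 1000), 10)
  expect_equal(delta_v_percent(800, 1000), -20)
  expect_error(delta_v_percent(100, 0), "> 0")
})

make_eval_fixture <- function(seed = 1, n = 50) {
  sim <- simulate_volume_matrix(simulation_config(n_subjects = n, seed = seed))
  band <- sliding_window_loam(relative_deviations(sim$volumes),
                              window_size = min(40, n), step = 5,
                              n_draws = 200, seed = seed)
  list(sim = sim, band = band)
}

test_that("a candidate equal to the consensus is always comparable", {
  fx <- make_eval_fixture(1)
  cand <- rowMeans(fx$sim$volumes)
  cls <- classify_candidate(cand, fx$sim$volumes, fx$band)
  expect_true(all(cls$comparable))
  expect_equal(cls$delta_v_pct, rep(0, nrow(cls)))
  expect_true(all(is.na(cls$exceedance_pp)))
})

test_that("candidate alignment is by subject id and validated", {
  fx <- make_eval_fixture(2, n = 20)
  cand <- rowMeans(fx$sim$volumes)
  names(cand) <- rownames(fx$sim$volumes)
  # shuffled names still align correctly
  cls <- classify_candidate(sample(cand), fx$sim$volumes, fx$band)
  expect_equal(cls$delta_v_pct, rep(0, 20))
  expect_error(classify_candidate(cand[-3], fx$sim$volumes, fx$band),
               "alignment error")
  df <- data.frame(subject_id = names(cand), volume_mm3 = unname(cand))
  cls2 <- classify_candidate(df, fx$sim$volumes, fx$band)
  expect_equal(cls2$comparable, cls$comparable)
})

test_that("the one-sided rule never flags under-segmentation; two-sided does", {
  fx <- make_eval_fixture(3, n = 30)
  cand <- rowMeans(fx$sim$volumes) * 0.4   # 60% under the consensus
  one <- classify_candidate(cand, fx$sim$volumes, fx$band, rule = "one_sided")
  expect_true(all(one$comparable))
  expect_true(all(one$delta_v_pct < 0))
  two <- classify_candidate(cand, fx$sim$volumes, fx$band, rule = "two_sided")
  expect_false(any(two$comparable))
  expect_true(all(two$exceedance_pp > 0))
})

test_that("exceedance is positive and equals deviation minus the limit", {
  fx <- make_eval_fixture(4, n = 30)
  cand <- rowMeans(fx$sim$volumes) * 1.5
  cls <- classify_candidate(cand, fx$sim$volumes, fx$band)
  inc <- !cls$comparable
  expect_true(any(inc))
  expect_equal(cls$exceedance_pp[inc],
               cls$delta_v_pct[inc] - cls$upper_limit_pct[inc])
  expect_true(all(cls$exceedance_pp[inc] > 0))
})

test_that("quartile summary partitions subjects with ties going low", {
  fx <- make_eval_fixture(5, n = 100)
  cand <- simulate_candidate(fx$sim)
  cls <- classify_candidate(cand, fx$sim$volumes, fx$band)
  qs <- quartile_summary(cls)
  expect_equal(qs$n[qs$quartile != "All"], rep(25L, 4))
  expect_equal(sum(qs$n[qs$quartile != "All"]), qs$n[qs$quartile == "All"])
  expect_equal(qs$n_comparable + qs$n_incomparable, qs$n)
  # forced small case: volumes 1..8, incomparable exactly subjects 1 and 2
  res <- data.frame(
    subject_id = paste0("S", 1:8),
    mean_human_volume = 1:8,
    candidate_volume = 1:8, delta_v_pct = 0, upper_limit_pct = 10,
    comparable = c(FALSE, FALSE, rep(TRUE, 6)),
    exceedance_pp = c(5, 3, rep(NA, 6)))
  qs8 <- quartile_summary(res)
  expect_equal(qs8$n[1:4], c(2L, 2L, 2L, 2L))
  expect_equal(qs8$n_incomparable[1:4], c(2L, 0L, 0L, 0L))
  expect_equal(qs8$exceedance_median_pp[1], 4)
  expect_error(quartile_summary(res[1:3, ]), "at least 4")
})

test_that("exceedance summaries are computed among incomparable subjects only", {
  res <- data.frame(
    subject_id = paste0("S", 1:8), mean_human_volume = 1:8,
    candidate_volume = 1:8, delta_v_pct = 0, upper_limit_pct = 10,
    comparable = rep(c(TRUE, FALSE), 4),
    exceedance_pp = rep(c(NA, 7), 4))
  qs <- quartile_summary(res)
  expect_equal(qs$exceedance_median_pp[qs$quartile == "All"], 7)
  all_comp <- transform(res, comparable = TRUE, exceedance_pp = NA_real_)
  qs2 <- quartile_summary(all_comp)
  expect_true(all(is.na(qs2$exceedance_median_pp)))
  expect_equal(qs2$n_incomparable, rep(0L, 5))
})

test_that("refitting with a duplicated observer barely moves the band", {
  fx <- make_eval_fixture(6, n = 60)
  dup <- fx$sim$volumes[, 1]
  names(dup) <- rownames(fx$sim$volumes)
  refit <- refit_with_candidate(fx$sim$volumes, dup, window_size = 40,
                                step = 5, n_draws = 200, seed = 6)
  grid <- exp(seq(log(fx$band$volume_range[1]),
                  log(fx$band$volume_range[2]), length.out = 30))
  d <- predict(refit, grid, "loam") - predict(fx$band, grid, "loam")
  expect_lt(max(abs(d)), 3)  # pct points; same deviation structure
})

test_that("band comparison flags CI overlap pointwise", {
  fx <- make_eval_fixture(7, n = 40)
  self <- compare_bands(fx$band, fx$band)
  expect_equal(self$overlap_fraction, 1)
  shift <- function(b, by) {
    b$anchors$ci_lower_pct <- b$anchors$ci_lower_pct + by
    b$anchors$ci_upper_pct <- b$anchors$ci_upper_pct + by
    b
  }
  apart <- compare_bands(fx$band, shift(fx$band, 1000))
  expect_equal(apart$overlap_fraction, 0)
  disjoint <- fx$band
  disjoint$volume_range <- fx$band$volume_range * 1e9
  expect_error(compare_bands(fx$band, disjoint), "disjoint")
})
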