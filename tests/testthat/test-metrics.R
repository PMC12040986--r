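test_that("dice handles identity, disjoint, partial and empty cases", {
  a <- cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2))
  expect_equal(dice(a, a), 100)
  b <- cube_mask(c(6, 6, 6), c(4, 4, 4), c(5, 5, 5))
  expect_equal(dice(a, b), 0)
  # |A|=4, |B|=4, |A n B| = 2
  x <- mask_from_indices(c(4, 4, 4), 1:4)
  y <- mask_from_indices(c(4, 4, 4), 3:6)
  expect_equal(dice(x, y), 50)
  e <- mask_from_indices(c(6, 6, 6), integer(0))
  expect_equal(dice(e, e), 100)
  expect_equal(dice(a, e), 0)
  expect_error(dice(a, cube_mask(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))),
               "lattice")
  expect_error(dice(a, cube_mask(c(6, 6, 6), c(1, 1, 1), c(2, 2, 2),
                                 spacing = c(2, 1, 1))), "spacing")
})

test_that("rve is the absolute relative volume difference in percent", {
  expect_equal(rve(1000, 1000), 0)
  expect_equal(rve(1125, 1000), 12.5)
  expect_equal(rve(750, 1000), 25)
  expect_error(rve(100, 0), "> 0")
})

test_that("surface voxels follow the 6-connectivity boundary definition", {
  single <- mask_from_indices(c(5, 5, 5), 63L)  # voxel (3,3,3)
  s <- surface_voxels(single)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(2, 2, 2))
  c3 <- cube_mask(c(5, 5, 5), c(2, 2, 2), c(4, 4, 4))
  expect_equal(nrow(surface_voxels(c3)), 26L)
  c5 <- cube_mask(c(7, 7, 7), c(2, 2, 2), c(6, 6, 6))
  expect_equal(nrow(surface_voxels(c5)), 98L)
  expect_error(surface_voxels(mask_from_indices(c(3, 3, 3), integer(0))),
               "empty")
  # array border counts as background: a full lattice is all surface on
  # the faces only
  full <- label_map(array(1L, c(4, 4, 4)))
  expect_equal(nrow(surface_voxels(full)), 64 - 8)
})

test_that("surface extraction matches the brute-force neighbour oracle", {
  set.seed(21)
  for (i in 1:10) {
    m <- random_mask(c(8, 7, 6), spacing = c(1, 0.7, 1.3))
    got <- surface_voxels(m)
    want <- oracle_surface(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 unname(want[order(want[, 1], want[, 2], want[, 3]), ,
                             drop = FALSE]),
                 ignore_attr = TRUE)
  }
})

test_that("assd and hd95 match forced small cases", {
  a <- mask_from_indices(c(8, 3, 3), 2)       # voxel (2,1,1)
  b <- mask_from_indices(c(8, 3, 3), 5)       # voxel (5,1,1): 3 apart in x
  expect_equal(assd(a, b), 3.0)
  c1 <- mask_from_indices(c(8, 3, 3), 1)
  c2 <- mask_from_indices(c(8, 3, 3), 3)
  expect_equal(hd95(c1, c2), 2.0)
  cu <- cube_mask(c(8, 8, 8), c(2, 2, 2), c(4, 4, 4))
  expect_equal(assd(cu, cu), 0)
  expect_equal(hd95(cu, cu), 0)
  e <- mask_from_indices(c(8, 8, 8), integer(0))
  expect_error(assd(cu, e), "nonempty")
  expect_error(hd95(e, cu), "nonempty")
})

test_that("shifted-cube distances equal the exhaustive oracle", {
  a <- cube_mask(c(9, 9, 9), c(2, 2, 2), c(4, 4, 4))
  b <- cube_mask(c(9, 9, 9), c(3, 2, 2), c(5, 4, 4))  # shifted 1 voxel in x
  pooled <- oracle_pooled_distances(a, b)
  expect_equal(assd(a, b), mean(pooled), tolerance = 1e-12)
  expect_equal(hd95(a, b), oracle_pctl(pooled, 0.95), tolerance = 1e-12)
})

test_that("metrics are symmetric, bounded, and spacing-covariant", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_mask(c(7, 7, 7))
    b <- random_mask(c(7, 7, 7))
    expect_equal(dice(a, b), dice(b, a))
    expect_gte(dice(a, b), 0); expect_lte(dice(a, b), 100)
    expect_equal(assd(a, b), assd(b, a))
    expect_equal(hd95(a, b), hd95(b, a))
    pooled <- oracle_pooled_distances(a, b)
    expect_gte(hd95(a, b), min(pooled) - 1e-12)
    expect_lte(hd95(a, b), max(pooled) + 1e-12)  # <= exact Hausdorff
    # scaling spacing by k scales distances by k, volume by k^3
    k <- 2.5
    ak <- label_map(a$voxels, a$spacing * k)
    bk <- label_map(b$voxels, b$spacing * k)
    expect_equal(assd(ak, bk), k * assd(a, b), tolerance = 1e-12)
    expect_equal(hd95(ak, bk), k * hd95(a, b), tolerance = 1e-12)
    expect_equal(volume_mm3(ak), k^3 * volume_mm3(a), tolerance = 1e-9)
    expect_equal(dice(ak, bk), dice(a, b))
  }
})

test_that("pairwise metrics enumerate observer pairs and candidate rows", {
  set.seed(41)
  masks <- lapply(1:5, function(j) {
    m <- random_mask(c(6, 6, 6))
    m$observer_id <- paste0("O", j); m$subject_id <- "S1"; m
  })
  pp <- pairwise_metrics(masks)
  expect_equal(nrow(pp), choose(5, 2))
  cand <- masks[[1]]; cand$observer_id <- "AI"
  pc <- pairwise_metrics(masks, candidate = cand)
  expect_equal(nrow(pc), 5)
  expect_equal(pc$observer_a, rep("AI", 5))
  # identical pair scores identity values
  ident <- pairwise_metrics(list(masks[[2]], masks[[2]]))
  expect_equal(ident$dice_pct, 100)
  expect_equal(ident$assd_mm, 0)
  expect_equal(ident$hd95_mm, 0)
  expect_equal(ident$rve_pct, 0)
  expect_error(pairwise_metrics(masks[1]), "at least 2")
})

test_that("empty masks yield NA surface metrics, never silent zeros", {
  e <- mask_from_indices(c(5, 5, 5), integer(0))
  m <- cube_mask(c(5, 5, 5), c(2, 2, 2), c(3, 3, 3))
  out <- pairwise_metrics(list(e, m))
  expect_true(is.na(out$assd_mm))
  expect_true(is.na(out$hd95_mm))
  expect_equal(out$rve_pct, 100)   # empty prediction vs nonempty reference
  expect_equal(out$dice_pct, 0)
  # an empty *reference* makes RVE undefined
  rev_out <- pairwise_metrics(list(m, e))
  expect_true(is.na(rev_out$rve_pct))
})
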