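test_that("two-sample contrast of identical groups finds nothing", {
  set.seed(9)
  m <- stats::rnorm(25, mean = 4)
  a <- lapply(1:3, function(i) mock_tmap(m + stats::rnorm(25, sd = 0.1),
                                         paste0("a", i)))
  ct <- two_sample_perm(a, a, n_perm = 200, seed = 3)
  expect_identical(sum(ct$specific), 0L)
})

test_that("exhaustive relabeling reproduces the closed-form minimum p", {
  # one voxel separated by a large constant, 3 vs 3: C(6,3) = 20
  # relabelings enumerated, so the minimal one-tailed FWE p is 1/20
  a <- lapply(1:3, function(i) mock_tmap(c(50, 0, 0), paste0("a", i)))
  b <- lapply(1:3, function(i) mock_tmap(c(0, 0, 0), paste0("b", i)))
  ct <- two_sample_perm(a, b, n_perm = 5000, seed = 1)
  expect_true(ct$result$exhaustive)
  expect_identical(ct$result$n_perm, 20L)
  expect_equal(ct$result$fwe_p[1], 1 / 20)  # minimal attainable p at 3 vs 3

  # independent relabeling oracle on noisy data
  set.seed(31)
  xa <- matrix(stats::rnorm(4 * 3, mean = 2), nrow = 4)
  xb <- matrix(stats::rnorm(4 * 3), nrow = 4)
  a2 <- lapply(1:3, function(i) mock_tmap(xa[, i], paste0("a", i)))
  b2 <- lapply(1:3, function(i) mock_tmap(xb[, i], paste0("b", i)))
  ct2 <- two_sample_perm(a2, b2, n_perm = 5000, seed = 1)
  x <- cbind(xa, xb)
  combos <- utils::combn(6, 3)
  tfun <- function(ga, gb) {
    sp <- ((length(ga) - 1) * stats::var(ga) + (length(gb) - 1) * stats::var(gb)) /
      (length(ga) + length(gb) - 2)
    (mean(ga) - mean(gb)) / sqrt(sp * (1 / length(ga) + 1 / length(gb)))
  }
  max_t <- apply(combos, 2, function(j)
    max(vapply(1:4, function(v) tfun(x[v, j], x[v, -j]), 0)))
  obs <- vapply(1:4, function(v) tfun(x[v, 1:3], x[v, 4:6]), 0)
  oracle_p <- vapply(obs, function(o) sum(max_t >= o) / 20, 0)
  expect_equal(ct2$result$fwe_p, oracle_p, tolerance = 1e-10)
})

test_that("swapping the groups negates the observed statistic", {
  set.seed(17)
  a <- lapply(1:4, function(i) mock_tmap(stats::rnorm(15, 1), paste0("a", i)))
  b <- lapply(1:4, function(i) mock_tmap(stats::rnorm(15), paste0("b", i)))
  ab <- two_sample_perm(a, b, n_perm = 100, seed = 5)
  ba <- two_sample_perm(b, a, n_perm = 100, seed = 5)
  expect_equal(ab$result$observed, -ba$result$observed, tolerance = 1e-12)
  expect_error(two_sample_perm(a[1], b, n_perm = 10), "at least 2")
})

test_that("pooled and Welch statistics agree with stats::t.test", {
  set.seed(23)
  xa <- matrix(stats::rnorm(6 * 4, mean = 1, sd = 2), nrow = 6)
  xb <- matrix(stats::rnorm(6 * 5), nrow = 6)
  a <- lapply(1:4, function(i) mock_tmap(xa[, i], paste0("a", i)))
  b <- lapply(1:5, function(i) mock_tmap(xb[, i], paste0("b", i)))
  pooled <- two_sample_perm(a, b, n_perm = 50, seed = 1, pooled = TRUE)
  welch <- two_sample_perm(a, b, n_perm = 50, seed = 1, pooled = FALSE)
  for (v in 1:6) {
    expect_equal(pooled$result$observed[v],
                 unname(stats::t.test(xa[v, ], xb[v, ],
                                      var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    expect_equal(welch$result$observed[v],
                 unname(stats::t.test(xa[v, ], xb[v, ])$statistic),
                 tolerance = 1e-10)
  }
})

test_that("spatial correlation matches the hand oracle and rejects constants", {
  expect_equal(spatial_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  x <- c(0.3, -1, 2, 0.5)
  expect_equal(spatial_correlation(x, x), 1)
  expect_equal(spatial_correlation(x, -x), -1)
  expect_error(spatial_correlation(x, rep(1, 4)), "constant")
  expect_error(spatial_correlation(x[1:2], x[1:2]), "fewer than 3")
  g <- tiny_grid(3)
  v1 <- volume(array(seq_len(27), dim = rep(3, 3)), g)
  v2 <- volume(array(rev(seq_len(27)), dim = rep(3, 3)), g)
  expect_equal(spatial_correlation(v1, v2), -1)
})

test_that("leave-k-out subsets are distinct, reproducible, and exact at k = 0", {
  set.seed(41)
  tmaps <- lapply(1:8, function(i)
    mock_tmap(stats::rnorm(30, mean = 5, sd = 3), paste0("c", i)))
  r0 <- leave_k_out_stability(tmaps, k = 0, n_subsets = 1, seed = 2,
                              t_threshold = 4)
  expect_equal(r0$correlations, 1)

  r2 <- leave_k_out_stability(tmaps, k = 2, n_subsets = 20, seed = 2,
                              t_threshold = 4)
  expect_length(r2$correlations, 20L)
  r2b <- leave_k_out_stability(tmaps, k = 2, n_subsets = 20, seed = 2,
                               t_threshold = 4)
  expect_identical(r2$correlations, r2b$correlations)
  expect_true(all(r2$correlations >= -1 & r2$correlations <= 1))

  expect_error(leave_k_out_stability(tmaps, k = 2, n_subsets = 50),
               "distinct subsets")
  expect_error(leave_k_out_stability(tmaps, k = 8, n_subsets = 1), "k")
})

test_that("stability degrades monotonically with more cases left out", {
  st <- planted_study_cached()
  prof <- stability_profile(st$tmaps, ks = c(5, 9), n_subsets = 100, seed = 11)
  med <- prof$summary$median
  expect_gte(med[1], med[2])
  expect_true(all(prof$summary$median > 0.9))
})

test_that("the planted hub is specific to the lesion cohort, not to control spheres", {
  st <- planted_study_cached()
  grid <- st$grid
  grey <- grey_shell_mask(grid)
  # sphere radius scaled to the desk-scale brain (12 mm on a real
  # template is ~1/6 of the hemispheric extent)
  sph <- generate_sphere_cohort(grid, sphere_cohort_spec(grey, n_masks = 100,
                                                         radius_mm = 4,
                                                         seed = 7))
  stm <- cohort_tmaps(st$connectome, sph)
  ct <- two_sample_perm(st$tmaps, stm, n_perm = 500, seed = 8)
  expect_gt(sum(ct$specific & st$hub_mask), 0)

  # under random label shuffling the specific set appears at most at
  # the nominal rate (binomial 99% bound over 12 runs at alpha 0.05)
  pool <- c(st$tmaps, stm)
  hits <- vapply(1:12, function(i) {
    set.seed(100 + i)
    lab <- sample(length(pool))
    cs <- two_sample_perm(pool[lab[1:23]], pool[lab[-(1:23)]],
                          n_perm = 250, seed = 300 + i)
    sum(cs$specific) > 0
  }, TRUE)
  expect_lte(sum(hits), stats::qbinom(0.99, 12, 0.05))
})
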