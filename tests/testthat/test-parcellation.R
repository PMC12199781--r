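# a small connectome in which every target voxel carries exactly one
# cortical ROI group's latent signal
planted_parcellation <- function(noise_sd = 1e-4, n_subjects = 5, seed = 42) {
  g <- volume_grid(c(10, 10, 10))
  idx <- in_mask_indices(g)
  roi_vox <- split(idx[1:80], rep(1:4, each = 20))
  tgt_vox <- idx[101:180]
  tgt_assign <- rep(1:4, each = 20)
  regions <- c(roi_vox, lapply(1:4, function(k) tgt_vox[tgt_assign == k]))
  spec <- network_spec(regions, coupling = 1, noise_sd = noise_sd,
                       n_timepoints = 30, latent = c(1:4, 1:4))
  conn <- generate_connectome(g, n_subjects, spec, seed = seed)
  roi_lab <- array(0, g$dims)
  for (k in 1:4) roi_lab[roi_vox[[k]]] <- k
  tgt <- array(0, g$dims)
  tgt[tgt_vox] <- 1
  list(grid = g, conn = conn, roi = volume(roi_lab, g, kind = "count"),
       target = volume(tgt, g, kind = "binary"), tgt_vox = tgt_vox,
       tgt_assign = tgt_assign, roi_vox = roi_vox)
}

test_that("winner-takes-all recovers a noiseless planted assignment completely", {
  pp <- planted_parcellation()
  atlas <- winner_takes_all(pp$conn, pp$roi, pp$target)
  expect_identical(atlas$label_map$data[pp$tgt_vox], as.numeric(pp$tgt_assign))
  expect_identical(sum(atlas$tie_flags$data), 0)
  # subject order must not matter
  conn_rev <- connectome(rev(pp$conn$subjects), pp$grid)
  atlas_rev <- winner_takes_all(conn_rev, pp$roi, pp$target)
  expect_identical(atlas_rev$label_map$data, atlas$label_map$data)
})

test_that("exact correlation ties go to the lowest label and are flagged", {
  g <- volume_grid(c(6, 6, 6))
  idx <- in_mask_indices(g)
  roi_vox <- split(idx[1:40], rep(1:4, each = 10))
  tgt_vox <- idx[51:60]
  # all four ROI groups carry literally the same series, so every
  # target voxel ties exactly across the four labels
  set.seed(13)
  shared <- stats::rnorm(20)
  subjects <- lapply(1:3, function(s) {
    m <- matrix(stats::rnorm(length(idx) * 20), nrow = length(idx))
    m[match(c(unlist(roi_vox), tgt_vox), idx), ] <-
      matrix(shared, nrow = 50, ncol = 20, byrow = TRUE)
    m
  })
  conn <- connectome(subjects, g)
  roi_lab <- array(0, g$dims)
  for (k in 1:4) roi_lab[roi_vox[[k]]] <- k
  tgt <- array(0, g$dims); tgt[tgt_vox] <- 1
  atlas <- winner_takes_all(conn, volume(roi_lab, g, "count"),
                            volume(tgt, g, "binary"))
  expect_true(all(atlas$label_map$data[tgt_vox] == 1))
  expect_identical(sum(atlas$tie_flags$data), 10)
  expect_error(winner_takes_all(conn, volume(array(0, g$dims), g, "count"),
                                volume(tgt, g, "binary")),
               "empty ROI")
})

test_that("parcel strengths reduce T-maps as documented", {
  pp <- planted_parcellation()
  atlas <- winner_takes_all(pp$conn, pp$roi, pp$target)
  nvox <- length(in_mask_indices(pp$grid))

  # constant T-map: every parcel strength equals the constant
  tm_const <- mock_tmap(rep(3.5, nvox), case_id = "const")
  st <- lesion_parcel_strengths(list(tm_const), atlas, pp$grid)
  expect_equal(st$strength, rep(3.5, 4))

  # hand-computed means on a structured map
  vals <- rep(0, nvox)
  pos <- match(pp$tgt_vox, in_mask_indices(pp$grid))
  vals[pos] <- rep(c(1, 2, 3, 4), each = 20) + 0.5
  tm2 <- mock_tmap(vals, case_id = "structured")
  st2 <- lesion_parcel_strengths(list(tm2), atlas, pp$grid)
  expect_equal(st2$strength[match(c("motor", "associative", "limbic", "other"),
                                  st2$parcel)],
               c(1.5, 2.5, 3.5, 4.5))
  # peak reduction
  st2p <- lesion_parcel_strengths(list(tm2), atlas, pp$grid, reduce = "peak")
  expect_equal(sort(st2p$strength), c(1.5, 2.5, 3.5, 4.5))
})

test_that("repeated-measures ANOVA and Bonferroni post-hoc behave as documented", {
  # no within-case variation: no effect
  flat <- data.frame(case_id = rep(c("a", "b", "c"), each = 4),
                     parcel = rep(c("motor", "associative", "limbic",
                                    "other"), 3),
                     strength = rep(c(1, 2, 3), each = 4))
  expect_equal(parcel_anova(flat)$omnibus_p, 1)

  # motor shifted by delta = 2 at sigma = 1, n = 23: corrected p < 0.001
  set.seed(7)
  str <- data.frame(case_id = rep(sprintf("c%02d", 1:23), each = 4),
                    parcel = rep(c("motor", "associative", "limbic",
                                   "other"), 23),
                    strength = stats::rnorm(92))
  str$strength[str$parcel == "motor"] <-
    str$strength[str$parcel == "motor"] + 2
  pa <- parcel_anova(str)
  expect_lt(pa$omnibus_p, 0.001)
  motor_rows <- pa$pairwise$parcel_a == "motor" | pa$pairwise$parcel_b == "motor"
  expect_true(all(pa$pairwise$p_bonferroni[motor_rows] < 0.001))
  # Bonferroni is p * 6 in the uncapped region
  uncapped <- pa$pairwise$p * 6 < 1
  expect_equal(pa$pairwise$p_bonferroni[uncapped],
               (pa$pairwise$p * 6)[uncapped])
  expect_error(parcel_anova(str[1:4, ]), "fewer than 2")
})

test_that("the lesion-coupled parcel dominates strength in planted cohorts", {
  ranks <- vapply(1:10, function(rep_i) {
    pp <- planted_parcellation(noise_sd = 1, n_subjects = 8,
                               seed = 500 + rep_i)
    atlas <- winner_takes_all(pp$conn, pp$roi, pp$target)
    # lesions inside the motor ROI region couple to the motor latent
    les <- lapply(1:5, function(j) {
      set.seed(700 + 10 * rep_i + j)
      voxel_lesion(pp$grid, sample(pp$roi_vox[[1]], 3), sprintf("c%d", j))
    })
    tm <- cohort_tmaps(pp$conn, les)
    st <- lesion_parcel_strengths(tm, atlas, pp$grid)
    agg <- tapply(st$strength, st$parcel, mean, na.rm = TRUE)
    names(which.max(agg)) == "motor"
  }, TRUE)
  expect_gte(mean(ranks), 0.9)
})

test_that("masking out a region subtracts voxels and drops emptied cases", {
  g <- tiny_grid(4)
  region_data <- array(0, dim = rep(4, 3)); region_data[1:8] <- 1
  region <- volume(region_data, g, kind = "binary")
  far <- voxel_lesion(g, 20:24, "far")
  inside <- voxel_lesion(g, 2:5, "inside")
  half <- voxel_lesion(g, 6:10, "half")   # 3 voxels in region, 2 out

  expect_message(out <- mask_out_region(list(far, inside, half), region),
                 "inside")
  ids <- vapply(out, `[[`, "", "case_id")
  expect_setequal(ids, c("far", "half"))
  expect_identical(out[[match("far", ids)]]$volume$data, far$volume$data)
  expect_identical(sum(out[[match("half", ids)]]$volume$data), 2)
  expect_error(mask_out_region(list(inside), region), "all lesions")
})
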