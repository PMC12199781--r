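test_that("shared latent signal drives voxel correlations as coupling dictates", {
  g <- tiny_grid(6)
  idx <- in_mask_indices(g)
  region <- idx[1:10]

  # coupling 1, vanishing noise: same-region voxels correlate to ~1
  spec1 <- network_spec(list(region), coupling = 1, noise_sd = 1e-8,
                        n_timepoints = 50)
  conn1 <- generate_connectome(g, 2, spec1, seed = 4)
  x <- conn1$subjects[[1]]
  expect_gt(stats::cor(x[1, ], x[2, ]), 0.999)

  # coupling 0: empirical mean correlation of random voxel pairs near 0
  spec0 <- network_spec(list(region), coupling = 0, noise_sd = 1,
                        n_timepoints = 100)
  conn0 <- generate_connectome(g, 2, spec0, seed = 5)
  x0 <- conn0$subjects[[1]]
  set.seed(6)
  pairs <- replicate(100, sample(nrow(x0), 2))
  rs <- apply(pairs, 2, function(p) stats::cor(x0[p[1], ], x0[p[2], ]))
  expect_lt(abs(mean(rs)), 3 / sqrt(100))
})

test_that("connectome generation is deterministic given the seed", {
  g <- tiny_grid(5)
  spec <- network_spec(list(in_mask_indices(g)[1:5]), n_timepoints = 20)
  a <- generate_connectome(g, 3, spec, seed = 11)
  b <- generate_connectome(g, 3, spec, seed = 11)
  expect_identical(a$subjects, b$subjects)
  c <- generate_connectome(g, 3, spec, seed = 12)
  expect_false(identical(a$subjects, c$subjects))
})

test_that("connectome generation rejects degenerate inputs", {
  g <- tiny_grid(4)
  spec <- network_spec(list(in_mask_indices(g)[1:2]), n_timepoints = 20)
  expect_error(generate_connectome(g, 1, spec, seed = 1), "n_subjects")
  expect_error(network_spec(list(1:2), coupling = 1.5), "coupling")
  expect_error(network_spec(list(1:2), noise_sd = 0), "noise_sd")
  bad <- network_spec(list(1:2), n_timepoints = 2)
  expect_error(generate_connectome(g, 2, bad, seed = 1), "n_timepoints")
})

test_that("lesion cohorts have the requested size and determinism", {
  g <- default_grid()
  idx <- in_mask_indices(g)
  spec <- network_spec(list(idx[200:260]), n_timepoints = 20)
  les <- generate_lesion_cohort(g, spec, 23, seed = 9, radius_mm = 4)
  expect_length(les, 23L)
  expect_true(all(vapply(les, function(l) sum(l$volume$data), 0) >= 1))
  les2 <- generate_lesion_cohort(g, spec, 23, seed = 9, radius_mm = 4)
  expect_identical(lapply(les, function(l) l$volume$data),
                   lapply(les2, function(l) l$volume$data))

  pts <- generate_lesion_cohort(g, spec, 5, seed = 10, radius_mm = 0)
  expect_true(all(vapply(pts, function(l) sum(l$volume$data), 0) == 1))
})

test_that("sphere cohort masks obey the world-distance definition", {
  g <- volume_grid(c(15, 15, 15), voxel_size = c(2, 2, 2))
  grey <- volume(array(as.numeric(g$brain_mask), dim = g$dims), g,
                 kind = "binary")
  coh <- generate_sphere_cohort(g, sphere_cohort_spec(grey, n_masks = 5,
                                                      radius_mm = 12,
                                                      seed = 3))
  expect_length(coh, 5L)
  world <- function(v) lnmapper:::voxel_world_coords(g, v)
  # brute-force diameter oracle: any two voxels of one sphere mask are
  # at most one diameter apart
  for (m in coh) {
    vox <- which(m$volume$data == 1)
    xyz <- world(vox)
    expect_lte(max(stats::dist(xyz)), 2 * 12 + 1e-9)
  }
  # exhaustive distance oracle for the sphere extraction itself, at a
  # centre far from the mask edge
  centre_idx <- which(g$brain_mask)[8 + 15 * (7 + 15 * 7)]
  vox <- lnmapper:::sphere_voxels(g, centre_idx, 12)
  all_idx <- which(g$brain_mask)
  d <- sqrt(rowSums(sweep(world(all_idx), 2, drop(world(centre_idx)))^2))
  expect_setequal(vox, all_idx[d <= 12])
})

test_that("tiny sphere radius keeps exactly the centre voxel", {
  g <- volume_grid(c(9, 9, 9), voxel_size = c(2, 2, 2))
  grey <- volume(array(1, dim = g$dims), g, kind = "binary")
  coh <- generate_sphere_cohort(g, sphere_cohort_spec(grey, n_masks = 3,
                                                      radius_mm = 0.1,
                                                      seed = 2))
  expect_true(all(vapply(coh, function(m) sum(m$volume$data), 0) == 1))
})

test_that("sphere cohort demands enough grey voxels and distinct centres", {
  g <- tiny_grid(3)
  grey_small <- array(0, dim = rep(3, 3)); grey_small[1:5] <- 1
  gm <- volume(grey_small, g, kind = "binary")
  expect_error(generate_sphere_cohort(g, sphere_cohort_spec(gm, n_masks = 10,
                                                            radius_mm = 2)),
               "fewer grey")
  coh <- generate_sphere_cohort(g, sphere_cohort_spec(gm, n_masks = 5,
                                                      radius_mm = 0.1,
                                                      seed = 1))
  centres <- vapply(coh, function(m) which(m$volume$data == 1), 0)
  expect_length(unique(centres), 5L)
})

test_that("cohorts round-trip through the manifest writer", {
  g <- tiny_grid(6)
  spec <- network_spec(list(in_mask_indices(g)[1:6]), n_timepoints = 20)
  coh <- generate_lesion_cohort(g, spec, 3, seed = 2, radius_mm = 2)
  dir <- withr::local_tempdir()
  mf <- write_cohort(coh, dir, manifest = list(seed = 2))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_length(man$cases, 3L)
  back <- read_volume(file.path(dir, man$cases[[1]]), grid = g,
                      kind = "binary")
  expect_identical(back$data, coh[[1]]$volume$data)
})
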