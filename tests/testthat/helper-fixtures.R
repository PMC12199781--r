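# Small in-code fixtures shared across test files.

# a fully masked cubic grid
tiny_grid <- function(n = 4, voxel = 2) {
  volume_grid(rep(n, 3), voxel_size = rep(voxel, 3))
}

# a t-map object carrying arbitrary values (bypasses the connectome)
mock_tmap <- function(values, case_id = "case", df = 9L, defined = NULL,
                      fisher_z = FALSE) {
  if (is.null(defined)) defined <- is.finite(values)
  structure(list(case_id = case_id, values = as.numeric(values),
                 defined = defined, df = as.integer(df),
                 fisher_z = fisher_z), class = "tmap")
}

# single-voxel lesion at a given linear index
point_lesion <- function(grid, lin_idx, case_id = "case") {
  d <- array(0, grid$dims)
  d[lin_idx] <- 1
  lesion_mask(case_id, volume(d, grid, kind = "binary"))
}

# lesion covering an explicit voxel set
voxel_lesion <- function(grid, vox, case_id = "case") {
  d <- array(0, grid$dims)
  d[vox] <- 1
  lesion_mask(case_id, volume(d, grid, kind = "binary"))
}

# small spherical-mask grid used by the permutation calibration tests
null_grid <- function() {
  g0 <- volume_grid(c(12, 12, 12))
  ctr <- (g0$dims - 1) / 2
  idx0 <- which(g0$brain_mask)
  ijk <- arrayInd(idx0, g0$dims) - 1L
  inside <- rowSums(sweep(ijk, 2, ctr)^2) <= 25
  mask <- array(FALSE, g0$dims)
  mask[idx0[inside]] <- TRUE
  volume_grid(c(12, 12, 12), brain_mask = mask)
}
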