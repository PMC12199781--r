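# Synthetic connectomes, lesion cohorts and sphere control cohorts with
# known ground truth, so every mapping stage can be validated end to end
# without patient data.

# evaluate `code` under a local, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specify a planted functional network
#'
#' Describes the latent structure of a simulated resting-state
#' connectome: a set of node regions (voxel sets, the network "hubs"),
#' per-region loadings on latent signals, and the noise level.  Regions
#' sharing a \code{latent} id load on the same latent time series and are
#' therefore functionally connected to each other — this is how a remote
#' hub (e.g. a pseudo-thalamus) is wired to a lesion-site region.
#'
#' @param node_regions list of integer vectors of linear array indices
#'   (each a voxel set inside the brain mask).
#' @param coupling numeric in [0,1], one value per region (recycled):
#'   loading of region voxels on their latent signal.
#' @param noise_sd positive standard deviation of i.i.d. Gaussian voxel
#'   noise.
#' @param n_timepoints number of BOLD samples per subject (>= 20 for
#'   realistic use; >= 3 for correlation to be defined).
#' @param latent integer region-to-latent assignment (same id = shared
#'   signal); defaults to one latent per region.
#' @return An object of class \code{network_spec}.
#' @export
network_spec <- function(node_regions, coupling = 0.8, noise_sd = 1,
                         n_timepoints = 150, latent = seq_along(node_regions)) {
  if (!is.list(node_regions) || length(node_regions) == 0L)
    stop("`node_regions` must be a non-empty list of voxel index vectors")
  coupling <- rep_len(as.numeric(coupling), length(node_regions))
  if (any(coupling < 0 | coupling > 1)) stop("`coupling` must lie in [0, 1]")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  latent <- rep_len(as.integer(latent), length(node_regions))
  structure(list(node_regions = lapply(node_regions, as.integer),
                 coupling = coupling, noise_sd = as.numeric(noise_sd),
                 n_timepoints = as.integer(n_timepoints), latent = latent),
            class = "network_spec")
}

#' Simulate a normative resting-state connectome
#'
#' For each subject, every in-mask voxel's time series is
#' \code{coupling * latent(region) + N(0, noise_sd)}; voxels belonging to
#' no region are pure noise, and a voxel in several regions sums their
#' contributions.  Latent signals are i.i.d. standard Gaussian per latent
#' id per subject per timepoint — no temporal autocorrelation is
#' modelled, since the downstream analysis consumes only spatial
#' correlation structure.
#'
#' @param grid a \code{volume_grid}.
#' @param n_subjects number of simulated subjects (>= 2).
#' @param spec a \code{network_spec}.
#' @param seed integer RNG seed; the output is deterministic given it.
#' @return A \code{connectome} (see \code{\link{connectome}}).
#' @export
generate_connectome <- function(grid, n_subjects, spec, seed) {
  stopifnot(inherits(grid, "volume_grid"), inherits(spec, "network_spec"))
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  if (spec$n_timepoints < 3)
    stop("`n_timepoints` must be >= 3 (correlation undefined below)")
  idx <- in_mask_indices(grid)
  pos <- integer(prod(grid$dims))
  pos[idx] <- seq_along(idx)          # array index -> connectome row
  for (r in spec$node_regions) {
    if (!all(grid$brain_mask[r]))
      stop("node region extends outside the brain mask")
  }
  nt <- spec$n_timepoints
  lat_ids <- sort(unique(spec$latent))
  subjects <- with_seed(seed, lapply(seq_len(n_subjects), function(s) {
    x <- matrix(stats::rnorm(length(idx) * nt, sd = spec$noise_sd),
                nrow = length(idx), ncol = nt)
    lat <- matrix(stats::rnorm(length(lat_ids) * nt), nrow = length(lat_ids))
    for (k in seq_along(spec$node_regions)) {
      rows <- pos[spec$node_regions[[k]]]
      li <- match(spec$latent[k], lat_ids)
      x[rows, ] <- x[rows, ] +
        spec$coupling[k] * matrix(lat[li, ], nrow = length(rows),
                                  ncol = nt, byrow = TRUE)
    }
    x
  }))
  connectome(subjects, grid)
}

#' Simulate a lesion cohort at network nodes
#'
#' Each lesion is a sphere of \code{radius_mm} (in world coordinates)
#' centred at a voxel drawn uniformly from a randomly chosen node region,
#' clipped to the brain mask.  Every mask has at least one voxel (the
#' centre).  \code{radius_mm = 0} gives single-voxel lesions.
#'
#' @param grid a \code{volume_grid}.
#' @param spec a \code{network_spec} supplying the node regions.
#' @param n_lesions number of cases to simulate.
#' @param seed integer RNG seed.
#' @param radius_mm lesion sphere radius in mm.
#' @param regions indices into \code{spec$node_regions} eligible to host
#'   lesions (defaults to all; restrict to plant lesions at one hub).
#' @return List of \code{lesion_mask} objects with ids "case01", ...
#' @export
generate_lesion_cohort <- function(grid, spec, n_lesions, seed,
                                   radius_mm = 4,
                                   regions = seq_along(spec$node_regions)) {
  stopifnot(inherits(grid, "volume_grid"), inherits(spec, "network_spec"))
  if (n_lesions < 1) stop("`n_lesions` must be >= 1")
  host <- spec$node_regions[regions]
  if (length(host) == 0L || any(lengths(host) == 0L))
    stop("eligible node regions are empty")
  with_seed(seed, {
    lapply(seq_len(n_lesions), function(i) {
      reg <- host[[sample.int(length(host), 1L)]]
      centre <- reg[sample.int(length(reg), 1L)]
      vox <- sphere_voxels(grid, centre, radius_mm)
      vox <- vox[grid$brain_mask[vox]]
      if (length(vox) == 0L) vox <- centre
      data <- array(0, dim = grid$dims)
      data[vox] <- 1
      lesion_mask(sprintf("case%02d", i), volume(data, grid, kind = "binary"))
    })
  })
}

#' Specify a sphere control cohort
#'
#' The control cohort: spheres of fixed radius whose centres are drawn
#' uniformly over grey-matter voxels without replacement (so the masks
#' are distinct), each masked to grey matter.
#'
#' @param grey_mask a binary \code{lnm_volume} marking grey matter.
#' @param n_masks number of control masks (default 100).
#' @param radius_mm sphere radius in mm (default 12).
#' @param seed integer RNG seed.
#' @return An object of class \code{sphere_cohort_spec}.
#' @export
sphere_cohort_spec <- function(grey_mask, n_masks = 100, radius_mm = 12,
                               seed = 1) {
  stopifnot(inherits(grey_mask, "lnm_volume"))
  if (grey_mask$kind != "binary") stop("`grey_mask` must be binary")
  if (n_masks < 1) stop("`n_masks` must be >= 1")
  if (radius_mm <= 0) stop("`radius_mm` must be > 0")
  structure(list(grey_mask = grey_mask, n_masks = as.integer(n_masks),
                 radius_mm = as.numeric(radius_mm), seed = as.integer(seed)),
            class = "sphere_cohort_spec")
}

#' Generate the sphere control cohort
#'
#' @param grid a \code{volume_grid} (must match the grey mask's grid).
#' @param spec a \code{sphere_cohort_spec}.
#' @return List of \code{lesion_mask} objects with ids "sphere001", ...
#' @export
generate_sphere_cohort <- function(grid, spec) {
  stopifnot(inherits(grid, "volume_grid"),
            inherits(spec, "sphere_cohort_spec"))
  check_same_grid(grid, spec$grey_mask$grid, what = "grey mask")
  grey <- which(spec$grey_mask$data == 1 & grid$brain_mask)
  if (length(grey) == 0L) stop("grey mask is empty inside the brain mask")
  if (length(grey) < spec$n_masks)
    stop("fewer grey-matter voxels (", length(grey),
         ") than requested masks (", spec$n_masks, ")")
  centres <- with_seed(spec$seed, grey[sample.int(length(grey), spec$n_masks)])
  lapply(seq_len(spec$n_masks), function(i) {
    vox <- sphere_voxels(grid, centres[i], spec$radius_mm)
    vox <- intersect(vox, grey)
    data <- array(0, dim = grid$dims)
    data[vox] <- 1
    lesion_mask(sprintf("sphere%03d", i), volume(data, grid, kind = "binary"))
  })
}

# linear indices of all voxels whose world-coordinate centre lies within
# radius_mm of the centre voxel's world position
sphere_voxels <- function(grid, centre_idx, radius_mm) {
  if (radius_mm <= 0) return(as.integer(centre_idx))
  c_ijk <- arrayInd(centre_idx, grid$dims) - 1L
  # candidate box in voxel units (loose bound via smallest voxel edge)
  half <- ceiling(radius_mm / min(grid$voxel_size)) + 1L
  rng <- lapply(1:3, function(a)
    max(0L, c_ijk[a] - half):min(grid$dims[a] - 1L, c_ijk[a] + half))
  box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  world <- cbind(box, 1) %*% t(grid$affine)
  c_world <- c(cbind(c_ijk, 1) %*% t(grid$affine))[1:3]
  d2 <- (world[, 1] - c_world[1])^2 + (world[, 2] - c_world[2])^2 +
    (world[, 3] - c_world[3])^2
  keep <- box[d2 <= radius_mm^2, , drop = FALSE]
  as.integer(keep[, 1] + 1L + grid$dims[1] * (keep[, 2] + grid$dims[2] * keep[, 3]))
}

#' Write a lesion cohort to disk
#'
#' Writes each mask as NIfTI plus a JSON manifest mapping case ids to
#' files and recording the generation parameters.
#'
#' @param cohort list of \code{lesion_mask}.
#' @param dir output directory (created if needed).
#' @param manifest named list of provenance fields stored in the manifest.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(cohort, function(m) {
    f <- file.path(dir, paste0(m$case_id, ".nii.gz"))
    write_volume(m$volume, f)
    basename(f)
  }, character(1))
  manifest$cases <- stats::setNames(as.list(files),
                                    vapply(cohort, `[[`, "", "case_id"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Default desk-scale grid
#'
#' A 24 x 28 x 24 voxel grid at 2 mm isotropic with an ellipsoidal brain
#' mask (semi-axes 10, 12, 10 voxels), roughly proportioned like a
#' paediatric template at coarse resolution.  Used by the simulation
#' examples and the package's own validation runs.
#'
#' @return A \code{volume_grid}.
#' @export
default_grid <- function() {
  dims <- c(24L, 28L, 24L)
  semi <- c(10, 12, 10)
  ctr <- (dims - 1) / 2
  g <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1), k = 0:(dims[3] - 1))
  inside <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
    ((g$k - ctr[3]) / semi[3])^2 <= 1
  volume_grid(dims, voxel_size = c(2, 2, 2),
              brain_mask = array(inside, dim = dims))
}

#' Simulate a complete planted-network study
#'
#' Builds the synthetic analogue of a literature lesion cohort study.
#' The planted network consists of four spatially separate lesion-site
#' subregions (emulating the heterogeneous distribution of real lesion
#' tracings over putamen, pallidum and neighbouring structures) plus one
#' remote hub region, all wired to a single shared latent signal.  A
#' normative connectome of \code{n_subjects} is simulated on that
#' structure, and \code{n_lesions} lesion masks are planted at the
#' lesion-site subregions only — never at the hub.  The remote hub is
#' the ground-truth network node a lesion network map should recover.
#'
#' @param n_subjects connectome size (default 100).
#' @param n_timepoints BOLD samples per subject (default 150).
#' @param n_lesions cohort size (default 23).
#' @param coupling latent-signal loading of all regions (default 0.8).
#' @param noise_sd voxel noise SD (default 1).
#' @param seed integer RNG seed.
#' @param grid a \code{volume_grid}; defaults to \code{default_grid()}.
#' @return List with elements \code{grid}, \code{spec}, \code{connectome},
#'   \code{lesions}, \code{lesion_site} (union of the site subregions)
#'   and \code{hub} (linear voxel indices).
#' @export
simulate_planted_study <- function(n_subjects = 100, n_timepoints = 150,
                                   n_lesions = 23, coupling = 0.8,
                                   noise_sd = 1, seed = 1, grid = default_grid()) {
  ctr <- (grid$dims - 1) / 2
  site_centres <- list(c(-6, -5, -2), c(6, -5, -2), c(-6, 3, -4), c(0, -8, 2))
  sites <- lapply(site_centres, function(o)
    region_sphere(grid, ctr + o, radius_vox = 2.5))
  hub <- region_sphere(grid, ctr + c(2, 3, 1), radius_vox = 4)
  place_spec <- network_spec(node_regions = sites, coupling = coupling,
                             noise_sd = noise_sd,
                             n_timepoints = n_timepoints)
  lesions <- generate_lesion_cohort(grid, place_spec, n_lesions,
                                    seed = seed + 1L, radius_mm = 4)
  # sites and hub load on the shared network latent; each case's lesion
  # voxels additionally carry a case-private latent at full loading —
  # real lesion seeds have a dominant individual connectivity
  # fingerprint on top of the weaker common network component, and
  # without it all seed series collapse onto one signal
  fingerprints <- lapply(lesions, function(l) which(l$volume$data == 1))
  spec <- network_spec(node_regions = c(sites, list(hub), fingerprints),
                       coupling = c(rep(coupling, length(sites) + 1L),
                                    rep(1, length(fingerprints))),
                       noise_sd = noise_sd,
                       n_timepoints = n_timepoints,
                       latent = c(rep(1L, length(sites) + 1L),
                                  seq_along(fingerprints) + 1L))
  conn <- generate_connectome(grid, n_subjects, spec, seed = seed)
  list(grid = grid, spec = spec, connectome = conn, lesions = lesions,
       lesion_site = sort(unique(unlist(sites))), hub = hub)
}

#' Cortex-like grey-matter shell mask
#'
#' The demonstration grey-matter mask for sphere control cohorts: the
#' outer rind of the ellipsoidal brain mask (between \code{inner_frac}
#' and 1 of the ellipsoid radius).  Mimics the cortex-dominated
#' geometry of a real grey-matter mask, in which control spheres rarely
#' cover deep structures.
#'
#' @param grid a \code{volume_grid} whose brain mask is an ellipsoid
#'   (works for any mask: the shell is taken from the mask's bounding
#'   ellipsoid).
#' @param inner_frac inner radius as a fraction of the ellipsoid radius
#'   (default 0.72).
#' @return A binary \code{lnm_volume}.
#' @export
grey_shell_mask <- function(grid, inner_frac = 0.72) {
  ctr <- (grid$dims - 1) / 2
  idx <- in_mask_indices(grid)
  ijk <- arrayInd(idx, grid$dims) - 1L
  # normalized ellipsoid radius per voxel, using the mask's extents
  semi <- vapply(1:3, function(a) max(abs(ijk[, a] - ctr[a])) + 0.5, 0)
  rho <- sqrt(((ijk[, 1] - ctr[1]) / semi[1])^2 +
              ((ijk[, 2] - ctr[2]) / semi[2])^2 +
              ((ijk[, 3] - ctr[3]) / semi[3])^2)
  data <- array(0, dim = grid$dims)
  data[idx[rho >= inner_frac]] <- 1
  volume(data, grid, kind = "binary")
}

# in-mask voxels within radius_vox (voxel units) of a fractional centre
region_sphere <- function(grid, centre_ijk, radius_vox) {
  idx <- in_mask_indices(grid)
  ijk <- arrayInd(idx, grid$dims) - 1L
  d2 <- (ijk[, 1] - centre_ijk[1])^2 + (ijk[, 2] - centre_ijk[2])^2 +
    (ijk[, 3] - centre_ijk[3])^2
  idx[d2 <= radius_vox^2]
}
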