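# End-to-end orchestration: one configuration object carrying the
# analysis defaults, and a runner that executes simulate/map -> overlap
# -> permutation -> specificity -> stability -> parcellation -> review
# with full provenance.

#' Build a run configuration
#'
#' Collects all analysis parameters with the standard defaults:
#' binarization threshold t = 7, overlap fraction 0.95, 5000
#' permutations at FWE alpha 0.05, leave-out sizes 5/7/9 with 100
#' subsets each, and 100 control spheres of 12 mm radius.  Any field can
#' be overridden; the full configuration is serialized into every
#' output's provenance.
#'
#' @param ... overrides of the defaults listed above; unknown names are
#'   an error.
#' @return A named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    t_threshold = 7, frac = 0.95, n_perm = 5000, alpha = 0.05,
    tail = "one", fisher_z = FALSE,
    k_leave_out = c(5, 7, 9), n_subsets = 100,
    run_specificity = TRUE, sphere_radius_mm = 12, sphere_n = 100,
    seed = 1,
    connectome_dir = NULL, lesion_dir = NULL, grey_mask = NULL,
    roi_labels = NULL, target_mask = NULL, findings_tsv = NULL,
    out_dir = "lnm_run")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file of configuration fields.
#' @return A \code{run_config}.
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  if (cfg$t_threshold <= 0) stop("t_threshold must be > 0")
  if (cfg$frac <= 0 || cfg$frac > 1) stop("frac must lie in (0, 1]")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!cfg$tail %in% c("one", "two")) stop("tail must be 'one' or 'two'")
  if (cfg$sphere_radius_mm <= 0) stop("sphere_radius_mm must be > 0")
  if (cfg$sphere_n < 1) stop("sphere_n must be >= 1")
  invisible(cfg)
}

#' Run the full lesion network mapping pipeline
#'
#' Executes every stage on the supplied inputs and writes NIfTI, TSV and
#' JSON outputs plus a manifest (configuration, seed, file hashes) into
#' \code{config$out_dir}.  With \code{simulate = TRUE}, inputs are
#' generated by \code{\link{simulate_planted_study}} instead of read
#' from the configured paths — the self-contained demonstration mode.
#'
#' Stages: cohort T-maps; binary-overlap network map; sign-flip
#' permutation map; specificity contrast against the sphere control
#' cohort (needs a grey-matter mask); leave-k-out stability; winner-
#' takes-all parcellation with the ANOVA post-hoc (needs ROI labels and
#' a target mask); review tabulation (needs a findings TSV).  Stages
#' whose inputs are not configured are skipped and noted in the
#' manifest; a stage failure aborts with the stage name.
#'
#' @param config a \code{run_config}.
#' @param simulate generate synthetic inputs instead of reading paths.
#' @param sim_args named list passed to
#'   \code{\link{simulate_planted_study}} when simulating.
#' @return The output directory path, invisibly; the manifest is
#'   \code{<out_dir>/manifest.json}.
#' @export
run_pipeline <- function(config, simulate = FALSE, sim_args = list()) {
  stopifnot(inherits(config, "run_config"))
  if (!simulate && isTRUE(config$run_specificity) && is.null(config$grey_mask))
    stop("configuration error in stage 'specificity': sphere control ",
         "cohort requested but no grey-matter mask configured", call. = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages_done <<- c(stages_done, name)
    res
  }

  if (simulate) {
    study <- stage("simulate", do.call(simulate_planted_study,
                                       c(list(seed = config$seed), sim_args)))
    grid <- study$grid
    conn <- study$connectome
    lesions <- study$lesions
    if (is.null(config$grey_mask)) {
      grey <- array(as.numeric(grid$brain_mask), dim = grid$dims)
      config$grey_mask <- volume(grey, grid, kind = "binary")
    }
  } else {
    grid_lesions <- stage("load", load_run_inputs(config))
    grid <- grid_lesions$grid
    conn <- grid_lesions$connectome
    lesions <- grid_lesions$lesions
  }

  tmaps <- stage("map", cohort_tmaps(conn, lesions, fisher_z = config$fisher_z))
  for (tm in tmaps)
    write_tmap(tm, grid, file.path(out, paste0("tmap_", tm$case_id, ".nii.gz")),
               extra = list(t_threshold = config$t_threshold))

  net <- stage("overlap",
               binary_overlap_lnm(tmaps, t_threshold = config$t_threshold,
                                  frac = config$frac))
  write_volume(vector_to_volume(net$values, grid, kind = "binary"),
               file.path(out, "lnm_overlap.nii.gz"))

  perm <- stage("permtest",
                signflip_onesample(tmaps, n_perm = config$n_perm,
                                   alpha = config$alpha, tail = config$tail,
                                   seed = config$seed))
  write_volume(vector_to_volume(ifelse(is.na(perm$fwe_p), 0,
                                       as.numeric(perm$significant)),
                                grid, kind = "binary"),
               file.path(out, "lnm_signflip_significant.nii.gz"))

  specificity <- NULL
  if (isTRUE(config$run_specificity)) {
    specificity <- stage("specificity", {
      grey <- as_volume_input(config$grey_mask, grid, "binary")
      spec <- sphere_cohort_spec(grey, n_masks = config$sphere_n,
                                 radius_mm = config$sphere_radius_mm,
                                 seed = config$seed + 101L)
      spheres <- generate_sphere_cohort(grid, spec)
      sphere_tmaps <- cohort_tmaps(conn, spheres, fisher_z = config$fisher_z)
      two_sample_perm(tmaps, sphere_tmaps, n_perm = config$n_perm,
                      alpha = config$alpha, seed = config$seed + 102L)
    })
    write_volume(vector_to_volume(as.numeric(specificity$specific), grid,
                                  kind = "binary"),
                 file.path(out, "specific_vs_spheres.nii.gz"))
  }

  stability <- stage("stability", {
    ks <- config$k_leave_out[config$k_leave_out < length(tmaps)]
    if (length(ks) == 0L) NULL else
      stability_profile(tmaps, ks = ks, n_subsets = config$n_subsets,
                        seed = config$seed + 201L,
                        t_threshold = config$t_threshold)
  })
  if (!is.null(stability)) {
    utils::write.table(
      data.frame(k = rep(stability$summary$k, each = config$n_subsets),
                 correlation = unlist(lapply(stability$reports,
                                             `[[`, "correlations"))),
      file.path(out, "stability_correlations.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  parcel <- NULL
  if (!is.null(config$roi_labels) && !is.null(config$target_mask)) {
    parcel <- stage("parcellate", {
      roi <- as_volume_input(config$roi_labels, grid, "count")
      tgt <- as_volume_input(config$target_mask, grid, "binary")
      atlas <- winner_takes_all(conn, roi, tgt, fisher_z = config$fisher_z)
      strengths <- lesion_parcel_strengths(tmaps, atlas, grid)
      list(atlas = atlas, strengths = strengths,
           stats = parcel_anova(strengths))
    })
    write_volume(parcel$atlas$label_map, file.path(out, "parcellation.nii.gz"))
    utils::write.table(parcel$strengths,
                       file.path(out, "parcel_strengths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(parcel$stats, file.path(out, "parcel_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  review <- NULL
  if (!is.null(config$findings_tsv)) {
    review <- stage("review", tabulate_findings(load_findings(config$findings_tsv)))
    utils::write.table(review, file.path(out, "review_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfg_out <- config
  cfg_out$grey_mask <- if (is.null(config$grey_mask)) NULL else "<volume>"
  cfg_out$roi_labels <- if (is.null(config$roi_labels)) NULL else "<volume>"
  cfg_out$target_mask <- if (is.null(config$target_mask)) NULL else "<volume>"
  files <- list.files(out, pattern = "\\.(nii\\.gz|tsv|json)$")
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "lnmapper",
    version = as.character(utils::packageVersion("lnmapper")),
    stages = stages_done,
    config = unclass(cfg_out),
    seed = config$seed,
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out, f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# accept an lnm_volume or a NIfTI path for optional pipeline inputs
as_volume_input <- function(x, grid, kind) {
  if (inherits(x, "lnm_volume")) {
    check_same_grid(grid, x$grid, what = "configured volume")
    return(x)
  }
  read_volume(x, grid = grid, kind = kind)
}

load_run_inputs <- function(config) {
  if (is.null(config$connectome_dir) || is.null(config$lesion_dir))
    stop("connectome_dir and lesion_dir must be configured (or use simulate)")
  mask_path <- file.path(config$connectome_dir, "brain_mask.nii.gz")
  if (!file.exists(mask_path))
    stop("connectome_dir must contain brain_mask.nii.gz")
  mask_vol <- read_volume(mask_path, kind = "binary")
  grid <- volume_grid(mask_vol$grid$dims, mask_vol$grid$voxel_size,
                      mask_vol$grid$affine,
                      brain_mask = array(mask_vol$data == 1,
                                         dim = mask_vol$grid$dims))
  subj_files <- sort(list.files(config$connectome_dir, full.names = TRUE,
                                pattern = "^subject.*\\.tsv$"))
  if (length(subj_files) == 0L)
    stop("connectome_dir must contain subject*.tsv voxel x time matrices")
  subjects <- lapply(subj_files, function(f)
    as.matrix(utils::read.delim(f, header = FALSE)))
  conn <- connectome(subjects, grid)
  lesion_files <- sort(list.files(config$lesion_dir, full.names = TRUE,
                                  pattern = "\\.nii(\\.gz)?$"))
  if (length(lesion_files) == 0L) stop("lesion_dir contains no NIfTI masks")
  lesions <- lapply(lesion_files, function(f)
    lesion_mask(sub("\\.nii(\\.gz)?$", "", basename(f)),
                read_volume(f, grid = grid, kind = "binary")))
  list(grid = grid, connectome = conn, lesions = lesions)
}
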