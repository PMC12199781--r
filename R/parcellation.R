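# Winner-takes-all functional parcellation of a target structure (the
# thalamus) from cortical ROI groups, per-lesion parcel connectivity
# strengths, and the repeated-measures ANOVA / paired-t post-hoc.

#' Winner-takes-all functional parcellation
#'
#' For each connectome subject, each ROI group's mean time series is
#' correlated with every target-mask voxel; correlations are averaged
#' across subjects (optionally through Fisher z) and each target voxel
#' is assigned to the ROI group with the largest average.  Exact ties go
#' to the lowest-index label and are flagged.
#'
#' @param conn a \code{connectome}.
#' @param roi_labels an \code{lnm_volume} of integer labels 1..K marking
#'   the cortical ROI groups (0 = unlabelled), on the connectome grid.
#' @param target_mask a binary \code{lnm_volume} marking the structure to
#'   parcellate.
#' @param labels character names of the K groups, lowest index first.
#' @param fisher_z average Fisher-z rather than raw r across subjects.
#' @return Object of class \code{parcellation_atlas}: \code{label_map}
#'   (integer \code{lnm_volume}, 0 outside the target), \code{labels},
#'   \code{tie_flags} (binary \code{lnm_volume}), \code{mean_r}
#'   (target-voxel x K matrix), \code{target_idx}.
#' @export
winner_takes_all <- function(conn, roi_labels, target_mask,
                             labels = c("motor", "associative", "limbic",
                                        "other"),
                             fisher_z = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  grid <- conn$grid
  check_same_grid(grid, roi_labels$grid, what = "ROI labels")
  check_same_grid(grid, target_mask$grid, what = "target mask")
  idx <- in_mask_indices(grid)
  pos <- integer(prod(grid$dims)); pos[idx] <- seq_along(idx)

  k <- length(labels)
  roi_rows <- lapply(seq_len(k), function(g) {
    vox <- which(roi_labels$data == g & grid$brain_mask)
    pos[vox]
  })
  if (any(lengths(roi_rows) == 0L))
    stop("empty ROI group(s): ",
         paste(labels[lengths(roi_rows) == 0L], collapse = ", "))
  tgt <- which(target_mask$data == 1 & grid$brain_mask)
  if (length(tgt) == 0L) stop("target mask is empty inside the brain mask")
  trows <- pos[tgt]

  acc <- matrix(0, nrow = length(tgt), ncol = k)
  for (s in seq_len(conn$n_subjects)) {
    subj <- conn$subjects[[s]]
    seeds <- vapply(roi_rows, function(rows)
      colMeans(subj[rows, , drop = FALSE]), numeric(ncol(subj)))
    seeds <- seeds - rep(colMeans(seeds), each = nrow(seeds))
    ssq <- colSums(seeds^2)
    if (any(ssq <= 0))
      stop("zero-variance ROI mean series in subject ", s)
    x <- subj[trows, , drop = FALSE]
    x <- x - rowMeans(x)
    sx <- rowSums(x^2)
    r <- (x %*% seeds) / sqrt(outer(sx, ssq))
    r[sx <= 0, ] <- 0      # flat target voxel: no evidence either way
    r <- pmin(pmax(r, -1), 1)
    acc <- acc + if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) else r
  }
  mean_r <- acc / conn$n_subjects

  win <- max.col(mean_r, ties.method = "first")
  best <- mean_r[cbind(seq_along(win), win)]
  tie <- rowSums(mean_r == best) > 1L

  lab_data <- array(0, dim = grid$dims); lab_data[tgt] <- win
  tie_data <- array(0, dim = grid$dims); tie_data[tgt] <- as.numeric(tie)
  structure(list(label_map = volume(lab_data, grid, kind = "count"),
                 labels = labels,
                 tie_flags = volume(tie_data, grid, kind = "binary"),
                 mean_r = mean_r, target_idx = tgt),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  tab <- table(factor(x$label_map$data[x$target_idx], levels = seq_along(x$labels),
                      labels = x$labels))
  cat("<parcellation_atlas> ", length(x$target_idx), " target voxels: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "; ",
      sum(x$tie_flags$data), " ties\n", sep = "")
  invisible(x)
}

#' Per-lesion connectivity strength to each parcel
#'
#' Reduces each case's T-map over each parcel's voxels.  The default
#' reduction is the mean (robust); \code{"peak"} takes the maximum.
#' Undefined T-map voxels are excluded; a parcel with no usable voxel
#' yields a missing strength for that case.
#'
#' @param tmaps list of \code{tmap}.
#' @param atlas a \code{parcellation_atlas}.
#' @param grid the shared \code{volume_grid}.
#' @param reduce \code{"mean"} or \code{"peak"}.
#' @return data.frame with columns case_id, parcel, strength (class
#'   \code{parcel_strengths}).
#' @export
lesion_parcel_strengths <- function(tmaps, atlas, grid,
                                    reduce = c("mean", "peak")) {
  reduce <- match.arg(reduce)
  idx <- in_mask_indices(grid)
  pos <- integer(prod(grid$dims)); pos[idx] <- seq_along(idx)
  parcel_rows <- lapply(seq_along(atlas$labels), function(g)
    pos[atlas$target_idx[atlas$label_map$data[atlas$target_idx] == g]])
  rows <- do.call(rbind, lapply(tmaps, function(tm) {
    strength <- vapply(parcel_rows, function(rr) {
      v <- tm$values[rr]
      v <- v[tm$defined[rr] & is.finite(v)]
      if (length(v) == 0L) return(NA_real_)
      if (reduce == "mean") mean(v) else max(v)
    }, 0)
    data.frame(case_id = tm$case_id, parcel = atlas$labels,
               strength = strength)
  }))
  rownames(rows) <- NULL
  class(rows) <- c("parcel_strengths", "data.frame")
  rows
}

#' Repeated-measures ANOVA and paired post-hoc over parcel strengths
#'
#' One-way repeated-measures ANOVA with parcel as the within-case factor,
#' followed by all pairwise paired t-tests with Bonferroni correction
#' (multiply by the number of pairs, cap at 1).  Cases with any missing
#' strength are dropped.  Degenerate inputs: identical strengths across
#' parcels give "no effect" (p = 1); a pairwise difference that is
#' constant and non-zero gives p = 0 (perfectly consistent), constant
#' zero gives p = 1.
#'
#' @param table a \code{parcel_strengths} data.frame.
#' @return List with \code{omnibus_p}, \code{pairwise} (data.frame of
#'   parcel_a, parcel_b, mean_diff, p, p_bonferroni), \code{n_cases}.
#' @export
parcel_anova <- function(table) {
  wide <- stats::reshape(as.data.frame(table), idvar = "case_id",
                         timevar = "parcel", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^strength\\.", "", colnames(mat))
  complete <- stats::complete.cases(mat)
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2L) stop("fewer than 2 cases with complete strengths")
  k <- ncol(mat)

  centred <- mat - rowMeans(mat)   # within-case deviations
  if (all(abs(centred) < 1e-12)) {
    omnibus_p <- 1
  } else {
    long <- data.frame(strength = as.vector(mat),
                       parcel = factor(rep(colnames(mat), each = nrow(mat))),
                       case = factor(rep(seq_len(nrow(mat)), k)))
    fit <- stats::aov(strength ~ parcel + Error(case/parcel), data = long)
    tabs <- summary(fit)
    pv <- tryCatch(tabs[["Error: case:parcel"]][[1]][["Pr(>F)"]][1],
                   error = function(e) NA_real_)
    omnibus_p <- if (is.na(pv)) 1 else pv
  }

  pairs <- utils::combn(colnames(mat), 2)
  n_pairs <- ncol(pairs)
  pairwise <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    d <- mat[, pairs[1, j]] - mat[, pairs[2, j]]
    p <- if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else stats::t.test(d)$p.value
    data.frame(parcel_a = pairs[1, j], parcel_b = pairs[2, j],
               mean_diff = mean(d), p = p,
               p_bonferroni = min(1, p * n_pairs))
  }))
  list(omnibus_p = omnibus_p, pairwise = pairwise, n_cases = nrow(mat))
}

#' Mask a region out of lesion seeds
#'
#' Removes the region's voxels from every lesion's foreground (the
#' "masked-out thalamus" control).  Cases emptied by the subtraction are
#' dropped with a notice; if every case empties, that is an error.
#'
#' @param lesions list of \code{lesion_mask}.
#' @param region a binary \code{lnm_volume} on the shared grid.
#' @return List of \code{lesion_mask} (possibly shorter than the input).
#' @export
mask_out_region <- function(lesions, region) {
  stopifnot(inherits(region, "lnm_volume"))
  out <- list()
  dropped <- character(0)
  for (l in lesions) {
    check_same_grid(l$volume$grid, region$grid, what = l$case_id)
    data <- l$volume$data
    data[region$data == 1] <- 0
    if (sum(data) == 0) {
      dropped <- c(dropped, l$case_id)
    } else {
      out[[length(out) + 1L]] <-
        lesion_mask(l$case_id, volume(data, l$volume$grid, kind = "binary"))
    }
  }
  if (length(dropped) > 0L)
    message("dropped ", length(dropped), " case(s) emptied by masking: ",
            paste(dropped, collapse = ", "))
  if (length(out) == 0L) stop("all lesions were emptied by the region mask")
  out
}
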