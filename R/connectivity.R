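# Seed-based functional connectivity: per-subject seed correlation maps
# and their across-subject one-sample t summaries (the per-lesion T-map).

# t-scores at voxels with zero variance across subjects but a non-zero
# mean saturate at this sentinel; it binarizes correctly at any finite
# threshold and is excluded from permutation max-statistic pools
SATURATION <- 1e9

#' Construct a connectome
#'
#' An ordered collection of per-subject voxel x time BOLD matrices on a
#' shared grid.  Rows follow \code{\link{in_mask_indices}} order; time
#' series lengths may differ across subjects (each subject's correlation
#' is computed on its full length) but must be >= 3.
#'
#' @param subjects list of numeric matrices, one per subject, with
#'   \code{length(in_mask_indices(grid))} rows.
#' @param grid a \code{volume_grid}.
#' @return An object of class \code{connectome}.
#' @export
connectome <- function(subjects, grid) {
  stopifnot(inherits(grid, "volume_grid"), is.list(subjects))
  if (length(subjects) < 1L) stop("connectome needs at least one subject")
  nvox <- length(in_mask_indices(grid))
  for (s in seq_along(subjects)) {
    m <- subjects[[s]]
    if (!is.matrix(m) || nrow(m) != nvox)
      stop("subject ", s, " is not a matrix with ", nvox, " in-mask rows")
    if (ncol(m) < 3L) stop("subject ", s, " has fewer than 3 timepoints")
  }
  structure(list(grid = grid, subjects = subjects,
                 n_subjects = length(subjects)), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", x$n_subjects, " subjects, ",
      nrow(x$subjects[[1]]), " in-mask voxels, ",
      paste(range(vapply(x$subjects, ncol, 0L)), collapse = "-"),
      " timepoints\n", sep = "")
  invisible(x)
}

# rows of the connectome matrices covered by a lesion's foreground
lesion_rows <- function(grid, lesion) {
  check_same_grid(grid, lesion$volume$grid, what = lesion$case_id)
  fg <- which(lesion$volume$data == 1)
  rows <- match(fg, in_mask_indices(grid))
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0L)
    stop("lesion '", lesion$case_id, "' is empty after brain masking")
  rows
}

#' Average BOLD signal in a seed region
#'
#' The unweighted mean over lesion foreground voxels at each timepoint;
#' non-contiguous foci are pooled into one series.
#'
#' @param subject voxel x time matrix in \code{in_mask_indices} order.
#' @param lesion a \code{lesion_mask}.
#' @param grid the shared \code{volume_grid}.
#' @return Numeric time series of length \code{ncol(subject)}.
#' @export
seed_timeseries <- function(subject, lesion, grid) {
  rows <- lesion_rows(grid, lesion)
  if (length(rows) == 1L) subject[rows, ] else colMeans(subject[rows, , drop = FALSE])
}

#' Seed-to-voxel Pearson correlation map
#'
#' Pearson r between the seed time series and every in-mask voxel's
#' series.  Voxels whose series has zero variance are flagged undefined
#' (\code{NA}), never silently set to 0: absent signal must not
#' masquerade as absent connectivity.
#'
#' @param subject voxel x time matrix.
#' @param seed_ts seed time series (variance must be > 0).
#' @param case_id,subject_index identifiers carried in the result.
#' @return Object of class \code{rmap}: list with \code{values} (r per
#'   in-mask voxel, \code{NA} where undefined) and \code{defined}.
#' @export
correlation_map <- function(subject, seed_ts, case_id = NA_character_,
                            subject_index = NA_integer_) {
  if (length(seed_ts) != ncol(subject))
    stop("seed series length does not match subject timepoints")
  s <- seed_ts - mean(seed_ts)
  ss <- sum(s^2)
  if (ss <= 0) stop("seed time series has zero variance")
  x <- subject - rowMeans(subject)
  sx <- rowSums(x^2)
  r <- as.numeric(x %*% s) / sqrt(sx * ss)
  defined <- sx > 0
  r[!defined] <- NA_real_
  r <- pmin(pmax(r, -1), 1)  # guard float excursions beyond [-1, 1]
  structure(list(case_id = case_id, subject_index = subject_index,
                 values = r, defined = defined), class = "rmap")
}

#' Summarize correlation maps into a lesion T-map
#'
#' Voxel-wise one-sample t over the subjects' r values (optionally Fisher
#' z-transformed first): \code{t = mean(x) / (sd(x)/sqrt(n))} with the
#' sample (n-1) standard deviation and \code{df = n - 1}.  Voxels
#' undefined in any subject are flagged undefined and excluded from all
#' downstream stages.  A zero sd with non-zero mean saturates at the
#' sentinel \code{+/-1e9} (it thresholds correctly and is kept out of
#' permutation null pools); zero sd with zero mean gives t = 0.
#'
#' @param rmaps list of \code{rmap} over all connectome subjects for one
#'   case (>= 2 subjects, same case id).
#' @param fisher_z if \code{TRUE}, apply atanh to r before the t-test.
#' @return Object of class \code{tmap}: \code{values}, \code{defined},
#'   \code{df}, \code{case_id}, \code{fisher_z}.
#' @export
lesion_tmap <- function(rmaps, fisher_z = FALSE) {
  if (length(rmaps) < 2L) stop("one-sample t needs at least 2 subjects")
  ids <- unique(vapply(rmaps, `[[`, "", "case_id"))
  if (length(ids) > 1L) stop("r-maps mix case ids: ", paste(ids, collapse = ", "))
  x <- vapply(rmaps, `[[`, numeric(length(rmaps[[1]]$values)), "values")
  onesample_tmap_from_matrix(x, case_id = ids, fisher_z = fisher_z)
}

# x: voxel x subject matrix of r values
onesample_tmap_from_matrix <- function(x, case_id, fisher_z) {
  defined <- apply(!is.na(x), 1L, all)
  if (fisher_z) x <- atanh(pmin(pmax(x, -1 + 1e-12), 1 - 1e-12))
  n <- ncol(x)
  m <- rowMeans(x)
  sdv <- sqrt(pmax(rowSums((x - m)^2), 0) / (n - 1))
  sdv[sdv < 1e-10] <- 0   # numerically constant (e.g. a seed's own voxel)
  t <- ifelse(sdv > 0, m / (sdv / sqrt(n)),
              ifelse(m == 0, 0, sign(m) * SATURATION))
  t[!defined] <- NA_real_
  structure(list(case_id = case_id, values = t, defined = defined,
                 df = n - 1L, fisher_z = fisher_z), class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat("<tmap> case ", x$case_id, ": df=", x$df,
      if (x$fisher_z) ", Fisher z" else "", "; ",
      sum(!x$defined), " undefined voxels\n", sep = "")
  invisible(x)
}

#' Compute T-maps for a whole lesion cohort
#'
#' Runs seed averaging and correlation mapping for every case against
#' every connectome subject, then the voxel-wise one-sample t summary per
#' case.  Equivalent to looping \code{\link{seed_timeseries}},
#' \code{\link{correlation_map}} and \code{\link{lesion_tmap}}, but
#' passes over each subject's data once.
#'
#' @param conn a \code{connectome}.
#' @param lesions list of \code{lesion_mask}.
#' @param fisher_z passed to the t summary.
#' @return Named list of \code{tmap}, one per case.
#' @export
cohort_tmaps <- function(conn, lesions, fisher_z = FALSE) {
  stopifnot(inherits(conn, "connectome"))
  rows_by_case <- lapply(lesions, function(l) lesion_rows(conn$grid, l))
  nvox <- nrow(conn$subjects[[1]])
  ncase <- length(lesions)
  rvals <- array(NA_real_, dim = c(nvox, conn$n_subjects, ncase))
  for (s in seq_len(conn$n_subjects)) {
    subj <- conn$subjects[[s]]
    x <- subj - rowMeans(subj)
    sx <- rowSums(x^2)
    seeds <- vapply(rows_by_case, function(rows) {
      if (length(rows) == 1L) subj[rows, ] else colMeans(subj[rows, , drop = FALSE])
    }, numeric(ncol(subj)))                       # time x case
    seeds <- seeds - rep(colMeans(seeds), each = nrow(seeds))
    ssq <- colSums(seeds^2)
    if (any(ssq <= 0))
      stop("zero-variance seed series for case(s): ",
           paste(vapply(lesions[ssq <= 0], `[[`, "", "case_id"),
                 collapse = ", "))
    r <- (x %*% seeds) / sqrt(outer(sx, ssq))
    r[sx <= 0, ] <- NA_real_
    rvals[, s, ] <- pmin(pmax(r, -1), 1)
  }
  out <- lapply(seq_len(ncase), function(k)
    onesample_tmap_from_matrix(rvals[, , k, drop = TRUE],
                               case_id = lesions[[k]]$case_id,
                               fisher_z = fisher_z))
  names(out) <- vapply(lesions, `[[`, "", "case_id")
  out
}

#' Tail probability of the binarization threshold
#'
#' Student-t tail probability of a t-score threshold at the connectome's
#' degrees of freedom — the uncorrected significance the threshold
#' corresponds to (e.g. t = 7 at df = 99 is far below p = 0.001).
#'
#' @param t_threshold t-score threshold.
#' @param df degrees of freedom (>= 1).
#' @param sides \code{"two"} for P(|T| >= t), \code{"one"} for P(T >= t).
#' @return The tail probability.
#' @export
tmap_threshold_pvalue <- function(t_threshold, df, sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (df < 1) stop("`df` must be >= 1")
  if (sides == "two") 2 * stats::pt(-abs(t_threshold), df)
  else stats::pt(t_threshold, df, lower.tail = FALSE)
}

#' Write a T-map as NIfTI with a JSON sidecar
#'
#' Out-of-mask and undefined voxels are written as 0; the sidecar records
#' case id, df, the Fisher-z flag and any threshold provenance.
#'
#' @param tm a \code{tmap}.
#' @param grid the shared \code{volume_grid}.
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param extra named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_tmap <- function(tm, grid, path, extra = list()) {
  vals <- ifelse(tm$defined, tm$values, 0)
  write_volume(vector_to_volume(vals, grid), path)
  side <- c(list(case_id = tm$case_id, df = tm$df, fisher_z = tm$fisher_z,
                 n_undefined = sum(!tm$defined)), extra)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
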