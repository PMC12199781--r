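# The lesion network map itself, by two routes: (1) threshold each case
# T-map, binarize and overlap, keeping voxels connected to at least a
# stated fraction of cases; (2) a sign-flip one-sample permutation test
# across case T-maps with max-statistic family-wise error control.

#' Binarize a T-map
#'
#' Voxel = 1 iff t is strictly greater than the threshold; undefined
#' voxels become 0.  The saturation sentinel binarizes to 1 at any finite
#' threshold.
#'
#' @param tmap a \code{tmap}.
#' @param t_threshold finite t-score threshold (default 7).
#' @return Numeric 0/1 vector over in-mask voxels.
#' @export
binarize_tmap <- function(tmap, t_threshold = 7) {
  if (!is.finite(t_threshold)) stop("`t_threshold` must be finite")
  as.numeric(tmap$defined & !is.na(tmap$values) & tmap$values > t_threshold)
}

#' Overlap binarized case maps
#'
#' Per-voxel count of cases whose binarized T-map is positive.
#'
#' @param binary_maps list of 0/1 vectors over in-mask voxels (all the
#'   same length), or a list of binarized \code{tmap}s via
#'   \code{\link{binarize_tmap}}.
#' @param t_threshold threshold recorded for provenance.
#' @return Object of class \code{overlap_map}: \code{values} (counts),
#'   \code{n_cases}, \code{t_threshold}.
#' @export
overlap_maps <- function(binary_maps, t_threshold = NA_real_) {
  if (length(binary_maps) < 1L) stop("need at least one binary map")
  len <- unique(lengths(binary_maps))
  if (length(len) != 1L)
    stop("binary maps differ in length; inputs must share one grid")
  counts <- Reduce(`+`, binary_maps)
  structure(list(values = counts, n_cases = length(binary_maps),
                 t_threshold = t_threshold), class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat("<overlap_map> ", x$n_cases, " cases; max count ",
      max(x$values), "\n", sep = "")
  invisible(x)
}

#' Threshold an overlap map into the lesion network map
#'
#' Keeps voxels connected to at least \code{frac} of the cases:
#' \code{min_count = ceiling(frac * n_cases)}.  At the default 0.95 with
#' 23 cases this is 22 of 23.
#'
#' @param overlap an \code{overlap_map}.
#' @param frac fraction of cases required, in (0, 1] (default 0.95).
#' @param case_ids optional case ids recorded for provenance.
#' @return Object of class \code{lnm}: \code{values} (0/1 vector),
#'   \code{min_count}, \code{frac}, \code{n_cases}, \code{case_ids}.
#' @export
lnm_from_overlap <- function(overlap, frac = 0.95, case_ids = NULL) {
  stopifnot(inherits(overlap, "overlap_map"))
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("`frac` must lie in (0, 1]")
  min_count <- as.integer(ceiling(frac * overlap$n_cases))
  structure(list(values = as.numeric(overlap$values >= min_count),
                 min_count = min_count, frac = frac,
                 n_cases = overlap$n_cases, case_ids = case_ids),
            class = "lnm")
}

#' @export
print.lnm <- function(x, ...) {
  cat("<lnm> ", sum(x$values), " voxels connected to >= ", x$min_count,
      "/", x$n_cases, " cases (frac ", x$frac, ")\n", sep = "")
  invisible(x)
}

#' Binary-overlap lesion network mapping in one call
#'
#' \code{\link{binarize_tmap}} + \code{\link{overlap_maps}} +
#' \code{\link{lnm_from_overlap}}.
#'
#' @param tmaps list of \code{tmap}.
#' @inheritParams binarize_tmap
#' @inheritParams lnm_from_overlap
#' @return An \code{lnm} (see \code{\link{lnm_from_overlap}}).
#' @export
binary_overlap_lnm <- function(tmaps, t_threshold = 7, frac = 0.95) {
  ov <- overlap_maps(lapply(tmaps, binarize_tmap, t_threshold = t_threshold),
                     t_threshold = t_threshold)
  lnm_from_overlap(ov, frac = frac,
                   case_ids = vapply(tmaps, `[[`, "", "case_id"))
}

#' Sign-flip one-sample permutation test across case T-maps
#'
#' The observed statistic is the voxel-wise one-sample t over the case
#' T-map values.  The null is built by independently flipping the sign
#' of each whole case map; family-wise error is controlled by comparing
#' each voxel's statistic to the permutation distribution of the
#' image-wide maximum (one-tailed) or maximum absolute value
#' (two-tailed).  When \code{2^n_cases <= n_perm} the flip set is
#' enumerated exhaustively (p = count / 2^n, identity included);
#' otherwise random flips are drawn and p uses add-one counting
#' \code{(1 + count) / (1 + n_perm)} so it is never 0.  Voxels undefined
#' or saturated in any case are excluded from the statistic pool.
#'
#' @param tmaps list of >= 2 \code{tmap}.
#' @param n_perm number of permutations (default 5000).
#' @param alpha FWE significance level (default 0.05).
#' @param tail \code{"one"} (positive; the analysis targets connected,
#'   not anti-connected, voxels) or \code{"two"}.
#' @param seed integer RNG seed.
#' @return Object of class \code{perm_result}: \code{observed} (t per
#'   voxel, \code{NA} where excluded), \code{fwe_p} (in (0, 1], \code{NA}
#'   where excluded), \code{significant} (logical), \code{n_perm} (number
#'   actually used), \code{exhaustive}, \code{alpha}, \code{tail},
#'   \code{seed}, \code{df}.
#' @export
signflip_onesample <- function(tmaps, n_perm = 5000, alpha = 0.05,
                               tail = c("one", "two"), seed = 1) {
  tail <- match.arg(tail)
  n <- length(tmaps)
  if (n < 2L) stop("sign-flip test needs at least 2 case maps")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  x <- vapply(tmaps, `[[`, numeric(length(tmaps[[1]]$values)), "values")
  usable <- apply(is.finite(x) & abs(x) < SATURATION, 1L, all)
  if (!any(usable)) stop("no voxel is defined across all case maps")
  xs <- x[usable, , drop = FALSE]

  if (all(abs(xs) < .Machine$double.eps)) {
    warning("all case maps are zero; every p-value is 1")
    return(perm_result_all(x, usable, rep(1, sum(usable)), n_perm, FALSE,
                           alpha, tail, seed, n))
  }

  exhaustive <- 2^n <= n_perm
  flips <- if (exhaustive) {
    as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    with_seed(seed, matrix(sample(c(1, -1), n * n_perm, replace = TRUE),
                           nrow = n_perm, ncol = n))
  }
  nper <- nrow(flips)

  ss <- rowSums(xs^2)                       # flip-invariant
  tmat <- flip_tstats(xs, ss, t(flips), n)  # voxel x perm
  obs <- flip_tstats(xs, ss, matrix(1, n, 1), n)[, 1]
  stat_obs <- if (tail == "two") abs(obs) else obs
  maxdist <- apply(if (tail == "two") abs(tmat) else tmat, 2L, max)
  exceed <- vapply(stat_obs, function(v) sum(maxdist >= v), 0)
  fwe <- if (exhaustive) exceed / nper else (1 + exceed) / (1 + nper)
  perm_result_all(x, usable, fwe, nper, exhaustive, alpha, tail, seed, n,
                  obs = obs)
}

# one-sample t per voxel for each sign pattern; signs: n x P of +-1.
# sum of squares is sign-invariant, so only the mean needs recomputing.
flip_tstats <- function(xs, ss, signs, n) {
  m <- (xs %*% signs) / n
  v <- pmax(ss - n * m^2, 0) / (n - 1)
  t <- m / sqrt(v / n)
  t[v == 0 & m == 0] <- 0
  t[v == 0 & m != 0] <- sign(m[v == 0 & m != 0]) * SATURATION
  t
}

perm_result_all <- function(x, usable, fwe, n_perm, exhaustive, alpha, tail,
                            seed, n, obs = NULL) {
  nvox <- nrow(x)
  observed <- rep(NA_real_, nvox)
  p <- rep(NA_real_, nvox)
  if (is.null(obs)) obs <- rep(0, sum(usable))
  observed[usable] <- obs
  p[usable] <- fwe
  sig <- !is.na(p) & p < alpha & (tail == "two" | observed > 0)
  structure(list(observed = observed, fwe_p = p, significant = sig,
                 n_perm = n_perm, exhaustive = exhaustive, alpha = alpha,
                 tail = tail, seed = seed, df = n - 1L),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("<perm_result> ", x$n_perm,
      if (x$exhaustive) " exhaustive" else " random",
      " permutations, ", x$tail, "-tailed; ",
      sum(x$significant), " voxels FWE p < ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Dice overlap of two binary sets
#'
#' \code{2|A n B| / (|A| + |B|)}; 0 when both sets are empty.
#'
#' @param a,b logical or 0/1 vectors of equal length.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(0)
  2 * sum(a & b) / denom
}
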