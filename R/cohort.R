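# Specificity and stability of a lesion network map: a two-sample
# permutation contrast of case T-maps against a control cohort, and
# leave-k-out resampling of the overlap map.

#' Two-sample permutation contrast of case T-map cohorts
#'
#' The observed statistic is the voxel-wise two-sample t for group a
#' minus group b (pooled variance by default; Welch optional).  The null
#' randomly relabels cases into groups of the original sizes; FWE uses
#' the max-statistic across voxels as in \code{\link{signflip_onesample}}.
#' When \code{choose(na+nb, na) <= n_perm} the relabelings are enumerated
#' exhaustively (p = count / total, identity included); otherwise random
#' relabelings use add-one counting.  The specific set holds voxels
#' where a exceeds b with FWE p below alpha.
#'
#' @param a,b lists of \code{tmap} (>= 2 each); all maps share a grid.
#' @param n_perm number of permutations (default 5000).
#' @param alpha FWE significance level (default 0.05).
#' @param tail \code{"one"} (a > b) or \code{"two"}.
#' @param seed integer RNG seed.
#' @param pooled use the pooled-variance statistic (default) or Welch.
#' @return Object of class \code{cohort_contrast}: a \code{perm_result}
#'   in \code{$result} plus \code{$specific} (logical: a > b and FWE p <
#'   alpha) and the group sizes.
#' @export
two_sample_perm <- function(a, b, n_perm = 5000, alpha = 0.05,
                            tail = c("one", "two"), seed = 1, pooled = TRUE) {
  tail <- match.arg(tail)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("both groups need at least 2 case maps")
  nvox <- length(a[[1]]$values)
  x <- cbind(vapply(a, `[[`, numeric(nvox), "values"),
             vapply(b, `[[`, numeric(nvox), "values"))
  n <- na + nb
  usable <- apply(is.finite(x) & abs(x) < SATURATION, 1L, all)
  if (!any(usable)) stop("no voxel is defined across all case maps")
  xs <- x[usable, , drop = FALSE]

  exhaustive <- choose(n, na) <= n_perm
  ind <- if (exhaustive) {
    combos <- utils::combn(n, na)
    apply(combos, 2L, function(j) as.numeric(seq_len(n) %in% j))
  } else {
    with_seed(seed, vapply(seq_len(n_perm), function(i)
      as.numeric(seq_len(n) %in% sample.int(n, na)), numeric(n)))
  }                                              # n x P indicator of group a
  nper <- ncol(ind)

  tstat <- relabel_tstats(xs, ind, na, nb, pooled)
  obs <- relabel_tstats(xs, matrix(as.numeric(seq_len(n) <= na), n, 1),
                        na, nb, pooled)[, 1]
  stat_obs <- if (tail == "two") abs(obs) else obs
  maxdist <- apply(if (tail == "two") abs(tstat) else tstat, 2L, max)
  exceed <- vapply(stat_obs, function(v) sum(maxdist >= v), 0)
  fwe <- if (exhaustive) exceed / nper else (1 + exceed) / (1 + nper)

  res <- perm_result_all(x, usable, fwe, nper, exhaustive, alpha, tail,
                         seed, n, obs = obs)
  res$df <- if (pooled) n - 2L else NA_integer_
  specific <- !is.na(res$fwe_p) & res$fwe_p < alpha & res$observed > 0
  structure(list(result = res, specific = specific, n_a = na, n_b = nb,
                 pooled = pooled), class = "cohort_contrast")
}

# two-sample t per voxel for each relabeling; ind: n x P group-a indicator
relabel_tstats <- function(xs, ind, na, nb, pooled) {
  n <- na + nb
  sa <- xs %*% ind                 # group-a sums, voxel x P
  stot <- rowSums(xs)
  ma <- sa / na
  mb <- (stot - sa) / nb
  if (pooled) {
    qtot <- rowSums(xs^2)
    ssw <- pmax(qtot - na * ma^2 - nb * mb^2, 0)
    sp2 <- ssw / (n - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    qa <- (xs^2) %*% ind
    qtot <- rowSums(xs^2)
    va <- pmax(qa - na * ma^2, 0) / (na - 1)
    vb <- pmax((qtot - qa) - nb * mb^2, 0) / (nb - 1)
    se <- sqrt(va / na + vb / nb)
  }
  d <- ma - mb
  t <- d / se
  t[se == 0 & d == 0] <- 0
  t[se == 0 & d != 0] <- sign(d[se == 0 & d != 0]) * SATURATION
  t
}

#' @export
print.cohort_contrast <- function(x, ...) {
  cat("<cohort_contrast> ", x$n_a, " vs ", x$n_b, " cases; ",
      sum(x$specific), " specific voxels (FWE p < ", x$result$alpha,
      ")\n", sep = "")
  invisible(x)
}

#' Spatial Pearson correlation of two maps
#'
#' Pearson r over in-mask voxel pairs; constant maps are an error (the
#' correlation is undefined, and a silent 0 would be misleading).
#'
#' @param x,y numeric vectors over in-mask voxels, or \code{lnm_volume}s
#'   on a shared grid.
#' @param mask optional logical vector restricting the comparison.
#' @return Pearson correlation in [-1, 1].
#' @export
spatial_correlation <- function(x, y, mask = NULL) {
  if (inherits(x, "lnm_volume")) {
    check_same_grid(x$grid, y$grid, what = "second map")
    idx <- in_mask_indices(x$grid)
    x <- x$data[idx]; y <- y$data[idx]
  }
  if (!is.null(mask)) {
    x <- x[as.logical(mask)]; y <- y[as.logical(mask)]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 voxels available for correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spatial correlation undefined for a constant map")
  stats::cor(x, y)
}

#' Leave-k-out stability of the overlap map
#'
#' Draws \code{n_subsets} distinct random subsets of size
#' \code{n_cases - k}, recomputes the overlap-fraction map
#' (count / subset size) for each, and correlates it with the
#' full-cohort overlap-fraction map over in-mask voxels.  Fraction maps
#' (not binary network maps) are correlated because Pearson r on a
#' near-empty binary map is degenerate.
#'
#' @param tmaps list of \code{tmap} for the full cohort.
#' @param k number of cases left out (0 <= k < n_cases; k = 0 is the
#'   degenerate identity check).
#' @param n_subsets number of distinct subsets (default 100).
#' @param seed integer RNG seed.
#' @param t_threshold binarization threshold (default 7).
#' @param reference optional \code{overlap_map} of the full cohort
#'   (recomputed from \code{tmaps} if missing).
#' @return Object of class \code{stability_report}: \code{k},
#'   \code{n_subsets}, \code{correlations}, \code{seed}.
#' @export
leave_k_out_stability <- function(tmaps, k, n_subsets = 100, seed = 1,
                                  t_threshold = 7, reference = NULL) {
  n <- length(tmaps)
  if (k < 0 || k >= n) stop("`k` must satisfy 0 <= k < n_cases")
  if (n_subsets < 1) stop("`n_subsets` must be >= 1")
  m <- n - k
  if (choose(n, m) < n_subsets)
    stop("only ", choose(n, m), " distinct subsets of size ", m,
         " exist; ", n_subsets, " requested")
  bin <- vapply(tmaps, binarize_tmap, numeric(length(tmaps[[1]]$values)),
                t_threshold = t_threshold)                 # voxel x case
  if (is.null(reference))
    reference <- overlap_maps(asplit(bin, 2L), t_threshold = t_threshold)
  ref_frac <- reference$values / reference$n_cases

  subsets <- with_seed(seed, {
    seen <- character(0)
    out <- vector("list", n_subsets)
    i <- 0L
    while (i < n_subsets) {
      s <- sort(sample.int(n, m))
      key <- paste(s, collapse = ",")
      if (!key %in% seen) {
        i <- i + 1L
        seen <- c(seen, key)
        out[[i]] <- s
      }
    }
    out
  })
  correlations <- vapply(subsets, function(s) {
    frac <- rowSums(bin[, s, drop = FALSE]) / length(s)
    if (stats::sd(frac) == 0 || stats::sd(ref_frac) == 0) return(NA_real_)
    stats::cor(frac, ref_frac)
  }, 0)
  structure(list(k = as.integer(k), n_subsets = as.integer(n_subsets),
                 correlations = correlations, seed = as.integer(seed)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> leave-", x$k, "-out, ", x$n_subsets,
      " subsets; median r = ",
      round(stats::median(x$correlations, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Summarize stability across several k
#'
#' Convenience wrapper running \code{\link{leave_k_out_stability}} for
#' each k and returning a per-k summary table.
#'
#' @inheritParams leave_k_out_stability
#' @param ks integer vector of leave-out sizes (default \code{c(5, 7, 9)}).
#' @return List with \code{reports} (one per k) and \code{summary}
#'   (data.frame of k, median, q25, q75).
#' @export
stability_profile <- function(tmaps, ks = c(5, 7, 9), n_subsets = 100,
                              seed = 1, t_threshold = 7) {
  reports <- lapply(seq_along(ks), function(i)
    leave_k_out_stability(tmaps, ks[i], n_subsets = n_subsets,
                          seed = seed + i, t_threshold = t_threshold))
  summary <- data.frame(
    k = as.integer(ks),
    median = vapply(reports, function(r)
      stats::median(r$correlations, na.rm = TRUE), 0),
    q25 = vapply(reports, function(r)
      unname(stats::quantile(r$correlations, 0.25, na.rm = TRUE)), 0),
    q75 = vapply(reports, function(r)
      unname(stats::quantile(r$correlations, 0.75, na.rm = TRUE)), 0))
  list(reports = reports, summary = summary)
}
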