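# Tabulation of MRI findings across studies following the MRI
# classification system for cerebral palsy (MRICS): per finding, the
# number of studies assessing it, the pooled patient count, the number
# affected and the rounded percentage.

#' MRICS finding vocabulary
#'
#' The controlled vocabulary: the five MRICS general categories, the
#' grey-matter sub-patterns, and the specific subcortical sites.
#'
#' @return Character vector of valid finding tokens.
#' @export
mrics_vocabulary <- function() {
  c("white_matter_injury", "grey_matter_injury", "maldevelopment",
    "miscellaneous", "normal",
    "bg_thalamus", "cortical_subcortical", "focal_infarct",
    "thalamus", "pallidum", "putamen", "subthalamic_nucleus",
    "corpus_callosum", "internal_capsule", "brainstem",
    "substantia_nigra", "caudate", "cerebellum", "hippocampus")
}

#' Construct study finding records
#'
#' @param study_id character study identifiers.
#' @param finding finding tokens from \code{\link{mrics_vocabulary}}.
#' @param n_total patients assessed for the finding in the study.
#' @param n_affected patients presenting the finding (<= n_total).
#' @param excluded_for_bias studies excluded from the quantitative
#'   tabulation (e.g. a lesion pattern as inclusion criterion).
#' @return data.frame of class \code{study_findings}.
#' @export
study_findings <- function(study_id, finding, n_total, n_affected,
                           excluded_for_bias = FALSE) {
  df <- data.frame(study_id = as.character(study_id),
                   finding = as.character(finding),
                   n_total = as.integer(n_total),
                   n_affected = as.integer(n_affected),
                   excluded_for_bias = as.logical(excluded_for_bias))
  bad <- !df$finding %in% mrics_vocabulary()
  if (any(bad))
    stop("unknown finding token(s): ",
         paste(unique(df$finding[bad]), collapse = ", "))
  if (any(df$n_total < 0) || any(df$n_affected < 0))
    stop("patient counts must be non-negative")
  over <- df$n_affected > df$n_total
  if (any(over))
    stop("n_affected exceeds n_total for: ",
         paste(df$study_id[over], df$finding[over], collapse = "; "))
  class(df) <- c("study_findings", "data.frame")
  df
}

#' Load study findings from TSV
#'
#' Expects a header with columns study_id, finding, n_total, n_affected
#' and optionally excluded_for_bias (0/1 or TRUE/FALSE) and n_studies (a
#' study-count weight for rows that encode already-pooled counts).
#' Malformed rows and unknown finding tokens are rejected with their
#' line numbers.
#'
#' @param path path to a tab-separated file.
#' @return A \code{study_findings} data.frame (with an \code{n_studies}
#'   column when present in the file).
#' @export
load_findings <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study_id", "finding", "n_total", "n_affected")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L)
    stop("missing column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "))
  line <- seq_len(nrow(raw)) + 1L   # header is line 1
  problems <- character(0)
  bad_tok <- !raw$finding %in% mrics_vocabulary()
  if (any(bad_tok))
    problems <- c(problems, paste0("line ", line[bad_tok],
                                   ": unknown finding '",
                                   raw$finding[bad_tok], "'"))
  nt <- suppressWarnings(as.integer(raw$n_total))
  na_ <- suppressWarnings(as.integer(raw$n_affected))
  bad_num <- is.na(nt) | is.na(na_) | nt < 0 | na_ < 0
  if (any(bad_num))
    problems <- c(problems, paste0("line ", line[bad_num],
                                   ": non-numeric or negative counts"))
  over <- !bad_num & na_ > nt
  if (any(over))
    problems <- c(problems, paste0("line ", line[over],
                                   ": n_affected > n_total"))
  if (length(problems) > 0L)
    stop("malformed findings file:\n  ", paste(problems, collapse = "\n  "))
  excl <- if ("excluded_for_bias" %in% names(raw))
    as.logical(raw$excluded_for_bias) else FALSE
  df <- study_findings(raw$study_id, raw$finding, nt, na_, excl)
  if ("n_studies" %in% names(raw))
    df$n_studies <- as.integer(raw$n_studies)
  df
}

#' Write study findings to TSV
#'
#' @param findings a \code{study_findings} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_findings <- function(findings, path) {
  utils::write.table(findings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# round half away from zero (printed clinical percentages use half-up,
# unlike R's banker-style round())
round_half_up <- function(x) floor(x + 0.5)

#' Tabulate findings across studies
#'
#' Drops studies excluded for reporting bias, then pools per finding:
#' the number of studies assessing it, the total patients in those
#' studies, the number affected, and the percentage rounded half-up to
#' an integer.  Counts pool only over studies that report the finding.
#'
#' @param findings a \code{study_findings} data.frame; an optional
#'   \code{n_studies} column weights rows that already encode pooled
#'   counts.
#' @return data.frame with columns finding, n_studies, n_total,
#'   n_affected, percent, ordered by decreasing n_affected.
#' @export
tabulate_findings <- function(findings) {
  stopifnot(is.data.frame(findings))
  f <- findings[!findings$excluded_for_bias, , drop = FALSE]
  if (nrow(f) == 0L) stop("no studies remain after bias exclusion")
  w <- if ("n_studies" %in% names(f)) f$n_studies else rep(1L, nrow(f))
  out <- do.call(rbind, lapply(split(seq_len(nrow(f)), f$finding), function(i) {
    nt <- sum(f$n_total[i])
    data.frame(finding = f$finding[i][1],
               n_studies = sum(w[i]),
               n_total = nt,
               n_affected = sum(f$n_affected[i]),
               percent = if (nt == 0) 0L else
                 as.integer(round_half_up(100 * sum(f$n_affected[i]) / nt)))
  }))
  out <- out[order(-out$n_affected, out$finding), , drop = FALSE]
  rownames(out) <- NULL
  out
}
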