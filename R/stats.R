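# Cohort-level statistics: mean +/- SEM summaries, two-sample rank test,
# Holm step-down adjustment over an explicit comparison family, paired t
# test, immunoblot densitometry normalization.

#' Construct a cohort of per-cell summaries
#'
#' @param condition condition label.
#' @param values numeric vector of per-cell window summaries.
#' @return A [Cohort-class].
#' @export
cohort <- function(condition, values) {
  new("Cohort", condition = as.character(condition),
      values = as.numeric(values))
}

#' @rdname cohort
#' @param object a [Cohort-class].
#' @export
setMethod("condition", "Cohort", function(object) object@condition)

#' @rdname cohort
#' @export
setMethod("cohortValues", "Cohort", function(object) object@values)

setMethod("show", "Cohort", function(object) {
  n <- length(object@values)
  cat("Cohort '", object@condition, "': n = ", n, sep = "")
  if (n >= 2L)
    cat(", mean +/- SEM = ", sprintf("%.2f", mean(object@values)),
        " +/- ", sprintf("%.2f", sd(object@values) / sqrt(n)), sep = "")
  cat("\n")
})

#' Summarize one or several cohorts
#'
#' Arithmetic mean, standard error of the mean (sample SD with n - 1
#' denominator over sqrt(n)) and cell count. For a single-cell cohort
#' the SEM is undefined and returned as `NA` with a warning.
#'
#' @param x a [Cohort-class] (`summarizeCohort`) or a list of them
#'   (`summarizeCohorts`).
#' @return `summarizeCohort`: named list with `mean`, `sem`, `n`.
#'   `summarizeCohorts`: `data.frame` with columns `condition`, `mean`,
#'   `sem`, `n`.
#' @export
summarizeCohort <- function(x) {
  stopifnot(is(x, "Cohort"))
  v <- x@values
  n <- length(v)
  if (n < 2L) {
    warning("SEM undefined for n < 2")
    return(list(mean = mean(v), sem = NA_real_, n = n))
  }
  list(mean = mean(v), sem = sd(v) / sqrt(n), n = n)
}

#' @rdname summarizeCohort
#' @export
summarizeCohorts <- function(x) {
  stopifnot(is.list(x), all(vapply(x, is, logical(1), "Cohort")))
  rows <- lapply(x, function(ch) {
    s <- summarizeCohort(ch)
    data.frame(condition = ch@condition, mean = s$mean, sem = s$sem,
               n = s$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sample rank-sum test
#'
#' Two-sided Wilcoxon–Mann–Whitney test of a location difference between
#' two independent samples. The exact null distribution is enumerated
#' when the smaller sample has at most `exactMax` observations and the
#' pooled data are tie-free; otherwise the normal approximation with tie
#' and continuity correction is used. Set `exact` to force either path.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact logical or `NULL` (auto, per the rule above).
#' @param exactMax largest min-group size for the automatic exact path.
#' @return List with `statistic` (the Mann–Whitney W for the first
#'   sample) and `p.value` (two-sided).
#' @export
rankSumTest <- function(a, b, exact = NULL, exactMax = 12L) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (!length(a) || !length(b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact))
    exact <- min(length(a), length(b)) <= exactMax && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down adjustment of a family of p values: sorted ascending, the
#' k-th smallest is multiplied by (K - k + 1), running maxima enforce
#' monotonicity, results are capped at 1 and returned in input order.
#' The family must be assembled explicitly by the caller — which
#' pairwise comparisons share one adjustment is a scientific decision,
#' never inferred.
#'
#' @param p numeric vector of raw p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holmBonferroni <- function(p) {
  stopifnot(is.numeric(p))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Paired t test
#'
#' Two-sided paired Student's t test on the within-pair differences.
#' Identical inputs (every difference zero) are the degenerate null case
#' and return t = 0, p = 1; a nonzero constant difference has zero
#' variance and is an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return List with `statistic` (t) and `p.value`.
#' @export
pairedTTest <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("paired samples must have equal length")
  if (length(x) < 2L)
    stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p.value = 1))
    stop("zero variance of the paired differences")
  }
  ht <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Normalize immunoblot band densitometry
#'
#' Each blot (one antibody re-probe of the same membrane) is first
#' normalized to its own mean band intensity, removing per-blot exposure
#' gain; each lane is then divided by the same lane of the (identically
#' normalized) pan-antibody blot, removing per-lane loading differences.
#'
#' @param intensities strictly positive numeric matrix, lanes in rows,
#'   blots (antibodies) in columns, with column names.
#' @param panReference column name of the pan-antibody blot.
#' @return Matrix of normalized intensities for the non-reference blots
#'   (lanes x remaining antibodies).
#' @export
normalizeBlot <- function(intensities, panReference = "panAkt") {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (any(intensities <= 0))
    stop("band intensities must be strictly positive")
  if (is.null(colnames(intensities)) ||
      !panReference %in% colnames(intensities))
    stop("missing pan-reference blot '", panReference, "'")
  byBlot <- sweep(intensities, 2L, colMeans(intensities), "/")
  pan <- byBlot[, panReference]
  out <- byBlot[, setdiff(colnames(byBlot), panReference), drop = FALSE]
  sweep(out, 1L, pan, "/")
}

#' Pairwise cohort comparisons with one adjustment family
#'
#' Runs [rankSumTest()] for every requested pair of cohorts and adjusts
#' the resulting p values together with [holmBonferroni()]. The `family`
#' argument is the explicit list of comparisons sharing the adjustment;
#' pass `adjust = FALSE` to report raw p values only (as is conventional
#' in tabulated pairwise p values).
#'
#' @param cohorts list of [Cohort-class] objects.
#' @param family list of character pairs `c(conditionA, conditionB)`;
#'   defaults to all pairs in order.
#' @param adjust apply the Holm step-down adjustment over the family.
#' @return `data.frame` with columns `condition_a`, `condition_b`,
#'   `statistic`, `p_raw` and (if adjusted) `p_adjusted`.
#' @export
compareCohorts <- function(cohorts, family = NULL, adjust = TRUE) {
  stopifnot(is.list(cohorts),
            all(vapply(cohorts, is, logical(1), "Cohort")))
  names(cohorts) <- vapply(cohorts, condition, character(1))
  if (is.null(family)) {
    cn <- names(cohorts)
    family <- if (length(cn) < 2L) list() else
      utils::combn(cn, 2L, simplify = FALSE)
  }
  if (!length(family))
    stop("no comparisons requested")
  rows <- lapply(family, function(pair) {
    if (!all(pair %in% names(cohorts)))
      stop("unknown condition in comparison: ",
           paste(pair, collapse = " vs "))
    ht <- rankSumTest(cohorts[[pair[1L]]]@values,
                      cohorts[[pair[2L]]]@values)
    data.frame(condition_a = pair[1L], condition_b = pair[2L],
               statistic = ht$statistic, p_raw = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust)
    out$p_adjusted <- holmBonferroni(out$p_raw)
  out
}
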