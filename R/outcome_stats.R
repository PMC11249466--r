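#' Stratum descriptive statistics
#'
#' Mean, SD, median, minimum and maximum of one variable per complexity
#' stratum, in the layout of a registry outcome table.  The median is the
#' usual mean-of-middle-two convention for even counts.  An empty stratum
#' (requested via `strata` but absent from the data) is reported as a row of
#' `NA`, never as zero.
#'
#' @param cohort registry data.frame.
#' @param variable name of the numeric column to describe.
#' @param by stratum column, default `"complexity_score"`.
#' @param strata strata to report; default the sorted observed values.
#' @return data.frame with columns `stratum`, `n`, `mean`, `sd`, `median`,
#'   `min`, `max`.
#' @export
describe_strata <- function(cohort, variable, by = "complexity_score",
                            strata = NULL) {
  stopifnot(is.data.frame(cohort), variable %in% names(cohort),
            by %in% names(cohort))
  g <- cohort[[by]]
  if (is.null(strata)) strata <- sort(unique(g))
  rows <- lapply(strata, function(s) {
    x <- cohort[[variable]][g == s]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(stratum = s, n = 0L, mean = NA_real_, sd = NA_real_,
                        median = NA_real_, min = NA_real_, max = NA_real_))
    data.frame(stratum = s, n = length(x), mean = mean(x),
               sd = stats::sd(x), median = stats::median(x),
               min = min(x), max = max(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-trend test across complexity strata
#'
#' The study's nonparametric testing policy: group homogeneity is tested with
#' the (tie-corrected) Kruskal-Wallis test; pairwise two-sided Mann-Whitney
#' u-tests follow only when the omnibus test is significant at `alpha`
#' (`pairwise = "gated"`, the default) or unconditionally
#' (`pairwise = "always"`).  The u-test is exact when both groups have at
#' most `exact_max_n` observations and no ties are present, otherwise it uses
#' the tie-corrected normal approximation (without continuity correction, so
#' that the two-group case agrees asymptotically with Kruskal-Wallis).  No
#' multiple-testing correction is applied by default; set `adjust = "holm"`
#' (or any [stats::p.adjust()] method) to adjust the pairwise p-values.
#'
#' @param cohort registry data.frame.
#' @param variable numeric column to test.
#' @param by stratum column.
#' @param alpha gate level for the pairwise follow-ups, default 0.05.
#' @param pairwise `"gated"`, `"always"` or `"never"`.
#' @param adjust p-adjustment method for pairwise tests, default `"none"`.
#' @param exact_max_n largest per-group size for exact u-tests, default 20.
#' @return list of class `grip_trend`: `variable`, `kw_statistic`, `kw_df`,
#'   `kw_p`, `pairwise` (data.frame `group1`, `group2`, `u_statistic`, `p`,
#'   or NULL when not run).
#' @export
trend_test <- function(cohort, variable, by = "complexity_score",
                       alpha = 0.05, pairwise = c("gated", "always", "never"),
                       adjust = "none", exact_max_n = 20) {
  pairwise <- match.arg(pairwise)
  stopifnot(is.data.frame(cohort), variable %in% names(cohort),
            by %in% names(cohort))
  x <- cohort[[variable]]
  g <- factor(cohort[[by]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need at least two strata with at least two records each", call. = FALSE)
  if (length(unique(x)) == 1L) {
    kw <- list(statistic = c("Kruskal-Wallis chi-squared" = 0),
               parameter = c(df = length(sizes) - 1L), p.value = 1)
  } else {
    kw <- stats::kruskal.test(x, g)
  }
  res <- structure(list(variable = variable,
                        kw_statistic = unname(kw$statistic),
                        kw_df = unname(kw$parameter),
                        kw_p = kw$p.value,
                        pairwise = NULL), class = "grip_trend")
  run_pairs <- switch(pairwise, always = TRUE, never = FALSE,
                      gated = res$kw_p < alpha)
  if (run_pairs) {
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    pw <- apply(pairs, 2, function(pr) {
      xa <- x[g == pr[1]]; xb <- x[g == pr[2]]
      ties <- anyDuplicated(c(xa, xb)) > 0
      use_exact <- !ties && length(xa) <= exact_max_n && length(xb) <= exact_max_n
      wt <- suppressWarnings(stats::wilcox.test(
        xa, xb, exact = use_exact, correct = FALSE))
      c(u = unname(wt$statistic), p = wt$p.value)
    })
    res$pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                               u_statistic = pw["u", ],
                               p = stats::p.adjust(pw["p", ], method = adjust))
  }
  res
}

#' @export
print.grip_trend <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis on '%s': H = %.3f, df = %.0f, p = %.4g\n",
              x$variable, x$kw_statistic, x$kw_df, x$kw_p))
  if (!is.null(x$pairwise)) {
    cat("Pairwise Mann-Whitney u-tests:\n")
    print(x$pairwise, row.names = FALSE)
  } else cat("(pairwise u-tests not run)\n")
  invisible(x)
}

# round half away from zero (reproduces the registry tables' integer
# percents; base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer percentage rates from per-stratum counts
#'
#' Per-stratum event rate as an integer percent,
#' `round(100 * count / n)` with halves rounded away from zero.
#'
#' @param counts per-stratum event counts.
#' @param ns per-stratum sizes (same length, each `n >= count >= 0`).
#' @return integer vector of percentages.
#' @examples
#' rate_table(c(0, 1, 1, 0, 2, 1), c(18, 44, 45, 31, 34, 18))  # 0 2 2 0 6 6
#' @export
rate_table <- function(counts, ns) {
  if (length(counts) != length(ns))
    stop("domain error: counts and ns must have equal length", call. = FALSE)
  if (any(!is.finite(counts)) || any(!is.finite(ns)) ||
      any(counts < 0) || any(ns <= 0) || any(counts > ns))
    stop("domain error: need 0 <= count <= n for every stratum", call. = FALSE)
  as.integer(round_half_away(100 * counts / ns))
}

#' Median pain trajectory per stratum
#'
#' Median NAS pain score per stratum for discharge and each follow-up
#' timepoint (rest/exercise split), mirroring a follow-up pain table.
#'
#' @param cohort registry data.frame with the nine `pain_*` columns.
#' @param by stratum column.
#' @return data.frame, one row per stratum, columns `stratum` plus the nine
#'   pain columns holding medians.
#' @export
pain_trajectory <- function(cohort, by = "complexity_score") {
  cols <- c("pain_discharge", "pain_1m_rest", "pain_1m_exercise",
            "pain_6m_rest", "pain_6m_exercise", "pain_1y_rest",
            "pain_1y_exercise", "pain_3y_rest", "pain_3y_exercise")
  stopifnot(is.data.frame(cohort), all(cols %in% names(cohort)),
            by %in% names(cohort))
  strata <- sort(unique(cohort[[by]]))
  out <- data.frame(stratum = strata)
  for (cn in cols)
    out[[cn]] <- vapply(strata, function(s)
      stats::median(cohort[[cn]][cohort[[by]] == s]), numeric(1))
  out
}
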