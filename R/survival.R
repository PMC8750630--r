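# Kaplan-Meier estimation, log-rank testing and best-expression-cutoff
# scanning for survival-based prioritization of candidate antigens.

# Normalize a cohort data frame: needs time (years) and event columns;
# `time_years` is accepted as an alias. Expression is looked up either in
# `expression` or in `expression_<gene>`.
.as_cohort <- function(cohort, gene = NULL) {
  if (!"time" %in% names(cohort) && "time_years" %in% names(cohort)) {
    cohort$time <- cohort$time_years
  }
  if (!all(c("time", "event") %in% names(cohort))) {
    stop("cohort must have 'time' (years) and 'event' columns", call. = FALSE)
  }
  if (any(cohort$time < 0)) stop("negative follow-up time", call. = FALSE)
  cohort$event <- as.integer(as.logical(cohort$event))
  if (!is.null(gene)) {
    col <- if (paste0("expression_", gene) %in% names(cohort))
      paste0("expression_", gene) else gene
    if (!col %in% names(cohort)) {
      stop("no expression column for gene '", gene, "'", call. = FALSE)
    }
    cohort$expression <- cohort[[col]]
  }
  if (!is.null(cohort$expression) && any(!is.finite(cohort$expression))) {
    stop("non-finite expression values", call. = FALSE)
  }
  cohort
}

#' Kaplan-Meier survival fraction at a fixed time
#'
#' Product-limit estimate of the survival function at time `t` (years), with
#' the standard life-table tie convention (deaths precede censorings at equal
#' times). Without censoring this equals the empirical fraction surviving
#' past `t`.
#'
#' @param cohort Data frame with `time` (years) and `event` columns.
#' @param t Non-negative time in years.
#' @return Survival fraction in \[0, 1\].
#' @export
km_survival <- function(cohort, t) {
  if (t < 0) stop("domain error: t must be >= 0", call. = FALSE)
  cohort <- .as_cohort(cohort)
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  summary(fit, times = t, extend = TRUE)$surv
}

#' Two-group log-rank test
#'
#' @param groupA,groupB Cohort data frames (`time`, `event`).
#' @return p-value of the two-group log-rank chi-square test. Identical
#'   groups give p = 1; a group without any event triggers a warning but the
#'   statistic is still computed.
#' @export
logrank_test <- function(groupA, groupB) {
  groupA <- .as_cohort(groupA); groupB <- .as_cohort(groupB)
  if (nrow(groupA) == 0 || nrow(groupB) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (sum(groupA$event) == 0 || sum(groupB$event) == 0) {
    warning("a group has zero observed events", call. = FALSE)
  }
  dat <- rbind(
    data.frame(time = groupA$time, event = groupA$event, grp = "A"),
    data.frame(time = groupB$time, event = groupB$event, grp = "B")
  )
  if (sum(dat$event) == 0) return(1)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  chisq <- sd$chisq
  if (!is.finite(chisq)) return(1)
  pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Best-expression-cutoff scan
#'
#' Scans candidate expression cutoffs (quantiles of the expression values
#' between configurable bounds), dichotomizes the cohort at each, runs a
#' log-rank test, and returns the cutoff minimizing the p-value -- the
#' "best expression cutoff p-score" semantics used by pathology-atlas
#' prognostics. No multiple-testing correction is applied across the scan;
#' the resulting minimum-p is anti-conservative under the null, which is a
#' property of the score, not a bug (quantified in the test suite).
#'
#' @param cohort Data frame with `time`, `event` and an expression column
#'   (either `expression` or `expression_<gene>`).
#' @param gene Optional gene name selecting the expression column.
#' @param probs Quantile grid for candidate cutoffs (default 20%--80% in 5%
#'   steps).
#' @param min_n Minimum cohort size (default 20).
#' @param t_report Survival readout horizon in years (default 5).
#' @return A `cutoff_scan` object: `gene_id`, `best_cutoff`, `p_score`,
#'   `direction` (`"unfavorable"` iff the high-expression group has lower
#'   survival at `t_report`), `surv5_high`, `surv5_low`, and the full `grid`
#'   of (cutoff, p) pairs.
#' @export
best_cutoff_scan <- function(cohort, gene = NULL,
                             probs = seq(0.2, 0.8, by = 0.05),
                             min_n = 20L, t_report = 5) {
  cohort <- .as_cohort(cohort, gene)
  if (is.null(cohort$expression)) {
    stop("cohort has no expression column", call. = FALSE)
  }
  if (nrow(cohort) < min_n) {
    stop("cohort smaller than ", min_n, " subjects", call. = FALSE)
  }
  if (length(unique(cohort$expression)) < 2) {
    stop("scan error: expression is constant", call. = FALSE)
  }
  cand <- sort(unique(quantile(cohort$expression, probs = probs,
                               type = 7, names = FALSE)))
  grid <- data.frame(cutoff = numeric(), p = numeric())
  for (cut in cand) {
    high <- cohort$expression >= cut
    if (!any(high) || all(high)) next
    p <- logrank_test(cohort[high, , drop = FALSE],
                      cohort[!high, , drop = FALSE])
    grid <- rbind(grid, data.frame(cutoff = cut, p = p))
  }
  if (nrow(grid) == 0) {
    stop("scan error: no cutoff produced two non-empty groups",
         call. = FALSE)
  }
  best <- grid[which.min(grid$p), ]  # which.min: lowest cutoff wins ties
  high <- cohort$expression >= best$cutoff
  surv_high <- km_survival(cohort[high, , drop = FALSE], t_report)
  surv_low <- km_survival(cohort[!high, , drop = FALSE], t_report)
  structure(list(
    gene_id = gene %||% "expression",
    best_cutoff = best$cutoff,
    p_score = best$p,
    direction = if (surv_high < surv_low) "unfavorable" else "favorable",
    surv5_high = surv_high,
    surv5_low = surv_low,
    t_report = t_report,
    grid = grid
  ), class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "Best-cutoff scan [%s]: cutoff %.4g, p-score %.4g (%s)\n",
    x$gene_id, x$best_cutoff, x$p_score, x$direction))
  cat(sprintf("  %g-year survival: high %.1f%%  low %.1f%%\n",
              x$t_report, 100 * x$surv5_high, 100 * x$surv5_low))
  invisible(x)
}

#' Five-year survival difference between expression groups
#'
#' @param cohort Cohort with `time`, `event` and expression (see
#'   [best_cutoff_scan()]).
#' @param cutoff Expression cutoff; `>= cutoff` defines the high group.
#' @param gene Optional gene selecting the expression column.
#' @param t Readout horizon in years (default 5).
#' @return `100 * (KM_low(t) - KM_high(t))`, in percentage points; positive
#'   when high expression carries the worse survival.
#' @export
five_year_delta <- function(cohort, cutoff, gene = NULL, t = 5) {
  cohort <- .as_cohort(cohort, gene)
  high <- cohort$expression >= cutoff
  if (!any(high)) stop("empty group: high", call. = FALSE)
  if (all(high)) stop("empty group: low", call. = FALSE)
  100 * (km_survival(cohort[!high, , drop = FALSE], t) -
           km_survival(cohort[high, , drop = FALSE], t))
}
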