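# Group statistics: mean +/- SEM summaries, pooled Student's t-tests with the
# inclusive star scheme (*p<=0.05, **p<=0.01, ***p<=0.001, ****p<=0.0001),
# percent change versus control, and the dose-response report across all
# modalities. The experimental unit is the fiber: per-fiber values are
# averaged before any group statistic.

#' Mean and standard error of the mean for one group
#'
#' @param values Per-fiber values (n >= 2 so the SEM is defined).
#' @param group Group label (dye count).
#' @return One-row data frame of class `group_summary` with `group`, `n`,
#'   `mean`, `sem` (`sd/sqrt(n)` with the n-1 denominator).
#' @export
#' @examples
#' group_summary(c(1, 2, 3), group = 0)  # mean 2, sem 1/sqrt(3)
group_summary <- function(values, group = NA_integer_) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("need >= 2 fibers for a group summary (SEM undefined)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  structure(data.frame(group = group, n = length(values), mean = mean(values),
                       sem = stats::sd(values) / sqrt(length(values))),
            class = c("group_summary", "data.frame"))
}

#' Significance stars for a p-value
#'
#' Inclusive thresholds: `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001,
#' `****` p <= 0.0001; otherwise `ns`.
#'
#' @param p A p-value in \[0, 1\].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
p_stars <- function(p) {
  check_scalar(p, "p", lower = 0, upper = 1)
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else "ns"
}

#' Two-sample Student's t-test
#'
#' Two-tailed, pooled-variance (classic Student) test with
#' `df = nA + nB - 2`, the convention matching mean +/- SEM group reporting;
#' Welch's unequal-variance variant is available behind `welch = TRUE`.
#' Degenerate zero-variance inputs are handled explicitly: equal means give
#' `t = 0, p = 1`; unequal means give `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b Numeric samples, each with >= 2 values.
#' @param welch Use Welch's t-test instead of pooled variance.
#' @return List with `t`, `p`, `df`, `stars`, `degenerate`.
#' @export
#' @examples
#' pooled_t_test(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, p ~ 0.0214
pooled_t_test <- function(a, b, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need >= 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2L,
                  stars = "ns", degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2L, stars = "****",
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  p <- ht$p.value
  list(t = unname(ht$statistic), p = p, df = unname(ht$parameter),
       stars = p_stars(p), degenerate = FALSE)
}

#' Percent change of a treated mean versus control
#'
#' `100 * (treated - control) / control`, sign preserved; a negative value of
#' magnitude x is reported in prose as an "x % reduction".
#'
#' @param control_mean Control group mean (non-zero).
#' @param treated_mean Treated group mean.
#' @return Signed percent change.
#' @export
#' @examples
#' percent_change(430.2, 343.3)  # -20.2 => a 20 % reduction
percent_change <- function(control_mean, treated_mean) {
  check_scalar(control_mean, "control_mean")
  check_scalar(treated_mean, "treated_mean")
  if (control_mean == 0) stop("control mean must be non-zero", call. = FALSE)
  100 * (treated_mean - control_mean) / control_mean
}

#' Dose-response report across all modalities
#'
#' For every numeric feature column: one table of group, n, mean, SEM,
#' percent change versus control, pooled-t p-value and stars. When a cohort
#' manifest with `truth_*` columns is supplied, a truth-vs-estimate recovery
#' table (per group and metric: configured truth, estimated group mean,
#' relative error) is appended.
#'
#' @param features Data frame with `fiber_id`, `dye_count` and one numeric
#'   column per metric (one row per fiber).
#' @param manifest Optional manifest data frame from [gen_cohort()] /
#'   [read_manifest()].
#' @param welch Use Welch's t-test instead of pooled Student.
#' @return List with `tables` (named list of per-metric data frames) and
#'   `recovery` (data frame or `NULL`).
#' @export
dose_response_report <- function(features, manifest = NULL, welch = FALSE) {
  if (!is.data.frame(features) ||
      !all(c("fiber_id", "dye_count") %in% names(features))) {
    stop("`features` needs fiber_id and dye_count columns", call. = FALSE)
  }
  if (!0 %in% features$dye_count) {
    stop("control group (dye count 0) missing", call. = FALSE)
  }
  metrics <- names(features)[vapply(features, is.numeric, TRUE)]
  metrics <- setdiff(metrics, c("dye_count"))
  groups <- sort(unique(features$dye_count))

  tables <- list()
  for (m in metrics) {
    ctrl <- features[[m]][features$dye_count == 0]
    ctrl <- ctrl[is.finite(ctrl)]
    rows <- list()
    for (g in groups) {
      v <- features[[m]][features$dye_count == g]
      v <- v[is.finite(v)]
      if (length(v) < 2L) next
      gs <- group_summary(v, group = g)
      if (g == 0) {
        pc <- 0; tt <- list(t = 0, p = 1, stars = "ns")
      } else {
        pc <- if (mean(ctrl) != 0) percent_change(mean(ctrl), mean(v)) else NA_real_
        tt <- pooled_t_test(ctrl, v, welch = welch)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, n = gs$n, mean = gs$mean, sem = gs$sem, pct_change = pc,
        t = tt$t, p = tt$p, stars = tt$stars, stringsAsFactors = FALSE)
    }
    tables[[m]] <- do.call(rbind, rows)
  }

  recovery <- NULL
  if (!is.null(manifest)) {
    truth_cols <- grep("^truth_", names(manifest), value = TRUE)
    rec <- list()
    for (tc in truth_cols) {
      m <- sub("^truth_", "", tc)
      if (!m %in% metrics) next
      for (g in groups) {
        truth <- unique(manifest[[tc]][manifest$dye_count == g])
        if (length(truth) != 1L || !is.finite(truth) || truth == 0) next
        v <- features[[m]][features$dye_count == g]
        v <- v[is.finite(v)]
        if (!length(v)) next
        est <- mean(v)
        rec[[length(rec) + 1L]] <- data.frame(
          metric = m, group = g, truth = truth, estimate = est,
          rel_error = (est - truth) / truth, stringsAsFactors = FALSE)
      }
    }
    recovery <- if (length(rec)) do.call(rbind, rec) else NULL
  }
  list(tables = tables, recovery = recovery)
}
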