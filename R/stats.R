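# Group summaries and significance tests for between-species structome
# comparisons: per-metric mean/SD over cells, two-sample t-tests (Welch by
# default, classical pooled as an option) computable from summary
# statistics alone — required when the comparison group is only available
# as published (n, mean, SD) — and one-way ANOVA.

#' Summarise one metric over a group of cells
#'
#' @param values numeric vector of per-cell values.
#' @param group_label label of the group (e.g. a species).
#' @param metric name of the metric.
#' @return a one-row data frame of class `"metric_summary"`: `group`,
#'   `metric`, `n`, `mean`, `sd` (sample SD, n-1 denominator), `min`, `max`.
#'   For `n = 1` the SD is `NA`.
#' @export
#' @examples
#' summarize_metric(c(3.90, 3.41, 2.76, 2.16, 3.10, 2.07, 7.41),
#'                  "M. smegmatis", "length")
summarize_metric <- function(values, group_label = "", metric = "") {
  if (length(values) < 1L || any(!is.finite(values))) {
    stop("'values' must be a non-empty vector of finite numbers",
         call. = FALSE)
  }
  out <- data.frame(
    group = as.character(group_label),
    metric = as.character(metric),
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
    min = min(values),
    max = max(values),
    stringsAsFactors = FALSE
  )
  class(out) <- c("metric_summary", "data.frame")
  out
}

# accept a metric_summary row, or any list/one-row df with n, mean, sd
as_summary_triplet <- function(g) {
  if (is.data.frame(g)) g <- as.list(g[1, ])
  need <- c("n", "mean", "sd")
  if (!all(need %in% names(g))) {
    stop("group summaries need fields n, mean and sd", call. = FALSE)
  }
  list(n = as.numeric(g$n), mean = as.numeric(g$mean), sd = as.numeric(g$sd))
}

new_test_result <- function(statistic, df, p_value, test_name,
                            two_sided = TRUE, extra = list()) {
  structure(
    c(list(statistic = statistic, df = df, p_value = p_value,
           test_name = test_name, two_sided = two_sided), extra),
    class = "structome_test"
  )
}

#' @export
print.structome_test <- function(x, ...) {
  p_txt <- if (x$p_value < 1e-15) "< 1e-15" else format(x$p_value, digits = 4)
  cat(sprintf("%s: statistic = %.4g, df = %.4g, p = %s (%s)\n",
              x$test_name, x$statistic, x$df, p_txt,
              if (x$two_sided) "two-sided" else "one-sided"))
  invisible(x)
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sided two-sample t-test from (n, mean, SD) triplets
#' only, so that measured cells can be compared against groups available
#' solely as published summaries. The default Welch variant uses
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom; `pooled` is the classical equal-variance test with
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param g1,g2 group summaries: [summarize_metric()] rows or lists with
#'   `n`, `mean`, `sd`.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return a `structome_test` with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' msm <- list(n = 7, mean = 1170, sd = 180)
#' mtb <- list(n = 5, mean = 720, sd = 170)
#' t_test_from_summaries(msm, mtb)
t_test_from_summaries <- function(g1, g2, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  a <- as_summary_triplet(g1)
  b <- as_summary_triplet(g2)
  if (a$n < 2 || b$n < 2) {
    stop("both groups need n >= 2", call. = FALSE)
  }
  if (!is.finite(a$sd) || !is.finite(b$sd) || (a$sd == 0 && b$sd == 0)) {
    stop("at least one group must have a positive, finite SD", call. = FALSE)
  }
  delta <- a$mean - b$mean
  if (variant == "welch") {
    v1 <- a$sd^2 / a$n
    v2 <- b$sd^2 / b$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (a$n - 1) + v2^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- if (delta == 0) 0 else delta / se
  p <- 2 * stats::pt(-abs(t), df)
  new_test_result(t, df, p,
                  test_name = sprintf("Two-sample t-test (%s)", variant),
                  extra = list(group1 = a, group2 = b))
}

#' Two-sample t-test from raw values
#'
#' Identical, by construction, to [t_test_from_summaries()] applied to the
#' [summarize_metric()] of each group.
#'
#' @param values1,values2 numeric vectors, each with at least 2 values.
#' @inheritParams t_test_from_summaries
#' @return a `structome_test`.
#' @export
t_test_from_values <- function(values1, values2,
                               variant = c("welch", "pooled")) {
  if (length(values1) < 2 || length(values2) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  t_test_from_summaries(summarize_metric(values1), summarize_metric(values2),
                        variant = match.arg(variant))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across k groups (delegated to
#' [stats::oneway.test()] with `var.equal = TRUE`): F statistic with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups a list of numeric vectors, one per group; at least 2
#'   groups with at least 2 values each.
#' @return a `structome_test` with the F statistic, numerator df in `df`
#'   and denominator df in `df2`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2)) {
    stop("need at least 2 groups with at least 2 values each", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  f <- unname(ht$statistic)
  p <- unname(ht$p.value)
  # zero between- and within-group SS (all groups identical): F = 0, p = 1
  if (is.nan(f)) {
    f <- 0
    p <- 1
  }
  new_test_result(f, unname(ht$parameter[1]), p, test_name = "One-way ANOVA",
                  extra = list(df2 = unname(ht$parameter[2])))
}

#' Compare two profile tables metric by metric
#'
#' For each metric, summarises both groups and runs the chosen two-sample
#' t-test. The second group may be a profile table of measured cells or a
#' summary table (rows with `metric`, `n`, `mean`, `sd`) such as published
#' species summaries. No multiplicity correction is applied by default;
#' set `p_adjust = "bonferroni"` for a conservative correction.
#'
#' @param table_a a profile table ([cell_profile] rows), >= 2 cells.
#' @param table_b a second profile table, or a summary table with columns
#'   `metric`, `n`, `mean`, `sd`.
#' @param metrics character vector of profile metrics to compare; default
#'   all numeric profile metrics present in both inputs.
#' @param alpha significance level for the `significant` flag.
#' @param variant t-test variant, see [t_test_from_summaries()].
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return a data frame: per metric, both (n, mean, sd), t, df, p, and the
#'   significance flag at `alpha`.
#' @export
compare_profiles <- function(table_a, table_b, metrics = NULL, alpha = 0.05,
                             variant = c("welch", "pooled"),
                             p_adjust = "none") {
  variant <- match.arg(variant)
  numeric_metrics <- setdiff(profile_columns, c("cell_id", "n_sections"))
  b_is_summary <- is.data.frame(table_b) &&
    all(c("metric", "n", "mean", "sd") %in% names(table_b)) &&
    !all(numeric_metrics %in% names(table_b))
  if (nrow(table_a) < 2) stop("'table_a' needs >= 2 cells", call. = FALSE)
  if (!b_is_summary && nrow(table_b) < 2) {
    stop("'table_b' needs >= 2 cells", call. = FALSE)
  }
  available_b <- if (b_is_summary) unique(table_b$metric) else {
    intersect(numeric_metrics, names(table_b))
  }
  if (is.null(metrics)) {
    metrics <- intersect(intersect(numeric_metrics, names(table_a)),
                         available_b)
  }
  unknown <- setdiff(metrics, intersect(numeric_metrics, names(table_a)))
  unknown <- union(unknown, setdiff(metrics, available_b))
  if (length(unknown)) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(metrics, function(m) {
    s1 <- summarize_metric(table_a[[m]], metric = m)
    s2 <- if (b_is_summary) {
      as_summary_triplet(table_b[table_b$metric == m, ][1, ])
    } else {
      as_summary_triplet(summarize_metric(table_b[[m]], metric = m))
    }
    if (isTRUE(s1$sd == 0) && isTRUE(s2$sd == 0)) {
      # both groups degenerate: identical means are trivially equal
      # (p = 1); differing means admit no t-test (NA, with a warning)
      if (s1$mean == s2$mean) {
        tt <- list(statistic = 0, df = s1$n + s2$n - 2, p_value = 1)
      } else {
        warning(sprintf("metric '%s': zero variance in both groups", m),
                call. = FALSE)
        tt <- list(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
      }
    } else {
      tt <- t_test_from_summaries(s1, s2, variant = variant)
    }
    data.frame(metric = m,
               n1 = s1$n, mean1 = s1$mean, sd1 = s1$sd,
               n2 = s2$n, mean2 = s2$mean, sd2 = s2$sd,
               statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Summarise every metric of a profile table
#'
#' @param profiles a profile table.
#' @param group_label label attached to each summary row.
#' @return a summary table: one [summarize_metric()] row per metric.
#' @export
summarize_profiles <- function(profiles, group_label = "") {
  metrics <- setdiff(intersect(profile_columns, names(profiles)),
                     c("cell_id", "n_sections"))
  out <- do.call(rbind, lapply(metrics, function(m) {
    summarize_metric(profiles[[m]], group_label = group_label, metric = m)
  }))
  class(out) <- c("metric_summary", "data.frame")
  out
}
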