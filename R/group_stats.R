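#' Normality test (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with mean and SD
#' estimated from the sample (Lilliefors correction, via
#' [nortest::lillie.test()]), as appropriate when the reference parameters
#' are unknown. The sample is called normal when `p >= 0.05`. Constant
#' samples are non-normal by convention (degenerate SD), with a warning.
#' Samples of size 3 are too small for the Lilliefors null distribution and
#' are treated as normal with a warning (normality cannot be rejected).
#'
#' @param sample numeric vector, n >= 3.
#' @return A one-row tibble: statistic, p_value, is_normal, n.
#' @export
test_normality <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 3) stop("normality test needs n >= 3")
  if (stats::sd(sample) == 0) {
    warning("degenerate sample (zero SD): treated as non-normal")
    return(tibble::tibble(statistic = NA_real_, p_value = 0,
                          is_normal = FALSE, n = n))
  }
  if (n < 4) {
    warning("n = 3: normality cannot be rejected at this size")
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          is_normal = TRUE, n = n))
  }
  kt <- nortest::lillie.test(sample)
  tibble::tibble(statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 is_normal = kt$p.value >= 0.05,
                 n = n)
}

summarize_sample <- function(x, normal) {
  if (normal) {
    sprintf("%.4g ± %.3g", mean(x), stats::sd(x))
  } else {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    sprintf("%.4g (%.4g~%.4g)", q[2], q[1], q[3])
  }
}

#' Two-group comparison with a normality gate
#'
#' Both samples are first tested for normality ([test_normality()]). If both
#' pass, the groups are compared with a two-sided two-sample Student's
#' t-test (equal variances by default); otherwise with a two-sided
#' Mann-Whitney U test. Group summaries follow the matching convention:
#' mean with SD when normal, median with the 25th-75th percentile IQR
#' otherwise.
#'
#' @param a,b numeric samples, each n >= 3.
#' @param metric_name label for the compared quantity.
#' @param group_labels length-2 character vector.
#' @param var_equal equal-variance t-test (default `TRUE`); set `FALSE` for
#'   the Welch variant.
#' @param alpha significance level (reported, default 0.05).
#' @return A `group_comparison` object: list with metric_name, group_labels,
#'   summaries, normality tibbles, test_used ("students_t" or
#'   "mann_whitney_u"), statistic, p_value, significant, alpha, and the raw
#'   samples.
#' @export
compare_groups <- function(a, b, metric_name = "metric",
                           group_labels = c("A", "B"), var_equal = TRUE,
                           alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("each group needs n >= 3")
  na <- suppressWarnings(test_normality(a))
  nb <- suppressWarnings(test_normality(b))
  both_normal <- na$is_normal && nb$is_normal
  if (both_normal) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    test_used <- "students_t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    test_used <- "mann_whitney_u"
    statistic <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(list(metric_name = metric_name,
                 group_labels = group_labels,
                 summary = c(summarize_sample(a, both_normal),
                             summarize_sample(b, both_normal)),
                 normality = dplyr::bind_rows(
                   dplyr::mutate(na, group = group_labels[1]),
                   dplyr::mutate(nb, group = group_labels[2])),
                 test_used = test_used,
                 statistic = statistic,
                 p_value = p,
                 significant = p < alpha,
                 alpha = alpha,
                 samples = list(a = a, b = b)),
            class = "group_comparison")
}

#' @exportS3Method base::print
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s [%s] vs %s [%s]; %s, statistic = %.4g, P = %.4g%s\n",
              x$metric_name, x$group_labels[1], x$summary[1],
              x$group_labels[2], x$summary[2], x$test_used, x$statistic,
              x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Tidy a group comparison
#'
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return A one-row tibble: metric, group summaries, test_used, statistic,
#'   p_value, significant.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric_name,
                 group1 = x$group_labels[1],
                 summary1 = x$summary[1],
                 group2 = x$group_labels[2],
                 summary2 = x$summary[2],
                 test_used = x$test_used,
                 statistic = x$statistic,
                 p_value = x$p_value,
                 significant = x$significant)
}

#' One-line summary of a group comparison
#' @param x a `group_comparison`.
#' @param ... unused.
#' @return A one-row tibble: metric, n1, n2, test_used, p_value, alpha.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(metric = x$metric_name,
                 n1 = length(x$samples$a),
                 n2 = length(x$samples$b),
                 test_used = x$test_used,
                 p_value = x$p_value,
                 alpha = x$alpha)
}

#' Compare every metric column between two groups
#'
#' Takes a tidy per-specimen table (one row per specimen, a grouping column
#' and one column per metric) and runs [compare_groups()] per metric,
#' mirroring the two-group summary-table layout ("value, value, P"). No
#' multiple-testing correction is applied (noted in the table footer).
#'
#' @param table data frame with a grouping column and numeric metric
#'   columns.
#' @param grouping name of the grouping column (exactly 2 levels required).
#' @param metrics metric column names; default `c("CC", "NSE", "APL")`.
#' @param ... passed to [compare_groups()].
#' @return A `group_comparison_set`: list of `group_comparison` objects with
#'   a combined tidy table in `$table`.
#' @export
batch_compare <- function(table, grouping = "group",
                          metrics = c("CC", "NSE", "APL"), ...) {
  if (!grouping %in% names(table)) {
    stop(sprintf("missing grouping column '%s'", grouping))
  }
  gl <- sort(unique(as.character(table[[grouping]])))
  if (length(gl) != 2) {
    stop(sprintf("need exactly 2 groups, found %d", length(gl)))
  }
  missing_cols <- setdiff(metrics, names(table))
  if (length(missing_cols)) {
    stop(sprintf("missing metric column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  results <- lapply(metrics, function(m) {
    a <- table[[m]][table[[grouping]] == gl[1]]
    b <- table[[m]][table[[grouping]] == gl[2]]
    compare_groups(a, b, metric_name = m, group_labels = gl, ...)
  })
  names(results) <- metrics
  out <- structure(list(comparisons = results,
                        table = dplyr::bind_rows(lapply(results, tidy)),
                        footer = "no multiple-testing correction applied"),
                   class = "group_comparison_set")
  out
}

#' @exportS3Method base::print
print.group_comparison_set <- function(x, ...) {
  for (cmp in x$comparisons) print(cmp)
  cat("(", x$footer, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.group_comparison_set <- function(x, ...) x$table
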