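# Cohort statistics stage: descriptives with 95% CIs, normality-gated
# two-group comparisons (Welch t vs Mann-Whitney U) and correlation
# screens (Pearson vs Spearman), plus the table writer.

# Shapiro-Wilk gate at alpha = 0.05; constant samples never pass
is_normalish <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value > alpha
}

#' Descriptive summary of one variable
#'
#' Mean, sample standard deviation (n - 1), 95% confidence interval using
#' the t quantile (`mean +/- t(n-1, 0.975) sd / sqrt(n)`), median,
#' interquartile bounds and a Shapiro-Wilk normality flag (alpha 0.05).
#'
#' @param values numeric vector, >= 2 finite values.
#' @param variable variable name carried in the output.
#' @return object of class `fm_descriptive` (also a plain list):
#'   `variable, n, mean, sd, ci_low, ci_high, median, iqr_low, iqr_high,
#'   normal_flag`.
#' @export
describe <- function(values, variable = "value") {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2L) stop("describe requires at least 2 finite values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  half <- stats::qt(0.975, df = n - 1L) * s / sqrt(n)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(variable = variable, n = n, mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half,
                 median = q[2L], iqr_low = q[1L], iqr_high = q[3L],
                 normal_flag = is_normalish(x)),
            class = "fm_descriptive")
}

#' Two-group comparison with a normality gate
#'
#' If both groups pass the Shapiro-Wilk gate (alpha 0.05), a two-tailed
#' Welch t-test; otherwise a Mann-Whitney U test with normal approximation
#' and tie correction. Two-sided p either way.
#'
#' @param values_a,values_b numeric vectors, each >= 3 finite values.
#' @param variable variable name carried in the output.
#' @param labels length-2 character vector of group labels.
#' @return object of class `fm_group_comparison`: `variable, labels,
#'   n_a, mean_a, sd_a, n_b, mean_b, sd_b, test_used` (`"t"` or
#'   `"mann_whitney"`), `statistic`, `p_value`.
#' @export
compare_groups <- function(values_a, values_b, variable = "value",
                           labels = c("A", "B")) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 3L || length(b) < 3L) {
    stop("compare_groups requires at least 3 finite values per group",
         call. = FALSE)
  }
  parametric <- is_normalish(a) && is_normalish(b)
  if (parametric) {
    ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    test_used <- "t"
  } else {
    ht <- stats::wilcox.test(a, b, alternative = "two.sided",
                             exact = FALSE, correct = TRUE)
    test_used <- "mann_whitney"
  }
  structure(list(variable = variable, labels = labels,
                 n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
                 n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
                 test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "fm_group_comparison")
}

#' Correlation between two variables
#'
#' `method = "auto"` follows the cohort analysis convention: Pearson when
#' both variables pass the normality gate, Spearman rank otherwise.
#'
#' @param x,y paired numeric vectors, >= 4 complete pairs, each with
#'   nonzero variance.
#' @param variable_x,variable_y names carried in the output.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return object of class `fm_correlation`: `pair, method, r, p_value, n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      variable_x = "x", variable_y = "y") {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) {
    stop("correlate requires at least 4 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlate requires nonzero variance in both vectors", call. = FALSE)
  }
  if (method == "auto") {
    method <- if (is_normalish(x) && is_normalish(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(pair = c(variable_x, variable_y), method = method,
                 r = unname(ct$estimate), p_value = ct$p.value, n = length(x)),
            class = "fm_correlation")
}

#' Build cohort summary tables
#'
#' From a measurement table (data frame or CSV path with the standard
#' columns), produces:
#' \describe{
#'   \item{descriptives}{one row per measure: n, mean, sd, 95% CI, median,
#'     IQR bounds, normality flag.}
#'   \item{subgroups}{per measure and per grouping (sex M/F, side L/R):
#'     group sizes, means, sds, the gated test used, its statistic and
#'     two-sided p.}
#'   \item{correlations}{the offset (FNSAO) against age and every other
#'     measure, auto-gated Pearson/Spearman.}
#' }
#' Deterministic given the input; rerunning on the same CSV reproduces the
#' output byte for byte.
#'
#' @param measurements data frame or path to a measurement CSV.
#' @param out_dir optional directory; when given, writes
#'   `table1_descriptives.csv`, `table3_subgroups.csv`,
#'   `correlations.csv`.
#' @return list of the three data frames, invisibly when writing.
#' @export
build_tables <- function(measurements, out_dir = NULL) {
  df <- if (is.character(measurements)) read_measurements(measurements)
        else measurements
  if (nrow(df) < 2L) stop("build_tables requires at least 2 records", call. = FALSE)
  missing <- setdiff(.measure_fields, names(df))
  if (length(missing)) {
    stop(sprintf("measurement table lacks columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }

  table1 <- do.call(rbind, lapply(.measure_fields, function(f) {
    d <- describe(df[[f]], f)
    as.data.frame(unclass(d), stringsAsFactors = FALSE)
  }))

  groupings <- list(sex = c("M", "F"), side = c("L", "R"))
  table3 <- do.call(rbind, unlist(recursive = FALSE, lapply(names(groupings), function(gv) {
    lv <- groupings[[gv]]
    lapply(.measure_fields, function(f) {
      cmp <- compare_groups(df[[f]][df[[gv]] == lv[1L]],
                            df[[f]][df[[gv]] == lv[2L]],
                            variable = f, labels = lv)
      data.frame(grouping = gv, variable = f,
                 group_a = lv[1L], n_a = cmp$n_a, mean_a = cmp$mean_a,
                 sd_a = cmp$sd_a,
                 group_b = lv[2L], n_b = cmp$n_b, mean_b = cmp$mean_b,
                 sd_b = cmp$sd_b,
                 test_used = cmp$test_used, statistic = cmp$statistic,
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    })
  })))

  partners <- c("age", setdiff(.measure_fields, "fnsao_mm"))
  correlations <- do.call(rbind, lapply(partners, function(v) {
    ct <- correlate(df[[v]], df$fnsao_mm, method = "auto",
                    variable_x = v, variable_y = "fnsao_mm")
    data.frame(variable = v, against = "fnsao_mm", method = ct$method,
               r = ct$r, p_value = ct$p_value, n = ct$n,
               stringsAsFactors = FALSE)
  }))

  out <- list(descriptives = table1, subgroups = table3,
              correlations = correlations)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(table1, file.path(out_dir, "table1_descriptives.csv"),
                     row.names = FALSE)
    utils::write.csv(table3, file.path(out_dir, "table3_subgroups.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    return(invisible(out))
  }
  out
}
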