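#' Summarize a group of marker values
#'
#' Median with Tukey hinges (lower and upper fourths) as the quartiles —
#' the same definition used for Tukey box plots, so summaries printed here
#' match the "median (IQR: Q1–Q3)" reporting style.
#'
#' @param values Numeric vector (NAs dropped), n >= 1 after removal.
#' @param label Optional group label.
#' @return A one-row tibble with `group`, `n`, `median`, `iqr_low`,
#'   `iqr_high`.
#' @export
summarize_group <- function(values, label = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values", call. = FALSE)
  fn <- stats::fivenum(values)
  tibble::tibble(group = label, n = length(values), median = fn[3],
                 iqr_low = fn[2], iqr_high = fn[4])
}

shapiro_p <- function(x) {
  if (length(unique(x)) < 3L || length(x) < 3L) return(0)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Compare two groups with a normality-gated test
#'
#' Applies the Shapiro–Wilk test to each group; if both pass at
#' `alpha_normality`, an unpaired two-tailed Welch t test is used, otherwise
#' a two-tailed Wilcoxon rank-sum test (exact for small samples without
#' ties). The result records which path was taken.
#'
#' @param a,b Numeric vectors (each n >= 3, as required by Shapiro–Wilk).
#' @param alpha_normality Normality gate level.
#' @param test `"auto"` (the normality-gated default) or force `"t"` /
#'   `"wilcoxon"`.
#' @return An object of class `test_result` with `test_name`, `statistic`,
#'   `p_value` and per-group `normality_p`.
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05,
                               test = c("auto", "t", "wilcoxon")) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs n >= 3 for the normality gate", call. = FALSE)
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  use_t <- switch(test, auto = pa > alpha_normality && pb > alpha_normality,
                  t = TRUE, wilcoxon = FALSE)
  if (use_t) {
    ht <- stats::t.test(a, b, var.equal = FALSE)
    name <- "t_unpaired_two_tailed"
  } else {
    exact <- (length(a) + length(b)) <= 12 &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE))
    name <- "wilcoxon_rank_sum_two_tailed"
  }
  structure(
    list(test_name = name, statistic = unname(ht$statistic),
         p_value = ht$p.value, normality_p = c(a = pa, b = pb),
         n = c(a = length(a), b = length(b))),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_name, x$statistic, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' All-pairs comparison of three or more groups (Tukey HSD)
#'
#' Studentized-range adjusted pairwise comparisons controlling the
#' family-wise error rate. With fewer than three groups the caller is
#' directed to [compare_two_groups()] instead.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @return A tibble with one row per pair: `group_1`, `group_2`,
#'   `difference`, `p_adjusted`.
#' @export
tukey_hsd_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3L)
    stop("fewer than 3 groups: use compare_two_groups()", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  fit <- stats::aov(values ~ groups, data = data.frame(values, groups))
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble::tibble(group_1 = vapply(pairs, `[`, "", 1),
                 group_2 = vapply(pairs, `[`, "", 2),
                 difference = unname(tk[, "diff"]),
                 p_adjusted = unname(tk[, "p adj"]))
}

#' Relative amplitude of a treated group (dampening ratio)
#'
#' 100 × treated median / control median: e.g. the reduction of native
#' b-wave amplitudes in ReaChR-expressing animals relative to wild type.
#' Computed from group medians (the summary statistic that the underlying
#' amplitudes are reported by), unrounded.
#'
#' @param treated,control Group summaries from [summarize_group()], or bare
#'   numeric medians.
#' @return The ratio in percent.
#' @export
dampening_ratio <- function(treated, control) {
  med <- function(x) if (is.data.frame(x)) x$median else as.numeric(x)
  tm <- med(treated); cm <- med(control)
  if (!is.finite(cm) || cm <= 0)
    stop("control median must be positive", call. = FALSE)
  100 * tm / cm
}
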