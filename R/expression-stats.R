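#' Relative expression by the delta-delta-Ct method
#'
#' Computes fold change of `gene` in `treated` relative to `control`,
#' normalised to `reference_gene`. Replicate Ct values within a sample are
#' averaged first; each sample then contributes delta-Ct = Ct(gene) -
#' Ct(reference); group delta-Ct is the mean over samples;
#' delta-delta-Ct = deltaCt(treated) - deltaCt(control); and relative
#' expression is `2^-ddCt`. Samples missing a reference Ct are dropped with
#' a warning; a group left empty after drops is an error.
#'
#' @param qpcr data frame with columns `sample`, `group`, `gene`, `ct`.
#' @param gene gene of interest.
#' @param reference_gene housekeeping gene (for example GAPDH or beta-actin).
#' @param treated,control group labels for the contrast.
#' @return A `fold_change_result`: list with `gene`, `contrast`,
#'   `delta_ct_treated`, `delta_ct_control`, `delta_delta_ct`,
#'   `fold_change` (`2^-ddCt`), `percent_change` (`100*(fold-1)`,
#'   negative = suppression), and per-group sample counts `n_treated`,
#'   `n_control`.
#' @examples
#' qpcr <- tibble::tibble(
#'   sample = c("c1", "c1", "t1", "t1"),
#'   group = c("control", "control", "OM", "OM"),
#'   gene = c("CTGF", "GAPDH", "CTGF", "GAPDH"),
#'   ct = c(24, 20, 26, 20))
#' delta_delta_ct(qpcr, "CTGF", "GAPDH", treated = "OM", control = "control")
#' @export
delta_delta_ct <- function(qpcr, gene, reference_gene, treated, control) {
  qpcr <- as_tibble(qpcr)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(qpcr))) {
    abort("`qpcr` must have columns sample, group, gene, ct")
  }
  group_dct <- function(grp) {
    sub <- qpcr[qpcr$group == grp & qpcr$gene %in% c(gene, reference_gene), ]
    if (nrow(sub) == 0L) abort(sprintf("no Ct rows for group '%s'", grp))
    # replicate wells within a sample are averaged before normalisation
    per <- sub |>
      dplyr::group_by(.data$sample, .data$gene) |>
      dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "gene", values_from = "ct")
    if (!gene %in% names(per)) {
      abort(sprintf("gene '%s' has no Ct in group '%s'", gene, grp))
    }
    if (!reference_gene %in% names(per)) {
      abort(sprintf("reference gene '%s' has no Ct in group '%s'",
                    reference_gene, grp))
    }
    missing_ref <- is.na(per[[reference_gene]]) | is.na(per[[gene]])
    if (any(missing_ref)) {
      warn(sprintf("dropping %d sample(s) in group '%s' with missing Ct",
                   sum(missing_ref), grp))
      per <- per[!missing_ref, ]
    }
    if (nrow(per) == 0L) {
      abort(sprintf("group '%s' has no usable samples after drops", grp))
    }
    list(dct = mean(per[[gene]] - per[[reference_gene]]), n = nrow(per))
  }
  tr <- group_dct(treated)
  co <- group_dct(control)
  ddct <- tr$dct - co$dct
  fold <- 2^(-ddct)
  structure(list(
    gene = gene,
    contrast = c(treated = treated, control = control),
    delta_ct_treated = tr$dct,
    delta_ct_control = co$dct,
    delta_delta_ct = ddct,
    fold_change = fold,
    percent_change = 100 * (fold - 1),
    n_treated = tr$n,
    n_control = co$n
  ), class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<ddCt> %s: %s vs %s\n", x$gene,
              x$contrast[["treated"]], x$contrast[["control"]]))
  cat(sprintf("  ddCt = %.4f, fold = %.4f (%+.1f%%)\n",
              x$delta_delta_ct, x$fold_change, x$percent_change))
  invisible(x)
}

#' Percent suppression and induction conversions
#'
#' `percent_suppression(fold)` is `100 * (1 - fold)`: the convention under
#' which a fold change of 0.42 is reported as 58% suppression (a negative
#' value means induction). `percent_induction(fold)` is `100 * (fold - 1)`.
#' `suppression_to_fold()` and `induction_to_fold()` invert them, so both
#' readings of a printed percentage ("reduced by 58%" versus "reduced to
#' 58%") are one call away.
#'
#' @param fold positive fold change (relative expression).
#' @return A percentage (suppression/induction) or a fold (inverses).
#' @examples
#' percent_suppression(0.42) # 58
#' percent_induction(1.71)   # 71
#' suppression_to_fold(58)   # 0.42
#' @export
percent_suppression <- function(fold) {
  if (any(!is.finite(fold)) || any(fold <= 0)) abort("`fold` must be > 0")
  100 * (1 - fold)
}

#' @rdname percent_suppression
#' @export
percent_induction <- function(fold) {
  if (any(!is.finite(fold)) || any(fold <= 0)) abort("`fold` must be > 0")
  100 * (fold - 1)
}

#' @rdname percent_suppression
#' @param percent percentage to convert back to a fold.
#' @export
suppression_to_fold <- function(percent) 1 - percent / 100

#' @rdname percent_suppression
#' @export
induction_to_fold <- function(percent) 1 + percent / 100

new_ttest_result <- function(t, df, p, m1, sd1, n1, m2, sd2, n2) {
  structure(list(t = t, df = df, p = p,
                 mean1 = m1, sd1 = sd1, n1 = n1,
                 mean2 = m2, sd2 = sd2, n2 = n2),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<pooled t-test> t = %.4f, df = %d, p = %.3f\n",
              x$t, x$df, x$p))
  cat(sprintf("  group 1: %.3f +/- %.3f (n=%d); group 2: %.3f +/- %.3f (n=%d)\n",
              x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2))
  invisible(x)
}

#' Pooled two-sample t-test on raw values
#'
#' Equal-variance (Student) independent two-sample t-test with
#' `n1 + n2 - 2` degrees of freedom and a two-sided p-value. The degenerate
#' zero-pooled-variance case returns `t = 0, p = 1` when the means are also
#' equal and is rejected otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return A `ttest_result` with `t`, `df`, `p` and the group summaries.
#' @seealso [t_test_from_summary()] for the summary-statistic form.
#' @export
pooled_t_test <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    abort("both groups need at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_ttest_result(0, length(x) + length(y) - 2L, 1,
                              mean(x), 0, length(x), mean(y), 0, length(y)))
    }
    abort("zero pooled variance with unequal means: t is undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  new_ttest_result(unname(ht$statistic), as.integer(unname(ht$parameter)),
                   ht$p.value,
                   mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y))
}

#' Pooled two-sample t-test from printed summary statistics
#'
#' Same test as [pooled_t_test()], computed from group means, SDs and sizes
#' only -- the form needed to verify published comparisons such as serum
#' TGF-B1 9.62 +/- 8.25 (n = 24) versus 1.85 +/- 3.36 (n = 11). For any raw
#' data with exactly these summaries the two functions agree.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return A `ttest_result`.
#' @examples
#' t_test_from_summary(9.62, 8.25, 24, 1.85, 3.36, 11)
#' @export
t_test_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  n1 <- assert_scalar_count(n1, "n1", min = 2L)
  n2 <- assert_scalar_count(n2, "n2", min = 2L)
  if (sd1 < 0 || sd2 < 0) abort("SDs must be >= 0")
  df <- n1 + n2 - 2L
  pooled_var <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (pooled_var == 0) {
    if (m1 == m2) return(new_ttest_result(0, df, 1, m1, sd1, n1, m2, sd2, n2))
    abort("zero pooled variance with unequal means: t is undefined")
  }
  t <- (m1 - m2) / sqrt(pooled_var * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(t), df)
  new_ttest_result(t, df, p, m1, sd1, n1, m2, sd2, n2)
}

#' Normalise an assay measurement to protein amount or cell count
#'
#' Calcification assays report a raw quantity (for example micrograms of
#' calcium) that must be divided by a per-well denominator -- total protein
#' in mg, or the cell count -- before wells are comparable.
#'
#' @param raw raw assay value (>= 0 in typical use).
#' @param denominator protein amount or cell count; must be > 0.
#' @param raw_unit,denominator_unit unit labels carried into the result.
#' @return A `normalized_measurement`: list with `raw`, `denominator`,
#'   `normalized` (= raw / denominator) and `unit`.
#' @export
normalize_measurement <- function(raw, denominator,
                                  raw_unit = "ug_calcium",
                                  denominator_unit = "mg_protein") {
  if (!is.numeric(denominator) || any(denominator <= 0)) {
    abort("`denominator` must be > 0")
  }
  structure(list(raw = raw, denominator = denominator,
                 normalized = raw / denominator,
                 unit = paste0(raw_unit, "/", denominator_unit)),
            class = "normalized_measurement")
}

#' Descriptive summary of a two-group cohort table
#'
#' Overall and per-group sizes, mean +/- SD for age and every biomarker
#' column, and the count and percentage (one decimal) of a sex category.
#'
#' @param cohort data frame with columns `subject`, `group`, `sex`, `age`
#'   and numeric biomarker columns (any other numeric columns are treated
#'   as biomarkers).
#' @param sex_category the sex label to count (default `"male"`).
#' @return A `cohort_summary`: list with `n_total`, `sex_count`,
#'   `sex_percent`, `age_mean`, `age_sd`, `group_n` (named vector) and
#'   `stats` (tibble `group`, `variable`, `n`, `mean`, `sd`, including an
#'   `"overall"` group).
#' @examples
#' cohort_summary(gen_cohort(aac_cohort_config(seed = 1)))
#' @export
cohort_summary <- function(cohort, sex_category = "male") {
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0L) abort("`cohort` is empty")
  need <- c("group", "sex", "age")
  if (!all(need %in% names(cohort))) {
    abort("`cohort` must have columns group, sex, age")
  }
  vars <- c("age", setdiff(names(cohort)[vapply(cohort, is.numeric, TRUE)],
                           "age"))
  long <- cohort |>
    dplyr::select(dplyr::all_of(c("group", vars))) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable")
  per_group <- long |>
    dplyr::group_by(.data$group, .data$variable) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  overall <- long |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(group = "overall", n = dplyr::n(),
                     mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::select("group", "variable", "n", "mean", "sd")
  group_n <- table(cohort$group)
  structure(list(
    n_total = nrow(cohort),
    sex_category = sex_category,
    sex_count = sum(cohort$sex == sex_category),
    sex_percent = round(100 * sum(cohort$sex == sex_category) / nrow(cohort), 1),
    age_mean = mean(cohort$age),
    age_sd = stats::sd(cohort$age),
    group_n = stats::setNames(as.integer(group_n), names(group_n)),
    stats = dplyr::bind_rows(per_group, overall)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort> n = %d; %s: %d (%.1f%%); age %.1f +/- %.1f\n",
              x$n_total, x$sex_category, x$sex_count, x$sex_percent,
              x$age_mean, x$age_sd))
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_n), x$group_n),
                         collapse = " "), "\n")
  invisible(x)
}
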