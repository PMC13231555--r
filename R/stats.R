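#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Computes the rank-sum U statistic for `x` versus `y` with midrank tie
#' handling. When both samples have at most `exact_max` observations the
#' two-sided p-value is computed by full enumeration of all
#' `choose(n+m, n)` group assignments (a permutation test on U, valid under
#' ties); otherwise by the normal approximation with the tie-corrected
#' variance, reporting the standardized Z.
#'
#' @param x,y Numeric samples.
#' @param continuity Apply a 0.5 continuity correction to the normal
#'   approximation (off by default).
#' @param exact_max Largest per-group size for which enumeration is used.
#' @return List with `U` (for `x`), `Z`, `p_value`, `exact` flag.
#' @export
mann_whitney <- function(x, y, continuity = FALSE, exact_max = 8L) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  N <- n + m
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  sigma <- sqrt(sigma2)
  Z <- if (sigma > 0) {
    num <- U - mu
    if (continuity) num <- sign(num) * max(0, abs(num) - 0.5)
    num / sigma
  } else 0

  exact <- n <= exact_max && m <= exact_max
  if (exact) {
    # enumerate every way of assigning n of the N pooled ranks to group x
    splits <- combn(N, n)
    u_all <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu))
  } else {
    p <- if (sigma > 0) 2 * pnorm(-abs(Z)) else 1
  }
  list(U = U, Z = Z, p_value = min(p, 1), exact = exact,
       n = c(n = n, m = m))
}

summary_median_iqr <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.2f (%.2f, %.2f)", q[2], q[1], q[3])
}
summary_mean_sd <- function(v) sprintf("%.2f ± %.2f", mean(v), sd(v))

#' Distribution-gated two-group comparison
#'
#' Compares one measurement between the control and patient groups the way
#' the clinical tables do: Shapiro-Wilk normality per group at
#' `alpha_normality`; if both groups pass, a two-sample t-test (pooled when
#' an F-test accepts equal variances, Welch otherwise) with mean +/- sd
#' summaries; if either fails (or a group is too small to test), a
#' Mann-Whitney U test with median (Q1, Q3) summaries, exact by enumeration
#' when both groups have at most 8 observations.
#'
#' @param table A `cohort_table` (see [make_cohort()], [cohort_table()]).
#' @param measurement Column name to compare.
#' @param alpha Significance level reported alongside.
#' @param alpha_normality Level of the per-group Shapiro-Wilk gate.
#' @param continuity Continuity correction for the Mann-Whitney normal
#'   approximation.
#' @return A `group_comparison`: measurement, test used, statistic
#'   (t or Z), p_value, per-group formatted summaries and sizes.
#' @export
compare_groups <- function(table, measurement, alpha = 0.05,
                           alpha_normality = 0.05, continuity = FALSE) {
  if (!measurement %in% names(table))
    stop("measurement '", measurement, "' not found in the cohort table",
         call. = FALSE)
  g <- split(table[[measurement]], table$group)
  if (!all(c("control", "patient") %in% names(g)) ||
      any(lengths(g[c("control", "patient")]) == 0))
    stop("both groups must be present", call. = FALSE)
  x <- g$control; y <- g$patient
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group", call. = FALSE)

  normal_ok <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 3) return(FALSE)
    shapiro.test(v)$p.value >= alpha_normality
  }
  both_normal <- normal_ok(x) && normal_ok(y)

  if (both_normal) {
    equal_var <- var.test(x, y)$p.value >= 0.05
    tt <- t.test(x, y, var.equal = equal_var)
    res <- list(test = if (equal_var) "student_t" else "welch_t",
                statistic = unname(tt$statistic),
                p_value = tt$p.value,
                summary_control = summary_mean_sd(x),
                summary_patient = summary_mean_sd(y))
  } else {
    mw <- mann_whitney(x, y, continuity = continuity)
    res <- list(test = "mann_whitney_u",
                statistic = mw$Z,
                p_value = mw$p_value,
                summary_control = summary_median_iqr(x),
                summary_patient = summary_median_iqr(y))
  }
  structure(c(list(measurement = measurement), res,
              list(n_control = length(x), n_patient = length(y),
                   alpha = alpha, significant = res$p_value < alpha)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s vs %s | %s %s = %.3f, p = %.4g%s\n",
              x$measurement, x$summary_control, x$summary_patient,
              x$test, if (grepl("_t$", x$test)) "t" else "Z",
              x$statistic, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

# The 13 standard measurements in table row order: totals then arterial
# bins then venous bins.
standard_measurements <- function() {
  ref <- cohort_reference()$measurement
  c("TIPVV", "IPVVa", "IPVVv",
    grep("^IPVVa_", ref, value = TRUE),
    grep("^IPVVv_", ref, value = TRUE))
}

#' Compare all standard measurements between groups
#'
#' @inheritParams compare_groups
#' @param measurements Character vector of columns; defaults to the 13
#'   standard rows (3 totals + 5 arterial + 5 venous bins).
#' @return List of `group_comparison` objects.
#' @export
compare_all <- function(table, measurements = standard_measurements(),
                        alpha = 0.05, continuity = FALSE) {
  lapply(measurements, function(mm)
    compare_groups(table, mm, alpha = alpha, continuity = continuity))
}

#' Group effect on a volume outcome, adjusted by robust-SE regression
#'
#' Ordinary-least-squares fit of `outcome ~ group + age + sex + bsa` (by
#' default) with heteroskedasticity-consistent standard errors
#' (sandwich estimator, HC3 by default). Group is coded patient = 1,
#' sex female = 1.
#'
#' @param table A `cohort_table`.
#' @param outcome Outcome column (default `"IPVVa"`).
#' @param covariates Adjustment columns; `"group"` and `"sex"` get the
#'   indicator coding above, anything else is used as-is.
#' @param robust One of `"HC3"`, `"HC2"`, `"HC1"`, `"HC0"`, or
#'   `"classical"` for the model-based covariance.
#' @return Data.frame with `term`, `estimate`, `robust_se`, `t`, `p`,
#'   carrying the fitted `lm` in attribute `"fit"`.
#' @export
adjusted_regression <- function(table, outcome = "IPVVa",
                                covariates = c("group", "age", "sex", "bsa"),
                                robust = c("HC3", "HC2", "HC1", "HC0",
                                           "classical")) {
  robust <- match.arg(robust)
  miss <- setdiff(c(outcome, covariates), names(table))
  if (length(miss))
    stop("column(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- data.frame(.outcome = table[[outcome]])
  for (cc in covariates) {
    df[[cc]] <- switch(cc,
                       group = as.numeric(table$group == "patient"),
                       sex = as.numeric(table$sex == "female"),
                       table[[cc]])
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10)
    stop("need at least 10 complete rows, have ", nrow(df), call. = FALSE)
  fit <- lm(.outcome ~ ., data = df)
  if (anyNA(coef(fit)))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  vc <- if (robust == "classical") vcov(fit) else
    sandwich::vcovHC(fit, type = robust)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  out <- data.frame(term = rownames(ct),
                    estimate = ct[, 1], robust_se = ct[, 2],
                    t = ct[, 3], p = ct[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "robust") <- robust
  out
}

#' Render comparison and regression results as table-style files
#'
#' Writes `comparisons.csv` (one row per measurement, totals first, then
#' arterial bins, then venous bins, each with per-group summaries, the
#' statistic and p-value), `regression.csv`, and a human-readable
#' `report.txt`. Optionally writes per-bin boxplot PNGs. No
#' multiple-comparison adjustment is applied; the report footnotes this.
#'
#' @param comparisons List of `group_comparison` objects (row order is
#'   preserved).
#' @param regression Optional data.frame from [adjusted_regression()].
#' @param out_dir Output directory (created if needed).
#' @param cohort Optional `cohort_table`; required for `plots`.
#' @param plots Write boxplot PNGs of each compared measurement by group.
#' @return Named character vector of the files written.
#' @export
render_report <- function(comparisons, regression = NULL, out_dir,
                          cohort = NULL, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comp_df <- if (length(comparisons)) {
    do.call(rbind, lapply(comparisons, function(cp) data.frame(
      measurement = cp$measurement,
      control = cp$summary_control,
      patient = cp$summary_patient,
      test = cp$test,
      statistic = round(cp$statistic, 3),
      p_value = signif(cp$p_value, 4),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(measurement = character(), control = character(),
               patient = character(), test = character(),
               statistic = numeric(), p_value = numeric())
  }
  files <- c(comparisons = file.path(out_dir, "comparisons.csv"))
  write.csv(comp_df, files[["comparisons"]], row.names = FALSE)
  if (!is.null(regression)) {
    files["regression"] <- file.path(out_dir, "regression.csv")
    write.csv(regression, files[["regression"]], row.names = FALSE)
  }

  txt <- c("Group comparison of intrapulmonary vessel volumes (mL/m^2)",
           "",
           utils::capture.output(print(comp_df, row.names = FALSE)),
           "",
           if (!is.null(regression)) c(
             sprintf("Adjusted regression (robust %s standard errors):",
                     attr(regression, "robust") %||% ""),
             utils::capture.output(print(regression, row.names = FALSE)),
             ""),
           paste("Normally distributed measurements: mean ± sd and",
                 "t-test; otherwise median (Q1, Q3) and Mann-Whitney U."),
           "p-values are unadjusted for multiple comparisons.")
  files["report"] <- file.path(out_dir, "report.txt")
  writeLines(txt, files[["report"]])

  if (plots) {
    if (is.null(cohort))
      stop("`cohort` is required for plots", call. = FALSE)
    for (cp in comparisons) {
      f <- file.path(out_dir, paste0("boxplot_",
                                     gsub("[^A-Za-z0-9._-]", "_",
                                          cp$measurement), ".png"))
      grDevices::png(f, width = 480, height = 480)
      graphics::boxplot(cohort[[cp$measurement]] ~ cohort$group,
                        xlab = "group", ylab = paste(cp$measurement, "(mL/m^2)"),
                        main = cp$measurement, col = c("grey85", "indianred"))
      grDevices::dev.off()
      files[paste0("plot_", cp$measurement)] <- f
    }
  }
  files
}
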