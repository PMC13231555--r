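test_that("exact Mann-Whitney matches enumeration-derived references", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 6)     # all C(4,2)=6 rank splits enumerated
  expect_true(mw$exact)

  # identical multisets are exchangeable: p = 1
  expect_equal(mann_whitney(c(5, 7, 7), c(5, 7, 7))$p_value, 1)
})

test_that("exact Mann-Whitney agrees with wilcox.test for all n,m <= 8", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:8, 1); m <- sample(2:8, 1)
    x <- round(rnorm(n), 2); y <- round(rnorm(m), 2)
    if (anyDuplicated(c(x, y))) next  # wilcox.test exact path forbids ties
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    got <- mann_whitney(x, y)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney Z uses the tie-corrected variance", {
  set.seed(21)
  x <- sample(1:5, 30, replace = TRUE)  # heavy ties
  y <- sample(2:6, 25, replace = TRUE)
  got <- mann_whitney(x, y)
  expect_false(got$exact)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # swapping the samples flips Z but not p
  rev <- mann_whitney(y, x)
  expect_equal(rev$Z, -got$Z, tolerance = 1e-12)
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)
})

test_that("the normality gate picks the t-test or Mann-Whitney as appropriate", {
  set.seed(31)
  n <- 60
  ct <- make_cohort(n, seed = 31L)
  # planted Gaussian measurement -> t-test with mean +/- sd summaries
  ct$gauss <- rnorm(2 * n, mean = 10, sd = 1)
  cmp <- compare_groups(ct, "gauss")
  expect_true(cmp$test %in% c("student_t", "welch_t"))
  expect_match(cmp$summary_control, "±")
  # heavily skewed measurement -> Mann-Whitney with median (Q1, Q3)
  ct$skew <- rlnorm(2 * n, sdlog = 1.5)
  cmp2 <- compare_groups(ct, "skew")
  expect_equal(cmp2$test, "mann_whitney_u")
  expect_match(cmp2$summary_patient, "\\(")
  expect_error(compare_groups(ct, "no_such_column"), "not found")
})

test_that("equal groups give a large p and label swap flips nothing material", {
  ct <- make_cohort(40, seed = 5L)
  ct2 <- ct
  ct2$group <- ifelse(ct$group == "control", "patient", "control")
  a <- compare_groups(ct, "TIPVV")
  b <- compare_groups(ct2, "TIPVV")
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
})

test_that("a planted effect is detected with high power", {
  ct <- make_cohort(100, effect = c("IPVVa_0.8-1.6mm" = 0.7), seed = 8L)
  cmp <- compare_groups(ct, "IPVVa_0.8-1.6mm")
  expect_lt(cmp$p_value, 0.001)
  # untouched bins stay unremarkable most of the time; just check validity
  cmp0 <- compare_groups(ct, "IPVVv_>4mm")
  expect_true(cmp0$p_value >= 0 && cmp0$p_value <= 1)

  # power by simulation: a 30% reduction at n = 100/group rejects > 90%
  hits <- vapply(1:50, function(i) {
    cti <- make_cohort(100, effect = c("IPVVa_0.8-1.6mm" = 0.7),
                       seed = 500L + i)
    compare_groups(cti, "IPVVa_0.8-1.6mm")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("robust-SE regression recovers a planted group effect", {
  set.seed(13)
  n <- 200
  tab <- data.frame(
    group = rep(c("control", "patient"), each = n / 2),
    age = runif(n, 20, 80),
    sex = sample(c("male", "female"), n, replace = TRUE),
    bsa = runif(n, 1.4, 2.1))
  tab$IPVVa <- 50 - 5 * (tab$group == "patient") + rnorm(n, sd = 1)
  res <- adjusted_regression(tab)
  g <- res[res$term == "group", ]
  expect_lt(abs(g$estimate - (-5)), 3 * g$robust_se)
  expect_lt(g$p, 1e-6)

  # noiseless limit: coefficients recovered to numerical precision
  tab$IPVVa <- 50 - 5 * (tab$group == "patient") + 0.1 * tab$bsa
  res0 <- suppressWarnings(adjusted_regression(tab))  # perfect fit warns
  expect_equal(res0$estimate[res0$term == "group"], -5, tolerance = 1e-8)

  # collinear design errors, naming the offender
  tab$dup <- tab$bsa
  expect_error(adjusted_regression(tab, covariates = c("group", "bsa", "dup")),
               "collinear.*dup")
  expect_error(adjusted_regression(tab[1:5, ]), "at least 10")
})

test_that("robust and classical SEs agree under homoskedastic noise", {
  set.seed(17)
  n <- 400
  tab <- data.frame(group = rep(c("control", "patient"), each = n / 2),
                    age = runif(n, 20, 80),
                    sex = sample(c("male", "female"), n, replace = TRUE),
                    bsa = runif(n, 1.4, 2.1))
  tab$IPVVa <- 40 + 2 * (tab$group == "patient") + rnorm(n)
  hc <- adjusted_regression(tab, robust = "HC3")
  cl <- adjusted_regression(tab, robust = "classical")
  expect_equal(hc$robust_se, cl$robust_se, tolerance = 0.15)
})

test_that("the rendered report has the 13 table rows in canonical order", {
  ct <- make_cohort(30, seed = 19L)
  cmps <- compare_all(ct)
  expect_length(cmps, 13)  # 3 totals + 5 arterial + 5 venous bins
  reg <- adjusted_regression(ct)
  out <- withr::local_tempdir()
  files <- render_report(cmps, reg, out, cohort = ct, plots = TRUE)
  got <- read.csv(files[["comparisons"]])
  expect_equal(got$measurement[1:3], c("TIPVV", "IPVVa", "IPVVv"))
  expect_equal(got$measurement[4], "IPVVa_0.8-1.6mm")
  expect_equal(nrow(got), 13)
  # summary style matches the gated test: mean ± sd or median (Q1, Q3)
  expect_match(got$control[1], "±|\\(")
  expect_true(file.exists(files[["regression"]]))
  expect_true(any(grepl("unadjusted for multiple comparisons",
                        readLines(files[["report"]]))))
  expect_true(file.exists(files[["plot_TIPVV"]]))

  # empty comparison list -> header-only file
  files0 <- render_report(list(), NULL, withr::local_tempdir())
  expect_equal(nrow(read.csv(files0[["comparisons"]])), 0)
})

test_that("cohorts are reproducible and warn at minimal sample size", {
  a <- make_cohort(10, seed = 99L)
  b <- make_cohort(10, seed = 99L)
  expect_identical(a, b)
  expect_warning(make_cohort(2, seed = 1L), "fragile")
  expect_error(make_cohort(1), "at least 2")
})

test_that("cohort_table assembles measurements from normalized reports", {
  ph <- make_cylinder(2.2, 15)
  rf <- vessel_radius_field(ph$mask)
  subj <- compute_bsa(as_subject_table(data.frame(
    id = c("s1", "s2"), group = c("control", "patient"),
    age = c(40, 35), sex = c("female", "female"),
    height_cm = c(164, 163), weight_kg = c(66, 59))))
  rep1 <- normalize_report(bin_volumes(rf, ph$mask), subj[1, ])
  rep2 <- normalize_report(bin_volumes(rf, ph$mask), subj[2, ])
  tab <- cohort_table(subj, list(s1 = rep1, s2 = rep2))
  expect_equal(tab$TIPVV, tab$IPVVa + tab$IPVVv)
  expect_equal(tab$IPVVa[1], unname(rep1$totals_per_m2[["IPVVa"]]))
  expect_error(cohort_table(subj, list(s1 = rep1)), "s2")
})
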