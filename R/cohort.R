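# Synthetic two-group cohort generator for exercising the statistics
# pipeline without patient data. Per-bin BSA-normalized volumes are drawn
# from log-normal distributions (the clinical tables report right-skewed
# medians with IQRs); the default medians and spreads are the published
# CTPA-negative reference values, and `effect` multiplies the patient
# group's medians bin by bin.

# Reference medians and quartiles (mL/m^2) for the ten compartment-bin
# measurements in a CTPA-negative population.
cohort_reference <- function() {
  ref <- data.frame(
    measurement = c("IPVVa_0.8-1.6mm", "IPVVa_1.6-2.4mm", "IPVVa_2.4-3.2mm",
                    "IPVVa_3.2-4.0mm", "IPVVa_>4mm",
                    "IPVVv_0.8-1.6mm", "IPVVv_1.6-2.4mm", "IPVVv_2.4-3.2mm",
                    "IPVVv_3.2-4.0mm", "IPVVv_>4mm"),
    median = c(5.14, 9.40, 12.93, 6.49, 12.34,
               4.24, 9.08, 15.40, 8.85, 17.52),
    q1 = c(4.15, 7.78, 11.00, 5.44, 9.18,
           3.67, 7.58, NA, 7.34, 13.95),
    q3 = c(6.03, 11.97, 15.03, 7.98, 15.86,
           4.96, 11.75, NA, 10.89, 23.02),
    sd = c(rep(NA, 7), 3.68, NA, NA),
    stringsAsFactors = FALSE)
  # log-sd from the IQR of a log-normal; where only mean +/- sd is
  # published, use the coefficient of variation as the log-sd (small-sigma
  # approximation)
  ref$sdlog <- ifelse(is.na(ref$q1),
                      ref$sd / ref$median,
                      (log(ref$q3) - log(ref$q1)) / (2 * qnorm(0.75)))
  ref
}

#' Simulate a two-group cohort with per-bin vessel volumes
#'
#' Draws `n_per_group` control and `n_per_group` patient subjects.
#' Demographics follow a CTPA-referral population (age, sex mix, height and
#' weight differ by group); per-bin normalized volumes are log-normal with
#' group medians differing by the multiplicative `effect`. With
#' `effect = 1` everywhere the groups are exchangeable on every volume
#' measurement (a null cohort).
#'
#' @param n_per_group Subjects per group (>= 2; a warning is issued below 5,
#'   where group tests are fragile).
#' @param effect Multiplicative shift of the patient group's per-bin
#'   medians: a scalar, or a named vector over (a subset of) the ten
#'   measurement names (`"IPVVa_0.8-1.6mm"`, ..., `"IPVVv_>4mm"`).
#' @param seed Integer seed; fixes the cohort exactly.
#' @return A `cohort_table` data.frame: subject columns (`id`, `group`,
#'   `age`, `sex`, `height_cm`, `weight_kg`, `bsa`), the ten per-bin
#'   measurements (mL/m^2) and totals `IPVVa`, `IPVVv`, `TIPVV`.
#' @export
make_cohort <- function(n_per_group, effect = 1, seed = 1L) {
  if (n_per_group < 2) stop("need at least 2 subjects per group", call. = FALSE)
  if (n_per_group < 5) warning("fewer than 5 subjects per group: ",
                               "group tests will be fragile", call. = FALSE)
  ref <- cohort_reference()
  eff <- setNames(rep(1, nrow(ref)), ref$measurement)
  if (length(effect) == 1L && is.null(names(effect))) {
    eff[] <- effect
  } else {
    bad <- setdiff(names(effect), ref$measurement)
    if (length(bad)) stop("unknown measurement(s) in `effect`: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    eff[names(effect)] <- effect
  }

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  n <- 2L * n_per_group
  group <- rep(c("control", "patient"), each = n_per_group)
  # demographics: medians and IQR-derived spreads by group
  demo <- function(n, med, q1, q3, lo, hi)
    pmin(pmax(rnorm(n, med, (q3 - q1) / (2 * qnorm(0.75))), lo), hi)
  is_pat <- group == "patient"
  age <- ifelse(is_pat, demo(n, 34, 27, 44, 18, 85), demo(n, 45, 32, 60, 18, 85))
  sex <- ifelse(runif(n) < ifelse(is_pat, 0.86, 0.63), "female", "male")
  height <- ifelse(is_pat, demo(n, 163, 160, 168, 140, 200),
                   demo(n, 164, 160, 173, 140, 200))
  weight <- ifelse(is_pat, demo(n, 59, 52, 65, 35, 150),
                   demo(n, 66, 58, 75, 35, 150))
  subjects <- data.frame(
    id = sprintf("%s%03d", ifelse(is_pat, "p", "c"),
                 c(seq_len(n_per_group), seq_len(n_per_group))),
    group = group, age = round(age), sex = sex,
    height_cm = round(height), weight_kg = round(weight),
    stringsAsFactors = FALSE)
  subjects <- compute_bsa(as_subject_table(subjects))

  vols <- sapply(seq_len(nrow(ref)), function(i) {
    med <- ifelse(is_pat, ref$median[i] * eff[i], ref$median[i])
    rlnorm(n, meanlog = log(med), sdlog = ref$sdlog[i])
  })
  colnames(vols) <- ref$measurement
  out <- cbind(subjects, as.data.frame(vols, check.names = FALSE))
  out$IPVVa <- rowSums(vols[, grep("^IPVVa_", ref$measurement), drop = FALSE])
  out$IPVVv <- rowSums(vols[, grep("^IPVVv_", ref$measurement), drop = FALSE])
  out$TIPVV <- out$IPVVa + out$IPVVv
  class(out) <- c("cohort_table", "subject_table", "data.frame")
  out
}

#' Assemble a cohort table from subjects and volume reports
#'
#' @param subjects A `subject_table` with `bsa` computed.
#' @param reports Named list (by subject id) of normalized `volume_report`s.
#' @return A `cohort_table` with the same measurement columns as
#'   [make_cohort()].
#' @export
cohort_table <- function(subjects, reports) {
  stopifnot(inherits(subjects, "data.frame"))
  if (!all(subjects$id %in% names(reports)))
    stop("missing volume report(s) for subject(s): ",
         paste(setdiff(subjects$id, names(reports)), collapse = ", "),
         call. = FALSE)
  meas <- cohort_reference()$measurement
  rows <- lapply(subjects$id, function(sid) {
    rep <- reports[[sid]]
    stopifnot(inherits(rep, "volume_report"))
    if (!isTRUE(rep$normalized))
      stop("report for subject ", sid, " is not BSA-normalized", call. = FALSE)
    b <- rep$bins
    supra <- b$bin != "sub_threshold"
    v <- setNames(numeric(length(meas)), meas)
    for (cc in c("artery", "vein")) {
      pre <- if (cc == "artery") "IPVVa_" else "IPVVv_"
      sel <- b$compartment == cc & supra
      v[paste0(pre, b$bin[sel])] <- b$volume_ml_per_m2[sel]
    }
    c(v, IPVVa = unname(rep$totals_per_m2["IPVVa"]),
      IPVVv = unname(rep$totals_per_m2["IPVVv"]),
      TIPVV = unname(rep$totals_per_m2["TIPVV"]))
  })
  out <- cbind(as.data.frame(subjects), do.call(rbind, rows))
  class(out) <- c("cohort_table", "subject_table", "data.frame")
  out
}
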