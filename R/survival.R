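#' Time to absence of HRF for one patient
#'
#' Absence of HRF is defined as the first time the HRF count is 0 at 2
#' consecutive visits, the pair requirement demonstrating that resolution
#' was maintained for more than one visit. The event time is the week of the
#' FIRST visit of the earliest consecutive-zero pair. Patients with such a
#' pair starting at or before the baseline visit are excluded. Patients
#' without an event are censored at their last observed week (dropout before
#' the event, or still in the study at the final visit without the event).
#'
#' @param weeks Numeric vector of visit weeks, sorted ascending, on the
#'   planned grid (week 0 = baseline).
#' @param counts Integer HRF counts at those visits.
#' @return A list with `status` (`"event"`, `"censored"` or `"excluded"`),
#'   `time` (weeks; `NA` when excluded) and `event` (1/0; `NA` when
#'   excluded).
#' @examples
#' event_time_to_absence(c(0, 4, 8, 12, 16), c(3, 1, 0, 0, 2))  # event at 8
#' @export
event_time_to_absence <- function(weeks, counts) {
  stopifnot(length(weeks) == length(counts))
  if (length(weeks) == 0)
    stop("no visits supplied", call. = FALSE)
  o <- order(weeks)
  weeks <- weeks[o]; counts <- counts[o]
  if (length(weeks) < 2)
    return(list(status = "censored", time = weeks[1], event = 0L))
  zero <- counts == 0
  pair_first <- which(zero[-length(zero)] & zero[-1])
  if (length(pair_first) > 0) {
    t0 <- weeks[pair_first[1]]
    if (t0 <= 0)
      return(list(status = "excluded", time = NA_real_, event = NA_integer_))
    return(list(status = "event", time = t0, event = 1L))
  }
  list(status = "censored", time = weeks[length(weeks)], event = 0L)
}

#' Per-patient absence events for a trial dataset
#'
#' Applies [event_time_to_absence()] to every patient's count series for the
#' given endpoint and returns one row per non-excluded patient, carrying the
#' arm and stratification covariates needed by the survival analyses.
#'
#' @param dataset A `trial_dataset`.
#' @param endpoint Count endpoint column (default `"count_inner_r1"`).
#' @return Data.frame with `patient_id`, `arm`, `time`, `event`,
#'   `bcva_stratum`, `prior_anti_vegf`, `region_stratum`; attribute
#'   `n_excluded` counts baseline-zero exclusions.
#' @export
absence_events <- function(dataset, endpoint = "count_inner_r1") {
  if (!endpoint %in% names(dataset))
    stop("no endpoint column '", endpoint, "'", call. = FALSE)
  df <- as.data.frame(dataset)
  out <- list(); n_excl <- 0L
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, ]
    rows <- rows[order(rows$visit_week), ]
    r <- event_time_to_absence(rows$visit_week, rows[[endpoint]])
    if (r$status == "excluded") { n_excl <- n_excl + 1L; next }
    out[[length(out) + 1L]] <- data.frame(
      patient_id = pid, arm = as.character(rows$arm[1]),
      time = r$time, event = r$event,
      bcva_stratum = rows$bcva_stratum[1],
      prior_anti_vegf = rows$prior_anti_vegf[1],
      region_stratum = rows$region_stratum[1],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(patient_id = character(), arm = character(),
               time = numeric(), event = integer(),
               bcva_stratum = character(), prior_anti_vegf = character(),
               region_stratum = character())
  attr(res, "n_excluded") <- n_excl
  res
}

#' Kaplan-Meier estimate of time to absence of HRF
#'
#' Product-limit estimator per arm (via [survival::survfit()]) with
#' percentile times of the cumulative incidence 1 - S(t): the reported
#' percentile `p` is the earliest time at which cumulative incidence reaches
#' at least `p`, and `NA` ("not reached") when the curve never attains it
#' within follow-up.
#'
#' @param time Event/censoring times (weeks).
#' @param event 1 = event, 0 = censored.
#' @param arm Optional grouping factor; percentiles are reported per group.
#' @param percentiles Cumulative-incidence percentiles (default 0.25, 0.50).
#' @return Object of class `hrf_km`: `fit` (the `survfit`), `percentiles`
#'   (data.frame arm x percentile with `time_weeks`, `NA` = not reached),
#'   `n`, `n_events`.
#' @export
km_estimate <- function(time, event, arm = NULL,
                        percentiles = c(0.25, 0.50)) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  if (is.null(arm)) arm <- rep("all", length(time))
  arm <- factor(arm)
  d <- data.frame(time = time, event = event, arm = arm)
  fit <- survival::survfit(survival::Surv(time, event) ~ arm, data = d,
                           conf.type = "log-log")
  sm <- summary(fit, censored = TRUE)
  stratum <- if (is.null(sm$strata)) factor(rep(levels(arm)[1],
                                                length(sm$time)))
             else factor(sub("^arm=", "", as.character(sm$strata)),
                         levels = levels(arm))
  pct <- do.call(rbind, lapply(levels(arm), function(a) {
    tt <- sm$time[stratum == a]; ss <- sm$surv[stratum == a]
    do.call(rbind, lapply(percentiles, function(p) {
      hit <- which(1 - ss >= p - 1e-12)
      data.frame(arm = a, percentile = p,
                 time_weeks = if (length(hit) > 0) tt[hit[1]] else NA_real_)
    }))
  }))
  structure(list(fit = fit, percentiles = pct,
                 n = as.vector(table(arm)),
                 n_events = as.vector(tapply(event, arm, sum))),
            class = "hrf_km")
}

#' @export
print.hrf_km <- function(x, ...) {
  cat("Kaplan-Meier time to absence of HRF (2 consecutive zero-count visits)\n")
  p <- x$percentiles
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-16s %2.0f%%: %s\n", p$arm[i], 100 * p$percentile[i],
                if (is.na(p$time_weeks[i])) "not reached"
                else paste0(p$time_weeks[i], " weeks")))
  invisible(x)
}

#' Plot cumulative incidence of absence of HRF
#' @param x An `hrf_km` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hrf_km <- function(x, ...) {
  graphics::plot(x$fit, fun = "event", xlab = "week",
                 ylab = "cumulative incidence",
                 col = c("#1f77b4", "#2ca02c", "#7f7f7f"), lwd = 2, ...)
  invisible(x)
}

#' Stratified Cox regression for time to absence of HRF
#'
#' @importFrom survival Surv strata coxph survdiff survfit
#'
#' Each faricimab arm is compared with the reference arm in a separate Cox
#' model (pairwise models, as in stratified trial analyses), stratified by
#' baseline BCVA category, prior anti-VEGF therapy and region. Ties are
#' handled with the Efron approximation, appropriate for the heavily tied
#' planned-visit time grid. A stratified log-rank test (same strata) is
#' reported alongside the Wald HR and CI. An HR > 1 means the comparator
#' arm reaches absence of HRF faster than the reference.
#'
#' @param events Data.frame from [absence_events()] (columns `time`,
#'   `event`, `arm`, plus the strata columns).
#' @param ref_arm Reference arm (default `"aflibercept_q8w"`).
#' @param strata_cols Stratification columns; use `character(0)` for an
#'   unstratified analysis.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `hrf_cox`: data.frame `contrasts` with `arm`,
#'   `hr`, `lower`, `upper`, `p_wald`, `p_logrank`, `n`, `n_events`, plus
#'   the per-contrast fitted models in `models`.
#' @export
stratified_cox <- function(events, ref_arm = "aflibercept_q8w",
                           strata_cols = c("bcva_stratum", "prior_anti_vegf",
                                           "region_stratum"),
                           conf_level = 0.95) {
  stopifnot(ref_arm %in% events$arm)
  others <- setdiff(unique(as.character(events$arm)), ref_arm)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(); models <- list()
  for (a in others) {
    d <- events[events$arm %in% c(ref_arm, a), , drop = FALSE]
    if (sum(d$event) < 1)
      stop("no events in comparison ", a, " vs ", ref_arm, call. = FALSE)
    if (length(unique(d$arm)) < 2)
      stop("monopolar comparison: only one arm present", call. = FALSE)
    d$trt <- factor(as.character(d$arm), levels = c(ref_arm, a))
    rhs <- "trt"
    if (length(strata_cols) > 0)
      rhs <- paste(c("trt", sprintf("strata(%s)",
                                    paste(strata_cols, collapse = ", "))),
                   collapse = " + ")
    form <- stats::as.formula(paste("Surv(time, event) ~", rhs))
    fit <- survival::coxph(form, data = d, ties = "efron")
    b <- stats::coef(fit)[1]
    se <- sqrt(stats::vcov(fit)[1, 1])
    lr_form <- form
    lr <- survival::survdiff(lr_form, data = d)
    p_lr <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
    out[[a]] <- data.frame(
      arm = a, ref = ref_arm,
      hr = exp(b), lower = exp(b - z * se), upper = exp(b + z * se),
      p_wald = 2 * stats::pnorm(-abs(b / se)),
      p_logrank = p_lr,
      n = nrow(d), n_events = sum(d$event),
      stringsAsFactors = FALSE)
    models[[a]] <- fit
  }
  structure(list(contrasts = do.call(rbind, out), models = models,
                 strata_cols = strata_cols, conf_level = conf_level),
            class = "hrf_cox")
}

#' @export
print.hrf_cox <- function(x, ...) {
  cat("Stratified Cox regression, time to absence of HRF",
      if (length(x$strata_cols) > 0)
        paste0("\n  strata: ", paste(x$strata_cols, collapse = ", "))
      else "\n  (unstratified)", "\n")
  ct <- x$contrasts
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %s vs %s: HR %.2f (%.0f%% CI %.2f, %.2f); Wald p = %.3g; log-rank p = %.3g\n",
                ct$arm[i], ct$ref[i], ct$hr[i], 100 * x$conf_level,
                ct$lower[i], ct$upper[i], ct$p_wald[i], ct$p_logrank[i]))
  invisible(x)
}

#' @export
coef.hrf_cox <- function(object, ...) {
  stats::setNames(object$contrasts$hr, object$contrasts$arm)
}
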