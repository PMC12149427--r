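#' Mixed model for repeated measures (MMRM) on a trial endpoint
#'
#' Fits the standard longitudinal trial model to post-baseline visits:
#' fixed effects for the baseline endpoint value, treatment arm, visit
#' (categorical), visit-by-arm interaction, baseline BCVA (continuous) and
#' the randomization-stratification factors (BCVA stratum <64 / >=64
#' letters, prior anti-VEGF therapy, geographic region), with a
#' within-patient residual covariance estimated by REML — unstructured by
#' default (distinct variance per visit, distinct correlation per visit
#' pair). Estimation uses all available post-baseline rows under the
#' missing-at-random assumption; no imputation. Adjusted means per arm and
#' visit and contrasts of each faricimab arm versus aflibercept (with
#' nominal, unadjusted p-values) are computed via [emmeans::emmeans()].
#'
#' Patients without a week-0 endpoint value are excluded (the baseline value
#' is a covariate). Covariates that are constant in the analysis set are
#' dropped from the fixed effects automatically. If the endpoint has
#' (numerically) zero residual variance the model degenerates to ordinary
#' least squares and adjusted means are exact cell means. If the requested
#' covariance structure fails to converge the model is refitted with
#' exchangeable covariance, and that fallback is reported prominently in the
#' result and by a warning.
#'
#' @param dataset A `trial_dataset` (see [read_trial_table()]).
#' @param endpoint Name of the endpoint column, e.g. `"vol_inner_r1_pl"`.
#' @param covariance `"unstructured"` (default), `"exchangeable"` or
#'   `"ar1"`.
#' @param ref_arm Reference arm for contrasts (default `"aflibercept_q8w"`).
#' @param emm_weights Weighting of factor covariate margins when averaging
#'   to adjusted means: `"proportional"` (observed margins, default) or
#'   `"equal"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `hrf_mmrm` with components `adjusted_means`,
#'   `contrasts`, `covariance` (estimated within-patient covariance matrix),
#'   `covariance_used`, `converged`, `degenerate`, `logLik`, `n_patients`,
#'   `endpoint`, `ref_arm`.
#' @export
fit_mmrm <- function(dataset, endpoint,
                     covariance = c("unstructured", "exchangeable", "ar1"),
                     ref_arm = "aflibercept_q8w",
                     emm_weights = c("proportional", "equal"),
                     conf_level = 0.95) {
  covariance <- match.arg(covariance)
  emm_weights <- match.arg(emm_weights)
  if (!endpoint %in% names(dataset))
    stop("no endpoint column '", endpoint, "' in dataset", call. = FALSE)
  df <- as.data.frame(dataset)
  base <- df[df$visit_week == 0, c("patient_id", endpoint)]
  names(base)[2] <- "baseline_value"
  d <- merge(df[df$visit_week > 0, , drop = FALSE], base,
             by = "patient_id")
  d <- d[!is.na(d[[endpoint]]) & !is.na(d$baseline_value), , drop = FALSE]
  post_weeks <- sort(unique(d$visit_week))
  if (length(post_weeks) < 2)
    stop("need at least 2 post-baseline visits", call. = FALSE)
  d$y <- d[[endpoint]]
  d$visitf <- factor(d$visit_week, levels = post_weeks)
  d$visit_idx <- as.integer(d$visitf)
  d$arm <- factor(as.character(d$arm), levels = trial_arms)
  d$arm <- droplevels(d$arm)
  d$patient <- factor(d$patient_id)
  d$bcva_stratum <- factor(d$bcva_stratum)
  d$prior_anti_vegf <- factor(d$prior_anti_vegf)
  d$region_stratum <- factor(d$region_stratum)
  d <- d[order(d$patient, d$visit_idx), , drop = FALSE]

  covars <- c("baseline_value", "bcva_baseline", "bcva_stratum",
              "prior_anti_vegf", "region_stratum")
  keep <- covars[vapply(covars, function(v) length(unique(d[[v]])) > 1,
                        logical(1))]
  rhs <- paste(c(keep, "arm * visitf"), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))

  # degenerate (zero residual variance) endpoint: GLS reduces to OLS
  ols <- stats::lm(form, data = d)
  scale_y <- mean(abs(d$y)) + 1e-12
  degenerate <- stats::sigma(ols) < 1e-8 * scale_y

  fit <- NULL; used <- covariance; converged <- TRUE
  if (!degenerate) {
    fit <- try_gls(form, d, covariance)
    if (is.null(fit) && covariance != "exchangeable") {
      warning("MMRM with ", covariance, " covariance failed to converge; ",
              "refitted with exchangeable covariance", call. = FALSE)
      used <- "exchangeable"
      fit <- try_gls(form, d, "exchangeable")
    }
    if (is.null(fit)) {
      warning("MMRM covariance estimation failed; falling back to ",
              "ordinary least squares (independence)", call. = FALSE)
      used <- "independence"; converged <- FALSE
    }
  } else {
    used <- "degenerate"
  }
  model <- if (is.null(fit)) ols else fit

  # a noiseless endpoint triggers lm's "essentially perfect fit" warning in
  # emmeans; harmless here because the degenerate flag already reports it
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  emm <- quiet_perfect(
    emmeans::emmeans(model, ~ arm | visitf, data = d,
                     weights = emm_weights,
                     mode = if (inherits(model, "gls")) "df.error"
                            else "asymptotic"))
  means <- as.data.frame(summary(emm, level = conf_level, infer = TRUE))
  ci_cols <- intersect(c("lower.CL", "upper.CL", "asymp.LCL", "asymp.UCL"),
                       names(means))
  adjusted_means <- data.frame(
    arm = means$arm,
    week = as.numeric(as.character(means$visitf)),
    estimate = means$emmean, se = means$SE,
    lower = means[[ci_cols[1]]], upper = means[[ci_cols[2]]])

  # nominal (unadjusted) p-values and CIs: no multiplicity adjustment
  ctr <- emmeans::contrast(emm, "trt.vs.ctrl",
                           ref = which(levels(d$arm) == ref_arm),
                           adjust = "none")
  cs <- as.data.frame(summary(ctr, level = conf_level, infer = TRUE,
                              adjust = "none"))
  ci_cols <- intersect(c("lower.CL", "upper.CL", "asymp.LCL", "asymp.UCL"),
                       names(cs))
  contrasts <- data.frame(
    contrast = cs$contrast,
    week = as.numeric(as.character(cs$visitf)),
    estimate = cs$estimate, se = cs$SE,
    lower = cs[[ci_cols[1]]], upper = cs[[ci_cols[2]]],
    p = cs$p.value)

  covmat <- mmrm_covariance(model, d, used)
  structure(list(adjusted_means = adjusted_means, contrasts = contrasts,
                 covariance = covmat, covariance_used = used,
                 converged = converged, degenerate = degenerate,
                 logLik = as.numeric(stats::logLik(model)),
                 n_patients = length(unique(d$patient)),
                 endpoint = endpoint, ref_arm = ref_arm,
                 conf_level = conf_level, model = model),
            class = "hrf_mmrm")
}

try_gls <- function(form, d, covariance) {
  cl <- switch(covariance,
    unstructured = bquote(
      nlme::gls(.(form), data = d,
                correlation = nlme::corSymm(form = ~visit_idx | patient),
                weights = nlme::varIdent(form = ~1 | visitf),
                method = "REML",
                control = nlme::glsControl(maxIter = 100, msMaxIter = 200))),
    exchangeable = bquote(
      nlme::gls(.(form), data = d,
                correlation = nlme::corCompSymm(form = ~visit_idx | patient),
                method = "REML",
                control = nlme::glsControl(maxIter = 100, msMaxIter = 200))),
    ar1 = bquote(
      nlme::gls(.(form), data = d,
                correlation = nlme::corAR1(form = ~visit_idx | patient),
                method = "REML",
                control = nlme::glsControl(maxIter = 100, msMaxIter = 200))))
  fit <- tryCatch(eval(cl), error = function(e) NULL)
  fit
}

# within-patient residual covariance matrix of the fitted model
mmrm_covariance <- function(model, d, used) {
  K <- nlevels(d$visitf)
  if (!inherits(model, "gls")) {
    return(diag(stats::sigma(model)^2, K))
  }
  v <- tryCatch({
    # use a patient observed at all visits so the full matrix is returned
    tab <- table(d$patient)
    full <- names(tab)[tab == K][1]
    if (is.na(full)) nlme::getVarCov(model)
    else nlme::getVarCov(model, individual = full)
  }, error = function(e) NULL)
  if (is.null(v)) {
    s2 <- stats::sigma(model)^2
    v <- diag(s2, K)
  }
  m <- matrix(as.numeric(v), K, K)
  dimnames(m) <- list(levels(d$visitf), levels(d$visitf))
  m
}

#' @export
print.hrf_mmrm <- function(x, ...) {
  cat("MMRM fit for endpoint '", x$endpoint, "'\n", sep = "")
  cat(sprintf("  %d patients; covariance: %s%s\n", x$n_patients,
              x$covariance_used,
              if (x$degenerate) " (zero residual variance)" else ""))
  wk <- max(x$adjusted_means$week)
  am <- x$adjusted_means[x$adjusted_means$week == wk, ]
  cat(sprintf("  adjusted means at week %g:\n", wk))
  for (i in seq_len(nrow(am)))
    cat(sprintf("    %-16s %8.1f (SE %.2f)\n",
                as.character(am$arm[i]), am$estimate[i], am$se[i]))
  ct <- x$contrasts[x$contrasts$week == wk, ]
  for (i in seq_len(nrow(ct)))
    cat(sprintf("  %s @ wk %g: %.1f [%.1f, %.1f], p = %.3g\n",
                as.character(ct$contrast[i]), wk, ct$estimate[i],
                ct$lower[i], ct$upper[i], ct$p[i]))
  invisible(x)
}

#' @export
summary.hrf_mmrm <- function(object, ...) {
  print(object)
  cat("\nAdjusted means (all visits):\n")
  print(object$adjusted_means, row.names = FALSE, digits = 4)
  cat("\nContrasts vs ", object$ref_arm, ":\n", sep = "")
  print(object$contrasts, row.names = FALSE, digits = 4)
  invisible(object)
}

#' @export
coef.hrf_mmrm <- function(object, ...) {
  am <- object$adjusted_means
  out <- stats::reshape(am[, c("arm", "week", "estimate")],
                        idvar = "arm", timevar = "week",
                        direction = "wide")
  names(out) <- sub("^estimate\\.", "week", names(out))
  rownames(out) <- NULL
  out
}

#' Plot adjusted mean trajectories with confidence bands
#' @param x An `hrf_mmrm` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.hrf_mmrm <- function(x, ...) {
  am <- x$adjusted_means
  arms <- levels(factor(am$arm))
  weeks <- sort(unique(am$week))
  cols <- c("#1f77b4", "#2ca02c", "#7f7f7f")[seq_along(arms)]
  ylim <- range(am$lower, am$upper)
  graphics::plot(NULL, xlim = range(weeks), ylim = ylim,
                 xlab = "week", ylab = x$endpoint,
                 main = "MMRM adjusted means", ...)
  for (k in seq_along(arms)) {
    a <- am[am$arm == arms[k], ]
    a <- a[order(a$week), ]
    graphics::lines(a$week, a$estimate, col = cols[k], lwd = 2)
    graphics::arrows(a$week, a$lower, a$week, a$upper, angle = 90,
                     code = 3, length = 0.03, col = cols[k])
  }
  graphics::legend("topright", legend = arms, col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}
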