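#' Specification of a synthetic three-arm trial
#'
#' Describes the data-generating process for a longitudinal DME trial with
#' arms `faricimab_q8w`, `faricimab_te` and `aflibercept_q8w` on a 4-weekly
#' visit grid to week 48. For each volume endpoint (inner/outer retina,
#' 1-mm/3-mm ring) the arm-mean trajectory is piecewise linear through four
#' anchors: baseline (week 0), an early inner-retina peak at `rise_week`
#' (baseline x (1 + `early_rise`); the rise emulates the transient
#' inner-retina increase attributed to turbid-fluid masking of HRF and is 0
#' in the outer retina), a common level at week 12, and an arm-specific
#' week-48 end level. Arms share the trajectory up to week 12 and separate
#' from week 16 onward, mirroring the completion of the head-to-head dosing
#' period.
#'
#' Counts follow the same trajectory shape scaled to a baseline count, drawn
#' as `max(Poisson, 1)` until the patient reaches the absorbing "HRF-free"
#' state; zero-attainment is a per-patient geometric waiting time on the
#' visit grid with arm-specific per-visit probability derived from
#' `p_zero_ref` and `zero_hr` on the complementary-log scale, so the planted
#' hazard ratios are exact under grouped proportional hazards.
#'
#' @param visit_weeks Planned visit grid (default `seq(0, 48, 4)`).
#' @param volumes Named list per endpoint (`inner_r1`, `outer_r1`,
#'   `inner_r3`, `outer_r3`) with elements `baseline` (mean pL), `wk48`
#'   (named per-arm week-48 mean pL), `early_rise` (fractional amplitude at
#'   `rise_week`), `wk12_frac` (common week-12 level as fraction of
#'   baseline).
#' @param rise_week Week of the inner-retina early peak (default 8).
#' @param count_baseline Named per-endpoint baseline mean HRF counts.
#' @param noise_dist `"lognormal"` (default; multiplicative, mean-preserving,
#'   positively skewed like observed HRF volumes) or `"normal"` (additive;
#'   used in estimator-recovery simulations).
#' @param noise_sd Log-scale SD for `"lognormal"`; for `"normal"`, SD as a
#'   fraction of the endpoint's baseline mean.
#' @param resid_cor Within-patient correlation structure for the noise:
#'   `"exchangeable"` (default), `"ar1"`, or `"unstructured"` (supply
#'   `resid_cor_matrix`).
#' @param resid_rho Correlation parameter for exchangeable/AR1 (default 0.6).
#' @param resid_cor_matrix Full positive-definite correlation matrix
#'   (visits x visits) when `resid_cor = "unstructured"`.
#' @param p_zero_ref Per-visit probability (from week 4 onward) that an
#'   aflibercept patient becomes HRF-free (default 0.03).
#' @param zero_hr Named hazard ratios vs aflibercept for zero-attainment
#'   (defaults 1.48 faricimab Q8W, 1.23 faricimab T&E).
#' @param p_zero_baseline Probability of being HRF-free already at baseline
#'   (such patients are excluded from time-to-absence analyses; default
#'   0.02).
#' @param dropout_p Per-visit dropout probability after baseline (default
#'   0.01); patients are censored at their last observed week.
#' @param irf_rho Pearson correlation, on the cube-root scale, between the
#'   baseline-to-week-48 HRF volume change (total retina, 3-mm) and the IRF
#'   volume change (default 0.42).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(
    visit_weeks = seq(0, 48, by = 4),
    volumes = list(
      inner_r1 = list(baseline = 250, early_rise = 0.25, wk12_frac = 1.10,
                      wk48 = c(faricimab_q8w = 104.1, faricimab_te = 110.1,
                               aflibercept_q8w = 180.3)),
      outer_r1 = list(baseline = 90, early_rise = 0, wk12_frac = 0.95,
                      wk48 = c(faricimab_q8w = 37.2, faricimab_te = 41.4,
                               aflibercept_q8w = 65.7)),
      inner_r3 = list(baseline = 1400, early_rise = 0.25, wk12_frac = 1.10,
                      wk48 = c(faricimab_q8w = 763.9, faricimab_te = 777.2,
                               aflibercept_q8w = 1030.6)),
      outer_r3 = list(baseline = 700, early_rise = 0, wk12_frac = 0.95,
                      wk48 = c(faricimab_q8w = 311.7, faricimab_te = 319.6,
                               aflibercept_q8w = 533.6))),
    rise_week = 8,
    count_baseline = c(inner_r1 = 5, outer_r1 = 4, inner_r3 = 14,
                       outer_r3 = 11),
    noise_dist = c("lognormal", "normal"),
    noise_sd = 0.5,
    resid_cor = c("exchangeable", "ar1", "unstructured"),
    resid_rho = 0.6,
    resid_cor_matrix = NULL,
    p_zero_ref = 0.03,
    zero_hr = c(faricimab_q8w = 1.48, faricimab_te = 1.23,
                aflibercept_q8w = 1.00),
    p_zero_baseline = 0.02,
    dropout_p = 0.01,
    irf_rho = 0.42) {
  noise_dist <- match.arg(noise_dist)
  resid_cor <- match.arg(resid_cor)
  stopifnot(p_zero_ref >= 0, p_zero_ref <= 1,
            p_zero_baseline >= 0, p_zero_baseline <= 1,
            dropout_p >= 0, dropout_p <= 1,
            irf_rho >= -1, irf_rho <= 1, noise_sd >= 0)
  K <- length(visit_weeks)
  R <- switch(resid_cor,
    exchangeable = matrix(resid_rho, K, K) + diag(1 - resid_rho, K),
    ar1 = resid_rho^abs(outer(seq_len(K), seq_len(K), "-")),
    unstructured = {
      if (is.null(resid_cor_matrix) ||
          !identical(dim(resid_cor_matrix), c(K, K)))
        stop("resid_cor_matrix must be a ", K, "x", K, " matrix",
             call. = FALSE)
      resid_cor_matrix
    })
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("residual correlation matrix is not positive definite",
         call. = FALSE)
  structure(list(visit_weeks = visit_weeks, volumes = volumes,
                 rise_week = rise_week, count_baseline = count_baseline,
                 noise_dist = noise_dist, noise_sd = noise_sd,
                 resid_cor = resid_cor, resid_rho = resid_rho, R = R,
                 p_zero_ref = p_zero_ref, zero_hr = zero_hr,
                 p_zero_baseline = p_zero_baseline, dropout_p = dropout_p,
                 irf_rho = irf_rho),
            class = "trajectory_spec")
}

#' Noise-free arm-mean trajectory of a volume endpoint
#'
#' @param spec A [trajectory_spec].
#' @param arm One of the three arm labels.
#' @param endpoint `"inner_r1"`, `"outer_r1"`, `"inner_r3"` or `"outer_r3"`.
#' @param weeks Weeks at which to evaluate (default the spec's visit grid).
#' @return Numeric vector of mean volumes (pL).
#' @export
trajectory_mean <- function(spec, arm, endpoint, weeks = spec$visit_weeks) {
  p <- spec$volumes[[endpoint]]
  if (is.null(p)) stop("unknown endpoint: ", endpoint, call. = FALSE)
  if (!arm %in% names(p$wk48)) stop("unknown arm: ", arm, call. = FALSE)
  anchors_t <- c(0, spec$rise_week, 12, 48)
  anchors_f <- c(1, 1 + p$early_rise, p$wk12_frac, p$wk48[[arm]] / p$baseline)
  p$baseline * stats::approx(anchors_t, anchors_f, xout = weeks,
                             rule = 2)$y
}

#' Generate a synthetic longitudinal trial dataset
#'
#' Draws `n_per_arm` patients per arm on the spec's visit grid with
#' correlated within-patient noise around the arm-mean trajectories,
#' stratification covariates (baseline BCVA with the <64 / >=64 letter
#' stratum, prior anti-VEGF therapy, geographic region), an absorbing
#' HRF-free state driving the count endpoints, dropout, and IRF volumes
#' whose cube-root change from baseline to week 48 is correlated with the
#' HRF total-retina 3-mm cube-root volume change at the planted `irf_rho`.
#'
#' @param spec A [trajectory_spec].
#' @param n_per_arm Patients per arm (>= 2).
#' @param seed Integer seed; fixed seed gives an identical dataset.
#' @return A `trial_dataset` (see [read_trial_table()] for the schema) with
#'   attribute `planted` recording the generating parameters.
#' @export
generate_trial <- function(spec, n_per_arm, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"), n_per_arm >= 2)
  set.seed(seed)
  weeks <- spec$visit_weeks
  K <- length(weeks)
  arms <- trial_arms
  npat <- n_per_arm * length(arms)
  arm <- rep(arms, each = n_per_arm)
  pid <- sprintf("P%04d", seq_len(npat))

  bcva <- pmax(24, pmin(83, round(stats::rnorm(npat, 62.5, 9))))
  bcva_stratum <- ifelse(bcva < 64, "<64", ">=64")
  prior <- ifelse(stats::runif(npat) < 0.4, "yes", "no")
  region <- sample(trial_regions, npat, replace = TRUE,
                   prob = c(0.5, 0.2, 0.3))

  # dropout: geometric on the post-baseline grid
  drop_draw <- stats::runif(npat * (K - 1)) < spec$dropout_p
  last_idx <- vapply(seq_len(npat), function(i) {
    d <- which(drop_draw[((i - 1) * (K - 1) + 1):(i * (K - 1))])
    if (length(d) == 0) K else d[1]
  }, integer(1))
  last_week <- weeks[last_idx]

  # absorbing HRF-free state
  p_arm <- 1 - (1 - spec$p_zero_ref)^spec$zero_hr[arm]
  at_zero_baseline <- stats::runif(npat) < spec$p_zero_baseline
  zero_idx <- rep(Inf, npat)              # visit index of first zero
  zero_idx[at_zero_baseline] <- 1
  u <- matrix(stats::runif(npat * (K - 1)), npat, K - 1)
  for (i in which(!at_zero_baseline)) {
    hit <- which(u[i, ] < p_arm[i])
    if (length(hit) > 0) zero_idx[i] <- hit[1] + 1
  }

  # correlated noise per endpoint
  L <- chol(spec$R)
  noise <- function() {
    z <- matrix(stats::rnorm(npat * K), npat, K) %*% L
    z
  }

  ep_names <- names(spec$volumes)
  vol <- list()
  for (e in ep_names) {
    mu <- vapply(arms, function(a) trajectory_mean(spec, a, e, weeks),
                 numeric(K))                       # K x arms
    m <- t(mu[, match(arm, arms)])                 # npat x K
    z <- noise()
    if (spec$noise_dist == "lognormal") {
      s <- spec$noise_sd
      vol[[e]] <- m * exp(s * z - s^2 / 2)
    } else {
      s <- spec$noise_sd * spec$volumes[[e]]$baseline
      vol[[e]] <- m + s * z
    }
  }

  cnt <- list()
  for (e in ep_names) {
    mu <- vapply(arms, function(a) trajectory_mean(spec, a, e, weeks),
                 numeric(K))
    shape <- t(mu[, match(arm, arms)]) /
      matrix(spec$volumes[[e]]$baseline, npat, K)
    lam <- spec$count_baseline[[e]] * shape
    draws <- matrix(stats::rpois(npat * K, as.vector(lam)), npat, K)
    draws <- pmax(draws, 1L)                       # zeros only by absorption
    absorbed <- outer(zero_idx, seq_len(K), "<=")
    draws[absorbed] <- 0L
    cnt[[e]] <- draws
  }

  # IRF volumes: cube-root change at week 48 correlated with HRF change
  hrf_total_r3 <- vol$inner_r3 + vol$outer_r3
  u_chg <- hrf_total_r3[, K]^(1 / 3) - hrf_total_r3[, 1]^(1 / 3)
  zu <- (u_chg - mean(u_chg)) / stats::sd(u_chg)
  w <- spec$irf_rho * zu +
    sqrt(max(0, 1 - spec$irf_rho^2)) * stats::rnorm(npat)
  irf0_cbrt <- pmax(1, stats::rnorm(npat, 7, 1.2))
  irf48_cbrt <- pmax(0.1, irf0_cbrt - 2 + 1.5 * w)
  frac <- (weeks - weeks[1]) / (weeks[K] - weeks[1])
  irf_cbrt <- outer(irf0_cbrt, 1 - frac) + outer(irf48_cbrt, frac)
  irf <- irf_cbrt^3

  rows <- data.frame(
    patient_id = rep(pid, each = K),
    arm = rep(arm, each = K),
    visit_week = rep(weeks, times = npat),
    bcva_baseline = rep(bcva, each = K),
    bcva_stratum = rep(bcva_stratum, each = K),
    prior_anti_vegf = rep(prior, each = K),
    region_stratum = rep(region, each = K),
    last_week = rep(last_week, each = K),
    vol_inner_r1_pl = as.vector(t(vol$inner_r1)),
    vol_outer_r1_pl = as.vector(t(vol$outer_r1)),
    vol_inner_r3_pl = as.vector(t(vol$inner_r3)),
    vol_outer_r3_pl = as.vector(t(vol$outer_r3)),
    count_inner_r1 = as.vector(t(cnt$inner_r1)),
    count_outer_r1 = as.vector(t(cnt$outer_r1)),
    count_inner_r3 = as.vector(t(cnt$inner_r3)),
    count_outer_r3 = as.vector(t(cnt$outer_r3)),
    irf_vol_pl = as.vector(t(irf)),
    stringsAsFactors = FALSE)
  keep <- rows$visit_week <= rows$last_week
  rows <- rows[keep, , drop = FALSE]
  ds <- validate_trial_table(rows)
  attr(ds, "planted") <- list(
    zero_hr = spec$zero_hr, p_zero_ref = spec$p_zero_ref,
    irf_rho = spec$irf_rho,
    week48_means = lapply(stats::setNames(ep_names, ep_names), function(e)
      vapply(arms, function(a) trajectory_mean(spec, a, e, 48), numeric(1))),
    seed = seed)
  ds
}

#' Simulate grid event times under grouped proportional hazards
#'
#' Geometric waiting times on a planned-visit grid: each subject has
#' per-visit event probability `p` from the first post-baseline visit;
#' subjects without an event by the end of the grid are censored at the last
#' week. A per-visit censoring (dropout) probability can compete with the
#' event. Used for survival-estimator recovery studies where the true
#' discrete hazard is known in closed form.
#'
#' @param n Number of subjects.
#' @param p Per-visit event probability (scalar or length-`n`).
#' @param weeks Visit grid including baseline (default `seq(0, 48, 4)`).
#' @param dropout_p Per-visit dropout probability (default 0).
#' @return Data.frame with `time` (weeks), `event` (0/1).
#' @export
simulate_grid_events <- function(n, p, weeks = seq(0, 48, by = 4),
                                 dropout_p = 0) {
  K <- length(weeks)
  p <- rep_len(p, n)
  time <- numeric(n); event <- integer(n)
  for (i in seq_len(n)) {
    t_ev <- Inf; t_cn <- Inf
    ue <- stats::runif(K - 1); uc <- stats::runif(K - 1)
    he <- which(ue < p[i]); hc <- which(uc < dropout_p)
    if (length(he) > 0) t_ev <- he[1]
    if (length(hc) > 0) t_cn <- hc[1]
    if (t_ev <= t_cn && is.finite(t_ev)) {
      time[i] <- weeks[t_ev + 1]; event[i] <- 1L
    } else if (is.finite(t_cn)) {
      time[i] <- weeks[t_cn + 1]; event[i] <- 0L
    } else {
      time[i] <- weeks[K]; event[i] <- 0L
    }
  }
  data.frame(time = time, event = event)
}
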