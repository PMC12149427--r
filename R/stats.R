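#' Van Elteren stratified Wilcoxon rank-sum test
#'
#' Stratum-weighted two-sample Wilcoxon rank-sum test: within each stratum
#' the Mann-Whitney statistic is computed on mid-ranks, strata are combined
#' with weights 1/(N_s + 1), and the standardised statistic is referred to
#' the normal distribution with tie-corrected variance and no continuity
#' correction. With a single stratum the test reduces exactly to the
#' ordinary (normal-approximation) Wilcoxon rank-sum test. Used as the
#' distribution-free sensitivity analysis for positively skewed endpoints.
#'
#' @param x,y Numeric samples for the two arms.
#' @param strata_x,strata_y Stratum labels aligned with `x` and `y`. Strata
#'   present in only one arm are ignored with a warning.
#' @return A list of class `htest` with the weighted statistic, z value and
#'   two-sided p-value.
#' @export
van_elteren <- function(x, y, strata_x = NULL, strata_y = NULL) {
  if (is.null(strata_x)) strata_x <- rep("all", length(x))
  if (is.null(strata_y)) strata_y <- rep("all", length(y))
  stopifnot(length(strata_x) == length(x), length(strata_y) == length(y))
  strata_x <- as.character(strata_x); strata_y <- as.character(strata_y)
  levels_ <- union(unique(strata_x), unique(strata_y))
  T_ <- 0; E_ <- 0; V_ <- 0; used <- 0L
  for (s in levels_) {
    xs <- x[strata_x == s]; ys <- y[strata_y == s]
    n1 <- length(xs); n2 <- length(ys); N <- n1 + n2
    if (n1 == 0 || n2 == 0) {
      warning("stratum '", s, "' present in only one arm; ignored",
              call. = FALSE)
      next
    }
    used <- used + 1L
    r <- rank(c(xs, ys))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    varU <- n1 * n2 / 12 * ((N + 1) - tie_term)
    w <- 1 / (N + 1)
    T_ <- T_ + w * U
    E_ <- E_ + w * n1 * n2 / 2
    V_ <- V_ + w^2 * varU
  }
  if (used == 0L) stop("no stratum contains both arms", call. = FALSE)
  if (V_ <= 0) stop("zero variance: all observations tied", call. = FALSE)
  z <- (T_ - E_) / sqrt(V_)
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(statistic = c(T = T_), parameter = c(z = z),
                 p.value = p,
                 method = "Van Elteren stratified Wilcoxon rank-sum test",
                 alternative = "two.sided",
                 data.name = paste(deparse(substitute(x)), "vs",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Pearson correlation of cube-root-transformed volume changes
#'
#' Computes, per patient, the change from baseline to the target week in the
#' cube-root-transformed HRF volume and in the cube-root-transformed IRF
#' volume (the transform is applied to each visit's volume BEFORE taking the
#' difference), and returns the Pearson correlation with a t-based
#' two-sided p-value. The cube root moves the strongly right-skewed volume
#' distributions towards symmetry and puts both endpoints on a length-like
#' scale.
#'
#' @param dataset A `trial_dataset`.
#' @param hrf_cols Volume columns summed to form the HRF volume (default the
#'   total retina, 3-mm disc: inner + outer 3-mm).
#' @param irf_col IRF volume column (default `"irf_vol_pl"`).
#' @param week Target week (default 48).
#' @return List with `r`, `p`, `n`, `conf_int`, and the underlying
#'   [stats::cor.test()] result in `test`.
#' @export
correlation_cuberoot <- function(dataset,
                                 hrf_cols = c("vol_inner_r3_pl",
                                              "vol_outer_r3_pl"),
                                 irf_col = "irf_vol_pl",
                                 week = 48) {
  df <- as.data.frame(dataset)
  miss <- setdiff(c(hrf_cols, irf_col), names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  hrf <- rowSums(df[, hrf_cols, drop = FALSE])
  b <- df$visit_week == 0
  w <- df$visit_week == week
  base <- data.frame(patient_id = df$patient_id[b],
                     hrf0 = hrf[b], irf0 = df[[irf_col]][b])
  last <- data.frame(patient_id = df$patient_id[w],
                     hrf1 = hrf[w], irf1 = df[[irf_col]][w])
  m <- merge(base, last, by = "patient_id")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3)
    stop("fewer than 3 complete baseline/week-", week, " pairs",
         call. = FALSE)
  d_hrf <- m$hrf1^(1 / 3) - m$hrf0^(1 / 3)
  d_irf <- m$irf1^(1 / 3) - m$irf0^(1 / 3)
  ct <- stats::cor.test(d_hrf, d_irf, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
       conf_int = as.numeric(ct$conf.int), test = ct)
}
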