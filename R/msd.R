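#' Time-averaged mean-square displacement of one track
#'
#' For every realized delay tau = k * dt (k >= 1) the TA-MSD is the mean
#' over all ordered, overlapping pairs of points (i, j) with
#' t_j - t_i = tau of the squared displacement |r_j - r_i|^2.  Delays not
#' realized because of gaps are omitted (never imputed) and the number of
#' contributing pairs per delay is recorded.
#'
#' @param track data.frame with columns `frame`, `t_s`, `x_um`, `y_um`
#'   (one track; see [split_tracks()]).
#' @param max_lag_frames largest frame lag computed (default: all realized
#'   lags).  Fits over the first 200 ms only need the first dozen delays,
#'   so capping the lag saves time on long tracks.
#' @return data.frame of class `msd_curve` with columns `tau_s`,
#'   `msd_um2`, `n_pairs`; attribute `frame_interval` carries dt.
#' @examples
#' tr <- data.frame(frame = 0:2, t_s = 0:2, x_um = c(0, 1, 2), y_um = 0)
#' tamsd(tr)  # msd(1 s) = 1, msd(2 s) = 4
#' @export
tamsd <- function(track, max_lag_frames = Inf) {
  n <- nrow(track)
  if (n < 2) stop("track must have at least 2 points")
  f <- as.integer(track$frame)
  dt <- infer_dt(track)
  kmax <- min(max(f) - min(f), max_lag_frames)
  x <- track$x_um; y <- track$y_um
  ks <- integer(0); ms <- numeric(0); np <- integer(0)
  for (k in seq_len(kmax)) {
    j <- match(f + k, f)          # partner at lag k (NA across gaps)
    ok <- !is.na(j)
    if (!any(ok)) next
    jj <- j[ok]; ii <- which(ok)
    d2 <- (x[jj] - x[ii])^2 + (y[jj] - y[ii])^2
    ks <- c(ks, k); ms <- c(ms, mean(d2)); np <- c(np, length(d2))
  }
  structure(data.frame(tau_s = ks * dt,
                       msd_um2 = ms,
                       n_pairs = np),
            class = c("msd_curve", "data.frame"),
            frame_interval = dt, scope = "track")
}

# frame interval from the time stamps (robust to gaps)
infer_dt <- function(track) {
  df <- diff(track$frame)
  dts <- diff(track$t_s) / df
  dt <- stats::median(dts)
  if (!is.finite(dt) || dt <= 0) stop("cannot infer a positive frame interval")
  dt
}

#' Ensemble (weighted) average of per-track MSD curves
#'
#' Per delay, the weighted mean across all tracks possessing that delay.
#' The default weighting `"by_pairs"` uses each track's pair count at the
#' delay (the variance-minimizing choice for averaging over all particles);
#' `"uniform"` weights every track equally.  The standard error of the mean
#' uses reliability weights: `sem = sqrt(sum w (x - xbar)^2 / (sum w - sum
#' w^2 / sum w)) / sqrt(n_eff)` with `n_eff = (sum w)^2 / sum w^2`, which
#' reduces to the ordinary SEM for uniform weights.
#'
#' @param curves list of `msd_curve` objects (or a single curve).
#' @param weighting `"by_pairs"` or `"uniform"`.
#' @return `msd_curve` data.frame with columns `tau_s`, `msd_um2`, `sem`,
#'   `n_pairs` (total pairs), `n_tracks`.
#' @export
ensemble_msd <- function(curves, weighting = c("by_pairs", "uniform")) {
  weighting <- match.arg(weighting)
  if (inherits(curves, "msd_curve")) curves <- list(curves)
  if (length(curves) == 0) stop("no MSD curves supplied")
  dt <- attr(curves[[1]], "frame_interval")
  if (is.null(dt)) dt <- min(curves[[1]]$tau_s)
  all <- do.call(rbind, lapply(seq_along(curves), function(i) {
    ci <- curves[[i]]
    data.frame(k = as.integer(round(ci$tau_s / dt)),
               msd = ci$msd_um2, n_pairs = ci$n_pairs)
  }))
  all$w <- if (weighting == "by_pairs") all$n_pairs else 1
  ks <- sort(unique(all$k))
  res <- lapply(ks, function(k) {
    sub <- all[all$k == k, ]
    sw <- sum(sub$w)
    xbar <- sum(sub$w * sub$msd) / sw
    n_eff <- sw^2 / sum(sub$w^2)
    sem <- if (nrow(sub) > 1 && sw > sum(sub$w^2) / sw) {
      s2 <- sum(sub$w * (sub$msd - xbar)^2) / (sw - sum(sub$w^2) / sw)
      sqrt(s2 / n_eff)
    } else 0
    data.frame(tau_s = k * dt, msd_um2 = xbar, sem = sem,
               n_pairs = sum(sub$n_pairs), n_tracks = nrow(sub))
  })
  structure(do.call(rbind, res),
            class = c("msd_curve", "data.frame"),
            frame_interval = dt, scope = "ensemble",
            weighting = weighting)
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Ordinary least squares of log10 MSD on log10 tau over the delays with
#' tau <= `fit_window_s`, i.e. the linearized model
#' `log(MSD(tau)) = alpha log tau + log(2 d D)`.  The slope is the
#' anomalous exponent alpha and `D = 10^intercept / (2 d)` the generalized
#' diffusion coefficient (um^2/s^alpha); d = 2 for membrane (TIRF) data.
#' The fit is gated on the coefficient of determination of this log-log
#' regression: tracks with `r2 <= r2_gate` are flagged as failing.
#'
#' @param curve an `msd_curve`.
#' @param fit_window_s fit only delays with tau <= this window (default
#'   0.2 s, i.e. the first 200 ms).
#' @param r2_gate R^2 gate (default 0.8); `passed_gate = r2 > r2_gate`.
#' @param d spatial dimensionality (default 2).
#' @return one-row data.frame of class `fit_result`: `D`, `neg_log10_D`,
#'   `alpha`, `r2`, `n_delays_used`, `passed_gate`, `failed` (TRUE when
#'   fewer than 3 usable delays).
#' @examples
#' tau <- seq(0.017, 0.2, by = 0.017)
#' curve <- structure(
#'   data.frame(tau_s = tau, msd_um2 = 4 * 0.1 * tau^0.5,
#'              n_pairs = 100L),
#'   class = c("msd_curve", "data.frame"), frame_interval = 0.017)
#' fit_powerlaw(curve)  # alpha = 0.5, D = 0.1, r2 = 1
#' @export
fit_powerlaw <- function(curve, fit_window_s = 0.2, r2_gate = 0.8, d = 2) {
  use <- curve$tau_s <= fit_window_s + 1e-12 & curve$msd_um2 > 0
  n_use <- sum(use)
  if (n_use < 3) {
    return(structure(data.frame(D = NA_real_, neg_log10_D = NA_real_,
                                alpha = NA_real_, r2 = NA_real_,
                                n_delays_used = n_use,
                                passed_gate = FALSE, failed = TRUE),
                     class = c("fit_result", "data.frame")))
  }
  lx <- log10(curve$tau_s[use])
  ly <- log10(curve$msd_um2[use])
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- fit$coefficients[2]
  D <- 10^fit$coefficients[1] / (2 * d)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  structure(data.frame(D = unname(D), neg_log10_D = unname(-log10(D)),
                       alpha = unname(alpha), r2 = r2,
                       n_delays_used = n_use,
                       passed_gate = r2 > r2_gate, failed = FALSE),
            class = c("fit_result", "data.frame"))
}

#' Fit all tracks of a cohort and classify their motion
#'
#' Convenience wrapper: per-track TA-MSD, power-law fit, R^2 gating and
#' motion classification.
#'
#' @param tracks `spt_tracks` data.frame.
#' @param fit_window_s,r2_gate,d see [fit_powerlaw()].
#' @param band Brownian classification band, see [classify_motion()].
#' @return data.frame with one row per track: `track_id`, fit columns and
#'   `motion_class`.
#' @export
fit_tracks <- function(tracks, fit_window_s = 0.2, r2_gate = 0.8, d = 2,
                       band = c(0.9, 1.1)) {
  trs <- split_tracks(tracks)
  rows <- lapply(names(trs), function(id) {
    tr <- trs[[id]]
    max_lag <- ceiling(fit_window_s / infer_dt(tr)) + 1L
    fit <- fit_powerlaw(tamsd(tr, max_lag_frames = max_lag),
                        fit_window_s, r2_gate, d)
    fit$track_id <- as.integer(id)
    fit$motion_class <- if (isTRUE(fit$passed_gate))
      classify_motion(fit$alpha, band) else NA_character_
    fit
  })
  out <- do.call(rbind, rows)
  out[, c("track_id", "D", "neg_log10_D", "alpha", "r2",
          "n_delays_used", "passed_gate", "failed", "motion_class")]
}

#' Apparent diffusion coefficient over time, on the -log10 scale
#'
#' For each delay, the apparent coefficient `D_app(tau) = MSD(tau) /
#' (2 d tau)`; the returned series is `-log10 D_app` versus tau.  For pure
#' Brownian motion the series is constant at `-log10 D`; an increasing
#' series signals subdiffusion/confinement.
#'
#' @param curve `msd_curve`.
#' @param d spatial dimensionality (default 2).
#' @return data.frame `tau_s`, `D_app`, `neg_log10_D_app` (zero-MSD delays
#'   skipped).
#' @export
logD_vs_time <- function(curve, d = 2) {
  use <- curve$msd_um2 > 0
  tau <- curve$tau_s[use]
  D_app <- curve$msd_um2[use] / (2 * d * tau)
  data.frame(tau_s = tau, D_app = D_app,
             neg_log10_D_app = -log10(D_app))
}

#' Classify motion from the fitted anomalous exponent
#'
#' Alpha below the band is anomalous/confined subdiffusion, inside the band
#' Brownian, above it directed.  The band is needed because the Brownian
#' case alpha = 1 is measure-zero under measurement noise; the default
#' (0.9, 1.1) is echoed in all reports.
#'
#' @param alpha fitted exponent(s), or a `fit_result`.
#' @param band numeric length-2 `(lo, hi)`.
#' @return character vector with levels `"anomalous_confined"`,
#'   `"brownian"`, `"directed"`.
#' @export
classify_motion <- function(alpha, band = c(0.9, 1.1)) {
  if (inherits(alpha, "fit_result") || is.data.frame(alpha))
    alpha <- alpha$alpha
  stopifnot(length(band) == 2, band[1] <= band[2])
  ifelse(alpha < band[1], "anomalous_confined",
         ifelse(alpha > band[2], "directed", "brownian"))
}

#' Estimate a confinement radius from a plateauing MSD curve
#'
#' Fits the saturating model `MSD(tau) = R_c^2 (1 - exp(-tau / tau_c))` by
#' nonlinear least squares.  Under the reflecting-disk convention used by
#' the simulator the long-lag plateau equals R_c^2 (the mean squared
#' separation of two independent uniform points on a disk of radius R_c),
#' so the fitted R_c is the disk radius.  Curves without a plateau are
#' refused: the log-log slope over the last third of delays must be below
#' `plateau_slope_max`.
#'
#' @param curve `msd_curve` (typically an ensemble curve).
#' @param plateau_slope_max late-delay log-log slope above which the curve
#'   is considered non-plateauing (default 0.3).
#' @return one-row data.frame of class `confinement_fit`: `R_c_um`,
#'   `tau_c_s`, `r2`.
#' @export
confinement_radius <- function(curve, plateau_slope_max = 0.3) {
  use <- curve$msd_um2 > 0
  tau <- curve$tau_s[use]; msd <- curve$msd_um2[use]
  if (length(tau) < 6) stop("too few delays for a confinement fit")
  tail_idx <- tau >= tau[1] + 2 / 3 * (tau[length(tau)] - tau[1])
  if (sum(tail_idx) < 3)
    tail_idx <- seq_along(tau) > length(tau) - 3
  slope <- stats::coef(stats::lm(log10(msd[tail_idx]) ~
                                   log10(tau[tail_idx])))[2]
  if (slope >= plateau_slope_max)
    stop(sprintf(paste0("curve does not plateau (late log-log slope ",
                        "%.2f >= %.2f); confinement fit refused"),
                 slope, plateau_slope_max))
  plateau0 <- mean(msd[tail_idx])
  tauc0 <- tau[which.min(abs(msd - plateau0 * (1 - exp(-1))))]
  fit <- minpack.lm::nlsLM(
    msd ~ p * (1 - exp(-tau / tc)),
    start = list(p = plateau0, tc = max(tauc0, tau[1])),
    lower = c(1e-12, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)[["p"]]; tc <- stats::coef(fit)[["tc"]]
  resid <- msd - p * (1 - exp(-tau / tc))
  r2 <- 1 - sum(resid^2) / sum((msd - mean(msd))^2)
  structure(data.frame(R_c_um = sqrt(p), tau_c_s = tc, r2 = r2),
            class = c("confinement_fit", "data.frame"))
}
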