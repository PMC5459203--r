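# Fluorescence-quench kinetics: trace normalization, first-order decay
# fits, the diffusion-limited capture model tau(c_NP) = A/c_NP + tau0, and
# the intraparticle diffusion-constant estimate D_intra = r^2 / tau0.

#' Construct a fluorescence time trace
#'
#' Time is in seconds with t = 0 at nanoparticle addition; the pre-addition
#' segment (t < 0) is the baseline used for normalization. If a lamp
#' reference is supplied the signal is divided by it point-wise first, to
#' correct for lamp-brightness fluctuations.
#'
#' @param time numeric, seconds, strictly increasing.
#' @param signal fluorescence, arbitrary units, > 0.
#' @param lamp_ref optional lamp reference channel, same length.
#' @param ph optional pH label; `solvent` optional ("water" or "HBG").
#' @param solvent see above.
#' @return A `mof_trace` data.frame (columns `time_s`, `signal`) with
#'   attributes `normalized`, `ph`, `solvent`.
#' @export
fluorescence_trace <- function(time, signal, lamp_ref = NULL,
                               ph = NA_real_, solvent = NA_character_) {
  if (length(time) != length(signal))
    stop_input("time and signal must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop_input("time must be strictly increasing")
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop_input("signal must be finite and > 0")
  if (!is.null(lamp_ref)) {
    if (length(lamp_ref) != length(signal) || any(lamp_ref <= 0))
      stop_input("lamp_ref must be positive and match signal length")
    signal <- signal / lamp_ref
  }
  df <- data.frame(time_s = time, signal = signal)
  attr(df, "normalized") <- FALSE
  attr(df, "ph") <- ph
  attr(df, "solvent") <- solvent
  class(df) <- c("mof_trace", "data.frame")
  df
}

#' Normalize a trace to its pre-addition baseline
#'
#' Divides the signal by the arithmetic mean of all pre-addition samples
#' (t < 0), so the baseline mean becomes exactly 1. Idempotent: a second
#' call renormalizes by a baseline mean that is already 1.
#'
#' @param trace a `mof_trace` with at least one point at t < 0.
#' @return The normalized `mof_trace`.
#' @export
normalize_trace <- function(trace) {
  base <- trace$signal[trace$time_s < 0]
  if (length(base) == 0)
    stop_input("trace has no pre-addition (t < 0) baseline samples")
  out <- trace
  out$signal <- trace$signal / mean(base)
  attr(out, "normalized") <- TRUE
  out
}

#' Fit a single-exponential decay to a loading/release trace
#'
#' Least-squares fit of `F(t) = offset + amplitude * exp(-rate * t)` on the
#' post-addition (t >= 0) segment, with `tau = 1/rate` and a 1-sigma rate
#' uncertainty from the fit covariance. Starting values come from a
#' log-linear regression of `F - offset0` against t.
#'
#' A trace is reported as "no detectable loading" — mirroring the dashes
#' real instruments produce at high pH — when the fitted rate's 95%
#' confidence interval includes zero or the total normalized drop is below
#' 2%.
#'
#' @param trace a normalized `mof_trace`, or any data.frame with `time_s`
#'   and `signal` (t >= 0 rows are used).
#' @param t_lag_max upper bound (s) for an optional mixing dead-time
#'   parameter; 0 (the default) fixes the lag at zero.
#' @return An object of class `mof_decay_fit`: `rate` (1/s), `tau` (s),
#'   `amplitude`, `offset`, `se_rate`, `r_squared`, `detected` (logical),
#'   `t_lag`. When `detected` is FALSE the kinetic fields are NA and
#'   `reason` explains why.
#' @export
#' @examples
#' tr <- gen_trace(rate = 0.013, offset = 0.2, baseline_s = 60,
#'                 duration_s = 500, noise = noise_model(0, 0, seed = 1))
#' fit_exponential(normalize_trace(tr))
fit_exponential <- function(trace, t_lag_max = 0) {
  keep <- trace$time_s >= 0
  t <- trace$time_s[keep]
  y <- trace$signal[keep]
  if (length(t) < 10)
    stop_input("need at least 10 post-addition points to fit a decay")

  none <- function(reason) structure(
    list(rate = NA_real_, tau = NA_real_, amplitude = NA_real_,
         offset = NA_real_, se_rate = NA_real_, r_squared = NA_real_,
         detected = FALSE, t_lag = 0, reason = reason),
    class = "mof_decay_fit")

  drop_total <- (max(y[seq_len(min(5, length(y)))]) -
                   mean(y[t >= stats::quantile(t, 0.8)]))
  if (is.finite(drop_total) && drop_total < 0.02 * max(y))
    return(none("total normalized drop < 2%"))

  off0 <- min(y)
  amp0 <- max(y[1:3]) - off0
  pos <- y - off0 + 0.05 * amp0 > 0
  rate0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(y[pos] - off0 + 0.05 * amp0) ~ t[pos]))[2]
    max(abs(sl), 1e-5)
  }, error = function(e) 1 / max(t))

  form <- if (t_lag_max > 0) {
    y ~ offset + amplitude * exp(-rate * pmax(t - t_lag, 0))
  } else {
    y ~ offset + amplitude * exp(-rate * t)
  }
  start <- list(offset = off0, amplitude = amp0, rate = unname(rate0))
  lower <- c(offset = -Inf, amplitude = 0, rate = 1e-8)
  upper <- c(offset = Inf, amplitude = Inf, rate = Inf)
  if (t_lag_max > 0) {
    start$t_lag <- 0
    lower <- c(lower, t_lag = 0)
    upper <- c(upper, t_lag = t_lag_max)
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data.frame(t = t, y = y),
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(none("decay fit did not converge"))

  est <- stats::coef(fit)
  se  <- tryCatch(sqrt(diag(stats::vcov(fit))),
                  error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  rate <- unname(est["rate"]); se_rate <- unname(se["rate"])

  # 95% CI including zero => rate indistinguishable from no loading
  if (is.finite(se_rate) && rate - 1.96 * se_rate <= 0)
    return(none("fitted rate CI includes zero"))

  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(rate = rate, tau = 1 / rate,
         amplitude = unname(est["amplitude"]),
         offset = unname(est["offset"]),
         se_rate = se_rate,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         detected = TRUE,
         t_lag = if (t_lag_max > 0) unname(est["t_lag"]) else 0),
    class = "mof_decay_fit")
}

#' @export
print.mof_decay_fit <- function(x, ...) {
  if (!isTRUE(x$detected)) {
    cat("<mof_decay_fit> no detectable loading (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<mof_decay_fit> rate = %.3g 1/s (se %.2g), tau = %.4g s, offset = %.3g, R^2 = %.4f\n",
    x$rate, x$se_rate, x$tau, x$offset, x$r_squared))
  invisible(x)
}

#' Transport parameter bundle
#'
#' @param d_ex bulk (external) guest diffusion coefficient, m^2/s.
#' @param d_intra effective intraparticle diffusion coefficient, m^2/s
#'   (optional; must be < d_ex when given).
#' @param radius_nm particle radius, nm.
#' @param density_eff_mg_cm3 effective suspension density of the particles,
#'   mg/cm^3.
#' @return A `mof_transport_params` list.
#' @export
transport_params <- function(d_ex, d_intra = NULL, radius_nm,
                             density_eff_mg_cm3) {
  stopifnot(d_ex > 0, radius_nm > 0, density_eff_mg_cm3 > 0)
  if (!is.null(d_intra) && (d_intra <= 0 || d_intra >= d_ex))
    stop_input("d_intra must satisfy 0 < d_intra < d_ex")
  structure(list(d_ex = d_ex, d_intra = d_intra, radius_nm = radius_nm,
                 density_eff_mg_cm3 = density_eff_mg_cm3),
            class = "mof_transport_params")
}

#' Diffusion-limited capture time for a particle suspension
#'
#' Closed-form estimate of the time for free guest molecules to reach the
#' particle surfaces when each particle drains a surrounding spherical
#' volume of radius half the mean interparticle distance:
#' `tau_diff = pi r^2 rho / (18 c_NP D_ex)`. The density and the particle
#' concentration enter only through their (dimensionless) ratio.
#'
#' @param c_np particle mass concentration, mg/cm^3 (> 0).
#' @param params a [transport_params()].
#' @return Capture time in seconds.
#' @export
#' @examples
#' p <- transport_params(d_ex = 3.9e-10, radius_nm = 26.5,
#'                       density_eff_mg_cm3 = 2)
#' tau_diff(5e-3, p)
tau_diff <- function(c_np, params) {
  if (any(!is.finite(c_np)) || any(c_np <= 0))
    stop_input("c_np must be > 0 (tau_diff diverges at zero concentration)")
  r_m <- params$radius_nm * mof_constants$nm_to_m
  pi * r_m^2 * params$density_eff_mg_cm3 / (18 * c_np * params$d_ex)
}

#' Fit the capture model tau(c_NP) = A / c_NP + tau0
#'
#' The model is linear in 1/c_NP, so the fit is (weighted) ordinary least
#' squares; per-point standard errors of tau are used as inverse-variance
#' weights when supplied. tau0, the high-concentration asymptote, is the
#' concentration-independent component of the loading time attributed to
#' internal transport and sorption; when the unconstrained estimate is
#' negative the model is refit under the physical constraint tau0 >= 0.
#'
#' @param c_np particle concentrations, mg/cm^3 (>= 3 values spanning at
#'   least one decade).
#' @param tau fitted loading times, s.
#' @param se_tau optional per-point standard errors of tau.
#' @return An object of class `mof_capture_fit`: `prefactor_a`
#'   (s * mg/cm^3), `tau0` (s), `se_a`, `se_tau0`, `r_squared`.
#' @export
#' @examples
#' cs <- c(0.001, 0.003, 0.01, 0.03)
#' fit_capture_model(cs, 0.3 / cs + 60)
fit_capture_model <- function(c_np, tau, se_tau = NULL) {
  if (length(c_np) < 3) stop_input("need at least 3 concentrations")
  if (length(tau) != length(c_np))
    stop_input("c_np and tau must have equal length")
  if (any(c_np <= 0) || any(tau < 0)) stop_input("inputs must be positive")
  if (max(c_np) / min(c_np) < 10)
    warning("concentration series spans less than one decade; ",
            "A and tau0 may be poorly separated", call. = FALSE)

  x <- 1 / c_np
  w <- if (!is.null(se_tau)) {
    if (any(se_tau <= 0)) stop_input("se_tau must be > 0")
    1 / se_tau^2
  }
  fit <- stats::lm(tau ~ x, weights = w)
  co <- stats::coef(fit)
  # an exact (noise-free) series makes summary.lm warn about perfect fits
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  tau0 <- unname(co[1]); a <- unname(co[2])
  se_tau0 <- unname(se[1]); se_a <- unname(se[2])

  if (tau0 < 0 || a < 0) {
    nl <- minpack.lm::nlsLM(tau ~ a_pre / c_np + t0,
                            start = list(a_pre = max(a, 1e-12),
                                         t0 = max(tau0, 0)),
                            lower = c(a_pre = 0, t0 = 0),
                            weights = if (is.null(w)) rep(1, length(tau)) else w)
    est <- stats::coef(nl); sev <- sqrt(diag(stats::vcov(nl)))
    a <- unname(est["a_pre"]); tau0 <- unname(est["t0"])
    se_a <- unname(sev[1]); se_tau0 <- unname(sev[2])
  }

  ss_res <- sum((tau - (a / c_np + tau0))^2)
  ss_tot <- sum((tau - mean(tau))^2)
  structure(
    list(prefactor_a = a, tau0 = tau0, se_a = se_a, se_tau0 = se_tau0,
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
    class = "mof_capture_fit")
}

#' @export
print.mof_capture_fit <- function(x, ...) {
  cat(sprintf(
    "<mof_capture_fit> tau = A/c_NP + tau0: A = %.3g s*mg/cm^3, tau0 = %.3g s\n",
    x$prefactor_a, x$tau0))
  invisible(x)
}

#' Effective intraparticle diffusion constant
#'
#' Dimensional estimate `D_intra = r^2 / tau0`: the diffusion coefficient at
#' which a molecule traverses one particle radius in the concentration-
#' independent loading time tau0.
#'
#' @param radius_nm particle radius, nm.
#' @param tau0 concentration-independent loading-time offset, s.
#' @return D_intra in m^2/s.
#' @export
#' @examples
#' d_intra_estimate(25, 60) # ~1e-17 m^2/s
d_intra_estimate <- function(radius_nm, tau0) {
  if (radius_nm <= 0 || tau0 <= 0)
    stop_input("radius and tau0 must be > 0")
  (radius_nm * mof_constants$nm_to_m)^2 / tau0
}

#' Read a fluorescence trace CSV
#'
#' Columns `time_s, signal[, lamp_ref]`; when `lamp_ref` is present the
#' signal is divided by it before any baseline normalization.
#'
#' @param path CSV path.
#' @param ph,solvent optional metadata attached to the trace.
#' @return A `mof_trace`.
#' @export
read_trace_csv <- function(path, ph = NA_real_, solvent = NA_character_) {
  if (!file.exists(path)) stop_input("trace CSV not found: ", path)
  df <- utils::read.csv(path)
  need <- c("time_s", "signal")
  if (!all(need %in% names(df)))
    stop_input("trace CSV must have columns time_s, signal: ", path)
  fluorescence_trace(df$time_s, df$signal, lamp_ref = df$lamp_ref,
                     ph = ph, solvent = solvent)
}

#' Write a fluorescence trace CSV
#'
#' @param trace a `mof_trace` or data.frame with `time_s`, `signal`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_s", "signal")], path,
                   row.names = FALSE)
  invisible(path)
}
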