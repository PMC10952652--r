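#' Flip-angle schedule for the excitation train
#'
#' Constant (CFA) or quadratically increasing variable (VFA) flip angles across
#' the `N` readout pulses:
#' \deqn{\alpha_i = \alpha_1 + (\alpha_N - \alpha_1)\left(\frac{i-1}{N-1}\right)^2.}
#' A low starting angle preserves longitudinal magnetization for
#' late-arriving blood while the rising tail boosts the excited signal at the
#' end of the readout.
#'
#' @param kind `"constant"` or `"quadratic"`.
#' @param alpha1 First flip angle (degrees).
#' @param alphaN Final flip angle (degrees); must equal `alpha1` for
#'   `kind = "constant"`.
#' @param N Number of pulses (>= 2).
#' @return A tibble of class `capria_fa` with columns `i` and `alpha`
#'   (degrees); attributes `kind`, `alpha1`, `alphaN`.
#' @examples
#' make_schedule("quadratic", 2, 9, 216)
#' @export
make_schedule <- function(kind = c("quadratic", "constant"), alpha1, alphaN, N) {
  kind <- match.arg(kind)
  stopifnot(N >= 2)
  if (!(alpha1 > 0 && alphaN < 90 && alpha1 <= alphaN))
    abort("require 0 < alpha1 <= alphaN < 90 (degrees).")
  if (kind == "constant" && alpha1 != alphaN)
    abort("a constant schedule requires alpha1 == alphaN.")
  i <- seq_len(N)
  alpha <- alpha1 + (alphaN - alpha1) * ((i - 1) / (N - 1))^2
  out <- tibble(i = i, alpha = alpha)
  structure(out, class = c("capria_fa", class(out)),
            kind = kind, alpha1 = alpha1, alphaN = alphaN)
}

#' Cumulative RF attenuation factors
#'
#' The fraction of labeled longitudinal magnetization surviving the previous
#' excitations: \eqn{R_1 = 1}, \eqn{R_i = \prod_{j<i} \cos\alpha_j}. Every
#' non-selective imaging pulse tips (and the spoiler destroys) part of the
#' label, so `R` is strictly decreasing for positive flip angles.
#'
#' @param schedule A [make_schedule()] tibble (or numeric vector of degrees).
#' @return Numeric vector `R` of length `N`.
#' @export
rf_attenuation <- function(schedule) {
  alpha <- schedule_degrees(schedule)
  n <- length(alpha)
  c(1, cumprod(cos(alpha * pi / 180))[-n])
}

schedule_degrees <- function(schedule) {
  if (is.numeric(schedule)) return(schedule)
  stopifnot(is.data.frame(schedule), "alpha" %in% names(schedule))
  schedule$alpha
}

#' Physiological and relaxation constants for the ASL signal models
#'
#' None of these are sequence parameters; the relaxation and partition defaults
#' are literature-standard 3T values and `f` defaults to 50 ml/100g/min
#' expressed in s^-1.
#'
#' @param delta_t Macrovascular transit time to the arterial voxel (s).
#' @param Delta_t Tissue transit time (s).
#' @param T1b Longitudinal relaxation of arterial blood (s).
#' @param T1t Longitudinal relaxation of tissue (s).
#' @param f Perfusion per unit tissue volume (s^-1); 50 ml/100g/min = 1/120 s^-1.
#' @param lam Blood-tissue water partition coefficient (dimensionless).
#' @param v Fractional macrovascular blood volume (dimensionless).
#' @param M0b Equilibrium blood magnetization (arbitrary units).
#' @param alpha_inv PCASL inversion efficiency (dimensionless, <= 1).
#' @return Object of class `capria_kinetics` (named list).
#' @export
kinetic_params <- function(delta_t = 0.75, Delta_t = 1.5,
                           T1b = 1.65, T1t = 1.3,
                           f = 50 / 100 / 60, lam = 0.9,
                           v = 0.02, M0b = 1, alpha_inv = 0.85) {
  vals <- c(delta_t = delta_t, Delta_t = Delta_t, T1b = T1b, T1t = T1t,
            f = f, lam = lam, v = v, M0b = M0b, alpha_inv = alpha_inv)
  if (any(vals <= 0)) abort("all kinetic parameters must be positive.")
  if (alpha_inv > 1) abort("`alpha_inv` must be <= 1.")
  if (v > 1) abort("`v` must be <= 1.")
  structure(as.list(vals), class = "capria_kinetics")
}

#' Angiographic (macrovascular) ASL difference signal per pulse
#'
#' Simplified PCASL angiographic model, ignoring dispersion: labeled blood
#' occupies the arterial voxel for \eqn{\delta_t < t_i \le \delta_t + \tau} and
#' the acquired signal is
#' \deqn{S_{angio,i} = 2 M_{0b}\,\alpha_{inv}\, v \sin(\alpha_i)
#'   e^{-\delta_t/T_{1b}} R_i,}
#' zero outside the bolus window.
#'
#' @param params [kinetic_params()].
#' @param schedule [make_schedule()] (or numeric degrees).
#' @param times Pulse times since labeling onset (s), monotone increasing.
#' @param tau Labeling duration (s).
#' @return Numeric vector of per-pulse signals.
#' @export
angio_signal <- function(params, schedule, times, tau) {
  alpha <- schedule_degrees(schedule)
  stopifnot(length(alpha) == length(times), !is.unsorted(times))
  R <- rf_attenuation(alpha)
  amp <- 2 * params$M0b * params$alpha_inv * params$v *
    sin(alpha * pi / 180) * exp(-params$delta_t / params$T1b) * R
  inside <- times > params$delta_t & times <= params$delta_t + tau
  ifelse(inside, amp, 0)
}

#' Buxton continuous-labeling perfusion difference signal
#'
#' Standard single-compartment kinetic model for (P)CASL with apparent tissue
#' relaxation \eqn{1/T_1' = 1/T_{1t} + f/\lambda}:
#' \deqn{\Delta M_B(t) = 0, \quad t < \Delta_t}
#' \deqn{\Delta M_B(t) = 2 M_{0b} f \alpha_{inv} T_1' e^{-\Delta_t/T_{1b}}
#'   (1 - e^{-(t-\Delta_t)/T_1'}), \quad \Delta_t \le t < \tau + \Delta_t}
#' \deqn{\Delta M_B(t) = 2 M_{0b} f \alpha_{inv} T_1' e^{-\Delta_t/T_{1b}}
#'   (1 - e^{-\tau/T_1'}) e^{-(t-\tau-\Delta_t)/T_1'}, \quad t \ge \tau+\Delta_t.}
#'
#' @param t Time since labeling onset (s), vectorized.
#' @param params [kinetic_params()].
#' @param tau Labeling duration (s).
#' @return \eqn{\Delta M_B(t)}, same length as `t`.
#' @export
buxton_casl_delta_m <- function(t, params, tau) {
  stopifnot(all(t >= 0))
  T1p <- 1 / (1 / params$T1t + params$f / params$lam)
  pre <- 2 * params$M0b * params$f * params$alpha_inv * T1p *
    exp(-params$Delta_t / params$T1b)
  dt <- params$Delta_t
  ifelse(t < dt, 0,
         ifelse(t < tau + dt,
                pre * (1 - exp(-(t - dt) / T1p)),
                pre * (1 - exp(-tau / T1p)) * exp(-(t - tau - dt) / T1p)))
}

#' Perfusion ASL difference signal per pulse
#'
#' The tissue signal available at pulse `i` is the Buxton magnetization
#' attenuated by the preceding excitations and tipped by the current pulse:
#' \eqn{S_{perf,i} = \Delta M_B(t_i)\, R_i \sin\alpha_i}.
#'
#' @inheritParams angio_signal
#' @return Numeric vector of per-pulse signals.
#' @export
perfusion_signal <- function(params, schedule, times, tau) {
  alpha <- schedule_degrees(schedule)
  stopifnot(length(alpha) == length(times), !is.unsorted(times))
  R <- rf_attenuation(alpha)
  buxton_casl_delta_m(times, params, tau) * R * sin(alpha * pi / 180)
}

#' Simulated signal timecourses as a tidy table
#'
#' Convenience wrapper evaluating both signal models for one schedule, suitable
#' for plotting or delimited export.
#'
#' @inheritParams angio_signal
#' @return Tibble with columns `i`, `t`, `alpha`, `R`, `angio`, `perfusion`.
#' @export
signal_timecourse <- function(params, schedule, times, tau) {
  alpha <- schedule_degrees(schedule)
  out <- tibble(
    i = seq_along(times), t = times, alpha = alpha,
    R = rf_attenuation(alpha),
    angio = angio_signal(params, schedule, times, tau),
    perfusion = perfusion_signal(params, schedule, times, tau)
  )
  class(out) <- c("capria_timecourse", class(out))
  out
}
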