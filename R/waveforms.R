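#' Cardiac state of one patient at one study time point
#'
#' Bundles the hemodynamic parameters that define one patient-state (before
#' or after aortic valve replacement): heart rate, stroke volume, systolic
#' ejection time, aortic valve area, aortic pressure targets, and the
#' ventricular parameters that drive the intramyocardial pressure waveforms.
#'
#' `lv_peak` defaults to the aortic systolic pressure plus the Gorlin
#' estimate of the mean transvalvular gradient (see
#' [transvalvular_gradient()]); in aortic stenosis the left ventricle must
#' generate the aortic pressure plus the valve gradient.
#'
#' @param heart_rate beats/min.
#' @param stroke_volume mL.
#' @param ejection_time systolic ejection time, ms.
#' @param aortic_valve_area cm^2.
#' @param p_sys,p_dia,p_mean aortic pressure targets, mmHg. `p_mean` defaults
#'   to `p_dia + (p_sys - p_dia)/3`.
#' @param lv_peak peak left-ventricular pressure, mmHg. Default
#'   `p_sys + transvalvular_gradient(...)`.
#' @param lv_edp left-ventricular end-diastolic pressure, mmHg.
#' @param tr_velocity tricuspid regurgitation jet velocity, m/s (Doppler),
#'   used to scale the right-ventricular pressure waveform.
#' @return An object of class `cardiac_state`.
#' @examples
#' pre <- cardiac_state(stroke_volume = 79.1, ejection_time = 336,
#'                      aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5)
#' pre$lv_peak  # aortic systolic + Gorlin gradient
#' @export
cardiac_state <- function(heart_rate = 70,
                          stroke_volume,
                          ejection_time,
                          aortic_valve_area,
                          p_sys, p_dia,
                          p_mean = NULL,
                          lv_peak = NULL,
                          lv_edp = 10,
                          tr_velocity = 2.5) {
  if (is.null(p_mean)) p_mean <- p_dia + (p_sys - p_dia) / 3
  period_ms <- 60000 / heart_rate
  if (!is.finite(ejection_time) || ejection_time <= 0 || ejection_time >= period_ms)
    stop("invalid cardiac state: ejection_time must lie in (0, cycle period) [",
         round(period_ms, 1), " ms]")
  if (!(p_dia < p_mean && p_mean < p_sys))
    stop("invalid cardiac state: require p_dia < p_mean < p_sys")
  if (min(p_sys, p_dia, p_mean) <= 0) stop("invalid cardiac state: pressures must be > 0")
  if (stroke_volume < 0) stop("invalid cardiac state: stroke_volume must be >= 0")
  if (aortic_valve_area <= 0) stop("invalid cardiac state: aortic_valve_area must be > 0")
  if (tr_velocity < 0) stop("invalid cardiac state: tr_velocity must be >= 0")
  if (is.null(lv_peak))
    lv_peak <- p_sys + transvalvular_gradient(stroke_volume, ejection_time,
                                              aortic_valve_area)
  if (lv_peak <= lv_edp) stop("invalid cardiac state: lv_peak must exceed lv_edp")
  structure(list(
    heart_rate = heart_rate, stroke_volume = stroke_volume,
    ejection_time = ejection_time, aortic_valve_area = aortic_valve_area,
    p_sys = p_sys, p_dia = p_dia, p_mean = p_mean,
    lv_peak = lv_peak, lv_edp = lv_edp, tr_velocity = tr_velocity,
    period = period_ms / 1000
  ), class = "cardiac_state")
}

#' Gorlin estimate of the mean transvalvular pressure gradient
#'
#' The Gorlin relation for the aortic valve,
#' `AVA = Q_sys / (44.3 * sqrt(dP))`, inverted for the mean systolic
#' gradient: `dP = (SV/ET / (44.3 * AVA))^2` mmHg, with the mean systolic
#' flow `SV/ET` in mL/s.
#'
#' @param stroke_volume mL.
#' @param ejection_time ms.
#' @param ava aortic valve area, cm^2.
#' @return Mean gradient in mmHg.
#' @export
transvalvular_gradient <- function(stroke_volume, ejection_time, ava) {
  q_sys <- stroke_volume / (ejection_time / 1000)
  (q_sys / (44.3 * ava))^2
}

#' Construct a one-cycle waveform
#'
#' A waveform is one cardiac cycle of a periodic signal sampled on a uniform
#' grid: `times[1] = 0`, `times[length(times)] = period`, and
#' `values[1] == values[length(values)]` so the periodic extension is
#' continuous.
#'
#' @param times seconds, strictly increasing, spanning exactly one cycle.
#' @param values flow (cm^3/s) or pressure (mmHg).
#' @param kind `"flow"` or `"pressure"`.
#' @return Object of class `coro_waveform`.
#' @export
waveform <- function(times, values, kind = c("flow", "pressure")) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(values), length(times) >= 2)
  if (any(!is.finite(values))) stop("waveform values must be finite")
  if (times[1] != 0) stop("waveform must start at t = 0")
  if (any(diff(times) <= 0)) stop("waveform times must be strictly increasing")
  structure(list(times = times, values = values, kind = kind,
                 period = times[length(times)]),
            class = "coro_waveform")
}

# Fast periodic linear interpolator over one cycle.
wf_fun <- function(wf) {
  f <- stats::approxfun(wf$times, wf$values, rule = 2)
  T <- wf$period
  function(t) f(t %% T)
}

# Cycle-mean via trapezoid on the waveform's own grid.
wf_mean <- function(wf) {
  trapz(wf$times, wf$values) / wf$period
}

# Trapezoidal quadrature.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Inflow waveform shape parameters
#'
#' The aortic inflow is a skewed half-sine systolic pulse,
#' `q(t) = Qp * sin(pi * (t/ET)^gamma)` for `t` in `[0, ET]` and zero in
#' diastole, with `gamma = 1 + skew_per_ava / AVA`. A stenotic valve
#' (small AVA) gives `gamma > 1` and a late-peaking ejection profile, the
#' characteristic slow-rising pulse of aortic stenosis; `skew_per_ava = 0`
#' recovers the plain half-sine. The amplitude is normalised so the pulse
#' integrates exactly to the stroke volume on the sampling grid.
#'
#' @param skew_per_ava skew coefficient (cm^2); `gamma = 1 + skew_per_ava/AVA`.
#' @param dt sampling interval, s.
#' @return List of shape parameters.
#' @export
inflow_shape <- function(skew_per_ava = 0.25, dt = 0.001) {
  stopifnot(skew_per_ava >= 0, dt > 0)
  list(family = "skewed_half_sine", skew_per_ava = skew_per_ava, dt = dt)
}

#' Prescribed aortic inflow waveform
#'
#' Builds the inlet flow waveform for one cardiac state: a (skewed)
#' half-sine pulse over the systolic ejection time, zero during diastole
#' (closed valve), integrating exactly to the stroke volume.
#'
#' @param state a [cardiac_state()].
#' @param shape shape parameters from [inflow_shape()].
#' @return A flow [waveform()] over one cycle.
#' @examples
#' st <- cardiac_state(stroke_volume = 79.1, ejection_time = 336,
#'                     aortic_valve_area = 0.6, p_sys = 141, p_dia = 78.5)
#' q <- make_inflow(st, inflow_shape(skew_per_ava = 0))
#' max(q$values)          # ~ pi * SV / (2 * ET) for the plain half-sine
#' @export
make_inflow <- function(state, shape = inflow_shape()) {
  stopifnot(inherits(state, "cardiac_state"))
  T <- state$period
  et <- state$ejection_time / 1000
  dt <- shape$dt
  times <- seq(0, T, by = dt)
  if (abs(times[length(times)] - T) > 1e-12) times <- c(times, T)
  if (state$stroke_volume == 0)
    return(waveform(times, numeric(length(times)), "flow"))
  gamma <- 1 + shape$skew_per_ava / state$aortic_valve_area
  s <- pmin(times / et, 1)
  v <- ifelse(times < et, sin(pi * s^gamma), 0)
  v[v < 0] <- 0
  # normalise so the trapezoidal integral over the cycle equals SV exactly
  v <- v * state$stroke_volume / trapz(times, v)
  waveform(times, v, "flow")
}

# Shared ventricular pressure template: half-cosine rise over t_rise
# starting t_ivc before ejection onset (isovolumic contraction leads the
# inflow, which starts at t = 0), a plateau at the peak through most of
# ejection, and a half-cosine decay back to the diastolic baseline. The
# phase shift wraps periodically, so value(0) = value(T) by construction.
ventricular_bump <- function(T, et, peak, base, dt = 0.001,
                             t_ivc = 0.06, t_rise = 0.15, t_decay = 0.12) {
  times <- seq(0, T, by = dt)
  if (abs(times[length(times)] - T) > 1e-12) times <- c(times, T)
  u <- (times + t_ivc) %% T
  u_sus <- max(t_rise, t_ivc + 0.9 * et)
  u_end <- min(u_sus + t_decay, 0.95 * T)
  env <- numeric(length(u))
  i1 <- u < t_rise
  env[i1] <- 0.5 * (1 - cos(pi * u[i1] / t_rise))
  i2 <- u >= t_rise & u <= u_sus
  env[i2] <- 1
  i3 <- u > u_sus & u < u_end
  env[i3] <- 0.5 * (1 + cos(pi * (u[i3] - u_sus) / (u_end - u_sus)))
  waveform(times, base + (peak - base) * env, "pressure")
}

#' Left-ventricular (intramyocardial) pressure waveform
#'
#' Analytic template standing in for an invasive LV trace: a rapid
#' half-cosine upstroke from `lv_edp` to `lv_peak` whose onset leads
#' ejection by the isovolumic contraction time (60 ms), a plateau through
#' most of ejection, and a smooth relaxation back to `lv_edp`. The default
#' upstroke (150 ms) gives a peak dP/dt of roughly
#' `(lv_peak - lv_edp) * pi / 0.3` mmHg/s, i.e. ~2000 mmHg/s for a
#' pressure-overloaded ventricle. Used as the intramyocardial pressure
#' `Pim` for left-tree coronary outlets; its early systolic upstroke is
#' what compresses the intramyocardial compliance and produces the
#' systolic impediment (and, in severe aortic stenosis, transient
#' reversal) of left coronary inflow.
#'
#' @param state a [cardiac_state()]; must satisfy `lv_peak > lv_edp >= 0`.
#' @param dt sampling interval, s.
#' @return A pressure [waveform()] (mmHg) over one cycle.
#' @export
make_lv_pressure <- function(state, dt = 0.001) {
  stopifnot(inherits(state, "cardiac_state"))
  if (state$lv_peak <= state$lv_edp)
    stop("invalid cardiac state: lv_peak must exceed lv_edp")
  ventricular_bump(state$period, state$ejection_time / 1000,
                   state$lv_peak, state$lv_edp, dt)
}

#' Right-ventricular pressure waveform
#'
#' Template RV pressure rescaled so that its peak equals the simplified
#' Bernoulli estimate of RV systolic pressure from the tricuspid
#' regurgitation jet, `4 * v_TR^2 + RAP` (the standard Doppler relation).
#' Used as `Pim` for right-tree coronary outlets.
#'
#' @param state a [cardiac_state()] with `tr_velocity` in m/s.
#' @param rap right atrial pressure, mmHg (default 5).
#' @param rv_edp right-ventricular diastolic baseline, mmHg.
#' @param dt sampling interval, s.
#' @return A pressure [waveform()] (mmHg) over one cycle.
#' @export
make_rv_pressure <- function(state, rap = 5, rv_edp = 2, dt = 0.001) {
  stopifnot(inherits(state, "cardiac_state"), state$tr_velocity >= 0)
  peak <- 4 * state$tr_velocity^2 + rap
  base <- min(rv_edp, peak)
  if (peak <= base) {  # degenerate: flat at the (tiny) peak pressure
    times <- seq(0, state$period, by = dt)
    return(waveform(times, rep(peak, length(times)), "pressure"))
  }
  ventricular_bump(state$period, state$ejection_time / 1000, peak, base, dt,
                   t_ivc = 0.05)
}

#' Write / read a waveform as two-column CSV
#'
#' Plain-text interchange format: header `time_s,value`, one row per sample.
#' The reader/writer round-trip is exact on the decimal text.
#'
#' @param wf a [waveform()].
#' @param path file path.
#' @param kind waveform kind for the reader.
#' @return `read_waveform_csv` returns a [waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  df <- data.frame(time_s = wf$times, value = wf$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, kind = c("flow", "pressure")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("waveform CSV must have columns time_s,value")
  waveform(df$time_s, df$value, kind)
}
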