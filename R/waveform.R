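## Pulsatile inflow waveform. The shape is a tabulated input: either user
## samples (time, velocity) or a synthetic hepatic-artery-like pulse with a
## prescribed period and minimum/mean/maximum velocity, calibrated so the
## trapezoidal time average matches the target mean exactly.

#' Construct an inflow waveform from samples
#'
#' @param time sample times, seconds, from 0 to the period (inclusive).
#' @param velocity inlet velocities, m/s; first and last sample must agree
#'   (periodicity).
#' @param scale_factor multiplicative factor already applied (bookkeeping).
#' @return object of class `inflow_waveform` with `period`, `time`,
#'   `velocity`, `v_min`/`v_mean`/`v_max` (trapezoidal mean) and
#'   `scale_factor`.
#' @export
inflow_waveform <- function(time, velocity, scale_factor = 1) {
  stopifnot(length(time) == length(velocity), length(time) >= 3L,
            !is.unsorted(time), time[1] == 0)
  if (abs(velocity[1] - velocity[length(velocity)]) >
      1e-9 * max(abs(velocity)))
    stop("waveform is not periodic: first and last sample differ")
  period <- time[length(time)]
  structure(list(period = period, time = time, velocity = velocity,
                 v_min = min(velocity), v_mean = .trapz_mean(time, velocity),
                 v_max = max(velocity), scale_factor = scale_factor),
            class = "inflow_waveform")
}

.trapz_mean <- function(t, v) {
  sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2) / (t[length(t)] - t[1])
}

#' Synthesize a hepatic-artery inflow waveform
#'
#' Half-sine systolic pulse over a diastolic baseline. The systolic duration
#' is solved numerically so that the trapezoidal mean of the sampled
#' waveform equals `v_mean`; the minimum and maximum are exact by
#' construction. Defaults reproduce a hepatic-artery pulse with period 0.8 s
#' and min/mean/max velocity 0.041/0.121/0.260 m/s.
#'
#' @param period cardiac period, s.
#' @param v_min,v_mean,v_max minimum, time-averaged and peak inlet
#'   velocities, m/s.
#' @param dt sample spacing, s.
#' @return an `inflow_waveform`.
#' @export
make_waveform <- function(period = 0.8, v_min = 0.041, v_mean = 0.121,
                          v_max = 0.260, dt = 0.002) {
  stopifnot(v_min < v_mean, v_mean < v_max, period > 0, dt > 0)
  base_tt <- seq(0, period, by = dt)
  if (base_tt[length(base_tt)] < period) base_tt <- c(base_tt, period)
  build <- function(Ts) {
    tt <- sort(unique(c(base_tt, Ts / 2)))  # include the exact systolic peak
    v <- v_min + (v_max - v_min) * ifelse(tt < Ts, sin(pi * tt / Ts), 0)
    v[length(v)] <- v[1]
    list(t = tt, v = v)
  }
  f <- function(Ts) { b <- build(Ts); .trapz_mean(b$t, b$v) - v_mean }
  Ts <- stats::uniroot(f, c(4 * dt, period - 2 * dt), tol = 1e-12)$root
  b <- build(Ts)
  inflow_waveform(b$t, b$v)
}

#' Scale a waveform to deliver a target total inflow
#'
#' Multiplies the velocities by a single scalar so that the time-averaged
#' volumetric inflow (velocity times inlet area) equals the total inflow
#' fixed by the outlet boundary conditions.
#'
#' @param w an `inflow_waveform`.
#' @param bc a `flow_bc` (its `total_inflow`, ml/min, is the target).
#' @param inlet_area inlet cross-sectional area, m^2.
#' @return the scaled `inflow_waveform` (with `scale_factor` updated).
#' @export
scale_waveform <- function(w, bc, inlet_area) {
  if (inlet_area <= 0) stop("inlet area must be > 0")
  if (w$v_mean <= 0) stop("waveform mean velocity must be > 0")
  target_m3s <- bc$total_inflow * 1e-6 / 60
  s <- target_m3s / (w$v_mean * inlet_area)
  inflow_waveform(w$time, w$velocity * s, scale_factor = w$scale_factor * s)
}

## normalized flow shape: function of absolute time t (any cycle) returning
## Q(t)/Q_mean; linear interpolation between samples
waveform_shape_fun <- function(w) {
  f <- stats::approxfun(w$time, w$velocity / w$v_mean, rule = 2)
  period <- w$period
  function(t) f(t %% period)
}

#' Write waveform samples as CSV
#' @param w an `inflow_waveform`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  write.csv(data.frame(time_s = w$time, velocity_m_s = w$velocity), path,
            row.names = FALSE)
  invisible(path)
}
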