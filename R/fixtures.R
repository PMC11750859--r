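# synthetic_fixtures: ground-truth-known voltage traces and analytic passive
# references, so the analysis and solver contracts are testable without
# simulating the full model. All randomness in the package lives here and is
# seeded; the simulator itself is deterministic.

#' Specify a synthetic spike-train trace
#'
#' @param baseline baseline potential, mV.
#' @param spike_times template peak times, ms (all within `[0, duration)`).
#' @param template `"gaussian"` (width = sd of the Gaussian bump, ms),
#'   `"triangular"` (width = total base width, ms) or `"biexponential"`
#'   (width = decay time constant, ms; rise constant is `width/5`). All
#'   templates peak exactly at the given spike times.
#' @param amplitude template peak amplitude above baseline, mV.
#' @param width template width parameter, ms (see `template`).
#' @param dt sampling step, ms.
#' @param duration trace duration, ms.
#' @param noise_sd sd of added Gaussian noise, mV (0 for none).
#' @param seed RNG seed; a fixed seed regenerates the trace bit-identically.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(baseline = -80, spike_times = numeric(0),
                         template = c("gaussian", "triangular",
                                      "biexponential"),
                         amplitude = 100, width = 0.5, dt = 0.1,
                         duration = 1000, noise_sd = 0, seed = 1) {
  template <- match.arg(template)
  stopifnot(dt > 0, duration > 0, amplitude > 0, width > 0, noise_sd >= 0)
  if (length(spike_times) > 0 &&
      (any(spike_times < 0) || any(spike_times >= duration)))
    stop("spike times must lie within [0, duration)")
  structure(list(baseline = baseline, spike_times = sort(spike_times),
                 template = template, amplitude = amplitude, width = width,
                 dt = dt, duration = duration, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# analytic template evaluated at times t (peak 1 at t = 0), plus its exact
# full width at half maximum
template_fun <- function(template, width) {
  switch(template,
    gaussian = list(
      f = function(t) exp(-t^2 / (2 * width^2)),
      fwhm = 2 * sqrt(2 * log(2)) * width),
    triangular = list(
      f = function(t) pmax(0, 1 - abs(t) / (width / 2)),
      fwhm = width / 2),
    biexponential = {
      tr <- width / 5; td <- width
      s_pk <- tr * td / (td - tr) * log(td / tr)
      pk <- exp(-s_pk / td) - exp(-s_pk / tr)
      f0 <- function(s) (exp(-s / td) - exp(-s / tr)) / pk
      g <- function(s) f0(s) - 0.5
      s_lo <- uniroot(g, c(0, s_pk), tol = 1e-12)$root
      s_hi <- uniroot(g, c(s_pk, 50 * td), tol = 1e-12)$root
      list(f = function(t) ifelse(t + s_pk >= 0, f0(t + s_pk), 0),
           fwhm = s_hi - s_lo)
    })
}

#' Generate a synthetic spike-train trace with exact ground truth
#'
#' The trace is `baseline` plus one analytic template per spike time plus
#' optional seeded Gaussian noise. The truth table carries the exact peak
#' time, peak value and width at half amplitude of each template
#' (closed-form, never measured from the sampled trace). Spikes closer to a
#' neighbor than twice the template half-width are flagged as overlapping.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `mf_fixture` with `time` (ms), `v` (mV), `truth`
#'   (data frame: `t_peak`, `v_peak`, `half_width`, `overlap`) and `spec`.
#' @export
make_spike_train_trace <- function(spec) {
  tp <- template_fun(spec$template, spec$width)
  time <- seq(0, spec$duration - spec$dt / 2, by = spec$dt)
  v <- rep(spec$baseline, length(time))
  for (t0 in spec$spike_times)
    v <- v + spec$amplitude * tp$f(time - t0)
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(spec$seed)
    v <- v + rnorm(length(v), sd = spec$noise_sd)
  }
  st <- spec$spike_times
  overlap <- rep(FALSE, length(st))
  if (length(st) > 1) {
    gap <- diff(st)
    tooclose <- gap < 2 * tp$fwhm
    overlap[-1] <- overlap[-1] | tooclose
    overlap[-length(st)] <- overlap[-length(st)] | tooclose
  }
  truth <- data.frame(t_peak = st,
                      v_peak = rep(spec$baseline + spec$amplitude,
                                   length(st)),
                      half_width = rep(tp$fwhm, length(st)),
                      overlap = overlap)
  structure(list(time = time, v = v, truth = truth, spec = spec),
            class = "mf_fixture")
}

#' Convert a fixture to a trace set
#' @param fix an `mf_fixture`.
#' @param site site label for the single trace column.
#' @return a `trace_set`.
#' @export
fixture_trace_set <- function(fix, site = "fixture") {
  trace_set(time = fix$time, v = matrix(fix$v, ncol = 1), dt = fix$spec$dt,
            sites = site, stim_end = NA)
}

#' Analytic passive references
#'
#' Closed-form oracles for the passive behavior of the solver:
#' * membrane time constant `tau_m = r_m * c_m` (ms),
#' * steady-state space constant `lambda = sqrt(r_m * d / (4 r_i))` (um),
#' * the isopotential RC step response
#'   `V(t) = v0 + I R (1 - exp(-t/tau_m))` with `R = r_m / area` (on the
#'   grid `t`, when `area_cm2` and `i_nA` are given),
#' * the sealed-end finite-cable attenuation profile
#'   `cosh((L - x)/lambda) / cosh((L - x0)/lambda)` normalized at the held
#'   position `x0` (on the grid `x`, when given).
#'
#' @param r_m specific membrane resistance, Ohm cm^2.
#' @param c_m specific membrane capacitance, uF/cm^2.
#' @param r_i intracellular resistivity, Ohm cm.
#' @param diameter cable diameter, um.
#' @param length cable length `L`, um.
#' @param t time grid for the RC response, ms.
#' @param area_cm2 membrane area of the isopotential compartment, cm^2.
#' @param i_nA step current, nA.
#' @param v0 initial/resting potential, mV.
#' @param x positions along the cable, um.
#' @param x0 held (clamped) position, um.
#' @return list with `tau_m` (ms), `lambda` (um), and data frames `rc`
#'   (`t`, `v`) and `attenuation` (`x`, `atten`) when their grids are given.
#' @export
make_passive_references <- function(r_m = 10000, c_m = 1, r_i = 110,
                                    diameter = 0.2, length = 1100,
                                    t = NULL, area_cm2 = NULL, i_nA = NULL,
                                    v0 = -80, x = NULL, x0 = 0) {
  tau_m <- r_m * c_m * 1e-3                      # Ohm cm^2 * uF/cm^2 -> ms
  lambda <- sqrt(r_m * diameter * 1e-4 / (4 * r_i)) * 1e4  # um
  out <- list(tau_m = tau_m, lambda = lambda)
  if (!is.null(t) && !is.null(area_cm2) && !is.null(i_nA)) {
    R <- r_m / area_cm2                          # Ohm
    dv <- i_nA * R * 1e-6                        # nA * Ohm -> mV
    out$rc <- data.frame(t = t, v = v0 + dv * (1 - exp(-t / tau_m)))
  }
  if (!is.null(x)) {
    atten <- cosh((length - x) / lambda) / cosh((length - x0) / lambda)
    out$attenuation <- data.frame(x = x, atten = atten)
  }
  out
}
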