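# cable_solver: implicit integration of the compartmental cable equation.
# The heavy loop lives in src/cable.cpp; this file assembles the per-segment
# quantities (capacitance nF, conductances uS, axial coupling uS) and wraps
# setup / init / step / run / steady-state.

#' Axial coupling conductances of the chain
#'
#' Between adjacent segments i and j the coupling is
#' `1 / (rho_i/2 + rho_j/2)` where `rho = r_i * seg_length /
#' cross_section_area` is the axial resistance of a whole segment.
#'
#' @param model a `cell_model`.
#' @return numeric vector of length `n_segments - 1`, uS; element i couples
#'   segments i and i+1.
#' @export
assemble_axial_coupling <- function(model) {
  s <- model$segments
  # rho in Ohm: r_i [Ohm cm] * L [um -> cm] / A [um^2 -> cm^2]
  a_cross <- pi * (s$diameter / 2)^2
  rho <- s$r_i * (s$seg_length * 1e-4) / (a_cross * 1e-8)
  n <- nrow(s)
  if (n < 2) return(numeric(0))
  1e6 / (rho[-n] / 2 + rho[-1] / 2)  # Ohm -> uS
}

segment_capacitance <- function(model) {
  # uF/cm^2 * um^2 -> nF: 1e-8 cm^2/um^2 * 1e3 nF/uF
  model$segments$c_m * model$segments$area * 1e-5
}

segment_leak <- function(model) {
  # leak density 1000/r_m mS/cm^2; conductance in uS
  (1000 / model$segments$r_m) * model$segments$area * 1e-5
}

density_to_uS <- function(dens, area) dens * area * 1e-5

gate_to_cpp <- function(g) {
  if (g$mode == "ab") {
    list(exponent = g$exponent, mode = 0L,
         afam = rate_family_code[[g$alpha$family]],
         apar = c(g$alpha$A, g$alpha$V0, g$alpha$B),
         bfam = rate_family_code[[g$beta$family]],
         bpar = c(g$beta$A, g$beta$V0, g$beta$B))
  } else {
    list(exponent = g$exponent, mode = 1L, vmin = g$vmin, dv = g$dv,
         xinf = g$xinf, tau = g$tau)
  }
}

#' Prepare a simulation: resolve channels onto the model
#'
#' Combines a cell model with a kinetics profile and K+-channel variant into
#' the per-segment arrays the integrator consumes. Na+ conductance comes from
#' the model's per-section `dens_na`; the model's `dens_k` is split across
#' the variant's K+ channels in proportion to their declared densities; leak
#' is `1/r_m` with the per-segment leak reversal.
#'
#' @param model a `cell_model`.
#' @param variant `"inactivating"`, `"non_inactivating"`, `"mixture"`, or a
#'   list of `channel_spec` from [make_variant()].
#' @param mixture_fraction inactivating fraction when `variant = "mixture"`.
#' @param profile a [kinetics_profile()].
#' @param passive if `TRUE`, strip all voltage-gated channels (leak only).
#' @return a `cable_sim` setup object.
#' @export
cable_setup <- function(model, variant = "inactivating",
                        mixture_fraction = 0.9,
                        profile = kinetics_profile("default"),
                        passive = FALSE) {
  s <- model$segments
  channels <- list()
  if (!passive) {
    if (is.character(variant))
      variant <- make_variant(variant, fraction = mixture_fraction,
                              profile = profile)
    g_k_total <- sum(vapply(variant, `[[`, numeric(1), "g"))
    na <- profile$na
    channels <- c(
      list(list(spec = na, gseg = density_to_uS(s$dens_na, s$area))),
      lapply(variant, function(ch) {
        frac <- if (g_k_total > 0) ch$g / g_k_total else 0
        list(spec = ch, gseg = density_to_uS(s$dens_k * frac, s$area))
      }))
  }
  cpp_channels <- lapply(channels, function(ch)
    list(g = ch$gseg, e = ch$spec$e,
         gates = lapply(ch$spec$gates, gate_to_cpp)))
  structure(list(model = model, channels = channels,
                 cpp_channels = cpp_channels,
                 cap = segment_capacitance(model),
                 gax = assemble_axial_coupling(model),
                 gleak = segment_leak(model),
                 eleak = s$e_leak),
            class = "cable_sim")
}

#' Initialize the simulation state
#'
#' Voltage set to `v0` (default: the per-segment leak reversal) and every
#' gate to its steady state `x_inf(v0)`. Re-initializing at the same voltage
#' is idempotent.
#'
#' @param sim a [cable_setup()] object.
#' @param v0 initial voltage, mV; scalar or per-segment vector.
#' @return a `sim_state` list with `v`, `gates`, `t`.
#' @export
cable_init <- function(sim, v0 = NULL) {
  n <- sim$model$n_segments
  if (is.null(v0)) v0 <- sim$model$segments$e_leak
  v <- rep_len(v0, n)
  gates <- lapply(sim$channels, function(ch)
    lapply(ch$spec$gates, function(g) eval_gate(g, v)$x_inf))
  structure(list(v = v, gates = gates, t = 0), class = "sim_state")
}

resolve_site <- function(model, site) {
  if (is.character(site)) landmark_center(model, site) else as.integer(site)
}

#' Advance the simulation
#'
#' `run_simulation` advances `n_steps` implicit steps of size `dt`,
#' recording the membrane potential at `record` every step; `cable_step`
#' is the single-step special case. Divergence (non-finite or runaway
#' voltage) aborts with the time and segment in the message.
#'
#' @param sim a [cable_setup()] object.
#' @param state a `sim_state` from [cable_init()] or a previous run.
#' @param dt time step, ms (> 0).
#' @param n_steps number of steps.
#' @param inj injected current, nA: scalar or vector of length `n_steps`.
#' @param inj_site landmark name or segment index receiving the injection.
#' @param record landmark names or segment indices to record.
#' @param clamp optional `list(site =, v =)`: hold one segment at a fixed
#'   voltage (Dirichlet row in the solve).
#' @return list with `state` (advanced) and `traces` (matrix
#'   `(n_steps + 1) x length(record)`, first row = state before stepping)
#'   and `time` (ms, relative to the incoming `state$t`).
#' @export
run_simulation <- function(sim, state, dt, n_steps, inj = 0,
                           inj_site = "soma", record = "soma",
                           clamp = NULL) {
  stopifnot(dt > 0, n_steps >= 1)
  inj <- rep_len(inj, n_steps)
  inj_seg <- if (is.null(inj_site)) -1L else resolve_site(sim$model, inj_site)
  rec <- vapply(record, function(r) resolve_site(sim$model, r), integer(1))
  clamp_idx <- -1L; clamp_v <- 0
  if (!is.null(clamp)) {
    clamp_idx <- resolve_site(sim$model, clamp$site)
    clamp_v <- clamp$v
  }
  out <- simulate_cpp(sim$cap, sim$gax, sim$gleak, sim$eleak,
                      sim$cpp_channels, state$v, state$gates, dt, inj,
                      inj_seg - 1L, rec - 1L, clamp_idx - 1L, clamp_v)
  new_state <- structure(list(v = out$v, gates = out$gates,
                              t = state$t + n_steps * dt),
                         class = "sim_state")
  if (length(rec) > 0)
    colnames(out$traces) <- if (is.character(record)) record else
      paste0("seg_", rec)
  list(state = new_state, traces = out$traces,
       time = state$t + seq(0, n_steps) * dt)
}

#' @rdname run_simulation
#' @export
cable_step <- function(sim, state, dt, inj = 0, inj_site = "soma") {
  run_simulation(sim, state, dt, 1L, inj = inj, inj_site = inj_site,
                 record = integer(0))$state
}

#' Run a stimulation protocol
#'
#' Simulates the equilibration window (`t_pre`), the pulse train and the
#' post-stimulus window (`t_post`) in one deterministic pass, recording the
#' membrane potential at the protocol's recording sites at every step.
#'
#' @param protocol a [protocol()] or preset name (see [preset()]).
#' @param model optional `cell_model`; defaults to [build_mossy_fiber()]
#'   with the protocol's depolarization zone and `g_na` override applied.
#' @param profile kinetics profile; defaults to the protocol's `kinetics`
#'   name resolved via [kinetics_profile()].
#' @return a `trace_set`: list with `time` (ms), `v` (matrix, one column per
#'   site), `sites`, `dt`, `stim_end` (ms) and the protocol.
#' @export
run_protocol <- function(protocol, model = NULL, profile = NULL) {
  if (is.character(protocol)) protocol <- preset(protocol)
  p <- protocol
  if (is.null(profile)) profile <- kinetics_profile(p$kinetics)
  if (is.null(model)) {
    model <- build_mossy_fiber()
    if (!is.null(p$g_na)) {
      axb <- model$segments$kind != "soma"
      model$segments$dens_na[axb] <- p$g_na
    }
    if (!is.null(p$zone))
      model <- apply_depolarization_zone(model, p$zone, p$el_target)
  }
  sim <- cable_setup(model, variant = p$variant$kind,
                     mixture_fraction = p$variant$fraction,
                     profile = profile)
  state <- cable_init(sim)
  t_end <- stimulus_end(p) + p$t_post
  n_steps <- ceiling(t_end / p$dt)
  tgrid <- seq(0, by = p$dt, length.out = n_steps)
  inj <- stimulus_current(p, tgrid)
  out <- run_simulation(sim, state, p$dt, n_steps, inj = inj,
                        inj_site = "soma", record = p$record)
  trace_set(time = out$time, v = out$traces, dt = p$dt,
            sites = p$record, protocol = p, stim_end = stimulus_end(p))
}

#' Steady-state voltage profile
#'
#' Integrates the unstimulated model until the largest voltage rate of
#' change falls below `tolerance`, or errors (carrying the residual) if the
#' cap is reached, e.g. when a depolarized zone fires spontaneously.
#'
#' @param sim a [cable_setup()] object (or a `cell_model`, in which case a
#'   setup with the given `...` arguments is built).
#' @param tolerance convergence threshold on `max |dV/dt|`, mV/ms.
#' @param dt integration step, ms.
#' @param t_max time cap, ms.
#' @param clamp optional `list(site =, v =)` holding one segment fixed.
#' @param ... passed to [cable_setup()] when `sim` is a `cell_model`.
#' @return numeric per-segment voltage profile (mV) with attributes
#'   `t` (ms simulated) and `residual` (mV/ms).
#' @export
steady_state_profile <- function(sim, tolerance = 1e-3, dt = 0.5,
                                 t_max = 20000, clamp = NULL, ...) {
  if (inherits(sim, "cell_model")) sim <- cable_setup(sim, ...)
  state <- cable_init(sim)
  chunk <- 100L
  repeat {
    out <- run_simulation(sim, state, dt, chunk, inj = 0,
                          inj_site = NULL, record = integer(0),
                          clamp = clamp)
    state <- out$state
    # residual from the last accepted step
    one <- run_simulation(sim, state, dt, 1L, inj = 0, inj_site = NULL,
                          record = integer(0), clamp = clamp)
    residual <- max(abs(one$state$v - state$v)) / dt
    if (residual < tolerance) {
      return(structure(state$v, t = state$t, residual = residual))
    }
    if (state$t >= t_max)
      stop("steady state not reached within ", t_max, " ms (residual ",
           format(residual, digits = 4), " mV/ms)")
  }
}

#' Construct a trace set
#'
#' @param time time grid, ms (uniform).
#' @param v matrix of membrane potentials, one column per site, mV.
#' @param dt sampling step, ms.
#' @param sites site labels.
#' @param protocol optional protocol provenance.
#' @param stim_end end of the stimulus train, ms (or `NA`).
#' @return list of class `trace_set`.
#' @export
trace_set <- function(time, v, dt, sites, protocol = NULL, stim_end = NA) {
  v <- as.matrix(v)
  stopifnot(length(time) == nrow(v), length(sites) == ncol(v))
  colnames(v) <- sites
  structure(list(time = time, v = v, dt = dt, sites = sites,
                 protocol = protocol, stim_end = stim_end),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", length(x$time), " samples at dt = ", x$dt,
      " ms; sites: ", paste(x$sites, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  data.frame(time_ms = x$time, x$v, check.names = FALSE)
}
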