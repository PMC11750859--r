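# channel_kinetics: declarative Hodgkin-Huxley style channel definitions.
# Kinetics are data, not code: gates are parameterized by closed-form rate
# families (exponential / sigmoid / linoid alpha-beta pairs) or by tabulated
# steady-state / time-constant curves, so published rate constants (e.g. the
# mossy-fiber-bouton set in ModelDB deposit 128079, files hhmfb.mod and
# KIn.mod) can be transcribed into configuration without code changes.

#' Closed-form voltage-rate parameterization
#'
#' Families (`V` in mV, rates in 1/ms):
#' * `exponential`: `A * exp((V - V0)/B)`
#' * `sigmoid`: `A / (1 + exp((V - V0)/B))`
#' * `linoid`: `A * (V - V0) / (1 - exp(-(V - V0)/B))`, with the removable
#'   singularity `A * B` at `V = V0`.
#'
#' @param family family name.
#' @param A,V0,B coefficients (B may be negative to flip the voltage axis).
#' @return list of class `rate_fun`.
#' @export
rate_fun <- function(family = c("exponential", "sigmoid", "linoid"),
                     A, V0, B) {
  family <- match.arg(family)
  stopifnot(is.finite(A), is.finite(V0), is.finite(B), B != 0)
  structure(list(family = family, A = A, V0 = V0, B = B),
            class = "rate_fun")
}

rate_family_code <- c(exponential = 1L, sigmoid = 2L, linoid = 3L)

#' Evaluate a rate parameterization at voltages `v` (mV)
#' @param rate a [rate_fun()].
#' @param v numeric voltages, mV.
#' @return numeric rates, 1/ms.
#' @export
eval_rate <- function(rate, v) {
  A <- rate$A; V0 <- rate$V0; B <- rate$B
  switch(rate$family,
    exponential = A * exp((v - V0) / B),
    sigmoid = A / (1 + exp((v - V0) / B)),
    linoid = {
      u <- (v - V0) / B
      out <- ifelse(abs(u) < 1e-7, A * B * (1 + u / 2),
                    A * (v - V0) / (1 - exp(-u)))
      out
    })
}

#' Declare a gating variable
#'
#' A gate is defined either by forward/backward rates `alpha(V)`, `beta(V)`
#' (then `x_inf = alpha/(alpha+beta)`, `tau = 1/(alpha+beta)`) or by
#' tabulated `x_inf(V)` and `tau(V)` on a uniform voltage grid with linear
#' interpolation (clamped at the grid ends).
#'
#' @param name gate label (e.g. `"m"`, `"h"`, `"n"`).
#' @param exponent positive integer power of the gate in the open fraction.
#' @param alpha,beta [rate_fun()] objects (closed-form definition).
#' @param table list with numeric `v` (uniform grid, mV), `xinf` in `[0,1]`
#'   and `tau > 0` in ms (tabulated definition).
#' @return list of class `gate_spec`.
#' @export
gate_spec <- function(name, exponent = 1L, alpha = NULL, beta = NULL,
                      table = NULL) {
  exponent <- as.integer(exponent)
  stopifnot(exponent >= 1)
  if (is.null(table)) {
    if (!inherits(alpha, "rate_fun") || !inherits(beta, "rate_fun"))
      stop("gate '", name, "': supply alpha and beta rate_fun, or a table")
    g <- list(name = name, exponent = exponent, mode = "ab",
              alpha = alpha, beta = beta)
  } else {
    v <- table$v
    dv <- diff(v)
    if (length(v) < 2 || any(abs(dv - dv[1]) > 1e-9 * abs(dv[1])))
      stop("gate '", name, "': tabulated grid must be uniform")
    if (any(table$xinf < 0 | table$xinf > 1)) stop("xinf must lie in [0,1]")
    if (any(table$tau <= 0)) stop("tau must be positive")
    g <- list(name = name, exponent = exponent, mode = "table",
              vmin = v[1], dv = dv[1], xinf = table$xinf, tau = table$tau)
  }
  structure(g, class = "gate_spec")
}

#' Evaluate a gate: steady state and time constant at voltage `v`
#'
#' @param gate a [gate_spec()].
#' @param v numeric voltages, mV (finite).
#' @return list with numeric `x_inf` (unitless, in `[0,1]`) and `tau` (ms).
#' @export
eval_gate <- function(gate, v) {
  stopifnot(all(is.finite(v)))
  if (gate$mode == "ab") {
    a <- eval_rate(gate$alpha, v)
    b <- eval_rate(gate$beta, v)
    list(x_inf = a / (a + b), tau = 1 / (a + b))
  } else {
    n <- length(gate$xinf)
    u <- pmin(pmax((v - gate$vmin) / gate$dv, 0), n - 1)
    i <- pmin(floor(u), n - 2)
    f <- u - i
    list(x_inf = gate$xinf[i + 1] * (1 - f) + gate$xinf[i + 2] * f,
         tau = gate$tau[i + 1] * (1 - f) + gate$tau[i + 2] * f)
  }
}

#' Convert a closed-form gate to a tabulated gate
#'
#' @param gate a [gate_spec()] in alpha/beta form.
#' @param vmin,vmax,dv tabulation grid, mV.
#' @return a tabulated `gate_spec` with the same name and exponent.
#' @export
tabulate_gate <- function(gate, vmin = -120, vmax = 60, dv = 0.05) {
  v <- seq(vmin, vmax, by = dv)
  ev <- eval_gate(gate, v)
  gate_spec(gate$name, gate$exponent,
            table = list(v = v, xinf = ev$x_inf, tau = ev$tau))
}

#' Export / import gate curves as CSV (columns v, xinf, tau)
#' @param gate a [gate_spec()].
#' @param path CSV file path.
#' @param v voltage grid for export, mV.
#' @export
export_gate_table <- function(gate, path, v = seq(-120, 60, by = 0.1)) {
  ev <- eval_gate(gate, v)
  write.csv(data.frame(v = v, xinf = ev$x_inf, tau = ev$tau), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname export_gate_table
#' @param name,exponent gate identity for the imported spec.
#' @export
import_gate_table <- function(path, name, exponent = 1L) {
  d <- read.csv(path)
  gate_spec(name, exponent,
            table = list(v = d$v, xinf = d$xinf, tau = d$tau))
}

#' Declare a channel
#'
#' @param label channel label.
#' @param g maximal conductance density, mS/cm^2 (may be `NA` when the
#'   density is supplied per-section by the cell model).
#' @param e reversal potential, mV.
#' @param gates list of [gate_spec()] (empty for an ohmic leak).
#' @return list of class `channel_spec`.
#' @export
channel_spec <- function(label, g, e, gates = list()) {
  if (!is.na(g) && g < 0) stop("conductance density must be >= 0")
  structure(list(label = label, g = g, e = e, gates = gates),
            class = "channel_spec")
}

#' Ohmic current density of a channel at given gate values
#'
#' @param channel a [channel_spec()] with a numeric `g` (mS/cm^2).
#' @param v membrane potential, mV.
#' @param gate_values numeric vector, one value in `[0,1]` per gate (in gate
#'   order); ignored for gate-less channels.
#' @return current density in uA/cm^2 (`mS/cm^2 * mV = uA/cm^2`), outward
#'   positive.
#' @export
channel_current_density <- function(channel, v, gate_values = numeric(0)) {
  gates <- channel$gates
  if (length(gate_values) != length(gates))
    stop("expected ", length(gates), " gate value(s)")
  if (any(gate_values < 0 | gate_values > 1))
    stop("gate values must lie in [0,1]")
  open <- 1
  for (k in seq_along(gates))
    open <- open * gate_values[[k]]^gates[[k]]$exponent
  channel$g * open * (v - channel$e)
}

#' Initialize all gates at their voltage steady state
#'
#' @param channels list of [channel_spec()].
#' @param v voltage, mV (scalar or per-segment vector).
#' @return named list (by channel label) of named lists (by gate name) of
#'   steady-state gate values `x_inf(v)`.
#' @export
steady_state_gates <- function(channels, v) {
  stopifnot(all(is.finite(v)))
  out <- lapply(channels, function(ch) {
    gv <- lapply(ch$gates, function(g) eval_gate(g, v)$x_inf)
    names(gv) <- vapply(ch$gates, `[[`, character(1), "name")
    gv
  })
  names(out) <- vapply(channels, `[[`, character(1), "label")
  out
}

# ---- built-in kinetics profiles -------------------------------------------

# Squid-type HH gates shifted by -15 mV so the resting point sits near
# -80 mV (classic parameterization rests near -65 mV).
hh_shifted_gates <- function(shift = -15) {
  s <- shift
  list(
    m = gate_spec("m", 3L,
                  alpha = rate_fun("linoid", A = 0.1, V0 = -40 + s, B = 10),
                  beta = rate_fun("exponential", A = 4, V0 = -65 + s, B = -18)),
    h = gate_spec("h", 1L,
                  alpha = rate_fun("exponential", A = 0.07, V0 = -65 + s, B = -20),
                  beta = rate_fun("sigmoid", A = 1, V0 = -35 + s, B = -10)),
    n = gate_spec("n", 4L,
                  alpha = rate_fun("linoid", A = 0.01, V0 = -55 + s, B = 10),
                  beta = rate_fun("exponential", A = 0.125, V0 = -65 + s, B = -80)))
}

# Generic Kv1.4-style slow inactivation gate: nearly complete inactivation
# above -30 mV, high availability at -80 mV, inactivation time constant
# ~15 ms when depolarized and recovery ~1.4 s at rest. Tabulated (the
# sigmoid-of-voltage tau has no alpha/beta closed form in the families).
kv14_h_inf <- function(v) 1 / (1 + exp((v + 50) / 6))
kv14_h_tau <- function(v) 15 + 1485 / (1 + exp((v + 60) / 7))

kv14_h_gate <- function(dv = 0.05) {
  v <- seq(-120, 60, by = dv)
  gate_spec("hk", 1L,
            table = list(v = v, xinf = kv14_h_inf(v), tau = kv14_h_tau(v)))
}

#' Kinetics profiles
#'
#' A profile supplies the Na+ channel and the inactivating / non-inactivating
#' K+ channel definitions used by the solver (conductance densities come from
#' the cell model). The `"default"` profile ships squid-type HH Na+ (m^3 h)
#' and K+ (n^4) gates voltage-shifted so rest sits near -80 mV, plus a
#' generic Kv1.4-style inactivating K+ channel (n^4 h with a slow, tabulated
#' inactivation gate) for engine testing and mechanism studies.
#'
#' The `"paper"` profile is a reserved configuration slot for rate constants
#' transcribed from published mossy-fiber-bouton channel models (ModelDB
#' deposit 128079: `hhmfb.mod` for Na+/K+/leak, `KIn.mod` for the
#' Kv1.4-like inactivating K+ channel). No such transcription ships with the
#' package; requesting `"paper"` without a file errors with instructions.
#' Supply a transcription as a YAML/JSON file via `file` or the option
#' `mossyburst.paper_kinetics` (see [load_kinetics_profile()] for the
#' schema).
#'
#' @param name `"default"` or `"paper"`.
#' @param file optional path to a YAML/JSON kinetics definition.
#' @return list of class `kinetics_profile` with elements `na`,
#'   `k_inactivating`, `k_noninactivating`, `leak`.
#' @export
kinetics_profile <- function(name = c("default", "paper"), file = NULL) {
  name <- match.arg(name)
  if (name == "default") {
    g <- hh_shifted_gates()
    prof <- list(
      name = "default",
      na = channel_spec("na", NA, 50, gates = list(g$m, g$h)),
      k_inactivating = channel_spec("k_in", NA, -85,
                                    gates = list(g$n, kv14_h_gate())),
      k_noninactivating = channel_spec("k_dr", NA, -85, gates = list(g$n)),
      leak = channel_spec("leak", 0.1, -80))
    return(structure(prof, class = "kinetics_profile"))
  }
  if (is.null(file)) file <- getOption("mossyburst.paper_kinetics", NULL)
  if (is.null(file) || !file.exists(file))
    stop("kinetics profile 'paper' is a reserved configuration slot and no ",
         "rate-constant file is installed. Transcribe the published ",
         "mossy-fiber-bouton kinetics (ModelDB deposit 128079, files ",
         "hhmfb.mod and KIn.mod) into the YAML schema of ",
         "load_kinetics_profile() and pass it via kinetics_profile('paper', ",
         "file = ...) or options(mossyburst.paper_kinetics = ...).",
         call. = FALSE)
  load_kinetics_profile(file)
}

#' Load a kinetics profile from a YAML or JSON definition
#'
#' Schema (YAML shown): top level `name:` and `channels:`; under `channels`,
#' keys `na`, `k_inactivating`, `k_noninactivating` each with `e:` (mV) and
#' `gates:` (list). A gate has `name`, `exponent` and either `alpha:`/
#' `beta:` (each `family`, `A`, `V0`, `B`) or `table:` (`v`, `xinf`, `tau`
#' arrays on a uniform grid).
#'
#' @param file path to a `.yaml`/`.yml` or `.json` file.
#' @return a `kinetics_profile`.
#' @export
load_kinetics_profile <- function(file) {
  cfg <- read_config(file)
  parse_gate_cfg <- function(g) {
    if (!is.null(g$table)) {
      gate_spec(g$name, g$exponent,
                table = list(v = unlist(g$table$v),
                             xinf = unlist(g$table$xinf),
                             tau = unlist(g$table$tau)))
    } else {
      mk <- function(r) rate_fun(r$family, r$A, r$V0, r$B)
      gate_spec(g$name, g$exponent, alpha = mk(g$alpha), beta = mk(g$beta))
    }
  }
  parse_ch <- function(label, ch) {
    channel_spec(label, if (is.null(ch[["g"]])) NA else ch[["g"]],
                 ch[["e"]], gates = lapply(ch[["gates"]], parse_gate_cfg))
  }
  need <- c("na", "k_inactivating", "k_noninactivating")
  miss <- setdiff(need, names(cfg$channels))
  if (length(miss) > 0)
    stop("kinetics file must define channels: ", paste(miss, collapse = ", "))
  prof <- list(name = if (is.null(cfg$name)) "custom" else cfg$name)
  for (lab in need) prof[[lab]] <- parse_ch(lab, cfg$channels[[lab]])
  prof$leak <- channel_spec("leak", 0.1, -80)
  structure(prof, class = "kinetics_profile")
}

#' Select the K+ channel variant
#'
#' Splits the total K+ conductance density between the inactivating and the
#' non-inactivating channel of a kinetics profile. A mixture with fraction
#' `f` returns two channels with densities `f * g_k` and `(1 - f) * g_k`;
#' pure kinds return one channel carrying the full density.
#'
#' @param kind `"inactivating"`, `"non_inactivating"` or `"mixture"`.
#' @param fraction fraction of inactivating channels in `[0,1]`
#'   (mixture only; default 0.9).
#' @param g_k total K+ conductance density, mS/cm^2.
#' @param profile a [kinetics_profile()].
#' @return list of `channel_spec` with densities summing to `g_k`.
#' @export
make_variant <- function(kind = c("inactivating", "non_inactivating", "mixture"),
                         fraction = 0.9, g_k = 36,
                         profile = kinetics_profile("default")) {
  kind <- match.arg(kind)
  set_g <- function(ch, g) { ch$g <- g; ch }
  if (kind == "inactivating")
    return(list(set_g(profile$k_inactivating, g_k)))
  if (kind == "non_inactivating")
    return(list(set_g(profile$k_noninactivating, g_k)))
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("mixture fraction must lie in [0,1]")
  chs <- list(set_g(profile$k_inactivating, fraction * g_k),
              set_g(profile$k_noninactivating, (1 - fraction) * g_k))
  chs[vapply(chs, function(ch) ch$g > 0, logical(1))]
}
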