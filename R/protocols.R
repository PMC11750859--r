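# protocols: stimulation trains, depolarization zones and the named preset
# table covering the repetitive-stimulation experiment matrix.

#' Stimulation protocol
#'
#' @param frequency pulse frequency, Hz (> 0).
#' @param count number of pulses (>= 0).
#' @param amplitude pulse amplitude, nA.
#' @param width pulse width, ms; the pulse period `1000/frequency` must be
#'   at least `width`.
#' @param zone depolarization zone: character vector of landmark names, a
#'   zone preset name (see [zone_landmarks()]), or `NULL` for none.
#' @param el_target leak reversal inside the zone, mV.
#' @param variant K+ channel variant: `"inactivating"`,
#'   `"non_inactivating"`, or `"mixture"`.
#' @param mixture_fraction inactivating fraction for the mixture variant.
#' @param g_na optional Na+ density override for axon and boutons, mS/cm^2
#'   (the soma keeps its own density).
#' @param dt integration/sampling step, ms.
#' @param t_pre equilibration before the first pulse, ms.
#' @param t_post observation window after the last pulse, ms.
#' @param record recording sites (landmark names); the trace is taken at
#'   the center segment of each.
#' @param kinetics kinetics profile name for [kinetics_profile()].
#' @return list of class `protocol`.
#' @export
protocol <- function(frequency = 50, count = 50, amplitude = 0.2, width = 2,
                     zone = NULL, el_target = -70,
                     variant = c("inactivating", "non_inactivating", "mixture"),
                     mixture_fraction = 0.9, g_na = NULL,
                     dt = 0.1, t_pre = 200, t_post = 2000,
                     record = c("soma", "bouton_10"),
                     kinetics = "default") {
  variant <- match.arg(variant)
  stopifnot(frequency > 0, count >= 0, width > 0, dt > 0,
            t_pre >= 0, t_post >= 0)
  if (1000 / frequency < width)
    stop("pulse period ", 1000 / frequency,
         " ms is shorter than the pulse width ", width, " ms")
  if (is.character(zone) && length(zone) == 1 &&
      zone %in% c("distal", "middle", "proximal", "uniform"))
    zone <- zone_landmarks(zone)
  structure(list(frequency = frequency, count = as.integer(count),
                 amplitude = amplitude, width = width,
                 zone = zone, el_target = el_target,
                 variant = list(kind = variant, fraction = mixture_fraction),
                 g_na = g_na, dt = dt, t_pre = t_pre, t_post = t_post,
                 record = record, kinetics = kinetics),
            class = "protocol")
}

#' Pulse-train current at time t
#'
#' Rectangular pulses of `amplitude` nA and `width` ms starting at
#' `t_pre + k * 1000/frequency` for `k = 0 .. count - 1`; zero elsewhere.
#'
#' @param protocol a [protocol()].
#' @param t time, ms (vectorized, `t >= 0`).
#' @return injected current, nA.
#' @export
stimulus_current <- function(protocol, t) {
  stopifnot(all(t >= 0))
  p <- protocol
  if (p$count == 0) return(rep(0, length(t)))
  period <- 1000 / p$frequency
  rel <- t - p$t_pre
  k <- floor(rel / period)
  on <- rel >= 0 & k <= (p$count - 1) & (rel - k * period) < p$width
  ifelse(on, p$amplitude, 0)
}

#' End of the stimulus train (offset of the last pulse), ms
#' @param protocol a [protocol()].
#' @export
stimulus_end <- function(protocol) {
  if (protocol$count == 0) return(protocol$t_pre)
  protocol$t_pre + (protocol$count - 1) * 1000 / protocol$frequency +
    protocol$width
}

preset_defs <- list(
  fig1a = list(args = list(frequency = 50, count = 50, zone = NULL,
                           record = "bouton_10"),
               desc = "50 x 50 Hz, uniform rest -80 mV"),
  fig1b = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "50 x 50 Hz, distal zone -70 mV"),
  fig1c = list(args = list(frequency = 50, count = 40, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "40 x 50 Hz, distal zone -70 mV"),
  fig1d = list(args = list(frequency = 20, count = 60, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "60 x 20 Hz, distal zone -70 mV"),
  fig1e = list(args = list(frequency = 20, count = 50, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "50 x 20 Hz, distal zone -70 mV"),
  fig1f = list(args = list(frequency = 100, count = 50, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "50 x 100 Hz, distal zone -70 mV"),
  fig1g = list(args = list(frequency = 100, count = 40, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "40 x 100 Hz, distal zone -70 mV"),
  fig1h = list(args = list(frequency = 100, count = 50, zone = "distal",
                           el_target = -70, g_na = 60, record = "bouton_10"),
               desc = "50 x 100 Hz, distal zone -70 mV, g_Na 60 mS/cm^2"),
  fig2 = list(args = list(frequency = 50, count = 50, zone = "distal",
                          el_target = -70, dt = 0.01,
                          record = c("soma", "bouton_10")),
              desc = "as fig1b at dt = 0.01 ms, soma + 10th bouton"),
  fig3a = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -70,
                           record = c("soma", "bouton_10")),
               desc = "50 x 50 Hz, distal -70 mV, inactivating K+"),
  fig3c = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -70, variant = "non_inactivating",
                           record = c("soma", "bouton_10")),
               desc = "50 x 50 Hz, distal -70 mV, non-inactivating K+"),
  fig3e = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -70, variant = "mixture",
                           mixture_fraction = 0.9,
                           record = c("soma", "bouton_10")),
               desc = "50 x 50 Hz, distal -70 mV, 90/10 K+ mixture"),
  fig3g = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -60, variant = "mixture",
                           mixture_fraction = 0.9,
                           record = c("soma", "bouton_10")),
               desc = "50 x 50 Hz, distal -60 mV, 90/10 K+ mixture"),
  fig3i = list(args = list(frequency = 50, count = 100, zone = "distal",
                           el_target = -60, variant = "non_inactivating",
                           record = c("soma", "bouton_10")),
               desc = "100 x 50 Hz, distal -60 mV, non-inactivating K+"),
  fig4a = list(args = list(frequency = 50, count = 50, zone = "distal",
                           el_target = -70, record = "bouton_10"),
               desc = "50 x 50 Hz, distal zone -70 mV"),
  fig4b = list(args = list(frequency = 50, count = 50, zone = "middle",
                           el_target = -70, record = "bouton_6"),
               desc = "50 x 50 Hz, middle zone -70 mV"),
  fig4c = list(args = list(frequency = 50, count = 50, zone = "middle",
                           el_target = -60, record = "bouton_6"),
               desc = "50 x 50 Hz, middle zone -60 mV"),
  fig4d = list(args = list(frequency = 50, count = 50, zone = "proximal",
                           el_target = -70, record = "bouton_2"),
               desc = "50 x 50 Hz, proximal zone -70 mV"),
  fig4e = list(args = list(frequency = 50, count = 50, zone = "proximal",
                           el_target = -60, record = "bouton_2"),
               desc = "50 x 50 Hz, proximal zone -60 mV"),
  fig4f = list(args = list(frequency = 50, count = 50, zone = "uniform",
                           el_target = -75, record = "bouton_6"),
               desc = "50 x 50 Hz, uniform zone -75 mV"),
  fig5a = list(args = list(frequency = 50, count = 50, zone = "middle",
                           el_target = -70,
                           record = c("soma", "bouton_6", "bouton_10")),
               desc = "50 x 50 Hz, middle -70 mV, three sites"),
  fig5b = list(args = list(frequency = 50, count = 50, zone = "middle",
                           el_target = -60,
                           record = c("soma", "bouton_6", "bouton_10")),
               desc = "50 x 50 Hz, middle -60 mV, three sites"))

#' Named protocol presets
#'
#' `preset(name)` returns the exact configuration of one panel of the
#' repetitive-stimulation experiment matrix (pulse train, depolarization
#' zone, K+ variant, recording sites); `list_presets()` tabulates all of
#' them. Presets are pure data: two calls yield identical configurations.
#'
#' @param name preset name, e.g. `"fig1b"`; an unknown name errors listing
#'   the available presets.
#' @return `preset()`: a [protocol()]; `list_presets()`: a data frame with
#'   columns `name` and `description`.
#' @export
preset <- function(name) {
  if (!name %in% names(preset_defs))
    stop("unknown preset '", name, "'; available: ",
         paste(names(preset_defs), collapse = ", "))
  do.call(protocol, preset_defs[[name]]$args)
}

#' @rdname preset
#' @export
list_presets <- function() {
  data.frame(name = names(preset_defs),
             description = vapply(preset_defs, `[[`, character(1), "desc"),
             row.names = NULL, stringsAsFactors = FALSE)
}
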