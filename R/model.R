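# model_core: the discretized soma -> axon -> bouton chain with passive
# properties, channel density placement and leak-reversal depolarization.

#' Default model configuration
#'
#' Parameter tree for [build_mossy_fiber()]. Defaults describe a granule-cell
#' mossy fiber approximated as a soma (10 um diameter), 11 axonal cylinders
#' (0.2 um diameter, 100 um long) and 10 en passant boutons (4 um diameter)
#' threaded between them, discretized at 1 segment per um. Boutons and the
#' soma are cylinders with length equal to their diameter so that the lateral
#' cylinder area approximates the area of a sphere of the same diameter.
#'
#' @param soma_diameter,soma_length soma cylinder geometry, um.
#' @param axon_diameter,axon_length axonal cylinder geometry, um.
#' @param n_axon number of axonal cylinders; the chain carries
#'   `n_axon - 1` in-line boutons (set `n_axon = 1` for a plain
#'   soma-plus-cable model).
#' @param bouton_diameter,bouton_length bouton cylinder geometry, um.
#' @param seg_per_um spatial discretization, segments per um.
#' @param c_m specific membrane capacitance, uF/cm^2.
#' @param r_m specific membrane resistance, Ohm cm^2 (leak conductance
#'   density is `1000 / r_m` mS/cm^2).
#' @param r_i intracellular resistivity, Ohm cm.
#' @param e_leak leak reversal potential, mV; the resting potential is set
#'   by this value (local depolarization is modeled by shifting it in a
#'   zone, emulating extracellular K+ accumulation).
#' @param na_density_soma,na_density_axon,na_density_bouton Na+ conductance
#'   densities, mS/cm^2.
#' @param k_density K+ conductance density (all compartments), mS/cm^2.
#' @return A list of class `mf_config`.
#' @export
mf_config <- function(soma_diameter = 10, soma_length = 10,
                      axon_diameter = 0.2, axon_length = 100, n_axon = 11,
                      bouton_diameter = 4, bouton_length = 4,
                      seg_per_um = 1,
                      c_m = 1, r_m = 10000, r_i = 110, e_leak = -80,
                      na_density_soma = 10, na_density_axon = 50,
                      na_density_bouton = 50, k_density = 36) {
  cfg <- as.list(environment())
  structure(cfg, class = "mf_config")
}

known_channels <- c("na", "k")

#' Declare one section of the chain
#'
#' @param name section label (e.g. `"axon_3"`).
#' @param kind one of `"soma"`, `"axon"`, `"bouton"`.
#' @param length,diameter cylinder geometry, um.
#' @param n_segments number of segments; default `round(length * seg_per_um)`
#'   (at least 1).
#' @param seg_per_um discretization used for the default segment count.
#' @param c_m,r_m,r_i passive constants (uF/cm^2, Ohm cm^2, Ohm cm).
#' @param channel_densities named numeric vector, channel label -> mS/cm^2;
#'   known labels are `"na"` and `"k"`.
#' @param e_leak leak reversal, mV.
#' @return A list of class `section_spec`.
#' @export
section_spec <- function(name, kind, length, diameter, n_segments = NULL,
                         seg_per_um = 1, c_m = 1, r_m = 10000, r_i = 110,
                         channel_densities = c(na = 0, k = 0),
                         e_leak = -80) {
  kind <- match.arg(kind, c("soma", "axon", "bouton"))
  if (!is.finite(length) || length <= 0 || !is.finite(diameter) || diameter <= 0)
    stop("section '", name, "': length and diameter must be positive")
  if (is.null(n_segments)) n_segments <- max(1L, as.integer(round(length * seg_per_um)))
  if (n_segments < 1) stop("section '", name, "': n_segments must be >= 1")
  if (r_m <= 0 || r_i <= 0 || c_m <= 0)
    stop("section '", name, "': passive constants must be positive")
  bad <- setdiff(names(channel_densities), known_channels)
  if (length(bad) > 0)
    stop("section '", name, "': unknown channel label(s): ",
         paste(bad, collapse = ", "))
  if (any(channel_densities < 0)) stop("channel densities must be >= 0")
  structure(list(name = name, kind = kind, length = length,
                 diameter = diameter, n_segments = as.integer(n_segments),
                 c_m = c_m, r_m = r_m, r_i = r_i,
                 channel_densities = channel_densities, e_leak = e_leak),
            class = "section_spec")
}

#' Build the mossy-fiber chain model
#'
#' Assembles the soma -> axon_1 -> bouton_1 -> axon_2 -> ... -> bouton_(n-1)
#' -> axon_n chain from a configuration tree, discretizes every section, and
#' computes per-segment areas, capacitances and channel densities. Na+
#' density defaults to 10 mS/cm^2 at the soma and 50 mS/cm^2 in axons and
#' boutons; K+ density is 36 mS/cm^2 everywhere; leak conductance is
#' `1/r_m` everywhere.
#'
#' @param config an `mf_config` (or plain list with the same fields).
#' @return A `cell_model`: list with `sections` (list of `section_spec`),
#'   `segments` (data frame, one row per segment: section, kind, per-segment
#'   length/diameter/area in um^2, `c_m`, `e_leak`, `dens_na`, `dens_k`,
#'   `r_i`), `landmarks` (named list of global segment-index ranges) and
#'   `n_segments`.
#' @examples
#' m <- build_mossy_fiber()
#' m$n_segments           # 1150
#' length(m$sections)     # 22
#' @export
build_mossy_fiber <- function(config = mf_config()) {
  cfg <- modifyList(unclass(mf_config()), unclass(config))
  if (cfg$n_axon < 1) stop("n_axon must be >= 1")
  n_bouton <- cfg$n_axon - 1

  mk <- function(name, kind, length, diameter, dens_na) {
    section_spec(name, kind, length, diameter,
                 seg_per_um = cfg$seg_per_um, c_m = cfg$c_m, r_m = cfg$r_m,
                 r_i = cfg$r_i,
                 channel_densities = c(na = dens_na, k = cfg$k_density),
                 e_leak = cfg$e_leak)
  }
  sections <- list(mk("soma", "soma", cfg$soma_length, cfg$soma_diameter,
                      cfg$na_density_soma))
  for (k in seq_len(cfg$n_axon)) {
    sections[[length(sections) + 1L]] <-
      mk(paste0("axon_", k), "axon", cfg$axon_length, cfg$axon_diameter,
         cfg$na_density_axon)
    if (k <= n_bouton)
      sections[[length(sections) + 1L]] <-
        mk(paste0("bouton_", k), "bouton", cfg$bouton_length,
           cfg$bouton_diameter, cfg$na_density_bouton)
  }
  cell_model(sections, config = cfg)
}

#' Assemble a cell model from an ordered list of sections
#'
#' @param sections ordered list of [section_spec()] objects forming the chain.
#' @param config optional configuration snapshot carried for provenance.
#' @return A `cell_model`.
#' @export
cell_model <- function(sections, config = NULL) {
  stopifnot(length(sections) >= 1)
  seg_list <- lapply(sections, function(s) {
    dl <- s$length / s$n_segments
    dens <- function(ch) if (ch %in% names(s$channel_densities))
      unname(s$channel_densities[[ch]]) else 0
    data.frame(section = s$name, kind = s$kind,
               seg_length = dl, diameter = s$diameter,
               area = pi * s$diameter * dl,
               c_m = s$c_m, r_m = s$r_m, r_i = s$r_i,
               e_leak = s$e_leak,
               dens_na = dens("na"), dens_k = dens("k"),
               stringsAsFactors = FALSE)[rep(1, s$n_segments), ]
  })
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL
  counts <- vapply(sections, `[[`, integer(1), "n_segments")
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  landmarks <- Map(function(a, b) a:b, starts, ends)
  names(landmarks) <- vapply(sections, `[[`, character(1), "name")
  structure(list(sections = sections, segments = segments,
                 landmarks = landmarks, n_segments = sum(counts),
                 config = config),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model> ", length(x$sections), " sections, ",
      x$n_segments, " segments\n", sep = "")
  kinds <- table(vapply(x$sections, `[[`, character(1), "kind"))
  cat("  ", paste(names(kinds), kinds, sep = ": ", collapse = ", "), "\n",
      sep = "")
  cat("  total membrane area: ",
      format(total_membrane_area(x), digits = 6), " um^2\n", sep = "")
  invisible(x)
}

#' Total membrane area of the model (um^2)
#' @param model a `cell_model`.
#' @export
total_membrane_area <- function(model) sum(model$segments$area)

#' Resolve landmark names to global segment indices
#'
#' @param model a `cell_model`.
#' @param zone character vector of landmark names (e.g.
#'   `c("bouton_10", "axon_10", "axon_11")`).
#' @return integer vector of global segment indices.
#' @export
resolve_landmarks <- function(model, zone) {
  bad <- setdiff(zone, names(model$landmarks))
  if (length(bad) > 0)
    stop("unknown landmark(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(names(model$landmarks), collapse = ", "))
  sort(unique(unlist(model$landmarks[zone], use.names = FALSE)))
}

#' Center segment of a named landmark (default recording site)
#' @param model a `cell_model`.
#' @param landmark single landmark name.
#' @return global segment index of the center segment.
#' @export
landmark_center <- function(model, landmark) {
  idx <- resolve_landmarks(model, landmark)
  idx[ceiling(length(idx) / 2)]
}

#' Shift the leak reversal of a landmark zone
#'
#' Emulates local depolarization (e.g. by extracellular K+ accumulation)
#' by setting the leak equilibrium potential of every segment in the zone
#' to `el_target`; all other segments are untouched.
#'
#' @param model a `cell_model`.
#' @param zone character vector of landmark names.
#' @param el_target target leak reversal, mV (finite).
#' @return the modified `cell_model`.
#' @export
apply_depolarization_zone <- function(model, zone, el_target) {
  stopifnot(is.finite(el_target))
  idx <- resolve_landmarks(model, zone)
  model$segments$e_leak[idx] <- el_target
  model
}

#' Named depolarization-zone presets
#'
#' The distal, middle and proximal zones are a bouton plus the axonal
#' cylinders on both sides (boutons 10, 6 and 2 respectively); the uniform
#' zone covers boutons 2-10 and the axons flanking them (axons 2-11).
#'
#' @param name one of `"distal"`, `"middle"`, `"proximal"`, `"uniform"`.
#' @return character vector of landmark names.
#' @export
zone_landmarks <- function(name = c("distal", "middle", "proximal", "uniform")) {
  name <- match.arg(name)
  switch(name,
         distal = c("axon_10", "bouton_10", "axon_11"),
         middle = c("axon_6", "bouton_6", "axon_7"),
         proximal = c("axon_2", "bouton_2", "axon_3"),
         uniform = c(paste0("axon_", 2:11), paste0("bouton_", 2:10)))
}
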