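# Shared helpers: small models built in code and a cache so expensive
# full-model simulations run once per test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache))
    assign(key, force(expr), envir = .run_cache)
  get(key, envir = .run_cache)
}

# isopotential soma, optionally passive
soma_model <- function() {
  cell_model(list(section_spec("soma", "soma", 10, 10,
                               channel_densities = c(na = 10, k = 36))))
}

# unbranched passive cable (one axon section)
cable_model <- function(length = 1100, diameter = 0.2) {
  cell_model(list(section_spec("cable", "axon", length, diameter)))
}

# uniform active chain of identical axon sections (for symmetry tests)
uniform_chain <- function(n_sections = 3) {
  secs <- lapply(seq_len(n_sections), function(k)
    section_spec(paste0("a", k), "axon", 100, 0.2,
                 channel_densities = c(na = 50, k = 36)))
  cell_model(secs)
}

# full model 50 x 50 Hz train, truncated post window (train metrics only)
train_run <- function(variant) {
  cached(paste0("train_", variant), {
    p <- protocol(frequency = 50, count = 50, variant = variant,
                  t_post = 100, record = c("soma", "bouton_10"))
    run_protocol(p)
  })
}

# full model, distal zone depolarized to -70 mV, full post window
distal_run <- function() {
  cached("distal_fig1b", {
    p <- protocol(frequency = 50, count = 50, zone = "distal",
                  el_target = -70, t_post = 2000,
                  record = c("soma", "bouton_10"))
    run_protocol(p)
  })
}

somatic_broadening_ratio <- function(tr) {
  ev <- detect_spikes(tr, site = "soma")
  ev <- ev[ev$t_peak <= tr$stim_end, ]
  ev$half_duration[nrow(ev)] / ev$half_duration[1]
}
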