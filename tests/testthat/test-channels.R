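test_that("alpha/beta gates satisfy the steady-state and tau identities", {
  g <- hh_shifted_gates()
  set.seed(7)
  v <- runif(1000, -120, 60)
  for (gate in g) {
    a <- eval_rate(gate$alpha, v)
    b <- eval_rate(gate$beta, v)
    ev <- eval_gate(gate, v)
    expect_equal(ev$x_inf, a / (a + b), tolerance = 1e-10)
    expect_equal(ev$tau, 1 / (a + b), tolerance = 1e-10)
  }
})

test_that("gate bounds hold over the full voltage range", {
  prof <- kinetics_profile("default")
  v <- seq(-120, 60, by = 0.1)
  for (ch in list(prof$na, prof$k_inactivating, prof$k_noninactivating)) {
    for (gate in ch$gates) {
      ev <- eval_gate(gate, v)
      expect_true(all(ev$x_inf >= 0 & ev$x_inf <= 1))
      expect_true(all(ev$tau > 0))
    }
  }
})

test_that("sigmoid steady state passes through 0.5 at its midpoint", {
  # alpha and beta mirrored about V = -50 => x_inf(-50) = 0.5
  gate <- gate_spec("x", 1,
                    alpha = rate_fun("sigmoid", A = 1, V0 = -50, B = 8),
                    beta = rate_fun("sigmoid", A = 1, V0 = -50, B = -8))
  expect_equal(eval_gate(gate, -50)$x_inf, 0.5, tolerance = 1e-12)
})

test_that("linoid family takes its removable-singularity limit", {
  r <- rate_fun("linoid", A = 0.1, V0 = -55, B = 10)
  expect_equal(eval_rate(r, -55), 0.1 * 10, tolerance = 1e-6)
  expect_equal(eval_rate(r, -55 + 1e-9), eval_rate(r, -55 - 1e-9),
               tolerance = 1e-6)
})

test_that("tabulated and closed-form paths agree", {
  g <- hh_shifted_gates()
  v <- seq(-120, 60, by = 0.01)
  for (gate in g) {
    tg <- tabulate_gate(gate, dv = 0.05)
    a <- eval_gate(gate, v)
    b <- eval_gate(tg, v)
    expect_lt(max(abs(a$x_inf - b$x_inf)), 1e-4)
  }
})

test_that("gate curves round-trip through CSV", {
  g <- hh_shifted_gates()$m
  path <- tempfile(fileext = ".csv")
  export_gate_table(g, path, v = seq(-120, 60, by = 0.05))
  g2 <- import_gate_table(path, "m", exponent = 3)
  v <- seq(-110, 50, by = 0.3)
  expect_equal(eval_gate(g2, v)$x_inf, eval_gate(g, v)$x_inf,
               tolerance = 1e-6)
})

test_that("channel current density is ohmic in the driving force", {
  k <- channel_spec("k", 36, -85,
                    gates = list(gate_spec("n", 4,
                      alpha = rate_fun("sigmoid", 1, -50, 8),
                      beta = rate_fun("sigmoid", 1, -50, -8))))
  expect_equal(channel_current_density(k, -85, 1), 0)       # V = E
  expect_equal(channel_current_density(k, -75, 1), 360)     # 36 * 10 uA/cm^2
  expect_equal(channel_current_density(k, -75, 0.5), 360 * 0.5^4)
  na <- kinetics_profile("default")$na
  na$g <- 50
  expect_equal(channel_current_density(na, 20, c(0.9, 0)), 0)  # h = 0
  expect_error(channel_current_density(k, -75, c(1, 1)), "gate value")
})

test_that("variant densities conserve the total K+ conductance", {
  for (f in seq(0, 1, by = 0.1)) {
    chs <- make_variant("mixture", fraction = f, g_k = 36)
    expect_equal(sum(vapply(chs, `[[`, numeric(1), "g")), 36)
  }
  chs <- make_variant("mixture", fraction = 0.9, g_k = 36)
  expect_equal(sort(vapply(chs, `[[`, numeric(1), "g")), c(3.6, 32.4))
  expect_length(make_variant("inactivating"), 1)
  expect_error(make_variant("mixture", fraction = 1.2), "\\[0,1\\]")
  # degenerate mixtures collapse to the pure variants
  expect_equal(make_variant("mixture", fraction = 1)[[1]]$label,
               make_variant("inactivating")[[1]]$label)
  expect_equal(make_variant("mixture", fraction = 0)[[1]]$label,
               make_variant("non_inactivating")[[1]]$label)
})

test_that("steady-state initialization is idempotent and balanced", {
  prof <- kinetics_profile("default")
  chans <- c(list(prof$na), make_variant("inactivating", profile = prof))
  gv <- steady_state_gates(chans, -70)
  expect_equal(gv$na$m, eval_gate(prof$na$gates[[1]], -70)$x_inf)
  expect_identical(gv, steady_state_gates(chans, -70))

  # isopotential compartment with e_leak solving the resting current
  # balance: dV/dt at t = 0 below 1e-6 mV/ms
  m <- soma_model()
  v0 <- -70
  dens <- list(na = 10, k_in = 36)
  ionic <- 0
  for (ch in chans) {
    ch$g <- dens[[ch$label]]
    vals <- vapply(ch$gates, function(g) eval_gate(g, v0)$x_inf, numeric(1))
    ionic <- ionic + channel_current_density(ch, v0, vals)  # uA/cm^2
  }
  g_leak <- 1000 / 10000                                    # mS/cm^2
  m$segments$e_leak <- v0 + ionic / g_leak
  sim <- cable_setup(m, variant = "inactivating")
  st <- cable_init(sim, v0 = v0)
  st2 <- cable_step(sim, st, dt = 0.01)
  expect_lt(max(abs(st2$v - st$v)) / 0.01, 1e-6)
})

test_that("repetitive AP clamp accumulates K+ inactivation only in the inactivating channel", {
  prof <- kinetics_profile("default")
  dt <- 0.01
  tt <- seq(0, 250, by = dt)
  v <- rep(-80, length(tt))
  onsets <- 10 + 0:9 * 20                     # 10 pulses at 50 Hz
  for (t0 in onsets)
    v <- v + 100 * exp(-(tt - t0 - 2)^2 / (2 * 0.7^2))
  evolve <- function(gate) {
    x <- numeric(length(tt))
    x[1] <- eval_gate(gate, v[1])$x_inf
    for (i in 2:length(tt)) {
      ev <- eval_gate(gate, v[i - 1])
      x[i] <- ev$x_inf + (x[i - 1] - ev$x_inf) * exp(-dt / ev$tau)
    }
    x
  }
  avail <- function(ch) {
    xs <- lapply(ch$gates, evolve)
    open <- Reduce(`*`, Map(function(x, g) x^g$exponent, xs, ch$gates))
    open[vapply(onsets, function(t0) which.min(abs(tt - t0)), integer(1))]
  }
  a_in <- avail(prof$k_inactivating)
  a_ni <- avail(prof$k_noninactivating)
  # from the second pulse on (after the initial delayed-rectifier
  # deactivation transient) availability falls monotonically and
  # substantially for the inactivating channel only
  expect_true(all(diff(a_in[-1]) < 0))
  expect_lt(a_in[10] / a_in[2], 0.8)
  expect_gt(a_ni[10] / a_ni[2], 0.95)
})

test_that("the paper kinetics slot errors until a transcription is supplied", {
  expect_error(kinetics_profile("paper"), "reserved configuration slot")
  expect_error(kinetics_profile("paper"), "hhmfb")
})

test_that("a kinetics profile loads from a YAML definition", {
  g <- hh_shifted_gates()
  cfg <- list(
    name = "custom",
    channels = list(
      na = list(e = 50, gates = list(
        list(name = "m", exponent = 3,
             alpha = list(family = "linoid", A = 0.1, V0 = -55, B = 10),
             beta = list(family = "exponential", A = 4, V0 = -80, B = -18)),
        list(name = "h", exponent = 1,
             alpha = list(family = "exponential", A = 0.07, V0 = -80, B = -20),
             beta = list(family = "sigmoid", A = 1, V0 = -50, B = -10)))),
      k_inactivating = list(e = -85, gates = list(
        list(name = "n", exponent = 4,
             alpha = list(family = "linoid", A = 0.01, V0 = -70, B = 10),
             beta = list(family = "exponential", A = 0.125, V0 = -80, B = -80)),
        list(name = "hk", exponent = 1,
             table = list(v = seq(-120, 60, by = 1),
                          xinf = kv14_h_inf(seq(-120, 60, by = 1)),
                          tau = kv14_h_tau(seq(-120, 60, by = 1)))))),
      k_noninactivating = list(e = -85, gates = list(
        list(name = "n", exponent = 4,
             alpha = list(family = "linoid", A = 0.01, V0 = -70, B = 10),
             beta = list(family = "exponential", A = 0.125, V0 = -80, B = -80))))))
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  prof <- load_kinetics_profile(path)
  expect_s3_class(prof, "kinetics_profile")
  v <- seq(-100, 40, by = 0.5)
  expect_equal(eval_gate(prof$na$gates[[1]], v)$x_inf,
               eval_gate(g$m, v)$x_inf, tolerance = 1e-8)
  expect_no_error(kinetics_profile("paper", file = path))
})
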