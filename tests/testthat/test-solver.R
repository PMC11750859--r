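test_that("axial coupling matches the hand-computed formula", {
  cab <- cable_model(length = 2, diameter = 0.2)
  g <- assemble_axial_coupling(cab)
  # rho = R_i * L / A_cross = 110 Ohm cm * 1e-4 cm / (pi * (0.1e-4 cm)^2)
  rho <- 110 * 1e-4 / (pi * (0.1e-4)^2)
  expect_equal(g, 1e6 / rho, tolerance = 1e-12)

  # doubling R_i halves every coupling
  cab2 <- cable_model()
  cab2$segments$r_i <- 220
  expect_equal(assemble_axial_coupling(cab2),
               assemble_axial_coupling(cable_model()) / 2, tolerance = 1e-12)

  # chain structure: one coupling per interface, all positive
  m <- build_mossy_fiber()
  gax <- assemble_axial_coupling(m)
  expect_length(gax, m$n_segments - 1)
  expect_true(all(gax > 0))
})

test_that("passive isopotential soma follows the analytic RC charging curve", {
  soma <- cell_model(list(section_spec("soma", "soma", 10, 10)))
  sim <- cable_setup(soma, passive = TRUE)
  st <- cable_init(sim, v0 = -80)
  out <- run_simulation(sim, st, dt = 0.01, n_steps = 5000, inj = 0.01,
                        inj_site = 1, record = 1)
  area <- total_membrane_area(soma) * 1e-8  # um^2 -> cm^2
  ref <- make_passive_references(t = out$time, area_cm2 = area,
                                 i_nA = 0.01, v0 = -80)
  expect_equal(ref$tau_m, 10)  # R_m C_m = 10 ms
  span <- diff(range(ref$rc$v))
  expect_lt(max(abs(out$traces[, 1] - ref$rc$v)) / span, 0.01)
})

test_that("the implicit scheme converges at first order on a passive transient", {
  soma <- cell_model(list(section_spec("soma", "soma", 10, 10)))
  sim <- cable_setup(soma, passive = TRUE)
  area <- total_membrane_area(soma) * 1e-8
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    st <- cable_init(sim, v0 = -80)
    n <- round(20 / dt)
    out <- run_simulation(sim, st, dt, n, inj = 0.01, inj_site = 1,
                          record = 1)
    ref <- make_passive_references(t = out$time, area_cm2 = area,
                                   i_nA = 0.01, v0 = -80)
    max(abs(out$traces[, 1] - ref$rc$v))
  }, numeric(1))
  expect_gt(err[1] / err[2], 1.7)
  expect_lt(err[1] / err[2], 2.3)
  expect_gt(err[2] / err[3], 1.7)
  expect_lt(err[2] / err[3], 2.3)
})

test_that("equilibrium persists with balanced leak and no injection", {
  m <- build_mossy_fiber()
  sim <- cable_setup(m, passive = TRUE)
  st <- cable_init(sim, v0 = -80)   # uniform e_leak = -80 balances exactly
  out <- run_simulation(sim, st, dt = 0.5, n_steps = 2000, inj = 0,
                        inj_site = NULL, record = "bouton_10")
  expect_lt(max(abs(out$traces[, 1] + 80)), 0.5)
})

test_that("membrane charge relaxes monotonically in a passive model", {
  cab <- cable_model(length = 300)
  sim <- cable_setup(cab, passive = TRUE)
  v0 <- -80 + 15 * exp(-(seq_len(300) - 150)^2 / 200)  # local perturbation
  st <- cable_init(sim, v0 = v0)
  q <- numeric(200)
  cap <- mossyburst:::segment_capacitance(cab)
  for (i in seq_along(q)) {
    st <- cable_step(sim, st, dt = 0.5, inj = 0, inj_site = 1)
    q[i] <- sum(cap * (st$v + 80))
  }
  expect_true(all(diff(q) < 0))
  expect_lt(q[200], 0.05 * q[1])
})

test_that("steady state of a uniform passive model equals the leak reversal", {
  cab <- cable_model(length = 200)
  ss <- steady_state_profile(cab, passive = TRUE, tolerance = 1e-6)
  expect_lt(max(abs(ss + 80)), 1e-3)
})

test_that("held-end passive cable reproduces the sealed-end cosh profile", {
  cab <- cable_model(length = 1100, diameter = 0.2)
  sim <- cable_setup(cab, passive = TRUE)
  ss <- steady_state_profile(sim, clamp = list(site = 1, v = -60),
                             tolerance = 1e-5)
  x <- seq_len(1100) - 0.5                    # segment centers, um
  ref <- make_passive_references(diameter = 0.2, length = 1100,
                                 x = x, x0 = 0.5)
  atten_sim <- (ss + 80) / (ss[1] + 80)
  rel <- abs(atten_sim - ref$attenuation$atten) / ref$attenuation$atten
  expect_lt(max(rel), 0.005)
  # analytic profile is 1 at the held position
  expect_equal(ref$attenuation$atten[1], 1)
})

test_that("AP peak time at dt = 0.1 ms matches a fine-timestep reference", {
  m <- build_mossy_fiber()
  sim <- cable_setup(m, variant = "inactivating")
  st <- cable_init(sim)
  eq <- run_simulation(sim, st, 0.1, 2000, inj = 0, inj_site = NULL,
                       record = integer(0))
  peak_t <- function(dt) {
    n <- ceiling(25 / dt)
    inj <- ifelse(seq(0, by = dt, length.out = n) < 2, 0.2, 0)
    out <- run_simulation(sim, eq$state, dt, n, inj = inj, record = "soma")
    expect_gt(max(out$traces[, 1]), -20)      # a spike was evoked
    (which.max(out$traces[, 1]) - 1) * dt
  }
  expect_lt(abs(peak_t(0.1) - peak_t(0.001)), 0.2)
})

test_that("orthodromic and antidromic delays agree on a symmetric chain", {
  chain <- uniform_chain(3)
  sim <- cable_setup(chain, variant = "inactivating")
  st <- cable_init(sim, v0 = -80)
  eq <- run_simulation(sim, st, 0.1, 2000, inj = 0, inj_site = NULL,
                       record = integer(0))
  delay <- function(from, to) {
    n <- 1200
    inj <- ifelse(seq(0, by = 0.025, length.out = n) < 1, 0.05, 0)
    out <- run_simulation(sim, eq$state, 0.025, n, inj = inj,
                          inj_site = from, record = c(from, to))
    expect_gt(max(out$traces[, 2]), 0)        # propagated spike
    diff(apply(out$traces, 2, which.max)) * 0.025
  }
  d_ortho <- delay(1, 300)
  d_anti <- delay(300, 1)
  expect_lt(abs(d_ortho - d_anti) / d_ortho, 0.05)
})

test_that("simulation is deterministic and stable at dt = 0.1 ms", {
  p <- protocol(frequency = 50, count = 5, zone = "distal", el_target = -70,
                t_pre = 50, t_post = 50, record = c("soma", "bouton_10"))
  a <- run_protocol(p)
  b <- run_protocol(p)
  expect_identical(a$v, b$v)
  expect_true(all(is.finite(a$v)))
})

test_that("zero-pulse protocols give flat traces at rest", {
  tr <- cached("rest_run", {
    run_protocol(protocol(count = 0, t_pre = 200, t_post = 1000,
                          record = c("soma", "bouton_10")))
  })
  expect_equal(nrow(detect_spikes(tr, site = "soma")), 0)
  expect_equal(nrow(detect_spikes(tr, site = "bouton_10")), 0)
  late <- tr$v[tr$time > 800, "soma"]
  expect_lt(diff(range(late)), 0.1)           # settled
})

test_that("divergence aborts with time and segment diagnostics", {
  cab <- cable_model(length = 10)
  sim <- cable_setup(cab, passive = TRUE)
  st <- cable_init(sim, v0 = -80)
  expect_error(run_simulation(sim, st, dt = 0.1, n_steps = 100, inj = 1e9,
                              inj_site = 1, record = 1),
               "diverged at t = .* segment")
})

test_that("trace sets round-trip through CSV", {
  p <- protocol(count = 2, t_pre = 10, t_post = 20,
                record = c("soma", "bouton_10"))
  tr <- run_protocol(p)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  tr2 <- read_trace_csv(path, stim_end = tr$stim_end)
  expect_equal(tr2$sites, tr$sites)
  expect_equal(tr2$dt, tr$dt, tolerance = 1e-9)
  expect_equal(unname(tr2$v), unname(tr$v), tolerance = 1e-6)
})
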