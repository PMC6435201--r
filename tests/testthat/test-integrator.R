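test_that("accumulate converts fluxes to amounts, charge and concentrations", {
  d <- donnan_start()
  zero <- compute_fluxes(d$state, d$bath, membrane_params())
  acc <- accumulate(d$state, d$bath, zero, NULL, st = 1e-3)
  expect_equal(acc$state, d$state)
  expect_equal(acc$diagnostics$dQ, 0)

  # a net influx of 6e6 cations in one step carries 9.6e-13 C
  f <- zero; f$NaFc <- 6e6 / 1e-3
  acc2 <- accumulate(d$state, d$bath, f, NULL, st = 1e-3)
  expect_equal(acc2$diagnostics$dQ, 9.6e-13)

  # anion buildup at 0.02 mM/s with z = -1.5 adds Na+ at 0.03 mM/s
  bu <- buildup_schedule(bAn = 0.02, t_on = 0, t_off = 10)
  p <- membrane_params(z = -1.5)
  acc3 <- accumulate(d$state, d$bath, zero, bu, st = 1, params = p)
  expect_equal(acc3$state$An_i - d$state$An_i, 0.02)
  expect_equal(acc3$state$Na_i - d$state$Na_i, 0.03)
  expect_equal(acc3$diagnostics$dQ, 0)  # buildups never carry charge
})

test_that("update_em is dQ over capacitance", {
  expect_equal(1e3 * update_em(0, -9.6e-13, 1.2e-11), -80)
  expect_equal(update_em(-0.05, 0, 1.2e-11), -0.05)
  expect_equal(1e3 * update_em(0, 1.2e-13, 1.2e-11), 10)
})

test_that("relax_volume implements the clamped water-permeability rule", {
  b <- bath_state(Na_o = 150, Cl_o = 150)
  s <- cell_state(Na_i = 150, Cl_i = 15, An_i = 135)  # balanced: 300 vs 300
  p <- membrane_params(z = -1, tau = 1)
  rv <- relax_volume(s, b, p, st = 1e-3)
  expect_equal(rv$diagnostics$osV, 1)
  expect_equal(rv$diagnostics$chV, 1)
  expect_equal(rv$state, s)

  # instant water: a 463.6 / 300 mOsm imbalance is removed in one step
  s2 <- cell_state(Na_i = 231.8, Cl_i = 96.8, An_i = 135)
  p0 <- membrane_params(z = -1, tau = 0)
  rv2 <- relax_volume(s2, b, p0, st = 1e-3)
  expect_equal(rv2$diagnostics$chV, 463.6 / 300)
  expect_equal(rv2$state$vol / s2$vol, 463.6 / 300, tolerance = 1e-12)
  # and the resulting internal osmolarity matches the bath exactly
  osm_in <- with(rv2$state, Na_i + K_i + Cl_i + An_i + osm_i)
  expect_equal(osm_in, 300)

  # tau above the watertight threshold: volume frozen
  p_inf <- membrane_params(z = -1, tau = 1e9)
  rv3 <- relax_volume(s2, b, p_inf, st = 1e-3)
  expect_equal(rv3$state$vol, s2$vol)
})

test_that("a balanced resting state is a fixed point of the step", {
  # Donnan equilibrium state: E_Na = E_Cl = Em, no water flux possible
  Na <- 231.986477689649; Cl <- 96.9884116601443
  s <- cell_state(Na_i = Na, Cl_i = Cl, An_i = 135,
                  Em = nernst_potential(150, Na))
  d <- donnan_start()
  out <- cd_step(s, d$bath, d$params, NULL, st = 1e-3)
  for (f in c("Na_i", "K_i", "Cl_i", "An_i", "Em", "vol"))
    expect_equal(out$state[[f]], s[[f]], tolerance = 1e-9)
})

test_that("trivial runs behave: t_end = 0 and bath-only buildup", {
  d <- donnan_start()
  tr <- cd_run(d$state, d$bath, d$params,
               settings = sim_settings(st = 1e-3, t_end = 0))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$Na_i, 150)

  # one step with only bOso active: bath osmolyte up by bOso*st, cell untouched
  p <- membrane_params()  # everything closed
  bu <- buildup_schedule(bOso = 0.5, t_on = 0, t_off = 10)
  out <- cd_step(d$state, d$bath, p, bu, st = 1e-3)
  expect_equal(out$bath$osm_o, 0.5 * 1e-3)
  expect_equal(out$state$Na_i, d$state$Na_i)
  expect_equal(out$state$vol, d$state$vol)
})

test_that("R reference step and compiled stepper perform identical arithmetic", {
  s <- cell_state(Na_i = 145, K_i = 5, Cl_i = 15, An_i = 135)
  b <- bath_state(Na_o = 145, K_o = 5, Cl_o = 150)
  p <- membrane_params(gNa = 1e10, gK = 1e10, gCl = 1e8, Rp = 2.4e10,
                       x = 3, y = 2, Rnkc = 1e7, Rkc = 1e7, z = -1.5, tau = 1)
  bu <- buildup_schedule(bAn = 0.02, bOso = 0.1, t_on = 0, t_off = 0.03)
  sr <- s; br <- b
  for (i in 1:50) {
    r <- cd_step(sr, br, p, bu, 1e-3)
    sr <- r$state; br <- r$bath
  }
  tc <- cd_run(s, b, p, bu, sim_settings(st = 1e-3, t_end = 0.05))
  fc <- attr(tc, "final_state")
  for (f in c("Na_i", "K_i", "Cl_i", "An_i", "osm_i", "Em", "vol", "atp_total"))
    expect_equal(sr[[f]], fc[[f]], tolerance = 1e-12)
  expect_equal(br$osm_o, attr(tc, "final_bath")$osm_o, tolerance = 1e-12)
})

test_that("membrane-potential drift equals accumulated charge over capacitance", {
  cases <- list(
    donnan_start(),
    pump_start(x = 3, y = 2, Rp = 2.4e10),
    list(state = cell_state(Na_i = 17.9, K_i = 132.1, Cl_i = 29.6, An_i = 120.4),
         bath = bath_state(145, 5, 150),
         params = membrane_params(gNa = 8e9, gK = 1.2e10, gCl = 1e8,
                                  Rp = 8e8, x = 3, y = 2, Rnkc = 1e8, z = -1))
  )
  for (cs in cases) {
    tr <- cd_run(cs$state, cs$bath, cs$params,
                 settings = sim_settings(st = 1e-3, t_end = 2, record_every = 100))
    f <- attr(tr, "final_state")
    expect_equal(f$Em - cs$state$Em, attr(tr, "q_cum") / cs$params$c,
                 tolerance = 1e-12)
    # and per-snapshot along the whole trajectory
    expect_equal(tr$Em - cs$state$Em, tr$q_cum / cs$params$c,
                 tolerance = 1e-12)
  }
})

test_that("impermeant amounts are conserved without buildups", {
  d <- donnan_start()
  d$params$tau <- 0  # strong volume changes
  d$state$osm_i <- 5
  d$bath$osm_o <- 5
  tr <- cd_run(d$state, d$bath, d$params,
               settings = sim_settings(st = 1e-3, t_end = 120, record_every = 1000))
  an_amount <- tr$An_i * tr$vol
  osm_amount <- tr$osm_i * tr$vol
  expect_equal(an_amount, rep(an_amount[1], length(an_amount)),
               tolerance = 1e-12)
  expect_equal(osm_amount, rep(osm_amount[1], length(osm_amount)),
               tolerance = 1e-12)
  expect_gt(tail(tr$vol, 1), 1.03 * tr$vol[1])  # the volume really moved
})

test_that("instant water keeps osmolarity equal to the bath after every step", {
  scn <- get_scenario("double_donnan_na")
  tr <- run_scenario(scn, t_end = 30, record_every = 97)
  osm_in <- tr$Na_i + tr$K_i + tr$Cl_i + tr$An_i + tr$osm_i
  osm_out <- tr$Na_o + tr$K_o + tr$Cl_o + tr$osm_o
  expect_equal(osm_in / osm_out, rep(1, nrow(tr)), tolerance = 1e-12)
})

test_that("volume relaxation matches the closed-form exponential", {
  # fluxless cell with an osmotic step: vol(t) = vol1 + (vol2-vol1)(1-e^(-t/tau))
  tau <- 60
  s <- cell_state(Na_i = 150, Cl_i = 15, An_i = 135, osm_i = 60)  # 360 mOsm
  b <- bath_state(Na_o = 150, Cl_o = 150)                         # 300 mOsm
  p <- membrane_params(z = -1, tau = tau)
  tr <- cd_run(s, b, p, settings = sim_settings(st = 1e-3, t_end = 240,
                                                record_every = 5000))
  vol1 <- s$vol
  vol2 <- s$vol * 360 / 300  # dilution to osmotic balance
  pred <- vol1 + (vol2 - vol1) * (1 - exp(-tr$t / tau))
  expect_equal(tr$vol, pred, tolerance = 1e-4)
})

test_that("halving the time step changes the 20-min Donnan state by < 0.1%", {
  d <- donnan_start()
  f1 <- attr(cd_run(d$state, d$bath, d$params,
                    settings = sim_settings(st = 1e-3, t_end = 1200,
                                            record_every = 1e6)), "final_state")
  f2 <- attr(cd_run(d$state, d$bath, d$params,
                    settings = sim_settings(st = 5e-4, t_end = 1200,
                                            record_every = 1e6)), "final_state")
  expect_equal(f1$Na_i, f2$Na_i, tolerance = 1e-3)
  expect_equal(f1$Cl_i, f2$Cl_i, tolerance = 1e-3)
  expect_equal(f1$Em, f2$Em, tolerance = 1e-3)
})

test_that("steady-state driver converges, reports residuals, detects swelling", {
  ps <- pump_start(x = 3, y = 3, Rp = 2.4e10)
  rep <- run_to_steady_state(ps$state, ps$bath, ps$params,
                             sim_settings(st = 1e-3, max_steady_time = 600))
  expect_true(rep$converged)
  expect_false(rep$swelling)
  # residuals below tolerance, expressed as ions/s
  volL <- rep$state$vol * physical_constants()$L
  expect_lt(max(abs(rep$net_flux)) / volL * 1e3, 1e-9)
  # already-balanced state converges immediately
  rep2 <- run_to_steady_state(rep$state, rep$bath, ps$params,
                              sim_settings(st = 1e-3, max_steady_time = 600))
  expect_true(rep2$converged)
  expect_lt(rep2$elapsed, 5)
  expect_equal(rep2$state$Na_i, rep$state$Na_i, tolerance = 1e-9)
})

test_that("RC charging transient matches the analytic membrane time constant", {
  d <- donnan_start()
  tr <- cd_run(d$state, d$bath, d$params,
               settings = sim_settings(st = 1e-4, t_end = 0.025,
                                       record_every = 1))
  tau_fit <- fit_rc_tau(tr$t, tr$Em)
  tau_rc <- d$params$c * input_resistance(d$params)  # c / (g_tot * e)
  expect_equal(tau_rc, 3.75e-3, tolerance = 1e-12)
  expect_equal(tau_fit, tau_rc, tolerance = 0.03)
  # the plateau is the mean of E_Na (0) and E_Cl (-61.48 mV)
  expect_equal(1e3 * tail(tr$Em, 1), -30.74, tolerance = 2e-3)
})
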