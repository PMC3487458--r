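test_that("preset channel inventories match the firing-class definitions", {
  nm <- function(p) vapply(make_preset(p)$channels, `[[`, "", "name")
  expect_setequal(nm("sustained"), c("Na", "KDr", "KHT", "KTEA"))
  expect_setequal(nm("adapting"),
                  c("Na", "KDr", "KTEA", "T", "L", "SK", "BK", "H"))
  pb <- nm("pause_build")
  expect_true(all(c("KA", "H") %in% pb))
  expect_false("KHT" %in% pb)
  expect_true("T" %in% nm("rebound_sustained"))
  expect_setequal(nm("onset"), c("Na", "KDr", "KLT", "H"))
  # rebound_transient reverses the SK/BK relative strengths of adapting
  gb <- function(p, ch) {
    chs <- make_preset(p)$channels
    chs[[which(vapply(chs, `[[`, "", "name") == ch)]]$gbar
  }
  expect_gt(gb("adapting", "SK"), gb("adapting", "BK"))
  expect_lt(gb("rebound_transient", "SK"), gb("rebound_transient", "BK"))
  expect_gt(gb("rebound_transient", "L"), gb("adapting", "L"))
  expect_error(make_preset("bursting"), "unknown preset")
})

test_that("leak-only membrane follows the RC closed form", {
  cfg <- leak_only(g_leak = 6.849, e_leak = -70, capacitance = 30)
  tr <- simulate_pulse(cfg, amplitude = 100, onset = 0, duration = 400,
                       total = 401)
  tau <- 30 / 6.849
  keep <- tr$t <= 400
  expected <- -70 + (100 / 6.849) * (1 - exp(-tr$t[keep] / tau))
  expect_lt(max(abs(tr$v_series[keep] - expected)), 0.02)
  # fixed point: no input, v stays at e_leak
  out <- simulate_pulse(cfg, 0, onset = 0, duration = 1, total = 100)
  expect_equal(out$v_series[length(out$v_series)], -70, tolerance = 1e-9)
  # halving dt barely moves the steady state
  t1 <- simulate_pulse(cfg, 100, 0, 400, 401, dt = 0.02)
  t2 <- simulate_pulse(cfg, 100, 0, 400, 401, dt = 0.01)
  expect_lt(abs(t1$v_series[length(t1$v_series)] -
                t2$v_series[length(t2$v_series)]), 0.01)
})

test_that("neuron_step matches the compiled trace step by step", {
  cfg <- make_preset("sustained")
  st <- init_state(cfg, v = -65)
  vs <- numeric(50)
  for (i in 1:50) {
    st <- neuron_step(st, cfg, i_inj = 0.1)   # 100 pA
    vs[i] <- st$v
  }
  ref <- icsim:::.simulate(cfg, total = 1, inj_amp = 100, inj_on = 0,
                           inj_off = 1, v0 = -65,
                           gate0 = init_state(cfg, -65)$gate_values)
  expect_equal(vs, ref$v[-1], tolerance = 1e-9)
})

test_that("spike detection uses a -10 mV crossing with 1 ms dead time", {
  expect_length(detect_spikes(rep(-70, 1000), 0.02), 0)
  v <- rep(-70, 500); v[200:210] <- 20
  expect_equal(detect_spikes(v, 0.02), 200 * 0.02, tolerance = 0.05)
  # two crossings 0.5 ms apart collapse to one
  v2 <- rep(-70, 500); v2[100:105] <- 0; v2[125:130] <- 0
  expect_length(detect_spikes(v2, 0.02), 1)
  # 2 ms apart stay separate
  v3 <- rep(-70, 500); v3[100:105] <- 0; v3[200:205] <- 0
  expect_length(detect_spikes(v3, 0.02), 2)
})

test_that("measure_passive recovers closed forms on a leak-only membrane", {
  m <- measure_passive(leak_only(g_leak = 6.849, capacitance = 30))
  expect_equal(m$r_m, 1e3 / 6.849, tolerance = 0.5)   # ~146 MOhm
  expect_equal(m$tau_m, 146 * 0.03, tolerance = 0.1)  # tau = RC ~ 4.38 ms
  expect_equal(m$v_rest, -70, tolerance = 0.01)
})

test_that("apply_bias is ohmic on a leak-only membrane and settles presets", {
  cfg <- apply_bias(leak_only(g_leak = 6.849), target_v = -60)
  expect_equal(cfg$bias_current, 10 * 6.849, tolerance = 1)
  s <- apply_bias(make_preset("sustained"), -60)
  out <- icsim:::.simulate(s, total = 500, record_v = FALSE)
  expect_lt(abs(out$v_final + 60), 0.5)
})

test_that("firing classes: regular, adapting, onset and rebound patterns", {
  tr <- simulate_pulse(make_preset("sustained"), 200, 100, 200, 450)
  isi <- diff(tr$spike_times[tr$spike_times > 100 & tr$spike_times < 300])
  expect_gt(length(isi), 5)
  expect_lt(stats::sd(isi[-1]) / mean(isi[-1]), 0.1)  # regular after first ISI

  tra <- simulate_pulse(make_preset("adapting"), 300, 100, 200, 450)
  isia <- diff(tra$spike_times[tra$spike_times > 100 & tra$spike_times < 300])
  expect_lt(isia[1], isia[length(isia)])              # rate adaptation

  expect_length(simulate_pulse(make_preset("onset"), 800, 100, 200,
                               450)$spike_times, 1)

  reb <- function(p) {
    t <- simulate_pulse(make_preset(p), -200, 100, 200, 450)
    sum(t$spike_times > 300 & t$spike_times < 350)
  }
  expect_gte(reb("rebound_sustained"), 1)
  expect_gte(reb("rebound_transient"), 1)
  expect_equal(reb("sustained"), 0)
})

test_that("pause_build fires later after release from hyperpolarization", {
  pb <- make_preset("pause_build")
  direct <- simulate_pulse(pb, 500, 100, 200, 450)
  lat_direct <- direct$spike_times[direct$spike_times > 100][1] - 100
  pre <- icsim:::.simulate(pb, total = 300, inj_amp = -500, inj_on = 100,
                           inj_off = 300)
  post <- icsim:::.simulate(pb, total = 200, inj_amp = 500, inj_on = 0,
                            inj_off = 200, v0 = pre$v_final,
                            gate0 = pre$gates_final, ca0 = pre$ca_final)
  lat_after <- detect_spikes(post$v, IC_DT)[1]
  expect_gt(lat_after, lat_direct)
})

test_that("spike counts converge in dt for pulse protocols", {
  for (p in c("sustained", "adapting")) {
    amp <- if (p == "sustained") 200 else 300
    n1 <- length(simulate_pulse(make_preset(p), amp, 100, 200, 420,
                                dt = 0.02)$spike_times)
    n2 <- length(simulate_pulse(make_preset(p), amp, 100, 200, 420,
                                dt = 0.01)$spike_times)
    expect_equal(n1, n2)
  }
  expect_error(simulate_pulse(make_preset("sustained"), 100, dt = 0.1),
               "dt")
})
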