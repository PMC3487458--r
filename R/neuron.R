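#' Single-compartment membrane integration and firing-type presets
#'
#' The membrane obeys `C dV/dt = -sum(I_chan) - I_leak - I_syn + I_inj` and is
#' advanced with an exponential-Euler scheme on the total-conductance form at
#' a fixed step (default 0.02 ms; steps above 0.05 ms are rejected).  Six
#' presets reproduce the firing classes seen in IC slice recordings:
#' sustained, adapting, pause-build, rebound-sustained, rebound-transient and
#' onset.
#'
#' @name neuron
NULL

#' Default integration step (ms)
#' @export
IC_DT <- 0.02

#' Construct a neuron configuration
#'
#' @param capacitance membrane capacitance (pF).
#' @param g_leak leak conductance (nS).
#' @param e_leak leak reversal (mV).
#' @param channels list of [channel_spec()] objects.
#' @param ca_pool a [calcium_pool()] (or NULL when no Ca machinery).
#' @param bias_current constant bias current (pA).
#' @param preset_name label for provenance.
#' @return a `neuron_config` list.
#' @export
neuron_config <- function(capacitance, g_leak, e_leak, channels,
                          ca_pool = NULL, bias_current = 0,
                          preset_name = "custom") {
  stopifnot(capacitance > 0, g_leak > 0)
  if (is.null(ca_pool)) ca_pool <- calcium_pool()
  structure(list(capacitance = capacitance, g_leak = g_leak, e_leak = e_leak,
                 channels = channels, ca_pool = ca_pool,
                 bias_current = bias_current, preset_name = preset_name),
            class = "neuron_config")
}

# Flatten a neuron_config into the matrices consumed by the C++ core.
.core_params <- function(cfg) {
  chs <- cfg$channels
  nch <- length(chs)
  chan <- matrix(0, nrow = nch, ncol = 6)
  grows <- list()
  for (c in seq_len(nch)) {
    sp <- chs[[c]]
    chan[c, ] <- c(sp$gbar, sp$erev, as.numeric(isTRUE(sp$carries_ca)),
                   as.numeric(!is.na(sp$ca_kd)),
                   ifelse(is.na(sp$ca_kd), 1, sp$ca_kd),
                   ifelse(is.na(sp$ca_hill), 1, sp$ca_hill))
    for (g in sp$gates) {
      ttype <- match(g$tau_type, c("constant", "bell", "sigmoid")) - 1
      grows[[length(grows) + 1]] <-
        c(c - 1, g$exponent, g$vhalf, g$slope, ttype, g$tau_params, g$ca_shift)
    }
  }
  gates <- if (length(grows)) do.call(rbind, grows) else matrix(0, 0, 10)
  list(gates = gates, chan = chan)
}

#' Create one of the six shipped firing-type presets
#'
#' Channel inventories: sustained = Na, KDr, KHT, KTEA (+ leak, no Ca
#' machinery); adapting = Na, KDr, KTEA, T, L, SK, BK, H; pause_build adds a
#' rapidly inactivating KA and a small Ih to the sustained backbone while
#' removing KHT and lowering KTEA and leak; rebound_sustained = sustained + a
#' T-type Ca conductance; rebound_transient = adapting with a larger L-type
#' conductance and the SK/BK strengths reversed; onset = Na, KDr,
#' low-threshold K (KLT) and Ih.
#'
#' Passive calibration targets: sustained rests at -70 mV with Rm 146 MOhm
#' and tau 4.4 ms; adapting at -70 mV with 142 MOhm and 5 ms.
#'
#' @param name one of `"sustained"`, `"adapting"`, `"pause_build"`,
#'   `"rebound_sustained"`, `"rebound_transient"`, `"onset"`.
#' @return a [neuron_config()].
#' @export
make_preset <- function(name) {
  ch <- function(...) {
    args <- list(...)
    lapply(seq(1, length(args), 2),
           function(i) make_channel(args[[i]], args[[i + 1]]))
  }
  switch(name,
    sustained = neuron_config(
      capacitance = 30.15, g_leak = 6.7172, e_leak = -69.8728,
      channels = ch("Na", 800, "KDr", 300, "KHT", 60, "KTEA", 60),
      preset_name = "sustained"),
    adapting = neuron_config(
      capacitance = 38.769, g_leak = 5.6044, e_leak = -71.7616,
      channels = ch("Na", 800, "KDr", 300, "KTEA", 60, "T", 12, "L", 10,
                    "SK", 30, "BK", 12, "H", 3),
      ca_pool = calcium_pool(influx_scale = 0.05, decay_tau = 80),
      preset_name = "adapting"),
    pause_build = neuron_config(
      capacitance = 30.15, g_leak = 5.4, e_leak = -71.7252,
      channels = ch("Na", 800, "KDr", 300, "KTEA", 30, "KA", 600, "H", 3),
      preset_name = "pause_build"),
    rebound_sustained = neuron_config(
      capacitance = 30.15, g_leak = 6.7172, e_leak = -70.3219,
      channels = ch("Na", 800, "KDr", 300, "KHT", 60, "KTEA", 60, "T", 25),
      ca_pool = calcium_pool(),
      preset_name = "rebound_sustained"),
    rebound_transient = neuron_config(
      capacitance = 38.769, g_leak = 5.6044, e_leak = -72.1052,
      channels = ch("Na", 800, "KDr", 300, "KTEA", 60, "T", 12, "L", 25,
                    "SK", 12, "BK", 30, "H", 3),
      ca_pool = calcium_pool(influx_scale = 0.05, decay_tau = 80),
      preset_name = "rebound_transient"),
    onset = neuron_config(
      capacitance = 30.15, g_leak = 6.7172, e_leak = -70.9355,
      channels = ch("Na", 1200, "KDr", 150, "KLT", 500, "H", 2),
      preset_name = "onset"),
    stop("unknown preset name: ", name)
  )
}

# Low-level simulation wrapper around the compiled core.
# syn_events: matrix (time_ms, class_1based, amp_nS) or NULL.
# syn_params: matrix (tau_r, tau_d, erev, mg) or NULL.
.simulate <- function(cfg, total, dt = IC_DT,
                      inj_amp = 0, inj_on = 0, inj_off = 0,
                      syn_events = NULL, syn_params = NULL,
                      v0 = NULL, gate0 = numeric(0), ca0 = -1,
                      record_v = TRUE) {
  if (dt > 0.05) stop("dt > 0.05 ms rejected for stability")
  p <- .core_params(cfg)
  if (is.null(syn_params)) syn_params <- matrix(0, 0, 4)
  if (is.null(syn_events) || nrow(syn_events) == 0) {
    syn_events <- matrix(0, 0, 3)
  } else {
    syn_events <- syn_events[order(syn_events[, 1]), , drop = FALSE]
  }
  ev <- syn_events
  if (nrow(ev)) ev[, 2] <- ev[, 2] - 1  # 0-based class for C++
  if (is.null(v0)) v0 <- cfg$e_leak
  cp <- cfg$ca_pool
  .simulate_core(p$gates, p$chan, cfg$capacitance, cfg$g_leak, cfg$e_leak,
                 c(cp$influx_scale, cp$decay_tau, cp$floor),
                 cfg$bias_current, inj_amp, inj_on, inj_off,
                 syn_params, ev, dt, total, v0, gate0, ca0, record_v)
}

#' Advance the membrane state by one step
#'
#' One exponential-Euler step of voltage, gates and calcium.  Mostly useful
#' for inspection and testing; long simulations should use
#' [simulate_pulse()] or [run_am_experiment()], which run the same update in
#' compiled code.
#'
#' @param state list with `v` (mV), `gate_values` (numeric vector, one entry
#'   per gate in channel order), `ca` (uM) and `t` (ms); use
#'   [init_state()] to build one.
#' @param cfg a [neuron_config()].
#' @param i_syn synaptic current (nA) treated as constant over the step.
#' @param i_inj injected current (nA).
#' @param dt step (ms), must be <= 0.05.
#' @return updated state.
#' @export
neuron_step <- function(state, cfg, i_syn = 0, i_inj = 0, dt = IC_DT) {
  out <- .simulate(cfg, total = dt, dt = dt,
                   inj_amp = (i_inj - i_syn) * 1e3, inj_on = 0, inj_off = dt,
                   v0 = state$v, gate0 = state$gate_values, ca0 = state$ca,
                   record_v = FALSE)
  list(v = out$v_final, gate_values = out$gates_final, ca = out$ca_final,
       t = state$t + dt)
}

#' Initial membrane state at a holding voltage
#' @param cfg a [neuron_config()].
#' @param v initial voltage (mV); defaults to the leak reversal.
#' @return a state list for [neuron_step()].
#' @export
init_state <- function(cfg, v = cfg$e_leak) {
  gates <- unlist(lapply(cfg$channels, function(sp)
    vapply(sp$gates, steady_state, numeric(1), v = v)))
  if (is.null(gates)) gates <- numeric(0)
  list(v = v, gate_values = as.numeric(gates), ca = cfg$ca_pool$floor, t = 0)
}

#' Detect spike times from a voltage trace
#'
#' Upward crossings of -10 mV with a 1 ms dead time.
#'
#' @param v_series voltage samples (mV).
#' @param dt sample interval (ms).
#' @param threshold crossing threshold (mV).
#' @param dead_time refractory window for detection (ms).
#' @return strictly increasing spike times (ms).
#' @export
detect_spikes <- function(v_series, dt, threshold = -10, dead_time = 1) {
  n <- length(v_series)
  if (n < 2) return(numeric(0))
  up <- which(v_series[-1] >= threshold & v_series[-n] < threshold)
  if (!length(up)) return(numeric(0))
  times <- up * dt
  keep <- times[1]
  for (tt in times[-1]) if (tt - keep[length(keep)] >= dead_time)
    keep <- c(keep, tt)
  keep
}

#' Simulate a current-pulse protocol
#'
#' @param cfg a [neuron_config()].
#' @param amplitude pulse amplitude (pA); negative for hyperpolarizing.
#' @param onset pulse onset (ms).
#' @param duration pulse duration (ms).
#' @param total total simulated time (ms); must exceed `onset + duration`.
#' @param dt integration step (ms).
#' @return a `trace` list: `dt`, `t` (ms), `v_series` (mV), `spike_times` (ms).
#' @export
simulate_pulse <- function(cfg, amplitude, onset = 100, duration = 200,
                           total = onset + duration + 100, dt = IC_DT) {
  stopifnot(total > onset + duration)
  out <- .simulate(cfg, total = total, dt = dt, inj_amp = amplitude,
                   inj_on = onset, inj_off = onset + duration)
  v <- out$v
  structure(list(dt = dt, t = seq(0, by = dt, length.out = length(v)),
                 v_series = v, spike_times = detect_spikes(v, dt)),
            class = "ic_trace")
}

#' Measure passive membrane properties
#'
#' Rests the model for 500 ms, applies a small hyperpolarizing step and reads
#' (i) the resting potential, (ii) `Rm = dV_ss / dI` and (iii) the membrane
#' time constant as the time for the deflection to reach `1 - 1/e` of its
#' steady-state value.
#'
#' @param cfg a [neuron_config()].
#' @param step_pa probe current (pA); default -10.
#' @return list `(v_rest, r_m, tau_m)` in (mV, MOhm, ms).
#' @export
measure_passive <- function(cfg, step_pa = -10) {
  settle <- .simulate(cfg, total = 500, record_v = FALSE)
  if (length(detect_spikes(.simulate(cfg, total = 500)$v, IC_DT)) > 0)
    stop("preset fires spontaneously at rest; passive measurement undefined")
  v_rest <- settle$v_final
  out <- .simulate(cfg, total = 500, inj_amp = step_pa, inj_on = 0, inj_off = 500,
                   v0 = settle$v_final, gate0 = settle$gates_final,
                   ca0 = settle$ca_final)
  v <- out$v
  n <- length(v)
  v_ss <- mean(v[(n - round(50 / IC_DT)):n])
  dv <- v_ss - v_rest
  r_m <- dv / step_pa * 1e3          # mV / pA = GOhm -> MOhm via 1e3
  target <- v_rest + (1 - exp(-1)) * dv
  idx <- if (dv < 0) which(v <= target)[1] else which(v >= target)[1]
  tau_m <- (idx - 1) * IC_DT
  list(v_rest = v_rest, r_m = r_m, tau_m = tau_m)
}

#' Find the bias current that holds the membrane at a target potential
#'
#' Root-finds the constant current for which a 500 ms unstimulated run
#' settles within 0.5 mV of `target_v`.
#'
#' @param cfg a [neuron_config()].
#' @param target_v target holding potential (mV), in [-70, -50].
#' @return the configuration with `bias_current` set.
#' @export
apply_bias <- function(cfg, target_v) {
  stopifnot(target_v >= -70, target_v <= -50)
  settled <- function(bias) {
    c2 <- cfg
    c2$bias_current <- bias
    out <- .simulate(c2, total = 500)
    v <- out$v
    if (length(detect_spikes(v, IC_DT)) > 0) return(NA_real_)
    mean(v[(length(v) - round(50 / IC_DT)):length(v)])
  }
  f <- function(bias) {
    s <- settled(bias)
    if (is.na(s)) 1e3 else s - target_v
  }
  # bracket using the passive estimate
  g_eff <- 1e3 / measure_passive(cfg)$r_m  # nS
  v0 <- settled(0)
  guess <- (target_v - v0) * g_eff
  lo <- min(0, 2 * guess); hi <- max(0, 2 * guess)
  root <- stats::uniroot(f, c(lo, hi), tol = 0.1)$root
  s <- settled(root)
  if (is.na(s) || abs(s - target_v) > 0.5)
    stop("bias target unreachable without spiking")
  cfg$bias_current <- root
  cfg
}
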