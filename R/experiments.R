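#' Scenario runners: AM protocol, ablations, sweeps and aging
#'
#' A scenario bundles a neuron preset, a convergence pattern of afferents,
#' synapse parameters and a stimulus protocol.  The AM protocol simulates 10
#' trials per modulation frequency (8-1024 Hz in octave steps, 750 ms
#' stimuli) with the bias current applied at least 200 ms before synaptic
#' stimulation, then builds the rate and temporal MTFs.  All comparisons
#' (plasticity ablations, sweeps, aging) reuse identical input spike trains
#' via the seed so that differences are attributable to the manipulated
#' parameter alone.
#'
#' @name experiments
NULL

#' Stimulus protocol
#'
#' @param mod_freqs modulation frequencies (Hz), octave-spaced.
#' @param duration stimulus duration (ms).
#' @param n_trials trials per modulation frequency.
#' @param pre_stimulus settling time before stimulation (ms, >= 200).
#' @param bias_target holding potential during the run (mV).
#' @return a `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(mod_freqs = IC_MOD_FREQS, duration = 750,
                              n_trials = 10, pre_stimulus = 200,
                              bias_target = -60) {
  stopifnot(duration > 0, pre_stimulus >= 200,
            all(abs(diff(log2(mod_freqs)) - 1) < 1e-9))
  list(mod_freqs = mod_freqs, duration = duration, n_trials = n_trials,
       pre_stimulus = pre_stimulus, bias_target = bias_target)
}

#' Scenario configuration
#'
#' @param preset neuron preset name (see [make_preset()]).
#' @param convergence a [convergence_spec()].
#' @param synapses list with `ampa`, `nmda`, `gaba` [synapse_params()];
#'   defaults from [default_synapse()].
#' @param protocol a [stimulus_protocol()].
#' @param gaba_scale,ampa_scale conductance scale factors (> 0); reducing
#'   `gaba_scale` models the age-related loss of GABAergic inhibition.
#' @param ipsc_decay_scale scale on the GABA-A decay time constant.
#' @param depression named logical vector, e.g. `c(AMPA = TRUE,
#'   GABA_A = TRUE)`; FALSE removes that receptor's depression.
#' @param recovery_tau_scale named numeric vector scaling recovery time
#'   constants, e.g. `c(AMPA = 1, GABA_A = 1.5)`.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(preset, convergence, synapses = NULL,
                            protocol = stimulus_protocol(),
                            gaba_scale = 1, ampa_scale = 1,
                            ipsc_decay_scale = 1,
                            depression = c(AMPA = TRUE, GABA_A = TRUE),
                            recovery_tau_scale = c(AMPA = 1, GABA_A = 1)) {
  stopifnot(gaba_scale >= 0, ampa_scale > 0, ipsc_decay_scale > 0)
  if (is.null(synapses))
    synapses <- list(ampa = default_synapse("AMPA"),
                     nmda = default_synapse("NMDA"),
                     gaba = default_synapse("GABA_A"))
  structure(list(preset = preset, convergence = convergence,
                 synapses = synapses, protocol = protocol,
                 gaba_scale = gaba_scale, ampa_scale = ampa_scale,
                 ipsc_decay_scale = ipsc_decay_scale,
                 depression = depression,
                 recovery_tau_scale = recovery_tau_scale),
            class = "scenario_config")
}

# Apply scenario modifiers to the synapse parameter sets.
.effective_synapses <- function(cfg) {
  syn <- cfg$synapses
  syn$ampa$g_peak <- syn$ampa$g_peak * cfg$ampa_scale
  syn$gaba$g_peak <- syn$gaba$g_peak * cfg$gaba_scale
  syn$gaba$tau_decay <- syn$gaba$tau_decay * cfg$ipsc_decay_scale
  if (!isTRUE(cfg$depression[["AMPA"]])) syn$ampa$depression_d <- 1
  if (!isTRUE(cfg$depression[["GABA_A"]])) syn$gaba$depression_d <- 1
  syn$ampa$tau_recovery <- syn$ampa$tau_recovery * cfg$recovery_tau_scale[["AMPA"]]
  syn$gaba$tau_recovery <- syn$gaba$tau_recovery * cfg$recovery_tau_scale[["GABA_A"]]
  syn
}

# Bias currents are deterministic per (preset, target); cache them.
.bias_cache <- new.env(parent = emptyenv())

.biased_preset <- function(preset, target_v) {
  key <- paste(preset, format(target_v))
  if (!is.null(.bias_cache[[key]])) return(.bias_cache[[key]])
  cfg <- apply_bias(make_preset(preset), target_v)
  .bias_cache[[key]] <- cfg
  cfg
}

# Simulate one trial; returns spike times relative to stimulus onset and,
# optionally, the voltage trace.
.run_trial <- function(neuron, syn, trains, pre, duration, record_v = FALSE) {
  ev <- .syn_event_matrix(trains$exc, trains$inh, syn)
  if (nrow(ev)) ev[, 1] <- ev[, 1] + pre
  out <- .simulate(neuron, total = pre + duration + 20,
                   syn_events = ev, syn_params = .syn_param_matrix(syn))
  spikes <- detect_spikes(out$v, IC_DT) - pre
  list(spikes = spikes[spikes >= 0 & spikes <= duration],
       v = if (record_v) out$v else NULL)
}

#' Run the amplitude-modulation experiment for a scenario
#'
#' For every modulation frequency and trial, afferent trains are generated,
#' the neuron is integrated with its bias applied during a pre-stimulus
#' settling period, and spikes are collected; the pooled result is an MTF.
#'
#' @param cfg a [scenario_config()].
#' @param keep_spikes return the per-trial spike trains alongside the MTF.
#' @return an `mtf_result`; with `keep_spikes = TRUE`, a list
#'   `(mtf, spikes)` where `spikes` is indexed `[[freq]][[trial]]`.
#' @export
run_am_experiment <- function(cfg, keep_spikes = FALSE) {
  pr <- cfg$protocol
  neuron <- .biased_preset(cfg$preset, pr$bias_target)
  syn <- .effective_synapses(cfg)
  trials_by_freq <- lapply(pr$mod_freqs, function(f) {
    lapply(seq_len(pr$n_trials), function(tr) {
      trains <- generate_convergent_set(cfg$convergence, f, pr$duration, tr)
      .run_trial(neuron, syn, trains, pr$pre_stimulus, pr$duration)$spikes
    })
  })
  mtf <- build_mtf(trials_by_freq, pr$mod_freqs, pr$duration)
  if (keep_spikes) list(mtf = mtf, spikes = trials_by_freq) else mtf
}

#' Paired comparison of synaptic-depression manipulations
#'
#' Reruns a scenario with one receptor's short-term depression removed or
#' its recovery time constant rescaled, under identical input spike trains.
#'
#' @param cfg baseline [scenario_config()] (depression on).
#' @param which `"AMPA"` or `"GABA_A"`.
#' @param mode `"off"` to remove depression, or a numeric recovery-tau scale
#'   factor (e.g. 0.5 or 1.5).
#' @return list `(baseline, modified)` of `mtf_result`s.
#' @export
plasticity_ablation <- function(cfg, which = c("AMPA", "GABA_A"),
                                mode = "off") {
  which <- match.arg(which)
  stopifnot(isTRUE(cfg$depression[[which]]))
  mod <- cfg
  if (identical(mode, "off")) {
    mod$depression[[which]] <- FALSE
  } else {
    stopifnot(is.numeric(mode), mode > 0)
    mod$recovery_tau_scale[[which]] <- mode
  }
  list(baseline = run_am_experiment(cfg), modified = run_am_experiment(mod))
}

#' Sweep two scenario axes and record the rate-MTF shape
#'
#' @param cfg a [scenario_config()].
#' @param axes character vector of two axis names from `gaba_g`, `ampa_g`,
#'   `ipsc_decay`, `n_exc`, `n_inh`.
#' @param grids list of two numeric grids (each length >= 3): conductances
#'   in nS, decay in ms, counts as integers.
#' @return list with `shape` (character matrix, axis 1 = rows), `grids`,
#'   `axes` and `mtfs` (list-matrix of `mtf_result`s).
#' @export
sweep_shapes <- function(cfg, axes, grids) {
  stopifnot(length(axes) == 2, length(grids) == 2,
            all(lengths(grids) >= 3),
            all(axes %in% c("gaba_g", "ampa_g", "ipsc_decay", "n_exc", "n_inh")))
  set_axis <- function(c2, axis, value) {
    switch(axis,
      gaba_g = { c2$synapses$gaba$g_peak <- value; c2 },
      ampa_g = { c2$synapses$ampa$g_peak <- value; c2 },
      ipsc_decay = { c2$synapses$gaba$tau_decay <- value; c2 },
      n_exc = { c2$convergence$n_exc <- as.integer(value); c2 },
      n_inh = { c2$convergence$n_inh <- as.integer(value); c2 })
  }
  n1 <- length(grids[[1]]); n2 <- length(grids[[2]])
  shape <- matrix(NA_character_, n1, n2,
                  dimnames = list(format(grids[[1]]), format(grids[[2]])))
  mtfs <- vector("list", n1 * n2)
  dim(mtfs) <- c(n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    c2 <- set_axis(set_axis(cfg, axes[1], grids[[1]][i]), axes[2], grids[[2]][j])
    m <- run_am_experiment(c2)
    shape[i, j] <- m$rate_shape
    mtfs[[i, j]] <- m
  }
  list(shape = shape, grids = grids, axes = axes, mtfs = mtfs)
}

#' Aging scenario: graded reduction of GABA-A conductance
#'
#' Runs a scenario at each GABA-A scale with identical input spike trains;
#' scale 1 is the "young" condition, 0.5 and 0.25 model the aged loss of
#' inhibition.
#'
#' @param cfg a [scenario_config()] with inhibition present.
#' @param gaba_scales conductance scale factors.
#' @return named list of `mtf_result`s, one per scale.
#' @export
aging_scenario <- function(cfg, gaba_scales = c(1, 0.5, 0.25)) {
  stopifnot(cfg$convergence$n_inh > 0, cfg$synapses$gaba$g_peak > 0)
  out <- lapply(gaba_scales, function(sc) {
    c2 <- cfg
    c2$gaba_scale <- sc
    run_am_experiment(c2)
  })
  names(out) <- paste0("gaba_", gaba_scales)
  out
}

#' Cycle-averaged membrane-potential contour
#'
#' Folds one trial's voltage trace at the modulation period and averages
#' over complete cycles.
#'
#' @param cfg a [scenario_config()].
#' @param mod_freq modulation frequency (Hz), on the protocol grid.
#' @param trial trial index.
#' @return list `(phase_deg, v_mean)`; the contour spans one period.
#' @export
membrane_contour <- function(cfg, mod_freq, trial = 1) {
  pr <- cfg$protocol
  stopifnot(mod_freq %in% pr$mod_freqs)
  neuron <- .biased_preset(cfg$preset, pr$bias_target)
  syn <- .effective_synapses(cfg)
  trains <- generate_convergent_set(cfg$convergence, mod_freq, pr$duration, trial)
  res <- .run_trial(neuron, syn, trains, pr$pre_stimulus, pr$duration,
                    record_v = TRUE)
  period_ms <- 1000 / mod_freq
  n_per <- round(period_ms / IC_DT)
  i0 <- round(pr$pre_stimulus / IC_DT) + 1
  v <- res$v[i0:(i0 + round(pr$duration / IC_DT) - 1)]
  n_cyc <- floor(length(v) / n_per)
  m <- matrix(v[seq_len(n_cyc * n_per)], nrow = n_per)
  list(phase_deg = (seq_len(n_per) - 0.5) / n_per * 360, v_mean = rowMeans(m))
}

#' Shipped figure-style scenario recipes
#'
#' Worked input-convergence configurations whose conductances were
#' calibrated so each reproduces its qualitative response transformation
#' (the response shape, not exact rates).  Recipes `"bp_exc_only"` and
#' `"br_preceding_inh"` are fragile: they reproduce their effects only for a
#' limited parameter set.
#'
#' @param name recipe name; see Details.
#' @param n_trials trials per modulation frequency.
#' @param seed master seed for the afferent streams.
#' @return a [scenario_config()].
#' @details Available recipes: `"lp_vcn_dnll"` (Adapting, 2 VCN + 4 DNLL
#'   high-pass, low-pass output), `"bp_lp_inhibition"` (Sustained, 3
#'   user-defined LP excitatory + 6 LP inhibitory, corner 32 Hz, band-pass
#'   output), `"ap_dcn_dnll"` (Adapting, 3 DCN + 2 DNLL all-pass, all-pass
#'   output), `"br_vnll"` (Adapting, 2 VCN + 6 VNLL band-pass at 36 Hz,
#'   band-reject output), `"plasticity"` (3 DCN + 2 DNLL all-pass, ablation
#'   baseline), `"recovery_tau"` (2 VCN + 4 DNLL high-pass), `"sweep"`
#'   (4 VCN + 4 DNLL high-pass), `"aging_lp"` (Sustained, 2 LSO + 3 DNLL
#'   all-pass at -60 mV), `"aging_lp_alt"` (Sustained, 2 DCN + 5 DNLL
#'   high-pass), `"aging_bp"` (Adapting, 3 user LP + 3 VNLL band-pass at
#'   12 Hz), `"aging_br"` (Adapting, 3 VCN + 4 VNLL band-pass at 32 Hz).
#' @export
ic_recipe <- function(name, n_trials = 10, seed = 1) {
  syn <- function(ampa, gaba, nmda = 1.5)
    list(ampa = default_synapse("AMPA", ampa),
         nmda = default_synapse("NMDA", nmda),
         gaba = default_synapse("GABA_A", gaba))
  proto <- function(bias = -60)
    stimulus_protocol(n_trials = n_trials, bias_target = bias)
  conv <- function(ne, ex, ni, inh)
    convergence_spec(ne, ex, ni, inh, seed = seed)
  switch(name,
    lp_vcn_dnll = scenario_config(
      "adapting",
      conv(2, make_preset_tuning("VCN"), 4, make_preset_tuning("DNLL_HP")),
      synapses = syn(5, 12), protocol = proto()),
    bp_lp_inhibition = scenario_config(
      "sustained",
      conv(3, user_defined_tuning("LP", corner = 32, peak_rate = 150),
           6, user_defined_tuning("LP", corner = 8,
                                  sync_template = "DNLL_AP", peak_rate = 120)),
      synapses = syn(5, 8), protocol = proto()),
    ap_dcn_dnll = scenario_config(
      "adapting",
      conv(3, make_preset_tuning("DCN"), 2, make_preset_tuning("DNLL_AP")),
      synapses = syn(5, 5), protocol = proto()),
    br_vnll = scenario_config(
      "adapting",
      conv(2, make_preset_tuning("VCN"),
           6, make_preset_tuning("VNLL_BP", bp_center = 36, vnll_shoulder = 10)),
      synapses = syn(6, 7), protocol = proto()),
    plasticity = scenario_config(
      "adapting",
      conv(3, make_preset_tuning("DCN"), 2, make_preset_tuning("DNLL_AP")),
      synapses = syn(3, 4), protocol = proto()),
    recovery_tau = scenario_config(
      "adapting",
      conv(2, make_preset_tuning("VCN"), 4, make_preset_tuning("DNLL_HP")),
      synapses = syn(5, 5), protocol = proto()),
    sweep = scenario_config(
      "adapting",
      conv(4, make_preset_tuning("VCN"), 4, make_preset_tuning("DNLL_HP")),
      synapses = syn(4, 5), protocol = proto()),
    aging_lp = {
      sy <- syn(0.5, 12, nmda = 2.6)
      sy$nmda$tau_decay <- 150
      scenario_config(
        "sustained",
        conv(2, make_preset_tuning("LSO"), 3, make_preset_tuning("DNLL_AP")),
        synapses = sy, protocol = proto(-58))
    },
    aging_lp_alt = scenario_config(
      "sustained",
      conv(2, make_preset_tuning("DCN"), 5, make_preset_tuning("DNLL_HP")),
      synapses = syn(6, 6), protocol = proto(-60)),
    aging_bp = scenario_config(
      "adapting",
      conv(3, user_defined_tuning("LP", corner = 32, peak_rate = 150),
           3, make_preset_tuning("VNLL_BP", bp_center = 12)),
      synapses = syn(5, 24), protocol = proto()),
    aging_br = scenario_config(
      "adapting",
      conv(3, make_preset_tuning("VCN"),
           4, make_preset_tuning("VNLL_BP", bp_center = 32)),
      synapses = syn(4, 18, nmda = 0.2), protocol = proto()),
    stop("unknown recipe: ", name))
}
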