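#' Synaptic conductances and short-term depression
#'
#' Excitatory events drive an AMPA and an NMDA conductance; inhibitory events
#' drive a GABA-A conductance.  Each event contributes a dual-exponential
#' kernel normalized so an isolated event peaks at `g_peak`.  AMPA and GABA-A
#' amplitudes undergo interval-dependent short-term depression: each afferent
#' carries an availability `s` that is multiplied by `depression_d` at every
#' event and recovers toward 1 with time constant `tau_recovery` (the AMPA
#' recovery constant is the one conventionally called TauR2, the GABA-A one
#' TauR).  NMDA is undepressed and carries the standard magnesium block.
#'
#' Default kinetics reflect the slow synaptic time constants measured in IC
#' neurons and are tagged "calibrated": AMPA 0.5/3 ms, NMDA 5/80 ms, GABA-A
#' 1/10 ms rise/decay; E_exc = 0 mV, E_GABA = -75 mV; d_AMPA = 0.55 with 40 ms
#' recovery, d_GABA = 0.6 with 50 ms recovery.
#'
#' @name synapse
NULL

#' Synapse parameter set for one receptor class
#'
#' @param receptor `"AMPA"`, `"NMDA"` or `"GABA_A"`.
#' @param g_peak peak conductance of an isolated event (nS).
#' @param tau_rise,tau_decay kernel time constants (ms); `tau_decay` must
#'   exceed `tau_rise`.
#' @param e_rev reversal potential (mV).
#' @param depression_d per-event availability multiplier in (0, 1]; 1 means
#'   no depression (NMDA is always undepressed).
#' @param tau_recovery recovery time constant of availability (ms).
#' @param mg_block logical; apply the voltage-dependent magnesium block
#'   (NMDA only).
#' @return a `synapse_params` list.
#' @export
synapse_params <- function(receptor = c("AMPA", "NMDA", "GABA_A"),
                           g_peak, tau_rise, tau_decay, e_rev,
                           depression_d = 1, tau_recovery = 1,
                           mg_block = FALSE) {
  receptor <- match.arg(receptor)
  if (tau_decay == tau_rise) stop("degenerate kernel: tau_decay == tau_rise")
  stopifnot(tau_decay > tau_rise, tau_rise > 0, g_peak >= 0,
            depression_d > 0, depression_d <= 1, tau_recovery > 0)
  structure(list(receptor = receptor, g_peak = g_peak, tau_rise = tau_rise,
                 tau_decay = tau_decay, e_rev = e_rev,
                 depression_d = depression_d, tau_recovery = tau_recovery,
                 mg_block = mg_block),
            class = "synapse_params")
}

#' Default synapse parameter sets
#'
#' @param receptor receptor class.
#' @param g_peak peak conductance (nS); defaults per class.
#' @return a [synapse_params()].
#' @export
default_synapse <- function(receptor = c("AMPA", "NMDA", "GABA_A"),
                            g_peak = NULL) {
  receptor <- match.arg(receptor)
  switch(receptor,
    AMPA = synapse_params("AMPA", g_peak = g_peak %||% 6, tau_rise = 0.5,
                          tau_decay = 3, e_rev = 0, depression_d = 0.55,
                          tau_recovery = 40),
    NMDA = synapse_params("NMDA", g_peak = g_peak %||% 2, tau_rise = 5,
                          tau_decay = 80, e_rev = 0, mg_block = TRUE),
    GABA_A = synapse_params("GABA_A", g_peak = g_peak %||% 6, tau_rise = 1,
                            tau_decay = 10, e_rev = -75, depression_d = 0.6,
                            tau_recovery = 50))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dual-exponential post-synaptic conductance kernel
#'
#' `g(t) = A (exp(-t/tau_decay) - exp(-t/tau_rise))`, with `A` chosen so the
#' kernel peaks at `g_peak`.
#'
#' @param t_since_event time since the triggering event (ms), >= 0; vectorised.
#' @param params a [synapse_params()].
#' @return conductance (nS).
#' @export
psc_conductance <- function(t_since_event, params) {
  stopifnot(all(t_since_event >= 0))
  tr <- params$tau_rise; td <- params$tau_decay
  tpk <- tr * td / (td - tr) * log(td / tr)
  a <- params$g_peak / (exp(-tpk / td) - exp(-tpk / tr))
  a * (exp(-t_since_event / td) - exp(-t_since_event / tr))
}

#' Running synapse availability state
#' @param s initial availability in (0, 1].
#' @param last_event_time last event time (ms); `-Inf` before any event.
#' @return a `synapse_state` list.
#' @export
synapse_state <- function(s = 1, last_event_time = -Inf) {
  stopifnot(s > 0, s <= 1)
  list(s = s, last_event_time = last_event_time)
}

#' Apply one synaptic event with interval-dependent depression
#'
#' Availability first recovers over the elapsed interval,
#' `s -> 1 - (1 - s) exp(-dt_ms / tau_recovery)`; the event amplitude is
#' scaled by the recovered value, after which `s` is multiplied by
#' `depression_d`.  NMDA events always scale by 1.
#'
#' @param state a [synapse_state()].
#' @param event_time event time (ms), strictly after the previous event.
#' @param params a [synapse_params()].
#' @return list `(scale, state)`.
#' @export
depression_step <- function(state, event_time, params) {
  if (event_time <= state$last_event_time)
    stop("event times must be strictly increasing")
  if (params$receptor == "NMDA") {
    state$last_event_time <- event_time
    return(list(scale = 1, state = state))
  }
  dt <- event_time - state$last_event_time
  s <- if (is.finite(dt)) 1 - (1 - state$s) * exp(-dt / params$tau_recovery) else 1
  state$s <- s * params$depression_d
  state$last_event_time <- event_time
  list(scale = s, state = state)
}

#' Per-event depression scales for a whole spike train
#'
#' @param times sorted event times (ms).
#' @param params a [synapse_params()].
#' @return numeric vector of amplitude scales in (0, 1].
#' @export
depression_scales <- function(times, params) {
  n <- length(times)
  if (!n) return(numeric(0))
  if (params$receptor == "NMDA" || params$depression_d == 1)
    return(rep(1, n))
  out <- numeric(n)
  st <- synapse_state()
  for (i in seq_len(n)) {
    r <- depression_step(st, times[i], params)
    out[i] <- r$scale
    st <- r$state
  }
  out
}

#' NMDA magnesium-block factor
#'
#' `1 / (1 + ([Mg]/3.57) exp(-0.062 v))`; monotone increasing in `v`.
#'
#' @param v membrane potential (mV); vectorised.
#' @param mg extracellular magnesium (mM).
#' @return unblocked fraction in (0, 1).
#' @export
nmda_block <- function(v, mg = 1) {
  1 / (1 + (mg / 3.57) * exp(-0.062 * v))
}

# Build the (time, class, amplitude) event matrix consumed by the integrator.
# exc_trains / inh_trains: lists of sorted spike-time vectors (ms).
# syn: list with $ampa, $nmda, $gaba synapse_params.
# Depression is per afferent: each train has its own availability.
.syn_event_matrix <- function(exc_trains, inh_trains, syn) {
  rows <- list()
  for (tr in exc_trains) {
    if (!length(tr)) next
    sc <- depression_scales(tr, syn$ampa)
    rows[[length(rows) + 1]] <- cbind(tr, 1, syn$ampa$g_peak * sc)
    rows[[length(rows) + 1]] <- cbind(tr, 2, syn$nmda$g_peak)
  }
  for (tr in inh_trains) {
    if (!length(tr)) next
    sc <- depression_scales(tr, syn$gaba)
    rows[[length(rows) + 1]] <- cbind(tr, 3, syn$gaba$g_peak * sc)
  }
  if (!length(rows)) return(matrix(0, 0, 3))
  m <- do.call(rbind, rows)
  m[order(m[, 1]), , drop = FALSE]
}

.syn_param_matrix <- function(syn) {
  rbind(c(syn$ampa$tau_rise, syn$ampa$tau_decay, syn$ampa$e_rev, 0),
        c(syn$nmda$tau_rise, syn$nmda$tau_decay, syn$nmda$e_rev, 1),
        c(syn$gaba$tau_rise, syn$gaba$tau_decay, syn$gaba$e_rev, 0))
}

#' Total synaptic current at a time point
#'
#' Linear superposition of all event kernels across afferents, with per-event
#' depression scaling and the NMDA magnesium block:
#' `I_syn = g_AMPA (v - 0) + g_NMDA block(v) (v - 0) + g_GABA (v - E_GABA)`.
#' Evaluated directly from the kernel closed form, so it serves as an
#' independent check of the accumulator scheme used by the integrator.
#'
#' @param exc_trains,inh_trains lists of sorted spike-time vectors (ms).
#' @param syn list with `ampa`, `nmda`, `gaba` [synapse_params()].
#' @param v membrane potential (mV).
#' @param t evaluation time (ms).
#' @return current (nA, positive = outward).
#' @export
total_synaptic_current <- function(exc_trains, inh_trains, syn, v, t) {
  gsum <- function(train, params, scales) {
    keep <- train <= t
    if (!any(keep)) return(0)
    sum(psc_conductance(t - train[keep], params) * scales[keep])
  }
  i <- 0
  for (tr in exc_trains) {
    sc <- depression_scales(tr, syn$ampa)
    i <- i + gsum(tr, syn$ampa, sc) * (v - syn$ampa$e_rev) +
      gsum(tr, syn$nmda, rep(1, length(tr))) * nmda_block(v) * (v - syn$nmda$e_rev)
  }
  for (tr in inh_trains) {
    sc <- depression_scales(tr, syn$gaba)
    i <- i + gsum(tr, syn$gaba, sc) * (v - syn$gaba$e_rev)
  }
  i * 1e-3  # nS * mV -> pA -> nA
}
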