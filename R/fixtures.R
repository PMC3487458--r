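#' Deterministic fixtures for testing
#'
#' Analytic spike trains with known vector strength, and a miniature
#' end-to-end scenario small enough for routine test runs.
#'
#' @name fixtures
NULL

#' Deterministic spike train with explicit phases
#'
#' Spike `k` (0-based cycle index) at phase `phi` occurs at
#' `t = (phi / 2 pi + k) / mod_freq` seconds; phases recycle across cycles,
#' so the vector strength of the result is computable in closed form from
#' the phase list alone.
#'
#' @param n number of spikes.
#' @param mod_freq modulation frequency (Hz).
#' @param phases phase values (radians), recycled over cycles.
#' @return sorted spike times (ms).
#' @export
analytic_train <- function(n, mod_freq, phases) {
  stopifnot(n >= 0, mod_freq > 0, length(phases) >= 1)
  if (n == 0) return(numeric(0))
  phi <- rep_len(phases, n)
  k <- seq_len(n) - 1
  sort((phi / (2 * pi) + k) / mod_freq * 1000)
}

#' Miniature end-to-end scenario
#'
#' Two excitatory and two inhibitory afferents, three modulation
#' frequencies, two trials and a 200 ms stimulus: completes in seconds and
#' exercises the full input-synapse-neuron-analysis path.
#'
#' @param seed master seed.
#' @return a [scenario_config()].
#' @export
toy_scenario <- function(seed = 42) {
  mf <- c(16, 32, 64)
  scenario_config(
    "sustained",
    convergence_spec(2, make_preset_tuning("VCN", mod_freqs = mf),
                     2, make_preset_tuning("DNLL_AP", mod_freqs = mf),
                     seed = seed),
    protocol = stimulus_protocol(mod_freqs = mf, duration = 200,
                                 n_trials = 2, pre_stimulus = 200,
                                 bias_target = -60))
}
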