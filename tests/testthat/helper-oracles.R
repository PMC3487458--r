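# Independent oracles used across tests.

# Brute-force vector strength via the complex resultant.
brute_vs <- function(spikes, mod_freq, window = c(50, 750)) {
  s <- spikes[spikes >= window[1] & spikes <= window[2]]
  if (!length(s)) return(list(vs = 0, n = 0L))
  z <- exp(1i * 2 * pi * mod_freq * s / 1000)
  list(vs = Mod(sum(z)) / length(s), n = length(s))
}

# Leak-only neuron for RC closed-form checks.
leak_only <- function(g_leak = 6.849, e_leak = -70, capacitance = 30) {
  neuron_config(capacitance, g_leak, e_leak, channels = list(),
                preset_name = "leak")
}

# A fast toy scenario shared across experiment tests.
toy <- function(seed = 42) toy_scenario(seed)
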