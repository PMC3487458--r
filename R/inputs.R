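#' MTF-shaped afferent spike-train generation
#'
#' Afferent inputs to the IC model are described by a rate MTF (spikes/s per
#' modulation frequency) and a temporal MTF (target vector strength per
#' modulation frequency).  Trains are generated cycle by cycle: the spike
#' count per modulation cycle is Poisson with mean `rate / mod_freq`, and
#' each spike's phase is drawn from a von Mises distribution whose
#' concentration is chosen so the expected resultant length equals the target
#' vector strength.  This construction controls rate and synchrony
#' independently, which is exactly how the afferent classes are specified.
#'
#' Shipped presets: LSO (low-pass rate with corner 64 Hz, low-pass synchrony
#' cutting off at 64 Hz), DCN (shallow monotone-increasing rate, low-pass
#' synchrony), VCN (flat rate, band-pass synchrony tuned to 128 Hz), DNLL
#' (all-pass or high-pass rate, low-pass synchrony) and VNLL (band-pass or
#' high-pass rate, band-pass synchrony peaking between 64 and 128 Hz).
#' Preset curves between the anchors stated above are smooth parametric
#' roll-offs; peak rates for the lemniscal presets are free scale parameters.
#'
#' @name inputs
NULL

#' Default stimulus modulation frequencies (Hz), octave-spaced
#' @export
IC_MOD_FREQS <- 8 * 2^(0:7)

#' Input tuning container
#'
#' @param source afferent class label.
#' @param mod_freqs modulation frequencies (Hz), octave-spaced ascending.
#' @param rate_at firing rate (spikes/s) at each modulation frequency.
#' @param vs_at target vector strength at each modulation frequency, in
#'   `[0, 1)`.
#' @param preferred_phase mean spike phase (radians).
#' @return an `input_tuning` list.
#' @export
input_tuning <- function(source, mod_freqs, rate_at, vs_at,
                         preferred_phase = 0) {
  stopifnot(length(rate_at) == length(mod_freqs),
            length(vs_at) == length(mod_freqs),
            all(rate_at >= 0), all(vs_at >= 0), all(vs_at < 1),
            all(diff(log2(mod_freqs)) > 0))
  structure(list(source = source, mod_freqs = mod_freqs, rate_at = rate_at,
                 vs_at = vs_at, preferred_phase = preferred_phase),
            class = "input_tuning")
}

# Parametric preset curves evaluated on the modulation-frequency grid.
.preset_curves <- function(source, f, bp_center = 32, vnll_shoulder = 40) {
  lf <- log2(f)
  switch(source,
    LSO = list(rate = 20 + 160 / (1 + (f / 96)^3),
               vs = 0.85 * pmin((f / 64)^0.15, 1) / (1 + (f / 100)^4)),
    DCN = list(rate = 85 + 20 * (lf - 3) / 7,
               vs = 0.85 / (1 + (f / 90)^3.5)),
    VCN = list(rate = rep(200, length(f)),
               vs = 0.75 * exp(-(lf - log2(128))^2 / (2 * 1.1^2))),
    DNLL_AP = list(rate = rep(120, length(f)),
                   vs = 0.55 / (1 + (f / 90)^3.5)),
    DNLL_HP = list(rate = 40 + 95 * (f / 128)^2 / (1 + (f / 128)^2),
                   vs = 0.7 / (1 + (f / 90)^3.5)),
    VNLL_BP = list(rate = 15 + 140 * exp(-(lf - log2(bp_center))^2 / (2 * 0.9^2)) +
                     vnll_shoulder / (1 + (f / 90)^3),
                   vs = 0.65 * exp(-(lf - log2(90))^2 / (2 * 1.1^2))),
    VNLL_HP = list(rate = 40 + 95 * (f / 128)^2 / (1 + (f / 128)^2),
                   vs = 0.65 * exp(-(lf - log2(90))^2 / (2 * 1.1^2))),
    stop("unknown input source: ", source))
}

#' Build a preset afferent tuning
#'
#' @param source one of `"LSO"`, `"DCN"`, `"VCN"`, `"DNLL_AP"`, `"DNLL_HP"`,
#'   `"VNLL_BP"`, `"VNLL_HP"`.
#' @param mod_freqs modulation-frequency grid (Hz).
#' @param bp_center centre (Hz) of the VNLL band-pass rate curve; may lie off
#'   the stimulus grid.
#' @param rate_scale multiplier applied to the rate curve.
#' @param vnll_shoulder low-frequency shoulder rate (spikes/s) of the VNLL
#'   band-pass curve, modelling the residual low-modulation-frequency
#'   response of VNLL units; rolls off above about 90 Hz.
#' @return an [input_tuning()].
#' @export
make_preset_tuning <- function(source, mod_freqs = IC_MOD_FREQS,
                               bp_center = 32, rate_scale = 1,
                               vnll_shoulder = 40) {
  cv <- .preset_curves(source, mod_freqs, bp_center, vnll_shoulder)
  input_tuning(source, mod_freqs, cv$rate * rate_scale, pmin(cv$vs, 0.95))
}

#' Build a user-defined excitatory/inhibitory tuning shape
#'
#' Normalized rate curves of low-pass, band-pass or all-pass shape, scaled by
#' `peak_rate`; the temporal MTF is copied from a preset template (LSO-like
#' low-pass synchrony by default, matching how the generalized shapes are
#' defined).
#'
#' @param rate_shape `"LP"`, `"BP"` or `"AP"`.
#' @param rbmf band-pass best modulation frequency (Hz); must be interior to
#'   the grid.
#' @param corner low-pass corner frequency (Hz); rates stay at or above 0.75
#'   of peak up to `corner` and fall below it above.
#' @param sync_template `"LSO"`, `"DNLL_AP"` or `"VNLL_BP"`; source of the
#'   vector-strength curve.
#' @param peak_rate peak firing rate (spikes/s).
#' @param mod_freqs modulation-frequency grid (Hz).
#' @param bp_center centre for a `"VNLL_BP"` sync template (Hz).
#' @return an [input_tuning()].
#' @export
user_defined_tuning <- function(rate_shape = c("LP", "BP", "AP"),
                                rbmf = NULL, corner = NULL,
                                sync_template = "LSO", peak_rate = 150,
                                mod_freqs = IC_MOD_FREQS, bp_center = 32) {
  rate_shape <- match.arg(rate_shape)
  lf <- log2(mod_freqs)
  norm <- switch(rate_shape,
    AP = rep(1, length(mod_freqs)),
    LP = {
      if (is.null(corner) || !(corner %in% mod_freqs))
        stop("LP shape requires a corner frequency on the stimulus grid")
      1 / (1 + (mod_freqs / (2.2 * corner))^2.5)
    },
    BP = {
      if (is.null(rbmf) || !(rbmf %in% mod_freqs[-c(1, length(mod_freqs))]))
        stop("BP shape requires an interior rBMF on the stimulus grid")
      exp(-(lf - log2(rbmf))^2 / (2 * 0.75^2))
    })
  cv <- .preset_curves(sync_template, mod_freqs, bp_center)
  input_tuning(paste0("user_", rate_shape), mod_freqs, peak_rate * norm,
               pmin(cv$vs, 0.95))
}

#' Von Mises concentration for a target vector strength
#'
#' Solves `I1(kappa)/I0(kappa) = target_vs` (the mean resultant length of a
#' von Mises distribution) by root finding.
#'
#' @param target_vs target vector strength in `[0, 0.99]`; larger values are
#'   capped at 0.99 with a warning.
#' @return concentration `kappa >= 0`.
#' @export
kappa_for_vs <- function(target_vs) {
  stopifnot(target_vs >= 0)
  if (target_vs >= 0.99) {
    if (target_vs > 0.99) warning("target vector strength capped at 0.99")
    target_vs <- 0.99
  }
  if (target_vs < 1e-12) return(0)
  ratio <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) ratio(k) - target_vs, c(1e-8, 500),
                 tol = 1e-6)$root
}

#' Draw von Mises phases
#'
#' Best-Fisher rejection sampler; falls back to the uniform distribution for
#' `kappa` near 0.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, >= 0.
#' @return phases in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- (mu + sign(u3[ok] - 0.5) * acos(f[ok])) %% (2 * pi)
    out <- c(out, th)
  }
  out[seq_len(n)]
}

# Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Generate one afferent spike train
#'
#' @param tuning an [input_tuning()].
#' @param mod_freq stimulus modulation frequency (Hz); must be on the tuning
#'   grid.
#' @param duration stimulus duration (ms).
#' @param seed integer seed; identical seeds reproduce the train exactly.
#' @return sorted spike times (ms) in `[0, duration]`.
#' @export
generate_train <- function(tuning, mod_freq, duration, seed = NULL) {
  idx <- match(mod_freq, tuning$mod_freqs)
  if (is.na(idx)) stop("mod_freq not on the tuning grid")
  rate <- tuning$rate_at[idx]
  if (rate == 0) return(numeric(0))
  kappa <- kappa_for_vs(tuning$vs_at[idx])
  gen <- function() {
    n_cyc <- ceiling(duration / 1000 * mod_freq)
    counts <- stats::rpois(n_cyc, rate / mod_freq)
    n <- sum(counts)
    if (n == 0) return(numeric(0))
    phases <- rvonmises(n, tuning$preferred_phase, kappa)
    cyc <- rep(seq_len(n_cyc) - 1, counts)
    tms <- (cyc + phases / (2 * pi)) / mod_freq * 1000
    sort(tms[tms <= duration])
  }
  if (is.null(seed)) gen() else .with_seed(seed, gen())
}

#' Convergence pattern of excitatory and inhibitory afferents
#'
#' @param n_exc,n_inh afferent counts, >= 0.  In vitro estimates place total
#'   convergence at 1-10 functional inputs; counts outside that range warn.
#' @param exc_tuning,inh_tuning [input_tuning()] objects.
#' @param seed master integer seed; per-afferent, per-trial streams are
#'   derived deterministically from it.
#' @return a `convergence_spec` list.
#' @export
convergence_spec <- function(n_exc, exc_tuning, n_inh, inh_tuning,
                             seed = 1) {
  stopifnot(n_exc >= 0, n_inh >= 0)
  if (n_exc + n_inh > 10 || n_exc + n_inh < 1)
    warning("total afferent count outside the plausible 1-10 range")
  structure(list(n_exc = n_exc, exc_tuning = exc_tuning, n_inh = n_inh,
                 inh_tuning = inh_tuning, seed = as.integer(seed)),
            class = "convergence_spec")
}

.derive_seed <- function(master, trial, afferent) {
  ((as.double(master) * 2654435 + trial * 97561 + afferent * 1013) %%
     2147483562) + 1
}

#' Generate all afferent trains for one trial
#'
#' Excitatory and inhibitory trains are statistically independent; every
#' (seed, trial, afferent) triple maps to its own reproducible stream, and
#' inhibitory afferents use an offset index block so no stream is shared.
#'
#' @param spec a [convergence_spec()].
#' @param mod_freq modulation frequency (Hz).
#' @param duration stimulus duration (ms).
#' @param trial trial index (integer).
#' @return list with elements `exc` and `inh`, each a list of spike-time
#'   vectors (ms).
#' @export
generate_convergent_set <- function(spec, mod_freq, duration, trial = 1) {
  fidx <- match(mod_freq, spec$exc_tuning$mod_freqs)
  exc <- lapply(seq_len(spec$n_exc), function(i)
    generate_train(spec$exc_tuning, mod_freq, duration,
                   seed = .derive_seed(spec$seed + fidx * 7919, trial, i)))
  inh <- lapply(seq_len(spec$n_inh), function(i)
    generate_train(spec$inh_tuning, mod_freq, duration,
                   seed = .derive_seed(spec$seed + fidx * 7919, trial, 1000 + i)))
  list(exc = exc, inh = inh)
}
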