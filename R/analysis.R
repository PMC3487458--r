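#' Vector strength, Rayleigh significance and MTF shape classification
#'
#' Synchrony is quantified by the vector strength
#' `VS = (1/n) sqrt(sum(cos(phi))^2 + sum(sin(phi))^2)` over the spike phases
#' relative to the modulation cycle, with significance assessed by the
#' Rayleigh statistic `2 n VS^2 > 13.8` (p < 0.001).  Rate MTF shapes are
#' classified from the normalized rate curve with thresholds 0.75 and 2/3,
#' temporal MTFs from the significant vector-strength curve.
#'
#' @name analysis
NULL

#' Rayleigh significance threshold (p < 0.001)
#' @export
RAYLEIGH_CRIT <- 13.8

#' Vector strength of a spike train
#'
#' Phases are `2 pi mod_freq t` (mod 2 pi) with `t` in seconds; spikes
#' outside the analysis window are ignored.  An empty set has VS 0 with
#' n = 0.
#'
#' @param spikes spike times (ms).
#' @param mod_freq modulation frequency (Hz), > 0.
#' @param window analysis window `c(from, to)` in ms; defaults to 50 ms
#'   after stimulus onset through 750 ms.
#' @return list `(vs, n)`.
#' @export
vector_strength <- function(spikes, mod_freq, window = c(50, 750)) {
  stopifnot(mod_freq > 0)
  s <- spikes[spikes >= window[1] & spikes <= window[2]]
  n <- length(s)
  if (n == 0) return(list(vs = 0, n = 0L))
  phi <- 2 * pi * mod_freq * s / 1000
  list(vs = sqrt(sum(cos(phi))^2 + sum(sin(phi))^2) / n, n = n)
}

#' Rayleigh statistic
#'
#' @param vs vector strength.
#' @param n spike count.
#' @return `2 n vs^2`; compare against [RAYLEIGH_CRIT].
#' @export
rayleigh_stat <- function(vs, n) 2 * n * vs^2

#' Normalize a rate MTF to its maximum
#'
#' The rate at the best modulation frequency (rBMF) becomes 1; ties for the
#' maximum resolve toward the lower modulation frequency.
#'
#' @param mean_rates mean rates per ascending modulation frequency.
#' @return list `(normalized, rbmf_index)`.
#' @export
normalize_rates <- function(mean_rates) {
  m <- max(mean_rates)
  if (m <= 0) stop("all-zero rate MTF: shape undefined")
  list(normalized = mean_rates / m, rbmf_index = which.max(mean_rates))
}

#' Classify a normalized rate MTF shape
#'
#' Rules, evaluated in order BR, BP, LP, HP, AP (first match): band-reject
#' requires a contiguous run below 2/3 strictly inside the range flanked on
#' both sides by values at or above 0.75; band-pass drops below 0.75 on both
#' sides of the maximum; low-pass on the high side alone; high-pass on the
#' low side alone; all-pass never drops below 0.75.  Anything else is
#' complex.
#'
#' @param normalized normalized rates per ascending modulation frequency
#'   (length >= 3).
#' @return one of `"BR"`, `"BP"`, `"LP"`, `"HP"`, `"AP"`, `"complex"`.
#' @export
classify_rmtf <- function(normalized) {
  x <- normalized
  k <- length(x)
  stopifnot(k >= 3)
  # band-reject: interior sub-2/3 run with >= 0.75 recovery on both flanks
  low <- which(x < 2 / 3)
  if (length(low)) {
    runs <- split(low, cumsum(c(1, diff(low) != 1)))
    for (r in runs) {
      if (r[1] > 1 && r[length(r)] < k &&
          any(x[seq_len(r[1] - 1)] >= 0.75) &&
          any(x[seq(r[length(r)] + 1, k)] >= 0.75))
        return("BR")
    }
  }
  imax <- which.max(x)
  low_drop <- imax > 1 && any(x[seq_len(imax - 1)] < 0.75)
  high_drop <- imax < k && any(x[seq(imax + 1, k)] < 0.75)
  if (low_drop && high_drop) return("BP")
  if (high_drop) return("LP")
  if (low_drop) return("HP")
  if (!low_drop && !high_drop) return("AP")
  "complex"
}

#' Classify a temporal MTF and extract tBMF and Fmax
#'
#' tBMF is the modulation frequency with the greatest vector strength among
#' significantly synchronized frequencies (ties resolve toward the lower
#' frequency); Fmax is the highest significantly synchronized frequency.
#' The tMTF is low-pass when the lowest tested frequency is significant and
#' is itself the tBMF, band-pass otherwise; with no significant frequency
#' all three are `NA`.
#'
#' @param vs vector strengths per ascending modulation frequency.
#' @param significant logical Rayleigh flags, same length.
#' @param mod_freqs modulation frequencies (Hz).
#' @return list `(label, tbmf, fmax)`; `label` is `"LP"`, `"BP"` or `NA`.
#' @export
classify_tmtf <- function(vs, significant, mod_freqs) {
  if (!any(significant))
    return(list(label = NA_character_, tbmf = NA_real_, fmax = NA_real_))
  sig_f <- mod_freqs[significant]
  sig_vs <- vs[significant]
  tbmf <- sig_f[which.max(sig_vs)]
  fmax <- max(sig_f)
  label <- if (significant[1] && tbmf == mod_freqs[1]) "LP" else "BP"
  list(label = label, tbmf = tbmf, fmax = fmax)
}

#' Build a modulation transfer function from spike trains
#'
#' Mean rate and its SD are computed across trials over the full stimulus
#' duration; vector strength and the Rayleigh statistic are computed on the
#' spikes pooled across trials within the analysis window (50 ms after onset
#' through stimulus end).  The response is flagged `"onset"` when at least
#' 80% of all spikes fall within the first 50 ms.
#'
#' @param trials_by_freq list (one element per modulation frequency) of
#'   lists of per-trial spike-time vectors (ms, relative to stimulus onset).
#' @param mod_freqs modulation frequencies (Hz).
#' @param duration stimulus duration (ms).
#' @param window synchrony analysis window (ms).
#' @return an `mtf_result` list with per-frequency vectors (`mean_rate`,
#'   `rate_sd`, `vs`, `n`, `rayleigh`, `significant`) and derived summaries
#'   (`rbmf`, `tbmf`, `fmax`, `rate_shape`, `sync_shape`, `response_mode`).
#' @export
build_mtf <- function(trials_by_freq, mod_freqs = IC_MOD_FREQS,
                      duration = 750, window = c(50, duration)) {
  stopifnot(length(trials_by_freq) == length(mod_freqs))
  nf <- length(mod_freqs)
  mean_rate <- rate_sd <- vs <- ray <- numeric(nf)
  n <- integer(nf)
  early <- total <- 0
  for (i in seq_len(nf)) {
    trials <- trials_by_freq[[i]]
    counts <- vapply(trials, function(s) sum(s >= 0 & s <= duration), numeric(1))
    rates <- counts / (duration / 1000)
    mean_rate[i] <- mean(rates)
    rate_sd[i] <- stats::sd(rates)
    pooled <- sort(unlist(trials))
    early <- early + sum(pooled < 50)
    total <- total + length(pooled)
    r <- vector_strength(pooled, mod_freqs[i], window)
    vs[i] <- r$vs
    n[i] <- r$n
    ray[i] <- rayleigh_stat(r$vs, r$n)
  }
  significant <- ray > RAYLEIGH_CRIT
  if (max(mean_rate) > 0) {
    nr <- normalize_rates(mean_rate)
    rbmf <- mod_freqs[nr$rbmf_index]
    rate_shape <- if (nf >= 3) classify_rmtf(nr$normalized) else NA_character_
  } else {
    rbmf <- NA_real_
    rate_shape <- NA_character_
  }
  tm <- classify_tmtf(vs, significant, mod_freqs)
  structure(list(mod_freqs = mod_freqs, mean_rate = mean_rate,
                 rate_sd = rate_sd, vs = vs, n = n, rayleigh = ray,
                 significant = significant, rbmf = rbmf, tbmf = tm$tbmf,
                 fmax = tm$fmax, rate_shape = rate_shape,
                 sync_shape = tm$label,
                 response_mode = if (total > 0 && early / total >= 0.8)
                   "onset" else "sustained"),
            class = "mtf_result")
}

#' Read spike-time tables for the analysis stack
#'
#' Accepts a CSV with columns `trial` and `t_ms` (one file per modulation
#' frequency) so the MTF analysis can run on external recordings.
#'
#' @param paths character vector of CSV paths, one per modulation frequency.
#' @param mod_freqs modulation frequencies (Hz) matching `paths`.
#' @param n_trials trial count (trials absent from a file count as empty).
#' @param ... passed to [build_mtf()].
#' @return an `mtf_result`.
#' @export
mtf_from_csv <- function(paths, mod_freqs, n_trials = 10, ...) {
  stopifnot(length(paths) == length(mod_freqs))
  trials_by_freq <- lapply(paths, function(p) {
    d <- utils::read.csv(p)
    stopifnot(all(c("trial", "t_ms") %in% names(d)))
    lapply(seq_len(n_trials), function(tr) sort(d$t_ms[d$trial == tr]))
  })
  build_mtf(trials_by_freq, mod_freqs, ...)
}

#' @export
print.mtf_result <- function(x, ...) {
  cat("MTF result:", length(x$mod_freqs), "modulation frequencies\n")
  cat(sprintf("  rate shape %s (rBMF %s Hz), sync shape %s (tBMF %s, Fmax %s Hz), %s\n",
              x$rate_shape, format(x$rbmf), x$sync_shape, format(x$tbmf),
              format(x$fmax), x$response_mode))
  df <- data.frame(mod_freq = x$mod_freqs,
                   rate = round(x$mean_rate, 1), sd = round(x$rate_sd, 1),
                   vs = round(x$vs, 3), rayleigh = round(x$rayleigh, 1),
                   sig = x$significant)
  print(df, row.names = FALSE)
  invisible(x)
}
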