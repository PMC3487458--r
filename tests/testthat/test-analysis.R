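test_that("vector strength matches analytic cases and the uniform null", {
  # all spikes at the same phase
  tr <- analytic_train(20, 16, phases = 0.7)
  expect_equal(vector_strength(tr, 16, c(0, 2000))$vs, 1, tolerance = 1e-9)
  # phases 0 and 90 degrees -> sqrt(2)/2
  tr2 <- analytic_train(40, 16, phases = c(0, pi / 2))
  expect_equal(vector_strength(tr2, 16, c(0, 4000))$vs, sqrt(2) / 2,
               tolerance = 1e-9)
  # uniform phases -> VS near zero
  set.seed(1)
  u <- sort(runif(1e5, 0, 1e6))
  expect_lt(vector_strength(u, 16, c(0, 1e6))$vs, 0.01)
  # empty set
  r <- vector_strength(numeric(0), 16)
  expect_equal(r$vs, 0); expect_equal(r$n, 0L)
})

test_that("VS is invariant to shifts by whole modulation periods", {
  set.seed(2)
  s <- sort(runif(300, 50, 750))
  for (f in c(8, 64, 512)) {
    v1 <- vector_strength(s, f, c(0, 4000))$vs
    v2 <- vector_strength(s + 5 * 1000 / f, f, c(0, 4000))$vs
    expect_equal(v1, v2, tolerance = 1e-9)
  }
})

test_that("Rayleigh statistic and significance threshold", {
  expect_equal(rayleigh_stat(0.6, 25), 18)
  expect_gt(rayleigh_stat(0.6, 25), RAYLEIGH_CRIT)
  expect_equal(rayleigh_stat(0, 0), 0)
  expect_equal(rayleigh_stat(0.26, 100), 13.52)
  expect_lt(rayleigh_stat(0.26, 100), RAYLEIGH_CRIT)   # below the 13.8 bar
})

test_that("rate normalization scales to the maximum with low-freq ties", {
  r <- normalize_rates(c(10, 20, 5))
  expect_equal(r$normalized, c(0.5, 1, 0.25))
  expect_equal(r$rbmf_index, 2)
  expect_equal(normalize_rates(c(3, 3, 3))$normalized, rep(1, 3))
  expect_equal(normalize_rates(c(5, 8, 8))$rbmf_index, 2)  # tie -> lower
  expect_error(normalize_rates(c(0, 0, 0)), "all-zero")
})

test_that("rate-shape classification follows the 0.75 and 2/3 rules", {
  expect_equal(classify_rmtf(c(1, 0.9, 0.7, 0.5, 0.4, 0.3, 0.2)), "LP")
  expect_equal(classify_rmtf(c(0.5, 0.8, 1, 0.7, 0.4)), "BP")
  expect_equal(classify_rmtf(c(1, 0.9, 0.6, 0.5, 0.8, 0.9)), "BR")
  expect_equal(classify_rmtf(c(0.4, 0.5, 0.8, 0.9, 1)), "HP")
  expect_equal(classify_rmtf(c(0.9, 0.95, 1, 0.9, 0.8)), "AP")
  # BR honors the 2/3 threshold exactly: 0.67 stays, 0.66 rejects
  expect_equal(classify_rmtf(c(1, 0.9, 0.66, 0.9, 1)), "BR")
  expect_equal(classify_rmtf(c(1, 0.9, 0.67, 0.9, 1)), "LP")
  # dips below 0.75 but not 2/3 on both sides of the max -> BP
  expect_equal(classify_rmtf(c(0.7, 1, 0.7)), "BP")
  # sub-2/3 run touching the edge is not band-reject
  expect_equal(classify_rmtf(c(0.5, 0.6, 0.8, 0.9, 1)), "HP")
  expect_true(is.character(classify_rmtf(c(1, 0.9, 0.8))))
})

test_that("temporal classification extracts tBMF and Fmax", {
  f3 <- c(8, 16, 32)
  r <- classify_tmtf(c(0.8, 0.6, 0.3), rep(TRUE, 3), f3)
  expect_equal(r, list(label = "LP", tbmf = 8, fmax = 32))
  r2 <- classify_tmtf(c(0.3, 0.7, 0.4), rep(TRUE, 3), f3)
  expect_equal(r2$label, "BP"); expect_equal(r2$tbmf, 16)
  r3 <- classify_tmtf(c(0.3, 0.7, 0.4), rep(FALSE, 3), f3)
  expect_true(is.na(r3$label) && is.na(r3$tbmf) && is.na(r3$fmax))
  # insignificant frequencies are excluded from tBMF/Fmax
  r4 <- classify_tmtf(c(0.5, 0.4, 0.9), c(TRUE, TRUE, FALSE), f3)
  expect_equal(r4$tbmf, 8); expect_equal(r4$fmax, 16)
})

test_that("build_mtf pools trials for synchrony and averages rates", {
  f3 <- c(8, 16, 32)
  tr <- analytic_train(100, 16, phases = 0.5)
  trials <- list(list(tr, tr), list(tr, tr), list(tr, tr))
  m <- build_mtf(trials, f3, duration = 750)
  expect_equal(m$rate_sd, rep(0, 3))                   # duplicate trials
  n16 <- sum(tr >= 50 & tr <= 750) * 2
  expect_equal(m$n[2], n16)                            # pooled count
  expect_equal(m$vs[2], 1, tolerance = 1e-9)
  # zero-spike input
  m0 <- build_mtf(list(list(numeric(0)), list(numeric(0)), list(numeric(0))),
                  f3)
  expect_equal(m0$mean_rate, rep(0, 3))
  expect_true(is.na(m0$rate_shape) && is.na(m0$sync_shape))
  # Rayleigh invariant to merging trials: same pooled spikes, any split
  sp <- analytic_train(60, 8, phases = c(0.2, 1.1))
  a <- build_mtf(list(list(sp), list(numeric(0)), list(numeric(0))), f3)
  b <- build_mtf(list(list(sp[c(TRUE, FALSE)], sp[c(FALSE, TRUE)]),
                      list(numeric(0)), list(numeric(0))), f3)
  expect_equal(a$rayleigh[1], b$rayleigh[1], tolerance = 1e-9)
})

test_that("onset responses are flagged from the first 50 ms", {
  f3 <- c(8, 16, 32)
  onset_trial <- c(seq(2, 40, by = 2), 300)            # 20 of 21 early
  m <- build_mtf(list(list(onset_trial), list(onset_trial),
                      list(onset_trial)), f3)
  expect_equal(m$response_mode, "onset")
  sust <- seq(10, 740, by = 10)
  m2 <- build_mtf(list(list(sust), list(sust), list(sust)), f3)
  expect_equal(m2$response_mode, "sustained")
})

test_that("the analysis stack runs on spike-time CSV tables", {
  f2 <- c(16, 32)
  paths <- replicate(2, tempfile(fileext = ".csv"))
  on.exit(unlink(paths))
  for (i in 1:2) {
    tr <- analytic_train(80, f2[i], phases = c(0.3, 0.9))
    utils::write.csv(data.frame(trial = rep(1:2, length.out = length(tr)),
                                t_ms = tr), paths[i], row.names = FALSE)
  }
  m <- mtf_from_csv(paths, f2, n_trials = 2)
  expect_s3_class(m, "mtf_result")
  expect_gt(m$vs[1], 0.9)
})
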