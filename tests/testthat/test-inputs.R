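test_that("preset tuning curves honor their anchors", {
  vcn <- make_preset_tuning("VCN")
  expect_equal(vcn$mod_freqs[which.max(vcn$vs_at)], 128)
  expect_lt(max(vcn$rate_at) - min(vcn$rate_at), 0.1 * mean(vcn$rate_at))

  lso <- make_preset_tuning("LSO")
  expect_lt(lso$rate_at[lso$mod_freqs == 512], 0.75 * max(lso$rate_at))
  # synchrony carries through 64 Hz but not beyond (at typical single-train n)
  n_typ <- lso$rate_at * 0.75
  sig <- rayleigh_stat(lso$vs_at, n_typ) > RAYLEIGH_CRIT
  expect_true(all(sig[lso$mod_freqs <= 64]))
  expect_false(any(sig[lso$mod_freqs >= 128]))

  dcn <- make_preset_tuning("DCN")
  expect_true(all(diff(dcn$rate_at) > 0))                 # monotone increasing
  expect_lt(diff(range(dcn$rate_at)), 0.5 * mean(dcn$rate_at))  # small range

  hp <- make_preset_tuning("DNLL_HP")
  expect_equal(classify_rmtf(hp$rate_at / max(hp$rate_at)), "HP")
  ap <- make_preset_tuning("DNLL_AP")
  expect_equal(classify_rmtf(ap$rate_at / max(ap$rate_at)), "AP")

  vb <- make_preset_tuning("VNLL_BP", bp_center = 32, vnll_shoulder = 10)
  expect_equal(vb$mod_freqs[which.max(vb$rate_at)], 32)
  pk <- vb$mod_freqs[which.max(vb$vs_at)]
  expect_true(pk >= 64 && pk <= 128)                      # BP synchrony
  expect_error(make_preset_tuning("MSO"), "unknown input source")
})

test_that("user-defined rate shapes classify as requested", {
  bp <- user_defined_tuning("BP", rbmf = 32)
  expect_equal(classify_rmtf(bp$rate_at / max(bp$rate_at)), "BP")
  expect_equal(bp$mod_freqs[which.max(bp$rate_at)], 32)
  ap <- user_defined_tuning("AP")
  expect_true(all(ap$rate_at / max(ap$rate_at) >= 0.75))
  lp <- user_defined_tuning("LP", corner = 32)
  norm <- lp$rate_at / max(lp$rate_at)
  expect_true(all(norm[lp$mod_freqs <= 32] >= 0.75))
  expect_true(all(norm[lp$mod_freqs > 32] < 0.75))
  expect_error(user_defined_tuning("BP", rbmf = 8), "interior")
  expect_error(user_defined_tuning("LP", corner = 48), "grid")
})

test_that("kappa_for_vs inverts the Bessel ratio", {
  expect_equal(kappa_for_vs(0), 0)
  k3 <- kappa_for_vs(0.3); k6 <- kappa_for_vs(0.6); k9 <- kappa_for_vs(0.9)
  expect_true(k3 < k6 && k6 < k9)
  for (v in c(0.3, 0.6, 0.9)) {
    k <- kappa_for_vs(v)
    expect_equal(besselI(k, 1, TRUE) / besselI(k, 0, TRUE), v,
                 tolerance = 1e-5)
  }
  expect_warning(kappa_for_vs(0.999), "capped")
})

test_that("von Mises sampler delivers the target resultant length", {
  set.seed(99)
  k <- kappa_for_vs(0.5)
  th <- rvonmises(1e6, 0, k)
  emp <- Mod(sum(exp(1i * th))) / length(th)
  expect_equal(emp, 0.5, tolerance = 0.002)
  # uniform limit
  th0 <- rvonmises(1e5, 0, 0)
  expect_lt(Mod(sum(exp(1i * th0))) / length(th0), 0.01)
})

test_that("generate_train recovers rate and synchrony targets", {
  tun <- input_tuning("test", IC_MOD_FREQS, rep(60, 8),
                      c(0.8, rep(0.5, 7)))
  expect_length(generate_train(input_tuning("z", IC_MOD_FREQS, rep(0, 8),
                                            rep(0, 8)), 8, 750, seed = 1), 0)
  counts <- vapply(1:200, function(i)
    length(generate_train(tun, 16, 750, seed = i)), numeric(1))
  expect_lt(abs(mean(counts) - 45), 3 * sqrt(45 / 200))  # 3 SE of the mean
  # vs target 0 -> mean VS near 0 across trains
  tun0 <- input_tuning("u", IC_MOD_FREQS, rep(100, 8), rep(0, 8))
  pooled <- sort(unlist(lapply(1:100, function(i)
    generate_train(tun0, 16, 750, seed = i))))
  expect_lt(brute_vs(pooled, 16, c(0, 750))$vs, 0.05)
  expect_error(generate_train(tun, 24, 750), "grid")
})

test_that("convergent sets are reproducible, distinct and independent", {
  spec <- convergence_spec(2, make_preset_tuning("VCN"),
                           4, make_preset_tuning("DNLL_HP"), seed = 5)
  a <- generate_convergent_set(spec, 16, 750, trial = 1)
  b <- generate_convergent_set(spec, 16, 750, trial = 1)
  expect_identical(a, b)                                 # same seed+trial
  expect_length(a$exc, 2); expect_length(a$inh, 4)
  trains <- c(a$exc, a$inh)
  for (i in seq_along(trains)) for (j in seq_len(i - 1))
    expect_false(identical(trains[[i]], trains[[j]]))    # pairwise distinct
  c2 <- generate_convergent_set(spec, 16, 750, trial = 2)
  expect_false(identical(a$exc[[1]], c2$exc[[1]]))       # trials differ
  spec0 <- convergence_spec(2, make_preset_tuning("VCN"), 0,
                            make_preset_tuning("DNLL_HP"), seed = 5)
  expect_length(generate_convergent_set(spec0, 16, 750, 1)$inh, 0)
})

test_that("excitatory and inhibitory trains are uncorrelated", {
  spec <- convergence_spec(1, make_preset_tuning("VCN"),
                           1, make_preset_tuning("DNLL_AP"), seed = 9)
  # cross-correlogram at zero lag vs shuffled, pooled over trials
  near <- 0; tot <- 0
  for (tr in 1:20) {
    s <- generate_convergent_set(spec, 8, 750, tr)
    e <- s$exc[[1]]; i <- s$inh[[1]]
    if (!length(e) || !length(i)) next
    d <- outer(e, i, "-")
    near <- near + sum(abs(d) < 1)
    tot <- tot + length(e) * length(i)
  }
  p_near <- near / tot
  expect_lt(abs(p_near - 2 / 750), 0.35 * 2 / 750)
})

test_that("generate_train leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_train(make_preset_tuning("VCN"), 16, 750, seed = 4))
  expect_identical(.Random.seed, before)
})
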