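test_that("scalp coupling index is 1 for duplicated wavelength signals", {
  n <- 600; rate <- 10
  t <- (0:(n - 1)) / rate
  card <- 0.02 * sin(2 * pi * 1.2 * t)
  geom <- toy_geometry(1)
  intens <- array(1, dim = c(2, 2, n))
  for (w in 1:2) intens[1, w, ] <- exp(-card)   # identical cardiac both wl
  set.seed(4)
  for (w in 1:2) intens[2, w, ] <- exp(rnorm(n, 0, 0.01))  # independent
  raw <- raw_fnirs(intens, rate, geom)
  res <- scalp_coupling_index(raw)
  expect_equal(unname(res$sci[1]), 1, tolerance = 1e-6)
  expect_true(res$mask$valid[1])
  expect_lt(abs(res$sci[2]), 0.4)
  expect_false(res$mask$valid[2])
  expect_match(res$mask$reason[2], "SCI")
})

test_that("SCI boundary is strict (exactly at threshold is valid) and zero-variance channels are flagged", {
  n <- 600; rate <- 10
  t <- (0:(n - 1)) / rate
  geom <- toy_geometry(1)
  intens <- array(1, dim = c(2, 2, n))
  set.seed(9)
  for (w in 1:2) intens[1, w, ] <- exp(-0.02 * sin(2 * pi * 1.2 * t) -
                                         rnorm(n, 0, 0.01))
  raw <- raw_fnirs(intens, rate, geom)
  sci1 <- scalp_coupling_index(raw)$sci[1]
  # a threshold set exactly to the channel's SCI keeps the channel valid
  res <- scalp_coupling_index(raw, threshold = unname(sci1))
  expect_true(res$mask$valid[1])
  # constant channel: SCI undefined -> invalid with reason
  expect_false(res$mask$valid[2])
  expect_match(res$mask$reason[2], "undefined")
})

test_that("SCI is invariant to per-wavelength affine intensity rescaling", {
  sched <- toy_schedule(rep("standard", 30))
  raw <- simulate_fnirs(sched, participant_profile(),
                        noise_model(bad_channel_fraction_fnirs = 0,
                                    motion_spike_rate = 0,
                                    motion_shift_rate = 0), seed = 8)
  s1 <- scalp_coupling_index(raw)$sci
  raw2 <- raw
  raw2$intensities[, 1, ] <- raw2$intensities[, 1, ] * 3.7
  raw2$intensities[, 2, ] <- raw2$intensities[, 2, ] * 0.2
  s2 <- scalp_coupling_index(raw2)$sci
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("the hand-built 2x2 Beer-Lambert system inverts correctly", {
  # epsilon [[1,2],[3,1]], d*DPF = 1, dOD = (5,5) -> concentrations (1, 2) mM
  geom <- data.frame(channel = "L1", source = "s", detector = "d",
                     separation_mm = 10, is_short = FALSE,
                     short_pair = NA, region = "toy",
                     stringsAsFactors = FALSE)
  params <- mbll_params(geom, extinction = rbind(c(1, 2), c(3, 1)),
                        dpf = c(1, 1))
  od <- structure(list(od = array(5, dim = c(1, 2, 4)), rate = 10,
                       geometry = geom, wavelengths = c(760, 850)),
                  class = "optical_density")
  hemo <- mbll(od, params)
  expect_equal(hemo$hbo[1, ], rep(1000, 4))  # 1 mM in uM
  expect_equal(hemo$hbr[1, ], rep(2000, 4))
  # zero optical density -> zero concentrations
  od0 <- od; od0$od[] <- 0
  h0 <- mbll(od0, params)
  expect_true(all(h0$hbo == 0) && all(h0$hbr == 0))
  # linearity: doubling dOD doubles both chromophores
  od2 <- od; od2$od <- od$od * 2
  h2 <- mbll(od2, params)
  expect_equal(h2$hbo, hemo$hbo * 2)
  expect_equal(h2$hbr, hemo$hbr * 2)
  expect_error(mbll_params(geom, extinction = rbind(c(1, 2), c(2, 4)),
                           dpf = c(1, 1)), "condition")
})

test_that("forward model and MBLL are exact inverses on noise-free signals", {
  n <- 400
  t <- (0:(n - 1)) / 10
  hrf <- hrf_double_gamma(t, 9)
  hbo <- rbind(1.0 * hrf, 0.5 * hrf, 0 * hrf)
  raw <- toy_raw_fnirs(hbo)
  hemo <- mbll(optical_density(raw))
  for (c in 1:3) {
    rec <- hemo$hbo[c, ] - mean(hemo$hbo[c, ])
    tru <- hbo[c, ] - mean(hbo[c, ])
    expect_lt(max(abs(rec - tru)) / max(1e-30, max(abs(tru))), 1e-9)
    rec_r <- hemo$hbr[c, ] - mean(hemo$hbr[c, ])
    tru_r <- -tru / 3
    expect_lt(max(abs(rec_r - tru_r)), 1e-9)
  }
})

test_that("motion correction removes spikes and steps but preserves smooth signals", {
  n <- 1200; rate <- 10
  t <- (0:(n - 1)) / rate
  smooth <- 0.05 * hrf_double_gamma(((t * 2) %% 40) / 2 + 0.001, 9) +
    0.02 * sin(2 * pi * 0.05 * t)
  geom <- toy_geometry(1)
  od <- structure(list(od = aperm(array(smooth, dim = c(n, 2, 2)), c(2, 3, 1)),
                       rate = rate, geometry = geom,
                       wavelengths = c(760, 850)), class = "optical_density")
  clean <- motion_correct(od)
  expect_gt(stats::cor(clean$od[1, 1, ], smooth), 0.99)

  # injected step of 10x the signal SD
  s <- stats::sd(smooth)
  stepped <- od
  stepped$od[1, 1, 600:n] <- stepped$od[1, 1, 600:n] + 10 * s
  cs <- motion_correct(stepped)
  jump_before <- abs(mean(stepped$od[1, 1, 601:650]) -
                       mean(stepped$od[1, 1, 550:599]))
  jump_after <- abs(mean(cs$od[1, 1, 601:650]) - mean(cs$od[1, 1, 550:599]))
  expect_lt(jump_after, 0.1 * jump_before)

  # injected single-sample spike of 20x the signal SD
  spiked <- od
  spiked$od[1, 1, 700] <- spiked$od[1, 1, 700] + 20 * s
  csp <- motion_correct(spiked)
  resid <- abs(csp$od[1, 1, 700] - smooth[700])
  expect_lt(resid, 0.1 * 20 * s)
})

test_that("the physiological low-pass meets its frequency specifications", {
  n <- 6000; rate <- 10
  t <- (0:(n - 1)) / rate
  mk_hemo <- function(x) structure(list(hbo = matrix(x, 1),
                                        hbr = matrix(x, 1), rate = rate),
                                   class = "hemo_timeseries")
  mid <- 2000:4000
  dc <- lowpass_physiological(mk_hemo(rep(2, n)))
  expect_equal(dc$hbo[1, mid], rep(2, length(mid)), tolerance = 1e-9)
  g_card <- max(abs(lowpass_physiological(
    mk_hemo(sin(2 * pi * 1.2 * t)))$hbo[1, mid]))
  expect_gte(-20 * log10(g_card), 20)
  g_resp <- max(abs(lowpass_physiological(
    mk_hemo(sin(2 * pi * 0.25 * t)))$hbo[1, mid]))
  expect_gte(-20 * log10(g_resp), 20)
  g_slow <- max(abs(lowpass_physiological(
    mk_hemo(sin(2 * pi * 0.01 * t)))$hbo[1, mid]))
  expect_gte(g_slow, 0.95); expect_lte(g_slow, 1.05)
  expect_error(lowpass_physiological(mk_hemo(rep(1, 100))), "filter lengths")
})

test_that("short-channel regression removes scalp components", {
  n <- 2000
  set.seed(21)
  short_sig <- as.numeric(stats::filter(rnorm(n), rep(1, 20) / 20,
                                        circular = TRUE))
  geom <- toy_geometry(3)
  mk <- function(l1, l2, l3, s) structure(
    list(hbo = rbind(l1, l2, l3, s), hbr = rbind(l1, l2, l3, s) * -0.3,
         rate = 10, geometry = geom), class = "hemo_timeseries")
  neural <- sin(2 * pi * 0.02 * (1:n) / 10)
  neural <- neural - mean(neural)
  sh <- short_sig - mean(short_sig)
  sh <- sh - sum(sh * neural) / sum(neural^2) * neural  # orthogonalize
  uncorr <- rnorm(n)

  hemo <- mk(0.8 * sh, neural + 0.8 * sh, uncorr, sh)
  out <- short_channel_regression(hemo)
  expect_equal(nrow(out$hbo), 3)
  # long = 0.8 * short exactly -> residual ~ 0
  expect_lt(sqrt(mean(out$hbo[1, ]^2)) / sqrt(mean(hemo$hbo[1, ]^2)), 1e-9)
  # orthogonal mixture -> neural recovered
  expect_gt(stats::cor(out$hbo[2, ], neural), 0.99)
  # uncorrelated long channel passes through nearly unchanged
  expect_gt(stats::cor(out$hbo[3, ], uncorr), 0.999)

  # OLS property: residual variance never exceeds the intercept-only fit
  for (ch in 1:3) {
    expect_lte(stats::var(out$hbo[ch, ]),
               stats::var(hemo$hbo[ch, ]) * (1 + 1e-12))
  }

  # all short channels invalid -> pass-through with warning
  bad_mask <- data.frame(channel = "S1", valid = FALSE, reason = "SCI")
  expect_warning(out2 <- short_channel_regression(hemo, bad_mask), "skipped")
  expect_equal(out2$hbo, hemo$hbo[1:3, ])
  expect_true(out2$scr_skipped)
})

test_that("HbO epoching baseline-corrects and finds the response peak", {
  # constant signal -> all-zero epochs
  geom <- toy_geometry(1)
  hemo <- structure(list(hbo = matrix(5, 2, 600), hbr = matrix(0, 2, 600),
                         rate = 10, geometry = geom),
                    class = "hemo_timeseries")
  ev <- data.frame(onset = c(10, 20), class = c("target", "standard"))
  ep <- epoch_hbo(hemo, ev)
  expect_equal(dim(ep$target$mean)[2], round(21 * 10) + 1)  # 211 samples
  expect_true(all(abs(ep$target$mean) < 1e-12))

  # synthetic HRF peaking at 9 s recovered within +-1 s
  n <- 1200
  t <- (0:(n - 1)) / 10
  onsets <- c(20, 50, 80)
  sig <- numeric(n)
  for (o in onsets) {
    idx <- round(o * 10) + 1
    len <- min(n - idx + 1, 400)
    sig[idx:(idx + len - 1)] <- sig[idx:(idx + len - 1)] +
      0.2 * hrf_double_gamma((0:(len - 1)) / 10, 9)
  }
  hemo2 <- structure(list(hbo = rbind(sig, sig * 0), hbr = matrix(0, 2, n),
                          rate = 10, geometry = geom),
                     class = "hemo_timeseries")
  ev2 <- data.frame(onset = onsets, class = "target")
  ep2 <- epoch_hbo(hemo2, ev2)
  pk_t <- ep2$times[which.max(ep2$target$mean[1, ])]
  expect_lt(abs(pk_t - 9), 1)
  # events too close to the recording end are dropped with a warning
  ev3 <- rbind(ev2, data.frame(onset = 115, class = "target"))
  expect_warning(ep3 <- epoch_hbo(hemo2, ev3), "dropped")
  expect_equal(ep3$target$n_events, 3)
})
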