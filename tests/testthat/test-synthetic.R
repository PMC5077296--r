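test_that("waveform generation is deterministic and validates sampling", {
  prm <- waveform_gen_params(shoulder_amp = 0.1, noise_sd = 0.05)
  w1 <- gen_waveform(prm, seed = 9)
  w2 <- gen_waveform(prm, seed = 9)
  expect_identical(w1$samples, w2$samples)
  w3 <- gen_waveform(prm, seed = 10)
  expect_false(identical(w1$samples, w3$samples))
  expect_true(w1$meta$ground_truth_shoulder)
  expect_equal(max(w1$samples), 1)
  # too-coarse sampling over the template support errors
  expect_error(gen_waveform(waveform_gen_params(dt_ms = 1, t_pre_ms = 2,
                                                t_post_ms = 2)),
               "16 samples")
})

test_that("noiseless templates without a bump repolarize monotonically", {
  for (w_rise in c(0.25, 0.3, 0.4)) {
    wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0,
                                           w_rise_ms = w_rise))
    x <- wf$samples
    p <- which.max(x)
    off <- p + which(x[p:length(x)] <= 0.1)[1] - 1
    expect_true(all(diff(x[p:off]) < 0))
  }
})

test_that("generator ground truth agrees with the detector on a grid", {
  for (s in seq(0, 0.3, by = 0.02)) {
    prm <- waveform_gen_params(shoulder_amp = s)
    det <- detect_shoulder(gen_waveform(prm))$detected
    orc <- shoulder_oracle(prm)$detected
    expect_equal(det, orc, info = paste("amplitude", s))
  }
})

test_that("a zero-rate session is a valid silent recording", {
  ses <- gen_session(field_gen_params(peak_rate_hz = 0, baseline_rate_hz = 0,
                                      duration_s = 300), seed = 2)
  expect_length(ses$spikes$times, 0)
  expect_equal(classify_activity(ses$spikes), "silent")
})

test_that("sessions are deterministic, in-bounds, with midpoint LEDs", {
  prm <- field_gen_params(duration_s = 120)
  s1 <- gen_session(prm, seed = 5)
  s2 <- gen_session(prm, seed = 5)
  expect_identical(s1$tracking$pos_xy, s2$tracking$pos_xy)
  expect_identical(s1$spikes$times, s2$spikes$times)
  pos <- s1$tracking$pos_xy
  expect_true(all(pos[, 1] >= 0 & pos[, 1] <= 70))
  expect_true(all(pos[, 2] >= 0 & pos[, 2] <= 70))
  mid <- (s1$tracking$led1_xy + s1$tracking$led2_xy) / 2
  expect_equal(mid, pos, tolerance = 1e-12)
  # LED separation is the 3.5 cm head stage geometry
  d <- sqrt(rowSums((s1$tracking$led1_xy - s1$tracking$led2_xy)^2))
  expect_equal(max(abs(d - 3.5)), 0, tolerance = 1e-9)
})

test_that("O-maze sessions stay on the annulus", {
  ar <- arena("o_maze")
  ses <- gen_session(field_gen_params(arena = ar, duration_s = 120,
                                      field_center_cm = c(35, 45)), seed = 8)
  ctr <- c(ar$width_cm / 2, ar$height_cm / 2)
  r <- sqrt(rowSums(sweep(ses$tracking$pos_xy, 2, ctr)^2))
  r_out <- min(ar$width_cm, ar$height_cm) / 2
  expect_true(all(r <= r_out + 1e-6))
  expect_true(all(r >= r_out - ar$path_width_cm - 1e-6))
})

test_that("spike counts are Poisson-consistent with the path intensity", {
  # observed total spike count across sessions vs integral of lambda along
  # the simulated path
  tot_obs <- 0
  tot_exp <- 0
  for (seed in 1:40) {
    ses <- gen_session(field_gen_params(duration_s = 60, peak_rate_hz = 4,
                                        baseline_rate_hz = 0.2), seed = seed)
    pos <- ses$tracking$pos_xy
    d2 <- (pos[, 1] - 35)^2 + (pos[, 2] - 35)^2
    lam <- 0.2 + 4 * exp(-d2 / (2 * 8^2))
    dt <- diff(ses$tracking$t)
    tot_exp <- tot_exp + sum(lam[-1] * dt)
    tot_obs <- tot_obs + length(ses$spikes$times)
  }
  expect_lt(abs(tot_obs - tot_exp), 4 * sqrt(tot_exp))
})

test_that("per-bin spike mass matches the thinning intensity", {
  # spikes within 10 cm of the field center, pooled over repetitions
  in_obs <- 0; in_exp <- 0; n_tot <- 0
  for (seed in 1:40) {
    ses <- gen_session(field_gen_params(duration_s = 60, peak_rate_hz = 4,
                                        baseline_rate_hz = 0.2), seed = seed)
    tt <- ses$tracking$t
    pos <- ses$tracking$pos_xy
    if (!length(ses$spikes$times)) next
    ix <- findInterval(ses$spikes$times, tt)
    d_spk <- sqrt((pos[ix, 1] - 35)^2 + (pos[ix, 2] - 35)^2)
    in_obs <- in_obs + sum(d_spk <= 10)
    d2 <- (pos[, 1] - 35)^2 + (pos[, 2] - 35)^2
    lam <- 0.2 + 4 * exp(-d2 / (2 * 8^2))
    dt <- c(diff(tt), median(diff(tt)))
    in_exp <- in_exp + sum((lam * dt)[sqrt(d2) <= 10])
    n_tot <- n_tot + length(ses$spikes$times)
  }
  expect_lt(abs(in_obs - in_exp), 4 * sqrt(in_exp))
})

test_that("morphology cohorts respect the feature invariants", {
  coh <- gen_morph_cohort(morph_gen_params("active"),
                          morph_gen_params("silent"), 8, seed = 31)
  expect_length(coh$trees, 16)
  expect_equal(as.character(unique(coh$labels)), c("silent", "active"))
  X <- coh$features
  expect_true(all(X[, "n_primary"] >= 1 & X[, "n_primary"] <= 4))
  expect_true(all(X[, "n_endings"] >= X[, "n_primary"]))
  order_sum <- rowSums(X[, paste0("order", 1:7)])
  expect_true(all(order_sum <= X[, "total_length"] + 1e-6))
  # determinism
  coh2 <- gen_morph_cohort(morph_gen_params("active"),
                           morph_gen_params("silent"), 8, seed = 31)
  expect_identical(coh$features, coh2$features)
})

test_that("the configured effect moves the targeted order means", {
  pa <- morph_gen_params("active", effect_size = 2, effect_orders = 5)
  ps <- morph_gen_params("silent")
  coh <- gen_morph_cohort(pa, ps, 25, seed = 12)
  a5 <- coh$features[coh$labels == "active", "order5"]
  s5 <- coh$features[coh$labels == "silent", "order5"]
  # a 2-SD shift must separate by clearly more than 1 pooled SD
  pooled <- sqrt((var(a5) + var(s5)) / 2)
  expect_gt((mean(a5) - mean(s5)) / pooled, 1)
  # untargeted orders stay put (within sampling noise)
  a2 <- coh$features[coh$labels == "active", "order2"]
  s2 <- coh$features[coh$labels == "silent", "order2"]
  expect_lt(abs(mean(a2) - mean(s2)) / sd(s2), 1)
})
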