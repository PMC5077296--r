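test_that("average_spikes normalizes and averages pointwise", {
  tmpl <- waveform_template_fun(waveform_gen_params())
  t <- seq(-1.5, 4, by = 1 / 40)
  v <- tmpl(t)
  # single snippet is returned normalized
  one <- average_spikes(matrix(3 * v, nrow = 1), dt_ms = 1 / 40)
  expect_equal(max(one$samples), 1)
  expect_equal(one$samples, v / max(v))
  # two identical snippets equal one
  two <- average_spikes(rbind(v, v), dt_ms = 1 / 40)
  expect_equal(two$samples, one$samples)
  # arithmetic oracle: mean of x and (2*peakshape - x) is peakshape
  x <- v + 0.1 * sin(t)
  avg <- average_spikes(rbind(x, 2 * v - x), dt_ms = 1 / 40)
  expect_equal(avg$samples, v / max(v), tolerance = 1e-12)
  expect_error(average_spikes(list(v, v[-1]), dt_ms = 1 / 40), "length")
})

test_that("spike half-width matches closed forms and is stable to resampling", {
  # symmetric triangle of base 1 ms -> width at half max 0.5 ms
  dt <- 1 / 40
  t <- seq(-1, 1, by = dt)
  tri <- pmax(0, 1 - abs(t) / 0.5) + 1e-9  # base 1 ms
  expect_equal(spike_width(waveform(tri, dt)), 0.5, tolerance = 1e-3)

  # Gaussian of sigma 0.2 ms -> 2*sigma*sqrt(2 ln 2)
  g <- exp(-t^2 / (2 * 0.2^2))
  expect_equal(spike_width(waveform(g, dt)), 2 * 0.2 * sqrt(2 * log(2)),
               tolerance = 1e-3)

  # upsampling x4 changes the result by < 2%
  t4 <- seq(-1, 1, by = dt / 4)
  g4 <- exp(-t4^2 / (2 * 0.2^2))
  w1 <- spike_width(waveform(g, dt))
  w4 <- spike_width(waveform(g4, dt / 4))
  expect_lt(abs(w4 - w1) / w1, 0.02)

  # error when the half-max is never crossed
  expect_error(spike_width(waveform(g[t > -0.05], dt)), "half-maximum")
})

test_that("monotone noiseless repolarization yields no shoulder", {
  wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0))
  res <- detect_shoulder(wf)
  expect_false(res$detected)
  expect_true(is.na(res$intersection_latency_ms))
  expect_true(is.na(res$shoulder_width_ms))
})

test_that("shoulder detection matches the dense-grid oracle", {
  prm <- waveform_gen_params(shoulder_amp = 0.15)
  res <- detect_shoulder(gen_waveform(prm))
  orc <- shoulder_oracle(prm)
  expect_true(res$detected)
  expect_true(orc$detected)
  expect_lt(abs(res$intersection_latency_ms - orc$latency_ms), 0.1)
  # latency close to the true bump delay
  expect_lt(abs(res$intersection_latency_ms - prm$shoulder_delay_ms), 0.1)
  expect_gt(res$shoulder_width_ms, 0)
})

test_that("detection is a step in amplitude and width is non-decreasing", {
  grid <- seq(0, 0.3, by = 0.02)
  res <- lapply(grid, function(s) {
    detect_shoulder(gen_waveform(waveform_gen_params(shoulder_amp = s)))
  })
  det <- vapply(res, `[[`, logical(1), "detected")
  # step function: false below a threshold, true above
  expect_true(all(diff(det) >= 0))
  expect_false(det[1])
  expect_true(det[length(det)])
  w <- vapply(res[det], `[[`, numeric(1), "shoulder_width_ms")
  expect_true(all(diff(w) >= -1e-9))
})

test_that("detect_shoulder is invariant under positive amplitude scaling", {
  wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0.12))
  r1 <- detect_shoulder(wf)
  r2 <- detect_shoulder(waveform(wf$samples * 37.5, wf$dt_ms))
  expect_equal(r1$detected, r2$detected)
  expect_equal(r1$intersection_latency_ms, r2$intersection_latency_ms,
               tolerance = 1e-9)
  expect_equal(r1$shoulder_width_ms, r2$shoulder_width_ms, tolerance = 1e-9)
  expect_equal(r1$spike_width_ms, r2$spike_width_ms, tolerance = 1e-9)
})

test_that("results are stable across 20-50 kHz sampling", {
  for (s in c(0, 0.15)) {
    r20 <- detect_shoulder(gen_waveform(
      waveform_gen_params(dt_ms = 1 / 20, shoulder_amp = s)))
    r50 <- detect_shoulder(gen_waveform(
      waveform_gen_params(dt_ms = 1 / 50, shoulder_amp = s)))
    expect_equal(r20$detected, r50$detected)
    expect_lt(abs(r20$spike_width_ms - r50$spike_width_ms), 0.05)
    if (r20$detected) {
      expect_lt(abs(r20$intersection_latency_ms - r50$intersection_latency_ms),
                0.05)
      expect_lt(abs(r20$shoulder_width_ms - r50$shoulder_width_ms), 0.05)
    }
  }
})

test_that("detect_shoulder rejects degenerate traces", {
  expect_error(detect_shoulder(waveform(rep(1, 32), 1 / 40)), "flat")
  # trace truncated before reaching the 10% offset (but > 0.5 ms after peak)
  wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0))
  p <- which.max(wf$samples)
  cut <- waveform(wf$samples[1:(p + 21)], wf$dt_ms)
  expect_gt(min(cut$samples[p:length(cut$samples)]), 0.1)
  expect_error(detect_shoulder(cut), "truncated")
  # too little tail after the peak is a different failure
  short <- waveform(wf$samples[1:(p + 10)], wf$dt_ms)
  expect_error(detect_shoulder(short), "0.5 ms")
})

test_that("spike/shoulder width correlation behaves at the extremes", {
  mk <- function(sw, shw) {
    structure(list(detected = TRUE, intersection_latency_ms = 0.3,
                   shoulder_width_ms = shw, spike_width_ms = sw),
              class = "shoulder_result")
  }
  # exact proportionality -> r = 1, 3 collinear points are enough
  res <- lapply(c(0.3, 0.5, 0.9), function(s) mk(s, 2 * s))
  ct <- shoulder_width_correlation(res)
  expect_equal(ct$r, 1, tolerance = 1e-12)
  expect_true(is.finite(ct$p))
  expect_equal(ct$slope, 2, tolerance = 1e-9)
  # zero variance errors
  expect_error(shoulder_width_correlation(lapply(1:4, function(i) mk(0.4, i / 10))),
               "variance")
  expect_error(shoulder_width_correlation(res[1:2]), "3")
  # independent widths: |r| < 0.3 in the vast majority of runs (n = 100)
  set.seed(123)
  hits <- sum(vapply(1:50, function(k) {
    rr <- lapply(1:100, function(i) mk(runif(1), runif(1)))
    abs(shoulder_width_correlation(rr)$r) < 0.3
  }, logical(1)))
  expect_gte(hits, 45)
})

test_that("shoulder variability comparison is calibrated under the null", {
  # identical generators for "identified" and "classified" cells: the
  # Mann-Whitney p on shoulder widths must not be systematically small
  set.seed(21)
  ps <- replicate(40, {
    widths <- function(seeds) {
      vapply(seeds, function(sd0) {
        wf <- gen_waveform(waveform_gen_params(shoulder_amp = 0.2,
                                               noise_sd = 0.02), seed = sd0)
        detect_shoulder(wf)$shoulder_width_ms
      }, numeric(1))
    }
    a <- widths(sample.int(1e6, 6))
    b <- widths(sample.int(1e6, 8))
    mannwhitney_2s(a, b)$p
  })
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps), 0.3)
})
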