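cfg <- run_config()

test_that("speed is zero for a stationary animal and exact for linear motion", {
  ar <- arena("square")
  tt <- seq(0, 10, by = 0.04)
  still <- tracking_data(tt, cbind(rep(35, length(tt)), rep(35, length(tt))),
                         NULL, arena = ar)
  expect_equal(max(abs(compute_speed(still, cfg))), 0)

  # constant velocity 10 cm/s along x
  x <- pmin(5 + 10 * tt, 69)
  lin <- tracking_data(tt, cbind(x, rep(35, length(tt))), NULL, arena = ar)
  sp <- compute_speed(lin, cfg)
  interior <- 20:120
  expect_equal(unname(sp[interior]), rep(10, length(interior)),
               tolerance = 1e-9)

  # fast sinusoidal jitter (period << 600 ms) is smoothed away
  jit <- tracking_data(tt, cbind(35 + sin(2 * pi * tt / 0.08),
                                 rep(35, length(tt))), NULL, arena = ar)
  spj <- compute_speed(jit, cfg)
  expect_lt(max(abs(spj[interior])), 0.5)
})

test_that("rate at a single occupied pixel equals n/T (kernel cancels)", {
  ar <- arena("square")
  tt <- seq(0, 100, by = 0.04)
  tr <- tracking_data(tt, cbind(rep(36, length(tt)), rep(36, length(tt))),
                      NULL, arena = ar)
  spk <- spike_train(seq(0.5, 99.5, length.out = 50), 0, 100)
  map <- compute_rate_map(tr, spk, cfg, speed_filter = FALSE)
  px <- c(floor(36 / 2.5) + 1, floor(36 / 2.5) + 1)
  expect_equal(map$r[px[1], px[2]], 50 / map$occupancy_s, tolerance = 1e-9)
  # zero spikes -> zero rate on all valid pixels
  map0 <- compute_rate_map(tr, spike_train(numeric(0), 0, 100), cfg,
                           speed_filter = FALSE)
  expect_true(all(map0$r[map0$valid_mask] == 0))
})

test_that("coverage counts raw visited pixels against the arena", {
  ar <- arena("square")
  # raster over the full arena
  gx <- rep(seq(1.25, 68.75, by = 2.5), each = 28)
  gy <- rep(seq(1.25, 68.75, by = 2.5), times = 28)
  tt <- seq_along(gx) * 0.04
  tr <- tracking_data(tt, cbind(gx, gy), NULL, arena = ar)
  map <- compute_rate_map(tr, spike_train(numeric(0), 0, max(tt)), cfg,
                          speed_filter = FALSE)
  expect_equal(spatial_coverage(map), 1.0)
  # quarter-arena raster
  q <- gx < 35 & gy < 35
  trq <- tracking_data(tt[q] - min(tt[q]) + 0.04, cbind(gx[q], gy[q]), NULL,
                       arena = ar)
  mapq <- compute_rate_map(trq, spike_train(numeric(0), 0, 60), cfg,
                           speed_filter = FALSE)
  expect_equal(spatial_coverage(mapq), 0.25, tolerance = 0.04)
})

test_that("field segmentation follows the 20%-of-peak / 12-pixel rule", {
  # uniform rate over 100 valid pixels: a single field covering all of them
  r <- matrix(NA_real_, 10, 10)
  valid <- matrix(TRUE, 10, 10)
  r[valid] <- 2
  map <- fake_rate_map(r, valid = valid)
  f <- detect_fields(map, cfg)
  expect_length(f, 1)
  expect_equal(f[[1]]$area_pixels, 100)

  # an 11-pixel suprathreshold blob is below the area rule
  r2 <- matrix(0.01, 10, 10)
  blob <- cbind(rep(3:5, times = 4)[1:11], rep(3:6, each = 3)[1:11])
  r2[blob] <- 5
  f2 <- detect_fields(fake_rate_map(r2), cfg)
  expect_length(f2, 0)
  # one more pixel crosses the boundary
  r2[6, 6] <- 5
  f2b <- detect_fields(fake_rate_map(r2), cfg)
  expect_length(f2b, 1)
  expect_equal(f2b[[1]]$area_pixels, 12)

  # two bumps separated by a subthreshold trough are two fields
  r3 <- matrix(0, 20, 10)
  r3[2:5, 2:5] <- 4
  r3[14:17, 2:5] <- 5
  f3 <- detect_fields(fake_rate_map(r3), cfg)
  expect_length(f3, 2)
})

test_that("selectivity uses the strict 20%-of-visited rule", {
  r <- matrix(0, 20, 15)          # 300 visited pixels
  r[3:7, 3:5] <- 5                # one 15-pixel field
  map <- fake_rate_map(r)
  f <- detect_fields(map, cfg)
  expect_length(f, 1)
  expect_true(classify_selectivity(map, f, cfg))
  # a field covering the whole arena is not selective
  ru <- matrix(1, 10, 10)
  mapu <- fake_rate_map(ru)
  expect_false(classify_selectivity(mapu, detect_fields(mapu, cfg), cfg))
  # fields totalling exactly 20% fail the strict inequality
  r20 <- matrix(0, 20, 15)
  r20[1:12, 1:5] <- 5             # 60 pixels of 300 = 20%
  map20 <- fake_rate_map(r20)
  f20 <- detect_fields(map20, cfg)
  expect_equal(sum(vapply(f20, `[[`, numeric(1), "area_pixels")), 60)
  expect_false(classify_selectivity(map20, f20, cfg))
})

test_that("inclusion criteria are enforced with strict inequalities", {
  r <- matrix(1, 28, 28)
  visited <- matrix(FALSE, 28, 28)
  visited[1:28, 1:18] <- TRUE      # coverage 18/28 = 0.64
  map_low <- fake_rate_map(r, visited = visited)
  spk <- spike_train(seq(1, 599, length.out = 100), 0, 600)
  expect_equal(inclusion_check(map_low, spk, cfg)$reason, "coverage")

  map_ok <- fake_rate_map(r)
  expect_true(inclusion_check(map_ok, spk, cfg)$included)
  # 24 spikes fail the strict > 25 rule, as do exactly 25
  spk24 <- spike_train(seq(1, 599, length.out = 24), 0, 600)
  expect_equal(inclusion_check(map_ok, spk24, cfg)$reason, "n_spikes")
  # 60 spikes in 600 s = exactly 0.1 Hz fails the strict rate rule
  spk60 <- spike_train(seq(1, 599, length.out = 60), 0, 600)
  expect_equal(inclusion_check(map_ok, spk60, cfg)$reason, "rate")
  # O-maze uses laps, not coverage
  omap <- fake_rate_map(r)
  omap$arena <- arena("o_maze")
  expect_equal(inclusion_check(omap, spk, cfg, laps = 1.5)$reason, "laps")
  expect_true(inclusion_check(omap, spk, cfg, laps = 2.4)$included)
  expect_error(inclusion_check(omap, spk, cfg), "lap")
})

test_that("lap counting unwraps the angular position", {
  ar <- arena("o_maze")
  th <- seq(0, 2 * pi * 2.5, length.out = 2000)  # 2.5 revolutions
  r0 <- 18
  tr <- tracking_data(seq_along(th) * 0.04,
                      cbind(35 + r0 * cos(th), 25 + r0 * sin(th)), NULL,
                      arena = ar)
  expect_equal(count_laps(tr), 2.5, tolerance = 0.01)
})

test_that("spatial information matches closed forms and a direct oracle", {
  # uniform rate -> 0 bits
  expect_equal(spatial_information(fake_rate_map(matrix(3, 6, 6))), 0)
  # equal occupancy over N pixels, firing in one -> log2(N) bits/spike
  for (N in c(4, 16)) {
    side <- sqrt(N)
    r <- matrix(0, side, side)
    r[1, 1] <- 7
    expect_equal(spatial_information(fake_rate_map(r)), log2(N))
  }
  # random map agrees with independent direct summation
  set.seed(5)
  r <- matrix(rexp(400), 20, 20)
  z <- matrix(runif(400, 0.1, 2), 20, 20)
  map <- fake_rate_map(r, z = z)
  expect_equal(spatial_information(map), si_oracle(map), tolerance = 1e-12)
  # zero mean rate errors
  expect_error(spatial_information(fake_rate_map(matrix(0, 4, 4))), "rate")
})

test_that("ISI histogram and autocorrelogram capture train structure", {
  expect_error(isi_histogram(spike_train(1, 0, 2)), "2 spikes")
  two <- spike_train(c(0.1000, 0.1052), 0, 1)
  h <- isi_histogram(two, bin_ms = 1, max_ms = 20)
  expect_equal(sum(h$counts), 1)
  expect_equal(h$mid_ms[which(h$counts == 1)], 5.5)

  reg <- spike_train(seq(0.125, 20, by = 0.125), 0, 21)
  hr <- isi_histogram(reg, bin_ms = 5, max_ms = 300)
  expect_equal(sum(hr$counts > 0), 1)         # all mass in one bin
  expect_equal(sum(hr$counts), length(reg$times) - 1)

  ac <- spike_autocorrelogram(reg, bin_ms = 5, max_lag_ms = 300)
  expect_equal(ac$counts, rev(ac$counts))      # symmetric
  pos <- ac$counts[ac$lag_ms > 0]
  lag_pos <- ac$lag_ms[ac$lag_ms > 0]
  top <- lag_pos[order(pos, decreasing = TRUE)][1:2]
  expect_true(all(abs(((top + 2.5) %% 125)) < 5))  # peaks at ~125 ms multiples

  # Poisson train: mean ISI recovers the rate
  set.seed(9)
  n <- 2000
  isis <- rexp(n, rate = 8)
  pt <- spike_train(cumsum(isis), 0, sum(isis) + 1)
  est <- 1 / mean(diff(pt$times))
  expect_lt(abs(est - 8), 4 * 8 / sqrt(n))
  # and its autocorrelogram is flat within sampling error
  acp <- spike_autocorrelogram(pt, bin_ms = 20, max_lag_ms = 400)
  posc <- acp$counts[acp$lag_ms > 0]
  expect_lt(max(abs(posc - mean(posc))) / mean(posc), 0.25)
})

test_that("raising the speed threshold never increases occupancy", {
  ses <- gen_session(field_gen_params(duration_s = 180), seed = 4)
  occ <- vapply(c(0.5, 1, 2, 4), function(th) {
    compute_rate_map(ses$tracking, ses$spikes,
                     run_config(speed_thresh_cm_s = th))$occupancy_s
  }, numeric(1))
  expect_true(all(diff(occ) <= 1e-9))
})

test_that("a simulated field session is recovered end to end", {
  ses <- gen_session(field_gen_params(field_center_cm = c(45, 25)), seed = 3)
  rep <- spatial_report(ses$tracking, ses$spikes, cfg)
  expect_true(rep$included)
  expect_equal(rep$n_fields, 1)
  expect_true(rep$selective)
  f <- rep$fields[[1]]
  expect_lt(sqrt(sum((f$center_cm - c(45, 25))^2)), 5)
  expect_gt(rep$in_field_rate, rep$out_field_rate)
  expect_gt(rep$spatial_info_bits_per_spike, 0.5)
})
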