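test_that("trace extraction reproduces the planted trace shape", {
  # static spot, zero noise: constant trace equal to the planted flux
  p <- make_preset("fusion_noSyn",
    overrides = list(n_docked = 5, n_events = 0L,
                     optics = list(field_size_px = 128L),
                     noise = list(background = 0, shot_noise = FALSE,
                                  read_noise_sd = 0)))
  m <- render_movie(p, seed = 21)
  gt <- ground_truth(m)
  tr <- extract_trace(m, gt$x[1], gt$y[1])
  expect_lt(diff(range(tr$intensity)) / mean(tr$intensity), 1e-3)
  expect_equal(mean(tr$intensity), 12000, tolerance = 0.02)

  # fused spot, zero noise: extracted trace proportional to the planted one
  pf <- make_preset("fusion_noSyn",
    overrides = list(n_docked = 5, n_events = 5L,
                     optics = list(field_size_px = 128L),
                     noise = list(background = 0, shot_noise = FALSE,
                                  read_noise_sd = 0)))
  mf <- render_movie(pf, seed = 22)
  gf <- ground_truth(mf)
  i <- which(gf$fused)[1]
  trf <- extract_trace(mf, gf$x[i], gf$y[i])
  planted <- vesiclekit:::trace_levels(pf, gf$baseline[i], TRUE, gf$t_event_s[i])
  ratio <- trf$intensity / planted
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)

  # empty region: fluctuations at the noise level only
  pb <- small_fusion_preset(n_docked = 0, n_events = 0L)
  mb <- render_movie(pb, seed = 23)
  trb <- extract_trace(mb, 128, 128)
  expect_lt(abs(mean(trb$intensity)), 5 * sd(trb$intensity))

  # border spot refused by name
  expect_error(extract_trace(mb, 2, 128, spot_id = "edge"), "edge")
})

test_that("robust trace noise estimation resists steps", {
  expect_equal(estimate_noise_sigma(rep(5, 50)), 0)
  set.seed(24)
  x <- rnorm(1e4)
  expect_lt(abs(estimate_noise_sigma(x) - 1), 0.05)
  step <- c(rep(10, 25), rep(1000, 25))
  expect_equal(estimate_noise_sigma(step), 0)
})

test_that("detect_step finds noiseless steps exactly and nothing in constants", {
  p <- make_preset("fusion_noSyn",
                   overrides = list(noise = list(shot_noise = FALSE,
                                                 read_noise_sd = 0)))
  expect_null(detect_step(synth_trace(p, fused = FALSE)))
  ev <- detect_step(synth_trace(p, fused = TRUE, event_time = 25))
  expect_equal(ev$t_event_s, 25)
  expect_equal(ev$step_ratio, 2.0, tolerance = 1e-12)
})

test_that("step detection meets the recall/false-rate contract at signal-to-noise 10", {
  p <- make_preset("fusion_noSyn")
  # trace-level signal-to-noise ~ step size over per-frame sigma; scale the
  # baseline down so the Poisson noise puts the step at ~10 sigma
  b <- 100   # step = b, sigma ~ sqrt(1.5 b) ~ 12 -> SNR ~ 8-12
  set.seed(25)
  hits <- 0; within1 <- 0
  for (r in 1:500) {
    t_ev <- runif(1, 2, 48)
    tr <- synth_trace(p, fused = TRUE, event_time = t_ev, baseline = b)
    ev <- detect_step(tr)
    if (!is.null(ev)) {
      hits <- hits + 1
      if (abs(ev$t_event_s - ceiling(t_ev)) <= 1) within1 <- within1 + 1
    }
  }
  expect_gte(hits / 500, 0.99)
  expect_gte(within1 / max(hits, 1), 0.99)

  false_ev <- 0
  for (r in 1:500) {
    tr <- synth_trace(p, fused = FALSE, baseline = b)
    if (!is.null(detect_step(tr))) false_ev <- false_ev + 1
  }
  expect_lte(false_ev / 500, 0.01)
})

test_that("sub-dequenching crosstalk steps are rejected", {
  # a significant upward step of only ~20% (crosstalk from a fusing
  # neighbour) must not count as a content-mixing event
  v <- c(rep(1000, 25), rep(1200, 31))
  tr <- tibble::tibble(spot_id = 1L, frame = seq_along(v) - 1L,
                       t_s = seq_along(v) - 6, intensity = v + rnorm(56, 0, 5))
  set.seed(26)
  expect_null(detect_step(tr))
  # the same step passes with the ratio floor disabled
  expect_false(is.null(detect_step(tr, min_ratio = 1)))
})

test_that("post-synchronization aligns each field of view on its first event", {
  ev <- tibble::tibble(fov_id = c("a", "a", "a"), t_event_s = c(12, 15, 20))
  expect_equal(synchronize_events(ev)$t_sync_s, c(0, 3, 8))

  ev2 <- tibble::tibble(fov_id = c("a", "a", "b", "b"),
                        t_event_s = c(5, 6, 30, 31))
  expect_equal(synchronize_events(ev2)$t_sync_s, c(0, 1, 0, 1))

  ev3 <- tibble::tibble(fov_id = "c", t_event_s = 17)
  expect_equal(synchronize_events(ev3)$t_sync_s, 0)

  # idempotence
  s1 <- synchronize_events(ev2)
  s2 <- synchronize_events(dplyr::mutate(s1, t_event_s = t_sync_s))
  expect_equal(s2$t_sync_s, s1$t_sync_s)
})

test_that("histograms are self-normalized 1-s bins over the 50-s window", {
  h <- build_histogram(c(0.0, 0.2, 3.4), n_docked = 10)
  expect_equal(h$bins$prob[1], 2 / 3)
  expect_equal(h$bins$prob[4], 1 / 3)
  expect_equal(sum(h$bins$prob), 1)
  expect_equal(nrow(h$bins), 50)
  expect_message(h2 <- build_histogram(c(1, 55)), "dropped")
  expect_equal(h2$n_events, 1)

  # sampled histogram matches the law bin-wise within 3 binomial SEs
  p <- make_preset("fusion_noSyn")
  set.seed(27)
  tt <- sample_event_times(p, 1e5)
  hh <- build_histogram(tt, 2000)
  expected <- diff(event_time_cdf(p, 0:50))
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(hh$bins$prob - expected) < 3 * se + 1e-9))

  cum <- cumulative_distribution(hh)
  expect_true(all(diff(cum$cumulative) >= 0))
  expect_equal(cum$cumulative[50], 1)
  expect_error(cumulative_distribution(build_histogram(numeric(0), 5)), "empty")
})

test_that("the bi-exponential fitter recovers the published fit functions", {
  printed <- list(c(-0.0046, 0.048, 27.1, 0.26, 0.58),
                  c(-0.001, 0.064, 15.4, 0.22, 0.51))
  for (kp in printed) {
    t <- seq(0.5, 49.5, by = 1)
    y <- kp[1] + kp[2] * exp(-t / kp[3]) + kp[4] * exp(-t / kp[5])
    f <- suppressWarnings(fit_biexponential(data.frame(t = t, y = y)))
    est <- c(f$y0, f$A1, f$tau1_s, f$A2, f$tau2_s)
    expect_true(all(abs(est - kp) / abs(kp) < 0.005))
    expect_gte(f$tau1_s, f$tau2_s)
  }
})

test_that("noiseless bi-exponentials round-trip to under 1% relative error", {
  set.seed(28)
  t <- seq(0.5, 49.5, by = 1)
  for (r in 1:10) {
    tau2 <- runif(1, 0.2, 3)
    tau1 <- tau2 * runif(1, 5, 40)
    A1 <- runif(1, 0.01, 0.2); A2 <- runif(1, 0.05, 0.5)
    y0 <- runif(1, -0.01, 0.01)
    y <- y0 + A1 * exp(-t / tau1) + A2 * exp(-t / tau2)
    f <- suppressWarnings(fit_biexponential(data.frame(t = t, y = y)))
    est <- c(f$A1, f$tau1_s, f$A2, f$tau2_s)
    expect_true(all(abs(est - c(A1, tau1, A2, tau2)) /
                      c(A1, tau1, A2, tau2) < 0.01))
    expect_lt(abs(f$y0 - y0), 1e-4)
  }

  # single-exponential input is flagged degenerate
  ys <- 0.3 * exp(-t / 5)
  fs <- suppressWarnings(fit_biexponential(data.frame(t = t, y = ys)))
  expect_true(fs$degenerate)
})

test_that("tau recovery from 166-event histograms stays within the simulated envelope", {
  # envelope established by simulation at this event count: the sampling
  # noise of a 166-event, 1-s-binned histogram allows large tau errors; the
  # median relative error and the fraction within 50% are the stable summaries
  p <- make_preset("fusion_noSyn")
  set.seed(42)
  rel <- t(replicate(60, {
    tt <- sample_event_times(p, 166)
    h <- suppressMessages(build_histogram(tt - min(tt), 2000))
    f <- suppressWarnings(fit_biexponential(h))
    c(abs(f$tau1_s - 27.1) / 27.1, abs(f$tau2_s - 0.58) / 0.58)
  }))
  expect_gte(mean(rel[, 1] < 0.5), 0.30)
  expect_gte(mean(rel[, 2] < 0.5), 0.30)
  expect_lt(median(rel[, 1]), 0.9)
  expect_lt(median(rel[, 2]), 0.9)
})

test_that("fusion probability is events per docked vesicle", {
  expect_equal(fusion_probability(166, 2000), 0.083)
  expect_equal(fusion_probability(84, 1300), 0.0646, tolerance = 1e-3)
  expect_equal(fusion_probability(0, 500), 0)
  expect_error(fusion_probability(5, 0), "positive")
})

test_that("tidiers expose fit parameters and histogram metadata", {
  t <- seq(0.5, 49.5, by = 1)
  y <- 0.01 + 0.05 * exp(-t / 20) + 0.3 * exp(-t / 0.6)
  f <- suppressWarnings(fit_biexponential(data.frame(t = t, y = y)))
  td <- generics::tidy(f)
  expect_equal(td$term, c("y0", "A1", "tau1_s", "A2", "tau2_s"))
  expect_equal(nrow(generics::glance(f)), 1)
  h <- build_histogram(c(1, 2, 3), n_docked = 30)
  expect_equal(nrow(generics::tidy(h)), 50)
  expect_equal(generics::glance(h)$n_events, 3)
})
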