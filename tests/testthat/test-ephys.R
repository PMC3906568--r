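test_that("exposure-edge analysis recovers frame times with hysteresis", {
  rate <- 1e5
  ttl <- numeric(5000)
  starts <- c(0, 10, 20, 30, 40) * 1e-3
  for (s in starts) ttl[(s * rate + 1):(s * rate + 500)] <- 5
  ft <- frame_times_from_exposure(new_trace(ttl, rate, 0, "TTL"))
  expect_equal(ft$start, starts)
  expect_equal(ft$duration, rep(5e-3, 5))
  # additive noise at 10% of the amplitude: hysteresis keeps edges intact
  set.seed(2)
  noisy <- ttl + rnorm(length(ttl), 0, 0.5)
  fn <- frame_times_from_exposure(new_trace(noisy, rate, 0, "TTL"))
  expect_equal(nrow(fn), 5L)
  expect_equal(fn$start, starts, tolerance = 2 / (rate * 1e-2))
  expect_warning(z <- frame_times_from_exposure(new_trace(rep(0, 100),
                                                          rate, 0)),
                 "dynamic range")
  expect_equal(nrow(z), 0L)
})

test_that("test-pulse analysis recovers the cell parameters", {
  cell <- cell_model(Ra = 10e6, Rm = 100e6, Cm = 30e-12)
  tp <- sim_test_pulse(cell)
  mp <- membrane_properties(tp$response, tp$command, "vc")
  expect_equal(mp$Raccess, cell$Ra, tolerance = 0.02)
  expect_equal(mp$Rm, cell$Rm, tolerance = 0.02)
  expect_equal(mp$Cm, cell$Cm, tolerance = 0.02)
  expect_equal(mp$Rin, mp$Raccess + mp$Rm)
  # vanishing access resistance: Rin converges to Rm
  lo <- cell_model(Ra = 1e3, Rm = 100e6, Cm = 30e-12)
  tl <- sim_test_pulse(lo)
  # the capacitive transient is sub-sample here, so the tau fit reports
  # failure while the resistances remain valid
  expect_warning(ml <- membrane_properties(tl$response, tl$command, "vc"),
                 "fit failed")
  expect_equal(ml$Rin, lo$Rm, tolerance = 0.01)
  # current-clamp pulse: Rin = Ra + Rm, resting potential = baseline
  rate <- 1e5
  ic_cmd <- new_trace(build_waveform(
    list(type = "squarePulse", start = 0.05, duration = 0.2,
         amplitude = -50e-12), rate, round(0.3 * rate)), rate, 0, "A")
  ic <- sim_clamp_response(cell, ic_cmd, "ic")
  mi <- membrane_properties(ic, ic_cmd, "ic")
  expect_equal(mi$Rin, cell$Ra + cell$Rm, tolerance = 0.01)
  expect_equal(mi$resting_potential, cell$Vrest, tolerance = 1e-6)
  flat <- new_trace(rep(0, 1000), rate, 0, "V")
  expect_error(membrane_properties(ic, flat, "vc"), "zero-amplitude")
})

test_that("parameter recovery holds over 200 random noiseless cells", {
  set.seed(123)
  worst <- 0
  for (k in 1:200) {
    cell <- cell_model(Ra = runif(1, 5e6, 20e6),
                       Rm = runif(1, 50e6, 500e6),
                       Cm = runif(1, 10e-12, 100e-12))
    tp <- sim_test_pulse(cell)
    mp <- membrane_properties(tp$response, tp$command, "vc")
    worst <- max(worst, abs(mp$Raccess / cell$Ra - 1),
                 abs(mp$Rm / cell$Rm - 1), abs(mp$Cm / cell$Cm - 1))
  }
  expect_lt(worst, 0.02)
})

test_that("IV metrics match hand-computed values on constructed trains", {
  # adaptation ratio from ISIs (10, 20, 30, 40) ms = mean(30, 40)/10 = 3.5
  rate <- 2e4
  spk_times <- cumsum(c(0.12, 0.01, 0.02, 0.03, 0.04))
  v <- rep(-65e-3, round(0.6 * rate))
  for (s in spk_times) v[round(s * rate) + 1] <- 30e-3
  spiky <- new_trace(v, rate, 0, "V")
  flatv <- new_trace(rep(-65e-3, length(v)), rate, 0, "V")
  m <- iv_metrics(list(flatv, spiky), c(0, 100e-12), c(0.1, 0.5))
  expect_equal(m$isis, c(10, 20, 30, 40) * 1e-3)
  expect_equal(m$adaptation_ratio, 3.5)
  expect_equal(m$first_spike_latency, 0.02, tolerance = 1e-6)
  # constant train -> adaptation ratio 1
  vv <- rep(-65e-3, round(0.6 * rate))
  for (s in seq(0.15, 0.45, by = 0.05)) vv[round(s * rate) + 1] <- 30e-3
  m2 <- iv_metrics(list(flatv, new_trace(vv, rate, 0, "V")),
                   c(0, 100e-12), c(0.1, 0.5))
  expect_equal(m2$adaptation_ratio, 1.0)
})

test_that("IV metrics recover passive properties of a simulated cell", {
  cell <- cell_model(Ra = 10e6, Rm = 100e6, Cm = 30e-12)
  rate <- 5e4
  steps <- c(-100e-12, -50e-12, 50e-12, 100e-12)
  n <- round(0.7 * rate)
  traces <- lapply(steps, function(s) {
    cmd <- new_trace(build_waveform(
      list(type = "squarePulse", start = 0.1, duration = 0.4,
           amplitude = s), rate, n), rate, 0, "A")
    sim_clamp_response(cell, cmd, "ic")
  })
  m <- iv_metrics(traces, steps, c(0.1, 0.5))
  expect_equal(m$input_resistance, cell$Ra + cell$Rm, tolerance = 0.02)
  expect_equal(m$resting_potential, cell$Vrest, tolerance = 1e-6)
  expect_equal(m$tau_m, cell$Rm * cell$Cm, tolerance = 0.05)
  expect_equal(m$sag_ratio, 0, tolerance = 0.02)
  expect_length(m$isis, 0L)
  # spiking cell produces spikes and a defined latency
  lif <- cell_model(Ra = 10e6, Rm = 100e6, Cm = 30e-12, spiking = TRUE)
  tsp <- lapply(c(100e-12, 300e-12), function(s) {
    cmd <- new_trace(build_waveform(
      list(type = "squarePulse", start = 0.1, duration = 0.4,
           amplitude = s), rate, n), rate, 0, "A")
    sim_clamp_response(lif, cmd, "ic")
  })
  ms <- iv_metrics(tsp, c(100e-12, 300e-12), c(0.1, 0.5))
  expect_gt(max(ms$n_spikes), 2)
  expect_gt(ms$first_spike_latency, 0)
})

test_that("event detection finds injected PSCs and measures their shape", {
  # one clean event: amplitude within 10%, tau within 20%
  f1 <- inject_psc_trace(7, n_events = 1L, noise_sd = 2e-12)
  ev1 <- detect_events(f1$trace, decay_tau_guess = 5e-3)
  expect_equal(nrow(ev1), 1L)
  expect_equal(ev1$amplitude, -50e-12, tolerance = 0.10)
  expect_equal(ev1$decay_tau, 5e-3, tolerance = 0.20)
  expect_lt(abs(ev1$onset_time - f1$onsets), 2e-3)
  # flat trace -> no events
  flat <- new_trace(rep(0, 20000), 2e4, 0, "A")
  expect_equal(nrow(detect_events(flat)), 0L)
  expect_error(detect_events(new_trace(rep(0, 100), 2e4, 0, "A")),
               "shorter")
  expect_error(detect_events(flat, decay_tau_guess = -1), "tau")
})

test_that("20 injected events at SNR 10 are recalled without false alarms", {
  hits <- 0L; total <- 0L; false_det <- 0L
  for (s in 1:3) {
    f <- inject_psc_trace(s, n_events = 20L, amplitude = -50e-12,
                          noise_sd = 5e-12)
    ev <- detect_events(f$trace, decay_tau_guess = 5e-3)
    hits <- hits + sum(vapply(f$onsets, function(o)
      any(abs(ev$onset_time - o) <= 2e-3), logical(1)))
    total <- total + length(f$onsets)
    false_det <- false_det + sum(vapply(ev$onset_time, function(o)
      !any(abs(f$onsets - o) <= 2e-3), logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_equal(false_det, 0L)
})

test_that("event detection is equivariant to shifts and scaling", {
  f <- inject_psc_trace(11, n_events = 5L)
  ev <- detect_events(f$trace, decay_tau_guess = 5e-3)
  shifted <- new_trace(f$trace$samples, f$trace$rate, t0 = 2.5, "A")
  evs <- detect_events(shifted, decay_tau_guess = 5e-3)
  expect_equal(evs$onset_time, ev$onset_time + 2.5)
  scaled <- new_trace(f$trace$samples * 7, f$trace$rate, 0, "A")
  evc <- detect_events(scaled, decay_tau_guess = 5e-3)
  expect_equal(evc$onset_time, ev$onset_time)
  expect_equal(evc$amplitude, ev$amplitude * 7, tolerance = 1e-9)
})

test_that("charge transfer integrates current above baseline", {
  rate <- 1e4
  x <- numeric(10000)
  x[2001:2500] <- 100e-12   # 100 pA for 50 ms -> 5 pC
  tr <- new_trace(x, rate, 0, "A")
  q <- charge_transfer(tr, c(0.19, 0.26), c(0, 0.1))
  expect_equal(q, 5e-12, tolerance = 0.01)
  expect_equal(charge_transfer(tr, c(0.5, 0.9), c(0, 0.1)), 0,
               tolerance = 1e-18)
  # additivity over adjacent windows
  q1 <- charge_transfer(tr, c(0.19, 0.22), c(0, 0.1))
  q2 <- charge_transfer(tr, c(0.22, 0.26), c(0, 0.1))
  expect_equal(q1 + q2, q, tolerance = 1e-15)
  # exponential PSC: integral ~ A * tau over a window >= 7 tau
  tau <- 5e-3
  t <- seq_len(8000) / rate
  psc <- new_trace(c(numeric(2000), -50e-12 * exp(-t / tau)), rate, 0, "A")
  qe <- charge_transfer(psc, c(0.2, 0.2 + 7 * tau), c(0, 0.1))
  expect_equal(qe, -50e-12 * tau, tolerance = 0.01)
  expect_error(charge_transfer(tr, c(0.9, 1.1), c(0, 0.1)), "outside")
})

test_that("map classification flags evoked sites and handles the null", {
  # degenerate null: zero spontaneous rate, one test event -> flagged
  sites <- lapply(1:4, function(k)
    map_site(c(k, 0), trial_events = list(numeric(0), numeric(0)),
             stim_time = 0.5))
  sites[[1]]$trial_events[[1]] <- 0.51
  tab <- classify_map_sites(sites, test_window = 0.05,
                            baseline_window = 0.5)
  expect_true(tab$evoked_flag[1])
  expect_equal(tab$p_value[1], 0)
  expect_false(any(tab$evoked_flag[-1]))
  expect_error(classify_map_sites(list(), 0.05, 0.5), "empty")
  expect_error(classify_map_sites(sites, -1, 0.5), "positive")
})

test_that("map classifier is calibrated under the Poisson null with power", {
  set.seed(99)
  n_maps <- 60; n_sites <- 100; n_trials <- 10
  lambda <- 1; stim <- 0.5; twin <- 0.05; bwin <- 0.5
  sim_map <- function(n_evoked_sites) {
    sites <- lapply(seq_len(n_sites), function(k) {
      trials <- lapply(seq_len(n_trials), function(j) {
        ev <- runif(rpois(1, lambda * (bwin + twin)), 0, bwin + twin)
        if (k <= n_evoked_sites) ev <- c(ev, stim + runif(5, 0, twin))
        sort(ev)
      })
      map_site(c(k, 0), trials, stim)
    })
    classify_map_sites(sites, twin, bwin, alpha = 0.05)
  }
  any_flag <- vapply(seq_len(n_maps),
                     function(m) any(sim_map(0)$evoked_flag), logical(1))
  se <- sqrt(0.05 * 0.95 / n_maps)
  expect_lte(mean(any_flag), 0.05 + 2 * se)
  evoked_hit <- vapply(seq_len(20), function(m)
    mean(sim_map(10)$evoked_flag[1:10]), numeric(1))
  expect_gte(mean(evoked_hit == 1), 0.95)
})
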