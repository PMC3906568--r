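test_that("voltage-clamp response matches the closed-form RC solution", {
  cell <- cell_model(Ra = 10e6, Rm = 100e6, Cm = 30e-12)
  rate <- 2e5
  n <- round(0.05 * rate)
  on_t <- 0.01
  cmd <- new_trace(build_waveform(list(type = "squarePulse", start = on_t,
                                       duration = 0.03, amplitude = 0.01),
                                  rate, n, holding = cell$Vrest),
                   rate, 0, "V")
  out <- sim_clamp_response(cell, cmd, "vc")
  on <- round(on_t * rate) + 1L
  off <- round((on_t + 0.03) * rate)
  tau <- cell$Cm * cell$Ra * cell$Rm / (cell$Ra + cell$Rm)
  t <- (seq(on, off) - on) / rate
  dv <- 0.01
  closed <- dv / (cell$Ra + cell$Rm) +
    (dv / cell$Ra - dv / (cell$Ra + cell$Rm)) * exp(-t / tau)
  expect_lt(max(abs(out$samples[on:off] - closed)) / max(closed), 1e-12)
  # headline numbers: 1.0 nA peak, 90.909 pA steady state, tau = 272.7 us
  expect_equal(out$samples[on], 1e-9, tolerance = 1e-12)
  expect_equal(out$samples[off], 90.909e-12, tolerance = 1e-4)
  expect_equal(tau, 272.7e-6, tolerance = 1e-3)
  # flat command -> flat trace at the holding current
  hold <- cell_model(holding_current = 5e-12)
  flat <- sim_clamp_response(
    hold, new_trace(rep(hold$Vrest, 100), 1e4, 0, "V"), "vc")
  expect_equal(flat$samples, rep(5e-12, 100), tolerance = 1e-15)
  expect_error(
    sim_clamp_response(cell, new_trace(rep(0, 10), 1e4, 0, "A"), "vc"),
    "units")
})

test_that("current-clamp step follows Rm*Cm charging plus the Ra drop", {
  cell <- cell_model(Ra = 10e6, Rm = 100e6, Cm = 30e-12)
  rate <- 1e5
  di <- 50e-12
  cmd <- new_trace(c(rep(0, 100), rep(di, 900)), rate, 0, "A")
  out <- sim_clamp_response(cell, cmd, "ic")
  t <- (0:899) / rate
  closed <- cell$Vrest + di * cell$Rm * (1 - exp(-t / (cell$Rm * cell$Cm))) +
    di * cell$Ra
  expect_lt(max(abs(out$samples[101:1000] - closed)), 1e-12)
})

test_that("clamp simulation is bit-reproducible for a fixed seed", {
  cell <- cell_model(noise_sd = 5e-12)
  cmd <- new_trace(rep(cell$Vrest, 1000), 1e4, 0, "V")
  a <- sim_clamp_response(cell, cmd, "vc", seed = 7)
  b <- sim_clamp_response(cell, cmd, "vc", seed = 7)
  c <- sim_clamp_response(cell, cmd, "vc", seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("mode transitions pass through I=0 with holding zeroed", {
  st <- clamp_set_mode(NULL, "vc")
  st$holding <- -65e-3
  st <- clamp_set_mode(st, "ic")
  expect_equal(st$mode_history, c("i0", "vc", "i0", "ic"))
  expect_equal(st$holding, 0)
})

test_that("camera exposure TTL rising edges equal frame start times", {
  rig <- rig_from_config(demo_rig_config())
  fs <- sim_camera_acquire(rig, "Camera", n_frames = 5, exposure = 5e-3,
                           interval = 10e-3, ttl_rate = 1e5)
  ft <- frame_times_from_exposure(fs$ttl)
  expect_equal(ft$start, c(0, 10, 20, 30, 40) * 1e-3)
  expect_equal(ft$start, fs$times)
  # rising-edge count equals frame count across parameter combinations
  for (p in list(c(3, 2e-3, 7e-3), c(8, 1e-3, 3e-3), c(1, 5e-3, 5e-3))) {
    f2 <- sim_camera_acquire(rig, "Camera", p[1], p[2], p[3])
    expect_equal(nrow(frame_times_from_exposure(f2$ttl)), p[1])
  }
  expect_error(sim_camera_acquire(rig, "Camera", 2, 10e-3, 5e-3),
               "exposure")
  # static scene -> identical frames
  f3 <- sim_camera_acquire(rig, "Camera", 3, 1e-3, 2e-3,
                           scene = function(x, y) x * 1e6)
  expect_equal(f3$frames[, , 1], f3$frames[, , 3])
  # triggered mode delays the first exposure to the trigger time
  f4 <- sim_camera_acquire(rig, "Camera", 2, 1e-3, 5e-3,
                           trigger_mode = "triggered", trigger_time = 0.02)
  expect_equal(frame_times_from_exposure(f4$ttl)$start[1], 0.02)
})

test_that("a moved stage displaces the imaged scene by the pixel delta", {
  rig <- rig_from_config(demo_rig_config())
  scene <- function(x, y) exp(-((x - 20e-6)^2 + y^2) / (2 * (5e-6)^2))
  f1 <- sim_camera_acquire(rig, "Camera", 1, 1e-3, 2e-3, scene = scene,
                           shape = c(24L, 24L))
  move_stage(rig, "Stage", c(-10e-6, 0, 0))  # 5 px at 2 um/px
  f2 <- sim_camera_acquire(rig, "Camera", 1, 1e-3, 2e-3, scene = scene,
                           shape = c(24L, 24L))
  p1 <- which(f1$frames[, , 1] == max(f1$frames[, , 1]), arr.ind = TRUE)
  p2 <- which(f2$frames[, , 1] == max(f2$frames[, , 1]), arr.ind = TRUE)
  expect_equal(p2[1, "col"] - p1[1, "col"], 5L, ignore_attr = TRUE)
})

test_that("scanner observation inverts the true voltage map", {
  lin <- list(A = 0, B = 0, C = 3e3, D = 0, E = 0,
              F = 0, G = 0, H = 0, I = 2.8e3, J = 0)
  obs <- sim_scanner_observe(lin, Vx = 1.5, Vy = -0.7)
  expect_equal(obs$x, 1.5 / 3e3, tolerance = 1e-12)
  expect_equal(obs$y, -0.7 / 2.8e3, tolerance = 1e-12)
  tm <- ground_truth_map()
  a <- sim_scanner_observe(tm, c(0.1, 0.5), c(0.2, 0.1),
                           noise_sd = 1e-6, seed = 3)
  b <- sim_scanner_observe(tm, c(0.1, 0.5), c(0.2, 0.1),
                           noise_sd = 1e-6, seed = 3)
  expect_identical(a, b)
})

test_that("reservations are atomic, FIFO, and never double-claimed", {
  rig <- rig_from_config(demo_rig_config())
  mgr <- rig_manager(rig)
  r1 <- reserve_devices(mgr, c("DAQ", "Camera"), owner = "t1")
  expect_true(r1$granted)
  # disjoint sets proceed concurrently
  r2 <- reserve_devices(mgr, c("Scanner"), owner = "t2")
  expect_true(r2$granted)
  # overlapping request queues and errors when asked to block
  expect_error(reserve_devices(mgr, c("Camera", "Scanner"), owner = "t3"),
               "busy")
  r3 <- reserve_devices(mgr, c("Camera", "Scanner"), owner = "t3",
                        wait = FALSE)
  expect_false(r3$granted)
  release_reservation(mgr, r1)
  expect_false(r3$granted)  # still waiting on Scanner
  release_reservation(mgr, r2)
  expect_true(r3$granted)   # both free -> granted FIFO
  # duplicated device names collapse to a single claim
  r4 <- reserve_devices(mgr, c("DAQ", "DAQ"), owner = "t4")
  expect_length(r4$devices, 1L)
  expect_error(reserve_devices(mgr, "nope"), "unknown device")
})

test_that("randomized reservation schedules never double-claim a device", {
  rig <- random_rig(6, seed = 5)
  mgr <- rig_manager(rig)
  set.seed(11)
  all_res <- list()
  for (step in 1:200) {
    granted <- Filter(function(r) r$granted, all_res)
    if (length(granted) && runif(1) < 0.45) {
      release_reservation(mgr, granted[[sample(length(granted), 1)]])
    } else {
      devs <- sample(rig_device_names(rig), sample(1:3, 1))
      all_res <- c(all_res, list(reserve_devices(mgr, devs, wait = FALSE)))
    }
    # claim ledger invariant: each device held by at most one owner
    expect_false(any(duplicated(names(mgr$claims))))
    held <- unlist(lapply(Filter(function(r) r$granted, all_res),
                          function(r) r$devices))
    expect_false(any(duplicated(held)))
  }
  # drain: releasing every granted reservation (repeatedly, since releases
  # promote queued requests) must empty the claim table
  repeat {
    granted <- Filter(function(r) r$granted, all_res)
    if (!length(granted)) break
    for (r in granted) release_reservation(mgr, r)
  }
  for (r in all_res) release_reservation(mgr, r)  # cancel stale pendings
  expect_length(mgr$claims, 0L)
  expect_length(mgr$queue, 0L)
})
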