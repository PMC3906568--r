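const_video <- function(value, n = 10L, ny = 8L, nx = 8L, dt = 0.1) {
  new_frame_series(array(value, c(ny, nx, n)), (seq_len(n) - 1L) * dt)
}

test_that("rolling background subtraction acts as a temporal high-pass", {
  tc <- 0.5
  # a scene that switches on after the seed frame then stays static
  fs <- const_video(100, n = 41L, dt = 0.1)
  fs$frames[, , 1] <- 0
  out <- rolling_background_subtract(fs, tc)
  # first output frame is frame_1 - frame_0
  expect_equal(out$frames[, , 1], fs$frames[, , 2] - fs$frames[, , 1])
  # static scene decays toward zero: < 1% of amplitude by t = 5 tc
  k5 <- which.min(abs(out$times - (0.1 + 5 * tc)))
  expect_lt(max(abs(out$frames[, , k5])), 0.05 * 100)
  # geometric recursion oracle: output_k = 100 * (1 - a)^(k-1)
  a <- 0.1 / tc
  expect_equal(out$frames[1, 1, ], 100 * (1 - a)^(seq_len(40) - 1))
  # a single bright transient appears positive, then negatively damped
  tr <- const_video(0, n = 20L)
  tr$frames[, , 5] <- 50
  o2 <- rolling_background_subtract(tr, tc)
  expect_equal(o2$frames[1, 1, 4], 50)  # output index 4 = input frame 5
  expect_lt(o2$frames[1, 1, 5], 0)
  expect_error(rolling_background_subtract(fs, -1), "time_constant")
  expect_warning(rolling_background_subtract(
    new_frame_series(array(1, c(2, 2, 3)), c(0, 0.1, 0.5)), 1),
    "non-uniform")
})

test_that("bleach correction flattens exponential decay, keeps transients", {
  t <- seq(0, 20, by = 0.1)
  pure <- 200 * exp(-t / 6) + 50
  cor1 <- bleach_correct(pure, t)
  expect_true(attr(cor1, "bleach_corrected"))
  expect_lt(diff(range(cor1)) / cor1[1], 0.001)
  # constant input is returned unchanged
  cst <- bleach_correct(rep(80, 50))
  expect_equal(as.numeric(cst), rep(80, 50))
  # transient riding on the bleach: its fractional amplitude is preserved
  # within 5% while the baseline is flattened
  trans <- 40 * exp(-(t - 8)^2 / 0.5)
  mixed <- bleach_correct(pure + trans, t)
  ipk <- which.max(trans)
  rel_before <- 40 / pure[ipk]
  rel_after <- (max(mixed) - mixed[1]) / mixed[1]
  expect_equal(rel_after, rel_before, tolerance = 0.05)
  baseline_after <- mixed[-(seq(ipk - 30, ipk + 30))]
  expect_lt(diff(range(baseline_after)) / mixed[1], 0.02)
  expect_error(bleach_correct(1:5), ">= 10")
})

test_that("frame registration recovers known integer shifts", {
  fs <- spot_video(shifts = rbind(c(0, 0), c(0, 0), c(0, 0)))
  reg0 <- register_frames(fs)
  expect_equal(reg0$shifts, matrix(0, 3, 2), ignore_attr = TRUE)
  fs2 <- spot_video(shifts = rbind(c(0, 0), c(3, -2)))
  reg <- register_frames(fs2)
  expect_equal(reg$shifts[2, ], c(3, -2), ignore_attr = TRUE)
  # inverse consistency: corrected frame matches the reference
  expect_equal(reg$registered$frames[5:28, 5:28, 2],
               fs2$frames[5:28, 5:28, 1], tolerance = 1e-9)
  # random walk of known shifts at SNR 10: >= 95% exact
  set.seed(4)
  walk <- matrix(sample(-3:3, 40, replace = TRUE), 20, 2)
  fs3 <- spot_video(shifts = walk, noise_sd = 10, seed = 8)
  reg3 <- register_frames(fs3)
  expected <- sweep(walk, 2, walk[1, ])  # shifts relative to frame 1
  exact <- mean(rowSums(reg3$shifts == expected) == 2)
  expect_gte(exact, 0.95)
  expect_warning(register_frames(const_video(0, 3)), "flat")
})

test_that("ROI dF/F series reflects fractional intensity changes", {
  expect_equal(max(abs(roi_dff_series(
    const_video(100), new_roi("rect", c(3, 3), c(4, 4)),
    c(0, 1))$samples)), 0)
  # roi mean doubles after t*: dF/F = 1 after t*
  fs <- const_video(100, n = 20L)
  fs$frames[, , 11:20] <- 200
  dff <- roi_dff_series(fs, new_roi("ellipse", c(3, 3), c(4, 4)), c(0, 0.9))
  expect_equal(dff$samples[1:10], rep(0, 10))
  expect_equal(dff$samples[11:20], rep(1, 10))
  # invariant under multiplying the video by a positive constant
  fs7 <- fs; fs7$frames <- fs$frames * 7
  expect_equal(roi_dff_series(fs7, new_roi("rect", c(3, 3), c(4, 4)),
                              c(0, 0.9))$samples, dff$samples)
  # simulated transient of 20% over baseline at moderate noise
  set.seed(5)
  fc <- const_video(100, n = 40L)
  resp <- ifelse(fc$times >= 2, 0.2 * exp(-(fc$times - 2) / 1), 0)
  for (k in seq_along(fc$times))
    fc$frames[, , k] <- 100 * (1 + resp[k]) + rnorm(64, 0, 5)
  d2 <- roi_dff_series(fc, new_roi("rect", c(3.5, 3.5), c(8, 8)), c(0, 1.9))
  expect_equal(max(d2$samples), 0.20, tolerance = 0.05)
  expect_error(roi_dff_series(fs, new_roi("rect", c(100, 100), c(1, 1)),
                              c(0, 1)), "intersect")
  zero <- const_video(0)
  expect_error(roi_dff_series(zero, new_roi("rect", c(3, 3), c(2, 2)),
                              c(0, 1)), "zero")
})

test_that("event-triggered averages align windows and skip partial ones", {
  rate <- 1e3
  t <- seq_len(5000) / rate
  kern <- exp(-(0:99) / 20)
  x <- numeric(5000)
  events <- c(0.5, 1.5, 2.5, 3.5)
  for (e in events) x[e * rate + (1:100)] <- kern
  tr <- new_trace(x, rate, 0, "dF/F")
  eta <- event_triggered_average(tr, events, c(0.1, 0.3))
  expect_equal(eta$n_used, 4L)
  # identical transients, no noise: average equals one transient
  seg <- eta$average$samples[101:200]
  expect_equal(seg, kern, tolerance = 1e-12)
  # event too close to the edge is skipped and counted
  eta2 <- event_triggered_average(tr, c(events, 4.95), c(0.1, 0.3))
  expect_equal(eta2$n_used, 4L)
  expect_equal(eta2$n_skipped, 1L)
  expect_error(event_triggered_average(tr, c(0.01), c(0.1, 0.3)),
               "no events")
  # residual noise shrinks as sigma / sqrt(N)
  set.seed(6)
  sigma <- 1
  n_ev <- 100L
  xs <- rnorm(200000, 0, sigma)
  ev_t <- seq(0.5, 199, length.out = n_ev)
  etan <- event_triggered_average(new_trace(xs, rate, 0, ""), ev_t,
                                  c(0.05, 0.05))
  expect_equal(sd(etan$average$samples), sigma / sqrt(n_ev),
               tolerance = 0.2)
})

test_that("mosaic composition places frames by their global transforms", {
  f1 <- new_frame(matrix(1, 10, 10), tf_identity())
  # single frame at native resolution reproduces the frame
  m1 <- compose_mosaic(list(f1), resolution = 1)
  expect_equal(dim(m1$pixels), c(10L, 10L))
  expect_equal(m1$pixels, matrix(1, 10, 10))
  # two tiles abutting: 10 x 20 canvas
  f2 <- new_frame(matrix(2, 10, 10), tf_translate(c(10, 0, 0)))
  m2 <- compose_mosaic(list(f1, f2), resolution = 1)
  expect_equal(dim(m2$pixels), c(10L, 20L))
  expect_equal(m2$pixels[1, 1], 1)
  expect_equal(m2$pixels[1, 20], 2)
  expect_false(any(is.na(m2$pixels)))
  # group adjustment shifts the mosaic frame, not its content
  adj <- alignment_adjustment(tf_translate(c(5, 0, 0)))
  m3 <- compose_mosaic(list(f1, f2), list(adj), resolution = 1)
  expect_equal(m3$pixels, m2$pixels)
  expect_equal(tf_apply(m3$transform, c(0, 0, 0)) -
               tf_apply(m2$transform, c(0, 0, 0)),
               c(5, 0, 0))
  # overlap: later frame wins by default, mean available
  f3 <- new_frame(matrix(4, 10, 10), tf_identity())
  expect_equal(compose_mosaic(list(f1, f3), resolution = 1)$pixels[5, 5], 4)
  expect_equal(compose_mosaic(list(f1, f3), resolution = 1,
                              overlap = "mean")$pixels[5, 5], 2.5)
  expect_error(compose_mosaic(list(), resolution = 1), "empty")
  expect_error(compose_mosaic(list(f1), resolution = 0), "resolution")
})

test_that("mosaic pixels map back into source frames within half a pixel", {
  f1 <- new_frame(matrix(runif(100), 10, 10),
                  tf_from_parts(offset = c(3, -2, 0), scale = c(2, 2, 1)))
  m <- compose_mosaic(list(f1), resolution = 2)
  inv <- tf_invert(f1$transform)
  for (idx in list(c(1, 1), c(5, 7), c(10, 10))) {
    g <- tf_apply(m$transform, c(idx[2] - 1, idx[1] - 1, 0))
    src <- tf_apply(inv, g)
    val <- m$pixels[idx[1], idx[2]]
    if (!is.na(val))
      expect_equal(val, f1$pixels[round(src[2]) + 1, round(src[1]) + 1])
  }
})
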