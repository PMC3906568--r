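# Shared fixtures, all generated in code.

# stage -> microscope -> {camera, scanner}, plus DAQ / clamp, as a config list
demo_rig_config <- function(camera_scale = NULL) {
  cfg <- list(devices = list(
    list(name = "DAQ", kind = "daq"),
    list(name = "Stage", kind = "stage",
         transform = list(offset = c(0, 0, 0))),
    list(name = "Microscope", kind = "microscope", parent = "Stage",
         objectives = list(
           list(slot = 0L, options = list(
             list(name = "5x", scale = c(2e-6, 2e-6), offset = c(0, 0, 0)))),
           list(slot = 1L, options = list(
             list(name = "63x", scale = c(1.59e-7, 1.59e-7),
                  offset = c(0, 0, 0))))),
         active_slot = 0L),
    list(name = "Camera", kind = "camera", parent = "Microscope",
         connections = list(
           exposure = list(daq = "DAQ", port = "di0", type = "di"))),
    list(name = "Scanner", kind = "scanner", parent = "Microscope",
         connections = list(
           vx = list(daq = "DAQ", port = "ao2", type = "ao")))))
  if (!is.null(camera_scale))
    cfg$devices[[4]]$transform <- list(scale = camera_scale)
  cfg
}

# random device hierarchy of n daqgeneric devices with random affines
random_rig <- function(n, seed) {
  set.seed(seed)
  devs <- lapply(seq_len(n), function(k) {
    list(name = paste0("dev", k), kind = "daqgeneric",
         parent = if (k == 1L) NULL else paste0("dev", sample(k - 1L, 1L)),
         transform = list(offset = runif(3, -1e-3, 1e-3),
                          scale = runif(3, 0.1, 10),
                          angle_deg = runif(1, -180, 180)))
  })
  rig_from_config(list(devices = devs))
}

# noiseless voltage-clamp test pulse against a model cell
sim_test_pulse <- function(cell, rate = 2e5, baseline = 0.01,
                           pulse = 0.03, dv = 0.01, seed = NULL) {
  n <- round((baseline + pulse + 0.01) * rate)
  cmd <- new_trace(
    build_waveform(list(type = "squarePulse", start = baseline,
                        duration = pulse, amplitude = dv),
                   rate, n, holding = cell$Vrest),
    rate, 0, "V")
  list(command = cmd,
       response = sim_clamp_response(cell, cmd, "vc", seed = seed))
}

# white-noise current trace with exponential PSCs injected at known onsets
inject_psc_trace <- function(seed, n_events = 20L, rate = 20e3,
                             duration = 4, amplitude = -50e-12,
                             tau = 5e-3, noise_sd = 5e-12,
                             min_sep = 0.05) {
  set.seed(seed)
  n <- round(duration * rate)
  x <- rnorm(n, 0, noise_sd)
  onsets <- sort(sample(seq(0.1, duration - 0.1, by = min_sep), n_events))
  t <- seq_len(round(8 * tau * rate)) / rate
  kern <- amplitude * exp(-t / tau)
  for (o in onsets) {
    i <- round(o * rate)
    idx <- i + seq_along(kern)
    idx <- idx[idx <= n]
    x[idx] <- x[idx] + kern[seq_along(idx)]
  }
  list(trace = new_trace(x, rate, 0, "A"), onsets = onsets)
}

# rig of n generic devices and a task spec with a random acyclic trigger
# forest (each device waits on at most one earlier device)
random_trigger_task <- function(n, seed) {
  set.seed(seed)
  devs <- lapply(seq_len(n), function(k)
    list(name = paste0("d", k), kind = "daqgeneric"))
  rig <- rig_from_config(list(devices = devs))
  spec <- list(protocol = list(duration = 0.1))
  for (k in seq_len(n)) {
    blk <- list()
    if (k > 1L && runif(1) < 0.6)
      blk$triggerDevice <- paste0("d", sample(k - 1L, 1L))
    spec[[paste0("d", k)]] <- blk
  }
  list(rig = rig, spec = spec)
}

# verify every triggered device starts before its trigger source
start_order_ok <- function(spec, order) {
  pos <- match(names(spec)[-1], order)
  for (dv in setdiff(names(spec), "protocol")) {
    trg <- spec[[dv]]$triggerDevice
    if (!is.null(trg) &&
        match(dv, order) >= match(trg, order)) return(FALSE)
  }
  TRUE
}

ground_truth_map <- function() {
  list(A = 2e4, B = -1e4, C = 3e3, D = 5e2, E = -1.2,
       F = 1.5e4, G = 2.5e4, H = 4e2, I = 2.8e3, J = 0.7)
}

# textured scene translated by integer per-frame shifts (circularly, so
# the whole field carries signal), signal sd 100 against additive noise
circshift2 <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1L - dy) %% ny) + 1L,
    ((seq_len(nx) - 1L - dx) %% nx) + 1L]
}

spot_video <- function(shifts, ny = 32L, nx = 32L, noise_sd = 0, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(ny * nx), ny, nx)
  base <- t(apply(base, 1, function(r)
    as.numeric(stats::filter(r, rep(1 / 5, 5), circular = TRUE))))
  base <- apply(base, 2, function(c_)
    as.numeric(stats::filter(c_, rep(1 / 5, 5), circular = TRUE)))
  base <- base / sd(base) * 100
  n <- nrow(shifts)
  frames <- array(0, c(ny, nx, n))
  for (k in seq_len(n))
    frames[, , k] <- circshift2(base, shifts[k, 1], shifts[k, 2]) +
      rnorm(ny * nx, 0, noise_sd)
  new_frame_series(frames, (seq_len(n) - 1L) * 0.1)
}
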