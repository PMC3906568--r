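#' Passive cell model for the simulated patch-clamp amplifier
#'
#' A single-compartment RC cell behind an access (series) resistance:
#' membrane resistance \code{Rm} and capacitance \code{Cm} from the
#' intracellular node to rest potential \code{Vrest}, pipette connected
#' through \code{Ra}. Optionally a leaky integrate-and-fire spiking
#' mechanism (synthetic, for exercising spike metrics): threshold,
#' reset and refractory period.
#'
#' @param Ra access resistance, ohms.
#' @param Rm membrane resistance, ohms.
#' @param Cm membrane capacitance, farads.
#' @param Vrest resting potential, volts.
#' @param holding_current standing pipette current, amps.
#' @param noise_sd recording noise SD (amps in VC, volts in IC).
#' @param spiking enable the integrate-and-fire mechanism (IC mode only).
#' @param threshold,reset,refractory,spike_peak LIF parameters (V, V, s, V).
#' @return list of class \code{"cell_model"}.
#' @export
cell_model <- function(Ra = 10e6, Rm = 100e6, Cm = 30e-12, Vrest = -65e-3,
                       holding_current = 0, noise_sd = 0, spiking = FALSE,
                       threshold = -40e-3, reset = -65e-3, refractory = 2e-3,
                       spike_peak = 30e-3) {
  if (Ra <= 0 || Rm <= 0 || Cm <= 0)
    stop("Ra, Rm and Cm must all be positive")
  structure(list(Ra = Ra, Rm = Rm, Cm = Cm, Vrest = Vrest,
                 holding_current = holding_current, noise_sd = noise_sd,
                 spiking = spiking, threshold = threshold, reset = reset,
                 refractory = refractory, spike_peak = spike_peak),
            class = "cell_model")
}

#' Simulate the amplifier response of a model cell to a command waveform
#'
#' Voltage clamp: the pipette potential follows the command; membrane
#' potential relaxes exponentially with tau = Cm * Ra * Rm / (Ra + Rm), and
#' the recorded current is the pipette current plus holding current. For a
#' step dV this reproduces the closed form
#' \deqn{I(t) = I_{hold} + dV/(Ra+Rm) + (dV/Ra - dV/(Ra+Rm)) e^{-t/\tau}.}
#' Current clamp: injected current charges the membrane with tau = Rm * Cm
#' and the recorded potential includes the instantaneous electrode drop
#' \code{I * Ra}. \code{i0} records the free membrane potential.
#' Integration is exact per sample (piecewise-constant command, exponential
#' update), so the noiseless output matches the closed form at machine
#' precision.
#'
#' @param cell a \code{\link{cell_model}}.
#' @param command command \code{\link{new_trace}} (units V for vc, A for ic).
#' @param mode \code{"vc"}, \code{"ic"} or \code{"i0"}.
#' @param seed integer seed for the noise generator (or NULL).
#' @return response \code{trace} (A in vc, V otherwise).
#' @export
sim_clamp_response <- function(cell, command, mode = c("vc", "ic", "i0"),
                               seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cell, "cell_model"), inherits(command, "trace"))
  want <- c(vc = "V", ic = "A", i0 = "A")[[mode]]
  if (nzchar(command$units) && command$units != want)
    stop("command units '", command$units, "' do not match mode '", mode,
         "' (expected ", want, ")")
  n <- length(command$samples)
  dt <- 1 / command$rate
  out <- numeric(n)
  Ra <- cell$Ra; Rm <- cell$Rm; Cm <- cell$Cm
  if (mode == "vc") {
    tau <- Cm * (Ra * Rm) / (Ra + Rm)
    decay <- exp(-dt / tau)
    v <- cell$Vrest
    g <- 1 / Ra + 1 / Rm
    for (i in seq_len(n)) {
      vp <- command$samples[i]
      out[i] <- (vp - v) / Ra + cell$holding_current
      vinf <- (vp / Ra + cell$Vrest / Rm) / g
      v <- vinf + (v - vinf) * decay
    }
    units <- "A"
  } else {
    tau <- Rm * Cm
    decay <- exp(-dt / tau)
    v <- cell$Vrest
    refr_left <- 0
    cmd <- if (mode == "i0") rep(0, n) else command$samples
    for (i in seq_len(n)) {
      ii <- cmd[i]
      if (cell$spiking && refr_left > 0) {
        out[i] <- cell$reset
        refr_left <- refr_left - dt
        v <- cell$reset
        next
      }
      out[i] <- v + ii * Ra
      vinf <- cell$Vrest + ii * Rm
      v <- vinf + (v - vinf) * decay
      if (cell$spiking && v >= cell$threshold) {
        out[i] <- cell$spike_peak
        v <- cell$reset
        refr_left <- cell$refractory
      }
    }
    units <- "V"
  }
  if (cell$noise_sd > 0)
    out <- out + with_seed(seed, stats::rnorm(n, 0, cell$noise_sd))
  new_trace(out, command$rate, command$t0, units, "primary")
}

#' Amplifier mode switching with the safe intermediate state
#'
#' Creates a small stateful clamp-device handle and switches its mode.
#' Any transition between \code{vc} and \code{ic} passes through \code{i0}
#' with the holding output zeroed before the new mode is engaged; the full
#' path is appended to \code{$mode_history} for audit.
#' @param state a list from \code{clamp_state()} (or NULL to create one).
#' @param mode target mode.
#' @return updated state list.
#' @export
clamp_set_mode <- function(state = NULL, mode = c("vc", "ic", "i0")) {
  mode <- match.arg(mode)
  if (is.null(state))
    state <- list(mode = "i0", holding = 0, mode_history = "i0")
  if (!identical(state$mode, mode)) {
    if (!"i0" %in% c(state$mode, mode)) {
      state$holding <- 0
      state$mode_history <- c(state$mode_history, "i0")
    }
    state$mode <- mode
    state$mode_history <- c(state$mode_history, mode)
  }
  state
}

#' Simulate a camera acquisition
#'
#' Renders \code{n_frames} frames by sampling an analytic scene function at
#' the global coordinates of each pixel center (through the camera's current
#' global transform), and produces the exposure TTL trace that real cameras
#' export: high during each exposure, with frame start times equal to the
#' TTL rising edges exactly.
#'
#' @param rig a rig.
#' @param camera camera device name.
#' @param n_frames number of frames.
#' @param exposure exposure time per frame, s (must be <= interval).
#' @param interval frame interval, s.
#' @param trigger_mode \code{"normal"} (starts at t0) or \code{"triggered"}
#'   (first exposure begins at \code{trigger_time}).
#' @param scene function(x, y) of global coordinates (m) returning intensity;
#'   vectorized over equal-length x and y.
#' @param shape c(ny, nx) sensor size in pixels.
#' @param ttl_rate sample rate of the exposure TTL trace, Hz.
#' @param trigger_time trigger arrival time, s (triggered mode).
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param seed noise seed.
#' @return list of class \code{"frame_series"}: \code{frames} (ny x nx x n
#'   array), \code{times}, \code{exposure}, \code{transform} (pixel to
#'   global), \code{objective}, and \code{ttl} (a \code{trace}).
#' @export
sim_camera_acquire <- function(rig, camera, n_frames, exposure, interval,
                               trigger_mode = c("normal", "triggered"),
                               scene = function(x, y) 0 * x,
                               shape = c(16L, 16L), ttl_rate = 1e5,
                               trigger_time = 0, noise_sd = 0, seed = NULL) {
  trigger_mode <- match.arg(trigger_mode)
  dev <- rig_device(rig, camera)
  if (dev$kind != "camera") stop("'", camera, "' is not a camera")
  if (exposure > interval) stop("exposure (", exposure,
                                ") exceeds frame interval (", interval, ")")
  offset <- if (trigger_mode == "triggered") trigger_time else 0
  # snap frame starts to the TTL sample grid so edges and times agree exactly
  start_idx <- round((offset + (seq_len(n_frames) - 1L) * interval) * ttl_rate)
  times <- start_idx / ttl_rate
  exp_samp <- max(1L, round(exposure * ttl_rate))
  n_ttl <- max(start_idx) + exp_samp + round(0.2 * interval * ttl_rate) + 1L
  ttl <- numeric(n_ttl)
  for (s in start_idx) ttl[(s + 1L):(s + exp_samp)] <- 5
  tf <- global_transform(rig, camera)
  ny <- shape[1]; nx <- shape[2]
  px <- cbind(rep(seq_len(nx) - 1L, each = ny),
              rep(seq_len(ny) - 1L, times = nx), 0)
  gl <- tf_apply(tf, px)
  base <- matrix(scene(gl[, 1], gl[, 2]), ny, nx)
  frames <- array(rep(base, n_frames), dim = c(ny, nx, n_frames))
  if (noise_sd > 0)
    frames <- frames + with_seed(seed,
      array(stats::rnorm(length(frames), 0, noise_sd), dim = dim(frames)))
  obj <- tryCatch({
    scopes <- Filter(function(d) d$kind == "microscope",
                     lapply(parent_chain(rig, camera),
                            function(nm) rig$devices[[nm]]))
    if (length(scopes)) active_objective(rig, scopes[[1]]$name)$name else NA
  }, error = function(e) NA)
  structure(list(frames = frames, times = times, exposure = exposure,
                 transform = tf, objective = obj,
                 ttl = new_trace(ttl, ttl_rate, 0, "TTL", "exposure")),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_series> %d frames of %dx%d px, t = [%g, %g] s\n",
              d[3], d[1], d[2], min(x$times), max(x$times)))
  invisible(x)
}

#' Observe the laser spot position for commanded mirror voltages
#'
#' Ground truth for scanner calibration: the spot appears at the position
#' whose image under the true quadratic voltage map equals the commanded
#' (Vx, Vy), found by Newton inversion, plus Gaussian position noise. This
#' emulates the camera-based spot localization used during calibration.
#'
#' @param true_map named list/vector with coefficients A..J of the quadratic
#'   map Vx = A x^2 + B y^2 + C x + D y + E; Vy = F x^2 + G y^2 + H x + I y
#'   + J (x, y in meters).
#' @param Vx,Vy commanded voltages (vectors of equal length).
#' @param noise_sd position observation noise SD, meters.
#' @param seed noise seed.
#' @return data.frame with columns x, y (m), Vx, Vy.
#' @export
sim_scanner_observe <- function(true_map, Vx, Vy, noise_sd = 0, seed = NULL) {
  stopifnot(length(Vx) == length(Vy))
  tm <- as.list(true_map)
  fwd <- function(x, y)
    c(tm$A * x^2 + tm$B * y^2 + tm$C * x + tm$D * y + tm$E,
      tm$F * x^2 + tm$G * y^2 + tm$H * x + tm$I * y + tm$J)
  # linear-part initial guess, then Newton
  lin <- matrix(c(tm$C, tm$D, tm$H, tm$I), 2L, 2L, byrow = TRUE)
  if (abs(det(lin)) < 1e-15)
    stop("true map has a singular linear part; cannot invert")
  pos <- matrix(NA_real_, length(Vx), 2L)
  for (k in seq_along(Vx)) {
    target <- c(Vx[k], Vy[k])
    p <- solve(lin, target - c(tm$E, tm$J))
    for (it in 1:50) {
      r <- fwd(p[1], p[2]) - target
      if (max(abs(r)) < 1e-13) break
      Jm <- matrix(c(2 * tm$A * p[1] + tm$C, 2 * tm$B * p[2] + tm$D,
                     2 * tm$F * p[1] + tm$H, 2 * tm$G * p[2] + tm$I),
                   2L, 2L, byrow = TRUE)
      if (abs(det(Jm)) < 1e-15)
        stop("voltage (", Vx[k], ", ", Vy[k],
             ") outside the invertible range of the map")
      p <- p - solve(Jm, r)
    }
    if (max(abs(fwd(p[1], p[2]) - target)) > 1e-9)
      stop("voltage (", Vx[k], ", ", Vy[k],
           ") outside the invertible range of the map")
    pos[k, ] <- p
  }
  if (noise_sd > 0)
    pos <- pos + with_seed(seed,
      matrix(stats::rnorm(length(pos), 0, noise_sd), ncol = 2L))
  data.frame(x = pos[, 1], y = pos[, 2], Vx = Vx, Vy = Vy)
}
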