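#' Fit the mirror voltage map from spot observations
#'
#' The galvanometric scanner maps a sample-plane position (x, y) to mirror
#' command voltages through a quadratic model
#' \deqn{V_x = A x^2 + B y^2 + C x + D y + E}
#' \deqn{V_y = F x^2 + G y^2 + H x + I y + J.}
#' The model is linear in its coefficients, so the least-squares optimum is
#' found by ordinary linear least squares on the design matrix
#' \code{[x^2, y^2, x, y, 1]} (identical to the optimum an iterative
#' least-squares optimizer would reach). Calibrations are stored per
#' (laser, objective) combination because different lasers and objectives
#' change the optical path.
#'
#' @param samples data.frame with columns \code{x}, \code{y} (m),
#'   \code{Vx}, \code{Vy} (V); at least 5 non-degenerate points.
#' @param laser,objective labels keying the calibration.
#' @return list of class \code{"scanner_calibration"}: coefficients
#'   \code{A}..\code{J}, \code{residual_v} (volts RMS),
#'   \code{fit_residual} (meters RMS, via inverse mapping of the fitted
#'   voltages), \code{laser}, \code{objective}.
#' @export
fit_voltage_map <- function(samples, laser = "laser", objective = "obj") {
  stopifnot(is.data.frame(samples),
            all(c("x", "y", "Vx", "Vy") %in% names(samples)))
  n <- nrow(samples)
  if (n < 5L) stop("need at least 5 calibration samples, got ", n)
  X <- cbind(samples$x^2, samples$y^2, samples$x, samples$y, 1)
  qrX <- qr(X)
  if (qrX$rank < 5L)
    stop("degenerate calibration sample layout (rank ", qrX$rank,
         " design); spread the points in both x and y")
  cx <- qr.coef(qrX, samples$Vx)
  cy <- qr.coef(qrX, samples$Vy)
  co <- c(cx, cy)
  names(co) <- LETTERS[1:10]
  fit_v <- cbind(X %*% cx - samples$Vx, X %*% cy - samples$Vy)
  residual_v <- sqrt(mean(fit_v^2))
  cal <- structure(c(as.list(co),
                     list(laser = laser, objective = objective,
                          residual_v = residual_v, fit_residual = NA_real_)),
                   class = "scanner_calibration")
  # position-space residual: invert the fitted map at the observed voltages
  pos <- tryCatch(voltage_to_position(cal, samples$Vx, samples$Vy),
                  error = function(e) NULL)
  if (!is.null(pos))
    cal$fit_residual <- sqrt(mean((pos$x - samples$x)^2 +
                                  (pos$y - samples$y)^2))
  cal
}

#' @export
print.scanner_calibration <- function(x, ...) {
  cat(sprintf("<scanner_calibration> %s / %s, residual %.3g V",
              x$laser, x$objective, x$residual_v))
  if (is.finite(x$fit_residual))
    cat(sprintf(" (%.3g m)", x$fit_residual))
  cat("\n")
  invisible(x)
}

#' Evaluate the calibrated map: position to mirror voltages
#' @param cal a \code{\link{fit_voltage_map}} calibration.
#' @param x,y global position, meters (vectorized).
#' @return data.frame with \code{Vx}, \code{Vy}.
#' @export
position_to_voltage <- function(cal, x, y) {
  stopifnot(inherits(cal, "scanner_calibration"))
  data.frame(Vx = cal$A * x^2 + cal$B * y^2 + cal$C * x + cal$D * y + cal$E,
             Vy = cal$F * x^2 + cal$G * y^2 + cal$H * x + cal$I * y + cal$J)
}

#' Invert the calibrated map: voltages to position (Newton iteration)
#' @param cal a calibration.
#' @param Vx,Vy voltages (vectorized).
#' @export
voltage_to_position <- function(cal, Vx, Vy) {
  tm <- cal[c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")]
  obs <- sim_scanner_observe(tm, Vx, Vy, noise_sd = 0)
  data.frame(x = obs$x, y = obs$y)
}

#' Calibration store keyed by laser / objective
#'
#' @param store an existing store (or NULL to create one).
#' @param cal calibration to add.
#' @export
calibration_store <- function(store = NULL, cal = NULL) {
  if (is.null(store)) store <- structure(list(), class = "calibration_store")
  if (!is.null(cal))
    store[[paste(cal$laser, cal$objective, sep = "/")]] <- cal
  store
}

#' Look up the calibration for the active (laser, objective) pair
#' @param store a \code{\link{calibration_store}}.
#' @param laser,objective active configuration.
#' @export
get_calibration <- function(store, laser, objective) {
  key <- paste(laser, objective, sep = "/")
  cal <- store[[key]]
  if (is.null(cal))
    stop("no scanner calibration stored for ", key)
  cal
}

#' Run an automated scanner calibration against a ground-truth map
#'
#' Commands a rectangular grid of mirror voltages, observes the laser spot
#' position for each (as the camera-based calibration procedure would), and
#' fits the quadratic voltage map to the collected samples.
#'
#' @param true_map ground-truth coefficients A..J (the simulated optics).
#' @param grid_n grid points per axis (default 5).
#' @param v_range list with \code{Vx = c(lo, hi)}, \code{Vy = c(lo, hi)}.
#' @param noise_sd spot-localization noise SD, meters.
#' @param seed noise seed.
#' @inheritParams fit_voltage_map
#' @return a \code{scanner_calibration}.
#' @export
calibrate_scanner <- function(true_map, grid_n = 5,
                              v_range = list(Vx = c(-2, 2), Vy = c(-2, 2)),
                              noise_sd = 0, seed = NULL,
                              laser = "laser", objective = "obj") {
  g <- expand.grid(Vx = seq(v_range$Vx[1], v_range$Vx[2], length.out = grid_n),
                   Vy = seq(v_range$Vy[1], v_range$Vy[2], length.out = grid_n))
  obs <- sim_scanner_observe(true_map, g$Vx, g$Vy, noise_sd = noise_sd,
                             seed = seed)
  fit_voltage_map(obs, laser = laser, objective = objective)
}

#' Generate a timed scan pattern
#'
#' Produces the (x, y) position series a scanner follows, one point per
#' sample at \code{sample_rate}. Raster lines are scanned left to right
#' (alternating direction if \code{bidirectional}, with reversed rows
#' shifted by \code{field_shift} samples to cancel the comb artifact);
#' overscan extends each line by \code{overscan * cols} rounded samples on
#' both ends, flagged \code{keep = FALSE} so reconstruction can drop the
#' turnaround. Spirals are Archimedean (r = pitch * theta / 2 pi) at
#' constant angular sampling.
#'
#' @param pattern list with \code{kind} = raster | line | circle | spiral |
#'   points and geometry fields: raster \code{extent} (x0, y0, width,
#'   height), \code{rows}, \code{cols}, \code{overscan}, \code{bidirectional},
#'   \code{field_shift}; line \code{from}, \code{to}, \code{n}; circle
#'   \code{center}, \code{radius}, \code{n}; spiral \code{center},
#'   \code{pitch}, \code{turns}, \code{n}; points \code{xy} (n x 2).
#' @param sample_rate dwell sample rate, Hz.
#' @return data.frame with \code{t}, \code{x}, \code{y}, \code{keep},
#'   and \code{row} for rasters.
#' @export
generate_scan_pattern <- function(pattern, sample_rate) {
  if (sample_rate <= 0) stop("sample_rate must be > 0")
  kind <- match.arg(pattern$kind,
                    c("raster", "line", "circle", "spiral", "points"))
  out <- switch(kind,
    raster = .raster_pattern(pattern),
    line = {
      n <- as.integer(pattern$n)
      from <- si_value(pattern$from); to <- si_value(pattern$to)
      f <- seq(0, 1, length.out = n)
      data.frame(x = from[1] + f * (to[1] - from[1]),
                 y = from[2] + f * (to[2] - from[2]), keep = TRUE)
    },
    circle = {
      n <- as.integer(pattern$n)
      ctr <- si_value(pattern$center); r <- si_value(pattern$radius)
      if (r <= 0) stop("circle radius must be > 0")
      th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
      data.frame(x = ctr[1] + r * cos(th), y = ctr[2] + r * sin(th),
                 keep = TRUE)
    },
    spiral = {
      n <- as.integer(pattern$n)
      ctr <- si_value(pattern$center)
      pitch <- si_value(pattern$pitch)
      th <- seq(0, pattern$turns * 2 * pi, length.out = n)
      r <- pitch * th / (2 * pi)
      data.frame(x = ctr[1] + r * cos(th), y = ctr[2] + r * sin(th),
                 keep = TRUE)
    },
    points = {
      xy <- pattern$xy
      data.frame(x = xy[, 1], y = xy[, 2], keep = TRUE)
    })
  if (!all(is.finite(out$x)) || !all(is.finite(out$y)))
    stop("scan pattern contains non-finite points")
  out$t <- (seq_len(nrow(out)) - 1L) / sample_rate
  out[, c("t", setdiff(names(out), "t"))]
}

.raster_pattern <- function(pattern) {
  ext <- si_value(pattern$extent)  # x0, y0, width, height
  rows <- as.integer(pattern$rows)
  cols <- as.integer(pattern$cols)
  if (any(ext[3:4] <= 0)) stop("raster extent has zero size")
  overscan <- pattern$overscan %||% 0
  if (overscan < 0) stop("negative overscan")
  bidi <- isTRUE(pattern$bidirectional)
  shift <- as.integer(pattern$field_shift %||% 0L)
  os <- round(cols * overscan)
  dx <- ext[3] / max(cols - 1L, 1L)
  xs <- ext[1] + (seq_len(cols + 2L * os) - 1L - os) * dx
  keep <- c(rep(FALSE, os), rep(TRUE, cols), rep(FALSE, os))
  ys <- if (rows == 1L) ext[2] else
    ext[2] + (seq_len(rows) - 1L) * ext[4] / (rows - 1L)
  res <- lapply(seq_len(rows), function(r) {
    x <- xs; k <- keep
    reversed <- bidi && r %% 2L == 0L
    if (reversed) {
      x <- rev(x); k <- rev(k)
      if (shift != 0L) {
        # shift the sampling phase of reversed rows by `shift` samples
        x <- x + shift * (x[2] - x[1])
      }
    }
    data.frame(x = x, y = ys[r], keep = k, row = r, reversed = reversed)
  })
  do.call(rbind, res)
}

#' Estimate the bidirectional field shift from a comb-artifacted image
#'
#' Finds the integer sample shift of reversed rows that maximizes the mean
#' cross-correlation between adjacent rows of a bidirectional raster image.
#' @param img matrix with rows = scan lines (even lines acquired reversed).
#' @param max_shift search range in samples.
#' @return integer shift estimate.
#' @export
estimate_field_shift <- function(img, max_shift = 10L) {
  shifts <- -max_shift:max_shift
  score <- vapply(shifts, function(s) {
    tot <- 0
    for (r in seq(2L, nrow(img), by = 2L)) {
      row <- img[r, ]
      sh <- if (s >= 0) c(row[-seq_len(s)], rep(NA, s)) else
        c(rep(NA, -s), row[seq_len(length(row) + s)])
      ref <- img[r - 1L, ]
      ok <- !is.na(sh)
      if (sum(ok) > 2 && stats::sd(sh[ok]) > 0 && stats::sd(ref[ok]) > 0)
        tot <- tot + stats::cor(sh[ok], ref[ok])
    }
    tot
  }, numeric(1))
  shifts[which.max(score)]
}

#' Laser state: output power and per-configuration attenuation
#' @param output_power current laser output power, W.
#' @param attenuation attenuation factor of the optical train, in [0, 1].
#' @return list of class \code{"laser_state"}, with
#'   \code{expected_sample_power = output_power * attenuation}.
#' @export
laser_state <- function(output_power, attenuation = 1) {
  output_power <- si_value(output_power)
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must lie in [0, 1]")
  structure(list(output_power = output_power, attenuation = attenuation,
                 expected_sample_power = output_power * attenuation),
            class = "laser_state")
}

#' Pulse duration needed to deliver a requested photostimulation energy
#'
#' duration = energy / expected power at sample.
#' @param state a \code{\link{laser_state}}.
#' @param requested_energy energy to deliver, J (>= 0).
#' @return pulse duration, s.
#' @export
laser_energy_calc <- function(state, requested_energy) {
  requested_energy <- si_value(requested_energy)
  if (requested_energy < 0) stop("requested energy must be >= 0")
  if (state$expected_sample_power <= 0)
    stop("expected sample power must be > 0")
  requested_energy / state$expected_sample_power
}
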