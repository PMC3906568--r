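#' A single image frame with its pixel-to-global transform
#'
#' @param pixels numeric matrix (rows = y, columns = x).
#' @param transform \code{transform3d} mapping pixel coordinates
#'   (x = column index, y = row index, 0-based, pixel centers at integers)
#'   to global coordinates (m).
#' @param t_start frame start time, s.
#' @param exposure exposure, s.
#' @param objective objective name, if known.
#' @return list of class \code{"frame"}.
#' @export
new_frame <- function(pixels, transform = tf_identity(), t_start = 0,
                      exposure = NA_real_, objective = NA_character_) {
  stopifnot(is.matrix(pixels), is.finite(t_start))
  tf_invert(transform)  # errors early if singular
  structure(list(pixels = pixels, transform = transform, t_start = t_start,
                 exposure = exposure, objective = objective),
            class = "frame")
}

#' Assemble a frame series from an array of frames
#' @param frames ny x nx x n array.
#' @param times per-frame start times, s.
#' @param transform shared pixel-to-global transform.
#' @param exposure exposure, s.
#' @export
new_frame_series <- function(frames, times, transform = tf_identity(),
                             exposure = NA_real_) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == length(times))
  structure(list(frames = frames, times = times, transform = transform,
                 exposure = exposure, objective = NA, ttl = NULL),
            class = "frame_series")
}

#' Continuously updating background subtraction
#'
#' Maintains an exponential running-mean background
#' \code{B_t = (1 - a) B_{t-1} + a F_t} with \code{a = dt / time_constant}
#' (clamped to 1), seeded with the first frame, and outputs
#' \code{F_t - B_{t-1}}. This acts as a temporal high-pass filter: static
#' structure decays from the output with the given time constant while
#' fast fluorescence transients pass through. Frame intervals that vary by
#' more than 10% trigger a warning and per-frame alpha is used.
#'
#' @param series a \code{frame_series} (>= 2 frames).
#' @param time_constant background update time constant, s (> 0).
#' @return a \code{frame_series} of background-subtracted frames (one fewer
#'   than the input: output t starts at the second frame).
#' @export
rolling_background_subtract <- function(series, time_constant) {
  if (time_constant <= 0) stop("time_constant must be > 0")
  n <- dim(series$frames)[3]
  if (n < 2L) stop("need at least 2 frames")
  dts <- diff(series$times)
  if (max(dts) - min(dts) > 0.1 * mean(dts))
    warning("non-uniform frame intervals; using per-frame update factor")
  bg <- series$frames[, , 1]
  out <- array(0, dim = dim(series$frames) - c(0, 0, 1))
  for (k in 2:n) {
    out[, , k - 1L] <- series$frames[, , k] - bg
    a <- min(1, dts[k - 1L] / time_constant)
    bg <- (1 - a) * bg + a * series$frames[, , k]
  }
  res <- series
  res$frames <- out
  res$times <- series$times[-1]
  res$final_background <- bg
  res
}

#' Correct an ROI fluorescence series for photobleaching
#'
#' Fits \code{F(t) = A exp(-t / tau_b) + C} by least squares and divides the
#' series by the normalized fit, \code{corrected = F * Fhat(0) / Fhat(t)}.
#' Multiplicative correction preserves dF/F semantics. If the fit fails
#' (e.g. constant input), the series is returned unchanged with
#' \code{attr(, "bleach_corrected") = FALSE}.
#'
#' @param series numeric vector (>= 10 samples) of ROI means.
#' @param times sample times, s (default: sample index).
#' @return corrected numeric vector with attributes
#'   \code{bleach_corrected} (logical) and \code{bleach_fit} (A, tau, C).
#' @export
bleach_correct <- function(series, times = seq_along(series) - 1) {
  if (length(series) < 10L) stop("need >= 10 samples")
  rng <- diff(range(series))
  co <- NULL
  if (rng > .Machine$double.eps * max(abs(series), 1)) {
    fit_subset <- function(w) {
      df <- data.frame(f = series[w], t = times[w])
      # log-linear starting values against a floor just below the minimum
      C0 <- min(df$f) - 0.05 * rng
      lf <- stats::lm.fit(cbind(1, df$t), log(pmax(df$f - C0, rng * 1e-6)))
      tau0 <- -1 / lf$coefficients[2]
      if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(times)) / 2
      # nls stalls on zero-residual (noise-free) input; warnOnly keeps the
      # best iterate, which is already at the optimum in that case
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(f ~ A * exp(-t / tau) + C, data = df,
                     start = list(A = exp(lf$coefficients[[1]]), tau = tau0,
                                  C = C0),
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (is.null(fit)) NULL else stats::coef(fit)
    }
    co <- fit_subset(seq_along(series))
    if (!is.null(co)) {
      # refit excluding positive excursions (transients) above 2 robust SDs
      pred <- co[["A"]] * exp(-times / co[["tau"]]) + co[["C"]]
      resid <- series - pred
      w <- which(resid <= 2 * stats::mad(resid))
      if (length(w) >= 10L && length(w) < length(series)) {
        co2 <- fit_subset(w)
        if (!is.null(co2)) co <- co2
      }
    }
  }
  if (is.null(co)) {
    out <- series
    attr(out, "bleach_corrected") <- FALSE
    return(out)
  }
  fhat <- co[["A"]] * exp(-times / co[["tau"]]) + co[["C"]]
  if (any(fhat <= 0) || !all(is.finite(fhat))) {
    out <- series
    attr(out, "bleach_corrected") <- FALSE
    return(out)
  }
  out <- series * fhat[1] / fhat
  attr(out, "bleach_corrected") <- TRUE
  attr(out, "bleach_fit") <- co
  out
}

#' Register frames against a reference by integer-pixel cross-correlation
#'
#' The shift of each frame is the argmax of its 2D cross-correlation with
#' the reference (computed via FFT); frames are shifted back by that amount
#' with zero padding. Flat frames get zero shift with a warning.
#'
#' @param series a \code{frame_series}.
#' @param reference \code{"first"} or \code{"mean"}.
#' @return list: \code{shifts} (n x 2 matrix, dx dy in px),
#'   \code{registered} (a \code{frame_series}).
#' @export
register_frames <- function(series, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  fr <- series$frames
  n <- dim(fr)[3]
  ref <- if (reference == "first") fr[, , 1] else apply(fr, c(1, 2), mean)
  if (stats::sd(ref) == 0) {
    warning("flat reference frame; no registration possible")
    return(list(shifts = matrix(0, n, 2), registered = series))
  }
  ny <- dim(fr)[1]; nx <- dim(fr)[2]
  Fr <- stats::fft(ref - mean(ref))
  shifts <- matrix(0L, n, 2)
  out <- fr
  for (k in seq_len(n)) {
    f <- fr[, , k]
    if (stats::sd(f) == 0) {
      warning("flat frame ", k, "; zero shift assumed")
      next
    }
    xc <- Re(stats::fft(Fr * Conj(stats::fft(f - mean(f))),
                        inverse = TRUE))
    pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
    dy <- pk[1] - 1L; dx <- pk[2] - 1L
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    # xc peak at (ref lag of frame): frame shifted by +s peaks at -s here
    dx <- -dx; dy <- -dy
    shifts[k, ] <- c(dx, dy)
    out[, , k] <- .shift_matrix(f, -dx, -dy)
  }
  reg <- series
  reg$frames <- out
  list(shifts = shifts, registered = reg)
}

.shift_matrix <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  sr <- seq_len(ny) - dy   # source row for each target row
  sc <- seq_len(nx) - dx
  okr <- sr >= 1L & sr <= ny
  okc <- sc >= 1L & sc <= nx
  out[which(okr), which(okc)] <- m[sr[okr], sc[okc]]
  out
}

#' Region of interest in global coordinates
#' @param shape \code{"rect"} or \code{"ellipse"}.
#' @param center c(x, y) global center, m.
#' @param size c(width, height), m (full extents).
#' @param label optional label.
#' @export
new_roi <- function(shape = c("rect", "ellipse"), center, size,
                    label = "") {
  shape <- match.arg(shape)
  size <- si_value(size)
  if (any(size <= 0)) stop("ROI must have nonzero area")
  structure(list(shape = shape, center = si_value(center), size = size,
                 label = label), class = "roi")
}

.roi_mask <- function(roi, series) {
  d <- dim(series$frames)
  ny <- d[1]; nx <- d[2]
  px <- cbind(rep(seq_len(nx) - 1L, each = ny),
              rep(seq_len(ny) - 1L, times = nx), 0)
  gl <- tf_apply(series$transform, px)
  u <- (gl[, 1] - roi$center[1]) / (roi$size[1] / 2)
  v <- (gl[, 2] - roi$center[2]) / (roi$size[2] / 2)
  inside <- if (roi$shape == "rect") abs(u) <= 1 & abs(v) <= 1 else
    u^2 + v^2 <= 1
  matrix(inside, ny, nx)
}

#' ROI dF/F time series from a frame series
#'
#' F(t) is the mean pixel intensity inside the ROI (selected through the
#' frame transform); F0 is the mean of F over the baseline window;
#' the result is (F - F0) / F0 on the frame time base. Invariant under
#' multiplying the whole video by a positive constant.
#'
#' @param series a \code{frame_series}.
#' @param roi a \code{\link{new_roi}} (global coordinates).
#' @param baseline_window c(t0, t1), s; must contain >= 1 frame.
#' @param ratio_series optional second frame series for ratiometric
#'   indicators: the two ROI means are divided elementwise before dF/F.
#' @return a \code{trace} (dimensionless dF/F, frame-rate sampled).
#' @export
roi_dff_series <- function(series, roi, baseline_window,
                           ratio_series = NULL) {
  mask <- .roi_mask(roi, series)
  if (!any(mask)) stop("ROI does not intersect the frames")
  f <- apply(series$frames, 3, function(m) mean(m[mask]))
  if (!is.null(ratio_series)) {
    mask2 <- .roi_mask(roi, ratio_series)
    f2 <- apply(ratio_series$frames, 3, function(m) mean(m[mask2]))
    f <- f / f2
  }
  inb <- series$times >= baseline_window[1] & series$times <= baseline_window[2]
  if (!any(inb)) stop("baseline window contains no frames")
  f0 <- mean(f[inb])
  if (f0 == 0) stop("baseline fluorescence is zero; dF/F undefined")
  dt <- if (length(series$times) > 1) mean(diff(series$times)) else 1
  new_trace((f - f0) / f0, 1 / dt, series$times[1], "dF/F", roi$label)
}

#' Event-triggered average of a trace
#'
#' Averages windows of the series aligned at each event time; events whose
#' window extends beyond the series are skipped and counted.
#'
#' @param series a \code{trace}.
#' @param event_times event (trigger) times, s.
#' @param window c(pre, post), s (pre > 0 reaches before the event).
#' @return list: \code{average} (a \code{trace} with t0 = -pre),
#'   \code{n_used}, \code{n_skipped}.
#' @export
event_triggered_average <- function(series, event_times, window) {
  rate <- series$rate
  pre_n <- round(window[1] * rate)
  post_n <- round(window[2] * rate)
  n <- length(series$samples)
  used <- 0L
  acc <- numeric(pre_n + post_n + 1L)
  for (te in event_times) {
    i <- round((te - series$t0) * rate) + 1L
    if (i - pre_n < 1L || i + post_n > n) next
    acc <- acc + series$samples[(i - pre_n):(i + post_n)]
    used <- used + 1L
  }
  if (used == 0L) stop("no events with a full window inside the series")
  list(average = new_trace(acc / used, rate, -pre_n / rate, series$units,
                           "eta"),
       n_used = used, n_skipped = length(event_times) - used)
}

#' Alignment adjustment applied on top of frame transforms
#'
#' Manual alignment corrections are stored separately from the data: the
#' original frame transforms are never modified, and one adjustment can be
#' applied to a whole group of frames.
#' @param transform a \code{transform3d} applied in global coordinates.
#' @param applies_to integer indices of the frames it applies to (default:
#'   all).
#' @export
alignment_adjustment <- function(transform, applies_to = NULL) {
  structure(list(transform = transform, applies_to = applies_to),
            class = "alignment_adjustment")
}

#' Compose a mosaic image from positioned frames
#'
#' Renders each frame into a common global-coordinate pixel grid through
#' \code{adjustment o transform}, nearest-neighbor, later frames painted on
#' top (or averaged with \code{overlap = "mean"}). The output carries its
#' own pixel-to-global transform.
#'
#' @param frames list of \code{\link{new_frame}} objects.
#' @param adjustments optional list of \code{\link{alignment_adjustment}}.
#' @param resolution mosaic pixel size, m/px (> 0).
#' @param overlap \code{"last"} or \code{"mean"}.
#' @return list of class \code{"mosaic"}: \code{pixels}, \code{transform}.
#' @export
compose_mosaic <- function(frames, adjustments = NULL, resolution,
                           overlap = c("last", "mean")) {
  overlap <- match.arg(overlap)
  if (length(frames) == 0L) stop("empty frame list")
  if (resolution <= 0) stop("resolution must be > 0")
  eff_tf <- lapply(seq_along(frames), function(k) {
    tf <- frames[[k]]$transform
    for (adj in adjustments) {
      if (is.null(adj$applies_to) || k %in% adj$applies_to)
        tf <- tf_compose(adj$transform, tf)
    }
    tf
  })
  # global footprint: transformed pixel-corner bounding boxes
  corners <- lapply(seq_along(frames), function(k) {
    p <- frames[[k]]$pixels
    nx <- ncol(p); ny <- nrow(p)
    cs <- rbind(c(-0.5, -0.5, 0), c(nx - 0.5, -0.5, 0),
                c(-0.5, ny - 0.5, 0), c(nx - 0.5, ny - 0.5, 0))
    tf_apply(eff_tf[[k]], cs)
  })
  allc <- do.call(rbind, corners)
  x0 <- min(allc[, 1]); x1 <- max(allc[, 1])
  y0 <- min(allc[, 2]); y1 <- max(allc[, 2])
  nx_m <- max(1L, round((x1 - x0) / resolution))
  ny_m <- max(1L, round((y1 - y0) / resolution))
  # mosaic pixel j (0-based col) center at x0 + (j + 0.5) * res
  mtf <- tf_compose(tf_translate(c(x0 + resolution / 2,
                                   y0 + resolution / 2, 0)),
                    tf_scale(c(resolution, resolution, 1)))
  gx <- x0 + (seq_len(nx_m) - 0.5) * resolution
  gy <- y0 + (seq_len(ny_m) - 0.5) * resolution
  canvas <- matrix(NA_real_, ny_m, nx_m)
  acc <- matrix(0, ny_m, nx_m)
  cnt <- matrix(0L, ny_m, nx_m)
  for (k in seq_along(frames)) {
    p <- frames[[k]]$pixels
    inv <- tf_invert(eff_tf[[k]])
    pts <- cbind(rep(gx, each = ny_m), rep(gy, times = nx_m), 0)
    loc <- tf_apply(inv, pts)
    cx <- round(loc[, 1]); cy <- round(loc[, 2])
    ok <- cx >= 0 & cx <= ncol(p) - 1L & cy >= 0 & cy <= nrow(p) - 1L
    vals <- p[cbind(cy[ok] + 1L, cx[ok] + 1L)]
    idx <- which(ok)
    if (overlap == "last") {
      canvas[idx] <- vals
    } else {
      acc[idx] <- acc[idx] + vals
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  if (overlap == "mean") {
    canvas[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
  }
  structure(list(pixels = canvas, transform = mtf,
                 resolution = resolution), class = "mosaic")
}
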