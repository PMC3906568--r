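#' Frame start times from a camera exposure TTL trace
#'
#' Thresholds the TTL at the midpoint of its dynamic range with a hysteresis
#' band of 10% of the amplitude (rising threshold at mid + 5%, falling at
#' mid - 5%), so band-limited noise does not produce spurious edges. Rising
#' edges give frame start times, falling edges give exposure ends.
#'
#' @param ttl a \code{\link{new_trace}} with the exposure signal.
#' @return data.frame with \code{start} and \code{duration} (s); empty with
#'   a warning when the trace has no dynamic range.
#' @export
frame_times_from_exposure <- function(ttl) {
  stopifnot(inherits(ttl, "trace"))
  x <- ttl$samples
  if (length(x) == 0L) stop("empty trace")
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 0) {
    warning("exposure trace has no dynamic range; no frames detected")
    return(data.frame(start = numeric(), duration = numeric()))
  }
  amp <- hi - lo
  mid <- (hi + lo) / 2
  up <- mid + 0.05 * amp
  dn <- mid - 0.05 * amp
  state <- x[1] >= up
  starts <- integer(); ends <- integer()
  if (state) starts <- 1L
  for (i in 2:length(x)) {
    if (!state && x[i] >= up) {
      state <- TRUE
      starts <- c(starts, i)
    } else if (state && x[i] <= dn) {
      state <- FALSE
      ends <- c(ends, i)
    }
  }
  dur <- rep(NA_real_, length(starts))
  for (k in seq_along(starts)) {
    e <- ends[ends > starts[k]]
    if (length(e)) dur[k] <- (e[1] - starts[k]) / ttl$rate
  }
  data.frame(start = ttl$t0 + (starts - 1L) / ttl$rate, duration = dur)
}

#' Membrane properties from a test-pulse response
#'
#' Voltage clamp: with a step command of amplitude dV, the access resistance
#' is \code{Ra = dV / (Ipeak - I0)} (the instantaneous current jump charges
#' the membrane through the pipette alone), the input resistance is
#' \code{Rin = dV / (Iss - I0)} from the steady-state current, and
#' \code{Rm = Rin - Ra}. The capacitive transient decays with
#' \code{tau = Cm * Ra * Rm / (Ra + Rm)}, fitted by a single exponential,
#' giving \code{Cm = tau * Rin / (Ra * Rm)}. Current clamp: \code{Rin =
#' dVss / dI} (total resistance including the electrode) and the resting
#' potential is the pre-pulse mean.
#'
#' @param response recorded \code{trace} (A in vc, V in ic).
#' @param command command \code{trace} containing exactly one step pulse
#'   with at least 5 ms of baseline before it.
#' @param mode \code{"vc"} or \code{"ic"}.
#' @return list of class \code{"membrane_props"}: \code{Rin}, \code{Raccess},
#'   \code{Rm}, \code{Cm}, \code{tau}, \code{holding_current},
#'   \code{resting_potential} (fields not defined in the mode are NA).
#' @export
membrane_properties <- function(response, command, mode = c("vc", "ic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(response, "trace"), inherits(command, "trace"))
  cmd <- command$samples
  base_lvl <- cmd[1]
  dev <- abs(cmd - base_lvl)
  amp <- max(dev)
  if (amp == 0) stop("zero-amplitude command pulse")
  in_pulse <- dev > amp / 2
  on <- which(in_pulse)[1]
  off <- max(which(in_pulse))
  if (on < 2L) stop("no pre-pulse baseline in command")
  rate <- response$rate
  d_cmd <- mean(cmd[on:off]) - base_lvl
  y <- response$samples
  base <- mean(y[seq_len(on - 1L)])
  if (mode == "ic") {
    nss <- max(3L, round(0.2 * (off - on + 1L)))
    vss <- mean(y[(off - nss + 1L):off])
    return(structure(list(Rin = (vss - base) / d_cmd, Raccess = NA_real_,
                          Rm = NA_real_, Cm = NA_real_, tau = NA_real_,
                          holding_current = NA_real_,
                          resting_potential = base),
                     class = "membrane_props"))
  }
  nss <- max(3L, round(0.2 * (off - on + 1L)))
  iss <- mean(y[(off - nss + 1L):off])
  pulse <- y[on:off]
  ipeak <- if (d_cmd > 0) max(pulse) else min(pulse)
  peak_idx <- on - 1L + which(pulse == ipeak)[1]
  Ra <- d_cmd / (ipeak - base)
  Rin <- d_cmd / (iss - base)
  if (!is.finite(Ra) || Ra <= 0 || !is.finite(Rin) || Rin <= 0)
    stop("could not estimate resistances (degenerate response)")
  Rm <- Rin - Ra
  tau <- tryCatch(.fit_exp_tau(y[peak_idx:off] - iss, rate),
                  error = function(e) {
                    warning("capacitive-transient fit failed: ",
                            conditionMessage(e))
                    NA_real_
                  })
  Cm <- tau * Rin / (Ra * Rm)
  structure(list(Rin = Rin, Raccess = Ra, Rm = Rm, Cm = Cm, tau = tau,
                 holding_current = base, resting_potential = NA_real_),
            class = "membrane_props")
}

#' @export
print.membrane_props <- function(x, ...) {
  cat(sprintf("<membrane_props> Rin=%.3g MOhm Ra=%.3g MOhm Rm=%.3g MOhm Cm=%.3g pF tau=%.3g us\n",
              x$Rin / 1e6, x$Raccess / 1e6, x$Rm / 1e6, x$Cm * 1e12,
              x$tau * 1e6))
  invisible(x)
}

# Single-exponential decay time constant of y (already baseline-subtracted,
# decaying toward 0), fitted by log-linear least squares over the samples
# whose magnitude exceeds 1% of the initial value; refined by nls when the
# log fit is noisy.
.fit_exp_tau <- function(y, rate, refine = FALSE) {
  s <- sign(y[1])
  if (s == 0) stop("exponential fit failed: zero initial value")
  v <- s * y
  # initial contiguous run above 1% of the starting magnitude (later
  # samples are noise around zero and would dominate the log fit)
  cutoff <- v[1] * 0.01
  end <- which(v <= cutoff)[1]
  if (is.na(end)) end <- length(v) + 1L
  keep <- seq_len(end - 1L)
  if (length(keep) < 3L) stop("exponential fit failed: too few usable samples")
  t <- (keep - 1L) / rate
  fit <- stats::lm.fit(cbind(1, t), log(v[keep]))
  tau <- -1 / fit$coefficients[2]
  if (!is.finite(tau) || tau <= 0)
    stop("exponential fit failed (non-decaying segment); residual RMS = ",
         signif(sqrt(mean(fit$residuals^2)), 3))
  if (refine) {
    df <- data.frame(t = t, v = v[keep])
    nl <- tryCatch(stats::nls(v ~ a * exp(-t / tau), data = df,
                              start = list(a = v[1], tau = tau)),
                   error = function(e) NULL)
    if (!is.null(nl)) tau <- stats::coef(nl)[["tau"]]
  }
  unname(tau)
}

#' Current-step IV protocol metrics
#'
#' Computes, from a family of current-clamp responses to step currents:
#' resting membrane potential (mean pre-step voltage across traces), input
#' resistance (least-squares slope of steady-state voltage deflection vs
#' injected current over subthreshold steps), membrane time constant
#' (exponential fit to the onset of the smallest hyperpolarizing step), sag
#' ratio on the largest hyperpolarizing step
#' \code{(Vmin - Vss) / (Vmin - Vbaseline)}, and spike-train measures:
#' spikes are upward crossings of -20 mV with a 2 ms refractory,
#' interspike intervals, first spike latency relative to step onset, and
#' adaptation ratio = mean of the last two ISIs / first ISI (needs >= 3
#' spikes). Spike measures are taken from the trace with the most spikes
#' (smallest step on ties).
#'
#' @param traces list of voltage \code{trace}s, one per step, common timing.
#' @param steps injected current amplitudes (A), one per trace.
#' @param step_window c(t_on, t_off) of the current step, s.
#' @param spike_threshold spike detection level, V.
#' @return list of class \code{"iv_metrics"}.
#' @export
iv_metrics <- function(traces, steps, step_window,
                       spike_threshold = -20e-3) {
  stopifnot(length(traces) == length(steps))
  rate <- traces[[1]]$rate
  t_on <- step_window[1]; t_off <- step_window[2]
  i_on <- round(t_on * rate) + 1L
  i_off <- round(t_off * rate)
  pre <- function(tr) mean(tr$samples[seq_len(i_on - 1L)])
  rmp <- mean(vapply(traces, pre, numeric(1)))
  spikes <- lapply(traces, function(tr)
    .detect_spikes(tr, spike_threshold, refractory = 2e-3))
  n_spk <- vapply(spikes, length, integer(1))
  sub <- which(n_spk == 0L)
  nss <- max(3L, round(0.2 * (i_off - i_on)))
  vss <- vapply(traces, function(tr)
    mean(tr$samples[(i_off - nss + 1L):i_off]), numeric(1))
  Rin <- if (length(sub) >= 2L) {
    dv <- vss[sub] - vapply(traces[sub], pre, numeric(1))
    unname(stats::coef(stats::lm(dv ~ steps[sub]))[2])
  } else NA_real_
  hyp <- which(steps < 0)
  tau_m <- NA_real_
  sag <- NA_real_
  if (length(hyp)) {
    small <- hyp[which.min(abs(steps[hyp]))]
    tr <- traces[[small]]
    seg <- tr$samples[i_on:i_off]
    tau_m <- tryCatch(.fit_exp_tau(seg - vss[small], rate),
                      error = function(e) NA_real_)
    big <- hyp[which.max(abs(steps[hyp]))]
    trb <- traces[[big]]$samples
    vmin <- min(trb[i_on:i_off])
    vb <- pre(traces[[big]])
    sag <- (vmin - vss[big]) / (vmin - vb)
    if (is.finite(sag)) sag <- max(0, min(1, sag))
  }
  isis <- numeric(0)
  latency <- NA_real_
  adapt <- NA_real_
  if (any(n_spk > 0L)) {
    best <- which(n_spk == max(n_spk))
    best <- best[which.min(abs(steps[best]))]
    st <- spikes[[best]]
    latency <- st[1] - t_on
    if (length(st) >= 2L) isis <- diff(st)
    if (length(st) >= 3L)
      adapt <- mean(utils::tail(isis, 2L)) / isis[1]
  }
  structure(list(resting_potential = rmp, input_resistance = Rin,
                 tau_m = tau_m, sag_ratio = sag, isis = isis,
                 first_spike_latency = latency, adaptation_ratio = adapt,
                 n_spikes = n_spk),
            class = "iv_metrics")
}

.detect_spikes <- function(tr, threshold, refractory = 2e-3) {
  x <- tr$samples
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  if (length(up) == 0L) return(numeric(0))
  t <- tr$t0 + (up - 1L) / tr$rate
  keep <- c(TRUE, diff(t) >= refractory)
  # enforce refractory sequentially
  out <- t[1]
  for (v in t[-1]) if (v - out[length(out)] >= refractory) out <- c(out, v)
  out
}

#' Detect repeated synaptic-like events in an analog trace
#'
#' Fixed detection pipeline: zero-phase low-pass filtering, deconvolution
#' with a single-exponential kernel of time constant \code{decay_tau_guess}
#' (frequency-domain division, regularized by an additive constant of 1e-6
#' of the peak spectral magnitude), a robust threshold at
#' \code{threshold_k} times the MAD of the deconvolved signal, and onset
#' extraction at threshold crossings separated by at least
#' \code{min_interval}. Each event is then measured on the original trace:
#' baseline (median of the preceding 5 ms), amplitude (extremum minus
#' baseline, signed), 10-90% rise time, and decay time constant from a
#' single-exponential fit after the peak.
#'
#' @param trace input \code{trace} (longer than 10 * decay_tau_guess).
#' @param decay_tau_guess expected event decay time constant, s.
#' @param threshold_k threshold in MAD units of the deconvolved signal.
#'   The default of 6 keeps the expected number of noise crossings on
#'   multi-second recordings well below one (family-wise control), while
#'   events at signal-to-noise 10 stand 10 or more MADs above the floor.
#' @param min_interval minimum onset separation, s.
#' @param polarity \code{"negative"} (inward currents) or \code{"positive"}.
#' @param lowpass normalized low-pass cutoff (fraction of Nyquist).
#' @return data.frame of class \code{"event_table"}: \code{onset_time},
#'   \code{amplitude}, \code{rise_time}, \code{decay_tau}, \code{baseline}.
#' @export
detect_events <- function(trace, decay_tau_guess = 5e-3, threshold_k = 6,
                          min_interval = 5e-3,
                          polarity = c("negative", "positive"),
                          lowpass = 0.4) {
  polarity <- match.arg(polarity)
  if (decay_tau_guess <= 0) stop("decay_tau_guess must be > 0")
  n <- length(trace$samples)
  rate <- trace$rate
  if (n <= 10 * decay_tau_guess * rate)
    stop("trace shorter than 10 * decay_tau_guess")
  pol <- if (polarity == "negative") -1 else 1
  x <- pol * trace$samples
  # zero-phase low-pass
  bf <- signal::butter(4, lowpass, type = "low")
  xf <- signal::filtfilt(bf, x - x[1]) + x[1]
  # exponential deconvolution in the frequency domain
  kt <- exp(-(seq_len(n) - 1L) / (decay_tau_guess * rate))
  K <- stats::fft(kt)
  reg <- 1e-6 * max(Mod(K))
  D <- stats::fft(xf) / (K + reg)
  d <- Re(stats::fft(D, inverse = TRUE)) / n
  med <- stats::median(d)
  sigma <- stats::mad(d)
  if (sigma == 0) sigma <- stats::sd(d)
  if (!is.finite(sigma) || sigma == 0)
    return(.empty_event_table())
  z <- (d - med) / sigma
  above <- z > threshold_k
  cross <- which(above & !c(FALSE, above[-n]))
  if (length(cross) == 0L) return(.empty_event_table())
  min_gap <- min_interval * rate
  onsets <- cross[1]
  for (c_ in cross[-1])
    if (c_ - onsets[length(onsets)] >= min_gap) onsets <- c(onsets, c_)
  base_n <- max(1L, round(5e-3 * rate))
  win_n <- max(3L, round(5 * decay_tau_guess * rate))
  rows <- lapply(seq_along(onsets), function(k) {
    i0 <- onsets[k]
    b0 <- max(1L, i0 - base_n)
    baseline <- stats::median(trace$samples[b0:max(b0, i0 - 1L)])
    i1 <- min(n, i0 + win_n)
    if (k < length(onsets)) i1 <- min(i1, onsets[k + 1L] - 1L)
    seg <- pol * (trace$samples[i0:i1] - baseline)
    pk <- which.max(seg)
    amp <- pol * seg[pk]
    rise <- .rise_time_1090(seg[seq_len(pk)], rate)
    dec <- if (i1 - (i0 + pk - 1L) >= 3L)
      tryCatch(.fit_exp_tau(seg[pk:length(seg)], rate),
               error = function(e) NA_real_) else NA_real_
    data.frame(onset_time = trace$t0 + (i0 - 1L) / rate,
               amplitude = amp, rise_time = rise, decay_tau = dec,
               baseline = baseline)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_table", class(out))
  out
}

.empty_event_table <- function() {
  out <- data.frame(onset_time = numeric(), amplitude = numeric(),
                    rise_time = numeric(), decay_tau = numeric(),
                    baseline = numeric())
  class(out) <- c("event_table", class(out))
  out
}

.rise_time_1090 <- function(seg, rate) {
  if (length(seg) < 2L) return(NA_real_)
  pk <- seg[length(seg)]
  t10 <- which(seg >= 0.1 * pk)[1]
  t90 <- which(seg >= 0.9 * pk)[1]
  if (is.na(t10) || is.na(t90)) return(NA_real_)
  (t90 - t10) / rate
}

#' Charge transfer in a window, relative to a baseline window
#'
#' Trapezoidal integral of (I - baseline mean) over \code{window}.
#' Additive over adjacent windows.
#' @param trace current \code{trace} (A).
#' @param window c(t0, t1), s, within the trace.
#' @param baseline_window c(b0, b1), s, within the trace.
#' @return charge, coulombs.
#' @export
charge_transfer <- function(trace, window, baseline_window) {
  rate <- trace$rate
  n <- length(trace$samples)
  # both endpoints land on samples, so adjacent windows share a boundary
  # sample and the trapezoid rule is exactly additive over them
  idx <- function(w) {
    i <- round((w - trace$t0) * rate) + 1L
    if (i[1] < 1L || i[2] > n || i[1] >= i[2])
      stop("window [", w[1], ", ", w[2], "] outside trace")
    i
  }
  bi <- idx(baseline_window)
  wi <- idx(window)
  base <- mean(trace$samples[bi[1]:bi[2]])
  y <- trace$samples[wi[1]:wi[2]] - base
  sum((y[-1] + y[-length(y)]) / 2) / rate
}

#' Build a photostimulation map site
#'
#' @param position c(x, y) global position, m.
#' @param trial_events list with one numeric vector of detected event onset
#'   times (s, trial clock) per trial.
#' @param stim_time photostimulation time within each trial, s.
#' @param metrics optional per-trial numeric metric values (e.g. charge).
#' @return list of class \code{"map_site"}.
#' @export
map_site <- function(position, trial_events, stim_time, metrics = NULL) {
  structure(list(position = as.numeric(position),
                 trial_events = trial_events,
                 stim_time = stim_time, metrics = metrics),
            class = "map_site")
}

#' Classify photostimulation sites as evoked vs spontaneous
#'
#' Estimates the spontaneous event rate by pooling baseline-window counts
#' over all sites and trials, then tests each site's post-stimulus count
#' against a Poisson null: \code{p = P(Pois(lambda * test_window * n_trials)
#' >= observed)}. Sites are flagged evoked by Benjamini-Hochberg control of
#' the false discovery rate at \code{alpha} across sites. When the pooled
#' rate is zero, any post-stimulus event is immediately evoked (p = 0).
#'
#' @param sites list of \code{\link{map_site}} objects.
#' @param test_window post-stimulus window length, s.
#' @param baseline_window pre-stimulus baseline window length, s (ends at
#'   the stimulus).
#' @param alpha FDR level.
#' @param metric per-site summary: \code{"count"} (test-window event count)
#'   or \code{"mean_metric"} (mean of the per-trial metrics supplied to
#'   \code{map_site}).
#' @return data.frame: x, y, n_trials, spontaneous_count, test_count,
#'   p_value, p_adj, evoked_flag, metric_value.
#' @export
classify_map_sites <- function(sites, test_window, baseline_window,
                               alpha = 0.05,
                               metric = c("count", "mean_metric")) {
  metric <- match.arg(metric)
  if (length(sites) == 0L) stop("empty site list")
  if (test_window <= 0 || baseline_window <= 0)
    stop("windows must be positive")
  count_site <- function(s) {
    stim <- s$stim_time
    if (stim - baseline_window < 0)
      stop("baseline window extends before trial start")
    nb <- sum(vapply(s$trial_events, function(ev)
      sum(ev >= stim - baseline_window & ev < stim), numeric(1)))
    nt <- sum(vapply(s$trial_events, function(ev)
      sum(ev >= stim & ev < stim + test_window), numeric(1)))
    c(nb, nt, length(s$trial_events))
  }
  cnt <- t(vapply(sites, count_site, numeric(3)))
  total_base_time <- sum(cnt[, 3] * baseline_window)
  if (total_base_time <= 0) stop("zero total baseline time")
  lambda <- sum(cnt[, 1]) / total_base_time
  mu <- lambda * test_window * cnt[, 3]
  p <- ifelse(mu > 0,
              stats::ppois(cnt[, 2] - 1, mu, lower.tail = FALSE),
              ifelse(cnt[, 2] > 0, 0, 1))
  p_adj <- stats::p.adjust(p, method = "BH")
  mv <- if (metric == "count") cnt[, 2] else
    vapply(sites, function(s)
      if (is.null(s$metrics)) NA_real_ else mean(unlist(s$metrics)),
      numeric(1))
  pos <- t(vapply(sites, function(s) s$position[1:2], numeric(2)))
  data.frame(x = pos[, 1], y = pos[, 2], n_trials = cnt[, 3],
             spontaneous_count = cnt[, 1], test_count = cnt[, 2],
             p_value = p, p_adj = p_adj, evoked_flag = p_adj <= alpha,
             metric_value = mv)
}

#' Export a classified map-site table to CSV (and optionally SQLite-style)
#' @param tab data.frame from \code{\link{classify_map_sites}}.
#' @param path output CSV path.
#' @export
write_map_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
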