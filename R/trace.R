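#' Uniformly sampled analog signal
#'
#' @param samples numeric vector.
#' @param rate sample rate, Hz (> 0).
#' @param t0 start time, s.
#' @param units unit string ("V", "A", "TTL", ...).
#' @param channel channel name.
#' @return An object of class \code{"trace"}.
#' @export
new_trace <- function(samples, rate, t0 = 0, units = "", channel = "") {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0,
                 units = units, channel = channel), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz, t0=%g s [%s] %s\n",
              length(x$samples), x$rate, x$t0, x$units, x$channel))
  invisible(x)
}

#' Sample times of a trace
#' @param x a trace.
#' @export
trace_times <- function(x) x$t0 + (seq_along(x$samples) - 1L) / x$rate

#' @export
length.trace <- function(x) length(x$samples)

#' Duration of a trace in seconds (n / rate)
#' @param x a trace.
#' @export
trace_duration <- function(x) length(x$samples) / x$rate

#' Build a command waveform from a descriptor
#'
#' Descriptors mirror the function-generator elements of the task runner:
#' \itemize{
#'   \item \code{squarePulse}: \code{start}, \code{duration}, \code{amplitude}
#'     (added to \code{holding})
#'   \item \code{pulseTrain}: \code{start}, \code{n}, \code{duration},
#'     \code{period}, \code{amplitude}
#'   \item \code{ramp}: \code{start}, \code{duration}, \code{from}, \code{to}
#'   \item \code{sine}: \code{start}, \code{duration}, \code{amplitude},
#'     \code{freq}, optional \code{phase_deg}
#'   \item \code{array}: explicit \code{samples} (must match length)
#' }
#' @param desc descriptor list with a \code{type} field, or a list of
#'   descriptors applied additively.
#' @param rate sample rate (Hz).
#' @param n number of samples.
#' @param holding holding level added to the whole waveform.
#' @return numeric vector of length \code{n}.
#' @export
build_waveform <- function(desc, rate, n, holding = 0) {
  n <- as.integer(n)
  w <- rep(si_value(holding), n)
  if (is.null(desc)) return(w)
  if (!is.null(desc$type)) desc <- list(desc)
  t <- (seq_len(n) - 1L) / rate
  for (el in desc) {
    type <- match.arg(el$type,
                      c("squarePulse", "pulseTrain", "ramp", "sine", "array"))
    if (type == "array") {
      s <- si_value(el$samples)
      if (length(s) != n)
        stop("array waveform length ", length(s), " != task length ", n)
      w <- w + s
      next
    }
    start <- si_value(el$start %||% 0)
    if (type == "squarePulse") {
      dur <- si_value(el$duration)
      amp <- si_value(el$amplitude)
      w <- w + amp * (t >= start & t < start + dur)
    } else if (type == "pulseTrain") {
      dur <- si_value(el$duration)
      amp <- si_value(el$amplitude)
      per <- si_value(el$period)
      for (k in seq_len(el$n) - 1L)
        w <- w + amp * (t >= start + k * per & t < start + k * per + dur)
    } else if (type == "ramp") {
      dur <- si_value(el$duration)
      sel <- t >= start & t < start + dur
      w[sel] <- w[sel] + si_value(el$from) +
        (si_value(el$to) - si_value(el$from)) * (t[sel] - start) / dur
    } else if (type == "sine") {
      dur <- si_value(el$duration)
      sel <- t >= start & t < start + dur
      ph <- (el$phase_deg %||% 0) * pi / 180
      w[sel] <- w[sel] + si_value(el$amplitude) *
        sin(2 * pi * si_value(el$freq) * (t[sel] - start) + ph)
    }
  }
  w
}

# Evaluate an expression with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
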