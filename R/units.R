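# Unit-suffix normalization for config values. Scalars are assumed SI;
# strings like "100 um", "40 kHz", "10 MOhm" are converted to SI numbers.

.unit_factors <- c(
  m = 1, mm = 1e-3, um = 1e-6, "µm" = 1e-6, nm = 1e-9,
  s = 1, ms = 1e-3, us = 1e-6, "µs" = 1e-6, ns = 1e-9,
  V = 1, mV = 1e-3, uV = 1e-6,
  A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9, pA = 1e-12,
  Hz = 1, kHz = 1e3, MHz = 1e6,
  Ohm = 1, kOhm = 1e3, MOhm = 1e6, GOhm = 1e9,
  F = 1, uF = 1e-6, nF = 1e-9, pF = 1e-12,
  W = 1, mW = 1e-3, uW = 1e-6,
  J = 1, mJ = 1e-3, uJ = 1e-6, nJ = 1e-9,
  deg = 1, px = 1
)

#' Normalize a config value with an optional unit suffix to SI
#'
#' Numeric values pass through unchanged (assumed SI). Character values of
#' the form \code{"<number> <unit>"} (e.g. \code{"100 um"}, \code{"40 kHz"},
#' \code{"10 MOhm"}) are converted. Vectors are handled elementwise.
#'
#' @param x numeric or character scalar/vector, or a list of such.
#' @return numeric vector in SI units.
#' @export
si_value <- function(x) {
  if (is.list(x)) x <- unlist(x, use.names = FALSE)
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x)) stop("cannot interpret value of class ", class(x)[1])
  vapply(x, function(v) {
    v <- trimws(v)
    m <- regmatches(v, regexec("^([-+0-9.eE]+)\\s*([A-Za-zµ/]*)$", v))[[1]]
    if (length(m) == 0L) stop("cannot parse quantity: '", v, "'")
    num <- suppressWarnings(as.numeric(m[2]))
    if (is.na(num)) stop("cannot parse quantity: '", v, "'")
    unit <- sub("/px$", "", m[3])  # "2 um/px" -> per-pixel scale in meters
    if (unit == "") return(num)
    f <- .unit_factors[[unit]]
    if (is.null(f)) stop("unknown unit '", m[3], "' in '", v, "'")
    num * f
  }, numeric(1), USE.NAMES = FALSE)
}
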