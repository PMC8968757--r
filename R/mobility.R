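# Number-based PSD reduction for mobility-sizer (SMPS/FMPS) scans.

#' Mobility-sizer scan
#'
#' A size-resolved number-concentration record: ascending, non-overlapping
#' diameter channels with a number concentration each, plus instrument
#' metadata. Each channel is represented by the geometric mean of its
#' bounds.
#'
#' @param d_lo,d_hi Channel lower/upper diameter bounds, nm; positive,
#'   ascending, non-overlapping.
#' @param concentration Number concentrations, particles/cm^3, >= 0.
#' @param instrument `"smps"`, `"fmps"` or `"other"`.
#' @param sample_flow Sample flow, L/min.
#' @param dilution_factor Total dilution applied upstream of the instrument.
#' @param integration_time Averaging time, s.
#'
#' @return An object of class `"mobility_scan"`.
#' @export
mobility_scan <- function(d_lo, d_hi, concentration,
                          instrument = c("other", "smps", "fmps"),
                          sample_flow = NA_real_, dilution_factor = 1,
                          integration_time = NA_real_) {
  instrument <- match.arg(instrument)
  n <- length(d_lo)
  if (n < 1L || length(d_hi) != n || length(concentration) != n) {
    abort_invalid("channel bounds and concentrations must have equal length >= 1")
  }
  if (any(d_lo <= 0) || any(d_hi <= d_lo)) {
    abort_invalid("channel bounds must be positive with d_hi > d_lo")
  }
  if (n > 1L && any(d_lo[-1] < d_hi[-n] - 1e-9)) {
    abort_invalid("channels must be ascending and non-overlapping")
  }
  if (any(concentration < 0)) abort_invalid("concentrations must be >= 0")
  structure(
    list(channels = data.frame(d_lo = d_lo, d_hi = d_hi,
                               midpoint = sqrt(d_lo * d_hi),
                               concentration = concentration),
         instrument = instrument, sample_flow = sample_flow,
         dilution_factor = dilution_factor,
         integration_time = integration_time),
    class = "mobility_scan"
  )
}

#' @export
print.mobility_scan <- function(x, ...) {
  ch <- x$channels
  cat(sprintf("Mobility scan (%s): %d channels, %.3g-%.3g nm, total %.3g /cm3\n",
              toupper(x$instrument), nrow(ch), min(ch$d_lo), max(ch$d_hi),
              sum(ch$concentration)))
  invisible(x)
}

#' Truncate a scan to a diameter range
#'
#' Retains the channels whose geometric midpoints lie in `[d_min, d_max]`,
#' e.g. to restrict a wide SMPS scan to the FMPS range for instrument
#' inter-comparison. Retained concentrations are never rescaled.
#'
#' @param scan A [mobility_scan()].
#' @param d_min,d_max Range bounds, nm.
#' @return A [mobility_scan()] with the retained channels.
#' @export
truncate_channels <- function(scan, d_min, d_max) {
  stopifnot(inherits(scan, "mobility_scan"))
  if (d_min >= d_max) abort_invalid("need d_min < d_max")
  keep <- scan$channels$midpoint >= d_min & scan$channels$midpoint <= d_max
  if (!any(keep)) {
    abort("no channels with midpoints in range", "aerodose_empty_scan")
  }
  ch <- scan$channels[keep, ]
  mobility_scan(ch$d_lo, ch$d_hi, ch$concentration,
                instrument = scan$instrument, sample_flow = scan$sample_flow,
                dilution_factor = scan$dilution_factor,
                integration_time = scan$integration_time)
}

#' Subtract a background scan
#'
#' Channel-wise subtraction of a background number-concentration scan
#' measured on the same channel grid, clamped at zero.
#'
#' @param scan,background [mobility_scan()] objects with identical grids.
#' @return A [mobility_scan()].
#' @export
background_subtract <- function(scan, background) {
  stopifnot(inherits(scan, "mobility_scan"), inherits(background, "mobility_scan"))
  a <- scan$channels; b <- background$channels
  if (nrow(a) != nrow(b) ||
      any(abs(a$d_lo - b$d_lo) > 1e-9) || any(abs(a$d_hi - b$d_hi) > 1e-9)) {
    abort_invalid("scan and background must share the same channel grid")
  }
  mobility_scan(a$d_lo, a$d_hi, pmax(a$concentration - b$concentration, 0),
                instrument = scan$instrument, sample_flow = scan$sample_flow,
                dilution_factor = scan$dilution_factor,
                integration_time = scan$integration_time)
}

#' Count median diameter and GSD of a scan
#'
#' Number-weighted geometric moment statistics: the count median diameter is
#' the geometric mean diameter `exp(sum(n_i log d_i) / sum(n_i))` over the
#' channel midpoints, and the GSD is the geometric standard deviation
#' `exp(sqrt(sum(n_i (log d_i - log CMD)^2) / sum(n_i)))`. A single-channel
#' scan returns that channel's midpoint with GSD 1.
#'
#' @param scan A [mobility_scan()].
#' @return A list with `cmd` (micrometres) and `gsd`.
#' @export
number_stats <- function(scan) {
  stopifnot(inherits(scan, "mobility_scan"))
  ch <- scan$channels
  ntot <- sum(ch$concentration)
  if (ntot <= 0) abort("zero total concentration", "aerodose_empty_scan")
  w <- ch$concentration / ntot
  mu <- sum(w * log(ch$midpoint))
  sg <- sqrt(sum(w * (log(ch$midpoint) - mu)^2))
  list(cmd = exp(mu) / 1000, gsd = max(exp(sg), 1))  # nm -> um
}

#' MMAD from a mobility scan
#'
#' The full number-to-mass conversion chain: geometric moment statistics of
#' the scan give (CMD, GSD); the Hatch-Choate relation with moment order 3
#' converts CMD to the mass median (physical) diameter; multiplying by the
#' square root of the e-liquid's effective density gives the mass median
#' aerodynamic diameter. Mobility diameter is treated as physical diameter.
#'
#' @param scan A [mobility_scan()].
#' @param eliquid An [eliquid()] supplying the effective density.
#' @return MMAD in micrometres.
#' @examples
#' # two log-symmetric channels reduce to CMD 100 nm, GSD 2
#' sc <- mobility_scan(c(40, 160), c(62.5, 250), c(500, 500))
#' mobility_mmad(sc, eliquid(0.3, 0.7))
#' @export
mobility_mmad <- function(scan, eliquid) {
  stopifnot(inherits(eliquid, "eliquid"))
  s <- number_stats(scan)
  mmd <- hatch_choate_mmd(s$cmd, s$gsd, b = 3)
  mmd_to_mmad(mmd, eliquid$effective_density)
}
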