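#' Round to significant figures, half away from zero
#'
#' Rounds `x` to `digits` significant figures using the round-half-away-from-zero
#' convention of hand-reported tables (e.g. 1.05e8 -> 1.1e8), rather than the
#' IEEE half-to-even rule used by [signif()].  Used when rendering kinetic
#' tables so that printed values match manuscript-style rounding.
#'
#' @param x numeric vector.
#' @param digits number of significant figures (default 2).
#' @return numeric vector rounded to `digits` significant figures.
#' @examples
#' signif_half_up(1.05e8, 2)  # 1.1e8
#' signif_half_up(0.2069, 2)  # 0.21
#' @export
signif_half_up <- function(x, digits = 2) {
  check_count(digits, "digits")
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz]))) - digits + 1
  # nudge by a relative epsilon so values that are exactly at .5 in decimal
  # (up to binary representation) round away from zero
  scaled <- abs(x[nz]) / 10^mag
  out[nz] <- sign(x[nz]) * floor(scaled + 0.5 + 1e-9) * 10^mag
  out
}

#' Convert between an exponential rate constant and its time constant
#'
#' A first-order process with rate constant `k` (s^-1) has time constant
#' `tau = 1/k` (s); e.g. the Cy3 photobleaching rate 0.053 s^-1 corresponds to
#' a time constant of 18.9 s.
#'
#' @param rate rate constant in s^-1 (> 0).
#' @param tau time constant in s (> 0).
#' @return the corresponding time constant (s) or rate constant (s^-1).
#' @examples
#' rate_to_time_constant(0.053)  # 18.87 s
#' time_constant_to_rate(18.9)   # 0.0529 s^-1
#' @export
rate_to_time_constant <- function(rate) {
  check_positive(rate, "rate")
  1 / rate
}

#' @rdname rate_to_time_constant
#' @export
time_constant_to_rate <- function(tau) {
  check_positive(tau, "tau")
  1 / tau
}

# Freedman-Diaconis bin width with fallbacks for low-IQR samples and a
# minimum-resolution guard: multimodal samples can have an IQR spanning the
# gap between modes, which would put a whole mode inside one bin.
fd_bin_width <- function(x, min_bins = 12) {
  n <- length(x)
  bw <- 2 * stats::IQR(x) / n^(1 / 3)
  if (!is.finite(bw) || bw <= 0) bw <- diff(range(x)) / max(ceiling(sqrt(n)), 1)
  span <- diff(range(x))
  if (span > 0 && is.finite(bw) && bw > 0) bw <- min(bw, span / min_bins)
  bw
}

# Histogram with left-closed bins [a, b) on a regular grid anchored at a
# multiple of `width`, covering all of `x`.
grid_hist <- function(x, width, origin = NULL) {
  if (is.null(origin)) origin <- floor(min(x) / width) * width
  top <- origin + ceiling((max(x) - origin) / width + 1e-9) * width
  if (top <= origin) top <- origin + width
  breaks <- seq(origin, top, by = width)
  # right = FALSE gives [a, b) bins; the last bin is closed to keep max(x)
  h <- graphics::hist(x, breaks = breaks, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  list(edges = breaks, mids = h$mids, counts = h$counts, width = width)
}
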