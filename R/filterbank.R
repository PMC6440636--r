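# ERB-spaced gammatone filterbank used for all band-power analyses.
# Filters are 4th-order gammatones realized as FIR prototypes; band powers
# are reported relative to each filter's own unit-impulse output power, so
# a unit impulse reads 0 dB in every band and any per-filter gain convention
# cancels in the spectral-difference and ILD computations.

#' ERB (equivalent rectangular bandwidth) of an auditory filter
#'
#' Glasberg & Moore: ERB(f) = 24.7 (4.37 f/1000 + 1) Hz.
#'
#' @param f Center frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' ERB-number scale (ERB-rate) and its inverse
#'
#' @param f Frequency in Hz.
#' @return ERB number (dimensionless).
#' @export
erb_number <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_number
#' @param e ERB number.
#' @export
erb_number_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Center frequencies spaced uniformly on the ERB scale
#'
#' @param fmin,fmax Frequency range in Hz; analysis default 200 Hz - 16 kHz.
#' @param density Filters per ERB (default 1).
#' @param fs Sampling rate in Hz; \code{fmax} must lie below Nyquist.
#' @return Ascending numeric vector of center frequencies in [fmin, fmax].
#' @export
erb_centers <- function(fmin = 200, fmax = 16000, density = 1, fs = 48000) {
  stopifnot(fmin > 0, fmax > fmin, density > 0)
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency fs/2")
  e1 <- erb_number(fmin)
  e2 <- erb_number(fmax)
  n <- floor((e2 - e1) * density) + 1
  erb_number_inv(e1 + (seq_len(n) - 1) / density)
}

#' FIR prototype of a 4th-order gammatone filter
#'
#' g(t) = t^3 exp(-2 pi b ERB(fc) t) cos(2 pi fc t), b = 1.019, normalized
#' to unit peak magnitude response at fc.
#'
#' @param fc Center frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param length_s Prototype duration in seconds; the default covers the
#'   envelope decay of the narrowest analysis filter at 200 Hz.
#' @return Numeric vector of filter coefficients.
#' @export
gammatone_fir <- function(fc, fs, length_s = 0.064) {
  n <- max(16L, as.integer(round(length_s * fs)))
  t <- (seq_len(n) - 1) / fs
  b <- 1.019 * erb_bandwidth(fc)
  g <- t^3 * exp(-2 * pi * b * t) * cos(2 * pi * fc * t)
  # unity peak magnitude at fc
  h <- sum(g * exp(-2i * pi * fc * t))
  g / Mod(h)
}

#' Band powers at the output of the gammatone filterbank
#'
#' Powers are 10 log10 of the summed squared filter output, referenced to
#' the filter's own unit-impulse output power, so a unit impulse yields 0 dB
#' in every band and scaling the input by g shifts all bands by
#' 20 log10(g). An all-zero channel returns the silence floor.
#'
#' @param channel Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param centers Filter center frequencies in Hz (see [erb_centers()]).
#' @param floor_db Silence floor in dB (default -120).
#' @return Numeric vector of band powers in dB, one per center.
#' @export
band_powers_db <- function(channel, fs, centers = erb_centers(fs = fs),
                           floor_db = -120) {
  stopifnot(length(channel) >= 1, fs > 0)
  vapply(centers, function(fc) {
    g <- gammatone_fir(fc, fs)
    y <- convolve_full(channel, g)
    p <- sum(y^2) / sum(g^2)
    max(floor_db, 10 * log10(p))
  }, numeric(1))
}

# full linear convolution via FFT
convolve_full <- function(x, y) {
  n <- length(x) + length(y) - 1L
  nf <- stats::nextn(n, 2)
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(y, numeric(nf - length(y)))), inverse = TRUE))[seq_len(n)] / nf
}

#' Frequency-region definitions
#'
#' Three contiguous analysis regions: low 200 Hz - 1 kHz, mid 1 - 5 kHz,
#' high 5 - 16 kHz. Filters belong to the region containing their center
#' frequency; boundaries are half-open [low, high) with the final region
#' closed at 16 kHz.
#'
#' @param boundaries Strictly increasing numeric vector of region edges, Hz.
#' @param labels Region labels, one fewer than the boundaries.
#' @return data.frame with columns \code{region}, \code{f_lo}, \code{f_hi}.
#' @export
frequency_regions <- function(boundaries = c(200, 1000, 5000, 16000),
                              labels = c("low", "mid", "high")) {
  stopifnot(all(diff(boundaries) > 0), length(labels) == length(boundaries) - 1)
  data.frame(region = labels,
             f_lo = boundaries[-length(boundaries)],
             f_hi = boundaries[-1])
}

#' Assign filter centers to frequency regions
#'
#' @param centers Center frequencies in Hz.
#' @param regions Region table from [frequency_regions()].
#' @return Character vector of region labels (NA outside all regions).
#' @export
region_of <- function(centers, regions = frequency_regions()) {
  out <- rep(NA_character_, length(centers))
  for (i in seq_len(nrow(regions))) {
    hi_ok <- if (i == nrow(regions)) centers <= regions$f_hi[i] else centers < regions$f_hi[i]
    out[centers >= regions$f_lo[i] & hi_ok] <- regions$region[i]
  }
  out
}
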