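# One-dimensional periodic modulation waveforms. These profiles govern how a
# texture property (orientation, contrast, luminance, ...) varies across the
# image: smoothly (sinewave), abruptly with uniform regions between edges
# (square-wave), or abruptly with non-uniform regions (cusp-wave, a square
# wave with an equal-amplitude sine removed). The missing-fundamental wave
# removes the square wave's fundamental harmonic (4/pi times its amplitude)
# instead.

#' Waveform kinds
#'
#' The four supported modulation waveform kinds: sinewave (`"SN"`),
#' square-wave (`"SQ"`), cusp-wave (`"CS"`, square minus equal-amplitude
#' sine) and missing-fundamental (`"MF"`, square minus `4/pi` times the
#' sine, i.e. its own fundamental).
#'
#' @export
waveform_kinds <- c("SN", "SQ", "CS", "MF")

# Shared shape definitions at unit amplitude, evaluated at fractional image
# position t in [0, 1). sign(0) is defined as +1 (deterministic tie-break at
# the zero crossings of the generating sinusoid).
waveform_shape <- function(kind, frequency, phase, t) {
  sn <- sin(2 * pi * frequency * t + phase)
  sq <- ifelse(sn >= 0, 1, -1)
  switch(kind,
    SN = sn,
    SQ = sq,
    CS = sq - sn,
    MF = sq - (4 / pi) * sn
  )
}

#' Sample a modulation waveform
#'
#' Samples one of the four modulation waveforms on a uniform grid of
#' `n_samples` points spanning the full image width, so a frequency of
#' `f` cycles-per-image (cpi) completes exactly `f` periods across the grid.
#' The cusp wave is constructed pointwise as square minus sine at identical
#' amplitude, frequency and phase; the missing-fundamental wave as square
#' minus `4/pi` times the sine.
#'
#' @param kind one of `"SN"`, `"SQ"`, `"CS"`, `"MF"`.
#' @param frequency modulation frequency in cycles per image (> 0).
#' @param phase phase in radians.
#' @param amplitude modulation amplitude (dimensionless scale factor, >= 0).
#' @param n_samples number of samples across the image; must satisfy the
#'   Nyquist bound `n_samples >= 2 * frequency`. The default 256 matches the
#'   filter-model grid width.
#' @return an object of class `"modulation_waveform"`: a list with fields
#'   `kind`, `amplitude`, `frequency`, `phase`, `n_samples` and `values`.
#' @examples
#' w <- sample_waveform("SQ", frequency = 1)
#' rms_amplitude(w)   # 1: the unit square wave carries unit rms energy
#' @export
sample_waveform <- function(kind = c("SN", "SQ", "CS", "MF"), frequency,
                            phase = 0, amplitude = 1, n_samples = 256L) {
  kind <- match.arg(kind)
  stopifnot_scalar_positive(frequency, "frequency")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0) {
    texmod_error("texmod_invalid_argument", "`amplitude` must be >= 0")
  }
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples <= 0 ||
      n_samples != round(n_samples)) {
    texmod_error("texmod_invalid_argument",
                 "`n_samples` must be a single positive integer")
  }
  n <- as.integer(n_samples)
  if (n < 2 * frequency) {
    texmod_error("texmod_invalid_argument", sprintf(
      "`n_samples` = %d undersamples frequency %g cpi (need >= %g)",
      n, frequency, 2 * frequency))
  }
  t <- (seq_len(n) - 1L) / n
  values <- amplitude * waveform_shape(kind, frequency, phase, t)
  structure(
    list(kind = kind, amplitude = amplitude, frequency = frequency,
         phase = phase, n_samples = n, values = values),
    class = "modulation_waveform"
  )
}

#' Evaluate a waveform at arbitrary image positions
#'
#' Evaluates the same analytic shape as [sample_waveform()] at continuous
#' fractional positions `t` in `[0, 1)` across the image; used when assigning
#' modulation values to Gabors at off-grid positions.
#'
#' @param wave a `"modulation_waveform"`.
#' @param t numeric vector of fractional positions in `[0, 1)`.
#' @return numeric vector of modulation values (includes the amplitude).
#' @export
waveform_value <- function(wave, t) {
  stopifnot(inherits(wave, "modulation_waveform"))
  wave$amplitude * waveform_shape(wave$kind, wave$frequency, wave$phase, t)
}

#' Root-mean-square amplitude of a waveform
#'
#' The rms value over the sampled profile (an integer number of cycles by
#' construction). At unit amplitude the square, sine and cusp waves carry rms
#' energies of 1, `sqrt(1/2)` (0.71) and `sqrt(3/2 - 4/pi)` (0.48)
#' respectively; the inverse of this ordering predicts detection thresholds
#' for a region-based mechanism that integrates texture energy.
#'
#' @param wave a `"modulation_waveform"`.
#' @return the rms value, a non-negative scalar.
#' @export
rms_amplitude <- function(wave) {
  stopifnot(inherits(wave, "modulation_waveform"))
  if (length(wave$values) == 0L) {
    texmod_error("texmod_invalid_argument", "empty waveform profile")
  }
  sqrt(mean(wave$values^2))
}

#' Amplitude of the fundamental Fourier component
#'
#' The amplitude of the discrete Fourier component at the waveform's own
#' modulation frequency. For a unit square wave this is `4/pi` (1.273); for a
#' unit cusp wave `4/pi - 1`; the missing-fundamental wave has (numerically)
#' none.
#'
#' @param wave a `"modulation_waveform"` whose frequency is an integer number
#'   of cycles on its grid (otherwise the component is not resolvable and an
#'   error is raised).
#' @return the fundamental amplitude, a non-negative scalar.
#' @export
fundamental_amplitude <- function(wave) {
  stopifnot(inherits(wave, "modulation_waveform"))
  f <- wave$frequency
  n <- wave$n_samples
  if (abs(f - round(f)) > 1e-9 || round(f) >= n / 2) {
    texmod_error("texmod_invalid_argument", sprintf(
      "frequency %g cpi is not resolvable on a grid of %d samples", f, n))
  }
  k <- as.integer(round(f))
  2 * Mod(stats::fft(wave$values)[k + 1L]) / n
}

#' Write a waveform profile to CSV
#'
#' Single-column CSV with a header row; kind, frequency, phase and amplitude
#' are stored as `#`-prefixed comment metadata lines before the header.
#'
#' @param wave a `"modulation_waveform"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "modulation_waveform"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kind: %s", wave$kind),
    sprintf("# frequency_cpi: %g", wave$frequency),
    sprintf("# phase_rad: %g", wave$phase),
    sprintf("# amplitude: %g", wave$amplitude),
    "value"
  ), con)
  writeLines(format(wave$values, digits = 15, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' @export
print.modulation_waveform <- function(x, ...) {
  cat(sprintf("<modulation_waveform> %s, %g cpi, amplitude %g, phase %g rad, %d samples\n",
              x$kind, x$frequency, x$amplitude, x$phase, x$n_samples))
  invisible(x)
}
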