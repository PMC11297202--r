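# Gabor micropattern geometry. The micropatterns are odd-symmetric (sine
# phase at the envelope centre), with spatial-frequency bandwidth specified
# in octaves at half height of the amplitude spectrum.

#' Gaussian envelope SD from spatial frequency and octave bandwidth
#'
#' For a Gabor with carrier spatial frequency `sf` (cycles per degree) and a
#' full bandwidth of `bandwidth` octaves at half height of its amplitude
#' spectrum, the envelope SD is
#' \deqn{\sigma = \frac{\sqrt{2\ln 2}}{2\pi\,sf}\cdot\frac{2^B + 1}{2^B - 1}.}
#'
#' @param sf carrier spatial frequency, cycles per degree (> 0).
#' @param bandwidth full bandwidth at half height, octaves (> 0).
#' @return envelope SD in degrees.
#' @examples
#' gabor_sigma_from_bandwidth(6, 1.5)  # ~0.065 deg
#' @export
gabor_sigma_from_bandwidth <- function(sf, bandwidth) {
  stopifnot_scalar_positive(sf, "sf")
  stopifnot_scalar_positive(bandwidth, "bandwidth")
  sqrt(2 * log(2)) / (2 * pi * sf) * (2^bandwidth + 1) / (2^bandwidth - 1)
}

#' Octave bandwidth from spatial frequency and envelope SD
#'
#' Inverse of [gabor_sigma_from_bandwidth()].
#'
#' @param sf carrier spatial frequency, cycles per degree.
#' @param sigma envelope SD, degrees.
#' @return full bandwidth at half height, octaves.
#' @export
gabor_bandwidth_from_sigma <- function(sf, sigma) {
  stopifnot_scalar_positive(sf, "sf")
  stopifnot_scalar_positive(sigma, "sigma")
  # Half-height half-width of the Gaussian amplitude spectrum around sf:
  h <- sqrt(2 * log(2)) / (2 * pi * sigma)
  if (h >= sf) {
    texmod_error("texmod_invalid_argument",
                 "envelope too narrow: lower half-height frequency is not positive")
  }
  log2((sf + h) / (sf - h))
}

#' Gabor micropattern parameters
#'
#' @param luminance_sf carrier spatial frequency, cycles per degree.
#' @param bandwidth full bandwidth at half height, octaves.
#' @param envelope_diameter spatial support of the rendered patch, in
#'   multiples of the envelope SD.
#' @return an object of class `"gabor_params"` with the derived envelope SD
#'   (`sigma`, degrees). The carrier is odd-symmetric: sine phase at the
#'   envelope centre, with a per-Gabor polarity of +/-1.
#' @export
gabor_params <- function(luminance_sf = 6, bandwidth = 1.5,
                         envelope_diameter = 5) {
  stopifnot_scalar_positive(envelope_diameter, "envelope_diameter")
  structure(
    list(luminance_sf = luminance_sf, bandwidth = bandwidth,
         envelope_diameter = envelope_diameter,
         sigma = gabor_sigma_from_bandwidth(luminance_sf, bandwidth)),
    class = "gabor_params"
  )
}
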