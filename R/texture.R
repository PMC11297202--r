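# Gabor-micropattern texture synthesis. A texture is a circular field of
# quasi-randomly placed odd-symmetric Gabors whose orientation, contrast, or
# the variance of either, is modulated along the horizontal axis by a 1-D
# waveform. Luminance-modulated (LM) textures are composited from two video
# frames (a contrast-modulated Gabor frame and a luminance grating frame)
# whose average implements the halving of effective contrast produced by
# frame alternation on the display.

texture_types <- c("LM", "OM", "CM", "OVM", "CVM")

default_orientation_jitter <- function(type) {
  switch(type, OM = 5, LM = 5, CM = 8, OVM = 10, CVM = 10)
}

#' Texture specification
#'
#' Describes one micropattern texture: its modulation type, field geometry,
#' Gabor population and per-type jitter magnitudes.
#'
#' @param modulation_type one of `"LM"`, `"OM"`, `"CM"`, `"OVM"`, `"CVM"`.
#' @param field_diameter texture diameter, degrees.
#' @param n_gabors number of micropatterns.
#' @param min_separation minimum centre-to-centre distance between Gabors,
#'   in multiples of the Gabor envelope SD.
#' @param mean_orientation mean Gabor orientation, degrees (90 = horizontal).
#' @param mean_contrast mean Michelson contrast of the Gabors.
#' @param orientation_jitter half-range of the two-valued orientation jitter,
#'   degrees; defaults to the per-type study values (±5 for OM and LM, ±8 for
#'   CM, ±10 for OVM and CVM).
#' @param contrast_jitter half-range of the two-valued contrast jitter used
#'   as the variance carrier for CVM textures, Michelson units.
#' @param orientation_grid orientation quantization step, degrees; 0.25 gives
#'   1440 orientation templates over the full circle.
#' @param gabor a [gabor_params()] object.
#' @return an object of class `"texture_spec"`.
#' @export
texture_spec <- function(modulation_type = c("OM", "LM", "CM", "OVM", "CVM"),
                         field_diameter = 10, n_gabors = 2500,
                         min_separation = 1.7, mean_orientation = 90,
                         mean_contrast = 0.333,
                         orientation_jitter = NULL,
                         contrast_jitter = 0.1,
                         orientation_grid = 0.25,
                         gabor = gabor_params()) {
  modulation_type <- match.arg(modulation_type)
  stopifnot_scalar_positive(field_diameter, "field_diameter")
  stopifnot_scalar_positive(min_separation, "min_separation")
  stopifnot_scalar_positive(orientation_grid, "orientation_grid")
  if (n_gabors < 1 || n_gabors != round(n_gabors)) {
    texmod_error("texmod_invalid_argument", "`n_gabors` must be a positive integer")
  }
  if (mean_contrast <= 0 || mean_contrast > 1) {
    texmod_error("texmod_invalid_argument", "`mean_contrast` must be in (0, 1]")
  }
  if (abs(360 / orientation_grid - round(360 / orientation_grid)) > 1e-9) {
    texmod_error("texmod_invalid_argument",
                 "`orientation_grid` must divide 360 evenly")
  }
  if (is.null(orientation_jitter)) {
    orientation_jitter <- default_orientation_jitter(modulation_type)
  }
  structure(
    list(modulation_type = modulation_type, field_diameter = field_diameter,
         n_gabors = as.integer(n_gabors), min_separation = min_separation,
         mean_orientation = mean_orientation, mean_contrast = mean_contrast,
         orientation_jitter = orientation_jitter,
         contrast_jitter = contrast_jitter,
         orientation_grid = orientation_grid, gabor = gabor),
    class = "texture_spec"
  )
}

#' Quasi-random Gabor placement with a minimum-separation constraint
#'
#' Dart-throwing with rejection: candidate centres are drawn uniformly inside
#' the circular field and accepted only if at least `min_sep` away from every
#' centre accepted so far. Uses R's global RNG; call `set.seed()` first for a
#' reproducible layout.
#'
#' @param n number of Gabors to place.
#' @param min_sep minimum pairwise centre distance, degrees.
#' @param field_diameter field diameter, degrees.
#' @param max_attempts rejection budget per Gabor before the density is
#'   declared infeasible.
#' @return an `n` x 2 matrix of (x, y) positions in degrees, centred on 0.
#' @export
place_gabors <- function(n, min_sep, field_diameter, max_attempts = 1e4) {
  if (n < 1 || n != round(n)) {
    texmod_error("texmod_invalid_argument", "`n` must be a positive integer")
  }
  stopifnot_scalar_positive(min_sep, "min_sep")
  stopifnot_scalar_positive(field_diameter, "field_diameter")
  r_field <- field_diameter / 2
  # Pigeonhole bound: discs of radius min_sep/2 around each centre are
  # disjoint and lie inside the field grown by min_sep/2; hexagonal packing
  # density caps how many can fit.
  n_bound <- floor(0.9069 * (r_field + min_sep / 2)^2 / (min_sep / 2)^2)
  if (n > n_bound) {
    texmod_error("texmod_infeasible_density", sprintf(
      "cannot place %d Gabors with min separation %g in a %g-deg field (packing bound %d); 0 placed",
      n, min_sep, field_diameter, n_bound), n_achieved = 0L)
  }
  xs <- numeric(n)
  ys <- numeric(n)
  placed <- 0L
  min_sep2 <- min_sep^2
  while (placed < n) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      x <- stats::runif(1, -r_field, r_field)
      y <- stats::runif(1, -r_field, r_field)
      if (x * x + y * y > r_field^2) next
      if (placed == 0L ||
          min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >= min_sep2) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      texmod_error("texmod_infeasible_density", sprintf(
        "placement rejection budget exhausted after %d Gabors of %d", placed, n),
        n_achieved = placed)
    }
    placed <- placed + 1L
    xs[placed] <- x
    ys[placed] <- y
  }
  cbind(x = xs, y = ys)
}

#' Quantize an orientation to the template grid
#'
#' Rounds to the nearest multiple of `grid` degrees and wraps into
#' `[0, 360)`. A 0.25-degree grid yields 1440 distinct orientation templates.
#'
#' @param theta orientation(s), degrees.
#' @param grid grid step, degrees.
#' @return quantized orientation(s) in `[0, 360)`.
#' @export
quantize_orientation <- function(theta, grid = 0.25) {
  stopifnot_scalar_positive(grid, "grid")
  (round(theta / grid) * grid) %% 360
}

#' Assign per-Gabor orientation and contrast under a modulation waveform
#'
#' Computes each Gabor's orientation and Michelson contrast from the
#' modulation waveform value `W(x)` at the Gabor's horizontal position
#' (modulation varies along the horizontal axis). Rules by texture type, with
#' `j` a per-Gabor random sign and `j0`, `c0` the spec's jitter half-ranges:
#'
#' * `OM`: orientation = mean + j*j0 + W(x); contrast = mean.
#' * `LM`: orientation = mean + j*j0; contrast = 2*mean*(1 + W(x)), the
#'   contrast profile of the Gabor frame before frame-alternation halving
#'   (at the study amplitude 0.5 this is amplitude 0.666*0.5 = 0.333 about a
#'   mean of 0.666).
#' * `CM`: orientation = mean + j*j0; contrast = mean + W(x).
#' * `OVM`: orientation = mean + j*j0*(1 + W(x)); contrast = mean
#'   (multiplicative modulation of the jitter magnitude, so orientation
#'   variance is modulated while the mean orientation is preserved).
#' * `CVM`: orientation = mean + j*j0; contrast = mean + s*c0*(1 + W(x)) with
#'   an independent per-Gabor sign `s` (contrast-variance analogue of OVM).
#'
#' Orientations are quantized to the template grid afterwards. Jitter signs
#' are drawn once per call (fixed for the stimulus). Contrasts falling
#' outside `[0, 1]` raise an error rather than being clipped.
#'
#' @param positions matrix from [place_gabors()].
#' @param spec a [texture_spec()].
#' @param wave a [sample_waveform()] object; its amplitude is the modulation
#'   amplitude (for OM/OVM in degrees, CM/CVM in Michelson units, LM as the
#'   Michelson contrast of the grating frame, at most 0.5).
#' @return a data frame with columns `x`, `y`, `orientation`, `contrast`,
#'   `polarity` (per-Gabor carrier sign).
#' @export
assign_modulation <- function(positions, spec, wave) {
  stopifnot(inherits(spec, "texture_spec"), inherits(wave, "modulation_waveform"))
  x <- positions[, 1]
  y <- positions[, 2]
  n <- length(x)
  # Fractional position across the image width, 0 at the left edge.
  t <- (x + spec$field_diameter / 2) / spec$field_diameter
  w <- waveform_value(wave, t)
  j <- sample(c(-1, 1), n, replace = TRUE)
  j0 <- spec$orientation_jitter
  mo <- spec$mean_orientation
  mc <- spec$mean_contrast
  type <- spec$modulation_type

  if (type == "LM" && wave$amplitude > 0.5 + 1e-12) {
    texmod_error("texmod_out_of_range",
                 "LM modulation amplitude (grating Michelson contrast) must be <= 0.5")
  }
  orientation <- switch(type,
    OM  = mo + j * j0 + w,
    OVM = mo + j * j0 * (1 + w),
    mo + j * j0
  )
  contrast <- switch(type,
    CM  = mc + w,
    LM  = 2 * mc * (1 + w),
    CVM = mc + sample(c(-1, 1), n, replace = TRUE) * spec$contrast_jitter * (1 + w),
    rep(mc, n)
  )
  if (any(contrast < 0 | contrast > 1)) {
    texmod_error("texmod_out_of_range", sprintf(
      "%d Gabor contrast(s) outside [0, 1]; reduce the modulation amplitude",
      sum(contrast < 0 | contrast > 1)))
  }
  if (type == "OVM" && wave$amplitude > 1) {
    texmod_error("texmod_out_of_range",
                 "OVM variance-modulation amplitude must be <= 1 (jitter magnitude must stay non-negative)")
  }
  data.frame(
    x = x, y = y,
    orientation = quantize_orientation(orientation, spec$orientation_grid),
    contrast = contrast,
    polarity = sample(c(-1, 1), n, replace = TRUE)
  )
}

# Additively draw one odd-symmetric Gabor into the canvas (in contrast
# units, background 0). Canvas coordinates: column = x, row = y, px/deg res.
draw_gabor <- function(canvas, cx, cy, orientation, contrast, polarity,
                       gabor, resolution) {
  npix <- nrow(canvas)
  sigma_px <- gabor$sigma * resolution
  half <- gabor$envelope_diameter / 2 * sigma_px
  centre <- (npix + 1) / 2
  px <- centre + cx * resolution
  py <- centre + cy * resolution
  i0 <- max(1L, floor(py - half))
  i1 <- min(npix, ceiling(py + half))
  j0 <- max(1L, floor(px - half))
  j1 <- min(npix, ceiling(px + half))
  if (i0 > i1 || j0 > j1) return(canvas)
  u <- (j0:j1) - px  # x offsets, px
  v <- (i0:i1) - py  # y offsets, px
  U <- matrix(u, nrow = length(v), ncol = length(u), byrow = TRUE)
  V <- matrix(v, nrow = length(v), ncol = length(u))
  r2 <- U^2 + V^2
  th <- orientation * pi / 180
  # Stripes run along the orientation axis; the carrier varies perpendicular.
  d <- -U * sin(th) + V * cos(th)
  g <- exp(-r2 / (2 * sigma_px^2)) *
    sin(2 * pi * gabor$luminance_sf / resolution * d)
  g[r2 > half^2] <- 0
  canvas[i0:i1, j0:j1] <- canvas[i0:i1, j0:j1] + polarity * contrast * g
  canvas
}

#' Luminance and contrast profiles of the two LM frames
#'
#' LM textures are built from two alternating frames: a luminance grating of
#' Michelson contrast equal to the modulation amplitude, and a Gabor-texture
#' frame whose contrasts follow `2*mean_contrast*(1 + W(x))`. At the study
#' amplitude 0.5 the grating has a peak-to-trough luminance ratio of 3 and
#' the texture frame a peak-to-trough contrast ratio of 3; averaging the two
#' frames halves all contrasts reaching the eye.
#'
#' @param wave a `"modulation_waveform"` whose amplitude is the grating
#'   Michelson contrast (<= 0.5).
#' @param mean_contrast mean displayed Gabor contrast (frame contrast is
#'   twice this).
#' @return a data frame with columns `position` (fractional image position),
#'   `grating_luminance` (normalized, mid-grey = 0.5) and `texture_contrast`.
#' @export
lm_frame_profiles <- function(wave, mean_contrast = 0.333) {
  stopifnot(inherits(wave, "modulation_waveform"))
  if (wave$amplitude > 0.5 + 1e-12) {
    texmod_error("texmod_out_of_range",
                 "LM grating Michelson contrast must be <= 0.5")
  }
  t <- (seq_len(wave$n_samples) - 1L) / wave$n_samples
  w <- wave$values
  data.frame(
    position = t,
    grating_luminance = 0.5 * (1 + w),
    texture_contrast = 2 * mean_contrast * (1 + w)
  )
}

#' Render a texture image
#'
#' Draws the assigned Gabors additively (within their envelope support) on a
#' mid-grey background in normalized luminance, `L = 0.5 * (1 + sum of
#' contrast profiles)`. For LM textures the returned image is the average of
#' the two alternation frames: the Gabor frame rendered from `assignments`
#' and the luminance grating frame derived from `wave`.
#'
#' @param spec a [texture_spec()].
#' @param assignments data frame from [assign_modulation()]; may have zero
#'   rows, in which case a uniform mid-grey field is returned.
#' @param wave the modulation waveform; required for LM textures.
#' @param resolution pixels per degree; must resolve the carrier
#'   (>= 2 x luminance SF).
#' @return a square numeric matrix of normalized luminances in `[0, 1]`, of
#'   class `"texture_image"`, with the resolution stored as an attribute.
#' @export
render_texture <- function(spec, assignments, wave = NULL, resolution = 51.2) {
  stopifnot(inherits(spec, "texture_spec"))
  if (resolution < 2 * spec$gabor$luminance_sf) {
    texmod_error("texmod_invalid_argument", sprintf(
      "resolution %g px/deg cannot resolve a %g cpd carrier", resolution,
      spec$gabor$luminance_sf))
  }
  npix <- round(spec$field_diameter * resolution)
  canvas <- matrix(0, npix, npix)
  for (i in seq_len(nrow(assignments))) {
    canvas <- draw_gabor(canvas, assignments$x[i], assignments$y[i],
                         assignments$orientation[i], assignments$contrast[i],
                         assignments$polarity[i], spec$gabor, resolution)
  }
  if (spec$modulation_type == "LM") {
    if (is.null(wave)) {
      texmod_error("texmod_invalid_argument",
                   "LM rendering needs the modulation waveform for the grating frame")
    }
    t_col <- (seq_len(npix) - 0.5) / npix
    grating_row <- 0.5 * (1 + waveform_value(wave, t_col))
    frame_gabor <- 0.5 * (1 + canvas)
    frame_grating <- matrix(grating_row, npix, npix, byrow = TRUE)
    img <- (frame_gabor + frame_grating) / 2
  } else {
    img <- 0.5 * (1 + canvas)
  }
  if (any(img < 0 | img > 1)) {
    texmod_error("texmod_out_of_range",
                 "composited luminance outside [0, 1]; overlapping Gabors or amplitude too large")
  }
  structure(img, class = c("texture_image", "matrix"),
            resolution = resolution, modulation_type = spec$modulation_type)
}

#' Synthesize a complete texture
#'
#' Convenience wrapper: place Gabors, assign the modulation, render.
#'
#' @inheritParams render_texture
#' @param wave modulation waveform.
#' @param seed optional integer seed for reproducible placement and jitter.
#' @return a list with `image`, `assignments` and `positions`.
#' @export
synthesize_texture <- function(spec, wave, resolution = 51.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positions <- place_gabors(spec$n_gabors,
                            spec$min_separation * spec$gabor$sigma,
                            spec$field_diameter)
  assignments <- assign_modulation(positions, spec, wave)
  list(image = render_texture(spec, assignments, wave, resolution),
       assignments = assignments, positions = positions)
}

#' Write a texture image as 8-bit PNG
#'
#' Gamma-naive mapping: normalized luminance in `[0, 1]` is written directly
#' as pixel value. Requires the `png` package.
#'
#' @param image a `"texture_image"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_texture_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    texmod_error("texmod_missing_dependency",
                 "the `png` package is required to write PNG output")
  }
  png::writePNG(unclass(image), path)
  invisible(path)
}
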