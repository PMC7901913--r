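#' Rate-coding specification for input images
#'
#' Each input pixel drives one input neuron whose firing rate is
#' proportional to the pixel's gray level: a level `g` in
#' `0..gray_levels-1` maps linearly from `f_min` (darkest) to `f_max`
#' (brightest). Spike trains are jittered-periodic by default:
#' inter-spike intervals are drawn from a Normal distribution with mean
#' `1/f` and standard deviation `cv/f`, truncated at a small positive
#' floor; a Poisson alternative (`isi = "poisson"`) is available for
#' sensitivity checks.
#'
#' @param f_min,f_max Firing-rate range in Hz (defaults 83 Hz and
#'   22.2 kHz).
#' @param gray_levels Number of gray levels (default 256).
#' @param presentation_time Duration each image is presented, in
#'   microseconds (default 350).
#' @param cv Coefficient of variation of the inter-spike intervals
#'   (default 0.1; ignored for Poisson trains).
#' @param isi `"normal"` (jittered-periodic) or `"poisson"`.
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(f_min = 83, f_max = 22200, gray_levels = 256,
                          presentation_time = 350, cv = 0.1,
                          isi = c("normal", "poisson")) {
  isi <- match.arg(isi)
  stopifnot(f_min > 0, f_max > f_min, gray_levels >= 2,
            presentation_time > 0, cv >= 0)
  structure(list(f_min = f_min, f_max = f_max,
                 gray_levels = as.integer(gray_levels),
                 presentation_time = presentation_time,
                 cv = cv, isi = isi),
            class = "encoding_spec")
}

#' Pixel firing rates for an image
#'
#' @param image Integer matrix with values in `0..gray_levels-1`.
#' @param spec An [encoding_spec()].
#' @return Firing rates in spikes per microsecond, one per pixel
#'   (column-major over the image).
#' @export
pixel_rates <- function(image, spec = encoding_spec()) {
  g <- as.vector(image)
  if (any(g < 0) || any(g > spec$gray_levels - 1) || any(g != round(g))) {
    stop("pixel values must be integers in [0, gray_levels - 1]", call. = FALSE)
  }
  f_hz <- spec$f_min + g / (spec$gray_levels - 1) * (spec$f_max - spec$f_min)
  f_hz * 1e-6
}

#' Encode an image as input spike trains
#'
#' Converts an image to per-pixel spike times within one presentation
#' window using the rate code of [encoding_spec()].
#'
#' @inheritParams pixel_rates
#' @param seed Optional integer seed; when given the encoding is
#'   deterministic and the caller's RNG stream is left untouched.
#' @return A tibble with columns `pixel` (column-major index into the
#'   image) and `time` (microseconds), sorted by time.
#' @examples
#' img <- matrix(0L, 4, 4); img[2, 2] <- 255L
#' encode_image(img, seed = 1)
#' @export
encode_image <- function(image, spec = encoding_spec(), seed = NULL) {
  rates <- pixel_rates(image, spec)
  run <- function() {
    encode_spikes_cpp(rates, spec$presentation_time, spec$cv,
                      isi_floor = 1e-4, poisson = spec$isi == "poisson")
  }
  res <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  tibble::tibble(pixel = res$pixel, time = res$time)
}
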