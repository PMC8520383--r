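# Contrast enhancement of the inverted green channel: a local adaptive pass
# feeding the small detection scales, and a global linear pass feeding the
# large scales.

#' Parameters of the local adaptive enhancement
#'
#' @param window odd window size in pixels over which the local mean and
#'   standard deviation are measured (default 5).
#' @param C gain control parameter: flat neighborhoods (small local sd) get a
#'   large gain `C / (sd + s)`, so faint thin vessels are amplified most.
#'   Default 3 on the `[0, 1]` intensity scale.
#' @param s small positive stabilizer added to the local standard deviation
#'   (default 1e-4).
#' @param gain_cap upper bound on the local gain (default 5); without it the
#'   gain diverges on perfectly flat regions and amplifies sensor noise.
#' @return a `local_enhance_params` list.
#' @export
local_enhance_params <- function(window = 5L, C = 3, s = 1e-4, gain_cap = 5) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stopf("window must be odd and >= 3, got %d", window)
  if (s <= 0) stopf("stabilizer s must be > 0")
  if (gain_cap <= 0) stopf("gain_cap must be > 0")
  structure(list(window = window, C = C, s = s, gain_cap = gain_cap),
            class = "local_enhance_params")
}

#' Local adaptive contrast enhancement
#'
#' For each pixel, with `m` and `sigma` the mean and (population) standard
#' deviation of the `window x window` neighborhood (symmetric-reflect padded
#' at borders), the output is
#' \deqn{f = m + A (x - m), \quad A = \min(C / (\sigma + s), \mathrm{cap})}
#' clipped to `[0, 1]`. The gain is largest where the neighborhood is most
#' uniform, lifting low-contrast thin vessels out of the background; this is
#' the image the small detection scales operate on.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param params a [local_enhance_params()] list.
#' @return enhanced matrix, clipped to `[0, 1]`.
#' @export
local_enhance <- function(img, params = local_enhance_params()) {
  check_image(img)
  if (!inherits(params, "local_enhance_params"))
    params <- do.call(local_enhance_params, params)
  m <- box_mean(img, params$window)
  v <- pmax(box_mean(img * img, params$window) - m * m, 0)
  a <- pmin(params$C / (sqrt(v) + params$s), params$gain_cap)
  clip01(m + a * (img - m))
}

#' Global linear contrast enhancement
#'
#' Stretches intensities about the global in-FOV mean:
#' \deqn{f_x = g_{mean} + (1 + c_g)(f - g_{mean})}
#' clipped to `[0, 1]`; pixels outside the field of view pass through
#' unchanged. This suppresses smooth illumination bias relative to the
#' vessel/background contrast and is the image the large detection scales
#' operate on.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param fov logical field-of-view mask (default: whole frame).
#' @param c_g non-negative gain control; `c_g = 0` is the identity. Default 1.
#' @return enhanced matrix.
#' @export
global_enhance <- function(img, fov = NULL, c_g = 1) {
  check_image(img)
  if (c_g < 0) stopf("c_g must be >= 0")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(img), ncol(img))
  check_mask(fov, "fov")
  check_same_shape(img, fov, "image vs FOV")
  if (!any(fov)) stopf("empty field of view")
  g_mean <- mean(img[fov])
  out <- img
  out[fov] <- clip01(g_mean + (1 + c_g) * (img[fov] - g_mean))
  out
}
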