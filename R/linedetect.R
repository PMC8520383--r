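# The oriented line detector. At each pixel the mean intensity along a
# centred line segment of length L, maximized over 12 orientations, is
# compared with the mean over a fixed 15 x 15 window; vessels aligned with
# the winning orientation yield a positive difference. Because the line mean
# does not require the centre pixel to be the brightest, the detector
# tolerates the bright central reflex of larger vessels.

#' Detector parameters
#'
#' @param window odd window size W (default 15): side of the square over
#'   which the background mean is taken, fixed across scales.
#' @param n_angles number of line orientations (default 12); together with
#'   `angle_step` they must cover 180 degrees.
#' @param angle_step angular step in degrees (default 15).
#' @param scales ordered odd line lengths L, each `<= window`
#'   (default 1, 3, ..., 15).
#' @return a `detector_params` list with an `angles` vector in degrees.
#' @export
detector_params <- function(window = 15L, n_angles = 12L, angle_step = 15,
                            scales = seq(1L, 15L, by = 2L)) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stopf("window must be odd, got %d", window)
  if (n_angles * angle_step != 180)
    stopf("n_angles * angle_step must equal 180 (got %d * %g)",
          n_angles, angle_step)
  scales <- as.integer(scales)
  if (any(scales %% 2L == 0L) || any(scales < 1L) || any(scales > window))
    stopf("scales must be odd and within [1, window]")
  structure(list(window = window, n_angles = as.integer(n_angles),
                 angle_step = angle_step, scales = scales,
                 angles = seq(0, 180 - angle_step, by = angle_step)),
            class = "detector_params")
}

#' Discrete line kernel
#'
#' The set of L pixel offsets visited by a centred line segment of length L
#' at orientation `angle`. Offsets are `(round(-k sin(theta)),
#' round(k cos(theta)))` for `k = -(L-1)/2, ..., (L-1)/2`, with theta measured
#' from the +column axis (angle 0 = horizontal line; rows grow downward).
#' When rounding collapses two values of k onto one pixel, k is nudged along
#' the line in steps of 0.25 (smallest magnitude first, positive first)
#' until L distinct pixels exist; nudges are applied to `k > 0` and mirrored,
#' so the kernel is always symmetric under negation and contains `(0, 0)`.
#'
#' @param L odd line length >= 1.
#' @param angle orientation in degrees, a multiple of the angle step in
#'   `[0, 180)`.
#' @return integer matrix `L x 2` of `(row, col)` offsets.
#' @export
line_kernel <- function(L, angle) {
  L <- as.integer(L)
  if (L %% 2L == 0L || L < 1L) stopf("line length must be odd and >= 1, got %d", L)
  theta <- angle * pi / 180
  dirr <- -sin(theta); dirc <- cos(theta)
  # snap coordinates lying on an exact half-integer (sin/cos values 0, 0.5, 1
  # hit them) before rounding, so the discretization is identical across
  # 90-degree-rotated angles despite floating-point trig
  snap_round <- function(x) {
    half <- abs(2 * x - round(2 * x)) < 1e-9
    x[half] <- round(2 * x[half]) / 2
    round(x)
  }
  half <- (L - 1L) %/% 2L
  offs <- matrix(0L, L, 2L)
  if (half > 0L) {
    taken <- "0,0"
    nudges <- c(0, as.vector(rbind(seq(0.25, 6, by = 0.25),
                                   -seq(0.25, 6, by = 0.25))))
    row_i <- 1L
    for (k in seq_len(half)) {
      placed <- FALSE
      for (d in nudges) {
        kk <- k + d
        p <- c(snap_round(kk * dirr), snap_round(kk * dirc))
        key <- paste(p, collapse = ",")
        if (!key %in% taken) {
          taken <- c(taken, key, paste(-p, collapse = ","))
          offs[2L * row_i, ] <- as.integer(p)
          offs[2L * row_i + 1L, ] <- as.integer(-p)
          row_i <- row_i + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) stopf("could not discretize line of length %d at %g degrees", L, angle)
    }
  }
  colnames(offs) <- c("row", "col")
  offs
}

#' Single-scale line-detector response
#'
#' For every in-FOV pixel, the response is `max_theta I_line(theta) - I_win`
#' where `I_line` is the image mean over the length-L kernel at orientation
#' theta and `I_win` the mean over the W x W window, both with
#' symmetric-reflect borders. Outside the FOV the response is 0.
#'
#' @param img numeric matrix.
#' @param L odd line length, `<= params$window`.
#' @param fov logical FOV mask (default whole frame).
#' @param params a [detector_params()] list.
#' @return numeric response matrix, 0 outside the FOV. The scale is recorded
#'   in attribute `"scale"`.
#' @export
single_scale_response <- function(img, L, fov = NULL, params = detector_params()) {
  check_image(img)
  L <- as.integer(L)
  if (L > params$window)
    stopf("line length %d exceeds the %d-pixel window", L, params$window)
  if (L %% 2L == 0L) stopf("line length must be odd, got %d", L)
  h <- nrow(img); w <- ncol(img)
  if (is.null(fov)) fov <- matrix(TRUE, h, w)
  check_mask(fov, "fov")
  check_same_shape(img, fov, "image vs FOV")

  k <- (params$window - 1L) %/% 2L + 1L  # +1 headroom for nudged offsets
  p <- pad_reflect(img, k)
  win <- box_mean(img, params$window)
  imax <- NULL
  for (ang in params$angles) {
    ker <- line_kernel(L, ang)
    lm <- matrix(0, h, w)
    for (i in seq_len(nrow(ker)))
      lm <- lm + shift_view(p, ker[i, 1L], ker[i, 2L], h, w, k)
    lm <- lm / L
    imax <- if (is.null(imax)) lm else pmax(imax, lm)
  }
  resp <- imax - win
  resp[!fov] <- 0
  attr(resp, "scale") <- L
  resp
}

#' Standardize a response map within the field of view
#'
#' Rescales to in-FOV mean 0 and (population) standard deviation 1, leaving
#' pixels outside the FOV at 0. Responses at different scales have different
#' dynamic ranges; standardization puts them on a comparable footing before
#' linear fusion.
#'
#' @param resp numeric response matrix.
#' @param fov logical FOV mask (default whole frame).
#' @return standardized matrix; attributes of `resp` are preserved.
#' @export
standardize_response <- function(resp, fov = NULL) {
  check_image(resp, "response")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(resp), ncol(resp))
  check_mask(fov, "fov")
  check_same_shape(resp, fov, "response vs FOV")
  v <- resp[fov]
  if (length(v) < 2L) stopf("standardization needs at least 2 in-FOV pixels")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0)
    stopf("zero in-FOV variance in response map (scale %s): nothing to standardize",
          if (is.null(attr(resp, "scale"))) "?" else attr(resp, "scale"))
  out <- resp
  out[fov] <- (v - m) / s
  out[!fov] <- 0
  out
}
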