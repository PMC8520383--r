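# Linear fusion of per-scale responses with the inverted green channel.
# Two modes: the all-scales baseline (every scale detected on one image) and
# the scale split, where small scales see the locally enhanced image and
# large scales the globally enhanced one.

#' Scale split between small and large detection scales
#'
#' Thin vessels are about 3-4 px wide and thick vessels 7-8 px; line lengths
#' below 9 px resolve the thin ones (and benefit from local enhancement)
#' while lengths of 9 px and above trace thick vessels and global contours
#' (and benefit from global enhancement).
#'
#' @param small ordered odd line lengths `< 9` (default 1, 3, 5, 7).
#' @param large ordered odd line lengths `>= 9` (default 9, 11, 13, 15); may
#'   be empty, in which case the split degenerates to the baseline on the
#'   small-scale image.
#' @return a `scale_split` list.
#' @export
scale_split <- function(small = c(1L, 3L, 5L, 7L), large = c(9L, 11L, 13L, 15L)) {
  small <- as.integer(small); large <- as.integer(large)
  if (length(intersect(small, large)))
    stopf("small and large scale sets must be disjoint")
  if (length(large) && (any(small >= 9L) || any(large < 9L)))
    stopf("small scales must be < 9 and large scales >= 9")
  structure(list(small = small, large = large), class = "scale_split")
}

fuse_sum <- function(responses, igc, fov, what) {
  for (r in responses) {
    check_image(r, "response")
    check_same_shape(r, igc, sprintf("%s response vs green channel", what))
  }
  acc <- igc
  for (r in responses) acc <- acc + r
  acc
}

#' All-scales baseline fusion
#'
#' Averages the standardized responses of every scale (all computed on one
#' image) together with the inverted green channel:
#' `value = (sum_L R_L + I_igc) / (n_L + 1)` inside the FOV, 0 outside.
#' Including the inverted green channel keeps vessel-interior pixels bright
#' even where every line response is weak.
#'
#' @param responses list of standardized response matrices, one per scale.
#' @param igc inverted green channel matrix (un-enhanced).
#' @param fov logical FOV mask (default whole frame).
#' @return fused numeric matrix with attributes `n_scales_used` and `mode`.
#' @export
fuse_baseline <- function(responses, igc, fov = NULL) {
  check_image(igc, "inverted green channel")
  if (!is.list(responses) || length(responses) < 1L)
    stopf("need at least one response map")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(igc), ncol(igc))
  check_mask(fov, "fov")
  out <- fuse_sum(responses, igc, fov, "baseline") / (length(responses) + 1)
  out[!fov] <- 0
  structure(out, n_scales_used = length(responses), mode = "baseline")
}

#' Scale-split fusion
#'
#' Averages small-scale responses computed on the locally enhanced image I1,
#' large-scale responses computed on the globally enhanced image I2, and the
#' inverted green channel:
#' `value = (sum_{L in small} R_L^{I1} + sum_{L in large} R_L^{I2} + I_igc)
#' / (n_S + n_G + 1)` inside the FOV, 0 outside. With the default split the
#' divisor is 9, matching the baseline over the full scale set.
#'
#' @param small_responses list of standardized responses on I1, one per
#'   `split$small` scale.
#' @param large_responses list of standardized responses on I2, one per
#'   `split$large` scale.
#' @param igc inverted green channel matrix (un-enhanced).
#' @param fov logical FOV mask (default whole frame).
#' @param split a [scale_split()].
#' @return fused numeric matrix with attributes `n_scales_used` and `mode`.
#' @export
fuse_split <- function(small_responses, large_responses, igc, fov = NULL,
                       split = scale_split()) {
  check_image(igc, "inverted green channel")
  if (length(small_responses) != length(split$small))
    stopf("got %d small-scale responses for %d small scales",
          length(small_responses), length(split$small))
  if (length(large_responses) != length(split$large))
    stopf("got %d large-scale responses for %d large scales",
          length(large_responses), length(split$large))
  if (is.null(fov)) fov <- matrix(TRUE, nrow(igc), ncol(igc))
  check_mask(fov, "fov")
  n <- length(small_responses) + length(large_responses)
  acc <- fuse_sum(small_responses, igc, fov, "small-scale")
  for (r in large_responses) {
    check_image(r, "response")
    check_same_shape(r, igc, "large-scale response vs green channel")
    acc <- acc + r
  }
  out <- acc / (n + 1)
  out[!fov] <- 0
  structure(out, n_scales_used = n, mode = "split")
}
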