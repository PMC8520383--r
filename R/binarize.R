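# Turning a fused response map into a binary vessel mask, plus thinning to
# 1-px centerlines for connectivity analysis.

#' Threshold a fused response map
#'
#' Pixels with value `>= t` inside the FOV become vessel (ties at `t` are
#' vessel). The threshold `t` is chosen by one of:
#' \describe{
#'   \item{`quantile`}{`value` is the vessel fraction q: the top q of in-FOV
#'     pixels become vessel. The default q = 0.104 is the vessel density of
#'     an expert's manual annotation of a standard retinal database, so the
#'     predicted mask matches the typical true vessel area.}
#'   \item{`otsu`}{Otsu's threshold of the in-FOV value distribution
#'     (data-independent alternative).}
#'   \item{`fixed`}{`value` is used as `t` directly.}
#' }
#'
#' @param fused numeric fused response matrix.
#' @param fov logical FOV mask (default whole frame).
#' @param method `"quantile"`, `"otsu"` or `"fixed"`.
#' @param value quantile q in (0, 1) for `quantile` (default 0.104), or the
#'   threshold itself for `fixed`; ignored for `otsu`.
#' @return logical vessel mask (`FALSE` everywhere outside the FOV).
#' @export
threshold_map <- function(fused, fov = NULL,
                          method = c("quantile", "otsu", "fixed"),
                          value = 0.104) {
  check_image(fused, "fused map")
  method <- match.arg(method)
  if (is.null(fov)) fov <- matrix(TRUE, nrow(fused), ncol(fused))
  check_mask(fov, "fov")
  check_same_shape(fused, fov, "fused map vs FOV")
  v <- fused[fov]
  t0 <- switch(method,
    fixed = value,
    quantile = {
      if (value <= 0 || value >= 1) stopf("quantile must be in (0, 1), got %g", value)
      k <- max(1L, round(value * length(v)))
      sort(v, decreasing = TRUE)[k]  # k-th largest: top-q fraction is vessel
    },
    otsu = {
      rng <- range(v)
      if (rng[1L] == rng[2L])
        stopf("all in-FOV values are equal; Otsu is undefined, use method = 'quantile'")
      scaled <- (v - rng[1L]) / (rng[2L] - rng[1L])
      t_s <- EBImage::otsu(matrix(scaled, nrow = 1L), range = c(0, 1))
      rng[1L] + t_s * (rng[2L] - rng[1L])
    })
  mask <- fused >= t0 & fov
  attr(mask, "threshold") <- t0
  mask
}

#' Thin a vessel mask to 1-pixel-wide centerlines
#'
#' Zhang-Suen iterative thinning: border pixels are peeled in two alternating
#' sub-passes whose conditions preserve 8-connectivity and line endpoints,
#' until no pixel changes. The skeleton is a subset of the input and has the
#' same number of 8-connected components.
#'
#' @param mask logical matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize_mask <- function(mask) {
  check_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(mask)
  x <- matrix(0L, h + 2L, w + 2L)
  x[2:(h + 1L), 2:(w + 1L)] <- mask * 1L
  ri <- 2:(h + 1L); ci <- 2:(w + 1L)
  nbrs <- function(x) {
    # clockwise from north: p2 p3 p4 p5 p6 p7 p8 p9
    list(x[ri - 1L, ci], x[ri - 1L, ci + 1L], x[ri, ci + 1L], x[ri + 1L, ci + 1L],
         x[ri + 1L, ci], x[ri + 1L, ci - 1L], x[ri, ci - 1L], x[ri - 1L, ci - 1L])
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- nbrs(x)
      b <- Reduce(`+`, p)
      # transitions 0 -> 1 around the ring
      a <- matrix(0L, h, w)
      for (i in 1:8) {
        j <- if (i == 8L) 1L else i + 1L
        a <- a + (p[[i]] == 0L & p[[j]] == 1L)
      }
      if (pass == 1L) {
        cond <- p[[1L]] * p[[3L]] * p[[5L]] == 0L & p[[3L]] * p[[5L]] * p[[7L]] == 0L
      } else {
        cond <- p[[1L]] * p[[3L]] * p[[7L]] == 0L & p[[1L]] * p[[5L]] * p[[7L]] == 0L
      }
      del <- x[ri, ci] == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(del)) {
        core <- x[ri, ci]
        core[del] <- 0L
        x[ri, ci] <- core
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  x[ri, ci] == 1L
}
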