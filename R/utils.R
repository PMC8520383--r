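# Internal numeric and raster helpers shared across the pipeline.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Mirror an out-of-range index back into 1..n (symmetric reflection, edge
# pixel included: 0 -> 1, -1 -> 2, n+1 -> n). Valid while the overhang is < n.
reflect_index <- function(i, n) {
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

# Pad a matrix by k pixels on every side with symmetric reflection.
pad_reflect <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  if (k >= h || k >= w)
    stopf("reflect padding of %d exceeds image size %dx%d", k, h, w)
  x[reflect_index((1L - k):(h + k), h), reflect_index((1L - k):(w + k), w)]
}

# Mean over a w x w window centred on each pixel, symmetric-reflect borders.
# Computed with a summed-area table: O(HW) regardless of w.
box_mean <- function(x, w) {
  if (w %% 2L == 0L) stopf("window size must be odd, got %d", w)
  k <- (w - 1L) %/% 2L
  p <- pad_reflect(x, k)
  hp <- nrow(p); wp <- ncol(p)
  cs <- apply(p, 2L, cumsum)        # cumulative sums down rows
  cs <- t(apply(cs, 1L, cumsum))    # then across columns
  s <- matrix(0, hp + 1L, wp + 1L)  # s[i+1, j+1] = sum(p[1:i, 1:j])
  s[2L:(hp + 1L), 2L:(wp + 1L)] <- cs
  h <- nrow(x); wd <- ncol(x)
  i1 <- 1L:h; j1 <- 1L:wd
  (s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
     s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

# Extract the H x W view of a padded matrix shifted by (dr, dc).
shift_view <- function(p, dr, dc, h, w, k) {
  p[(1L + k + dr):(h + k + dr), (1L + k + dc):(w + k + dc), drop = FALSE]
}

check_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("%s must be a logical matrix", name)
  invisible(mask)
}

check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stopf("%s must be a numeric matrix", name)
  if (anyNA(img) || any(!is.finite(img)))
    stopf("%s contains non-finite values", name)
  invisible(img)
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stopf("shape mismatch: %s (%s vs %s)", what,
          paste(dim(a)[1:2], collapse = "x"), paste(dim(b)[1:2], collapse = "x"))
  invisible(NULL)
}

#' Label connected components of a binary mask
#'
#' Breadth-first labelling with 8- (default) or 4-connectivity. EBImage's
#' `bwlabel()` is 4-connected; vessel skeletons and diagonal vessel segments
#' need the 8-connected notion, so this is implemented here.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  check_mask(mask)
  if (!connectivity %in% c(4, 8)) stopf("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  todo <- which(mask)
  current <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    lab[seed] <- current
    frontier <- seed
    while (length(frontier)) {
      r0 <- ((frontier - 1L) %% h) + 1L
      c0 <- ((frontier - 1L) %/% h) + 1L
      nr <- rep(r0, each = length(dr)) + dr
      nc <- rep(c0, each = length(dc)) + dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      idx <- unique((nc[ok] - 1L) * h + nr[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- current
      frontier <- idx
    }
  }
  lab
}

#' Count connected components of a binary mask
#'
#' @inheritParams label_components
#' @return integer component count.
#' @export
count_components <- function(mask, connectivity = 8) {
  max(label_components(mask, connectivity))
}
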