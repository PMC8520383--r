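# Independent brute-force oracles: direct per-pixel implementations of the
# detector, the enhancements, the fusion and the confusion counts, kept free
# of the package's vectorized code paths (only line_kernel's *rule* is
# re-enumerated here, independently).

# symmetric reflection of index i into 1..n (edge pixel included)
o_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

o_window_mean <- function(img, r, c, w) {
  k <- (w - 1) / 2
  ri <- vapply((r - k):(r + k), o_reflect, 0, n = nrow(img))
  ci <- vapply((c - k):(c + k), o_reflect, 0, n = ncol(img))
  mean(img[ri, ci])
}

# independent enumeration of the line-discretization rule: points
# round(k * (-sin t, cos t)) evaluated as in exact arithmetic (values within
# 1e-9 of a half-integer are treated as that half-integer), collisions
# resolved by the smallest-magnitude 0.25-step nudge of k (positive first),
# applied to k > 0 and mirrored
o_round <- function(x) {
  if (abs(2 * x - round(2 * x)) < 1e-9) x <- round(2 * x) / 2
  round(x)
}

o_offsets <- function(L, angle) {
  t <- angle * pi / 180
  pts <- list(c(0, 0))
  seen <- c("0 0")
  if (L > 1) {
    for (k in 1:((L - 1) / 2)) {
      for (d in c(0, c(rbind(1:24, -(1:24))) * 0.25)) {
        p <- c(o_round(-(k + d) * sin(t)), o_round((k + d) * cos(t)))
        key <- paste(p, collapse = " ")
        if (!(key %in% seen)) {
          pts <- c(pts, list(p), list(-p))
          seen <- c(seen, key, paste(-p, collapse = " "))
          break
        }
      }
    }
  }
  pts
}

o_line_mean <- function(img, r, c, offs) {
  mean(vapply(offs, function(p)
    img[o_reflect(r + p[1], nrow(img)), o_reflect(c + p[2], ncol(img))], 0))
}

o_single_scale <- function(img, L, fov, w = 15, angles = seq(0, 165, by = 15)) {
  kers <- lapply(angles, function(a) o_offsets(L, a))
  out <- matrix(0, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (!fov[r, c]) next
    imax <- max(vapply(kers, function(k) o_line_mean(img, r, c, k), 0))
    out[r, c] <- imax - o_window_mean(img, r, c, w)
  }
  out
}

o_local_enhance <- function(img, w = 5, C = 3, s = 1e-4, cap = 5) {
  out <- img
  k <- (w - 1) / 2
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    ri <- vapply((r - k):(r + k), o_reflect, 0, n = nrow(img))
    ci <- vapply((c - k):(c + k), o_reflect, 0, n = ncol(img))
    v <- img[ri, ci]
    m <- mean(v)
    sig <- sqrt(mean((v - m)^2))
    a <- min(C / (sig + s), cap)
    out[r, c] <- min(max(m + a * (img[r, c] - m), 0), 1)
  }
  out
}

o_fuse <- function(resp_list, igc, fov) {
  out <- matrix(0, nrow(igc), ncol(igc))
  for (r in seq_len(nrow(igc))) for (c in seq_len(ncol(igc))) {
    if (!fov[r, c]) next
    s <- igc[r, c]
    for (m in resp_list) s <- s + m[r, c]
    out[r, c] <- s / (length(resp_list) + 1)
  }
  out
}

o_confusion <- function(pred, truth, fov) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(pred)) {
    if (!fov[i]) next
    if (pred[i] && truth[i]) tp <- tp + 1L
    else if (pred[i] && !truth[i]) fp <- fp + 1L
    else if (!pred[i] && truth[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# small seeded random image
rand_img <- function(h = 32, w = 32, seed = 0) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# a horizontal bright bar of the given width and contrast on a flat field
bar_image <- function(h = 48, w = 48, row = 24, width = 3, level = 0.3,
                      contrast = 0.3) {
  img <- matrix(level, h, w)
  half <- (width - 1) / 2
  img[(row - half):(row + half), ] <- level + contrast
  img
}
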