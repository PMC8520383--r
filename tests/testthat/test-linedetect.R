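test_that("line kernels reproduce the frozen discretizations", {
  expect_equal(nrow(line_kernel(1, 75)), 1L)
  expect_equal(unname(line_kernel(1, 75)[1, ]), c(0L, 0L))

  k15 <- line_kernel(15, 0)
  expect_equal(sort(k15[, "col"]), -7:7)
  expect_true(all(k15[, "row"] == 0L))

  # L = 5 at 45 degrees: k = 2 collides with k = 1 after rounding and is
  # nudged to +2.25, landing on (-2, 2) (enumerated by hand from the rule)
  k5 <- line_kernel(5, 45)
  expect_setequal(paste(k5[, 1], k5[, 2]),
                  c("0 0", "-1 1", "1 -1", "-2 2", "2 -2"))
})

test_that("kernels are centred, negation-symmetric and duplicate-free", {
  for (L in seq(1, 15, by = 2)) for (a in seq(0, 165, by = 15)) {
    k <- line_kernel(L, a)
    keys <- paste(k[, 1], k[, 2])
    expect_equal(length(unique(keys)), L)
    expect_true("0 0" %in% keys)
    expect_setequal(keys, paste(-k[, 1], -k[, 2]))
    expect_true(all(abs(k) <= (L - 1) / 2 + 2))
  }
  expect_error(line_kernel(4, 0), "odd")
})

test_that("constant images give zero response; shift and scale behave", {
  fov <- matrix(TRUE, 32, 32)
  expect_equal(single_scale_response(matrix(0.7, 32, 32), 7),
               matrix(0, 32, 32), ignore_attr = TRUE)
  img <- rand_img(32, 32, seed = 2)
  r <- single_scale_response(img, 9)
  expect_equal(single_scale_response(img + 0.1, 9), r, tolerance = 1e-12,
               ignore_attr = TRUE)                      # shift invariance
  expect_equal(single_scale_response(img * 2.5, 9), 2.5 * r,
               tolerance = 1e-12, ignore_attr = TRUE)    # homogeneity
})

test_that("vectorized responses equal the brute-force oracle at all scales", {
  img <- rand_img(32, 32, seed = 0)
  rr <- matrix(1:32, 32, 32); cc <- t(rr)
  fov <- (rr - 16.5)^2 + (cc - 16.5)^2 <= 15^2
  for (L in seq(1, 15, by = 2)) {
    fast <- single_scale_response(img, L, fov)
    slow <- o_single_scale(img, L, fov)
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("a horizontal bar is detected at angle 0 with a clear margin", {
  img <- bar_image(row = 24, width = 3, contrast = 0.3)
  fov <- matrix(TRUE, 48, 48)
  for (L in c(3, 7, 11, 15)) {
    resp <- single_scale_response(img, L, fov)
    # centerline response beats off-vessel response 10+ px away
    expect_gt(min(resp[24, 15:35]), max(resp[c(1:14, 34:48), 15:35]))
    # the maximizing orientation at centerline pixels is 0 degrees
    for (c0 in c(20, 24, 28)) {
      means <- vapply(seq(0, 165, by = 15), function(a)
        o_line_mean(img, 24, c0, o_offsets(L, a)), 0)
      expect_equal(which.max(means), 1L)
    }
  }
})

test_that("responses commute with 90-degree rotation", {
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])  # clockwise
  ph <- phantom_suite(7)$thin
  igc <- inverted_green(ph$image)
  for (L in c(5, 15)) {
    r1 <- single_scale_response(rot90(igc), L, rot90(ph$fov))
    r2 <- rot90(single_scale_response(igc, L, ph$fov))
    expect_lt(max(abs(r1 - r2)), 1e-9)
  }
})

test_that("standardization yields in-FOV mean 0 / sd 1 and is idempotent", {
  img <- rand_img(32, 32, seed = 6)
  fov <- matrix(TRUE, 32, 32); fov[, 1:5] <- FALSE
  r <- single_scale_response(img, 7, fov)
  z <- standardize_response(r, fov)
  expect_lt(abs(mean(z[fov])), 1e-12)
  expect_lt(abs(sqrt(mean((z[fov] - mean(z[fov]))^2)) - 1), 1e-12)
  expect_true(all(z[!fov] == 0))
  expect_equal(standardize_response(z, fov), z, tolerance = 1e-12,
               ignore_attr = TRUE)
  # {1,2,3} with the population sd -> +/- sqrt(3/2)
  m <- matrix(0, 2, 2); m[1:3] <- 1:3
  fov3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(standardize_response(m, fov3)[1:3],
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(standardize_response(matrix(1, 8, 8)), "variance")
})
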