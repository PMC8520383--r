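make_std_responses <- function(img, scales, fov) {
  lapply(scales, function(L)
    standardize_response(single_scale_response(img, L, fov), fov))
}

test_that("baseline fusion implements (sum R_L + I_igc) / (n_L + 1)", {
  igc <- matrix(0.45, 16, 16)
  zeros <- replicate(8, matrix(0, 16, 16), simplify = FALSE)
  out <- fuse_baseline(zeros, igc)
  expect_equal(out[5, 5], 0.45 / 9)
  # single scale: (r + 0) / 2
  r <- matrix(2, 16, 16)
  expect_equal(fuse_baseline(list(r), matrix(0, 16, 16))[3, 3], 1)
})

test_that("both fusions match a direct per-pixel summation", {
  igc <- rand_img(32, 32, seed = 21)
  rr <- matrix(1:32, 32, 32); cc <- t(rr)
  fov <- (rr - 16.5)^2 + (cc - 16.5)^2 <= 15^2
  resp <- make_std_responses(igc, seq(1, 15, by = 2), fov)
  expect_lt(max(abs(fuse_baseline(resp, igc, fov) - o_fuse(resp, igc, fov))),
            1e-12)
  out_split <- fuse_split(resp[1:4], resp[5:8], igc, fov)
  expect_lt(max(abs(out_split - o_fuse(resp, igc, fov))), 1e-12)
})

test_that("split fusion with an empty large group reproduces the baseline", {
  igc <- rand_img(24, 24, seed = 8)
  fov <- matrix(TRUE, 24, 24)
  resp <- make_std_responses(igc, seq(1, 15, by = 2), fov)
  sp <- scale_split(small = seq(1L, 7L, by = 2L), large = integer(0))
  got <- fuse_split(resp[1:4], list(), igc, fov, sp)
  expect_equal(as.numeric(got), as.numeric(fuse_baseline(resp[1:4], igc, fov)),
               tolerance = 1e-15)
})

test_that("fusion is invariant to response order within each group", {
  igc <- rand_img(24, 24, seed = 13)
  fov <- matrix(TRUE, 24, 24)
  resp <- make_std_responses(igc, c(1, 3, 5, 7), fov)
  large <- make_std_responses(igc, c(9, 11, 13, 15), fov)
  a <- fuse_split(resp, large, igc, fov)
  b <- fuse_split(resp[c(3, 1, 4, 2)], large[c(4, 3, 2, 1)], igc, fov)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-15)
})

test_that("fusion validates shapes and group sizes", {
  igc <- matrix(0.5, 16, 16)
  expect_error(fuse_baseline(list(matrix(0, 8, 8)), igc), "shape")
  expect_error(fuse_split(list(matrix(0, 16, 16)), list(), igc), "small scales")
})

test_that("split fusion rank-lifts thin-vessel centerlines over the raw baseline", {
  ph <- phantom_suite(31)$thin
  igc <- inverted_green(ph$image)
  fs <- vessel_response(igc, ph$fov, "split")
  fb <- vessel_response(igc, ph$fov, "baseline")
  ranknorm <- function(f) {
    r <- f
    r[ph$fov] <- rank(f[ph$fov]) / sum(ph$fov)
    r
  }
  thin_mean <- function(f) mean(ranknorm(f)[ph$thin & ph$fov])
  expect_gte(thin_mean(fs), thin_mean(fb))
})
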