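test_that("phantoms honour their segment geometry exactly", {
  # no segments -> empty truth
  empty <- phantom_generate(phantom_spec(48, 48, segments = list(), seed = 1))
  expect_equal(sum(empty$truth), 0L)

  # one horizontal width-3 length-40 vessel -> exactly 120 truth pixels
  seg <- vessel_segment(c(24, 5), c(24, 44), width = 3, contrast = 0.15)
  ph <- phantom_generate(phantom_spec(48, 48, noise_sd = 0,
                                      segments = list(seg), seed = 1))
  expect_equal(sum(ph$truth), 120L)
  expect_equal(sum(ph$truth[23:25, 5:44]), 120L)
  # vessels are darker in green inside the vessel than just outside
  expect_lt(mean(ph$green[24, 5:44]), mean(ph$green[30, 5:44]))

  expect_error(phantom_generate(
    phantom_spec(48, 48, segments = list(vessel_segment(c(24, 5), c(24, 60),
                                                        3, 0.15)))),
    "outside")
})

test_that("identical specs give bit-identical phantoms without touching the RNG", {
  spec <- phantom_spec(64, 64, noise_sd = 0.05,
                       segments = list(vessel_segment(c(30, 10), c(30, 50),
                                                      3, 0.15)),
                       seed = 99)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- phantom_generate(spec)
  mid <- runif(1)           # caller's RNG stream must be undisturbed
  b <- phantom_generate(spec)
  expect_identical(a$image, b$image)
  expect_identical(mid, before)
  # a different seed changes the noise
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(phantom_generate(spec2)$image, a$image))
})

test_that("the standard suite has the documented fixtures and topology", {
  suite <- phantom_suite(3)
  expect_named(suite, c("thin", "thick", "parallel", "crossing", "reflex",
                        "gradient"))
  expect_equal(count_components(suite$parallel$truth), 2L)
  expect_equal(count_components(suite$crossing$truth), 1L)
  for (nm in names(suite)) {
    ph <- suite[[nm]]
    dens <- sum(ph$truth & ph$fov) / sum(ph$fov)
    expect_gt(dens, 0.07)   # near the ~10% vessel density of real retinas
    expect_lt(dens, 0.14)
    expect_true(all(ph$image >= 0 & ph$image <= 1))
  }
  # reflex fixture carries a bright centerline inside the vessel
  rf <- suite$reflex
  expect_gt(mean(rf$green[38, 20:70]), mean(rf$green[36, 20:70]))
  # thin pixels are flagged thin, the thick fixture has none
  expect_true(all(suite$thin$thin == suite$thin$truth))
  expect_equal(sum(suite$thick$thin), 0L)
})

test_that("phantom_write emits the four artifacts and a readable spec", {
  dir <- withr::local_tempdir()
  ph <- phantom_suite(5)$parallel
  phantom_write(ph, dir)
  expect_true(all(file.exists(file.path(dir, c("image.png", "truth.png",
                                               "fov.png", "spec.json")))))
  spec <- jsonlite::read_json(file.path(dir, "spec.json"))
  expect_equal(spec$seed, 5L)
  expect_equal(length(spec$segments), 2L)
  back <- fov_mask(mode = "file", path = file.path(dir, "truth.png"))
  expect_identical(back, ph$truth)
})
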