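test_that("magnitude map is the per-pixel Euclidean norm", {
  z <- matrix(0, 8, 8)
  f0 <- displacement_field(z, z)
  expect_equal(magnitude_map(f0), z)
  f345 <- displacement_field(matrix(3, 8, 8), matrix(4, 8, 8))
  expect_equal(magnitude_map(f345), matrix(5, 8, 8))
  set.seed(41)
  dx <- matrix(rnorm(64, sd = 10), 8, 8); dy <- matrix(rnorm(64, sd = 10), 8, 8)
  mag <- magnitude_map(displacement_field(dx, dy))
  for (i in 1:8) for (j in 1:8)
    expect_equal(mag[i, j], sqrt(dx[i, j]^2 + dy[i, j]^2))
  expect_error(displacement_field(matrix(NA_real_, 2, 2), matrix(0, 2, 2)),
               "non-finite")
})

test_that("unstable region segmentation matches forced arithmetic", {
  z <- matrix(0, 10, 10)
  r0 <- unstable_region(z, pixel_spacing_mm = 1)
  expect_equal(r0$unstable_area, 0)
  expect_true(r0$stable)

  # uniform 20 mm shift over a 10 cm x 10 cm region: all 100 cm^2 unstable
  f <- displacement_field(matrix(20, 100, 100), matrix(0, 100, 100),
                          pixel_spacing_mm = 1)
  r <- unstable_region(f)
  expect_equal(r$unstable_area, 100)
  expect_equal(r$unstable_fraction, 1)
  expect_false(r$stable)
  expect_equal(r$max_distension, 2)
})

test_that("pixel counting matches the brute-force oracle on random fields", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    mag <- matrix(runif(n * n, 0, 30), n, n)
    spacing <- runif(1, 0.5, 3)
    thr <- runif(1, 5, 25)
    r <- unstable_region(mag, pixel_spacing_mm = spacing,
                         shift_threshold_mm = thr)
    cnt <- oracle_unstable_pixels(mag, thr)
    expect_identical(r$n_unstable_pixels, cnt)
    expect_equal(r$unstable_area, cnt * (spacing / 10)^2)
  }
})

test_that("elasticity map flags strain above 20%", {
  rest <- matrix(10, 5, 5)
  expect_equal(elasticity_map(rest, rest)$strain, matrix(0, 5, 5))
  em <- elasticity_map(rest, matrix(12.5, 5, 5))
  expect_equal(em$strain, matrix(0.25, 5, 5))
  expect_true(all(em$flagged))
  set.seed(43)
  stretched <- matrix(runif(25, 9, 14), 5, 5)
  em2 <- elasticity_map(rest, stretched)
  expect_equal(sum(em2$flagged),
               sum((stretched - rest) / rest > 0.20))
  expect_error(elasticity_map(matrix(0, 2, 2), matrix(1, 2, 2)),
               "strictly positive")
})

test_that("phantom scenarios behave as constructed", {
  # amplitude below threshold: stable, zero unstable area by construction
  fs <- synth_field("stable", size = 64, amplitude_mm = 5, seed = 10)
  rs <- unstable_region(fs)
  expect_true(rs$stable)
  expect_equal(rs$unstable_area, 0)

  # focal bump: recovered area within 5% of the analytic level-set area
  ff <- synth_field("focal_laxity", size = 201, amplitude_mm = 30,
                    sigma_mm = 25, seed = 10)
  rf <- unstable_region(ff)
  exact <- focal_unstable_area(30, 25)
  expect_lt(abs(rf$unstable_area - exact) / exact, 0.05)
  expect_false(rf$stable)

  # determinism
  f1 <- synth_field("diffuse_laxity", size = 48, amplitude_mm = 22, seed = 77)
  f2 <- synth_field("diffuse_laxity", size = 48, amplitude_mm = 22, seed = 77)
  expect_identical(f1, f2)
  f3 <- synth_field("diffuse_laxity", size = 48, amplitude_mm = 22, seed = 78)
  expect_false(identical(f1$dx, f3$dx))
})

test_that("unstable area is monotone in amplitude and antitone in threshold", {
  areas <- vapply(c(16, 20, 25, 30), function(a)
    unstable_region(synth_field("focal_laxity", size = 101, amplitude_mm = a,
                                sigma_mm = 20, seed = 3))$unstable_area,
    numeric(1))
  expect_true(all(diff(areas) >= 0))
  f <- synth_field("focal_laxity", size = 101, amplitude_mm = 30,
                   sigma_mm = 20, seed = 3)
  mag <- magnitude_map(f)
  by_thr <- vapply(c(10, 15, 20, 25), function(t)
    unstable_region(mag, 1, shift_threshold_mm = t)$unstable_area, numeric(1))
  expect_true(all(diff(by_thr) <= 0))
})

test_that("a field whose maximum shift is at most 15 mm is always stable", {
  set.seed(44)
  for (i in 1:10) {
    f <- synth_field("diffuse_laxity", size = 32,
                     amplitude_mm = runif(1, 0, 15), seed = i)
    expect_true(unstable_region(f)$stable)
  }
})

test_that("displacement fields round-trip through delimited text plus sidecar", {
  set.seed(45)
  n <- 12
  mask <- matrix(runif(n * n) > 0.3, n, n)
  f <- displacement_field(matrix(round(rnorm(n * n), 4), n, n),
                          matrix(round(rnorm(n * n), 4), n, n),
                          pixel_spacing_mm = 2, mask = mask)
  dir <- withr::local_tempdir()
  write_field(f, file.path(dir, "dx.csv"), file.path(dir, "dy.csv"),
              file.path(dir, "meta.json"))
  back <- read_field(file.path(dir, "dx.csv"), file.path(dir, "dy.csv"),
                     file.path(dir, "meta.json"))
  expect_equal(unname(back$dx), unname(f$dx))
  expect_equal(unname(back$dy), unname(f$dy))
  expect_equal(unname(back$mask), unname(f$mask))
  expect_equal(back$pixel_spacing_mm, 2)
  # masked statistics honoured
  mag <- magnitude_map(f)
  r <- unstable_region(f)
  expect_equal(r$max_distension, max(mag[mask]) / 10)
})
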