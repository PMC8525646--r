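test_that("segmentation handles blank and degenerate images", {
  blank <- list(image = matrix(0.3, 64, 64), nm_per_pixel = 1, id = "blank")
  expect_warning(fs <- segment_filaments(blank), "no filaments")
  expect_equal(nrow(fs), 0)
  bad <- list(image = matrix(c(NA, runif(63 * 64 + 63)), 64, 64),
              nm_per_pixel = 1, id = "bad")
  expect_error(segment_filaments(bad), "finite")
})

test_that("a single noiseless disk is segmented with accurate area", {
  m <- single_disk_micrograph(r_nm = 9, nm_per_pixel = 1)
  fs <- segment_filaments(m)
  expect_equal(nrow(fs), 1)
  expect_lt(abs(fs$area_nm2 - pi * 81) / (pi * 81), 0.05)
  expect_false(fs$border)
})

test_that("a noiseless 7-site lattice yields exactly 7 filaments", {
  m <- gen_em_micrograph(c(160, 160), 40, 9, 1, jitter_sd = 0, noise_sd = 0,
                         centers = hex7_centers(40, c(80, 80)), seed = 1)
  fs <- segment_filaments(m, seg_params(exclude_border = FALSE))
  expect_equal(nrow(fs), 7)
})

test_that("interfilament distance on a perfect lattice is spacing minus diameter", {
  ctr <- hex7_centers(40, c(80, 80))
  fs <- data.frame(label = 1:7, cx_nm = ctr[, 1], cy_nm = ctr[, 2],
                   area_nm2 = rep(pi * 81, 7), border = FALSE)
  attr(fs, "image_size_nm") <- c(160, 160)
  mr <- interfilament_distance(fs)
  # only the central site has its full neighbourhood inside the frame
  expect_equal(mr$n_focal, 1)
  expect_equal(mr$mean_center_distance, 40, tolerance = 1e-12)
  expect_equal(mr$mean_interfilament_distance, 22, tolerance = 1e-12)
  expect_false(mr$negative_distance)
})

test_that("mean 6-NN distances equal an exhaustive brute-force oracle", {
  m <- gen_em_micrograph(c(320, 320), 40, 9, 1, jitter_sd = 2, noise_sd = 0.05,
                         seed = 21)
  fs <- segment_filaments(m)
  mr <- interfilament_distance(fs)
  bf <- brute_force_knn(fs, attr(fs, "image_size_nm"))
  expect_equal(sort(mr$per_filament_nn), sort(bf$per_focal), tolerance = 1e-12)
  expect_equal(mr$mean_center_distance, bf$mean, tolerance = 1e-12)
})

test_that("fewer than 7 filaments is an error", {
  fs <- data.frame(label = 1:6, cx_nm = runif(6, 0, 100), cy_nm = runif(6, 0, 100),
                   area_nm2 = rep(250, 6), border = FALSE)
  expect_error(interfilament_distance(fs), "at least 7")
})

test_that("FFT spacing finds the hexagonal plane spacing and flags noise", {
  m <- gen_em_micrograph(c(512, 512), 40, 9, 1, jitter_sd = 0, noise_sd = 0, seed = 31)
  sp <- estimate_spacing_fft(m)
  expect_true(sp$defined)
  # first diffraction ring of a hexagonal lattice sits at d * sqrt(3) / 2
  expect_lt(abs(sp$spacing_nm - 40 * sqrt(3) / 2) / (40 * sqrt(3) / 2), 0.05)
  expect_lt(abs(sp$lattice_d_nm - 40) / 40, 0.05)

  withr::with_seed(1, {
    noise <- list(image = matrix(runif(256^2), 256, 256), nm_per_pixel = 1, id = "wn")
  })
  expect_false(estimate_spacing_fft(noise)$defined)

  # doubling nm_per_pixel doubles the reported spacing, pixels unchanged
  m2 <- m; m2$nm_per_pixel <- 2
  sp2 <- estimate_spacing_fft(m2, spacing_range = c(20, 200))
  expect_equal(sp2$spacing_nm / sp$spacing_nm, 2, tolerance = 1e-12)
})

test_that("shoelace polygon area matches a fan-triangulation oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")

  withr::with_seed(7, {
    pts <- matrix(runif(40, 0, 10), ncol = 2)
    hull <- grDevices::chull(pts)          # convex polygon, CCW order
    poly <- pts[rev(hull), , drop = FALSE]
  })
  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  n <- nrow(poly)
  oracle <- sum(sapply(2:(n - 1),
                       function(i) tri_area(poly[1, ], poly[i, ], poly[i + 1, ])))
  expect_equal(polygon_area(poly), oracle, tolerance = 1e-12)
})

test_that("percent occurrence reproduces the worked per-animal summaries", {
  expect_equal(region_occurrence_summary(c(a = TRUE, b = TRUE, c = TRUE, d = TRUE)), 100)
  expect_equal(region_occurrence_summary(rep(FALSE, 4)), 0)
  expect_equal(region_occurrence_summary(c(TRUE, FALSE, FALSE, FALSE)), 25)
  expect_error(region_occurrence_summary(logical(0)), "empty")
})

test_that("morphometry is scale-equivariant in nm per pixel", {
  m <- gen_em_micrograph(c(256, 256), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05, seed = 41)
  fs1 <- segment_filaments(m)
  s <- 2.5
  m2 <- m; m2$nm_per_pixel <- m$nm_per_pixel * s
  p2 <- seg_params(min_area_nm2 = 50 * s^2, max_area_nm2 = 2000 * s^2)
  fs2 <- segment_filaments(m2, p2)
  expect_equal(nrow(fs1), nrow(fs2))
  expect_equal(fs2$area_nm2, fs1$area_nm2 * s^2, tolerance = 1e-12)
  mr1 <- interfilament_distance(fs1)
  mr2 <- interfilament_distance(fs2)
  expect_equal(mr2$mean_interfilament_distance,
               mr1$mean_interfilament_distance * s, tolerance = 1e-12)
})

test_that("morphometry is robust to lattice rotation", {
  res <- sapply(c(0, 15, 30) * pi / 180, function(th) {
    m <- gen_em_micrograph(c(384, 384), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05,
                           seed = 51, orientation = th)
    mr <- interfilament_distance(segment_filaments(m))
    c(mr$mean_csa, mr$mean_interfilament_distance)
  })
  expect_lt(diff(range(res[1, ])) / mean(res[1, ]), 0.03)
  expect_lt(diff(range(res[2, ])) / mean(res[2, ]), 0.03)
})

test_that("region sampling is seeded, reproducible and counts filaments", {
  m <- gen_em_micrograph(c(512, 512), 40, 9, 1, jitter_sd = 1, noise_sd = 0.05, seed = 61)
  fs <- segment_filaments(m)
  r1 <- sample_regions(fs, c(512, 512), n_regions = 3, seed = 9)
  r2 <- sample_regions(fs, c(512, 512), n_regions = 3, seed = 9)
  expect_identical(r1$label, r2$label)
  expect_identical(attr(r1, "regions"), attr(r2, "regions"))
  expect_gt(nrow(r1), 100)   # protocol: regions jointly include > 100 filaments
  r3 <- sample_regions(fs, c(512, 512), n_regions = 3, seed = 11)
  expect_false(identical(attr(r1, "regions"), attr(r3, "regions")))
})
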