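# Core depth-density operator: normalization, local statistics, the
# Gaussian scoring and both operator variants.

test_that("normalize_depth rescales mm to [0,1] and keeps the no-return sentinel", {
  expect_identical(normalize_depth(0), 0)
  expect_equal(normalize_depth(4500, 500, 4500), 1)
  expect_equal(normalize_depth(2500, 500, 4500), 0.5)
  # below-range values clip to 0, above-range to 1
  expect_equal(normalize_depth(c(100, 9000)), c(0, 1))
  # sentinel survives even when d_min would map it elsewhere
  m <- matrix(c(0, 500, 1500, 4500), 2)
  expect_equal(normalize_depth(m), matrix(c(0, 0, 0.25, 1), 2))
  expect_error(normalize_depth(100, 500, 500), "d_min")
  expect_error(normalize_depth(-3), ">= 0")
})

test_that("gauss matches the closed-form normal density", {
  expect_equal(gauss(1, 0, 1), exp(-0.5) / sqrt(2 * pi), tolerance = 1e-12)
  expect_equal(gauss(1, 0, 1), 0.2419707, tolerance = 1e-6)
  # peak value and 1/sigma prefactor scaling
  expect_equal(gauss(0.3, 0.3, 2), 1 / (2 * sqrt(2 * pi)))
  expect_equal(gauss(0, 0, 2), gauss(0, 0, 1) / 2)
})

test_that("manhattan_distance sums absolute offsets", {
  expect_equal(manhattan_distance(0, 0), 0)
  expect_equal(manhattan_distance(1, 0), 1)
  expect_equal(manhattan_distance(-2, 3), 5)
  expect_equal(manhattan_distance(-1:1, c(2, 0, -2)), c(3, 0, 3))
})

test_that("local_stats reproduces hand-computed window statistics", {
  # constant image: zero deviations everywhere that the window stays inside
  cst <- matrix(0.5, 9, 9)
  st <- local_stats(cst, 3)
  expect_equal(st$mean[2:8, 2:8], matrix(0.5, 7, 7))
  expect_equal(st$sd_mean[2:8, 2:8], matrix(0, 7, 7))
  expect_equal(st$sd_center[2:8, 2:8], matrix(0, 7, 7))

  # hand-worked 3x3 patch (rows 0.1,0.2,0.3 / 0.2,0.3,0.4 / 0.3,0.4,0.5)
  patch <- matrix(0.5, 5, 5)
  patch[2:4, 2:4] <- matrix(c(0.1, 0.2, 0.3, 0.2, 0.3, 0.4, 0.3, 0.4, 0.5),
                            3, byrow = TRUE)
  st <- local_stats(patch, 3)
  expect_equal(st$mean[3, 3], 0.3)
  expect_equal(st$sd_mean[3, 3], sqrt(0.12 / 9), tolerance = 1e-12)
  expect_equal(st$sd_center[3, 3], sqrt(0.12 / 9), tolerance = 1e-12)

  # whenever the centre equals the window mean the two deviations coincide
  set.seed(11)
  img <- matrix(runif(15 * 15), 15, 15)
  st <- local_stats(img, 5)
  at_mean <- abs(img - st$mean) < 1e-12
  expect_true(all(st$sd_mean >= 0) && all(st$sd_center >= 0))
  expect_equal(st$sd_mean[at_mean], st$sd_center[at_mean])
})

test_that("pixel_distance_difference divides deviations by Manhattan distance", {
  w <- matrix(0.2, 5, 5)
  w[4, 4] <- 0.8  # offset (1,1) from the centre
  pd <- pixel_distance_difference(w, 0.2, mean(w))
  expect_equal(pd$dif_center[4, 4], 0.6 / 2)
  expect_equal(pd$dif_center[3, 3], 0)  # centre convention
  expect_equal(pd$dif_mean[3, 3], 0)
  # window identical to the centre value: dif_center vanishes
  pd0 <- pixel_distance_difference(matrix(0.4, 7, 7), 0.4, 0.4)
  expect_true(all(pd0$dif_center == 0))
})

test_that("uniform surfaces are maximal same-surface evidence", {
  for (s in c(3, 7)) {
    dd <- depth_density(matrix(0.42, 15, 15), s = s)
    half <- (s - 1) %/% 2
    inner <- dd$values[(1 + half):(15 - half), (1 + half):(15 - half)]
    expect_true(all(inner == 1))
    # the zero padding depresses density at the borders by design
    expect_true(all(dd$values[1, ] < 1))
  }
  # 1x1 image: window is centre plus padding; result is a valid density
  one <- depth_density_naive(matrix(0.7, 1, 1))
  expect_true(one$values >= 0 && one$values <= 1)
  expect_identical(one$values, depth_density_naive(matrix(0.7, 1, 1))$values)
})

test_that("depth density stays in [0,1] on arbitrary inputs", {
  set.seed(101)
  for (rep in 1:5) {
    img <- matrix(runif(20 * 20), 20, 20)
    for (variant in c("v1", "v2")) {
      dd <- depth_density(img, s = 5, variant = variant)$values
      expect_true(all(dd >= 0 & dd <= 1))
      expect_false(anyNA(dd))
    }
  }
})

test_that("v1 densities are invariant to affine rescaling of depth", {
  set.seed(21)
  img <- 0.3 + 0.3 * matrix(runif(18 * 18), 18, 18)
  d1 <- depth_density(img, 5, "v1")$values
  d2 <- depth_density(0.8 * img + 0.1, 5, "v1")$values
  # compare where the window deviations are non-degenerate (all interior here)
  expect_equal(d1[3:16, 3:16], d2[3:16, 3:16], tolerance = 1e-8)
})

test_that("the operator commutes with transposition, flips and rotation", {
  set.seed(31)
  img <- matrix(runif(14 * 14), 14, 14)
  dd <- function(x) depth_density(x, 5, "v2")$values
  base <- dd(img)
  expect_equal(dd(t(img)), t(base), tolerance = 1e-12)
  expect_equal(dd(img[nrow(img):1, ]), base[nrow(base):1, ], tolerance = 1e-12)
  rot90 <- function(m) t(m[nrow(m):1, ])
  expect_equal(dd(rot90(img)), rot90(base), tolerance = 1e-12)
})

test_that("vectorized and naive implementations agree on random images", {
  set.seed(41)
  for (rep in 1:10) {
    img <- matrix(runif(16 * 16), 16, 16)
    s <- sample(c(3, 5, 7), 1)
    variant <- sample(c("v1", "v2"), 1)
    fast <- depth_density(img, s, variant)$values
    slow <- depth_density_naive(img, s, variant)$values
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
})

test_that("boundary bands score well below object interiors", {
  # two constant levels (gap 0.4) with a 2-pixel no-return band: interiors
  # are uniform windows (density 1); the band carries strictly lower density
  img <- make_boundary_patch(48, 0.3, 0.7, zero_band_width = 2)
  dd <- depth_density(img, 7, "v2")$values
  band_cols <- which(colSums(img == 0) == nrow(img))
  strip <- dd[8:41, (min(band_cols) - 3):(max(band_cols) + 3)]
  interior <- dd[8:41, 8:16]  # far from band and borders
  expect_true(all(interior == 1))
  expect_lt(median(strip), min(interior) - 0.3)
  expect_lt(median(dd[8:41, band_cols]), 0.65)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(depth_density(matrix(1.5, 4, 4)), "\\[0, 1\\]")
  expect_error(depth_density(matrix(0.5, 4, 4), s = 4), "odd")
  expect_error(depth_density(matrix(0.5, 4, 4), s = 1), "odd")
  expect_error(depth_density(matrix(0.5, 4, 4), sigma_floor = 0), "sigma_floor")
  expect_error(local_stats("not a matrix"), "matrix")
})
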