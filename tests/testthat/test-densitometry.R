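gaussian_lane <- function(centers, volumes, sigma = 3, n = 700,
                          background = 0, slope = 0) {
  x <- 0:(n - 1)
  y <- background + slope * x
  for (k in seq_along(centers))
    y <- y + volumes[k] * stats::dnorm(x, centers[k], sigma)
  lane_profile(x, pmax(y, 0))
}

test_that("background subtraction flattens constants and preserves clean profiles", {
  flat <- lane_profile(0:199, rep(7, 200))
  expect_true(all(subtract_background(flat)$intensities == 0))
  expect_true(all(subtract_background(flat, "rolling_min",
                                      window = 31)$intensities == 0))
  clean <- gaussian_lane(100, 500, n = 200)
  out <- subtract_background(clean, "rolling_min", window = 61)
  expect_equal(out$intensities, clean$intensities, tolerance = 1e-9)
  expect_error(subtract_background(clean, "rolling_min", window = 0))
  expect_error(subtract_background(clean, "rolling_min", window = 500))
})

test_that("a band on a linear ramp is recovered within 2%", {
  lp <- gaussian_lane(300, 1000, background = 20, slope = 0.05)
  sub <- subtract_background(lp, "linear")
  b <- quantify_bands(sub, c(long = 300), tolerance = 10)
  expect_equal(b$volume, 1000, tolerance = 0.02)
})

test_that("band integration matches the Gaussian volume within 1%", {
  for (sigma in c(2, 3, 5)) {
    lp <- gaussian_lane(350, 1234, sigma = sigma)
    b <- quantify_bands(lp, c(x = 350), tolerance = 5)
    expect_equal(b$volume, 1234, tolerance = 0.01)
    expect_equal(b$sigma, sigma, tolerance = 0.05)
  }
})

test_that("two-band quantification reproduces the 312:688 split", {
  ctr <- default_migration(c(long = 542, short = 500))
  lp <- gaussian_lane(ctr, c(312, 688))
  bands <- quantify_bands(lp, ctr)
  expect_equal(long_fraction(bands), 0.312, tolerance = 1e-3)
  # missing long band reads zero volume but keeps its label
  lp1 <- gaussian_lane(ctr["short"], 688)
  b1 <- quantify_bands(lp1, ctr)
  expect_equal(b1$volume[b1$label == "long"], 0)
  expect_equal(long_fraction(b1), 0)
})

test_that("band assignment resolves conflicts by proximity and errors on ties", {
  lp <- gaussian_lane(300, 500)
  b <- quantify_bands(lp, c(long = 295, short = 305.2), tolerance = 10)
  expect_equal(b$volume[b$label == "long"] > 0, TRUE)
  expect_equal(b$volume[b$label == "short"], 0)
  expect_error(quantify_bands(lp, c(long = 295, short = 305), tolerance = 10),
               "equidistant")
  expect_error(quantify_bands(lp, c(long = 5000), tolerance = 10))
})

test_that("long fractions follow band-volume arithmetic with optional molar correction", {
  b <- data.frame(label = c("long", "short"), volume = c(312, 688))
  expect_equal(long_fraction(b), 0.312, tolerance = 1e-12)
  expect_equal(long_fraction(data.frame(label = c("long", "short"),
                                        volume = c(0, 100))), 0)
  # equal volumes, lengths 542 and 500: molar fraction 500/1042
  beq <- data.frame(label = c("long", "short"), volume = c(100, 100))
  expect_equal(long_fraction(beq, c(long = 542, short = 500)),
               500 / 1042, tolerance = 1e-9)
  expect_error(long_fraction(data.frame(label = c("long", "short"),
                                        volume = c(0, 0))))
})

test_that("the long fraction is invariant to global intensity rescaling", {
  ctr <- default_migration(c(long = 542, short = 500))
  lp <- simulate_lane(c(long = 240, short = 760),
                      c(long = 542, short = 500), gel_params(seed = 4))
  f1 <- long_fraction(quantify_bands(subtract_background(lp), ctr))
  scaled <- lane_profile(lp$positions, lp$intensities * 7.3)
  f2 <- long_fraction(quantify_bands(subtract_background(scaled), ctr))
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("the long fraction is monotone in the true long abundance", {
  ctr <- default_migration(c(long = 542, short = 500))
  fs <- numeric(0)
  for (ab in seq(50, 950, by = 150)) {
    lp <- simulate_lane(c(long = ab, short = 500),
                        c(long = 542, short = 500), clean_gel())
    fs <- c(fs, long_fraction(quantify_bands(lp, ctr)))
  }
  expect_true(all(diff(fs) > 0))
})

test_that("band volumes are recovered within 2% under light noise", {
  # 30 seeded lanes, bands >= 4 sigma apart, noise <= 1% of peak height
  sigma <- 3
  set.seed(10)
  for (r in 1:30) {
    v <- c(stats::runif(1, 200, 800), stats::runif(1, 200, 800))
    centers <- c(250, 250 + 4 * (sigma + sigma) * stats::runif(1, 1, 3))
    peak_h <- min(v) * stats::dnorm(0, 0, sigma)
    x <- 0:699
    y <- v[1] * stats::dnorm(x, centers[1], sigma) +
      v[2] * stats::dnorm(x, centers[2], sigma) +
      stats::rnorm(700, 0, 0.01 * peak_h)
    lp <- lane_profile(x, pmax(y, 0))
    b <- quantify_bands(lp, c(a = centers[1], b = centers[2]), tolerance = 6)
    expect_equal(b$volume[1], v[1], tolerance = 0.02)
    expect_equal(b$volume[2], v[2], tolerance = 0.02)
  }
})

test_that("reference normalisation is a plain ratio with a guarded denominator", {
  expect_equal(normalize_to_reference(50, 100), 0.5)
  expect_equal(normalize_to_reference(0, 100), 0)
  expect_error(normalize_to_reference(50, 0))
  # synthetic target/reference lane at ratio 1.7 with 2% noise
  set.seed(2)
  x <- 0:699
  y <- 170 * stats::dnorm(x, 200, 3) + 100 * stats::dnorm(x, 500, 3)
  y <- pmax(y + stats::rnorm(700, 0, 0.02 * max(y)), 0)
  b <- quantify_bands(lane_profile(x, y),
                      c(target = 200, reference = 500), tolerance = 6)
  r <- normalize_to_reference(b$volume[b$label == "target"],
                              b$volume[b$label == "reference"])
  expect_equal(r, 1.7, tolerance = 0.1 / 1.7)
})
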