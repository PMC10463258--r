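test_that("peak detection finds each simulated base once", {
  rp <- reference_pair("ACGTACGTAC", "GGG", 5)
  p <- clean_params()
  tr <- simulate_trace(0.5, rp, p)
  pk <- detect_peaks(tr$channel_data, p$peak_spacing)
  truth <- tr$peak_positions
  expect_length(pk, length(truth))
  expect_true(all(abs(pk - truth) <= 1))
})

test_that("peak detection handles flat signals and unresolved doublets", {
  flat <- matrix(0, 100, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_length(detect_peaks(flat, 10), 0)
  expect_length(detect_peaks(flat + 3, 10), 0)
  # two Gaussians 4 scans apart with 12-scan expected spacing: one peak,
  # and it is the earlier one
  x <- 0:99
  two <- exp(-(x - 40)^2 / 2) + exp(-(x - 44)^2 / 2)
  m <- flat; m[, "A"] <- two
  pk <- detect_peaks(m, 12)
  expect_length(pk, 1)
  expect_equal(pk, 40)
  expect_error(detect_peaks(flat[1:5, ], 10))
})

test_that("amplitude tables behave on degenerate traces", {
  # a single-peak trace gives a 1 x 4 table
  m <- matrix(0, 30, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  m[16, "G"] <- 100
  tr <- chromatogram(m, peak_positions = 15)
  tab <- extract_peak_amplitudes(tr, spacing = 12, method = "max")
  expect_equal(dim(tab), c(1, 4))
  expect_equal(unname(tab[1, "G"]), 100)
  expect_error(extract_peak_amplitudes(chromatogram(m)))
})

test_that("a half-and-half mixture splits the decayed amplitude between both channels", {
  p <- clean_params()
  tr <- simulate_trace(0.5, serine_refs, p)
  sites <- find_informative_sites(serine_refs, 3)
  for (method in c("max", "height")) {
    amps <- extract_peak_amplitudes(tr, method = method)
    for (j in seq_len(nrow(sites))) {
      i <- sites$peak_index[j]
      expected <- 0.5 * p$base_amplitude * exp(-p$decay_rate * i)
      expect_equal(unname(amps[i + 1, sites$base_plus[j]]), expected,
                   tolerance = 1e-6)
      expect_equal(unname(amps[i + 1, sites$base_minus[j]]), expected,
                   tolerance = 1e-6)
    }
  }
})

test_that("informative sites are the first differing positions after the junction", {
  rp <- reference_pair("AAACCC", "GGG", 3)
  expect_equal(long_sequence(rp), "AAAGGGCCC")
  sites <- find_informative_sites(rp, n_sites = 3, window = 3)
  expect_equal(sites$peak_index, c(3, 4, 5))
  expect_equal(sites$base_plus, rep("G", 3))
  expect_equal(sites$base_minus, rep("C", 3))
  # default requests three sites
  expect_equal(nrow(find_informative_sites(serine_refs)), 3)
  # window truncation past the short read warns
  expect_warning(find_informative_sites(rp, 3, window = 10))
})

test_that("amplitude ratios reproduce direct arithmetic and drop dead sites", {
  tab <- matrix(rep(c(0, 70, 30, 0), 3), nrow = 3, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  sites <- data.frame(peak_index = 0:2, base_plus = "G", base_minus = "C",
                      stringsAsFactors = FALSE)
  est <- amplitude_ratio_estimate(tab, sites)
  expect_equal(est$fraction, 0.3, tolerance = 1e-12)
  expect_equal(est$sd, 0)
  expect_equal(est$n_sites, 3)
  # site with both predicted channels at zero is dropped
  tab2 <- tab; tab2[2, ] <- 0
  expect_warning(est2 <- amplitude_ratio_estimate(tab2, sites))
  expect_equal(est2$n_sites, 2)
  tab3 <- tab; tab3[, ] <- 0
  expect_error(suppressWarnings(amplitude_ratio_estimate(tab3, sites)))
})

test_that("pure traces give fractions exactly 0 and 1", {
  for (f in c(0, 1)) {
    tr <- simulate_trace(f, serine_refs, clean_params())
    expect_equal(fit_trace_mixture(tr, serine_refs)$fraction, f,
                 tolerance = 1e-6)
    expect_equal(fit_trace_mixture(tr, serine_refs, method = "lsq")$fraction,
                 f, tolerance = 1e-6)
  }
})

test_that("noiseless mixtures with decay round-trip through both estimators", {
  p <- clean_params(decay_rate = 0.01)   # strong decay: ratio must cancel it
  tr <- simulate_trace(0.25, serine_refs, p)
  fit <- fit_trace_mixture(tr, serine_refs)
  expect_equal(fit$fraction, 0.25, tolerance = 1e-6)
  expect_equal(fit$method, "amplitude_ratio")
  expect_true(all(fit$per_site_fractions >= 0 & fit$per_site_fractions <= 1))
  expect_equal(fit_trace_mixture(tr, serine_refs, method = "lsq")$fraction,
               0.25, tolerance = 1e-6)
})

test_that("least squares is exact on templates and refuses degenerate windows", {
  tr <- simulate_trace(1, serine_refs, clean_params())
  expect_equal(fit_trace_mixture(tr, serine_refs, method = "lsq")$fraction, 1,
               tolerance = 1e-9)
  tr04 <- simulate_trace(0.4, serine_refs, clean_params())
  expect_equal(fit_trace_mixture(tr04, serine_refs, method = "lsq")$fraction,
               0.4, tolerance = 1e-9)
  rp <- reference_pair("AAAA", "AA", 2)  # homopolymer: templates identical
  trh <- simulate_trace(0.5, rp, clean_params())
  expect_error(
    suppressWarnings(fit_trace_mixture(trh, rp, method = "lsq", window = 2)),
    "unidentifiable")
})

test_that("the closed-form least squares matches the grid-search oracle on noisy traces", {
  set.seed(7)
  for (r in 1:25) {
    f <- stats::runif(1)
    tr <- simulate_trace(f, serine_refs, trace_params(seed = 2000 + r))
    closed <- fit_trace_mixture(tr, serine_refs, method = "lsq")$fraction
    grid <- grid_search_fraction(tr, serine_refs)
    expect_lt(abs(closed - grid), 1e-3 + 1e-9)
  }
})

test_that("estimates increase strictly with the true fraction on clean traces", {
  fs <- seq(0, 1, 0.1)
  est_a <- est_l <- numeric(length(fs))
  for (k in seq_along(fs)) {
    tr <- simulate_trace(fs[k], serine_refs, clean_params())
    est_a[k] <- fit_trace_mixture(tr, serine_refs)$fraction
    est_l[k] <- fit_trace_mixture(tr, serine_refs, method = "lsq")$fraction
  }
  expect_true(all(diff(est_a) > 0))
  expect_true(all(diff(est_l) > 0))
  # method agreement on clean crosstalk-free traces
  expect_true(all(abs(est_a - est_l) <= 0.02))
})

test_that("reverse-complement handling recovers the fraction from the other strand", {
  rc <- reverse_complement(serine_refs)
  # involution
  expect_identical(reverse_complement(rc), serine_refs)
  # a read taken from the reverse primer sees the rc references
  tr_rev <- simulate_trace(0.35, rc, clean_params())
  expect_equal(fit_trace_mixture(tr_rev, rc)$fraction, 0.35,
               tolerance = 1e-6)
})

test_that("mixture_fit methods expose coefficients, residuals and simulations", {
  tr <- simulate_trace(0.3, serine_refs, clean_params())
  fit <- fit_trace_mixture(tr, serine_refs, method = "lsq")
  expect_equal(unname(coef(fit)), fit$fraction)
  expect_equal(dim(residuals(fit)), dim(fitted(fit)))
  expect_lt(max(abs(residuals(fit))), 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 5, params = clean_params())
  expect_length(sims, 2)
  expect_equal(fit_trace_mixture(sims[[1]], serine_refs)$fraction,
               fit$fraction, tolerance = 1e-6)
  expect_output(print(summary(fit)), "least_squares")
})
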