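test_that("pure-species noiseless traces put all signal in the expected channel", {
  tr <- simulate_trace(1, serine_refs, clean_params())
  long <- strsplit(long_sequence(serine_refs), "")[[1]]
  amps <- extract_peak_amplitudes(tr, method = "max")
  for (i in seq_along(long)) {
    expect_gt(amps[i, long[i]], 0)
    others <- amps[i, setdiff(colnames(amps), long[i])]
    expect_lt(max(others), 1e-6 * amps[i, long[i]])
  }
})

test_that("homopolymer insertions are invisible within the read overlap", {
  rp <- reference_pair("AAAA", "AAA", 2)
  mixed <- simulate_trace(0.5, rp, clean_params())
  pure <- simulate_trace(1, rp, clean_params())
  # all four overlap positions read A in both species: channel pattern of
  # the mixture equals the pure trace
  for (i in 1:4) {
    m <- extract_peak_amplitudes(mixed, method = "max")[i, ]
    p <- extract_peak_amplitudes(pure, method = "max")[i, ]
    expect_equal(m / sum(m), p / sum(p), tolerance = 1e-9)
  }
  expect_equal(nrow(find_informative_sites(rp, 2, window = 2)), 0)
})

test_that("noiseless channel sums at overlap peaks are independent of the mixture fraction", {
  p <- clean_params()
  n_short <- nchar(serine_refs$short_seq)
  sums <- sapply(c(0, 0.3, 0.7, 1), function(f) {
    tr <- simulate_trace(f, serine_refs, p)
    amps <- extract_peak_amplitudes(tr, method = "max")
    rowSums(amps)[seq_len(n_short)]
  })
  expected <- p$base_amplitude * exp(-p$decay_rate * (seq_len(n_short) - 1))
  for (k in 1:4)
    expect_equal(unname(sums[, k]), expected, tolerance = 1e-6)
})

test_that("trace simulation is deterministic in the seed and validates inputs", {
  p <- trace_params(seed = 99)
  t1 <- simulate_trace(0.4, serine_refs, p)
  t2 <- simulate_trace(0.4, serine_refs, p)
  expect_identical(t1, t2)
  t3 <- simulate_trace(0.4, serine_refs, trace_params(seed = 100))
  expect_false(identical(t1$channel_data, t3$channel_data))
  expect_error(simulate_trace(1.2, serine_refs, p))
  expect_error(trace_params(peak_sigma = 15))       # wider than spacing
  expect_error(reference_pair("ACGT", "AGC", 9))    # offset beyond end
})

test_that("single-species lanes yield one band and a degenerate long fraction", {
  gp <- clean_gel()
  ctr <- default_migration(c(long = 542, short = 500))
  lp <- simulate_lane(c(long = 0, short = 100), c(long = 542, short = 500), gp)
  bands <- quantify_bands(lp, ctr)
  expect_equal(bands$volume[bands$label == "long"], 0)
  expect_equal(long_fraction(bands), 0, tolerance = 1e-6)
  lp2 <- simulate_lane(c(long = 100, short = 0), c(long = 542, short = 500), gp)
  expect_equal(long_fraction(quantify_bands(lp2, ctr)), 1, tolerance = 1e-6)
})

test_that("noiseless molar lanes round-trip the 312:688 abundance ratio", {
  lp <- simulate_lane(c(long = 312, short = 688), c(long = 542, short = 500),
                      clean_gel())
  truth <- attr(lp, "truth")$bands
  expect_equal(truth$volume[truth$species == "long"] /
                 truth$volume[truth$species == "short"],
               312 / 688, tolerance = 1e-9)
  bands <- quantify_bands(lp, default_migration(c(long = 542, short = 500)))
  ratio <- long_fraction(bands)
  expect_equal(ratio, 0.312, tolerance = 1e-3)
})

test_that("mass stain scales band volume with fragment length", {
  L <- 500
  lp <- simulate_lane(c(long = 10, short = 10), c(long = L + 42, short = L),
                      clean_gel(stain_mode = "mass"))
  truth <- attr(lp, "truth")$bands
  expect_equal(truth$volume[truth$species == "long"] /
                 truth$volume[truth$species == "short"],
               (L + 42) / L, tolerance = 1e-12)
})

test_that("coincident migration positions are flagged in the lane truth", {
  same_pos <- function(len) 300
  gp <- gel_params(migration_model = same_pos, noise_sd = 0,
                   background_level = 0)
  lp <- simulate_lane(c(a = 5, b = 5), c(a = 100, b = 200), gp)
  expect_true(attr(lp, "truth")$coincident)
  expect_error(simulate_lane(c(a = 0, b = 0), c(a = 1, b = 2), gp))
})

test_that("dataset truth carries consistent derived fractions", {
  tr <- synthetic_truth(c(0.4, 0.3, 0.1, 0.2))
  expect_equal(tr$f_long, 0.5, tolerance = 1e-12)
  expect_equal(tr$s_short, 0.2, tolerance = 1e-12)
  expect_equal(tr$s_long, 0.4, tolerance = 1e-12)
  # product decomposition A=(1-fL)(1-sS) etc.
  expect_equal(unname(tr$fractions),
               c((1 - tr$f_long) * (1 - tr$s_short),
                 tr$f_long * (1 - tr$s_long),
                 (1 - tr$f_long) * tr$s_short,
                 tr$f_long * tr$s_long),
               tolerance = 1e-9)
  expect_error(synthetic_truth(c(0.5, 0.5, 0.5, 0.5)))
})

test_that("a pure-A truth produces pure short-band data", {
  tr <- synthetic_truth(c(1, 0, 0, 0), replicate_count = 2, seed = 3)
  ds <- generate_dataset(tr, trace_params = clean_params(),
                         gel_params = clean_gel())
  lane_truth <- attr(ds$replicates[[1]]$lane, "truth")$bands
  expect_equal(lane_truth$volume[lane_truth$species == "long"], 0)
  f <- fit_trace_mixture(ds$replicates[[1]]$trace_short, ds$refs)$fraction
  expect_equal(f, 0, tolerance = 1e-6)
})

test_that("identical truth and seed reproduce byte-identical bundles", {
  tr <- synthetic_truth(c(0.4, 0.3, 0.1, 0.2), seed = 11)
  d1 <- generate_dataset(tr)
  d2 <- generate_dataset(tr)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
  d3 <- generate_dataset(synthetic_truth(c(0.4, 0.3, 0.1, 0.2), seed = 12))
  expect_false(identical(serialize(d1, NULL), serialize(d3, NULL)))
})
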