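test_that("wiener entropy hits its closed-form limits and is scale invariant", {
  expect_equal(wiener_entropy(rep(3, 128)), 1.0, tolerance = 1e-12)
  expect_equal(wiener_entropy(c(0, 0, 5, 0)), 0.0, tolerance = 1e-12)
  expect_equal(wiener_entropy(c(1, 2, 4)), 6 / 7, tolerance = 1e-12)
  p <- stats::runif(64)
  expect_equal(wiener_entropy(p * 17.3), wiener_entropy(p), tolerance = 1e-12)
  expect_error(wiener_entropy(numeric(16)), "silent")
  expect_lte(wiener_entropy(stats::runif(256)), 1)
})

test_that("amplitude-threshold segmentation recovers planted bursts", {
  sr <- 44100
  # all-zero -> empty
  expect_identical(segment_sounds(numeric(sr), sr, threshold = 0.1), list())
  # one rectangular burst 0.10-0.20 s at amplitude 0.5
  x <- numeric(sr)
  idx <- (round(0.1 * sr)):(round(0.2 * sr))
  x[idx] <- 0.5 * sin(2 * pi * 2000 * idx / sr)
  segs <- segment_sounds(x, sr, threshold = 0.1)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$offset_s - segs[[1]]$onset_s, 0.10, tolerance = 0.01)
  # five bursts with known onsets vs a brute-force envelope scan
  onsets <- c(0.1, 0.5, 0.9, 1.4, 1.8)
  y <- numeric(2 * sr)
  for (o in onsets) {
    ii <- (round(o * sr)):(round((o + 0.08) * sr))
    y[ii] <- 0.6 * sin(2 * pi * 1500 * ii / sr)
  }
  segs <- segment_sounds(y, sr, threshold = 0.1)
  expect_length(segs, 5L)
  hop <- 0.002  # envelope smoothing window
  # oracle: first sample whose 2 ms moving-average |y| crosses threshold
  w <- round(0.002 * sr)
  env <- as.numeric(stats::filter(abs(y), rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  oracle_onsets <- (which(diff(env >= 0.1) == 1)) / sr
  found <- vapply(segs, function(s) s$onset_s, numeric(1))
  expect_length(oracle_onsets, 5L)
  expect_true(all(abs(found - oracle_onsets) <= hop + 1 / sr))
})

test_that("sorting features recover pure-tone and harmonic-stack structure", {
  sr <- 44100
  bin_hz <- sr / 512
  t <- seq(0, 0.12, by = 1 / sr)
  tone <- structure(list(samples = sin(2 * pi * 1000 * t), sample_rate = sr,
                         onset_s = 0, offset_s = 0.12), class = "vocal_segment")
  f <- compute_sorting_features(tone)
  expect_lt(abs(f$average_frequency - 1000), 1.5 * bin_hz)
  expect_lt(abs(f$fundamental_frequency - 1000), bin_hz)
  expect_lt(abs(f$modal_frequency - 1000), bin_hz)
  expect_equal(f$duration, 0.12, tolerance = 1e-12)
  expect_lt(f$wiener_entropy, 0.05)
  # harmonic stack f0 = 500, 4 harmonics: fundamental within one bin
  stack <- rowSums(sapply(1:4, function(h) 0.7^(h - 1) * sin(2 * pi * h * 500 * t)))
  seg <- structure(list(samples = stack, sample_rate = sr,
                        onset_s = 0, offset_s = 0.12), class = "vocal_segment")
  fs <- compute_sorting_features(seg)
  expect_lt(abs(fs$fundamental_frequency - 500), bin_hz)
  expect_error(compute_sorting_features(
    structure(list(samples = numeric(100), sample_rate = sr,
                   onset_s = 0, offset_s = 100 / sr), class = "vocal_segment")))
})

test_that("the 14 spectral features behave at their analytic limits", {
  sr <- 44100
  set.seed(4)
  t <- seq(0, 0.15, by = 1 / sr)
  # flat-spectrum noise -> spectral flatness near 1
  noise <- structure(list(samples = stats::rnorm(length(t)), sample_rate = sr,
                          onset_s = 0, offset_s = 0.15), class = "vocal_segment")
  fn <- compute_features14(noise)
  expect_gt(fn$spectral_flatness, 0.7)
  expect_gt(fn$entropy, 0.9)
  # pure tone: mean ~ median ~ peak ~ f
  tone <- structure(list(samples = sin(2 * pi * 2000 * t), sample_rate = sr,
                         onset_s = 0, offset_s = 0.15), class = "vocal_segment")
  ft <- compute_features14(tone)
  bin_hz <- sr / 512
  expect_lt(abs(ft$mean_freq - 2000), 2 * bin_hz)
  expect_lt(abs(ft$median_freq - 2000), bin_hz)
  expect_lt(abs(ft$peak_freq - 2000), bin_hz)
  expect_lt(abs(ft$mode_freq - 2000), bin_hz)
  expect_lt(ft$spectral_flatness, 0.05)
  expect_equal(ft$duration, 0.15, tolerance = 1e-12)
  expect_identical(ncol(ft), 14L)
  # symmetric two-tone spectrum at f +/- delta -> skew near 0; delta chosen
  # as an exact multiple of the bin width so leakage stays symmetric
  f0 <- 2000; delta <- 4 * bin_hz
  two <- structure(list(samples = sin(2 * pi * (f0 - delta) * t) +
                          sin(2 * pi * (f0 + delta) * t),
                        sample_rate = sr, onset_s = 0, offset_s = 0.15),
                   class = "vocal_segment")
  f2 <- compute_features14(two)
  expect_lt(abs(f2$skew), 0.3)
  expect_true(all(is.finite(as.numeric(f2))))
})

test_that("waveform amplitude scaling leaves spectral features unchanged", {
  p <- bird_profile("b", "M")
  seg <- generate_call_waveform(p, "stack", seed = 7L)
  seg2 <- seg
  seg2$samples <- seg$samples * 0.25
  f1 <- compute_features14(seg)
  f2 <- compute_features14(seg2)
  expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-9)
  s1 <- compute_sorting_features(seg)
  s2 <- compute_sorting_features(seg2)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-9)
})

test_that("features survive a WAV round trip", {
  p <- bird_profile("b", "M")
  seg <- generate_call_waveform(p, "kackle", seed = 8L)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(seg$samples, seg$sample_rate, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, seg$sample_rate)
  seg_rt <- seg
  seg_rt$samples <- back$samples
  f0 <- as.numeric(compute_features14(seg))
  f1 <- as.numeric(compute_features14(seg_rt))
  # 16-bit quantisation: features equal to within a relative tolerance
  expect_equal(f1, f0, tolerance = 1e-3)
})

test_that("k-means clustering separates planted structure and respects k", {
  # all identical vectors, k = 1: one cluster, no noise
  same <- data.frame(a = rep(1, 8), b = rep(2, 8))
  cl <- cluster_calls(same, k = 1, seed = 1L)
  expect_true(all(cl$cluster == "1"))
  expect_error(cluster_calls(same, k = 9, seed = 1L), "exceeds")
  # two clouds separated by 10 pooled SDs: partition identical to truth
  set.seed(13)
  two <- data.frame(a = c(stats::rnorm(40, 0), stats::rnorm(40, 10)),
                    b = c(stats::rnorm(40, 0), stats::rnorm(40, 10)))
  truth <- rep(c("A", "B"), each = 40)
  cl2 <- cluster_calls(two, k = 2, seed = 2L)
  expect_false(any(cl2$cluster == "NOISE"))
  expect_equal(adjusted_rand(cl2$cluster, truth), 1.0, tolerance = 1e-12)
  # label-permutation invariance: same partition under a different seed
  cl3 <- cluster_calls(two, k = 2, seed = 99L)
  expect_equal(adjusted_rand(cl2$cluster, cl3$cluster), 1.0, tolerance = 1e-12)
})

test_that("three planted call types are recovered from sorting features", {
  fx <- fixture_call_type_features(n_per_type = 8L, seed = 5L)
  cl <- cluster_calls(fx$features, k = 3, seed = 6L)
  ari <- adjusted_rand(cl$cluster, fx$truth)
  expect_gt(ari, 0.9)
  # agreement measured on partitions, and reproducible from the seed
  cl_b <- cluster_calls(fx$features, k = 3, seed = 6L)
  expect_identical(cl$cluster, cl_b$cluster)
  # manual edits override
  edit <- data.frame(segment_id = cl$segment_id[1], label = "manual")
  cl_e <- cluster_calls(fx$features, k = 3, seed = 6L, manual_edits = edit)
  expect_identical(cl_e$cluster[1], "manual")
})

test_that("partition agreement matches an established adjusted Rand implementation", {
  skip_if_not_installed("mclust")
  set.seed(77)
  for (i in 1:5) {
    a <- sample(letters[1:3], 40, TRUE)
    b <- sample(letters[1:4], 40, TRUE)
    expect_equal(partition_agreement(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})
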