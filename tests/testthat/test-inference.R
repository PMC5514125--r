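# reduced-scale simulated trial set with a configurable latency effect
simulate_latency_tables <- function(n_subjects = 6L, n_per_series = 40L,
                                    lat_means = c(m = 0.55, f = 0.67, uf = 0.67),
                                    sd = 0.2, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (fam in names(lat_means)) {
      lat <- rtruncnorm(n_per_series, lat_means[fam], sd, 0, 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = paste0("s", s), trial = "A", call_type = "stack",
        familiarity = fam, audience_id = paste0("aud", (s %% 3) + 1L),
        playback_order = fam, latency_s = lat, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("mixed-model estimates recover planted cell means on the sqrt scale", {
  tab <- simulate_latency_tables(seed = 101L)
  fit <- suppressWarnings(fit_mixed_model(tab, "sqrt_latency"))
  post <- simulate_posterior(fit, n_draws = 4000L, seed = 102L)
  truth_m <- truncnorm_expectation(sqrt, 0.55, 0.2)
  truth_uf <- truncnorm_expectation(sqrt, 0.67, 0.2)
  cells <- post$cells
  est_m <- cells$fitted[cells$familiarity == "m"]
  est_uf <- cells$fitted[cells$familiarity == "uf"]
  n_cell <- 6 * 40
  se <- stats::sd(sqrt(tab$latency_s)) / sqrt(n_cell)
  expect_lt(abs(est_m - truth_m), 3 * se)
  expect_lt(abs(est_uf - truth_uf), 3 * se)
  # CrI sanity: lower <= fitted <= upper
  expect_true(all(cells$lower <= cells$fitted & cells$fitted <= cells$upper))
})

test_that("a constant response yields null contrasts and zero variance", {
  tab <- simulate_latency_tables(seed = 5L)
  tab$latency_s <- 0.49
  fit <- suppressWarnings(fit_mixed_model(tab, "sqrt_latency"))
  post <- simulate_posterior(fit, n_draws = 1000L, seed = 6L)
  expect_lt(max(post$cells$fitted) - min(post$cells$fitted), 1e-10)
  fc <- familiarity_contrasts(post)
  expect_true(all(abs(fc$diff_fitted) < 1e-10))
})

test_that("posterior draws are seed-stable and centred on the estimates", {
  tab <- simulate_latency_tables(seed = 7L)
  fit <- suppressWarnings(fit_mixed_model(tab, "sqrt_latency"))
  p1 <- simulate_posterior(fit, n_draws = 3000L, seed = 8L)
  p2 <- simulate_posterior(fit, n_draws = 3000L, seed = 8L)
  expect_identical(p1$draws, p2$draws)
  mc_se <- apply(p1$draws, 2, stats::sd) / sqrt(3000)
  expect_true(all(abs(colMeans(p1$draws) - p1$cells$fitted) < 4 * mc_se))
})

test_that("exceedance comparison obeys the tie rule and symmetry", {
  x <- stats::rnorm(1000)
  expect_equal(compare_cells(x, x)$p, 0.5, tolerance = 1e-12)
  expect_equal(compare_cells(1:100, 101:200)$p, 0)
  expect_true(compare_cells(1:100, 101:200)$significant)
  set.seed(3)
  a <- stats::rnorm(10000)
  b <- stats::rnorm(10000)
  pab <- compare_cells(a, b)$p
  expect_lt(abs(pab - 0.5), 0.02)
  expect_equal(pab + compare_cells(b, a)$p, 1.0, tolerance = 1e-12)
})

test_that("sqrt-scale analysis preserves cell ordering under data scaling", {
  tab <- simulate_latency_tables(seed = 21L)
  fit1 <- suppressWarnings(fit_mixed_model(tab, "sqrt_latency"))
  post1 <- simulate_posterior(fit1, 1000L, seed = 22L)
  tab2 <- tab
  tab2$latency_s <- tab$latency_s * 4
  fit2 <- suppressWarnings(fit_mixed_model(tab2, "sqrt_latency"))
  post2 <- simulate_posterior(fit2, 1000L, seed = 22L)
  expect_equal(post2$cells$fitted, post1$cells$fitted * 2, tolerance = 1e-6)
  expect_identical(order(post1$cells$fitted), order(post2$cells$fitted))
})

test_that("habituation test flags planted decline but not stationary calling", {
  set.seed(31)
  subjects <- paste0("s", 1:6)
  # stationary: Poisson counts, same rate in every bin
  stat_tab <- expand.grid(subject_id = subjects, bin = 1:18)
  stat_tab$count <- stats::rpois(nrow(stat_tab), 50)
  h0 <- habituation_test(stat_tab, n_draws = 2000L, seed = 32L)
  expect_false(h0$significant)
  # planted monotone decline: rate halves across bins
  dec_tab <- expand.grid(subject_id = subjects, bin = 1:18)
  dec_tab$count <- stats::rpois(nrow(dec_tab), 60 - 2 * dec_tab$bin)
  h1 <- habituation_test(dec_tab, n_draws = 2000L, seed = 33L)
  expect_true(h1$significant)
  expect_gt(h1$first_fitted, h1$last_fitted)
  # single subject, constant counts -> p = 0.5 (ties)
  const_tab <- data.frame(subject_id = "s1", bin = 1:10, count = 7)
  hc <- habituation_test(const_tab, n_draws = 500L, seed = 34L)
  expect_equal(hc$p_first_vs_last, 0.5, tolerance = 1e-12)
  expect_error(habituation_test(data.frame(subject_id = "s", bin = 1, count = 2)),
               "bins")
})

test_that("composition test enforces the 8-non-null rule and matches ranks", {
  vals <- c(stats::runif(7))
  out <- answer_type_composition_test(vals, rep(c("m", "f", "uf"), length.out = 7))
  expect_true(out$skipped)
  # hand-ranked oracle on a small table
  v <- c(1, 2, 3, 4, 10, 11, 12, 13, 20, 21, 22, 23)
  g <- rep(c("m", "f", "uf"), each = 4)
  got <- answer_type_composition_test(v, g)
  expect_false(got$skipped)
  want <- stats::kruskal.test(v, factor(g))
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  ranks <- rank(v)
  n <- length(v)
  H <- 12 / (n * (n + 1)) * sum(tapply(ranks, g, function(r) length(r) * mean(r)^2)) -
    3 * (n + 1)
  expect_equal(got$statistic, H, tolerance = 1e-9)
})

test_that("baseline-playback correlation recovers planted slopes", {
  # identical vectors -> correlation 1
  x <- c(0.2, 0.4, 0.5, 0.7, 0.8, 0.9)
  out <- baseline_playback_correlation(x, x, n_draws = 1000L, seed = 41L)
  expect_equal(out$correlation, 1.0, tolerance = 1e-12)
  expect_error(baseline_playback_correlation(1:2, 1:2), ">= 3")
  # planted slope -0.5 over replicated draws: mean estimate within 3 SEs
  set.seed(42)
  n_reps <- 200L
  slopes <- vapply(seq_len(n_reps), function(i) {
    b <- stats::runif(6, 0.2, 0.9)
    p <- 0.8 - 0.5 * b + stats::rnorm(6, 0, 0.05)
    baseline_playback_correlation(b, p, n_draws = 200L, seed = i)$slope
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(n_reps)
  expect_lt(abs(mean(slopes) - (-0.5)), 3 * se)
  # planted zero relationship: CrI covers 0 about 95% of the time
  covered <- vapply(seq_len(n_reps), function(i) {
    set.seed(1000 + i)
    b <- stats::runif(8, 0.2, 0.9)
    p <- 0.5 + stats::rnorm(8, 0, 0.1)
    out <- baseline_playback_correlation(b, p, n_draws = 400L, seed = i)
    out$lower <= 0 && 0 <= out$upper
  }, logical(1))
  expect_gt(mean(covered), 0.85)
})

test_that("series truncation keeps contrast signs for stationary responses", {
  m <- exchange_model()
  trials <- lapply(1:3, function(s) {
    sch <- build_schedule("M", seed = 600L + s)
    ev <- generate_playback_responses(sch, m, seed = 700L + s, sex = "M")
    list(schedule = sch, events = ev, subject_id = paste0("s", s),
         trial = "A", audience_id = paste0("aud", s))
  })
  out <- suppressWarnings(
    subset_robustness(trials, response = "sqrt_count", n_draws = 500L, seed = 1L))
  expect_gte(out$agreement, 0.9)
  full <- out$contrasts[out$contrasts$variant == "full", ]
  expect_true(all(full$sign_agrees_full))
  # subset equal to series length reproduces the full analysis exactly
  short <- lapply(trials, function(tr) tr)
  out2 <- suppressWarnings(
    subset_robustness(short, response = "sqrt_count", n_first = 300L,
                      n_last = 300L, n_draws = 200L, seed = 2L))
  f <- out2$contrasts
  expect_equal(f$diff_fitted[f$variant == "first"],
               f$diff_fitted[f$variant == "full"], tolerance = 1e-9)
})
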