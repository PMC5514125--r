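# O(n^2) brute-force oracle: each responder event answers the nearest
# preceding trigger if within the window
brute_force_answers <- function(trigger, responder, window_s = 0.5) {
  out <- NULL
  for (j in seq_along(responder$onset_s)) {
    best <- NA_integer_
    for (i in seq_along(trigger$onset_s)) {
      lag <- responder$onset_s[j] - trigger$onset_s[i]
      if (lag > 0 && lag <= window_s) {
        if (is.na(best) || trigger$onset_s[i] > trigger$onset_s[best]) best <- i
      }
    }
    if (!is.na(best)) {
      out <- rbind(out, data.frame(trigger_idx = best, responder_idx = j))
    }
  }
  out
}

test_that("answer detection matches the brute-force oracle on random streams", {
  set.seed(42)
  trig <- data.frame(onset_s = sort(stats::runif(200, 0, 500)))
  resp <- data.frame(onset_s = sort(stats::runif(200, 0, 500)),
                     call_type = sample(c("stack", "tet"), 200, TRUE))
  got <- detect_answers(trig, resp, window_s = 0.5)
  want <- brute_force_answers(trig, resp, window_s = 0.5)
  expect_identical(got$trigger_idx, want$trigger_idx)
  expect_identical(got$responder_idx, want$responder_idx)
  # each responder answers at most one trigger; count bounded
  expect_false(any(duplicated(got$responder_idx)))
  expect_lte(nrow(got), nrow(resp))
})

test_that("answer windows are open at zero and closed at the boundary", {
  trig <- data.frame(onset_s = 10)
  expect_identical(nrow(detect_answers(trig, data.frame(onset_s = 10.3))), 1L)
  expect_identical(nrow(detect_answers(trig, data.frame(onset_s = 10.6))), 0L)
  expect_identical(nrow(detect_answers(trig, data.frame(onset_s = 10.5))), 1L)
  expect_identical(nrow(detect_answers(trig, data.frame(onset_s = 10.0))), 0L)
  expect_error(detect_answers(data.frame(onset_s = c(5, 1)),
                              data.frame(onset_s = 2)), "sorted")
})

test_that("answer detection is invariant to a common time shift", {
  set.seed(7)
  trig <- data.frame(onset_s = sort(stats::runif(100, 0, 200)))
  resp <- data.frame(onset_s = sort(stats::runif(100, 0, 200)))
  a <- detect_answers(trig, resp)
  trig2 <- data.frame(onset_s = trig$onset_s + 1234.5)
  resp2 <- data.frame(onset_s = resp$onset_s + 1234.5)
  b <- detect_answers(trig2, resp2)
  expect_identical(a$trigger_idx, b$trigger_idx)
  expect_equal(a$latency_s, b$latency_s, tolerance = 1e-9)
})

test_that("first-answer latency picks the earliest in-window response", {
  resp <- data.frame(onset_s = c(10.4, 10.9))
  expect_equal(first_answer_latency(10, resp), 0.4, tolerance = 1e-12)
  expect_true(is.na(first_answer_latency(8, resp)))
  # brute-force scan over random streams
  set.seed(8)
  em <- sort(stats::runif(150, 0, 300))
  resp <- data.frame(onset_s = sort(stats::runif(150, 0, 300)))
  got <- first_answer_latency(em, resp)
  want <- vapply(em, function(e) {
    lags <- resp$onset_s - e
    lags <- lags[lags > 0 & lags <= 1.5]
    if (length(lags)) min(lags) else NA_real_
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("series response tables have one row per series with planted counts", {
  m <- exchange_model(answer_prob = c(m = 0.5, f = 0.2, uf = 0.2),
                      answer_latency_mean = c(m = 0.3, f = 0.3, uf = 0.3),
                      answer_latency_sd = 0.1)
  sch <- build_schedule("M", seed = 51L)
  ev <- generate_playback_responses(sch, m, seed = 52L, sex = "M")
  br <- build_series_responses(sch, ev, subject_id = "s1", trial = "A")
  expect_identical(nrow(br$series), 15L)
  expect_identical(sort(unique(br$series$playback_order)), 1:15)
  # planted expectation: p_answer x P(latency <= 0.5)
  p_win <- (stats::pnorm(0.5, 0.3, 0.1) - stats::pnorm(0, 0.3, 0.1)) /
    (stats::pnorm(1.5, 0.3, 0.1) - stats::pnorm(0, 0.3, 0.1))
  for (fam in c("m", "f", "uf")) {
    p <- c(m = 0.5, f = 0.2, uf = 0.2)[fam] * p_win
    counts <- br$series$n_answers[br$series$familiarity == fam]
    expect_lt(abs(mean(counts) - 300 * p), 3 * sqrt(300 * p * (1 - p)))
  }
  # empty responder stream -> all zero
  br0 <- build_series_responses(sch, data.frame(bird_id = character(),
                                                call_type = character(),
                                                onset_s = numeric(),
                                                offset_s = numeric()))
  expect_true(all(br0$series$n_answers == 0L))
  expect_identical(nrow(br0$latencies), 0L)
  # clock mismatch warning
  bad <- data.frame(bird_id = "x", call_type = "stack",
                    onset_s = -5, offset_s = -4.9)
  expect_warning(build_series_responses(sch, bad), "precede")
})

test_that("answer-type proportions respect the 5-answer threshold", {
  few <- data.frame(responder_call_type = rep("stack", 4))
  out <- suppressMessages(answer_type_proportions(few))
  expect_null(out)
  all_stack <- data.frame(responder_call_type = rep("stack", 10))
  expect_equal(answer_type_proportions(all_stack), c(stack = 1.0))
  mixed <- data.frame(responder_call_type = c(rep("stack", 6), rep("distance", 4)))
  p <- answer_type_proportions(mixed)
  expect_equal(unname(p[c("stack", "distance")]), c(0.6, 0.4))
  expect_equal(sum(p), 1.0, tolerance = 1e-12)
})

test_that("500-s bins conserve in-span event counts", {
  expect_identical(bin_call_counts(c(10, 600), session_span = 1000), c(1L, 1L))
  expect_identical(bin_call_counts(numeric(0), session_span = 1500), c(0L, 0L, 0L))
  set.seed(10)
  ev <- stats::runif(2000, 0, 9000)
  counts <- bin_call_counts(ev, bin_s = 500, session_span = 9000)
  expect_identical(sum(counts), 2000L)
  # Poisson stream at 0.2/s: mean bin count near 100
  lam <- 0.2
  n <- stats::rpois(1, lam * 9000)
  ev2 <- stats::runif(n, 0, 9000)
  counts2 <- bin_call_counts(ev2, bin_s = 500, session_span = 9000)
  expect_lt(abs(mean(counts2) - 100), 3 * sqrt(100 / length(counts2)))
})

test_that("repeatability matches a hand-computed one-way ANOVA", {
  vals <- c(1, 2, 5, 6, 9, 10)
  grp <- rep(c("p1", "p2", "p3"), each = 2)
  r <- repeatability_index(vals, grp)
  # hand ANOVA: group means 1.5/5.5/9.5, SSA = 64, SSW = 1.5
  expect_equal(r$MSA, 32, tolerance = 1e-12)
  expect_equal(r$MSW, 0.5, tolerance = 1e-12)
  expect_equal(r$F, 64, tolerance = 1e-12)
  expect_equal(r$r, 31.5 / 32.5, tolerance = 1e-12)
  # cross-check against aov mean squares
  av <- summary(stats::aov(vals ~ factor(grp)))[[1]]
  expect_equal(r$MSA, av$`Mean Sq`[1], tolerance = 1e-9)
  expect_equal(r$MSW, av$`Mean Sq`[2], tolerance = 1e-9)
  # zero within-group variance -> r = 1; equal means -> r ~ 0
  expect_equal(repeatability_index(c(1, 1, 5, 5), c("a", "a", "b", "b"))$r, 1)
  r0 <- repeatability_index(c(1, 3, 1, 3, 2, 2), rep(c("a", "b", "c"), each = 2))
  expect_lt(r0$r, 0.5)
  expect_error(repeatability_index(rep(2, 6), rep(c("a", "b", "c"), each = 2)),
               "degenerate")
})

test_that("repeatability rises with between-group variance", {
  set.seed(3)
  within <- stats::rnorm(30, 0, 1)
  grp <- rep(1:5, each = 6)
  rs <- vapply(c(0.5, 2, 8), function(spread) {
    vals <- within + rep(seq(-spread, spread, length.out = 5), each = 6)
    repeatability_index(vals, grp)$r
  }, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("baseline exchange summaries apply the 3-call combination filter", {
  caller <- data.frame(bird_id = "c", call_type = c(rep("stack", 5), "hat"),
                       onset_s = c(1, 3, 5, 7, 9, 11), offset_s = c(1, 3, 5, 7, 9, 11) + 0.1)
  resp <- data.frame(bird_id = "r", call_type = rep("stack", 3),
                     onset_s = c(1.2, 3.3, 9.4), offset_s = c(1.3, 3.4, 9.5))
  summ <- exchange_answer_summary(caller, resp)
  expect_false("hat" %in% summ$caller_type)  # only 1 hat call: filtered
  row <- summ[summ$caller_type == "stack" & summ$responder_type == "stack", ]
  expect_identical(row$n_answers, 3L)
  expect_equal(row$proportion, 3 / 5, tolerance = 1e-12)
})
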