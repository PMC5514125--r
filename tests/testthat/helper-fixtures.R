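# Shared fixture builders; everything is generated in code at test time.

# a pair of profiles with distinct individual offsets
fixture_pair <- function() {
  list(bird_profile("male1", "M", f0_offset_hz = 0),
       bird_profile("female1", "F", f0_offset_hz = 60))
}

# features for three planted call types, k exemplars each: distinct
# fundamentals and durations, modest noise so clusters are well separated
fixture_call_type_features <- function(n_per_type = 10L, seed = 1L) {
  profile <- bird_profile("clusterbird", "M")
  types <- c("stack", "kackle", "hat")
  feats <- list()
  truth <- character(0)
  i <- 0L
  for (ct in types) {
    for (r in seq_len(n_per_type)) {
      i <- i + 1L
      seg <- generate_call_waveform(profile, ct, seed = seed * 1000L + i)
      feats[[i]] <- compute_sorting_features(seg)
      truth[i] <- ct
    }
  }
  list(features = do.call(rbind, feats), truth = truth)
}

# partition agreement (adjusted Rand); small closed-form implementation so
# tests do not depend on a clustering package for the primary check
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# quick single-subject playback trial at reduced scale for pipeline tests
fixture_small_trial <- function(seed = 1L, n_repeats = 10L, sex = "M",
                                model = exchange_model()) {
  sch <- build_schedule(sex, seed = seed, n_repeats = n_repeats)
  ev <- generate_playback_responses(sch, model, seed = seed + 1L, sex = sex)
  list(schedule = sch, events = ev)
}
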