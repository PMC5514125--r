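#' Type-I error calibration of the exceedance rule
#'
#' Simulates playback trials with no familiarity effect planted (equal
#' answer probability and latency distribution across mate, familiar and
#' unfamiliar series), runs the scoring + mixed-model + posterior
#' simulation pipeline on each replicate, and applies the directional
#' exceedance rule (mate cell declared faster when p < alpha) to the
#' mate-versus-familiar latency contrast. Under the null the rejection
#' rate should sit at the nominal level.
#'
#' Replicates use a reduced trial (10 repeats per exemplar, one subject)
#' so that many replicates fit in a short run; the rule under test is
#' identical to the full-scale analysis.
#'
#' @param n_reps Number of simulated replicates.
#' @param seed Integer master seed.
#' @param n_draws Posterior draws per replicate.
#' @param alpha Nominal level of the directional rule.
#' @param n_repeats Repeats per exemplar in the reduced schedule.
#' @return List with `rejection_rate`, `n_reps`, `alpha`.
#' @export
null_calibration_study <- function(n_reps = 500L, seed = 1L,
                                   n_draws = 4000L, alpha = 0.05,
                                   n_repeats = 10L) {
  sch <- build_schedule("M", seed = split_seed(seed, "null/schedule"),
                        n_repeats = n_repeats)
  m0 <- exchange_model(answer_prob = 0.5,
                       answer_latency_mean = c(m = 0.6, f = 0.6, uf = 0.6),
                       answer_latency_sd = 0.2)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    ev <- generate_playback_responses(sch, m0,
                                      seed = split_seed(seed, paste0("null/", r)))
    br <- build_series_responses(sch, ev)
    fit <- suppressMessages(suppressWarnings(
      fit_mixed_model(br$latencies, "sqrt_latency", fixed = "familiarity")))
    post <- simulate_posterior(fit, n_draws = n_draws,
                               seed = split_seed(seed, paste0("null/post/", r)))
    i_m <- which(post$cells$familiarity == "m")
    i_f <- which(post$cells$familiarity == "f")
    rej[r] <- compare_cells(post$draws[, i_m], post$draws[, i_f],
                            alpha = alpha)$p < alpha
  }
  list(rejection_rate = mean(rej), n_reps = n_reps, alpha = alpha)
}

#' Power and bias for a planted familiarity latency difference
#'
#' Simulates full-length playback series (300 emissions per series, one
#' call-type block, three familiarity series) for several subjects with
#' the generator's planted latency means (default: mate 0.55 s versus
#' non-mate 0.67 s, a 0.12 s difference), fits the latency mixed model
#' with a subject random intercept per replicate, and records (a) whether
#' the mate-versus-unfamiliar contrast is flagged by the directional
#' exceedance rule, and (b) the estimated cell-mean difference on the
#' square-root scale. The generative truth on that scale is the
#' truncated-normal expectation computed by numerical integration.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer master seed.
#' @param n_subjects Subjects per replicate.
#' @param n_draws Posterior draws per replicate.
#' @param model An [exchange_model()] carrying the planted effect.
#' @param alpha Level of the directional rule.
#' @return List with `power`, `estimates` (per-rep sqrt-scale differences),
#'   `truth_sqrt` (generative difference on the sqrt scale),
#'   `truth_latency_s` (difference of truncated-normal means in seconds),
#'   `mean_latency_diff_s` (mean recovered difference in seconds).
#' @export
latency_recovery_study <- function(n_reps = 200L, seed = 1L,
                                   n_subjects = 6L, n_draws = 2000L,
                                   model = exchange_model(), alpha = 0.05) {
  sch_full <- build_schedule("M", seed = split_seed(seed, "rec/schedule"),
                             n_repeats = 100L)
  sch <- sch_full[sch_full$call_type == "stack", ]
  mu <- model$answer_latency_mean
  sdv <- model$answer_latency_sd
  lb <- model$latency_bounds
  truth_sqrt <- truncnorm_expectation(sqrt, mu[["uf"]], sdv, lb[1], lb[2]) -
    truncnorm_expectation(sqrt, mu[["m"]], sdv, lb[1], lb[2])
  truth_lat <- truncnorm_expectation(identity, mu[["uf"]], sdv, lb[1], lb[2]) -
    truncnorm_expectation(identity, mu[["m"]], sdv, lb[1], lb[2])
  sig <- logical(n_reps)
  est <- numeric(n_reps)
  est_lat <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tabs <- lapply(seq_len(n_subjects), function(s) {
      ev <- generate_playback_responses(
        sch, model, seed = split_seed(seed, paste0("rec/", r, "/", s)))
      build_series_responses(sch, ev,
                             subject_id = paste0("s", s))$latencies
    })
    tab <- do.call(rbind, tabs)
    fit <- suppressMessages(suppressWarnings(
      fit_mixed_model(tab, "sqrt_latency", fixed = "familiarity",
                      random = "subject_id")))
    post <- simulate_posterior(fit, n_draws = n_draws,
                               seed = split_seed(seed, paste0("rec/post/", r)))
    i_m <- which(post$cells$familiarity == "m")
    i_uf <- which(post$cells$familiarity == "uf")
    sig[r] <- compare_cells(post$draws[, i_m], post$draws[, i_uf],
                            alpha = alpha)$p < alpha
    est[r] <- post$cells$fitted[i_uf] - post$cells$fitted[i_m]
    raw_means <- tapply(tab$latency_s, tab$familiarity, mean)
    est_lat[r] <- raw_means[["uf"]] - raw_means[["m"]]
  }
  list(power = mean(sig), estimates = est, truth_sqrt = truth_sqrt,
       truth_latency_s = truth_lat, mean_latency_diff_s = mean(est_lat))
}

#' Recovery of planted call types by feature clustering
#'
#' Generates synthetic calls of three types (distinct fundamentals,
#' harmonic counts and durations), extracts the sorting features and
#' clusters with k-means (k = 3), and scores the partition against the
#' generating labels with the adjusted Rand index, replicated across
#' seeds.
#'
#' @param n_reps Replicates.
#' @param seed Integer master seed.
#' @param n_per_type Exemplars per call type per replicate.
#' @return List with `mean_ari` and the per-rep `ari` vector.
#' @export
clustering_recovery_study <- function(n_reps = 20L, seed = 1L,
                                      n_per_type = 8L) {
  profile <- bird_profile("clusterbird", "M")
  types <- c("stack", "kackle", "hat")
  ari <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    feats <- list()
    truth <- character(0)
    i <- 0L
    for (ct in types) {
      for (k in seq_len(n_per_type)) {
        i <- i + 1L
        seg <- generate_call_waveform(
          profile, ct, seed = split_seed(seed, paste0("clust/", r, "/", i)))
        feats[[i]] <- compute_sorting_features(seg)
        truth[i] <- ct
      }
    }
    cl <- cluster_calls(do.call(rbind, feats), k = 3,
                        seed = split_seed(seed, paste0("clust/seed/", r)))
    ari[r] <- partition_agreement(cl$cluster, truth)
  }
  list(mean_ari = mean(ari), ari = ari)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 at chance.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar adjusted Rand index.
#' @export
partition_agreement <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_i * sum_j / n
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

#' Misassignment of the distinctiveness index at its two extremes
#'
#' Runs the PCA-LDA distinctiveness pipeline on synthetic stimulus
#' features in two regimes: (a) three caller identities with identical
#' call distributions (waveforms generated from one profile), where
#' misassignment should sit at the 2/3 chance level, and (b) three
#' identities with strongly separated fundamentals, where misassignment
#' should vanish.
#'
#' @param seed Integer master seed.
#' @param n_per_id Stimuli per identity in the indistinguishable regime
#'   (pooled large so resubstitution optimism stays small).
#' @return List with `chance_misassignment`, `separated_misassignment`,
#'   `n_chance` (stimuli in the chance regime).
#' @export
chance_misassignment_study <- function(seed = 1L, n_per_id = 30L) {
  # (a) identical distributions: same profile, different noise draws
  profile <- bird_profile("samebird", "M")
  ids <- rep(c("m", "f", "uf"), each = n_per_id)
  feats <- lapply(seq_along(ids), function(i) {
    seg <- generate_call_waveform(profile, "stack",
                                  seed = split_seed(seed, paste0("chance/", i)))
    compute_features14(seg)
  })
  chance_res <- distinctiveness_index(do.call(rbind, feats), ids)
  # (b) separated: distinct fundamentals per identity, 3 exemplars each
  offsets <- c(m = 0, f = 300, uf = 600)
  feats2 <- list()
  ids2 <- character(0)
  i <- 0L
  for (id in names(offsets)) {
    prof <- bird_profile(paste0("bird_", id), "M", f0_offset_hz = offsets[[id]])
    for (k in 1:3) {
      i <- i + 1L
      seg <- generate_call_waveform(
        prof, "stack", seed = split_seed(seed, paste0("sep/", id, "/", k)))
      feats2[[i]] <- compute_features14(seg)
      ids2[i] <- id
    }
  }
  sep_res <- distinctiveness_index(do.call(rbind, feats2), ids2)
  list(chance_misassignment = chance_res$proportion_incorrect,
       separated_misassignment = sep_res$proportion_incorrect,
       n_chance = length(ids))
}
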