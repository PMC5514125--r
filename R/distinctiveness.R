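#' Individual distinctiveness of a call type via PCA and LDA
#'
#' For one focal bird and call type, the stimulus set comprises 9 calls: 3
#' exemplars from each of the 3 caller identities (the mate, a familiar and
#' an unfamiliar bird). The 14 spectral features are standardised, reduced
#' by PCA (correlation-based, since units mix Hz, seconds and unitless
#' measures), and the first two principal components feed a linear
#' discriminant analysis on caller identity. The fitted discriminant then
#' predicts the training calls themselves (resubstitution; leave-one-out
#' available behind a flag) and the proportion of incorrect assignments is
#' the (inverse) distinctiveness index: low misassignment means highly
#' individually distinct calls.
#'
#' @param features Data.frame of numeric spectral features, one row per
#'   stimulus call (e.g. rows of [compute_features14()]).
#' @param identity Caller identity label per row (>= 3 identities, >= 2
#'   calls each).
#' @param n_components Number of leading principal components for the LDA.
#' @param method `"resubstitution"` or `"leave_one_out"`.
#' @return List with `proportion_incorrect`, `confusion` (table),
#'   `predicted`, `pca` (the `prcomp` object) and `lda` (the `lda` fit;
#'   `NULL` under leave-one-out).
#' @export
distinctiveness_index <- function(features, identity,
                                  n_components = 2L,
                                  method = c("resubstitution", "leave_one_out")) {
  method <- match.arg(method)
  identity <- factor(identity)
  x <- as.matrix(features[, vapply(features, is.numeric, logical(1)), drop = FALSE])
  stopifnot(nrow(x) == length(identity))
  if (nlevels(identity) < 3L) stop("need >= 3 identities")
  if (any(table(identity) < 2L)) stop("need >= 2 stimuli per identity")
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!any(keep)) stop("degenerate features: zero variance in every column")
  pca <- stats::prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  nc <- min(n_components, ncol(pca$x))
  pcs <- as.data.frame(pca$x[, seq_len(nc), drop = FALSE])
  if (method == "resubstitution") {
    fit <- MASS::lda(pcs, grouping = identity)
    pred <- stats::predict(fit, pcs)$class
  } else {
    fit <- NULL
    pred <- MASS::lda(pcs, grouping = identity, CV = TRUE)$class
  }
  confusion <- table(truth = identity, predicted = pred)
  list(proportion_incorrect = mean(pred != identity),
       confusion = confusion, predicted = pred, pca = pca, lda = fit)
}

#' Distinctiveness summary across birds
#'
#' Applies [distinctiveness_index()] per (focal bird, call type) and
#' reports the per-combination misassignment proportion plus the
#' across-bird mean and SD per call type.
#'
#' @param features Data.frame of numeric features plus columns
#'   `focal_bird`, `call_type`, `identity`.
#' @param ... Passed to [distinctiveness_index()].
#' @return List with `per_bird` (focal_bird, call_type,
#'   `proportion_incorrect`) and `summary` (call_type, `mean_incorrect`,
#'   `sd_incorrect`).
#' @export
distinctiveness_by_bird <- function(features, ...) {
  stopifnot(all(c("focal_bird", "call_type", "identity") %in% names(features)))
  meta <- c("focal_bird", "call_type", "identity")
  groups <- unique(features[, c("focal_bird", "call_type")])
  per <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- features[features$focal_bird == groups$focal_bird[i] &
                      features$call_type == groups$call_type[i], ]
    res <- distinctiveness_index(sub[, setdiff(names(sub), meta)],
                                 sub$identity, ...)
    data.frame(focal_bird = groups$focal_bird[i],
               call_type = groups$call_type[i],
               proportion_incorrect = res$proportion_incorrect,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  summ <- do.call(rbind, lapply(split(per, per$call_type), function(d) {
    data.frame(call_type = d$call_type[1],
               mean_incorrect = mean(d$proportion_incorrect),
               sd_incorrect = stats::sd(d$proportion_incorrect),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_bird = per, summary = summ)
}

#' Response magnitudes per bird and call type
#'
#' Magnitude of the response to the conspecific: response to the mate
#' minus response to the familiar (or unfamiliar) bird, as a difference in
#' answer counts and in mean first-answer latency (latencies averaged per
#' individual before differencing).
#'
#' @param series Series table from [build_series_responses()] (rows for
#'   one subject/trial set, columns `subject_id`, `call_type`,
#'   `familiarity`, `n_answers`).
#' @param latencies Matching long latency table (`latency_s`).
#' @return Data.frame with `subject_id`, `call_type`, `contrast`
#'   (`"m-f"`/`"m-uf"`), `delta_count`, `delta_latency`.
#' @export
response_magnitudes <- function(series, latencies) {
  keys <- unique(series[, c("subject_id", "call_type")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    sid <- keys$subject_id[i]; ct <- keys$call_type[i]
    ss <- series[series$subject_id == sid & series$call_type == ct, ]
    ll <- latencies[latencies$subject_id == sid & latencies$call_type == ct, ]
    cnt <- tapply(ss$n_answers, ss$familiarity, sum)
    lat <- tapply(ll$latency_s, ll$familiarity, mean)
    for (other in c("f", "uf")) {
      if (!all(c("m", other) %in% names(cnt))) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, call_type = ct, contrast = paste0("m-", other),
        delta_count = unname(cnt["m"] - cnt[other]),
        delta_latency = unname(lat["m"] - lat[other]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relate response magnitude to individual distinctiveness
#'
#' Mixed model of the response magnitude (count or latency difference) on
#' the per-(bird, call type) misassignment proportion, with a subject
#' random intercept (plain linear model when only one subject); the slope
#' is summarised by a posterior-simulation credible interval and
#' exceedance probability against zero.
#'
#' @param distinctiveness `per_bird` table from [distinctiveness_by_bird()]
#'   (columns `focal_bird`, `call_type`, `proportion_incorrect`).
#' @param magnitudes Table from [response_magnitudes()]; matched on
#'   (`subject_id` = `focal_bird`, `call_type`).
#' @param magnitude_col `"delta_count"` or `"delta_latency"`.
#' @param n_draws Posterior draws.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return List with `slope`, `lower`, `upper`, `p_slope_gt0`,
#'   `significant`, `n`, and the fitted `model`.
#' @export
relate_distinctiveness_to_response <- function(distinctiveness, magnitudes,
                                               magnitude_col = "delta_count",
                                               n_draws = 10000L, seed = 1L,
                                               alpha = 0.05) {
  d <- merge(magnitudes, distinctiveness,
             by.x = c("subject_id", "call_type"),
             by.y = c("focal_bird", "call_type"))
  if (length(unique(d$call_type)) < 3L) stop("need >= 3 call types")
  d$.y <- d[[magnitude_col]]
  d$.x <- d$proportion_incorrect
  if (length(unique(d$subject_id)) >= 2L) {
    model <- suppressMessages(
      lme4::lmer(.y ~ .x + (1 | subject_id), data = d, REML = FALSE))
  } else {
    model <- stats::lm(.y ~ .x, data = d)
  }
  bv <- fixef_vcov(model)
  beta <- bv$beta
  V <- bv$V
  set.seed(split_seed(seed, "distinctiveness/slope"))
  B <- MASS::mvrnorm(n_draws, mu = beta, Sigma = V)
  slope_draws <- B[, 2]
  p <- mean(slope_draws > 0) + 0.5 * mean(slope_draws == 0)
  ci <- stats::quantile(slope_draws, c(0.025, 0.975), names = FALSE)
  list(slope = unname(beta[2]), lower = ci[1], upper = ci[2],
       p_slope_gt0 = p, significant = p < alpha || p > 1 - alpha,
       n = nrow(d), model = model)
}
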