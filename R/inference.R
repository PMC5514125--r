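#' Fit the playback response mixed model
#'
#' Linear mixed-effect model of a square-root-transformed response
#' (first-answer latency or per-series answer count) on familiarity x
#' call type x trial with all interactions as fixed effects, and random
#' intercepts for subject identity, audience identity and playback order.
#' Fitted by maximum likelihood (interest is in the fixed effects). Fixed
#' factors with fewer than two observed levels are dropped from the
#' formula (reduced designs); likewise random factors with fewer than two
#' levels. If no random factor survives, an `lm` fit is returned inside
#' the same wrapper. The random-effect structure follows the study design
#' and is retained even when a variance component estimates to zero; a
#' singular fit raises a warning carrying the variance components.
#'
#' @param table Data.frame: the long latency table (`latency_s`) for
#'   `"sqrt_latency"`, or the series table (`n_answers`) for
#'   `"sqrt_count"`, both from [build_series_responses()].
#' @param response `"sqrt_latency"` or `"sqrt_count"`.
#' @param fixed Candidate fixed factors, in order.
#' @param random Candidate random-intercept factors.
#' @return Object of class `fp_fit`: list with `model` (lmerMod or lm),
#'   `fixed` (factors used), `response`, `data` and `diagnostics`
#'   (residual normality and heteroscedasticity summaries).
#' @export
fit_mixed_model <- function(table,
                            response = c("sqrt_latency", "sqrt_count"),
                            fixed = c("familiarity", "call_type", "trial"),
                            random = c("subject_id", "audience_id",
                                       "playback_order")) {
  response <- match.arg(response)
  ycol <- if (response == "sqrt_latency") "latency_s" else "n_answers"
  stopifnot(ycol %in% names(table))
  dat <- as.data.frame(table)
  dat$.y <- sqrt(dat[[ycol]])
  fixed <- fixed[fixed %in% names(dat)]
  fixed <- fixed[vapply(fixed, function(f) length(unique(dat[[f]])) >= 2L,
                        logical(1))]
  random <- random[random %in% names(dat)]
  random <- random[vapply(random, function(f) length(unique(dat[[f]])) >= 2L,
                          logical(1))]
  for (f in c(fixed, random)) dat[[f]] <- factor(dat[[f]])
  fix_part <- if (length(fixed)) paste(fixed, collapse = " * ") else "1"
  if (length(random)) {
    ran_part <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    form <- stats::as.formula(paste(".y ~", fix_part, "+", ran_part))
    model <- lme4::lmer(form, data = dat, REML = FALSE)
    if (lme4::isSingular(model)) {
      vc <- lme4::VarCorr(model)
      warning("singular fit; variance components:\n",
              paste(utils::capture.output(print(vc)), collapse = "\n"))
    }
    res <- stats::residuals(model)
    fitted_vals <- stats::fitted(model)
  } else {
    form <- stats::as.formula(paste(".y ~", fix_part))
    model <- stats::lm(form, data = dat)
    res <- stats::residuals(model)
    fitted_vals <- stats::fitted(model)
  }
  diagnostics <- list(
    shapiro_p = if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
      stats::shapiro.test(res)$p.value else NA_real_,
    abs_resid_fitted_cor = if (stats::sd(res) > 0 && stats::sd(fitted_vals) > 0)
      stats::cor(abs(res), fitted_vals) else NA_real_)
  structure(list(model = model, fixed = fixed, response = response,
                 data = dat, formula = form, diagnostics = diagnostics),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("<fp_fit>", x$response, "~", deparse(x$formula[[3]]), "\n")
  print(x$model)
  invisible(x)
}

#' Simulate fixed-effect cell means from the joint posterior
#'
#' Draws coefficient vectors from the asymptotic joint posterior of the
#' fixed effects under flat priors - a multivariate normal centred on the
#' ML estimates with the fixed-effect covariance - and maps each draw to
#' the mean of every fixed-effect cell (each observed combination of the
#' fixed factors). Per cell the fitted value and the 2.5/50/97.5
#' percentiles of the draws (the 95% credible interval) are reported. The
#' default 10 000 draws match the study's simulation count.
#'
#' @param fit An `fp_fit` from [fit_mixed_model()].
#' @param n_draws Number of posterior draws.
#' @param seed Integer seed.
#' @return Object of class `fp_posterior`: list with `cells` (data.frame
#'   of factor levels, `fitted`, `lower`, `median`, `upper`) and `draws`
#'   (n_draws x n_cells matrix, columns labelled by cell).
#' @export
simulate_posterior <- function(fit, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(fit, "fp_fit"))
  bv <- fixef_vcov(fit$model)
  beta <- bv$beta
  V <- bv$V
  if (length(fit$fixed)) {
    cells <- unique(fit$data[, fit$fixed, drop = FALSE])
    cells <- cells[do.call(order, cells), , drop = FALSE]
    rownames(cells) <- NULL
    rhs <- stats::as.formula(paste("~", paste(fit$fixed, collapse = " * ")))
    X <- stats::model.matrix(rhs, cells)
  } else {
    cells <- data.frame(cell = "overall")
    X <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  }
  set.seed(split_seed(seed, "inference/posterior"))
  B <- MASS::mvrnorm(n_draws, mu = beta, Sigma = V)
  if (is.null(dim(B))) B <- matrix(B, ncol = 1L)
  draws <- B %*% t(X)
  colnames(draws) <- apply(cells, 1, paste, collapse = ".")
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  cells$fitted <- as.numeric(X %*% beta)
  cells$lower <- qs[1, ]
  cells$median <- qs[2, ]
  cells$upper <- qs[3, ]
  structure(list(cells = cells, draws = draws, n_draws = n_draws),
            class = "fp_posterior")
}

#' @export
print.fp_posterior <- function(x, ...) {
  cat("<fp_posterior>", x$n_draws, "draws,", nrow(x$cells), "cells\n")
  print(x$cells, row.names = FALSE)
  invisible(x)
}

#' Compare two cells by exceedance probability
#'
#' Fraction of paired posterior draws in which the first cell mean exceeds
#' the second (ties counted one half). The difference is significant at
#' level `alpha` when p < alpha (first cell smaller) or p > 1 - alpha
#' (first cell larger) - the `< 5% of cases` decision rule.
#'
#' @param draws_a,draws_b Equal-length draw vectors, paired by draw index.
#' @param alpha Significance level.
#' @return List with `p` (exceedance probability), `significant`,
#'   `direction` (`"a_smaller"`, `"a_larger"` or `"none"`).
#' @export
compare_cells <- function(draws_a, draws_b, alpha = 0.05) {
  stopifnot(length(draws_a) == length(draws_b))
  d <- draws_a - draws_b
  # ties within numerical precision of the draw scale count one half
  tie_tol <- 1e-9 * max(abs(draws_a), abs(draws_b), 1)
  tie <- abs(d) <= tie_tol
  p <- mean(d > 0 & !tie) + 0.5 * mean(tie)
  sig <- p < alpha || p > 1 - alpha
  list(p = p, significant = sig,
       direction = if (p < alpha) "a_smaller" else if (p > 1 - alpha) "a_larger" else "none")
}

#' Mate-versus-nonmate contrasts from a posterior
#'
#' For every combination of the non-familiarity fixed factors (call type,
#' trial), compares the mate cell against the familiar and unfamiliar
#' cells: fitted difference (m - other, on the model's square-root scale),
#' exceedance probability and significance flag. Credible-interval overlap
#' of the two cells is reported alongside (non-overlap alone is treated as
#' significant in the two-step rule).
#'
#' @param post An `fp_posterior` whose cells include `familiarity`.
#' @param alpha Significance level for the exceedance rule.
#' @return Data.frame with one row per contrast: grouping factors,
#'   `contrast`, `diff_fitted`, `p`, `cri_overlap`, `significant`.
#' @export
familiarity_contrasts <- function(post, alpha = 0.05) {
  cells <- post$cells
  stopifnot("familiarity" %in% names(cells))
  meta <- setdiff(names(cells),
                  c("familiarity", "fitted", "lower", "median", "upper"))
  key <- if (length(meta)) {
    apply(cells[, meta, drop = FALSE], 1, paste, collapse = ".")
  } else {
    rep("all", nrow(cells))
  }
  out <- list()
  for (g in unique(key)) {
    idx <- which(key == g)
    fam <- cells$familiarity[idx]
    if (!"m" %in% fam) next
    i_m <- idx[fam == "m"]
    for (other in intersect(c("f", "uf"), fam)) {
      i_o <- idx[fam == other]
      cmp <- compare_cells(post$draws[, i_m], post$draws[, i_o], alpha)
      overlap <- cells$lower[i_m] <= cells$upper[i_o] &&
        cells$lower[i_o] <= cells$upper[i_m]
      row <- cells[i_m, meta, drop = FALSE]
      row$contrast <- paste0("m-", other)
      row$diff_fitted <- cells$fitted[i_m] - cells$fitted[i_o]
      row$p <- cmp$p
      row$cri_overlap <- overlap
      row$significant <- cmp$significant || !overlap
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Test for habituation across a trial
#'
#' Counts of calls in 500 s bins are modelled by a linear mixed model with
#' bin (factor) as the explanatory variable and individual identity as a
#' random factor (plain linear model when only one subject is supplied);
#' the first and last bins are then compared by posterior simulation.
#'
#' @param bin_counts Data.frame with columns `subject_id`, `bin` (integer
#'   or factor) and `count`.
#' @param n_draws Posterior draws.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return List with `p_first_vs_last`, `significant`, `first_fitted`,
#'   `last_fitted`, and the underlying `posterior`.
#' @export
habituation_test <- function(bin_counts, n_draws = 10000L, seed = 1L,
                             alpha = 0.05) {
  stopifnot(all(c("subject_id", "bin", "count") %in% names(bin_counts)))
  bins <- sort(unique(as.integer(bin_counts$bin)))
  if (length(bins) < 2L) stop("need >= 2 bins")
  dat <- data.frame(subject_id = bin_counts$subject_id,
                    bin = factor(as.integer(bin_counts$bin), levels = bins),
                    n_answers = bin_counts$count)  # modelled untransformed
  fit <- fit_mixed_model_raw(dat, ycol = "n_answers", fixed = "bin",
                             random = "subject_id")
  post <- simulate_posterior(fit, n_draws = n_draws, seed = seed)
  lab_first <- as.character(bins[1])
  lab_last <- as.character(bins[length(bins)])
  i_f <- which(post$cells$bin == lab_first)
  i_l <- which(post$cells$bin == lab_last)
  cmp <- compare_cells(post$draws[, i_f], post$draws[, i_l], alpha)
  list(p_first_vs_last = cmp$p, significant = cmp$significant,
       first_fitted = post$cells$fitted[i_f],
       last_fitted = post$cells$fitted[i_l],
       posterior = post)
}

# internal: fixed-effect estimates and covariance for lm or merMod fits.
# A fit with zero residual variance (exact relations, constant responses)
# can make the covariance uncomputable; the posterior then degenerates to a
# point mass at the estimates (zero matrix).
fixef_vcov <- function(model) {
  if (inherits(model, "merMod")) {
    beta <- lme4::fixef(model)
    V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(model))),
                  error = function(e) NULL)
  } else {
    beta <- stats::coef(model)
    V <- tryCatch(suppressWarnings(as.matrix(stats::vcov(model))),
                  error = function(e) NULL)
  }
  if (is.null(V) || any(is.na(V)) || any(!is.finite(V))) {
    V <- matrix(0, length(beta), length(beta))
  }
  list(beta = beta, V = V)
}

# internal: like fit_mixed_model but on the raw response column (used where
# no transform is applied, e.g. bin counts)
fit_mixed_model_raw <- function(dat, ycol, fixed, random) {
  dat$.y <- dat[[ycol]]
  fixed <- fixed[vapply(fixed, function(f) length(unique(dat[[f]])) >= 2L,
                        logical(1))]
  random <- random[vapply(random, function(f) length(unique(dat[[f]])) >= 2L,
                          logical(1))]
  for (f in c(fixed, random)) dat[[f]] <- factor(dat[[f]])
  fix_part <- if (length(fixed)) paste(fixed, collapse = " * ") else "1"
  if (length(random)) {
    form <- stats::as.formula(paste(".y ~", fix_part, "+",
                                    paste(sprintf("(1 | %s)", random),
                                          collapse = " + ")))
    model <- suppressMessages(lme4::lmer(form, data = dat, REML = FALSE))
  } else {
    form <- stats::as.formula(paste(".y ~", fix_part))
    model <- stats::lm(form, data = dat)
  }
  structure(list(model = model, fixed = fixed, response = ycol,
                 data = dat, formula = form, diagnostics = list()),
            class = "fp_fit")
}

#' Kruskal-Wallis test of answer-type composition across familiarity
#'
#' Compares a per-series proportion (of one answer type within one
#' playback call type) across the three familiarity levels with a
#' Kruskal-Wallis rank sum test. Run only when at least `min_nonnull`
#' non-missing values are available (sample size at least 8 times the
#' single explanatory variable); otherwise returns a skip record.
#'
#' @param values Numeric per-series proportions (may contain `NA`).
#' @param groups Familiarity level of each value.
#' @param min_nonnull Minimum non-missing values required.
#' @return List with `skipped` and either `reason` or `statistic`, `p`,
#'   `test` (the `htest`).
#' @export
answer_type_composition_test <- function(values, groups, min_nonnull = 8L) {
  ok <- !is.na(values)
  if (sum(ok) < min_nonnull) {
    return(list(skipped = TRUE,
                reason = sprintf("%d non-null values (< %d)", sum(ok), min_nonnull)))
  }
  kt <- stats::kruskal.test(values[ok], factor(groups[ok]))
  list(skipped = FALSE, statistic = unname(kt$statistic), p = kt$p.value,
       test = kt)
}

#' Correlate playback answer proportions with baseline answer proportions
#'
#' Linear fit of the per-pair proportion of answers during a playback
#' trial on the proportion during baseline (restricted upstream to
#' repeatable call-type combinations). The slope's credible interval and
#' exceedance probability against zero come from posterior simulation of
#' the coefficients.
#'
#' @param baseline,playback Paired numeric proportions (>= 3 pairs).
#' @param n_draws Posterior draws.
#' @param seed Integer seed.
#' @param alpha Significance level.
#' @return List with `slope`, `correlation`, `lower`, `upper`,
#'   `p_slope_gt0`, `significant`.
#' @export
baseline_playback_correlation <- function(baseline, playback,
                                          n_draws = 10000L, seed = 1L,
                                          alpha = 0.05) {
  stopifnot(length(baseline) == length(playback))
  if (length(baseline) < 3L) stop("need >= 3 pairs")
  fit <- stats::lm(playback ~ baseline)
  bv <- fixef_vcov(fit)
  set.seed(split_seed(seed, "inference/baseline-correlation"))
  B <- MASS::mvrnorm(n_draws, mu = bv$beta, Sigma = bv$V)
  slope_draws <- B[, 2]
  p <- mean(slope_draws > 0) + 0.5 * mean(slope_draws == 0)
  ci <- stats::quantile(slope_draws, c(0.025, 0.975), names = FALSE)
  list(slope = unname(stats::coef(fit)[2]),
       correlation = stats::cor(baseline, playback),
       lower = ci[1], upper = ci[2],
       p_slope_gt0 = p, significant = p < alpha || p > 1 - alpha)
}

# internal: restrict a schedule to the first or last n emissions per series
subset_schedule <- function(schedule, n, which = c("first", "last")) {
  which <- match.arg(which)
  flagged <- FALSE
  parts <- lapply(split(schedule, schedule$series_idx), function(s) {
    s <- s[order(s$emission_s), ]
    if (nrow(s) <= n) {
      flagged <<- TRUE
      return(s)
    }
    if (which == "first") s[seq_len(n), ] else s[seq(nrow(s) - n + 1L, nrow(s)), ]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$emission_s), ]
  rownames(out) <- NULL
  attr(out, "short_series_used_whole") <- flagged
  out
}

#' Robustness of familiarity contrasts to series truncation
#'
#' Re-runs the scoring and modelling pipeline restricted to the first and
#' last `n` playback calls of each series and tabulates, for every
#' mate-versus-nonmate contrast, the sign of the fitted difference and its
#' significance against the full-series analysis. Series shorter than the
#' subset length are used whole and flagged.
#'
#' @param trials List of per-trial inputs, each a list with `schedule`,
#'   `events` (sorted responder CallEvents), `subject_id`, `trial`,
#'   `audience_id`.
#' @param response Passed to [fit_mixed_model()].
#' @param n_first,n_last Subset sizes (playback calls per series).
#' @param n_draws Posterior draws per variant.
#' @param seed Integer seed.
#' @return List with `contrasts` (long data.frame: `variant` in
#'   full/first/last plus [familiarity_contrasts()] columns and
#'   `sign_agrees_full`), and `agreement` (proportion of first/last
#'   contrasts whose sign matches the full analysis).
#' @export
subset_robustness <- function(trials, response = c("sqrt_count", "sqrt_latency"),
                              n_first = 30L, n_last = 30L,
                              n_draws = 2000L, seed = 1L) {
  response <- match.arg(response)
  variants <- list(
    full = function(s) s,
    first = function(s) subset_schedule(s, n_first, "first"),
    last = function(s) subset_schedule(s, n_last, "last"))
  results <- list()
  for (v in names(variants)) {
    tabs <- lapply(trials, function(tr) {
      sch <- variants[[v]](tr$schedule)
      br <- build_series_responses(sch, tr$events, subject_id = tr$subject_id,
                                   trial = tr$trial, audience_id = tr$audience_id)
      if (response == "sqrt_count") br$series else br$latencies
    })
    tab <- do.call(rbind, tabs)
    fit <- fit_mixed_model(tab, response = response)
    post <- simulate_posterior(fit, n_draws = n_draws,
                               seed = split_seed(seed, paste0("subset/", v)))
    fc <- familiarity_contrasts(post)
    fc$variant <- v
    results[[v]] <- fc
  }
  full <- results$full
  key_cols <- setdiff(names(full), c("diff_fitted", "p", "cri_overlap",
                                     "significant", "variant"))
  key <- function(df) apply(df[, key_cols, drop = FALSE], 1, paste, collapse = ".")
  full_sign <- sign(full$diff_fitted)
  names(full_sign) <- key(full)
  all_rows <- do.call(rbind, results)
  all_rows$sign_agrees_full <- sign(all_rows$diff_fitted) ==
    full_sign[key(all_rows)]
  sub_rows <- all_rows[all_rows$variant != "full", ]
  list(contrasts = all_rows,
       agreement = mean(sub_rows$sign_agrees_full))
}
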