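#' Detect answers between two event streams
#'
#' An answer is a responder event whose onset lies within `window_s` after
#' a trigger onset (open at 0, closed at the window). Each responder event
#' answers at most one trigger - the nearest preceding one - while a
#' trigger may receive several answers. The baseline rule scores calls
#' within 0.5 s of the partner's call; both streams must be time-sorted.
#'
#' @param trigger_events Data.frame with `onset_s` (playback emissions or
#'   partner calls), sorted.
#' @param responder_events Data.frame with `onset_s` (and optionally
#'   `call_type`), sorted.
#' @param window_s Answer window in seconds.
#' @return Data.frame with one row per answer: `trigger_idx`,
#'   `responder_idx`, `trigger_onset_s`, `responder_onset_s`, `latency_s`,
#'   `responder_call_type`.
#' @export
detect_answers <- function(trigger_events, responder_events, window_s = 0.5) {
  assert_sorted_events(trigger_events, "trigger_events")
  assert_sorted_events(responder_events, "responder_events")
  t_on <- trigger_events$onset_s
  r_on <- responder_events$onset_s
  if (length(t_on) == 0L || length(r_on) == 0L) {
    return(data.frame(trigger_idx = integer(), responder_idx = integer(),
                      trigger_onset_s = numeric(), responder_onset_s = numeric(),
                      latency_s = numeric(),
                      responder_call_type = character(),
                      stringsAsFactors = FALSE))
  }
  # nearest strictly-preceding trigger for each responder event
  prev <- findInterval(r_on, t_on, left.open = TRUE)
  lat <- r_on - ifelse(prev >= 1L, t_on[pmax(prev, 1L)], NA_real_)
  ok <- prev >= 1L & !is.na(lat) & lat > 0 & lat <= window_s
  ct <- if ("call_type" %in% names(responder_events)) {
    responder_events$call_type
  } else {
    rep(NA_character_, length(r_on))
  }
  data.frame(trigger_idx = prev[ok], responder_idx = which(ok),
             trigger_onset_s = t_on[prev[ok]], responder_onset_s = r_on[ok],
             latency_s = lat[ok], responder_call_type = ct[ok],
             stringsAsFactors = FALSE)
}

#' Latency to the first answering call after an emission
#'
#' Earliest responder onset within (0, `window_s`] of the emission onset;
#' `NA` when no response falls in the window. The latency analysis window
#' is 0-1.5 s after stimulus onset.
#'
#' @param emission_s Onset of the emission (scalar) or vector of onsets.
#' @param responder_events Sorted data.frame with `onset_s`.
#' @param window_s Latency window, s.
#' @return Numeric latency (or vector, one per emission), `NA` if none.
#' @export
first_answer_latency <- function(emission_s, responder_events, window_s = 1.5) {
  assert_sorted_events(responder_events, "responder_events")
  r_on <- responder_events$onset_s
  vapply(emission_s, function(e) {
    i <- findInterval(e, r_on, left.open = TRUE) + 1L  # first onset > e
    if (i > length(r_on) || r_on[i] - e > window_s) NA_real_ else r_on[i] - e
  }, numeric(1))
}

#' Assemble per-series response rows from a trial
#'
#' For each playback series: the number of answers (responder events
#' attributed to that series' emissions under the 0.5 s answer rule) and
#' the latencies to the first answering call per emission (1.5 s window).
#' Responder events before the trial start indicate a clock mismatch and
#' are excluded with a warning.
#'
#' @param schedule Schedule data.frame from [build_schedule()].
#' @param responder_events Sorted CallEvent data.frame for the focal bird.
#' @param subject_id,trial,audience_id Covariates stamped on each row.
#' @param answer_window_s Answer-count window, s.
#' @param latency_window_s First-answer latency window, s.
#' @return List with `series` (one row per series: `subject_id`, `trial`,
#'   `call_type`, `familiarity`, `audience_id`, `playback_order`,
#'   `n_answers`) and `latencies` (long table with one row per emission
#'   that received a first answer: same covariates plus `emission_idx`,
#'   `latency_s`).
#' @export
build_series_responses <- function(schedule, responder_events,
                                   subject_id = "subject", trial = "A",
                                   audience_id = "aud1",
                                   answer_window_s = 0.5,
                                   latency_window_s = 1.5) {
  assert_sorted_events(responder_events, "responder_events")
  t0 <- min(schedule$emission_s)
  early <- responder_events$onset_s < t0
  if (any(early)) {
    warning(sprintf("%d responder events precede trial start; excluded", sum(early)))
    responder_events <- responder_events[!early, , drop = FALSE]
  }
  sched_sorted <- schedule[order(schedule$emission_s), ]
  ans <- detect_answers(
    data.frame(onset_s = sched_sorted$emission_s),
    responder_events, window_s = answer_window_s)
  series_of_answer <- sched_sorted$series_idx[ans$trigger_idx]

  series_ids <- unique(sched_sorted$series_idx)
  series_rows <- lapply(series_ids, function(sid) {
    sub <- sched_sorted[sched_sorted$series_idx == sid, ]
    data.frame(subject_id = subject_id, trial = trial,
               call_type = sub$call_type[1], familiarity = sub$familiarity[1],
               audience_id = audience_id, playback_order = sid,
               n_answers = sum(series_of_answer == sid),
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, series_rows)

  lat <- first_answer_latency(sched_sorted$emission_s, responder_events,
                              window_s = latency_window_s)
  has <- which(!is.na(lat))
  latencies <- data.frame(
    subject_id = rep(subject_id, length(has)),
    trial = rep(trial, length(has)),
    call_type = sched_sorted$call_type[has],
    familiarity = sched_sorted$familiarity[has],
    audience_id = rep(audience_id, length(has)),
    playback_order = sched_sorted$series_idx[has],
    emission_idx = has, latency_s = lat[has],
    stringsAsFactors = FALSE)
  list(series = series, latencies = latencies)
}

#' Proportions of answer call types in a series
#'
#' Series with fewer than `min_answers` answers (default 5) are excluded
#' so that very low counts cannot dominate the proportions; otherwise the
#' answers' call-type proportions (summing to 1) are returned.
#'
#' @param answers Data.frame of answers from [detect_answers()] (uses
#'   `responder_call_type`).
#' @param min_answers Minimum answers for a series to be considered.
#' @return Named proportion vector, or `NULL` (with attribute `reason`)
#'   when excluded.
#' @export
answer_type_proportions <- function(answers, min_answers = 5L) {
  n <- nrow(answers)
  if (n < min_answers) {
    message(sprintf("series excluded: only %d answers (< %d)", n, min_answers))
    return(NULL)
  }
  tab <- table(answers$responder_call_type)
  prop <- as.numeric(tab) / n
  names(prop) <- names(tab)
  prop
}

#' Count events in fixed-width time bins
#'
#' Half-open bins `[k*bin_s, (k+1)*bin_s)` over the session span (default
#' width 500 s, roughly the length of a playback series); counts over
#' in-span events sum to the number of such events.
#'
#' @param events Data.frame with `onset_s`, or numeric onsets.
#' @param bin_s Bin width, s.
#' @param session_span Total span, s (> 0); events at or beyond it are
#'   outside the last bin.
#' @return Integer vector of counts, one per bin.
#' @export
bin_call_counts <- function(events, bin_s = 500, session_span) {
  stopifnot(session_span > 0)
  on <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
  n_bins <- ceiling(session_span / bin_s)
  on <- on[on >= 0 & on < session_span]
  idx <- floor(on / bin_s) + 1L
  tabulate(idx, nbins = n_bins)
}

#' Repeatability of a behavioural measure from one-way ANOVA
#'
#' Given values grouped by individual (or pair), computes the among- and
#' within-group mean squares of a one-way ANOVA. The primary index is the
#' intraclass correlation r = (MSA - MSW) / (MSA + (n0 - 1) MSW), bounded
#' to [0, 1], with n0 the coefficient accounting for unequal group sizes;
#' the raw F ratio MSA / MSW is reported alongside.
#'
#' @param values Numeric measurements.
#' @param groups Grouping factor (>= 2 groups; at least one group with
#'   >= 2 values).
#' @return List with `r` (ICC, clamped to [0, 1]), `F` (MSA/MSW), `MSA`,
#'   `MSW`, `n0`, and degrees of freedom `df_among`, `df_within`.
#' @export
repeatability_index <- function(values, groups) {
  groups <- factor(groups)
  a <- nlevels(groups)
  N <- length(values)
  if (a < 2L) stop("need >= 2 groups")
  ni <- as.numeric(table(groups))
  if (all(ni < 2)) stop("need >= 2 values in some group")
  if (stats::var(values) == 0) stop("degenerate: all values identical")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssa <- sum(ni * (means[levels(groups)] - gm)^2)
  ssw <- sum((values - means[groups])^2)
  msa <- ssa / (a - 1)
  msw <- ssw / (N - a)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  r <- if (msw == 0) 1 else (msa - msw) / (msa + (n0 - 1) * msw)
  list(r = min(max(r, 0), 1), F = if (msw == 0) Inf else msa / msw,
       MSA = msa, MSW = msw, n0 = n0, df_among = a - 1L, df_within = N - a)
}

#' Summarise baseline answer behaviour by call-type combination
#'
#' For each (caller call type -> responder call type) combination: the
#' number of answers under the 0.5 s rule and the proportion of answers
#' out of all emitted calls of that caller type. Combinations in which the
#' caller used fewer than `min_calls` calls (default 3) are dropped as
#' rare/inconsistent.
#'
#' @param caller_events,responder_events Sorted CallEvent data.frames with
#'   `call_type`.
#' @param window_s Answer window, s.
#' @param min_calls Minimum caller-type usage to keep a combination.
#' @return Data.frame with `caller_type`, `responder_type`, `n_caller_calls`,
#'   `n_answers`, `proportion`.
#' @export
exchange_answer_summary <- function(caller_events, responder_events,
                                    window_s = 0.5, min_calls = 3L) {
  ans <- detect_answers(caller_events, responder_events, window_s)
  caller_counts <- table(caller_events$call_type)
  kept_types <- names(caller_counts)[caller_counts >= min_calls]
  resp_types <- sort(unique(responder_events$call_type))
  grid <- expand.grid(caller_type = kept_types, responder_type = resp_types,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) return(data.frame(
    caller_type = character(), responder_type = character(),
    n_caller_calls = integer(), n_answers = integer(), proportion = numeric()))
  trig_type <- caller_events$call_type[ans$trigger_idx]
  grid$n_caller_calls <- as.integer(caller_counts[grid$caller_type])
  grid$n_answers <- mapply(function(ct, rt) {
    sum(trig_type == ct & ans$responder_call_type == rt)
  }, grid$caller_type, grid$responder_type)
  grid$proportion <- grid$n_answers / grid$n_caller_calls
  grid
}
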