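#' Call-type rosters used in the playback design
#'
#' Male subjects are tested with five female call types; female subjects
#' additionally hear male song, giving six stimulus types. The four soft
#' unlearned calls are tet, stack, kackle and hat; the distance call is loud
#' (and learned in males).
#'
#' @param sex Sex of the *subject* (`"M"` or `"F"`): the roster returned is
#'   the set of opposite-sex vocalisation types the subject hears.
#' @return Character vector of call-type labels.
#' @export
call_type_roster <- function(sex = c("M", "F")) {
  sex <- match.arg(sex)
  base <- c("distance", "stack", "kackle", "hat", "tet")
  if (sex == "F") c(base, "song") else base
}

#' Construct a synthetic bird profile
#'
#' A `bird_profile` holds the per-call-type acoustic parameters of one
#' simulated bird: fundamental frequency (a call-type base plus an
#' individual offset), number of harmonics, duration and relative noise
#' floor. These parameters are the ground truth that the acoustic feature
#' extractors should recover.
#'
#' @param bird_id Character identifier.
#' @param sex `"M"` or `"F"` (sex of this bird).
#' @param repertoire Data frame with columns `call_type`, `fundamental_hz`,
#'   `n_harmonics`, `duration_s`, `noise_floor`. Defaults to a template
#'   roster with distinct per-type fundamentals plus `f0_offset_hz`.
#' @param f0_offset_hz Individual offset added to every call type's
#'   fundamental; distinct offsets across birds make individuals separable.
#' @return An object of class `bird_profile`.
#' @export
bird_profile <- function(bird_id, sex = c("M", "F"), repertoire = NULL,
                         f0_offset_hz = 0) {
  sex <- match.arg(sex)
  if (is.null(repertoire)) {
    # template fundamentals span the range of zebra finch calls (soft calls
    # and distance call roughly 500-1500 Hz fundamental band)
    repertoire <- data.frame(
      call_type      = c("distance", "stack", "kackle", "hat", "tet", "song"),
      fundamental_hz = c(700, 550, 900, 1200, 450, 600) + f0_offset_hz,
      n_harmonics    = c(8L, 6L, 5L, 4L, 6L, 10L),
      duration_s     = c(0.15, 0.09, 0.12, 0.07, 0.08, 0.80),
      noise_floor    = rep(0.05, 6),
      stringsAsFactors = FALSE
    )
    # only females hear song, and only males produce it
    if (sex == "F") repertoire <- repertoire[repertoire$call_type != "song", ]
  }
  stopifnot(all(c("call_type", "fundamental_hz", "n_harmonics",
                  "duration_s", "noise_floor") %in% names(repertoire)))
  if (any(repertoire$fundamental_hz <= 0)) stop("fundamental_hz must be > 0")
  if (any(repertoire$duration_s <= 0)) stop("duration_s must be > 0")
  if (any(repertoire$noise_floor < 0 | repertoire$noise_floor >= 1)) {
    stop("noise_floor must lie in [0, 1)")
  }
  structure(list(bird_id = as.character(bird_id), sex = sex,
                 repertoire = repertoire),
            class = "bird_profile")
}

#' @export
print.bird_profile <- function(x, ...) {
  cat("<bird_profile>", x$bird_id, "sex:", x$sex, "\n")
  print(x$repertoire, row.names = FALSE)
  invisible(x)
}

#' Construct an exchange model
#'
#' Parameters of the pair-exchange / playback-response generative model:
#' a homogeneous Poisson calling rate per bird and call type, an answer
#' probability and latency distribution indexed by familiarity, and the
#' composition of answer call types. Latencies follow a normal distribution
#' truncated to the latency analysis window (0, 1.5] s.
#'
#' Defaults plant the effects the pipeline is built to detect, at the scale
#' of the clearest published contrasts: answers to the mate are more likely
#' (0.57 vs 0.23 per emission) and faster (mean 0.55 s vs 0.67 s) than
#' answers to familiar or unfamiliar birds.
#'
#' @param base_call_rate Spontaneous calling rate, events/s per bird per
#'   call type.
#' @param answer_prob Named numeric vector of answer probabilities by
#'   familiarity (`m`, `f`, `uf`), or a single number used for all levels.
#' @param answer_latency_mean Named numeric vector of latency means (s) by
#'   familiarity, or a single number.
#' @param answer_latency_sd Latency SD (s) of the untruncated normal.
#' @param latency_bounds Truncation bounds (lower open, upper closed), s.
#' @param composition Named probability vector over answer call types;
#'   `NULL` defers to [default_answer_composition()] at generation time.
#' @return An object of class `exchange_model`.
#' @export
exchange_model <- function(base_call_rate = 0.05,
                           answer_prob = c(m = 0.57, f = 0.23, uf = 0.23),
                           answer_latency_mean = c(m = 0.55, f = 0.67, uf = 0.67),
                           answer_latency_sd = 0.2,
                           latency_bounds = c(0, 1.5),
                           composition = NULL) {
  if (any(answer_prob < 0 | answer_prob > 1)) stop("answer_prob must lie in [0, 1]")
  if (any(answer_latency_mean <= latency_bounds[1] |
          answer_latency_mean > latency_bounds[2])) {
    stop("answer_latency_mean must lie within latency_bounds")
  }
  if (!is.null(composition)) {
    stopifnot(!is.null(names(composition)), all(composition >= 0))
    composition <- composition / sum(composition)
  }
  structure(list(base_call_rate = base_call_rate,
                 answer_prob = answer_prob,
                 answer_latency_mean = answer_latency_mean,
                 answer_latency_sd = answer_latency_sd,
                 latency_bounds = latency_bounds,
                 composition = composition),
            class = "exchange_model")
}

# internal: look up a by-familiarity parameter that may be scalar or named
fam_param <- function(x, familiarity) {
  if (length(x) == 1L && is.null(names(x))) return(rep(unname(x), length(familiarity)))
  if (is.null(names(x)) || !all(familiarity %in% names(x))) {
    stop("parameter must be a scalar or named by familiarity level")
  }
  unname(x[familiarity])
}

#' Answer call-type composition observed in playback responses
#'
#' Answer types are dominated by stack calls (69.2% of female answers,
#' 50.1% of male answers), followed by distance calls (22.4% / 17.6%) and,
#' in males, hat calls (11.8%); the remainder is spread over the other soft
#' calls. Used as the default composition when generating answers.
#'
#' @param sex Sex of the *responding* bird.
#' @return Named probability vector over call types, summing to 1.
#' @export
default_answer_composition <- function(sex = c("M", "F")) {
  sex <- match.arg(sex)
  if (sex == "F") {
    p <- c(stack = 0.692, distance = 0.224, kackle = 0.028, hat = 0.028, tet = 0.028)
  } else {
    p <- c(stack = 0.501, distance = 0.176, hat = 0.118, kackle = 0.1025, tet = 0.1025)
  }
  p / sum(p)
}

#' Simulation configuration
#'
#' @param seed Integer master seed; all generator RNG streams derive from it
#'   via [split_seed()], so the same config reproduces byte-identical output.
#' @param n_pairs Number of focal pairs.
#' @param session_duration_s Baseline session length in seconds (default four
#'   scored hours).
#' @param trials Trial labels (the experiment is replicated on two days).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_pairs = 6L, session_duration_s = 14400,
                       trials = c("A", "B")) {
  stopifnot(session_duration_s > 0, n_pairs >= 1)
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 session_duration_s = session_duration_s, trials = trials),
            class = "sim_config")
}

#' Generate a synthetic call waveform
#'
#' Synthesises one call as a harmonic stack at the profile's fundamental
#' with geometric amplitude roll-off across harmonics, plus a white noise
#' floor band-limited above 400 Hz (zebra finch calls carry essentially no
#' energy below that, and recording chains high-pass their input). The
#' harmonic part is scaled to `1 - noise_floor` so the peak amplitude
#' never exceeds 1. Harmonics above Nyquist are dropped.
#'
#' @param profile A [bird_profile()].
#' @param call_type Call-type label present in the profile's repertoire.
#' @param seed Integer seed for the noise stream.
#' @param sample_rate Sampling rate in Hz.
#' @param harmonic_rolloff Amplitude ratio between successive harmonics.
#' @return A `vocal_segment`: list with `samples`, `sample_rate`, `onset_s`,
#'   `offset_s`, `bird_id`, `call_type`.
#' @export
generate_call_waveform <- function(profile, call_type, seed = 1L,
                                   sample_rate = 44100,
                                   harmonic_rolloff = 0.6) {
  rep_row <- profile$repertoire[profile$repertoire$call_type == call_type, ]
  if (nrow(rep_row) == 0L) {
    stop(sprintf("unknown call_type '%s' for bird %s", call_type, profile$bird_id))
  }
  n <- round(rep_row$duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f0 <- rep_row$fundamental_hz
  h_idx <- seq_len(rep_row$n_harmonics)
  h_idx <- h_idx[h_idx * f0 < sample_rate / 2]
  amps <- harmonic_rolloff^(h_idx - 1)
  wave <- rowSums(sapply(h_idx, function(h) {
    harmonic_rolloff^(h - 1) * sin(2 * pi * h * f0 * t)
  }))
  wave <- wave / max(abs(wave)) * (1 - rep_row$noise_floor)
  if (rep_row$noise_floor > 0) {
    set.seed(split_seed(seed, paste0("synthetic/waveform/", profile$bird_id,
                                     "/", call_type)))
    noise <- stats::runif(n, -1, 1)
    # band-limit the noise floor above 400 Hz (brickwall via FFT)
    nf_fft <- stats::fft(noise)
    cut <- which((seq_len(n) - 1) * sample_rate / n < 400 |
                   (n - seq_len(n) + 1) * sample_rate / n < 400)
    nf_fft[cut] <- 0
    noise <- Re(stats::fft(nf_fft, inverse = TRUE)) / n
    noise <- noise / max(abs(noise)) * rep_row$noise_floor
    wave <- wave + noise
  }
  structure(list(samples = wave, sample_rate = sample_rate,
                 onset_s = 0, offset_s = rep_row$duration_s,
                 bird_id = profile$bird_id, call_type = call_type),
            class = "vocal_segment")
}

# internal: empty CallEvent table
empty_call_events <- function() {
  data.frame(bird_id = character(), call_type = character(),
             onset_s = numeric(), offset_s = numeric(),
             stringsAsFactors = FALSE)
}

# internal: duration of a call type in a profile (0.1 s fallback)
profile_duration <- function(profile, call_type) {
  d <- profile$repertoire$duration_s[profile$repertoire$call_type == call_type]
  if (length(d) == 0L) 0.1 else d[1]
}

#' Generate a baseline pair-exchange session
#'
#' Each bird of the pair calls spontaneously as a homogeneous Poisson
#' process (rate `base_call_rate` per call type). After each spontaneous
#' call, the partner answers with the model's mate-level (`"m"`) answer
#' probability, at a lag drawn from the truncated-normal latency
#' distribution; answer call types follow the composition distribution.
#' Answers do not themselves trigger answers. Events beyond the session end
#' are dropped, so both streams lie in [0, `session_duration_s`] and are
#' time-sorted.
#'
#' @param pair List of two [bird_profile()]s.
#' @param model An [exchange_model()].
#' @param config A [sim_config()].
#' @return Named list of two CallEvent data.frames (one per bird; columns
#'   `bird_id`, `call_type`, `onset_s`, `offset_s`), each sorted by onset.
#' @export
generate_exchange_session <- function(pair, model, config) {
  stopifnot(length(pair) == 2L, inherits(model, "exchange_model"),
            inherits(config, "sim_config"))
  dur <- config$session_duration_s
  ids <- vapply(pair, function(p) p$bird_id, character(1))
  set.seed(split_seed(config$seed, paste0("synthetic/exchange/", ids[1], "/", ids[2])))

  spont <- lapply(pair, function(p) {
    types <- p$repertoire$call_type
    evs <- lapply(types, function(ct) {
      n <- stats::rpois(1, model$base_call_rate * dur)
      if (n == 0L) return(NULL)
      on <- sort(stats::runif(n, 0, dur))
      data.frame(bird_id = p$bird_id, call_type = ct, onset_s = on,
                 offset_s = pmin(on + profile_duration(p, ct), dur),
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, evs)
    if (is.null(ev)) empty_call_events() else ev[order(ev$onset_s), ]
  })

  p_ans <- fam_param(model$answer_prob, "m")
  mu <- fam_param(model$answer_latency_mean, "m")
  streams <- list(spont[[1]], spont[[2]])
  for (i in 1:2) {
    caller <- spont[[i]]
    responder <- pair[[3 - i]]
    if (nrow(caller) == 0L) next
    comp <- model$composition
    if (is.null(comp)) comp <- default_answer_composition(responder$sex)
    answers <- stats::runif(nrow(caller)) < p_ans
    n_a <- sum(answers)
    if (n_a == 0L) next
    lags <- rtruncnorm(n_a, mu, model$answer_latency_sd,
                       model$latency_bounds[1], model$latency_bounds[2])
    a_type <- sample(names(comp), n_a, replace = TRUE, prob = comp)
    on <- caller$onset_s[answers] + lags
    keep <- on <= dur
    if (!any(keep)) next
    ans <- data.frame(bird_id = responder$bird_id, call_type = a_type[keep],
                      onset_s = on[keep],
                      offset_s = pmin(on[keep] + vapply(a_type[keep], function(ct)
                        profile_duration(responder, ct), numeric(1)), dur),
                      stringsAsFactors = FALSE)
    j <- 3 - i
    streams[[j]] <- rbind(streams[[j]], ans)
  }
  streams <- lapply(streams, function(s) {
    s <- s[order(s$onset_s), ]
    rownames(s) <- NULL
    s
  })
  names(streams) <- ids
  streams
}

#' Generate focal-bird responses to a playback schedule
#'
#' For every scheduled emission, the focal bird answers with the
#' familiarity-dependent probability, at a latency drawn from the
#' truncated-normal distribution for that familiarity level; answer call
#' types follow the composition distribution. An optional background
#' Poisson stream adds stationary spontaneous calling over the trial span
#' (used e.g. to exercise habituation checks).
#'
#' @param schedule A playback schedule data.frame from [build_schedule()]
#'   (columns `emission_s`, `familiarity` at minimum).
#' @param model An [exchange_model()].
#' @param seed Integer seed.
#' @param bird_id Identifier stamped on response events.
#' @param sex Sex of the responding bird (sets the default composition).
#' @param background_rate Spontaneous events/s over the trial span (0 = none).
#' @param call_duration_s Duration stamped on response events.
#' @return CallEvent data.frame sorted by onset.
#' @export
generate_playback_responses <- function(schedule, model, seed = 1L,
                                        bird_id = "focal", sex = c("M", "F"),
                                        background_rate = 0,
                                        call_duration_s = 0.09) {
  sex <- match.arg(sex)
  stopifnot(inherits(model, "exchange_model"),
            all(c("emission_s", "familiarity") %in% names(schedule)))
  set.seed(split_seed(seed, "synthetic/playback-responses"))
  comp <- model$composition
  if (is.null(comp)) comp <- default_answer_composition(sex)

  p <- fam_param(model$answer_prob, schedule$familiarity)
  mu <- fam_param(model$answer_latency_mean, schedule$familiarity)
  answered <- stats::runif(nrow(schedule)) < p
  n_a <- sum(answered)
  events <- empty_call_events()
  if (n_a > 0L) {
    lags <- rep(NA_real_, n_a)
    mu_a <- mu[answered]
    for (m in unique(mu_a)) {   # one truncated-normal stream per latency mean
      idx <- which(mu_a == m)
      lags[idx] <- rtruncnorm(length(idx), m, model$answer_latency_sd,
                              model$latency_bounds[1], model$latency_bounds[2])
    }
    on <- schedule$emission_s[answered] + lags
    events <- data.frame(bird_id = bird_id,
                         call_type = sample(names(comp), n_a, TRUE, comp),
                         onset_s = on, offset_s = on + call_duration_s,
                         stringsAsFactors = FALSE)
  }
  if (background_rate > 0) {
    span <- max(schedule$emission_s) + model$latency_bounds[2]
    n_b <- stats::rpois(1, background_rate * span)
    if (n_b > 0) {
      on <- stats::runif(n_b, 0, span)
      bg <- data.frame(bird_id = bird_id,
                       call_type = sample(names(comp), n_b, TRUE, comp),
                       onset_s = on, offset_s = on + call_duration_s,
                       stringsAsFactors = FALSE)
      events <- rbind(events, bg)
    }
  }
  events <- events[order(events$onset_s), ]
  rownames(events) <- NULL
  events
}

#' Write a CallEvent table to CSV
#'
#' @param events CallEvent data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_events <- function(events, path) {
  utils::write.csv(events[, c("bird_id", "call_type", "onset_s", "offset_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a CallEvent table from CSV
#'
#' @param path CSV path with columns `bird_id`, `call_type`, `onset_s`,
#'   `offset_s`.
#' @return CallEvent data.frame sorted by onset.
#' @export
read_call_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("bird_id", "call_type", "onset_s", "offset_s") %in% names(ev)))
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  ev
}

#' Write / read a simulation setup as YAML or JSON
#'
#' Serialises a [sim_config()] and [exchange_model()] pair under their
#' field names, so a simulation is fully described by one small text file.
#' The format follows the file extension: `.yml`/`.yaml` or `.json`.
#'
#' @param config A [sim_config()].
#' @param model An [exchange_model()].
#' @param path Output path (`.yaml`, `.yml` or `.json`).
#' @return `path` invisibly; `read_sim_setup` returns a list with
#'   `config` and `model`.
#' @export
write_sim_setup <- function(config, model, path) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "exchange_model"))
  em <- unclass(model)
  # named vectors serialise as maps so familiarity names survive the trip
  for (fld in c("answer_prob", "answer_latency_mean", "composition")) {
    if (!is.null(em[[fld]]) && !is.null(names(em[[fld]]))) {
      em[[fld]] <- as.list(em[[fld]])
    }
  }
  payload <- list(sim_config = unclass(config), exchange_model = em)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' required")
    yaml::write_yaml(payload, path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("package 'jsonlite' required")
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension: ", path)
  }
  invisible(path)
}

#' @rdname write_sim_setup
#' @export
read_sim_setup <- function(path) {
  payload <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' required")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("package 'jsonlite' required")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension: ", path)
  }
  sc <- payload$sim_config
  em <- payload$exchange_model
  list(config = sim_config(seed = sc$seed, n_pairs = sc$n_pairs,
                           session_duration_s = sc$session_duration_s,
                           trials = sc$trials),
       model = exchange_model(
         base_call_rate = em$base_call_rate,
         answer_prob = unlist(em$answer_prob),
         answer_latency_mean = unlist(em$answer_latency_mean),
         answer_latency_sd = em$answer_latency_sd,
         latency_bounds = unlist(em$latency_bounds),
         composition = if (!is.null(em$composition)) unlist(em$composition)))
}
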