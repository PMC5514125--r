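#' Build a playback trial schedule
#'
#' One trial is a sequence of call-type blocks (one per type in the
#' subject's roster), each block holding three series, one per familiarity
#' level (mate `m`, familiar `f`, unfamiliar `uf`). A series presents the 3
#' exemplar stimuli of that (call type, familiarity), each repeated 100
#' times, in random order: 300 emissions. Inter-call intervals are uniform
#' on 2 +/- 0.5 s, series within a block are separated by 70 +/- 10 s of
#' silence and blocks by 130 +/- 10 s. Block order, familiarity order
#' within each block, and emission order are all drawn uniformly at random
#' from the seed. Male subjects hear 5 female call types (15 series);
#' female subjects additionally hear song (18 series).
#'
#' @param sex Subject sex, `"M"` or `"F"`.
#' @param exemplars Data.frame with columns `call_type`, `familiarity`,
#'   `stimulus_id`: exactly 3 stimulus IDs per (call type in roster,
#'   familiarity level). `NULL` builds placeholder IDs.
#' @param seed Integer seed.
#' @param n_repeats Repeats per exemplar (default 100).
#' @param n_exemplars Exemplars per series (default 3).
#' @param gap_range Inter-call interval range, s.
#' @param series_gap_range Inter-series silence range, s.
#' @param block_gap_range Inter-block silence range, s.
#' @return Data.frame of class `playback_schedule` with columns
#'   `emission_s`, `block_idx`, `series_idx`, `call_type`, `familiarity`,
#'   `stimulus_id`; `series_idx` numbers series in broadcast order (the
#'   playback-order covariate of the response models).
#' @export
build_schedule <- function(sex = c("M", "F"), exemplars = NULL, seed = 1L,
                           n_repeats = 100L, n_exemplars = 3L,
                           gap_range = c(1.5, 2.5),
                           series_gap_range = c(60, 80),
                           block_gap_range = c(120, 140)) {
  sex <- match.arg(sex)
  roster <- call_type_roster(sex)
  fams <- c("m", "f", "uf")
  if (is.null(exemplars)) {
    exemplars <- expand.grid(call_type = roster, familiarity = fams,
                             exemplar = seq_len(n_exemplars),
                             stringsAsFactors = FALSE)
    exemplars$stimulus_id <- with(exemplars,
                                  paste(call_type, familiarity, exemplar, sep = "_"))
  }
  stopifnot(all(c("call_type", "familiarity", "stimulus_id") %in% names(exemplars)))
  need <- expand.grid(call_type = roster, familiarity = fams,
                      stringsAsFactors = FALSE)
  have <- stats::aggregate(stimulus_id ~ call_type + familiarity,
                           exemplars, function(x) length(unique(x)))
  mg <- merge(need, have, all.x = TRUE)
  bad <- is.na(mg$stimulus_id) | mg$stimulus_id < n_exemplars
  if (any(bad)) {
    stop("missing exemplars for: ",
         paste(mg$call_type[bad], mg$familiarity[bad], sep = "/", collapse = ", "))
  }

  set.seed(split_seed(seed, paste0("playback/schedule/", sex)))
  block_order <- sample(roster)
  t_now <- 0
  series_counter <- 0L
  rows <- vector("list", length(roster) * 3L)
  for (b in seq_along(block_order)) {
    ct <- block_order[b]
    fam_order <- sample(fams)
    for (fam in fam_order) {
      series_counter <- series_counter + 1L
      ids <- unique(exemplars$stimulus_id[exemplars$call_type == ct &
                                            exemplars$familiarity == fam])[seq_len(n_exemplars)]
      order_ids <- sample(rep(ids, each = n_repeats))
      n_em <- length(order_ids)
      gaps <- stats::runif(n_em - 1L, gap_range[1], gap_range[2])
      times <- t_now + c(0, cumsum(gaps))
      rows[[series_counter]] <- data.frame(
        emission_s = times, block_idx = b, series_idx = series_counter,
        call_type = ct, familiarity = fam, stimulus_id = order_ids,
        stringsAsFactors = FALSE)
      t_now <- times[n_em]
      # silence before next series or block
      is_last_series <- fam == fam_order[3L]
      gap <- if (is_last_series) {
        stats::runif(1, block_gap_range[1], block_gap_range[2])
      } else {
        stats::runif(1, series_gap_range[1], series_gap_range[2])
      }
      t_now <- t_now + gap
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("playback_schedule", "data.frame")
  out
}

#' Serialise / read a playback schedule as CSV
#'
#' @param schedule A schedule from [build_schedule()].
#' @param path Output path.
#' @return `path` invisibly; `read_schedule` returns the schedule.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sch <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(sch) <- c("playback_schedule", "data.frame")
  sch
}

#' High-pass filter a stimulus waveform
#'
#' 4th-order Butterworth high-pass (default edge 85 Hz) applied forward and
#' backward (zero phase). Exposed separately from [preprocess_stimulus()]
#' so the filtering stage can be characterised on its own.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Hz.
#' @param cutoff_hz High-pass edge.
#' @return Filtered waveform.
#' @export
highpass_stimulus <- function(samples, sample_rate, cutoff_hz = 85) {
  bf <- signal::butter(4, cutoff_hz / (sample_rate / 2), type = "high")
  n <- length(samples)
  # zero-padding suppresses filtfilt edge transients, which for an 85 Hz
  # edge extend over several hundred samples; 8 cutoff periods suffice
  np <- ceiling(8 * sample_rate / cutoff_hz)
  xp <- c(numeric(np), samples, numeric(np))
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1L):(np + n)]
}

#' Preprocess a playback stimulus
#'
#' The stimulus chain applied to every extracted call before broadcast:
#' raised-cosine fades at both ends, 85 Hz high-pass (4th-order
#' Butterworth, zero phase), and peak amplitude normalised to a ceiling of
#' -0.1 dBFS (maximal sample value). Fades are applied as an envelope cap
#' (gain = min(1, cap / running max |x|)) with the cap scaled to the
#' signal's own peak, so the fade is scale-invariant and a no-op on
#' already-faded edges; fading precedes filtering (abrupt call edges
#' splatter energy below the cutoff, which the filter would otherwise
#' remove and a later fade partially re-create) and is re-applied after it
#' to cap any residual filter transient. For stimuli whose energy lies
#' above the filter's transition band the whole chain is idempotent.
#'
#' @param samples Numeric waveform (not all zero).
#' @param sample_rate Hz.
#' @param cutoff_hz High-pass edge (Hz).
#' @param ceiling_dbfs Peak normalisation target in dBFS (<= 0).
#' @param fade_s Fade length at each end, s.
#' @return Processed waveform with peak `10^(ceiling_dbfs/20)`.
#' @export
preprocess_stimulus <- function(samples, sample_rate, cutoff_hz = 85,
                                ceiling_dbfs = -0.1, fade_s = 0.005) {
  if (all(samples == 0)) stop("cannot normalize silence")
  nf <- min(round(fade_s * sample_rate), length(samples) %/% 2)
  y <- apply_envelope_fades(samples, nf)
  y <- highpass_stimulus(y, sample_rate, cutoff_hz)
  y <- apply_envelope_fades(y, nf)
  y / max(abs(y)) * 10^(ceiling_dbfs / 20)
}

# internal: raised-cosine envelope-cap fades, cap relative to the signal's
# own peak. If the global peak itself sits in a fade window the cap lowers
# it, so iterate with the reduced peak until the peak is attained outside
# the caps (fixed point); then re-application is a no-op.
apply_envelope_fades <- function(y, nf) {
  if (nf <= 1L) return(y)
  n <- length(y)
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 1) / (nf - 1))  # 0 -> 1
  head_idx <- seq_len(nf)
  tail_idx <- seq(n - nf + 1L, n)
  for (i in 1:50) {
    pk <- max(abs(y))
    env_in <- cummax(abs(y[head_idx]))
    y[head_idx] <- y[head_idx] *
      pmin(1, pk * ramp / pmax(env_in, .Machine$double.eps))
    env_out <- rev(cummax(rev(abs(y[tail_idx]))))
    y[tail_idx] <- y[tail_idx] *
      pmin(1, pk * rev(ramp) / pmax(env_out, .Machine$double.eps))
    if (max(abs(y)) >= pk * (1 - 1e-12)) break
  }
  y
}
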