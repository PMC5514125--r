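#' Short-time power spectra of a waveform
#'
#' Hann-windowed short-time Fourier transform returning per-frame power
#' spectra up to Nyquist. Defaults (512-sample window, 50% overlap at
#' 44.1 kHz) give ~86 Hz bins and ~5.8 ms hops, adequate for calls in the
#' 400-2500 Hz fundamental band.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Hz.
#' @param window_size Samples per analysis window.
#' @param overlap Fractional overlap between successive windows.
#' @return List with `power` (bins x frames matrix), `freq` (Hz per bin)
#'   and `hop_s` (frame advance in seconds).
#' @export
stft_power <- function(samples, sample_rate, window_size = 512, overlap = 0.5) {
  n <- length(samples)
  if (n < window_size) stop("segment shorter than one analysis window")
  hop <- max(1L, round(window_size * (1 - overlap)))
  starts <- seq(1L, n - window_size + 1L, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(window_size) / (window_size + 1))  # Hann
  nb <- window_size %/% 2 + 1L
  pw <- vapply(starts, function(s) {
    x <- samples[s:(s + window_size - 1L)] * win
    abs(stats::fft(x)[seq_len(nb)])^2
  }, numeric(nb))
  pw <- matrix(pw, nrow = nb)
  list(power = pw,
       freq = (seq_len(nb) - 1L) * sample_rate / window_size,
       hop_s = hop / sample_rate)
}

#' Wiener entropy of a power spectrum
#'
#' Ratio of the geometric to the arithmetic mean of the power bins, on a
#' linear [0, 1] scale: 1 for a flat (white-noise) spectrum, approaching 0
#' for a pure tone. Invariant to scaling of the spectrum. Set `log_scale`
#' for the dB-style `log` of the ratio used by some sonogram software.
#'
#' @param power_spectrum Non-negative numeric vector of power bins.
#' @param log_scale If `TRUE`, return `log` of the ratio (in (-Inf, 0]).
#' @return Scalar entropy.
#' @export
#' @examples
#' wiener_entropy(rep(1, 64))        # flat -> 1
#' wiener_entropy(c(1, 2, 4))        # 6/7
wiener_entropy <- function(power_spectrum, log_scale = FALSE) {
  p <- power_spectrum
  if (any(p < 0)) stop("power spectrum must be non-negative")
  am <- mean(p)
  if (am == 0) stop("silent frame")
  gm <- if (any(p == 0)) 0 else exp(mean(log(p)))
  w <- gm / am
  if (log_scale) log(w) else w
}

# internal: lowest prominent local maximum of a power spectrum above a
# high-pass edge; the "first peak" fundamental estimate
first_spectral_peak <- function(power, freq, min_freq = 85,
                                prominence = 0.05) {
  usable <- which(freq >= min_freq)
  if (length(usable) < 3L) return(NA_real_)
  thr <- prominence * max(power[usable])
  for (i in usable[c(-1, -length(usable))]) {
    if (power[i] >= thr && power[i] > power[i - 1L] && power[i] >= power[i + 1L]) {
      return(freq[i])
    }
  }
  freq[usable[which.max(power[usable])]]
}

#' Estimate the fundamental frequency of a segment
#'
#' Default method: lowest prominent peak of the time-averaged power
#' spectrum above the 85 Hz high-pass edge ("first peak"). The cepstral
#' alternative picks the dominant quefrency instead, which is more robust
#' when the first harmonic is weak.
#'
#' @param seg A `vocal_segment` (or list with `samples` and `sample_rate`).
#' @param method `"first_peak"` or `"cepstrum"`.
#' @param window_size,overlap FFT parameters, see [stft_power()].
#' @param min_freq High-pass edge in Hz.
#' @return Estimated fundamental in Hz.
#' @export
estimate_fundamental <- function(seg, method = c("first_peak", "cepstrum"),
                                 window_size = 512, overlap = 0.5,
                                 min_freq = 85) {
  method <- match.arg(method)
  sp <- stft_power(seg$samples, seg$sample_rate, window_size, overlap)
  if (method == "first_peak") {
    return(first_spectral_peak(rowMeans(sp$power), sp$freq, min_freq))
  }
  # cepstrum of the mean log spectrum
  ms <- rowMeans(sp$power)
  ms[ms <= 0] <- min(ms[ms > 0]) * 1e-6
  ceps <- abs(stats::fft(log(ms)))
  q <- seq_along(ceps) - 1L                # quefrency index
  fs_bins <- seg$sample_rate / window_size # Hz per spectral bin
  f_cand <- (length(ms) * fs_bins) / q     # implied fundamental
  ok <- which(q > 0 & f_cand >= min_freq & f_cand <= seg$sample_rate / 4)
  f_cand[ok[which.max(ceps[ok])]]
}

#' Extract sound segments from a waveform by amplitude threshold
#'
#' Emulates threshold-based call extraction: the absolute amplitude is
#' smoothed with a short moving average, maximal runs at or above the
#' threshold are taken, runs separated by less than `min_gap_s` are merged,
#' and runs shorter than `min_dur_s` are discarded. Segments are
#' non-overlapping and time-ordered.
#'
#' @param samples Numeric waveform.
#' @param sample_rate Hz.
#' @param threshold Envelope amplitude threshold (> 0).
#' @param min_gap_s Merge runs separated by less than this (s).
#' @param min_dur_s Discard runs shorter than this (s).
#' @param smooth_s Moving-average envelope window (s).
#' @return List of `vocal_segment`s with `onset_s`/`offset_s` within the
#'   source waveform; empty list for silent input.
#' @export
segment_sounds <- function(samples, sample_rate, threshold,
                           min_gap_s = 0.02, min_dur_s = 0.01,
                           smooth_s = 0.002) {
  stopifnot(threshold > 0)
  if (length(samples) == 0L) return(list())
  w <- max(1L, round(smooth_s * sample_rate))
  env <- as.numeric(stats::filter(abs(samples), rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  above <- env >= threshold
  if (!any(above)) return(list())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs closer than min_gap_s
  if (nrow(runs) > 1L) {
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)]) / sample_rate
      if (gap < min_gap_s) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  runs <- runs[(runs$end - runs$start + 1L) / sample_rate >= min_dur_s, ]
  lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    structure(list(samples = samples[s:e], sample_rate = sample_rate,
                   onset_s = (s - 1L) / sample_rate, offset_s = e / sample_rate,
                   bird_id = NA_character_, call_type = NA_character_),
              class = "vocal_segment")
  })
}

#' Compute the six call-sorting features of a segment
#'
#' Per-window short-time spectra give average frequency (spectral
#' centroid), modal frequency (most frequent per-window peak bin),
#' fundamental frequency (first prominent spectral peak above 85 Hz) and
#' Wiener entropy; each spectral measure is reported as its mean and SD
#' across analysis windows, plus the segment duration - the six sorting
#' parameters (and their SDs) used to cluster calls into types.
#'
#' @param seg A `vocal_segment`.
#' @param window_size,overlap FFT parameters.
#' @return One-row data.frame with columns `average_frequency`,
#'   `modal_frequency`, `fundamental_frequency`, `wiener_entropy`,
#'   `duration`, and `sd_average_frequency`, `sd_modal_frequency`,
#'   `sd_fundamental_frequency`, `sd_wiener_entropy`.
#' @export
compute_sorting_features <- function(seg, window_size = 512, overlap = 0.5) {
  sp <- stft_power(seg$samples, seg$sample_rate, window_size, overlap)
  tot <- colSums(sp$power)
  if (all(tot == 0)) stop("silent segment")
  keep <- tot > 0
  pw <- sp$power[, keep, drop = FALSE]
  tot <- tot[keep]
  centroid <- colSums(pw * sp$freq) / tot
  peak_f <- sp$freq[apply(pw, 2, which.max)]
  fund <- apply(pw, 2, function(p) first_spectral_peak(p, sp$freq))
  went <- apply(pw, 2, wiener_entropy)
  modal <- as.numeric(names(which.max(table(peak_f))))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  data.frame(
    average_frequency = mean(centroid),
    modal_frequency = modal,
    fundamental_frequency = mean(fund, na.rm = TRUE),
    wiener_entropy = mean(went),
    duration = seg$offset_s - seg$onset_s,
    sd_average_frequency = sd0(centroid),
    sd_modal_frequency = sd0(peak_f),
    sd_fundamental_frequency = sd0(fund[!is.na(fund)]),
    sd_wiener_entropy = sd0(went)
  )
}

#' Compute the 14 sonogram spectral features of a segment
#'
#' Statistics of the time-averaged, sum-normalised power spectrum treated
#' as a probability distribution over frequency - mean frequency and its
#' SD, median, skew, kurtosis, spectral flatness (Wiener entropy of the
#' mean spectrum), Shannon entropy (normalised to [0, 1]), mode frequency -
#' plus the precision of the mean-frequency estimate across windows, peak
#' frequency of the max-hold spectrum, first-peak fundamental, dominant
#' frequency (mean of per-window peak frequencies) and its maximum, and
#' the segment duration: 14 features per call.
#'
#' @param seg A `vocal_segment`.
#' @param window_size,overlap FFT parameters.
#' @return One-row data.frame with columns `mean_freq`, `sd_freq`,
#'   `median_freq`, `skew`, `kurtosis`, `spectral_flatness`, `entropy`,
#'   `mode_freq`, `freq_precision`, `peak_freq`, `fundamental_freq`,
#'   `dominant_freq`, `max_dominant_freq`, `duration`.
#' @export
compute_features14 <- function(seg, window_size = 512, overlap = 0.5) {
  sp <- stft_power(seg$samples, seg$sample_rate, window_size, overlap)
  tot <- colSums(sp$power)
  if (all(tot == 0)) stop("silent segment")
  pw <- sp$power[, tot > 0, drop = FALSE]
  ms <- rowMeans(pw)
  s <- ms / sum(ms)
  f <- sp$freq
  m1 <- sum(f * s)
  v <- sum((f - m1)^2 * s)
  sdv <- sqrt(v)
  cum <- cumsum(s)
  centroid <- colSums(pw * f) / colSums(pw)
  peak_f_frames <- f[apply(pw, 2, which.max)]
  nz <- s[s > 0]
  data.frame(
    mean_freq = m1,
    sd_freq = sdv,
    median_freq = f[which(cum >= 0.5)[1]],
    skew = if (sdv > 0) sum((f - m1)^3 * s) / sdv^3 else 0,
    kurtosis = if (sdv > 0) sum((f - m1)^4 * s) / sdv^4 else 0,
    spectral_flatness = wiener_entropy(ms),
    entropy = -sum(nz * log(nz)) / log(length(s)),
    mode_freq = f[which.max(s)],
    freq_precision = if (ncol(pw) > 1L) stats::sd(centroid) / sqrt(ncol(pw)) else 0,
    peak_freq = f[which.max(apply(pw, 1, max))],
    fundamental_freq = first_spectral_peak(ms, f),
    dominant_freq = mean(peak_f_frames),
    max_dominant_freq = max(peak_f_frames),
    duration = seg$offset_s - seg$onset_s
  )
}

#' Cluster calls into types by k-means on sorting features
#'
#' Features are z-scored per dimension (zero-variance dimensions dropped),
#' partitioned by k-means with multiple restarts, and segments far from
#' every centroid are flagged as noise: a segment is labelled `NOISE` when
#' its distance to the nearest centroid both exceeds the stated quantile of
#' all such distances and lies more than 3 SDs above their mean (so tight,
#' well-formed clusters produce no spurious noise). Manual refinements can
#' be supplied as a data.frame of `segment_id` to `label` overrides.
#'
#' @param features Data.frame of numeric feature columns (one row per
#'   segment), e.g. rows of [compute_sorting_features()].
#' @param k Number of clusters (>= 1, <= number of segments).
#' @param seed Integer seed (restarts are stochastic).
#' @param noise_quantile Distance quantile above which segments may be
#'   flagged `NOISE`.
#' @param nstart k-means restarts.
#' @param manual_edits Optional data.frame with columns `segment_id`,
#'   `label` applied after clustering.
#' @return Data.frame with `segment_id`, `cluster` (label or `"NOISE"`) and
#'   `centroid_distance`.
#' @export
cluster_calls <- function(features, k, seed = 1L, noise_quantile = 0.99,
                          nstart = 10L, manual_edits = NULL) {
  x <- as.matrix(features[, vapply(features, is.numeric, logical(1)), drop = FALSE])
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(x)) stop(sprintf("k = %d exceeds number of segments (%d)", k, nrow(x)))
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (any(keep)) {
    z <- scale(x[, keep, drop = FALSE])
  } else {
    z <- matrix(0, nrow(x), 1L)  # all segments identical
  }
  set.seed(split_seed(seed, "acoustics/cluster"))
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  d <- sqrt(rowSums((z - km$centers[km$cluster, , drop = FALSE])^2))
  labels <- as.character(km$cluster)
  if (any(d > 0)) {
    thr_q <- stats::quantile(d, noise_quantile, names = FALSE)
    thr_sd <- mean(d) + 3 * stats::sd(d)
    labels[d > thr_q & d > thr_sd] <- "NOISE"
  }
  out <- data.frame(segment_id = if (!is.null(rownames(features)))
    rownames(features) else as.character(seq_len(nrow(x))),
    cluster = labels, centroid_distance = d,
    stringsAsFactors = FALSE)
  if (!is.null(manual_edits)) {
    stopifnot(all(c("segment_id", "label") %in% names(manual_edits)))
    idx <- match(manual_edits$segment_id, out$segment_id)
    out$cluster[idx[!is.na(idx)]] <- manual_edits$label[!is.na(idx)]
  }
  out
}
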