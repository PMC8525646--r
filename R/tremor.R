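#' Detect high-frequency tremor bursts in a force-plate recording
#'
#' Operationalizes "periodic bursts of platform vibration in a fixed
#' frequency band": the signal is band-passed to `band` (4th-order
#' Butterworth, zero-phase), an RMS amplitude envelope is computed over a
#' sliding window, and a burst is a run where the envelope exceeds
#' `baseline mean + k * SD` for at least `min_dur`. Baseline statistics come
#' from the lowest-power third of 1-s windows, so they are not contaminated
#' by the bursts themselves and the rule is invariant to rescaling the whole
#' signal. Each burst's peak frequency is read from the periodogram of the
#' raw (unfiltered) segment. The animal is called tremor-positive when at
#' least `min_bursts` bursts occur.
#'
#' A candidate event only counts as a tremor burst if the vibration it
#' contains is actually in the band: the in-band fraction of the raw
#' segment's power must reach `band_frac` (default 0.5). Broadband noise
#' excursions carry only a few percent of their power in a 10 Hz band and
#' are rejected, while a genuine burst at signal-to-noise 10 is almost
#' entirely in-band. Above-threshold runs separated by gaps shorter than
#' `merge_gap` are merged before the duration test (the envelope can dip
#' briefly at burst onset/offset transients).
#'
#' @param r a `tremor_recording` (list with `signal`, `fs`; see
#'   [gen_tremor_signal()]), at least 10 s long.
#' @param band numeric `c(f_lo, f_hi)` in Hz, default `c(55, 65)`; must lie
#'   below the Nyquist frequency.
#' @param k threshold in baseline SDs (default 3).
#' @param min_dur minimum burst duration (s), default 0.1.
#' @param min_bursts bursts required for a positive call (default 3).
#' @param env_window RMS envelope window (s), default 0.05.
#' @param merge_gap maximum gap between runs that are merged (s), default
#'   0.05.
#' @param band_frac minimum in-band fraction of segment power for a burst
#'   (default 0.5).
#' @return A `tremor_call` list: `events` (data.frame `start_s`, `end_s`,
#'   `peak_freq_hz`, `band_power`, `band_fraction`; sorted, non-overlapping,
#'   within the recording), `positive`, `n_events`, `band`, `threshold`,
#'   labels.
#' @export
detect_tremor <- function(r, band = c(55, 65), k = 3, min_dur = 0.1,
                          min_bursts = 3, env_window = 0.05,
                          merge_gap = 0.05, band_frac = 0.5) {
  x <- r$signal; fs <- r$fs
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[2] >= fs / 2) stop("band must lie below the Nyquist frequency")
  dur <- length(x) / fs
  if (dur < 10) stop("recording must be at least 10 s long")
  if (any(!is.finite(x))) stop("non-finite samples")

  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  env <- sqrt(moving_average(y^2, max(1L, round(env_window * fs))))

  # baseline from the lowest-power third of 1 s windows
  wlen <- as.integer(fs)
  nwin <- floor(length(env) / wlen)
  wid <- rep(seq_len(nwin), each = wlen)
  wpow <- tapply(env[seq_len(nwin * wlen)]^2, wid, mean)
  quiet <- as.integer(names(sort(wpow)[seq_len(max(1, floor(nwin / 3)))]))
  base_env <- env[seq_len(nwin * wlen)][wid %in% quiet]
  thr <- mean(base_env) + k * sd(base_env)

  above <- env > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sel <- which(runs$values)
  events <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       peak_freq_hz = numeric(0), band_power = numeric(0),
                       band_fraction = numeric(0))
  if (length(sel)) {
    # merge runs separated by gaps shorter than merge_gap
    i0 <- starts[sel]; i1 <- ends[sel]
    merged <- list(c(i0[1], i1[1]))
    for (j in seq_along(i0)[-1]) {
      last <- merged[[length(merged)]]
      if (i0[j] - last[2] <= merge_gap * fs) {
        merged[[length(merged)]] <- c(last[1], i1[j])
      } else merged[[length(merged) + 1]] <- c(i0[j], i1[j])
    }
    for (mv in merged) {
      if (mv[2] - mv[1] + 1 < min_dur * fs) next
      seg <- x[mv[1]:mv[2]] - mean(x[mv[1]:mv[2]])
      n <- length(seg)
      pw <- Mod(fft(seg))^2 / n
      freq <- (seq_len(n) - 1) * fs / n
      half <- freq > 5 & freq <= fs / 2        # skip DC / drift
      inb <- freq >= band[1] & freq <= band[2]
      frac <- sum(pw[inb]) / sum(pw[half])
      if (frac < band_frac) next               # broadband excursion, not a burst
      pk <- freq[half][which.max(pw[half])]
      events <- rbind(events, data.frame(
        start_s = (mv[1] - 1) / fs, end_s = mv[2] / fs,
        peak_freq_hz = pk, band_power = mean(env[mv[1]:mv[2]]^2),
        band_fraction = frac))
    }
  }
  events$end_s <- pmin(events$end_s, dur)
  structure(list(events = events, n_events = nrow(events),
                 positive = nrow(events) >= min_bursts,
                 band = band, threshold = thr, k = k, min_dur = min_dur,
                 min_bursts = min_bursts,
                 animal_id = r$animal_id, genotype = r$genotype),
            class = "tremor_call")
}

#' Per-genotype tremor incidence
#'
#' Percent of animals called tremor-positive within each genotype.
#'
#' @param calls a data.frame with columns `genotype` and `positive`
#'   (logical), or a list of `tremor_call` objects.
#' @param digits rounding, default nearest integer.
#' @return data.frame `genotype`, `n`, `n_positive`, `percent_positive`.
#' @export
incidence_summary <- function(calls, digits = 0) {
  if (!is.data.frame(calls)) {
    calls <- do.call(rbind, lapply(calls, function(cl)
      data.frame(genotype = cl$genotype, positive = cl$positive)))
  }
  stopifnot(all(c("genotype", "positive") %in% names(calls)))
  if (!nrow(calls)) stop("no calls supplied")
  ag <- aggregate(positive ~ genotype, calls,
                  function(p) c(n = length(p), pos = sum(p)))
  out <- data.frame(genotype = ag$genotype,
                    n = ag$positive[, "n"], n_positive = ag$positive[, "pos"])
  out$percent_positive <- round(100 * out$n_positive / out$n, digits)
  out
}
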