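#' Simulate a somatic calcium trace with planted transients
#'
#' Baseline 1.0 plus Poisson-timed exponential-decay transients plus white
#' noise. The defaults mirror typical in vivo GCaMP imaging of cortical
#' neurons at 7.5 Hz (1800 frames in 4 minutes).
#'
#' @param rate event rate in events/min.
#' @param amp transient amplitude in dF/F units.
#' @param tau decay time constant in seconds.
#' @param fs sampling rate in Hz.
#' @param duration trace length in seconds.
#' @param noise_sd white-noise SD (same units as the trace).
#' @param seed RNG seed.
#' @return numeric trace of `round(fs * duration)` samples with attributes
#'   `fs`, `event_times` (s) and `event_amplitudes`.
#' @export
simulate_calcium <- function(rate, amp = 0.5, tau = 1.5, fs = 7.5,
                             duration = 240, noise_sd = 0.02, seed = 1) {
  if (fs <= 0) stopf("fs must be > 0")
  with_rng(seed, {
    n <- round(fs * duration)
    t <- (seq_len(n) - 1) / fs
    n_ev <- rpois(1, rate * duration / 60)
    ev_t <- sort(runif(n_ev, 0, duration))
    tr <- rep(1.0, n)
    for (te in ev_t) {
      k <- t >= te
      tr[k] <- tr[k] + amp * exp(-(t[k] - te) / tau)
    }
    tr <- tr + rnorm(n, 0, noise_sd)
    attr(tr, "fs") <- fs
    attr(tr, "event_times") <- ev_t
    attr(tr, "event_amplitudes") <- rep(amp, n_ev)
    tr
  })
}

#' Delta-F-over-F normalisation with a rolling-percentile baseline
#'
#' `F0` is a centred rolling percentile of the raw trace (default: 20th
#' percentile over 30 s) and `dff = (F - F0) / F0`.
#'
#' @param trace numeric fluorescence trace.
#' @param fs sampling rate in Hz (taken from the trace attribute if
#'   missing).
#' @param baseline_window_s rolling window length in seconds.
#' @param baseline_percentile percentile (0-1) used as baseline.
#' @return dff series with attribute `fs`.
#' @export
dff <- function(trace, fs = attr(trace, "fs"), baseline_window_s = 30,
                baseline_percentile = 0.2) {
  if (is.null(fs)) stopf("sampling rate fs is required")
  n <- length(trace)
  win <- max(3L, round(baseline_window_s * fs))
  if (win > n) stopf("baseline window (%g s) exceeds trace duration", baseline_window_s)
  f0 <- zoo::rollapply(as.numeric(trace), width = win,
                       FUN = quantile, probs = baseline_percentile,
                       names = FALSE, partial = TRUE, align = "center")
  if (any(f0 <= 0)) stopf("baseline F0 is not strictly positive; dF/F undefined")
  out <- (as.numeric(trace) - f0) / f0
  attr(out, "fs") <- fs
  out
}

#' Detect calcium transients in a dF/F series
#'
#' Events are excursions above `k_sd` robust SDs (MAD-based) of the series
#' lasting at least `min_dur` seconds. Because transients decay slowly, a
#' single suprathreshold excursion may contain several events riding on
#' each other's tails; within an excursion, a local maximum preceded by a
#' single-sample rise of at least `prominence` (transient onsets are much
#' faster than the sampling interval, noise wiggles are not) starts a new
#' event. The event amplitude is the peak value and the event time its
#' peak time.
#'
#' @param x dff series (attribute `fs` or argument).
#' @param fs sampling rate in Hz.
#' @param k_sd threshold in robust SD units (default 3).
#' @param min_dur minimum suprathreshold duration in seconds (default 0.4).
#' @param prominence valley depth splitting stacked events; defaults to
#'   the detection threshold.
#' @return data.frame `time_s`, `amplitude`, `duration_s`; attribute
#'   `frequency_per_min` = 60 * events / duration.
#' @export
detect_transients <- function(x, fs = attr(x, "fs"), k_sd = 3,
                              min_dur = 0.4, prominence = NULL) {
  if (is.null(fs)) stopf("sampling rate fs is required")
  if (!length(x)) stopf("empty trace")
  if (k_sd <= 0) stopf("k_sd must be > 0")
  v <- as.numeric(x)
  thr <- k_sd * mad(v)
  prom <- prominence %||% thr
  above <- v > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths >= max(1L, round(min_dur * fs)))
  rows <- list()
  for (k in which(keep)) {
    seg <- starts[k]:ends[k]
    pk <- split_peaks(v[seg], prom)
    for (p_ in pk) {
      rows[[length(rows) + 1]] <- data.frame(
        time_s = (seg[p_] - 1) / fs,
        amplitude = v[seg[p_]],
        duration_s = r$lengths[k] / fs / length(pk))
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_s = numeric(), amplitude = numeric(),
               duration_s = numeric())
  attr(ev, "frequency_per_min") <- 60 * nrow(ev) / (length(v) / fs)
  attr(ev, "threshold") <- thr
  ev
}

# indices of event peaks within a suprathreshold segment: a local maximum
# belongs to a new event when the trace rose by >= `prom` in one sample
# somewhere since the previous kept peak (onset-jump criterion)
split_peaks <- function(s, prom) {
  n <- length(s)
  if (n == 1) return(list(1L))
  up <- c(TRUE, diff(s) >= 0)
  down <- c(diff(s) <= 0, TRUE)
  ispk <- which(up & down)
  if (!length(ispk)) ispk <- which.max(s)
  kept <- ispk[1]
  for (p_ in ispk[-1]) {
    last <- kept[length(kept)]
    jump <- max(diff(s[last:p_]))
    if (jump >= prom) {
      kept <- c(kept, p_)
    } else if (s[p_] > s[last]) {
      kept[length(kept)] <- p_
    }
  }
  as.list(kept)
}

#' Simulate an LFP trace: 1/f background plus a gamma-band oscillation
#'
#' The trace is synthesised in the frequency domain: a `1/f^alpha` pink
#' background with random phases, normalised to unit variance over the
#' 0.5-100 Hz analysis range, plus independent band-limited noise in
#' `gamma_band` carrying exactly `gamma_power` expected variance. The
#' attributes record the planted decomposition so recovery can be tested.
#'
#' @param fs sampling rate in Hz (default 2000).
#' @param duration seconds.
#' @param gamma_power injected band variance (trace units squared).
#' @param gamma_band frequency interval in Hz (default 30-100).
#' @param pink_exponent alpha of the background.
#' @param seed RNG seed.
#' @return numeric trace with attributes `fs`, `background_band_power`
#'   (expected background variance inside `gamma_band`) and
#'   `injected_band_power`.
#' @export
simulate_lfp <- function(fs = 2000, duration = 60, gamma_power = 0,
                         gamma_band = c(30, 100), pink_exponent = 1,
                         seed = 1) {
  if (gamma_band[2] >= fs / 2 || gamma_band[1] <= 0) {
    stopf("gamma_band must lie strictly inside (0, fs/2)")
  }
  with_rng(seed, {
    n <- 2L * (round(fs * duration) %/% 2L)     # even length
    freqs <- seq(0, fs / 2, by = fs / n)        # rfft bin frequencies
    nf <- length(freqs)
    amp <- numeric(nf)
    pos <- freqs > 0
    amp[pos] <- freqs[pos]^(-pink_exponent / 2)
    # With x = (1/n) * sum_k X_k e^{2pi i k t / n} and X_k = A_k * zeta_k
    # (zeta complex, E|zeta|^2 = 1, Hermitian pairs), the expected variance
    # contributed by positive bins is (2/n^2) * sum(A_k^2).
    in_rng <- freqs >= 0.5 & freqs <= 100
    amp <- amp / sqrt(2 * sum(amp[in_rng]^2) / n^2)  # unit background variance
    gb <- freqs >= gamma_band[1] & freqs <= gamma_band[2]
    gamp <- numeric(nf)
    if (gamma_power > 0) {
      gamp[gb] <- sqrt(gamma_power * n^2 / (2 * sum(gb)))
    }
    z1 <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
    z2 <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(2)
    spec <- amp * z1 + gamp * z2
    spec[1] <- 0
    spec[nf] <- complex(real = Re(spec[nf]), imaginary = 0)
    full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
    x <- Re(fft(full, inverse = TRUE)) / n
    bg_band <- 2 * sum(amp[gb]^2) / n^2
    attr(x, "fs") <- fs
    attr(x, "background_band_power") <- bg_band
    attr(x, "injected_band_power") <- gamma_power
    x
  })
}

#' Welch power spectral density of an LFP trace
#'
#' Segment-averaged periodogram (default 2 s segments, 50% overlap, Hann
#' taper), restricted to the 0.5-100 Hz analysis range. The density is
#' one-sided, so the band integral approximates the signal variance in
#' that band (Parseval).
#'
#' @param x numeric trace.
#' @param fs sampling rate in Hz (must exceed 200 Hz so the analysis band
#'   is resolvable).
#' @param segment_s segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @param freq_range analysis range in Hz.
#' @return list of class `lfp_psd` with `freqs` (Hz) and `psd`
#'   (power/Hz), plus the estimation parameters.
#' @export
lfp_psd <- function(x, fs = attr(x, "fs"), segment_s = 2, overlap = 0.5,
                    freq_range = c(0.5, 100)) {
  if (is.null(fs)) stopf("sampling rate fs is required")
  if (fs <= 200) stopf("fs = %g Hz too low: the 0.5-100 Hz band is not resolvable", fs)
  n <- length(x)
  if (n / fs < 4) stopf("trace must be >= 4 s for spectral estimation")
  nseg <- round(segment_s * fs)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- signal::hanning(nseg)
  u <- sum(w^2)
  acc <- 0
  for (s in starts) {
    seg <- as.numeric(x[s:(s + nseg - 1L)])
    seg <- (seg - mean(seg)) * w
    sp <- fft(seg)
    acc <- acc + Mod(sp[1:(nseg %/% 2 + 1)])^2
  }
  pxx <- acc / length(starts) / (fs * u)
  pxx[2:(length(pxx) - 1)] <- 2 * pxx[2:(length(pxx) - 1)]  # one-sided
  freqs <- seq(0, fs / 2, by = fs / nseg)
  keep <- freqs >= freq_range[1] & freqs <= freq_range[2]
  structure(list(freqs = freqs[keep], psd = pxx[keep],
                 fs = fs, segment_s = segment_s, overlap = overlap,
                 freq_range = freq_range),
            class = "lfp_psd")
}

#' Band-integrated LFP power, optionally baseline-normalised
#'
#' Trapezoidal integral of the PSD over `band` (default the 30-100 Hz
#' gamma band). With a `baseline` PSD the ratio
#' `band_power / baseline band_power` is returned, the normalisation used
#' when comparing post-treatment recordings to their own baseline.
#'
#' @param psd an `lfp_psd`.
#' @param band Hz interval.
#' @param baseline optional `lfp_psd` for normalisation.
#' @return band power (or normalised ratio), with attribute `normalized`.
#' @export
band_power <- function(psd, band = c(30, 100), baseline = NULL) {
  if (band[1] < min(psd$freqs) || band[2] > max(psd$freqs)) {
    stopf("band [%g, %g] Hz outside the PSD range [%g, %g] Hz",
          band[1], band[2], min(psd$freqs), max(psd$freqs))
  }
  bp <- function(p) {
    k <- p$freqs >= band[1] & p$freqs <= band[2]
    f <- p$freqs[k]; y <- p$psd[k]
    sum(diff(f) * (head(y, -1) + tail(y, -1)) / 2)
  }
  val <- bp(psd)
  if (!is.null(baseline)) {
    base <- bp(baseline)
    if (base <= 0) stopf("baseline band power is zero; normalisation undefined")
    val <- val / base
    attr(val, "normalized") <- TRUE
  } else {
    attr(val, "normalized") <- FALSE
  }
  val
}
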