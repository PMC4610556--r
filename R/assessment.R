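#' Fatigue states
#'
#' The three recognized states, ordered by severity: `"NF"` (non-fatigue),
#' `"MF"` (moderate fatigue), `"SF"` (severe fatigue).
#'
#' @export
fatigue_states <- function() c("NF", "MF", "SF")

.as_state <- function(x) {
  x <- as.character(x)
  if (!all(x %in% fatigue_states())) {
    rlang::abort("fatigue states must be one of NF, MF, SF",
                 class = "drowsefuse_invalid_input")
  }
  x
}

#' Observer-panel consensus state
#'
#' Three trained observers score each video window 0 (NF), 1 (MF) or 2 (SF);
#' the consensus is the floored mean score,
#' \eqn{s' = \lfloor (s_1 + s_2 + s_3)/3 \rfloor}, mapped back to a state.
#'
#' @param scores Integer vector of exactly three scores in \{0, 1, 2\}.
#' @return `"NF"`, `"MF"` or `"SF"`.
#' @examples
#' observer_consensus(c(1, 2, 2))  # floor(5/3) = 1 -> "MF"
#' @export
observer_consensus <- function(scores) {
  if (length(scores) != 3 || !all(scores %in% 0:2)) {
    rlang::abort("observer scores must be three values in {0, 1, 2}",
                 class = "drowsefuse_invalid_input")
  }
  fatigue_states()[floor(sum(scores) / 3) + 1]
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into Hann-windowed
#' segments (default 2 s, 50 % overlap), each segment's one-sided
#' periodogram is computed, and the segment spectra are averaged.
#'
#' @param x Numeric signal (microvolts).
#' @param fs Sampling rate in Hz.
#' @param seg_sec Segment length in seconds.
#' @param overlap Fractional segment overlap.
#' @return Tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 2, overlap = 0.5) {
  stopifnot(fs > 0, seg_sec > 0, overlap >= 0, overlap < 1)
  L <- round(seg_sec * fs)
  if (length(x) < L) {
    rlang::abort("signal shorter than one Welch segment",
                 class = "drowsefuse_invalid_window")
  }
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1
  psd <- rowMeans(vapply(starts, function(s) {
    seg <- (x[s:(s + L - 1)] - mean(x[s:(s + L - 1)])) * w
    p <- abs(stats::fft(seg))^2 / scale
    p <- p[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist for even L)
    mid <- 2:(nf - if (L %% 2 == 0) 1 else 0)
    p[mid] <- 2 * p[mid]
    p
  }, numeric(nf)))
  tibble::tibble(freq = seq(0, nf - 1) * fs / L, psd = psd)
}

#' Band power of an EEG window
#'
#' Integrates the Welch PSD over the half-open frequency band
#' `[low, high)`.
#'
#' @inheritParams welch_psd
#' @param band Numeric `(low, high)` in Hz.
#' @export
band_power <- function(x, fs, band, seg_sec = 2, overlap = 0.5) {
  stopifnot(length(band) == 2, band[1] >= 0, band[2] > band[1])
  if (band[2] > fs / 2) {
    rlang::abort("band extends above the Nyquist frequency",
                 class = "drowsefuse_invalid_input")
  }
  spec <- welch_psd(x, fs, seg_sec, overlap)
  sel <- spec$freq >= band[1] & spec$freq < band[2]
  df <- spec$freq[2] - spec$freq[1]
  sum(spec$psd[sel]) * df
}

#' EEG band definitions
#'
#' Conventional drowsiness bands: theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-22 Hz.  All configurable.
#'
#' @param theta,alpha,beta Numeric `(low, high)` pairs in Hz.
#' @export
eeg_bands <- function(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 22)) {
  list(theta = theta, alpha = alpha, beta = beta)
}

#' EEG-based fatigue classification
#'
#' Computes the drowsiness index
#' \eqn{r_{\alpha,\theta,\beta} = (P_\alpha + P_\theta)/P_\beta} from Welch
#' band powers and maps it to a state: `r < 3` is NF, `3 <= r < 4` is MF,
#' `r >= 4` is SF.  Slow-wave (theta/alpha) power rises and beta power falls
#' as vigilance drops, so larger ratios indicate deeper fatigue.
#'
#' @inheritParams welch_psd
#' @param bands An [eeg_bands()] list.
#' @return List with `r` (the index) and `state`.
#' @export
eeg_classify <- function(x, fs, bands = eeg_bands(), seg_sec = 2,
                         overlap = 0.5) {
  p_theta <- band_power(x, fs, bands$theta, seg_sec, overlap)
  p_alpha <- band_power(x, fs, bands$alpha, seg_sec, overlap)
  p_beta <- band_power(x, fs, bands$beta, seg_sec, overlap)
  if (p_beta <= 0) {
    rlang::abort("zero beta-band power: degenerate spectrum",
                 class = "drowsefuse_degenerate_spectrum")
  }
  r <- (p_alpha + p_theta) / p_beta
  state <- if (r < 3) "NF" else if (r < 4) "MF" else "SF"
  list(r = r, state = state)
}

#' @rdname eeg_classify
#' @param r A precomputed drowsiness index.
#' @export
classify_eeg_ratio <- function(r) {
  stopifnot(is.numeric(r), all(r >= 0))
  ifelse(r < 3, "NF", ifelse(r < 4, "MF", "SF"))
}

#' Stanford Sleepiness Scale classification
#'
#' Maps the 7-point self-report to a state: 1-2 NF, 3-5 MF, 6-7 SF.
#'
#' @param points Integer in 1..7.
#' @export
sss_classify <- function(points) {
  if (!all(points %in% 1:7)) {
    rlang::abort("SSS points must lie in 1..7",
                 class = "drowsefuse_invalid_input")
  }
  ifelse(points <= 2, "NF", ifelse(points <= 5, "MF", "SF"))
}

#' Three-way ground-truth consensus
#'
#' A labelled window enters the ground-truth set only when the observer
#' panel, the EEG index and the self-report all agree; otherwise the window
#' is marked invalid and discarded.
#'
#' @param obs,eeg,sss Fatigue states (`"NF"`, `"MF"`, `"SF"`), vectorized.
#' @return Character vector: the common state, or `NA` where the three
#'   disagree.
#' @export
assessment_consensus <- function(obs, eeg, sss) {
  obs <- .as_state(obs); eeg <- .as_state(eeg); sss <- .as_state(sss)
  ifelse(obs == eeg & eeg == sss, obs, NA_character_)
}
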