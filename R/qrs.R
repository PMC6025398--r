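## Pan-Tompkins style QRS detection.
##
## Stages: zero-phase Butterworth band-pass (5-15 Hz) -> five-point
## derivative -> squaring -> 150 ms moving-window integration -> adaptive
## dual-threshold peak picking with 200 ms refractory blanking and
## search-back. R-peak times are refined to the band-passed extremum within
## +/-40 ms of the (delay-corrected) integrator fiducial.

## Second-order Butterworth biquad coefficients via the bilinear transform.
## Returns list(b, a) with a[1] == 1.
butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop_config("cutoff must lie in (0, fs/2)")
  w <- tan(pi * fc / fs)
  s2 <- sqrt(2)
  d <- 1 + s2 * w + w * w
  if (type == "low") {
    b <- c(w * w, 2 * w * w, w * w) / d
  } else {
    b <- c(1, -2, 1) / d
  }
  a <- c(1, 2 * (w * w - 1) / d, (1 - s2 * w + w * w) / d)
  list(b = b, a = a)
}

## One causal IIR pass (direct form) using stats::filter (C speed).
iir_pass <- function(x, coef) {
  z <- stats::filter(c(rep(0, length(coef$b) - 1L), x), coef$b,
                     method = "convolution", sides = 1)
  z <- z[-seq_len(length(coef$b) - 1L)]
  as.numeric(stats::filter(z, -coef$a[-1], method = "recursive"))
}

## Zero-phase filtering: forward pass, reverse, forward pass, reverse.
## Reflection padding suppresses edge transients.
filtfilt2 <- function(x, coef) {
  n <- length(x)
  np <- min(n - 1L, 300L)
  pad_l <- 2 * x[1] - x[(np + 1L):2L]
  pad_r <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- c(pad_l, x, pad_r)
  y <- iir_pass(y, coef)
  y <- rev(iir_pass(rev(y), coef))
  y[(np + 1L):(np + n)]
}

bandpass_ecg <- function(x, fs, f_low, f_high) {
  y <- filtfilt2(x, butter2(f_low, fs, "high"))
  filtfilt2(y, butter2(f_high, fs, "low"))
}

#' Default QRS detector parameters
#'
#' Canonical Pan-Tompkins front-end values: 5-15 Hz pass band, 150 ms
#' integration window, 200 ms refractory period, signal/noise threshold
#' update coefficients 0.125, first-threshold fraction 0.25, search-back at
#' 1.66 times the running RR average, and a +/-40 ms refinement window on
#' the band-passed signal.
#'
#' @return Named list of parameters, each overridable in [detect_r_peaks()].
#' @export
qrs_params <- function() {
  list(f_low = 5, f_high = 15,
       integration_ms = 150, refractory_ms = 200,
       thr_fraction = 0.25, update = 0.125,
       searchback_factor = 1.66, refine_ms = 40)
}

#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins style detector; see the package vignette for the stage
#' breakdown. Deterministic for a fixed input and parameter set. The beat
#' times are amplitude-scale invariant and shift with the signal.
#'
#' @param ecg An [ecg_record()]; `fs` must be at least 100 Hz and the record
#'   at least 5 s long.
#' @param params Parameter list as from [qrs_params()]; partial lists are
#'   merged over the defaults.
#' @return A [beat_annotations()] object. An all-constant signal yields zero
#'   beats with a warning (not an error).
#' @export
detect_r_peaks <- function(ecg, params = qrs_params()) {
  stopifnot(inherits(ecg, "ecg_record"))
  p <- utils::modifyList(qrs_params(), params)
  fs <- ecg$fs
  if (fs < 100) stop_classed("stresshrv_rate_error",
                             sprintf("sampling rate %g Hz unsupported (need >= 100 Hz)", fs))
  x <- ecg$samples
  n <- length(x)
  if (n / fs < 5) stop_domain("record shorter than 5 s")
  if (max(x) - min(x) < sqrt(.Machine$double.eps) * max(1, abs(x[1]))) {
    warning("constant signal: no QRS complexes detectable")
    return(beat_annotations(numeric(0), detector_meta = p))
  }

  bp <- bandpass_ecg(x, fs, p$f_low, p$f_high)
  ## five-point derivative, squared, integrated
  der <- as.numeric(stats::filter(c(rep(0, 4), bp), c(2, 1, 0, -1, -2) * fs / 8,
                                  method = "convolution", sides = 1))[-(1:4)]
  sq <- der * der
  w <- max(1L, as.integer(round(p$integration_ms / 1000 * fs)))
  mwi <- as.numeric(stats::filter(c(rep(0, w - 1L), sq), rep(1 / w, w),
                                  method = "convolution", sides = 1))[-seq_len(w - 1L)]

  ## candidate local maxima of the integrated signal
  dm <- diff(mwi)
  cand <- which(dm[-length(dm)] > 0 & dm[-1] <= 0) + 1L
  if (length(cand) == 0L) {
    warning("no peaks found in integrated signal")
    return(beat_annotations(numeric(0), detector_meta = p))
  }

  refr <- p$refractory_ms / 1000 * fs
  init <- seq_len(min(n, round(2 * fs)))
  spki <- 0.25 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  rr_hist <- numeric(0)
  qrs <- integer(0)
  last_qrs <- -Inf
  noise_peaks <- integer(0)   # sub-threshold candidates since last QRS

  for (i in cand) {
    peak <- mwi[i]
    thr1 <- npki + p$thr_fraction * (spki - npki)
    rr_avg <- if (length(rr_hist)) mean(utils::tail(rr_hist, 8)) else NA_real_
    if (i - last_qrs < refr) next
    if (peak >= thr1) {
      spki <- p$update * peak + (1 - p$update) * spki
      if (is.finite(last_qrs)) rr_hist <- c(rr_hist, i - last_qrs)
      qrs <- c(qrs, i)
      last_qrs <- i
      noise_peaks <- integer(0)
    } else {
      ## search-back: a long gap suggests a missed beat; re-examine the
      ## sub-threshold candidates with the lower threshold thr1/2
      if (!is.na(rr_avg) && (i - last_qrs) > p$searchback_factor * rr_avg &&
          length(noise_peaks)) {
        sb <- noise_peaks[mwi[noise_peaks] >= thr1 / 2]
        if (length(sb)) {
          j <- sb[which.max(mwi[sb])]
          if (j - last_qrs >= refr) {
            spki <- 0.25 * mwi[j] + 0.75 * spki
            rr_hist <- c(rr_hist, j - last_qrs)
            qrs <- sort(c(qrs, j))
            last_qrs <- max(qrs)
            noise_peaks <- integer(0)
          }
        }
      }
      npki <- p$update * peak + (1 - p$update) * npki
      noise_peaks <- c(noise_peaks, i)
    }
  }

  if (length(qrs) == 0L) {
    warning("no QRS complexes passed the detection thresholds")
    return(beat_annotations(numeric(0), detector_meta = p))
  }

  ## refine: the integrator output peaks roughly half an integration window
  ## after the R wave; take the band-passed maximum within +/- refine_ms of
  ## the delay-corrected fiducial
  ## the QRS energy driving an integrator peak at i lies within the
  ## integration window ending at i; find the band-passed maximum there,
  ## extended by refine_ms on both sides
  rw <- max(1L, as.integer(round(p$refine_ms / 1000 * fs)))
  refined <- vapply(qrs, function(i) {
    lo <- max(1L, as.integer(i) - w - rw)
    hi <- min(n, as.integer(i) + rw)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  ## enforce the refractory period after refinement
  keep <- c(TRUE, diff(refined) >= refr)
  while (!all(keep)) {
    refined <- refined[keep]
    keep <- c(TRUE, diff(refined) >= refr)
  }
  beat_annotations(ecg$t0 + (refined - 1L) / fs, detector_meta = p)
}

#' RR intervals from beat annotations
#'
#' @param beats A [beat_annotations()] with at least two beats.
#' @return An [rr_series()] with `interval[i] = (t[i+1] - t[i]) * 1000` ms and
#'   `beat_times` set to each interval's terminal beat; validity unknown
#'   until [filter_rr()] is applied.
#' @export
beats_to_rr <- function(beats) {
  stopifnot(inherits(beats, "beat_annotations"))
  bt <- beats$beat_times
  if (length(bt) < 2L) stop_domain("need at least 2 beats to form RR intervals")
  rr_series(diff(bt) * 1000, beat_times = bt[-1L])
}
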