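## Linear HRV features on an NN-interval block.
##
## Time domain: AVNN, SDNN (population denominator by default), RMSSD,
## pNNx with x = 20 ms by default and the *total NN count* as denominator.
## Frequency domain: LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) band powers of
## the NN series and their ratio, estimated by default with a Lomb-Scargle
## (least-squares) periodogram, which tolerates the gaps the validity
## filter leaves; alternatively by 4 Hz resampling + Welch averaging.

#' Spectral band definitions
#' @return list with `lf` and `hf`, each `c(lower, upper)` in Hz.
#' @export
hrv_bands <- function() list(lf = c(0.04, 0.15), hf = c(0.15, 0.40))

#' Average of NN intervals (ms)
#' @param nn Numeric vector of NN intervals (ms), nonempty.
#' @export
avnn <- function(nn) {
  if (length(nn) < 1L) stop_domain("AVNN needs at least 1 NN interval")
  mean(nn)
}

#' Standard deviation of NN intervals (ms)
#' @param nn Numeric vector of NN intervals (ms), length >= 2.
#' @param population Use the population denominator n (default TRUE);
#'   FALSE gives the sample form n-1.
#' @export
sdnn <- function(nn, population = TRUE) {
  n <- length(nn)
  if (n < 2L) stop_domain("SDNN needs at least 2 NN intervals")
  v <- stats::var(nn) * (n - 1) / if (population) n else (n - 1)
  sqrt(v)
}

#' Root mean square of successive NN differences (ms)
#' @param nn Numeric vector of NN intervals (ms), length >= 2.
#' @export
rmssd <- function(nn) {
  if (length(nn) < 2L) stop_domain("RMSSD needs at least 2 NN intervals")
  sqrt(mean(diff(nn)^2))
}

#' pNNx: percentage of successive NN differences exceeding x ms
#'
#' Counts pairs with |NN[i+1] - NN[i]| strictly greater than `x` and divides
#' by the *total* NN interval count (not the pair count), following the
#' classical pNN50 wording; set `denominator = "pairs"` for the
#' pair-count variant used by some tools.
#'
#' @param nn Numeric vector of NN intervals (ms), length >= 2.
#' @param x Threshold in ms (default 20).
#' @param denominator `"total"` (default) or `"pairs"`.
#' @return Percentage in [0, 100].
#' @export
pnnx <- function(nn, x = 20, denominator = c("total", "pairs")) {
  denominator <- match.arg(denominator)
  n <- length(nn)
  if (n < 2L) stop_domain("pNNx needs at least 2 NN intervals")
  if (x <= 0) stop_config("pNNx threshold must be positive")
  hits <- sum(abs(diff(nn)) > x)
  100 * hits / if (denominator == "total") n else (n - 1)
}

## Lomb-Scargle periodogram of irregularly sampled data, with the classic
## tau offset. Returns raw periodogram values (arbitrary scale) at `freqs`.
lomb_periodogram <- function(t, x, freqs) {
  x <- x - mean(x)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
}

## Spectral power in each band, in ms^2. The periodogram (either method) is
## normalised so that it integrates to the variance of the detrended NN
## series over the evaluated frequency range, making band powers absolute.
spectral_band_power <- function(t, x, bands, method = c("lomb", "welch"),
                                resample_fs = 4, oversample = 4) {
  method <- match.arg(method)
  span <- max(t) - min(t)
  if (method == "lomb") {
    f_ny <- 0.5 * length(x) / span     # mean Nyquist rate
    df <- 1 / (oversample * span)
    freqs <- seq(df, max(f_ny, bands$hf[2] + df), by = df)
    pw <- lomb_periodogram(t, x, freqs)
  } else {
    grid <- seq(min(t), max(t), by = 1 / resample_fs)
    ## cubic spline: linear interpolation would low-pass the HF band
    xs <- stats::spline(t, x, xout = grid, method = "natural")$y
    ps <- welch_psd(xs, resample_fs)
    freqs <- ps$freq
    pw <- ps$psd
    x <- xs                              # normalise to the resampled variance
  }
  tot <- sum(pw)
  v <- stats::var(x) * (length(x) - 1) / length(x)
  if (!is.finite(tot) || tot <= 0 || v <= 0)
    return(list(lf = 0, hf = 0))   # constant series: no spectral power
  in_band <- function(b) freqs > b[1] & freqs <= b[2]
  list(lf = v * sum(pw[in_band(bands$lf)]) / tot,
       hf = v * sum(pw[in_band(bands$hf)]) / tot)
}

## Welch averaged periodogram: Hann window, 50% overlap, segment length
## min(n, 256) samples. Returns positive-frequency psd (relative scale).
welch_psd <- function(x, fs, seg_len = 256L) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  acc <- numeric(seg_len %/% 2L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[2:(seg_len %/% 2L + 1L)]
  }
  list(freq = (1:(seg_len %/% 2L)) * fs / seg_len, psd = acc / length(starts))
}

#' LF and HF band power and their ratio
#'
#' @param nn Numeric vector of NN intervals (ms).
#' @param beat_times Terminal beat time (s) of each NN interval.
#' @param bands Band edges as from [hrv_bands()].
#' @param method `"lomb"` (default; least-squares periodogram, gap-tolerant,
#'   no interpolation) or `"welch"` (4 Hz linear resampling + averaged
#'   Hann-windowed periodograms).
#' @return list `lf_power` (ms^2), `hf_power` (ms^2), `lf_hf`. The block must
#'   span at least two LF-band cycles (2/0.04 = 50 s) and contain at least
#'   30 NN intervals; a zero HF power raises an undefined-ratio error.
#' @export
lf_hf <- function(nn, beat_times, bands = hrv_bands(),
                  method = c("lomb", "welch")) {
  method <- match.arg(method)
  if (length(nn) < 30L) stop_domain("spectral analysis needs >= 30 NN intervals")
  if (length(beat_times) != length(nn))
    stop_domain("beat_times must match nn in length")
  span <- max(beat_times) - min(beat_times)
  if (span < 2 / bands$lf[1])
    stop_domain(sprintf("block span %.1f s too short for the %.2f Hz band edge",
                        span, bands$lf[1]))
  bp <- spectral_band_power(beat_times, nn, bands, method)
  if (bp$hf <= 0)
    stop_classed("stresshrv_undefined_ratio", "HF power is zero: LF/HF undefined")
  list(lf_power = bp$lf, hf_power = bp$hf, lf_hf = bp$lf / bp$hf)
}

#' All linear HRV features for one analysis block
#'
#' Computes AVNN, SDNN, RMSSD, pNNx and LF/HF on the identical NN subset.
#' Spectral features require >= 30 intervals and a 50 s span; when those
#' preconditions fail the time-domain features are still reported and the
#' spectral columns are NA with the failure recorded in `spectral_error`.
#'
#' @param nn Numeric vector of NN intervals (ms) or the list returned by
#'   [nn_intervals()].
#' @param beat_times Terminal beat times (s); taken from `nn` if it is an
#'   [nn_intervals()] result.
#' @param x pNNx threshold in ms (default 20).
#' @param bands,method Passed to [lf_hf()].
#' @param block_id Optional label included in error messages.
#' @return One-row data.frame of class `hrv_features`: `avnn`, `sdnn`,
#'   `rmssd`, `pnnx`, `lf_power`, `hf_power`, `lf_hf`, `n_nn`, `block_span`,
#'   `spectral_error`.
#' @export
extract_block_features <- function(nn, beat_times = NULL, x = 20,
                                   bands = hrv_bands(),
                                   method = c("lomb", "welch"),
                                   block_id = NULL) {
  method <- match.arg(method)
  if (is.list(nn) && !is.null(nn$intervals)) {
    beat_times <- beat_times %||% nn$beat_times
    nn <- nn$intervals
  }
  tag <- if (is.null(block_id)) "" else sprintf(" [block %s]", block_id)
  if (length(nn) < 2L)
    stop_domain(paste0("block has fewer than 2 NN intervals", tag))
  span <- if (!is.null(beat_times)) max(beat_times) - min(beat_times)
          else sum(nn[-1]) / 1000
  spec <- list(lf_power = NA_real_, hf_power = NA_real_, lf_hf = NA_real_)
  spec_err <- NA_character_
  if (is.null(beat_times)) {
    spec_err <- "no beat times: spectral features unavailable"
  } else {
    spec_try <- tryCatch(lf_hf(nn, beat_times, bands, method),
                         error = function(e) conditionMessage(e))
    if (is.character(spec_try)) spec_err <- paste0(spec_try, tag)
    else spec <- spec_try
  }
  out <- data.frame(avnn = avnn(nn), sdnn = sdnn(nn), rmssd = rmssd(nn),
                    pnnx = pnnx(nn, x),
                    lf_power = spec$lf_power, hf_power = spec$hf_power,
                    lf_hf = spec$lf_hf,
                    n_nn = length(nn), block_span = span,
                    spectral_error = spec_err)
  class(out) <- c("hrv_features", "data.frame")
  out
}
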