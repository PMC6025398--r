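## Synthetic-study generator.
##
## Beat timing follows an integral pulse frequency modulation (IPFM) model:
## the instantaneous rate
##   m(t) = (1/T) * (1 + a_lf sin(2 pi f_lf t + phi_lf)
##                     + a_hf sin(2 pi f_hf t + phi_hf)),  T = mean_rr (s),
## fires a beat whenever its integral crosses the next integer. The two
## sinusoids give analytically known spectral structure (LF and HF power
## A^2/2 with A = a * mean_rr in ms, hence input LF/HF = (a_lf/a_hf)^2),
## which makes estimator-recovery tests possible. Broadband Gaussian jitter
## sd_rr (ms) is added per interval on top.

#' Autonomic state for the IPFM generator
#'
#' @param mean_rr Mean RR interval, ms, in (300, 3000).
#' @param sd_rr Broadband per-interval Gaussian jitter, ms (>= 0).
#' @param a_lf,a_hf LF / HF modulation amplitudes as dimensionless fractions
#'   of the mean rate (>= 0; their sum must stay below 1 so the rate cannot
#'   go non-positive).
#' @param f_lf,f_hf Modulation frequencies, Hz; must lie inside the LF
#'   (0.04-0.15) and HF (0.15-0.4) bands. Defaults 0.1 and 0.3.
#' @param duration Recording duration, s.
#' @return list of class `autonomic_state`.
#' @export
autonomic_state <- function(mean_rr, sd_rr = 4, a_lf = 0.03, a_hf = 0.03,
                            f_lf = 0.1, f_hf = 0.3, duration = 300) {
  if (mean_rr <= 300 || mean_rr >= 3000)
    stop_config("mean_rr must lie in (300, 3000) ms")
  if (a_lf < 0 || a_hf < 0 || sd_rr < 0)
    stop_config("amplitudes and sd_rr must be non-negative")
  if (a_lf + a_hf >= 1)
    stop_config("a_lf + a_hf must be < 1 (rate would go non-positive)")
  bands <- hrv_bands()
  if (f_lf < bands$lf[1] || f_lf > bands$lf[2])
    stop_config("f_lf must lie in the LF band")
  if (f_hf < bands$hf[1] || f_hf > bands$hf[2])
    stop_config("f_hf must lie in the HF band")
  if (duration <= 0) stop_config("duration must be positive")
  structure(list(mean_rr = mean_rr, sd_rr = sd_rr, a_lf = a_lf, a_hf = a_hf,
                 f_lf = f_lf, f_hf = f_hf, duration = duration),
            class = "autonomic_state")
}

#' Calibrate an autonomic state from target feature values
#'
#' Inverts the first-order relations between generator parameters and the
#' HRV features: for a sinusoid of amplitude A ms at frequency f sampled
#' every T_s seconds the successive-difference contribution is
#' 2 A^2 sin^2(pi f T_s), and iid jitter contributes 2 sd_rr^2, so
#' `rmssd^2 = 2 A_lf^2 s_lf^2 + 2 A_hf^2 s_hf^2 + 2 sd_rr^2` with
#' `A_lf^2 = lfhf * A_hf^2`. Solving for A_hf gives the amplitudes that
#' reproduce the target AVNN, RMSSD and input LF/HF ratio.
#'
#' @details
#' The targets are defined in the *interval* (NN-series) domain, where the
#' features are measured. IPFM low-passes rate modulations when they are
#' read out as intervals: a rate modulation of fraction `a` at frequency `f`
#' appears in the interval series with amplitude
#' `a * mean_rr * sinc(pi f T_s)`. The calibration solves for the
#' interval-domain amplitudes and converts back through the sinc factor, so
#' the measured LF/HF power ratio matches the `lfhf` setpoint without
#' systematic attenuation bias.
#'
#' @param avnn_ms Target mean RR (= AVNN), ms.
#' @param rmssd_ms Target RMSSD, ms.
#' @param lfhf Target LF/HF power ratio of the NN series (dimensionless).
#' @param sd_rr Broadband jitter, ms (default 4).
#' @param duration Recording duration, s (default 600 = two 5-min blocks).
#' @param f_lf,f_hf Modulation frequencies, Hz.
#' @return An [autonomic_state()]; the realised interval-domain ratio is in
#'   `attr(, "lfhf_interval")`.
#' @export
calibrate_autonomic_state <- function(avnn_ms, rmssd_ms, lfhf, sd_rr = 4,
                                      duration = 600, f_lf = 0.1, f_hf = 0.3) {
  t_s <- avnn_ms / 1000
  s_lf <- sin(pi * f_lf * t_s)
  s_hf <- sin(pi * f_hf * t_s)
  num <- rmssd_ms^2 - 2 * sd_rr^2
  if (num <= 0)
    stop_config("target RMSSD too small for the requested jitter")
  ## interval-domain amplitudes (ms)
  a_hf_sq <- num / (2 * (lfhf * s_lf^2 + s_hf^2))
  a_hf_ms <- sqrt(a_hf_sq)
  a_lf_ms <- sqrt(lfhf) * a_hf_ms
  ## undo the IPFM interval read-out attenuation sinc(pi f T_s)
  sinc <- function(z) ifelse(z == 0, 1, sin(z) / z)
  st <- autonomic_state(
    mean_rr = avnn_ms, sd_rr = sd_rr,
    a_lf = a_lf_ms / (avnn_ms * sinc(pi * f_lf * t_s)),
    a_hf = a_hf_ms / (avnn_ms * sinc(pi * f_hf * t_s)),
    f_lf = f_lf, f_hf = f_hf, duration = duration)
  attr(st, "lfhf_interval") <- lfhf
  st
}

#' Generate an RR series from an autonomic state (IPFM)
#'
#' A beat fires at every integer crossing of the integrated rate (the first
#' beat is at t = 0). Crossing times are located on a coarse grid and
#' polished with Newton steps on the closed-form integral, then independent
#' Gaussian jitter `sd_rr` is added to each interval and beat times are
#' rebuilt cumulatively. Bit-reproducible for a fixed seed.
#'
#' @param state An [autonomic_state()].
#' @param seed Integer seed (NULL = use the current RNG stream).
#' @return An [rr_series()] with beat times; ground truth (the state, the
#'   random phases and the ideal noise-free beat times) in
#'   `attr(, "ground_truth")`.
#' @export
generate_rr <- function(state, seed = NULL) {
  stopifnot(inherits(state, "autonomic_state"))
  with_seed(seed, {
    T_s <- state$mean_rr / 1000
    phi <- stats::runif(2, 0, 2 * pi)
    w1 <- 2 * pi * state$f_lf; w2 <- 2 * pi * state$f_hf
    M <- function(t) (t + state$a_lf / w1 * (cos(phi[1]) - cos(w1 * t + phi[1]))
                        + state$a_hf / w2 * (cos(phi[2]) - cos(w2 * t + phi[2]))) / T_s
    m <- function(t) (1 + state$a_lf * sin(w1 * t + phi[1])
                        + state$a_hf * sin(w2 * t + phi[2])) / T_s
    n_beats <- floor(M(state$duration))
    grid <- seq(0, state$duration, length.out = max(64L, 4L * n_beats))
    Mg <- M(grid)
    ks <- seq_len(n_beats)
    idx <- findInterval(ks, Mg)
    tk <- grid[idx]
    for (it in 1:4) tk <- tk - (M(tk) - ks) / m(tk)   # Newton polish
    beats_ideal <- c(0, tk)
    iv_ideal <- diff(beats_ideal) * 1000
    iv <- iv_ideal + stats::rnorm(length(iv_ideal), 0, state$sd_rr)
    iv <- pmax(iv, 1)                                  # guard positivity
    bt <- cumsum(iv) / 1000
    out <- rr_series(iv, beat_times = bt)
    sinc <- function(z) ifelse(z == 0, 1, sin(z) / z)
    att <- function(f) sinc(pi * f * T_s)
    attr(out, "ground_truth") <- list(
      state = state, phases = phi, beats_ideal = beats_ideal,
      lfhf_rate = if (state$a_hf > 0) (state$a_lf / state$a_hf)^2 else Inf,
      lfhf_interval = if (state$a_hf > 0)
        (state$a_lf * att(state$f_lf) / (state$a_hf * att(state$f_hf)))^2
      else Inf)
    out
  })
}

#' Default PQRST wave template
#'
#' Gaussian bumps (amplitude mV, centre s relative to the R peak, width s)
#' approximating the P wave, QRS complex and T wave.
#' @return data.frame `wave, amp, mu, sigma`.
#' @export
pqrst_template <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             amp = c(0.12, -0.15, 1.00, -0.25, 0.30),
             mu = c(-0.20, -0.028, 0.00, 0.028, 0.25),
             sigma = c(0.025, 0.010, 0.010, 0.010, 0.045))
}

#' Render a synthetic ECG from beat times
#'
#' Sums Gaussian-shaped P-QRS-T waves at each beat's R time and adds white
#' noise at the requested signal-to-noise ratio.
#'
#' @param rr An [rr_series()] with beat times, or a [beat_annotations()].
#' @param fs Sampling rate, Hz (>= 100).
#' @param noise_db Signal-to-noise ratio in dB (`Inf` = clean).
#' @param template Wave table as from [pqrst_template()]; a zero-amplitude
#'   template yields a flat record.
#' @param seed Integer seed for the noise.
#' @return An [ecg_record()]; true beat times in `attr(, "true_beats")`.
#' @export
generate_ecg <- function(rr, fs = 250, noise_db = Inf,
                         template = pqrst_template(), seed = NULL) {
  if (fs < 100) stop_classed("stresshrv_rate_error",
                             "fs too low to render QRS complexes (< 100 Hz)")
  beats <- if (inherits(rr, "beat_annotations")) rr$beat_times
           else c(rr$beat_times[1] - rr$intervals[1] / 1000, rr$beat_times)
  dur <- max(beats) + 0.5
  n <- ceiling(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  half <- 0.45   # template support half-width, s
  for (b in beats) {
    lo <- max(1L, floor((b - half) * fs) + 1L)
    hi <- min(n, ceiling((b + half) * fs) + 1L)
    tw <- tt[lo:hi] - b
    for (k in seq_len(nrow(template)))
      x[lo:hi] <- x[lo:hi] +
        template$amp[k] * exp(-0.5 * ((tw - template$mu[k]) / template$sigma[k])^2)
  }
  if (is.finite(noise_db)) {
    p_sig <- mean(x^2)
    x <- x + with_seed(seed, stats::rnorm(n, 0, sqrt(p_sig / 10^(noise_db / 10))))
  }
  out <- ecg_record(x, fs = fs, lead = "synthetic-I")
  attr(out, "true_beats") <- beats
  out
}

#' Inject beat-detection artifacts into an RR series
#'
#' Ectopic-like events split one interval into a short beat plus its
#' compensatory remainder (fraction 0.35/0.65); missed-beat events merge two
#' adjacent intervals. Corruption sites are disjoint.
#'
#' @param rr An [rr_series()].
#' @param ectopic_rate,missed_rate Per-interval corruption probabilities,
#'   each in [0, 0.2].
#' @param seed Integer seed.
#' @return Corrupted [rr_series()]; `attr(, "corruption_map")` is a
#'   data.frame `index,type` over indices in the *output* series.
#' @export
inject_artifacts <- function(rr, ectopic_rate = 0.02, missed_rate = 0.02,
                             seed = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  if (ectopic_rate < 0 || ectopic_rate > 0.2 ||
      missed_rate < 0 || missed_rate > 0.2)
    stop_config("corruption rates must lie in [0, 0.2]")
  with_seed(seed, {
    n <- length(rr$intervals)
    u <- stats::runif(n)
    ect <- which(u < ectopic_rate)
    mis <- which(u >= ectopic_rate & u < ectopic_rate + missed_rate)
    mis <- mis[mis < n]
    mis <- mis[!(mis + 1L) %in% c(ect, mis)]          # keep sites disjoint
    out_iv <- list(); out_map <- list()
    i <- 1L
    while (i <= n) {
      if (i %in% ect) {
        out_iv[[length(out_iv) + 1L]] <- c(0.35, 0.65) * rr$intervals[i]
        out_map[[length(out_map) + 1L]] <-
          data.frame(offset = c(0L, 1L), type = "ectopic", src = i)
        i <- i + 1L
      } else if (i %in% mis) {
        out_iv[[length(out_iv) + 1L]] <- rr$intervals[i] + rr$intervals[i + 1L]
        out_map[[length(out_map) + 1L]] <-
          data.frame(offset = 0L, type = "missed", src = i)
        i <- i + 2L
      } else {
        out_iv[[length(out_iv) + 1L]] <- rr$intervals[i]
        out_map[[length(out_map) + 1L]] <-
          data.frame(offset = 0L, type = "none", src = i)
        i <- i + 1L
      }
    }
    iv <- unlist(out_iv)
    map <- do.call(rbind, out_map)
    map$index <- seq_len(nrow(map))    # one map row per output interval
    t0 <- if (!is.null(rr$beat_times)) rr$beat_times[1] - rr$intervals[1] / 1000 else 0
    bt <- t0 + cumsum(iv) / 1000
    out <- rr_series(iv, beat_times = bt)
    attr(out, "corruption_map") <- map[map$type != "none", c("index", "type", "src")]
    out
  })
}

#' Default cohort specification
#'
#' Eleven subjects in the four-condition protocol order. Per-condition
#' autonomic templates are calibrated so cohort means approximate the
#' printed group means of the study the pipeline targets (e.g. mean RR
#' 675 ms and LF/HF 6.13 under stress); the calibration targets live in the
#' `targets` element and can be edited before [generate_cohort()].
#'
#' @param n_subjects Number of subjects (default 11, >= 2).
#' @param condition_len Seconds of usable recording per condition
#'   (default 600 = two 5-min blocks).
#' @param sd_rr Broadband jitter, ms.
#' @return list of class `cohort_spec`: `n_subjects`, `targets` (one row per
#'   condition: avnn/rmssd/lfhf/vas setpoints and CRTT targets),
#'   `between_subject` (variability scales), `crtt` (trial parameters).
#' @export
default_cohort_spec <- function(n_subjects = 11L, condition_len = 600,
                                sd_rr = 4) {
  if (n_subjects < 2L) stop_config("cohort needs >= 2 subjects")
  targets <- data.frame(
    condition = PROTOCOL_CONDITIONS,
    avnn = c(744.15, 727.95, 675.23, 741.37),
    rmssd = c(28.22, 24.06, 23.03, 26.00),
    lfhf = c(2.50, 2.52, 6.13, 2.63),
    vas = c(2.82, 3.45, 6.82, 4.73),
    stringsAsFactors = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    condition_len = condition_len,
    sd_rr = sd_rr,
    targets = targets,
    between_subject = list(mean_rr_cv = 0.03, amp_cv = 0.10,
                           vas_sd = 0.8, stai_sd = 0.3,
                           rt_effect = 0.08, rt_noise = 0.01),
    crtt = list(duration = 600, fixation_s = 15,
                isi_range = c(3, 10), display_range_ms = c(100, 500),
                median_rt = c(CRTT1 = 620, CRTT2 = 560),
                accuracy = c(CRTT1 = 0.95, CRTT2 = 0.88),
                miss_rate = 0.02, rt_sdlog = 0.15),
    stai = c(pre = 1.5, post = 2.0)),
    class = "cohort_spec")
}

## Generate one CRTT log. Stimuli are exactly half congruent (balanced
## shuffle); ISI ~ U(3,10) s, display ~ U(100,500) ms; responses are
## Bernoulli-correct around the accuracy target with a small miss rate and
## log-normal RTs around the median target.
generate_crtt_log <- function(median_rt, accuracy, crtt_par) {
  onset <- crtt_par$fixation_s
  onsets <- numeric(0)
  repeat {
    isi <- stats::runif(1, crtt_par$isi_range[1], crtt_par$isi_range[2])
    nxt <- onset + isi
    if (nxt > crtt_par$duration) break
    onsets <- c(onsets, nxt)
    onset <- nxt
  }
  n <- length(onsets)
  n_cong <- floor(n / 2)
  stim <- sample(c(rep("congruent", n_cong), rep("incongruent", n - n_cong)))
  display <- stats::runif(n, crtt_par$display_range_ms[1],
                          crtt_par$display_range_ms[2])
  missed <- stats::runif(n) < crtt_par$miss_rate
  correct <- stats::runif(n) < accuracy
  expected <- ifelse(stim == "congruent", "1", "3")
  other <- ifelse(stim == "congruent", "3", "1")
  key <- ifelse(missed, NA_character_, ifelse(correct, expected, other))
  rt <- ifelse(missed, NA_real_,
               stats::rlnorm(n, meanlog = log(median_rt),
                             sdlog = crtt_par$rt_sdlog))
  out <- data.frame(trial = seq_len(n), stimulus = stim,
                    onset_s = onsets, display_ms = display,
                    response_key = key, rt_ms = rt,
                    outcome = classify_response(stim, key),
                    stringsAsFactors = FALSE)
  class(out) <- c("crtt_log", "data.frame")
  out
}

#' Generate a full synthetic cohort
#'
#' For each subject, condition-labelled RR recordings (optionally rendered
#' to ECG) are laid out contiguously in protocol order with event
#' annotations, CRTT logs are drawn for the pre- and post-stress sessions,
#' and VAS/STAI questionnaire scores are drawn around condition-dependent
#' means. Subject-level variability: a log-normal factor on mean RR and on
#' the modulation amplitudes, shared across that subject's conditions. The
#' pre/post RT targets share a latent subject speed that enters the
#' post-stress session with opposite sign, reproducing the strong negative
#' pre/post RT association reported for this protocol.
#'
#' Everything is bit-reproducible given (spec, seed); per-subject and
#' per-condition streams are derived from the master seed by fixed offsets.
#'
#' @param spec A [default_cohort_spec()].
#' @param seed Master integer seed.
#' @param render_ecg If TRUE also render each condition's ECG at `fs` (slow;
#'   default FALSE emits RR-level recordings, which is what cohort-scale
#'   tests consume).
#' @param fs Sampling rate for rendered ECG.
#' @return list of class `synthetic_cohort` with one element per subject
#'   (`rr`, `events`, `crtt` [CRTT1/CRTT2 logs], `scores`, optionally
#'   `ecg`), plus `ground_truth`: a data.frame of the per-subject,
#'   per-condition true generator parameters.
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed = 1L,
                            render_ecg = FALSE, fs = 250) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  cohort <- vector("list", spec$n_subjects)
  names(cohort) <- subjects
  truth <- list()
  for (s in seq_len(spec$n_subjects)) {
    subj_seed <- derive_seed(seed, s)
    subj <- with_seed(subj_seed, {
      mean_fac <- exp(stats::rnorm(1, 0, spec$between_subject$mean_rr_cv))
      amp_fac <- exp(stats::rnorm(1, 0, spec$between_subject$amp_cv))
      speed <- stats::rnorm(1)
      list(mean_fac = mean_fac, amp_fac = amp_fac, speed = speed)
    })
    all_iv <- numeric(0); all_bt <- numeric(0)
    ev_label <- character(0); ev_onset <- numeric(0); ev_dur <- numeric(0)
    offset <- 0
    ecg_list <- if (render_ecg) list() else NULL
    for (ci in seq_len(nrow(spec$targets))) {
      tg <- spec$targets[ci, ]
      st <- calibrate_autonomic_state(
        avnn_ms = tg$avnn * subj$mean_fac,
        rmssd_ms = tg$rmssd * subj$amp_fac,
        lfhf = tg$lfhf, sd_rr = spec$sd_rr,
        duration = spec$condition_len)
      rr <- generate_rr(st, seed = derive_seed(seed, s, 100 + ci))
      if (render_ecg)
        ecg_list[[tg$condition]] <-
          generate_ecg(rr, fs = fs, seed = derive_seed(seed, s, 200 + ci))
      all_iv <- c(all_iv, rr$intervals)
      all_bt <- c(all_bt, offset + rr$beat_times)
      ev_label <- c(ev_label, tg$condition)
      ev_onset <- c(ev_onset, offset)
      ev_dur <- c(ev_dur, spec$condition_len)
      truth[[length(truth) + 1L]] <- data.frame(
        subject = subjects[s], condition = tg$condition,
        mean_rr = st$mean_rr, a_lf = st$a_lf, a_hf = st$a_hf,
        sd_rr = st$sd_rr, lfhf_input = attr(st, "lfhf_interval"),
        stringsAsFactors = FALSE)
      offset <- offset + spec$condition_len
    }
    scores <- with_seed(derive_seed(seed, s, 300), {
      vas <- pmin(10, pmax(0, stats::rnorm(
        nrow(spec$targets), spec$targets$vas, spec$between_subject$vas_sd)))
      stai <- pmax(1, pmin(4, stats::rnorm(2, unname(spec$stai),
                                           spec$between_subject$stai_sd)))
      data.frame(subject = subjects[s],
                 condition = spec$targets$condition, vas = vas,
                 stai_pre = stai[1], stai_post = stai[2],
                 stringsAsFactors = FALSE)
    })
    eff <- spec$between_subject$rt_effect
    noise <- spec$between_subject$rt_noise
    crtt_logs <- with_seed(derive_seed(seed, s, 400), {
      med1 <- spec$crtt$median_rt[["CRTT1"]] *
        (1 + eff * subj$speed + stats::rnorm(1, 0, noise))
      med2 <- spec$crtt$median_rt[["CRTT2"]] *
        (1 - eff * subj$speed + stats::rnorm(1, 0, noise))
      list(CRTT1 = generate_crtt_log(med1, spec$crtt$accuracy[["CRTT1"]], spec$crtt),
           CRTT2 = generate_crtt_log(med2, spec$crtt$accuracy[["CRTT2"]], spec$crtt))
    })
    cohort[[s]] <- list(
      subject = subjects[s],
      rr = rr_series(all_iv, beat_times = all_bt),
      events = event_annotations(ev_label, ev_onset, ev_dur),
      crtt = crtt_logs,
      scores = scores)
    if (render_ecg) cohort[[s]]$ecg <- ecg_list
  }
  structure(list(subjects = cohort, ground_truth = do.call(rbind, truth),
                 spec = spec, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Emits, per subject, the same CSV dialects the readers consume
#' (`<subject>_rr.csv`, `<subject>_events.csv`, `<subject>_crtt1.csv`,
#' `<subject>_crtt2.csv`, `<subject>_scores.csv`) plus the cohort-level
#' `ground_truth.csv`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in cohort$subjects) {
    pre <- file.path(dir, subj$subject)
    write_rr(subj$rr, paste0(pre, "_rr.csv"))
    write_events(subj$events, paste0(pre, "_events.csv"))
    write_crtt_log(subj$crtt$CRTT1, paste0(pre, "_crtt1.csv"))
    write_crtt_log(subj$crtt$CRTT2, paste0(pre, "_crtt2.csv"))
    utils::write.csv(subj$scores, paste0(pre, "_scores.csv"), row.names = FALSE)
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
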