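# Synthetic single-lead ECG generator.
#
# Each heartbeat is a sum of Gaussian kernels (P, Q, R, S, T) placed relative
# to its R-peak time; AFib beats have the P kernel suppressed and a sinusoidal
# fibrillatory (f-) wave added to the baseline, NSR beats keep the P wave.
# RR-intervals are drawn from a (truncated) normal distribution per rhythm
# class. Signals are in millivolts throughout; integer ADC scaling happens
# only in the WFDB exporter.

#' Beat morphology parameters
#'
#' Describes the five-wave (P, Q, R, S, T) Gaussian-kernel morphology of a
#' synthetic heartbeat plus the fibrillatory-wave component used for AFib.
#' Defaults are textbook Lead-I-like proportions.
#'
#' @param p,q,r,s,t Numeric vectors `c(amplitude_mV, center_s, width_s)`;
#'   `center_s` is the kernel centre relative to the R-peak (seconds).
#' @param fwave_amplitude Fibrillatory-wave amplitude in mV (AFib only).
#' @param fwave_freq Fibrillatory-wave frequency in Hz; must lie in
#'   \[4, 10\] when the amplitude is nonzero.
#' @return An object of class `beat_morphology` (a list of wave parameters).
#' @export
beat_morphology <- function(p = c(0.15, -0.12, 0.02),
                            q = c(-0.10, -0.035, 0.010),
                            r = c(1.0, 0.0, 0.012),
                            s = c(-0.20, 0.030, 0.010),
                            t = c(0.30, 0.25, 0.05),
                            fwave_amplitude = 0.05,
                            fwave_freq = 6) {
  waves <- list(P = p, Q = q, R = r, S = s, T = t)
  for (nm in names(waves)) {
    w <- waves[[nm]]
    if (length(w) != 3L || !is.numeric(w))
      stop(sprintf("wave %s must be c(amplitude, center, width)", nm))
    if (w[3] <= 0) stop(sprintf("wave %s width must be > 0", nm))
  }
  if (waves$R[1] <= 0) stop("R amplitude must be > 0")
  if (fwave_amplitude < 0) stop("fwave_amplitude must be >= 0")
  if (fwave_amplitude > 0 && (fwave_freq < 4 || fwave_freq > 10))
    stop("fwave_freq must lie in [4, 10] Hz")
  structure(list(waves = waves, fwave_amplitude = fwave_amplitude,
                 fwave_freq = fwave_freq),
            class = "beat_morphology")
}

#' Rhythm parameters
#'
#' RR-interval model for a rhythm class. NSR defaults to a tight normal
#' distribution (regular rhythm); AFib to a wide truncated normal (irregular
#' rhythm). The `short_rr` AFib preset lowers the truncation floor so that
#' templates containing a second R-peak are guaranteed, exercising the
#' zero-padding path.
#'
#' @param label `"NSR"` or `"AFib"`.
#' @param mean_rr Mean RR-interval, seconds.
#' @param sd_rr RR-interval standard deviation, seconds (>= 0).
#' @param rr_bounds Truncation bounds for the RR distribution, seconds.
#' @return An object of class `rhythm_params`.
#' @export
rhythm_params <- function(label = c("NSR", "AFib"),
                          mean_rr = NULL, sd_rr = NULL, rr_bounds = NULL) {
  label <- match.arg(label)
  if (label == "NSR") {
    mean_rr <- mean_rr %||% 0.85
    sd_rr <- sd_rr %||% 0.02
    rr_bounds <- rr_bounds %||% c(0.4, 1.6)
  } else {
    mean_rr <- mean_rr %||% 0.65
    sd_rr <- sd_rr %||% 0.15
    rr_bounds <- rr_bounds %||% c(0.35, 1.4)
  }
  stopifnot_scalar(mean_rr, "mean_rr", positive = TRUE)
  if (sd_rr < 0) stop("sd_rr must be >= 0")
  if (length(rr_bounds) != 2L || rr_bounds[1] >= rr_bounds[2])
    stop("rr_bounds must be c(lower, upper) with lower < upper")
  structure(list(label = label, mean_rr = mean_rr, sd_rr = sd_rr,
                 rr_bounds = rr_bounds),
            class = "rhythm_params")
}

#' Short-RR AFib rhythm preset
#'
#' AFib rhythm with the truncation floor lowered to 0.30 s so some
#' RR-intervals fall below the 400 ms post-R window and a second R-peak
#' intrudes into the fixed-length beat template.
#' @export
rhythm_afib_short_rr <- function() {
  rhythm_params("AFib", mean_rr = 0.45, sd_rr = 0.12, rr_bounds = c(0.30, 1.4))
}

#' Noise parameters
#'
#' @param white_sd White-noise standard deviation, mV.
#' @param wander_amplitude Baseline-wander amplitude, mV.
#' @param wander_freq Baseline-wander frequency, Hz; must stay below the
#'   0.5 Hz high-pass cutoff so preprocessing removes the wander.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(white_sd = 0.02, wander_amplitude = 0.1,
                         wander_freq = 0.25) {
  if (white_sd < 0 || wander_amplitude < 0 || wander_freq < 0)
    stop("noise parameters must be >= 0")
  if (wander_amplitude > 0 && wander_freq >= 0.5)
    stop("wander_freq must be < 0.5 Hz (the high-pass cutoff)")
  structure(list(white_sd = white_sd, wander_amplitude = wander_amplitude,
                 wander_freq = wander_freq),
            class = "noise_params")
}

new_ecg_record <- function(id, patient, signal, fs, intervals,
                           r_times = numeric(0), labels = character(0),
                           provenance = "synthetic") {
  structure(list(id = id, patient = patient, signal = as.numeric(signal),
                 fs = fs, intervals = intervals, r_times = r_times,
                 beat_labels = labels, provenance = provenance),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> patient %s, %.1f s at %g Hz (%s)\n",
              x$id, x$patient, length(x$signal) / x$fs, x$fs, x$provenance))
  if (nrow(x$intervals))
    cat("  intervals:",
        paste(sprintf("[%d,%d)=%s", x$intervals$start, x$intervals$end,
                      x$intervals$label), collapse = " "), "\n")
  if (length(x$r_times))
    cat(sprintf("  %d annotated R-peaks\n", length(x$r_times)))
  invisible(x)
}

#' Generate a synthetic single-lead ECG record
#'
#' Simulates a single-rhythm recording: RR-intervals are drawn from the
#' rhythm model, each beat contributes Gaussian P/Q/R/S/T kernels at its R
#' time, and (for AFib) a sinusoidal f-wave replaces the P wave. Baseline
#' wander and white noise are added last. Ground-truth R-peak times and
#' per-beat labels are returned with the record.
#'
#' @param rhythm A [rhythm_params()] object.
#' @param morph A [beat_morphology()] object.
#' @param noise A [noise_params()] object.
#' @param duration Record duration in seconds (>= 5).
#' @param fs Sampling rate in Hz (typically 250 or 300).
#' @param seed Integer RNG seed; identical inputs and seed give bit-identical
#'   signals.
#' @param id,patient Record and patient identifiers.
#' @return An `ecg_record` with fields `signal` (mV), `fs`, `intervals`
#'   (0-based half-open sample intervals with rhythm label), `r_times`
#'   (ground-truth R-peak times, seconds) and `beat_labels`.
#' @examples
#' rec <- generate_record(rhythm_params("AFib"), duration = 10, seed = 1)
#' diff(rec$r_times)  # irregular RR series
#' @export
generate_record <- function(rhythm = rhythm_params("NSR"),
                            morph = beat_morphology(),
                            noise = noise_params(),
                            duration = 60, fs = 250, seed = 1L,
                            id = "synth-001", patient = "pat-001") {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  if (duration < 5) stop("duration must be >= 5 s")
  stopifnot(inherits(rhythm, "rhythm_params"), inherits(morph, "beat_morphology"),
            inherits(noise, "noise_params"))

  n <- as.integer(rhalf(duration * fs))
  tt <- (seq_len(n) - 1) / fs

  set.seed(as.integer(seed))
  # draw a generous fixed-length RR block so the RNG consumption is
  # independent of the realised beat count
  n_rr <- as.integer(ceiling(duration / rhythm$rr_bounds[1])) + 2L
  rr <- rtruncnorm(n_rr, rhythm$mean_rr, rhythm$sd_rr,
                   rhythm$rr_bounds[1], rhythm$rr_bounds[2])
  r_times <- 0.5 + cumsum(c(0, rr))
  r_times <- r_times[r_times <= duration - 0.45]

  x <- numeric(n)
  for (nm in names(morph$waves)) {
    w <- morph$waves[[nm]]
    amp <- w[1]
    if (nm == "P" && rhythm$label == "AFib") next  # absent P-waves in AFib
    for (rt in r_times) {
      c0 <- rt + w[2]
      lo <- max(1L, as.integer(floor((c0 - 5 * w[3]) * fs)))
      hi <- min(n, as.integer(ceiling((c0 + 5 * w[3]) * fs)) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + amp * exp(-((tt[idx] - c0)^2) / (2 * w[3]^2))
    }
  }
  if (rhythm$label == "AFib" && morph$fwave_amplitude > 0)
    x <- x + morph$fwave_amplitude * sin(2 * pi * morph$fwave_freq * tt)
  if (noise$wander_amplitude > 0)
    x <- x + noise$wander_amplitude * sin(2 * pi * noise$wander_freq * tt)
  if (noise$white_sd > 0)
    x <- x + stats::rnorm(n, 0, noise$white_sd)

  intervals <- data.frame(start = 0L, end = n, label = rhythm$label,
                          stringsAsFactors = FALSE)
  new_ecg_record(id, patient, x, fs, intervals, r_times,
                 rep(rhythm$label, length(r_times)), "synthetic")
}

#' Generate a labelled synthetic dataset
#'
#' Produces `n_per_class` NSR and `n_per_class` AFib records. By default each
#' record belongs to its own patient; with `patients = k` the records of each
#' class are assigned round-robin over `k` patient ids per class, so
#' patient-stratified splitting is exercisable. `patient_morph_sd > 0` applies
#' a per-patient log-normal scaling to the wave amplitudes and widths,
#' emulating between-subject morphology differences.
#'
#' @param n_per_class Records per rhythm class (>= 1).
#' @param duration,fs Passed to [generate_record()].
#' @param nsr,afib Rhythm parameter objects for the two classes.
#' @param morph Baseline morphology shared by all patients.
#' @param noise Noise parameters.
#' @param patients Optional number of distinct patients per class.
#' @param patient_morph_sd Log-scale SD of per-patient morphology scaling.
#' @param seed Master RNG seed.
#' @return A list of `ecg_record`s with class `ecg_dataset`.
#' @export
generate_dataset <- function(n_per_class, duration = 30, fs = 250,
                             nsr = rhythm_params("NSR"),
                             afib = rhythm_params("AFib"),
                             morph = beat_morphology(),
                             noise = noise_params(),
                             patients = NULL, patient_morph_sd = 0,
                             seed = 1L) {
  if (!is.numeric(n_per_class) || n_per_class < 1)
    stop("n_per_class must be >= 1")
  n_per_class <- as.integer(n_per_class)
  n_pat <- if (is.null(patients)) n_per_class else as.integer(patients)
  if (n_pat < 1) stop("patients must be >= 1")

  # one patient pool shared by both classes (paroxysmal-AFib-style: a
  # patient contributes both rhythms); morphology scalings drawn once from
  # the master seed
  if (is.null(patients)) n_pat <- 2L * n_per_class
  set.seed(as.integer(seed))
  pat_ids <- sprintf("pat-%03d", seq_len(n_pat))
  # independent log-normal scale per wave and patient: between-patient
  # differences are waveform-shape differences, not a mere gain change
  wave_names <- c("P", "Q", "R", "S", "T")
  pat_scale <- matrix(exp(stats::rnorm(n_pat * 5L, 0, patient_morph_sd)),
                      n_pat, 5L, dimnames = list(pat_ids, wave_names))
  rec_seeds <- sample.int(2^30, 2L * n_per_class)

  records <- vector("list", 2L * n_per_class)
  k <- 0L
  for (cls in c("NSR", "AFib")) {
    rp <- if (cls == "NSR") nsr else afib
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      pid <- if (is.null(patients))
        sprintf("pat-%03d", k)  # distinct patient per record by default
      else sprintf("pat-%03d", ((i - 1L) %% n_pat) + 1L)
      m <- morph
      if (patient_morph_sd > 0) {
        for (nm in names(m$waves)) {
          sc <- pat_scale[pid, nm]
          m$waves[[nm]][1] <- m$waves[[nm]][1] * sc
          m$waves[[nm]][3] <- m$waves[[nm]][3] * sqrt(sc)
        }
      }
      records[[k]] <- generate_record(
        rhythm = rp, morph = m, noise = noise, duration = duration, fs = fs,
        seed = rec_seeds[k], id = sprintf("synth-%s-%03d", cls, i),
        patient = pid)
    }
  }
  structure(records, class = "ecg_dataset")
}

#' @export
print.ecg_dataset <- function(x, ...) {
  labs <- vapply(x, function(r) r$intervals$label[1], character(1))
  cat(sprintf("<ecg_dataset> %d records (%s)\n", length(x),
              paste(sprintf("%s: %d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}
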