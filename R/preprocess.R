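# Preprocessing chain: high-pass filtering, QRS detection and refinement,
# fixed-length beat segmentation, second-R-peak zero-padding and
# cosine-distance (DMEAN) outlier rejection.

template_pre <- function(fs) as.integer(rhalf(0.2 * fs))
template_post <- function(fs) as.integer(rhalf(0.4 * fs))

#' High-pass FIR filter with group-delay compensation
#'
#' Removes baseline wander and DC offset with a linear-phase windowed-sinc
#' (Hamming) high-pass filter, cutoff 0.5 Hz. The constant group delay of the
#' linear-phase FIR is compensated by shifting the output, so R-peak times
#' are preserved.
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling rate, Hz (> 1).
#' @param cutoff Cutoff frequency, Hz.
#' @param ntaps Number of filter taps (odd); default just under `5 * fs`,
#'   long enough for >= 20 dB attenuation through the 0.2-0.5 Hz stopband
#'   while still fitting a 5 s record. Taps are re-centred to a exact zero
#'   at DC.
#' @return Filtered signal, same length as `x`.
#' @export
highpass_filter <- function(x, fs, cutoff = 0.5, ntaps = NULL) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (fs <= 1) stop("fs must be > 1 Hz")
  if (is.null(ntaps)) ntaps <- as.integer(5 * fs) - 1L
  if (ntaps %% 2L == 0L) ntaps <- ntaps - 1L
  if (length(x) < ntaps)
    stop("signal shorter than the filter length (", ntaps, " taps)")
  h <- signal::fir1(ntaps - 1L, cutoff / (fs / 2), type = "high",
                    window = signal::hamming(ntaps))
  h <- h - sum(h) / ntaps
  delay <- (ntaps - 1L) / 2L
  padded <- c(numeric(ntaps - 1L), x, numeric(delay))
  y <- stats::filter(padded, h, method = "convolution", sides = 1)
  as.numeric(y[(ntaps - 1L + delay + 1L):(ntaps - 1L + delay + length(x))])
}

#' Detect R-peaks with an envelope and adaptive-threshold scheme
#'
#' QRS detection in the Hamilton/Pan-Tompkins family: band-pass (8-20 Hz) to
#' isolate QRS energy, differentiate, rectify, smooth with an 80 ms moving
#' average, then pick envelope peaks with an adaptive signal/noise threshold
#' and a 200 ms refractory period. Each envelope detection is mapped to the
#' absolute maximum of the input signal within +-100 ms.
#'
#' @param x Filtered signal (mV).
#' @param fs Sampling rate, Hz.
#' @return Integer vector of 1-based R-peak sample indices, strictly
#'   increasing; empty for flat input.
#' @export
detect_rpeaks <- function(x, fs) {
  n <- length(x)
  if (n < fs) return(integer(0))
  if (max(abs(x)) < 1e-9) return(integer(0))
  bf <- signal::butter(3, c(8, 20) / (fs / 2), type = "pass")
  bp <- signal::filtfilt(bf, x)
  env <- abs(c(diff(bp), 0))
  w <- max(1L, as.integer(rhalf(0.08 * fs)))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  refr <- as.integer(rhalf(0.2 * fs))

  # local maxima of the envelope
  cand <- which(diff(sign(diff(env))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  spk <- max(env[cand]); npk <- 0
  thr <- npk + 0.3125 * (spk - npk)
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    if (env[i] > thr) {
      if (i - last >= refr) {
        peaks <- c(peaks, i); last <- i
        spk <- 0.125 * env[i] + 0.875 * spk
      } else if (env[i] > env[last]) {  # stronger peak inside refractory
        peaks[length(peaks)] <- i; last <- i
        spk <- 0.125 * env[i] + 0.875 * spk
      }
    } else {
      npk <- 0.125 * env[i] + 0.875 * npk
    }
    thr <- npk + 0.3125 * (spk - npk)
  }
  if (!length(peaks)) return(integer(0))
  refine_rpeaks(x, peaks, fs, radius = 0.1)
}

#' Refine candidate R-peaks to local signal maxima
#'
#' Moves each candidate index to the absolute maximum of the signal within
#' `+-radius` seconds, preserving order and merging duplicates. Used both to
#' sharpen detector output and to correct provided (annotated) R-peak times.
#'
#' @param x Signal.
#' @param idx Candidate 1-based sample indices.
#' @param fs Sampling rate, Hz.
#' @param radius Search half-window, seconds (default 50 ms).
#' @return Sorted unique refined indices.
#' @export
refine_rpeaks <- function(x, idx, fs, radius = 0.05) {
  if (!length(idx)) return(integer(0))
  r <- max(1L, as.integer(rhalf(radius * fs)))
  n <- length(x)
  out <- vapply(as.integer(idx), function(i) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  sort(unique(out))
}

new_beat_matrix <- function(x, meta, fs) {
  structure(list(x = x, meta = meta, fs = fs,
                 pre = template_pre(fs), post = template_post(fs)),
            class = "beat_matrix")
}

#' @export
print.beat_matrix <- function(x, ...) {
  cat(sprintf("<beat_matrix> %d beats x %d samples (fs %g Hz, R at column %d)\n",
              nrow(x$x), ncol(x$x), x$fs, x$pre + 1L))
  if (nrow(x$meta)) print(table(x$meta$label))
  invisible(x)
}

#' Segment a signal into fixed-length R-centred beat templates
#'
#' Clips a window from 200 ms before to 400 ms after each R-peak
#' (`pre = round(0.2 fs)`, `post = round(0.4 fs)` samples; template length
#' `pre + post` with the R sample at 0-based index `pre`). Beats whose window
#' leaves the signal, straddles an interval boundary, or falls in an `other`
#' interval are dropped; the template label is the interval label.
#'
#' @param x Signal (mV), typically high-pass filtered.
#' @param rpeaks Sorted 1-based R-peak sample indices.
#' @param fs Sampling rate, Hz.
#' @param intervals Data frame `start`, `end` (0-based half-open samples),
#'   `label`; defaults to one NSR interval over the whole signal.
#' @param record,patient Identifiers carried into per-beat metadata.
#' @return A `beat_matrix`: template matrix plus row-aligned metadata
#'   (`record`, `patient`, `r_time`, `next_rr`, `label`, `padded`, `lcsd`).
#' @export
segment_beats <- function(x, rpeaks, fs, intervals = NULL,
                          record = "rec", patient = record) {
  pre <- template_pre(fs); post <- template_post(fs)
  L <- pre + post
  n <- length(x)
  if (is.null(intervals))
    intervals <- data.frame(start = 0L, end = n, label = "NSR",
                            stringsAsFactors = FALSE)
  rpeaks <- as.integer(rpeaks)
  if (is.unsorted(rpeaks, strictly = TRUE)) stop("rpeaks must be sorted")
  rr_next <- c(diff(rpeaks) / fs, NA_real_)

  rows <- list(); meta <- list(); kept <- 0L; dropped <- 0L
  for (k in seq_along(rpeaks)) {
    r0 <- rpeaks[k] - 1L  # 0-based R sample
    lo <- r0 - pre; hi <- r0 + post  # half-open [lo, hi)
    if (lo < 0L || hi > n) { dropped <- dropped + 1L; next }
    hit <- which(intervals$start <= lo & intervals$end >= hi)
    if (!length(hit) || !(intervals$label[hit[1]] %in% c("NSR", "AFib"))) {
      dropped <- dropped + 1L; next
    }
    kept <- kept + 1L
    rows[[kept]] <- x[(lo + 1L):hi]
    meta[[kept]] <- data.frame(
      record = record, patient = patient, r_time = r0 / fs,
      next_rr = rr_next[k], label = intervals$label[hit[1]],
      padded = FALSE, lcsd = NA_real_, stringsAsFactors = FALSE)
  }
  if (dropped)
    message(sprintf("segment_beats: dropped %d boundary/other beats (%s)",
                    dropped, record))
  xm <- if (kept) do.call(rbind, rows) else matrix(numeric(0), 0L, L)
  md <- if (kept) do.call(rbind, meta) else
    data.frame(record = character(0), patient = character(0),
               r_time = numeric(0), next_rr = numeric(0),
               label = character(0), padded = logical(0),
               lcsd = numeric(0), stringsAsFactors = FALSE)
  new_beat_matrix(xm, md, fs)
}

#' Zero-pad an intruding second R-peak out of a template
#'
#' When the next RR-interval is shorter than the 400 ms post-R window, the
#' following beat's R-peak intrudes into the template. All samples from 70 ms
#' before that second peak (to also cover its Q-wave) through the end of the
#' template are set to zero. If the computed start falls before the template's
#' own R sample it is clamped there (the whole post-R tail is zeroed) with a
#' warning. Idempotent.
#'
#' @param template Numeric template vector of length `pre + post`.
#' @param next_rr RR-interval to the next beat, seconds (NA = last beat).
#' @param fs Sampling rate, Hz.
#' @return `list(template, padded)`.
#' @export
pad_second_rpeak <- function(template, next_rr, fs) {
  pre <- template_pre(fs); post <- template_post(fs)
  if (length(template) != pre + post)
    stop("template length must be pre + post")
  if (is.na(next_rr) || next_rr >= post / fs)
    return(list(template = template, padded = FALSE))
  # round-half-even here: the derived padding example (next_rr 0.32 s at
  # 250 Hz -> start 62 samples after R) pins this convention
  start0 <- pre + as.integer(round((next_rr - 0.07) * fs))  # 0-based
  if (start0 < pre) {
    warning("second R-peak pad start clamped to the R sample")
    start0 <- pre
  }
  template[(start0 + 1L):(pre + post)] <- 0
  list(template = template, padded = TRUE)
}

apply_padding <- function(bm) {
  for (i in seq_len(nrow(bm$x))) {
    p <- pad_second_rpeak(bm$x[i, ], bm$meta$next_rr[i], bm$fs)
    bm$x[i, ] <- p$template
    bm$meta$padded[i] <- p$padded
  }
  bm
}

cosine_distance_to_mean <- function(x) {
  m <- colMeans(x)
  nm <- sqrt(sum(m^2))
  apply(x, 1L, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0 || nm == 0) return(Inf)  # degenerate: always an outlier
    1 - sum(v * m) / (nv * nm)
  })
}

#' DMEAN-style cosine-distance outlier rejection
#'
#' Per recording, computes the mean template and flags beat `i` as an outlier
#' when its cosine distance `1 - <x_i, m> / (||x_i|| ||m||)` to that mean
#' exceeds `threshold`. Zero-norm templates are flagged unconditionally. At
#' most `max_frac` of a recording's beats are removed: if more exceed the
#' threshold, only the highest-distance ones up to the cap are dropped.
#'
#' @param bm A `beat_matrix`.
#' @param threshold Cosine-distance threshold, default 0.2.
#' @param max_frac Maximum fraction of a recording's beats to discard.
#' @return `list(kept, outliers)`: the filtered `beat_matrix` and the integer
#'   row indices (into the input) that were removed.
#' @export
dmean_filter <- function(bm, threshold = 0.2, max_frac = 0.3) {
  stopifnot(inherits(bm, "beat_matrix"))
  drop_idx <- integer(0)
  for (rec in unique(bm$meta$record)) {
    rows <- which(bm$meta$record == rec)
    if (length(rows) < 2L) next
    d <- cosine_distance_to_mean(bm$x[rows, , drop = FALSE])
    bad <- which(d > threshold)
    cap <- floor(max_frac * length(rows))
    if (length(bad) > cap) {
      message(sprintf(
        "dmean_filter: capping outliers for %s at %d of %d flagged",
        rec, cap, length(bad)))
      bad <- bad[order(d[bad], decreasing = TRUE)][seq_len(cap)]
    }
    drop_idx <- c(drop_idx, rows[bad])
  }
  keep <- setdiff(seq_len(nrow(bm$x)), drop_idx)
  kept <- new_beat_matrix(bm$x[keep, , drop = FALSE],
                          bm$meta[keep, , drop = FALSE], bm$fs)
  rownames(kept$meta) <- NULL
  list(kept = kept, outliers = sort(drop_idx))
}

#' Run the full preprocessing chain on one record
#'
#' High-pass filter, R-peak detection (or refinement of provided candidate
#' peaks), beat segmentation, second-R-peak padding, per-beat LCSD
#' computation and DMEAN outlier rejection.
#'
#' @param record An `ecg_record`.
#' @param dmean_threshold Cosine-distance threshold (NULL disables DMEAN).
#' @param use_annotated_rpeaks Use the record's annotated R-peaks (refined to
#'   local maxima) instead of running the detector, when available.
#' @param lcsd_scope `"portion"` (denominator = mean RR within each labelled
#'   interval, the AFDB-style default) or `"record"` (whole-record mean RR,
#'   natural for short single-label records).
#' @return A `beat_matrix` with the `lcsd` metadata column filled for
#'   interior beats.
#' @export
preprocess_record <- function(record, dmean_threshold = 0.2,
                              use_annotated_rpeaks = FALSE,
                              lcsd_scope = c("portion", "record")) {
  stopifnot(inherits(record, "ecg_record"))
  lcsd_scope <- match.arg(lcsd_scope)
  xf <- highpass_filter(record$signal, record$fs)
  if (use_annotated_rpeaks && length(record$r_times)) {
    cand <- as.integer(rhalf(record$r_times * record$fs)) + 1L
    cand <- cand[cand >= 1L & cand <= length(xf)]
    rp <- refine_rpeaks(xf, cand, record$fs)
  } else {
    rp <- detect_rpeaks(xf, record$fs)
  }
  bm <- segment_beats(xf, rp, record$fs, record$intervals,
                      record = record$id, patient = record$patient)
  bm <- apply_padding(bm)
  series <- stats::setNames(list((rp - 1L) / record$fs), record$id)
  bm <- attach_lcsd(bm, series, scope = lcsd_scope,
                    intervals = stats::setNames(list(record$intervals),
                                                record$id))
  if (!is.null(dmean_threshold)) bm <- dmean_filter(bm, dmean_threshold)$kept
  bm
}

#' Preprocess a dataset into one pooled beat matrix
#'
#' @param dataset A list of `ecg_record`s (e.g. from [generate_dataset()]).
#' @param ... Passed to [preprocess_record()].
#' @return A pooled `beat_matrix`.
#' @export
preprocess_dataset <- function(dataset, ...) {
  mats <- lapply(dataset, preprocess_record, ...)
  mats <- Filter(function(m) nrow(m$x) > 0, mats)
  if (!length(mats)) stop("no beats survived preprocessing")
  fs <- mats[[1]]$fs
  if (!all(vapply(mats, function(m) m$fs, numeric(1)) == fs))
    stop("all records in a dataset must share one sampling rate")
  new_beat_matrix(do.call(rbind, lapply(mats, `[[`, "x")),
                  do.call(rbind, lapply(mats, `[[`, "meta")), fs)
}
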