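# Rhythm feature: the Local Change of Successive Differences (LCSD), a
# per-beat RR-irregularity statistic, plus the train-set standardization
# applied to model inputs.

#' Compute per-beat LCSD values
#'
#' For a strictly increasing R-peak time series `R_1 .. R_N`, the LCSD of an
#' interior beat `i` (1 < i < N) is the absolute difference of its two
#' adjacent RR-intervals divided by the mean RR-interval of the series:
#' `|(R_{i+1} - R_i) - (R_i - R_{i-1})| / mean(diff(R))`. The first and last
#' beats are undefined and returned as `NA`. The statistic is dimensionless,
#' non-negative and invariant under uniform time scaling.
#'
#' @param r_times Strictly increasing R-peak times, seconds.
#' @return Numeric vector of length `length(r_times)`; `NA` at the
#'   boundaries, and all `NA` when fewer than 3 peaks are given.
#' @examples
#' compute_lcsd(c(0.0, 0.8, 1.4, 2.4))  # NA 0.25 0.50 NA
#' @export
compute_lcsd <- function(r_times) {
  n <- length(r_times)
  if (n < 3L) return(rep(NA_real_, n))
  if (is.unsorted(r_times, strictly = TRUE))
    stop("r_times must be strictly increasing")
  rr <- diff(r_times)
  mean_rr <- mean(rr)
  out <- rep(NA_real_, n)
  i <- 2:(n - 1L)
  out[i] <- abs(rr[i] - rr[i - 1L]) / mean_rr
  out
}

#' Attach LCSD values to a beat matrix
#'
#' Computes LCSD from each recording's full detected R-peak series (not the
#' surviving-template set, so outlier removal never changes a neighbour's
#' value) and writes it into the `lcsd` metadata column, matching beats to
#' series entries by R time. With `scope = "portion"` the series is split at
#' labelled-interval boundaries and the mean-RR denominator is computed per
#' portion; with `"record"` the whole series is used.
#'
#' @param bm A `beat_matrix`.
#' @param series Named list: recording id -> numeric vector of R times
#'   (seconds) for that recording.
#' @param scope `"portion"` or `"record"`.
#' @param intervals Named list: recording id -> interval data frame (needed
#'   for `scope = "portion"`; falls back to `"record"` when absent).
#' @return The `beat_matrix` with `lcsd` filled (NA for boundary beats).
#' @export
attach_lcsd <- function(bm, series, scope = c("record", "portion"),
                        intervals = NULL) {
  stopifnot(inherits(bm, "beat_matrix"))
  scope <- match.arg(scope)
  tol <- 0.5 / bm$fs
  for (rec in unique(bm$meta$record)) {
    if (is.null(series[[rec]]))
      stop("no R-peak series provided for recording ", rec)
    rt <- series[[rec]]
    rows <- which(bm$meta$record == rec)
    iv <- if (!is.null(intervals)) intervals[[rec]] else NULL
    if (scope == "portion" && !is.null(iv) && nrow(iv) > 0L) {
      vals <- rep(NA_real_, length(rt))
      for (j in seq_len(nrow(iv))) {
        lo <- iv$start[j] / bm$fs; hi <- iv$end[j] / bm$fs
        in_port <- which(rt >= lo - tol & rt < hi)
        if (length(in_port) >= 3L)
          vals[in_port] <- compute_lcsd(rt[in_port])
      }
    } else {
      vals <- compute_lcsd(rt)
    }
    pos <- vapply(bm$meta$r_time[rows], function(t0) {
      k <- which.min(abs(rt - t0))
      if (abs(rt[k] - t0) <= tol) k else NA_integer_
    }, integer(1))
    bm$meta$lcsd[rows] <- ifelse(is.na(pos), NA_real_, vals[pos])
  }
  bm
}

#' Drop beats with undefined LCSD
#'
#' @param bm A `beat_matrix` whose `lcsd` column has been filled.
#' @return The matrix restricted to beats with a defined LCSD value.
#' @export
drop_undefined_lcsd <- function(bm) {
  keep <- which(!is.na(bm$meta$lcsd))
  n_drop <- nrow(bm$x) - length(keep)
  if (n_drop)
    message(sprintf("dropping %d beats with undefined LCSD", n_drop))
  out <- bm
  out$x <- bm$x[keep, , drop = FALSE]
  out$meta <- bm$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out
}

#' Fit a per-feature standardizer on training data
#'
#' Column means and standard deviations learned on the training rows only;
#' validation and test inputs are transformed with these training statistics.
#' Constant columns get their SD replaced by 1 (the standardized column is
#' then all zeros).
#'
#' @param x Numeric training matrix (rows = samples).
#' @return An object of class `standardizer`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd_ <- apply(x, 2L, stats::sd)
  if (nrow(x) < 2L) sd_ <- rep(1, ncol(x))
  zero <- which(!is.finite(sd_) | sd_ == 0)
  if (length(zero)) {
    message(sprintf("fit_standardizer: %d constant feature(s); sd set to 1",
                    length(zero)))
    sd_[zero] <- 1
  }
  structure(list(mean = mu, sd = sd_), class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param sc A `standardizer` from [fit_standardizer()].
#' @param x Matrix with the same number of columns as the training data.
#' @return The standardized matrix `(x - mean) / sd`.
#' @export
apply_standardizer <- function(sc, x) {
  if (!inherits(sc, "standardizer"))
    stop("fit_standardizer() must be called before apply_standardizer()")
  x <- as.matrix(x)
  if (ncol(x) != length(sc$mean))
    stop("column count does not match the fitted standardizer")
  sweep(sweep(x, 2L, sc$mean, "-"), 2L, sc$sd, "/")
}

#' Write standardizer parameters to JSON
#' @param sc A `standardizer`.
#' @param path Output file.
#' @export
write_standardizer <- function(sc, path) {
  jsonlite::write_json(list(mean = sc$mean, sd = sc$sd), path, digits = NA)
  invisible(path)
}

#' Read standardizer parameters from JSON
#' @param path JSON file written by [write_standardizer()].
#' @export
read_standardizer <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(d$mean), sd = as.numeric(d$sd)),
            class = "standardizer")
}

#' Export per-beat LCSD values as CSV
#' @param bm A `beat_matrix` with LCSD attached.
#' @param path Output CSV (`recording,beat_index,R_time_s,lcsd`).
#' @export
write_lcsd_csv <- function(bm, path) {
  d <- data.frame(recording = bm$meta$record,
                  beat_index = seq_len(nrow(bm$meta)),
                  R_time_s = bm$meta$r_time,
                  lcsd = bm$meta$lcsd)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
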