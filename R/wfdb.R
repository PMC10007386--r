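# Minimal WFDB-compatible I/O: text header (.hea), 16-bit little-endian
# signal files (format 16), and MIT-format binary annotation files.
# Covers exactly what AFDB-like records need: multi-channel format-16
# signals, rhythm-change annotations with aux strings ("(N", "(AFIB", ...)
# and QRS annotations. Annotation words are 2 bytes little-endian with the
# type code in the high 6 bits and the sample increment in the low 10 bits;
# SKIP (59) escapes larger increments with a 4-byte PDP-11-ordered operand
# and AUX (63) carries a byte-counted string.

ANN_NORMAL <- 1L
ANN_RHYTHM <- 28L
ANN_AUX <- 63L
ANN_SKIP <- 59L

ann_word <- function(code, incr) {
  stopifnot(incr >= 0, incr < 1024)
  v <- bitwOr(bitwShiftL(code, 10L), as.integer(incr))
  as.raw(c(bitwAnd(v, 255L), bitwShiftR(v, 8L)))
}

# 4-byte SKIP operand: high 16 bits first, each word little-endian
skip_operand <- function(x) {
  hi <- bitwShiftR(x, 16L); lo <- bitwAnd(x, 65535L)
  as.raw(c(bitwAnd(hi, 255L), bitwShiftR(hi, 8L),
           bitwAnd(lo, 255L), bitwShiftR(lo, 8L)))
}

write_annotations <- function(path, samples, codes, aux = NULL) {
  o <- order(samples)
  samples <- as.integer(samples[o]); codes <- as.integer(codes[o])
  if (!is.null(aux)) aux <- aux[o]
  out <- raw(0)
  prev <- 0L
  for (i in seq_along(samples)) {
    incr <- samples[i] - prev
    if (incr < 0) stop("annotation samples must be non-decreasing")
    if (incr >= 1024L) {
      out <- c(out, ann_word(ANN_SKIP, 0L), skip_operand(incr))
      incr <- 0L
    }
    out <- c(out, ann_word(codes[i], incr))
    prev <- samples[i]
    if (!is.null(aux) && !is.na(aux[i]) && nzchar(aux[i])) {
      ab <- charToRaw(aux[i])
      out <- c(out, ann_word(ANN_AUX, length(ab)), ab)
      if (length(ab) %% 2L == 1L) out <- c(out, as.raw(0))
    }
  }
  out <- c(out, as.raw(c(0, 0)))
  writeBin(out, path)
  invisible(path)
}

read_annotations <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  i <- 1L; tcur <- 0L
  samples <- integer(0); codes <- integer(0); aux <- character(0)
  pending_skip <- 0L
  while (i + 1L <= length(b)) {
    v <- as.integer(b[i]) + 256L * as.integer(b[i + 1L]); i <- i + 2L
    code <- bitwShiftR(v, 10L); incr <- bitwAnd(v, 1023L)
    if (v == 0L) break
    if (code == ANN_SKIP) {
      hi <- as.integer(b[i]) + 256L * as.integer(b[i + 1L])
      lo <- as.integer(b[i + 2L]) + 256L * as.integer(b[i + 3L])
      pending_skip <- hi * 65536L + lo
      i <- i + 4L
    } else if (code == ANN_AUX) {
      nb <- incr
      s <- rawToChar(b[i:(i + nb - 1L)])
      i <- i + nb + (nb %% 2L)
      if (length(aux)) aux[length(aux)] <- s
    } else {
      tcur <- tcur + incr + pending_skip
      pending_skip <- 0L
      samples <- c(samples, tcur); codes <- c(codes, code)
      aux <- c(aux, NA_character_)
    }
  }
  data.frame(sample = samples, code = codes, aux = aux,
             stringsAsFactors = FALSE)
}

#' Export an ECG record as WFDB-compatible files
#'
#' Writes `<record>.hea`, a format-16 `<record>.dat` (signal quantised to
#' integer ADC units), a rhythm annotation file `<record>.atr` holding the
#' interval labels as aux strings (`(N`, `(AFIB`) and, when R-peak times are
#' present, a `<record>.qrs` file of QRS annotations.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory.
#' @param gain ADC units per millivolt.
#' @return The record path prefix, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, record$id)
  adc <- as.integer(rhalf(record$signal * gain))
  n <- length(adc)
  hea <- c(sprintf("%s 1 %g %d", record$id, record$fs, n),
           sprintf("%s.dat 16 %g 16 0 %d 0 0 ECG1", record$id, gain, adc[1]),
           sprintf("# patient %s", record$patient))
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(adc, con, size = 2L, endian = "little")
  close(con)
  if (nrow(record$intervals)) {
    aux <- ifelse(record$intervals$label == "AFib", "(AFIB",
                  ifelse(record$intervals$label == "NSR", "(N", "(OTHER"))
    write_annotations(paste0(base, ".atr"),
                      record$intervals$start,
                      rep(ANN_RHYTHM, nrow(record$intervals)), aux)
  }
  if (length(record$r_times)) {
    rs <- as.integer(rhalf(record$r_times * record$fs))
    write_annotations(paste0(base, ".qrs"), rs,
                      rep(ANN_NORMAL, length(rs)))
  }
  invisible(base)
}

read_wfdb_signal <- function(base) {
  hea <- readLines(paste0(base, ".hea"), warn = FALSE)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  sig_lines <- hea[2:(1 + nsig)]
  f1 <- strsplit(trimws(sig_lines[1]), "\\s+")[[1]]
  if (f1[2] != "16") stop("only WFDB format 16 is supported")
  gain <- as.numeric(f1[3]); if (is.na(gain) || gain == 0) gain <- 200
  patient <- NA_character_
  pl <- grep("^# patient ", hea, value = TRUE)
  if (length(pl)) patient <- sub("^# patient ", "", pl[1])
  con <- file(paste0(base, ".dat"), "rb")
  raw_all <- readBin(con, "integer", n = nsig * nsamp, size = 2L,
                     endian = "little", signed = TRUE)
  close(con)
  if (length(raw_all) < nsig * nsamp) stop("signal file truncated: ", base)
  # samples are interleaved across channels; keep channel 0 only
  ch0 <- raw_all[seq(1L, by = nsig, length.out = nsamp)]
  list(signal = ch0 / gain, fs = fs, n = nsamp, patient = patient,
       id = top[1])
}

map_rhythm_label <- function(aux) {
  lab <- sub("^\\(", "", aux)
  ifelse(lab == "AFIB", "AFib", ifelse(lab == "N", "NSR", "other"))
}

#' Read an AFDB-like WFDB record
#'
#' Loads channel 0 (`ECG1`) of a WFDB record, converts rhythm-change
#' annotations into half-open labelled intervals (`(AFIB` to AFib, `(N` to
#' NSR, anything else to `other`) and retains QRS annotation times as
#' candidate R-peaks to be refined downstream.
#'
#' @param base Record path prefix (no extension).
#' @param qrs_ext Extension of the QRS annotation file, default `"qrs"`.
#' @return An `ecg_record` with provenance `"afdb-like"`.
#' @export
read_afdb_record <- function(base, qrs_ext = "qrs") {
  sig <- read_wfdb_signal(base)
  intervals <- data.frame(start = integer(0), end = integer(0),
                          label = character(0), stringsAsFactors = FALSE)
  atr <- paste0(base, ".atr")
  if (file.exists(atr)) {
    ann <- read_annotations(atr)
    rhy <- ann[ann$code == ANN_RHYTHM & !is.na(ann$aux), , drop = FALSE]
    if (nrow(rhy)) {
      starts <- rhy$sample
      ends <- c(rhy$sample[-1], sig$n)
      keep <- ends > starts
      intervals <- data.frame(start = as.integer(starts[keep]),
                              end = as.integer(pmin(ends[keep], sig$n)),
                              label = map_rhythm_label(rhy$aux[keep]),
                              stringsAsFactors = FALSE)
    }
  } else {
    warning("no rhythm annotation file for record ", basename(base),
            "; intervals left empty")
  }
  r_times <- numeric(0)
  qrsf <- paste0(base, ".", qrs_ext)
  if (file.exists(qrsf)) {
    qa <- read_annotations(qrsf)
    r_times <- qa$sample[qa$code == ANN_NORMAL] / sig$fs
  }
  new_ecg_record(sig$id, sig$patient %||% sig$id, sig$signal, sig$fs,
                 intervals, r_times, character(0), "afdb-like")
}

#' Read a CinC2017-style single-lead record
#'
#' Reads a short single-channel WFDB or CSV record and attaches one
#' whole-record interval whose label comes from a `record,label` manifest
#' (CinC2017 `REFERENCE.csv` dialect): `N` maps to NSR, `A` to AFib and any
#' other letter (other rhythms, `~` noisy) to `other`, which downstream beat
#' extraction excludes.
#'
#' @param path WFDB path prefix or a CSV file with columns `t,signal` (CSV
#'   requires `fs`).
#' @param manifest Data frame with columns `record` and `label`, or path to
#'   such a CSV (headerless, as in REFERENCE.csv).
#' @param fs Sampling rate for CSV input.
#' @return An `ecg_record` with provenance `"cinc-like"`.
#' @export
read_cinc_record <- function(path, manifest, fs = NULL) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, header = FALSE,
                                col.names = c("record", "label"),
                                stringsAsFactors = FALSE)
  if (grepl("\\.csv$", path)) {
    d <- utils::read.csv(path)
    if (is.null(fs)) stop("fs is required for CSV input")
    id <- sub("\\.csv$", "", basename(path))
    sig <- list(signal = d$signal, fs = fs, n = nrow(d), id = id,
                patient = id)
  } else {
    sig <- read_wfdb_signal(path)
  }
  row <- manifest[manifest$record == sig$id, , drop = FALSE]
  if (!nrow(row))
    stop("record ", sig$id, " not found in the label manifest")
  lab <- switch(row$label[1], N = "NSR", A = "AFib", "other")
  intervals <- data.frame(start = 0L, end = sig$n, label = lab,
                          stringsAsFactors = FALSE)
  new_ecg_record(sig$id, sig$patient %||% sig$id, sig$signal, sig$fs,
                 intervals, numeric(0), character(0), "cinc-like")
}
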