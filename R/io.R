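#' Continuous multichannel recording container
#'
#' @param signal channels x samples numeric matrix, in microvolts
#' @param rate sampling rate in Hz; raw acquisitions must be >= 1000 Hz
#' @param channel_ids character vector, one per row of `signal`
#' @param channel_roles per-channel role, `"lfp"` (microwire) or `"ieeg"`
#'   (macro contact)
#' @return an object of class `continuous_recording`
#' @export
continuous_recording <- function(signal, rate, channel_ids, channel_roles) {
  signal <- as.matrix(signal)
  stopifnot(length(channel_ids) == nrow(signal),
            length(channel_roles) == nrow(signal))
  if (rate < 1000) {
    stop("recording rate must be >= 1000 Hz", call. = FALSE)
  }
  if (anyNA(signal)) stop("recording contains NA samples", call. = FALSE)
  bad <- setdiff(channel_roles, c("lfp", "ieeg"))
  if (length(bad)) {
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(signal = signal, rate = rate,
                 channel_ids = as.character(channel_ids),
                 channel_roles = as.character(channel_roles)),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$rate, ncol(x$signal) / x$rate))
  cat("  roles:", paste(sprintf("%s[%s]", x$channel_ids, x$channel_roles),
                        collapse = " "), "\n")
  invisible(x)
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------
# No EDF reader/writer is available in the installed R stack, so a minimal
# single-rate EDF implementation is provided: 1-s data records, physical
# units uV, channel role carried in the transducer field.

edf_field <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' All channels share the sampling rate; the signal length must be a whole
#' number of seconds (EDF data records are 1 s here). Amplitudes are scaled
#' per channel to the 16-bit digital range, so round-trips are exact to
#' ~1e-4 relative quantization error.
#'
#' @param recording a [continuous_recording()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  rate <- recording$rate
  if (rate != round(rate)) stop("EDF writer needs an integer rate", call. = FALSE)
  n <- ncol(recording$signal)
  if (n %% rate != 0) {
    stop("signal length must be a whole number of seconds for EDF output",
         call. = FALSE)
  }
  ns <- nrow(recording$signal)
  n_rec <- n %/% rate

  pmin_s <- pmax_s <- character(ns)
  dig <- matrix(0L, ns, n)
  for (i in seq_len(ns)) {
    a <- max(abs(recording$signal[i, ]), 1e-6)
    pmax_s[i] <- edf_field(sprintf("%.6g", a), 8)
    pmin_s[i] <- edf_field(sprintf("%.6g", -a), 8)
    a_used <- as.numeric(trimws(pmax_s[i]))
    dig[i, ] <- as.integer(round(recording$signal[i, ] / a_used * 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_field("0", 8))
  wr(edf_field("X X X X", 80))
  wr(edf_field("Startdate X X X X", 80))
  wr(edf_field("01.01.00", 8)); wr(edf_field("00.00.00", 8))
  wr(edf_field(sprintf("%d", 256L * (1L + ns)), 8))
  wr(edf_field("", 44))
  wr(edf_field(sprintf("%d", n_rec), 8))
  wr(edf_field("1", 8))
  wr(edf_field(sprintf("%d", ns), 4))
  wr(paste(edf_field(recording$channel_ids, 16), collapse = ""))
  wr(paste(edf_field(recording$channel_roles, 80), collapse = ""))
  wr(paste(edf_field(rep("uV", ns), 8), collapse = ""))
  wr(paste(pmin_s, collapse = ""))
  wr(paste(pmax_s, collapse = ""))
  wr(paste(edf_field(rep("-32767", ns), 8), collapse = ""))
  wr(paste(edf_field(rep("32767", ns), 8), collapse = ""))
  wr(paste(edf_field(rep("", ns), 80), collapse = ""))
  wr(paste(edf_field(rep(sprintf("%d", rate), ns), 8), collapse = ""))
  wr(paste(edf_field(rep("", ns), 32), collapse = ""))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * rate + 1L):(r * rate)
    for (i in seq_len(ns)) {
      writeBin(dig[i, idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any single-rate EDF)
#'
#' Channels whose transducer field is not a known role (`lfp`/`ieeg`) are
#' skipped with a warning; the number skipped is recorded in the
#' `"skipped_channels"` attribute for manifest bookkeeping.
#'
#' @param path EDF file path
#' @return a [continuous_recording()]
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  roles <- vapply(seq_len(ns), function(i) rd(80), "")
  vapply(seq_len(ns), function(i) rd(8), "")   # phys dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "")  # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1L) {
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  }
  rate <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  known <- roles %in% c("lfp", "ieeg")
  n_skipped <- sum(!known)
  if (n_skipped > 0) {
    warning(sprintf("skipping %d channel(s) with unknown role: %s",
                    n_skipped, paste(labels[!known], collapse = ", ")),
            call. = FALSE)
  }
  rec <- continuous_recording(sig[known, , drop = FALSE], rate,
                              labels[known], roles[known])
  attr(rec, "skipped_channels") <- n_skipped
  rec
}

# ---- WAV (mono PCM16) ------------------------------------------------------

#' Write a mono 16-bit PCM WAV file
#' @param waveform numeric vector in [-1, 1]
#' @param rate sampling rate in Hz
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(waveform, rate, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- 2L * length(pcm)
  writeBin(charToRaw("RIFF"), con)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#' @param path WAV file path
#' @return list with `waveform` (numeric in [-1, 1]) and `rate`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4)) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little")
  if (rawToChar(readBin(con, "raw", 4)) != "WAVE") stop("not a WAV file")
  rate <- NULL; wav <- NULL
  repeat {
    id <- readBin(con, "raw", 4)
    if (length(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", size - 8)
    } else if (tag == "data") {
      wav <- readBin(con, "integer", size / 2, size = 2, endian = "little")
    } else {
      readBin(con, "raw", size)
    }
    if (!is.null(rate) && !is.null(wav)) break
  }
  list(waveform = wav / 32767, rate = rate)
}

# ---- TSV tables ------------------------------------------------------------

read_tsv_checked <- function(path, cols) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[, cols, drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trial table I/O (TSV: trial_id, stimulus_id, stim_type, onset_s,
#' duration_s, state)
#' @param trial_table data.frame in the trial-table dialect
#' @param path file path
#' @return the trial table (read) or `path` invisibly (write)
#' @export
write_trial_table <- function(trial_table, path) {
  cols <- c("trial_id", "stimulus_id", "stim_type", "onset_s",
            "duration_s", "state")
  write_tsv(trial_table[, cols], path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- read_tsv_checked(path, c("trial_id", "stimulus_id", "stim_type",
                                 "onset_s", "duration_s", "state"))
  d <- diff(df$onset_s)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop(sprintf("trial table onsets not strictly increasing at row %d (trial %s)",
                 bad, df$trial_id[bad]), call. = FALSE)
  }
  df
}

#' Spike table I/O (TSV: cluster_id, channel_id, spike_time_s)
#' @param spikes data.frame of sorted spike times
#' @param path file path
#' @export
write_spike_table <- function(spikes, path) {
  write_tsv(spikes[, c("cluster_id", "channel_id", "spike_time_s")], path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  df <- read_tsv_checked(path, c("cluster_id", "channel_id", "spike_time_s"))
  for (cl in unique(df$cluster_id)) {
    tt <- df$spike_time_s[df$cluster_id == cl]
    if (is.unsorted(tt)) {
      stop(sprintf("spike times of cluster %s are not sorted", cl),
           call. = FALSE)
    }
  }
  df
}

#' Hypnogram I/O (TSV: epoch_start_s, label; 30-s epochs)
#' @param hypnogram data.frame with `epoch_start_s` and `label`
#' @param path file path
#' @export
write_hypnogram <- function(hypnogram, path) {
  write_tsv(hypnogram[, c("epoch_start_s", "label")], path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- read_tsv_checked(path, c("epoch_start_s", "label"))
  if (nrow(df) > 1 && any(diff(df$epoch_start_s) != 30)) {
    stop("hypnogram epochs must be contiguous 30-s epochs", call. = FALSE)
  }
  df
}

#' Ground-truth sidecar I/O (JSON)
#' @param gt a `session_ground_truth` object
#' @param path file path
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hypnogram <- as.data.frame(x$hypnogram)
  x$channels <- as.data.frame(x$channels)
  x$clusters <- as.data.frame(x$clusters)
  class(x) <- "session_ground_truth"
  x
}
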