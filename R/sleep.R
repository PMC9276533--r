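#' Automatic iEEG-based sleep scoring from 30-s delta power
#'
#' Scores each 30-s epoch from the delta (0.5--4 Hz) power of the iEEG
#' spectrogram, averaged across iEEG channels: epochs above the 55th
#' percentile become NREM sleep; epochs below the 20th percentile become
#' wakefulness/REM candidates, split by a behaviour proxy (the stand-in for
#' video): candidates with awake evidence (eyes open, moving) become W;
#' candidates lying in the second part of the night inside long (> 3 min)
#' quiescent periods become REM. Everything else — including the
#' 20th--55th percentile range — is left `undetermined` and excluded from
#' downstream trial-state assignment. Percentiles are scale-free, so the
#' hypnogram is invariant to amplitude rescaling of the recording.
#'
#' @param spect a [spectrogram_30s()] object, or a numeric vector of
#'   per-epoch delta power
#' @param behavior optional data.frame with per-epoch logical columns
#'   `awake_evidence` and `quiescent` (mutually exclusive); without it,
#'   W/REM candidates stay undetermined (with a warning)
#' @param nrem_pct,wrem_pct percentile thresholds (defaults 0.55 / 0.20)
#' @param rem_min_s minimum quiescent run length for REM, default 180 s
#' @param epoch_s epoch length, default 30 s
#' @return hypnogram data.frame (`epoch_start_s`, `label`) with labels in
#'   `{W, NREM, REM, undetermined}` and attribute `provenance = "automatic"`
#' @export
auto_score <- function(spect, behavior = NULL, nrem_pct = 0.55,
                       wrem_pct = 0.20, rem_min_s = 180, epoch_s = 30) {
  if (inherits(spect, "spectrogram30s")) {
    delta <- epoch_band_power(spect, 0.5, 4)
    starts <- spect$epoch_start_s
  } else {
    delta <- as.numeric(spect)
    starts <- (seq_along(delta) - 1) * epoch_s
  }
  n <- length(delta)
  if (n < 20) stop("at least 20 epochs are needed for percentile scoring",
                   call. = FALSE)
  q_hi <- pctl(delta, nrem_pct)
  q_lo <- pctl(delta, wrem_pct)
  label <- rep("undetermined", n)
  label[delta > q_hi] <- "NREM"
  cand <- delta < q_lo
  if (any(cand)) {
    if (is.null(behavior)) {
      warning("no behaviour proxy: W/REM candidate epochs left undetermined",
              call. = FALSE)
    } else {
      stopifnot(nrow(behavior) == n)
      if (any(behavior$awake_evidence & behavior$quiescent)) {
        stop("behaviour flags must be mutually exclusive", call. = FALSE)
      }
      label[cand & behavior$awake_evidence] <- "W"
      # candidates inside long quiescent periods, in the second half of
      # the night (quiescence typically spans whole sleep bouts, so the
      # run itself may begin earlier)
      qruns <- mask_runs(behavior$quiescent)
      for (i in seq_len(nrow(qruns))) {
        len_s <- (qruns$end[i] - qruns$start[i]) * epoch_s
        if (len_s > rem_min_s) {
          idx <- qruns$start[i]:(qruns$end[i] - 1L)
          idx <- idx[idx > n / 2]
          label[idx][cand[idx]] <- "REM"
        }
      }
    }
  }
  h <- data.frame(epoch_start_s = starts, label = label,
                  stringsAsFactors = FALSE)
  attr(h, "provenance") <- "automatic"
  h
}

#' Per-state agreement between an automatic and a reference hypnogram
#'
#' For each automatic label in `{W, NREM, REM}`, the percentage of epochs
#' carrying that label whose reference label matches (automatic NREM
#' matches reference N2, N3 or NREM; W matches W; REM matches REM).
#' Undetermined automatic epochs are excluded from all denominators.
#'
#' @param auto automatic hypnogram (data.frame `epoch_start_s`, `label`)
#' @param reference reference hypnogram on the same epoch grid
#' @return named numeric vector of percent agreement for `W`, `NREM`,
#'   `REM` (`NaN` where the automatic scorer emitted no such epoch)
#' @export
agreement <- function(auto, reference) {
  if (nrow(auto) != nrow(reference) ||
      any(auto$epoch_start_s != reference$epoch_start_s)) {
    stop("hypnograms are not on the same epoch grid", call. = FALSE)
  }
  match_sets <- list(W = "W", NREM = c("N2", "N3", "NREM"), REM = "REM")
  vapply(names(match_sets), function(lbl) {
    idx <- auto$label == lbl
    if (!any(idx)) return(NaN)
    100 * mean(reference$label[idx] %in% match_sets[[lbl]])
  }, numeric(1))
}
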