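#' Trial epoch container
#'
#' An epoch is a time x electrode voltage matrix (microvolts) for one trial,
#' with its sampling rate and the time of the first sample relative to audio
#' onset. All package timing is expressed in seconds relative to audio onset
#' (audio onset = 0 s, video onset = -1 s).
#'
#' @param data numeric matrix, rows are time samples, columns electrodes.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds relative to audio onset
#'   (negative for pre-stimulus coverage).
#' @return An object of class `epoch_array`.
#' @export
epoch_array <- function(data, fs, t0) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_stgflow("epoch data must be a numeric matrix (time x electrode)")
  if (anyNA(data)) stop_stgflow("epoch data contains NA values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_stgflow("fs must be a positive scalar (Hz)")
  structure(list(data = data, fs = fs, t0 = t0), class = "epoch_array")
}

#' Time axis of an epoch
#'
#' @param epoch an [epoch_array()].
#' @return numeric vector of sample times (s, relative to audio onset).
#' @export
epoch_times <- function(epoch) {
  epoch$t0 + (seq_len(nrow(epoch$data)) - 1L) / epoch$fs
}

## indices of samples with t in [t_lo, t_hi)
epoch_window_idx <- function(epoch, t_lo, t_hi) {
  tt <- epoch_times(epoch)
  which(tt >= t_lo & tt < t_hi)
}

#' @export
print.epoch_array <- function(x, ...) {
  cat(sprintf("<epoch_array> %d samples x %d electrodes, fs = %g Hz, t = [%.3f, %.3f] s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0,
              x$t0 + (nrow(x$data) - 1) / x$fs))
  invisible(x)
}

#' Write a simulated or recorded dataset to disk
#'
#' Trial metadata go to a plain CSV (`trials.csv`, columns trial_id,
#' video_phoneme, audio_phoneme, response, category, audio_onset) and the
#' signals to an array container (`signals.rds`) holding one matrix per trial
#' with `fs` and `t0` attached. Both files are byte-identical across runs for
#' identical inputs.
#'
#' @param dataset a list with elements `trials` (data.frame) and `epochs`
#'   (list of [epoch_array()]), as returned by [simulate_dataset()].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- dataset$trials
  cols <- c("trial_id", "video_phoneme", "audio_phoneme", "response",
            "category", "audio_onset")
  write.csv(tr[, cols], file.path(dir, "trials.csv"), row.names = FALSE)
  sig <- lapply(dataset$epochs, function(e) {
    m <- e$data
    attr(m, "fs") <- e$fs
    attr(m, "t0") <- e$t0
    m
  })
  saveRDS(list(signals = sig, config = dataset$config %||% NULL),
          file.path(dir, "signals.rds"), version = 2)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing `trials.csv` and `signals.rds`.
#' @return a list with `trials`, `epochs` and `config`.
#' @export
read_dataset <- function(dir) {
  fcsv <- file.path(dir, "trials.csv")
  frds <- file.path(dir, "signals.rds")
  for (f in c(fcsv, frds))
    if (!file.exists(f)) stop_stgflow("missing dataset file: ", f)
  trials <- read.csv(fcsv, stringsAsFactors = FALSE)
  raw <- readRDS(frds)
  epochs <- lapply(raw$signals, function(m) {
    fs <- attr(m, "fs"); t0 <- attr(m, "t0")
    attr(m, "fs") <- NULL; attr(m, "t0") <- NULL
    epoch_array(m, fs = fs, t0 = t0)
  })
  list(trials = trials, epochs = epochs, config = raw$config)
}
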