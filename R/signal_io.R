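# EDF signal input, hypnogram label mapping, and epoch segmentation.

#' The five sleep stages
#'
#' Canonical AASM five-class stage labels in canonical order.
#' @return character vector `c("W", "N1", "N2", "N3", "R")`.
#' @export
sleep_stages <- function() c("W", "N1", "N2", "N3", "R")

.pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a multi-channel signal to an EDF file
#'
#' Minimal EDF writer (one-second data records, 16-bit integers). Physical
#' ranges default to `[-32768, 32767]` with unit scaling so that
#' integer-valued samples in range survive a write/read round trip exactly.
#' All channels must share the same duration in whole seconds.
#'
#' @param path output file.
#' @param channels list of channels, each `list(samples=, sampling_rate=,
#'   label=)`.
#' @param physical_min,physical_max physical calibration range applied to
#'   every channel.
#' @return `path`, invisibly.
#' @export
write_edf_signal <- function(path, channels,
                             physical_min = -32768, physical_max = 32767) {
  ns <- length(channels)
  dur <- unique(vapply(channels,
                       function(ch) length(ch$samples) / ch$sampling_rate,
                       numeric(1)))
  if (length(dur) != 1L || dur %% 1 != 0)
    stop("all channels must cover the same whole number of seconds")
  n_rec <- as.integer(dur)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .pad_field("0", 8),
    .pad_field("X X X X", 80),
    .pad_field("Startdate X X X X", 80),
    .pad_field("01.01.01", 8), .pad_field("00.00.00", 8),
    .pad_field(256 * (ns + 1L), 8),
    .pad_field("", 44),
    .pad_field(n_rec, 8),
    .pad_field(1, 8),
    .pad_field(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  field <- function(get, width)
    paste0(vapply(channels, function(ch) .pad_field(get(ch), width),
                  character(1)), collapse = "")
  sig_hdr <- paste0(
    field(function(ch) ch$label, 16),
    field(function(ch) "", 80),
    field(function(ch) "uV", 8),
    field(function(ch) physical_min, 8),
    field(function(ch) physical_max, 8),
    field(function(ch) -32768, 8),
    field(function(ch) 32767, 8),
    field(function(ch) "", 80),
    field(function(ch) as.integer(ch$sampling_rate), 8),
    field(function(ch) "", 32))
  writeChar(sig_hdr, con, nchars = nchar(sig_hdr), eos = NULL)
  scale <- (physical_max - physical_min) / (32767 - (-32768))
  dig <- lapply(channels, function(ch) {
    d <- round((ch$samples - physical_min) / scale) - 32768
    if (any(d < -32768 | d > 32767))
      stop("samples outside the physical calibration range")
    as.integer(d)
  })
  spr <- vapply(channels, function(ch) as.integer(ch$sampling_rate), integer(1))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      idx <- ((r - 1L) * spr[s] + 1L):(r * spr[s])
      writeBin(dig[[s]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read one channel from an EDF/EDF+ file
#'
#' Parses the standard EDF header, locates the named channel, and returns
#' its physically calibrated samples with the sampling rate taken from the
#' header (samples per record / record duration).
#'
#' @param path EDF file.
#' @param channel_name label of the channel to extract (exact match after
#'   trimming whitespace).
#' @return list with `samples`, `sampling_rate`, `channel_name`
#'   (class `eeg_recording`).
#' @export
read_edf_signal <- function(path, channel_name) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0"))
    stop("not an EDF file (unsupported version field): ", path)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")
  rdv <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), character(1))
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  sel <- which(labels == trimws(channel_name))
  if (length(sel) != 1L)
    stop("channel '", channel_name, "' not found; available: ",
         paste(labels, collapse = ", "))
  raw <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                   endian = "little")
      if (s == sel) raw[[r]] <- v
    }
  }
  dig <- unlist(raw)
  phys <- pmin[sel] + (dig - dmin[sel]) *
    (pmax[sel] - pmin[sel]) / (dmax[sel] - dmin[sel])
  structure(list(samples = phys,
                 sampling_rate = spr[sel] / rec_dur,
                 channel_name = labels[sel]),
            class = "eeg_recording")
}

#' Map a legacy hypnogram token to an AASM stage
#'
#' Sleep-EDF hypnograms score with R&K labels: stages 3 and 4 merge to N3
#' under the five-class AASM taxonomy; movement and unscored epochs map to
#' `NA` (the epoch is dropped, not relabeled). An unrecognised token is an
#' error rather than a silent drop.
#'
#' @param raw_label hypnogram token, e.g. `"Sleep stage 2"` or `"2"`.
#' @return one of `sleep_stages()`, or `NA_character_` for
#'   movement/unscored epochs.
#' @export
map_legacy_stage <- function(raw_label) {
  key <- trimws(sub("^Sleep stage ", "", trimws(raw_label)))
  switch(key,
    "W" = "W",
    "1" = ,
    "N1" = "N1",
    "2" = ,
    "N2" = "N2",
    "3" = ,
    "4" = ,
    "N3" = "N3",
    "R" = "R",
    "?" = NA_character_,
    "Movement time" = ,
    "M" = NA_character_,
    stop("unrecognised hypnogram token: '", raw_label, "'"))
}

#' Read a hypnogram annotation file
#'
#' Plain-text CSV with columns `onset`, `duration`, `label` (seconds,
#' seconds, raw stage token).
#'
#' @param path CSV file.
#' @return data.frame with the three columns.
#' @export
read_hypnogram <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "label")
  if (!all(need %in% names(h)))
    stop("hypnogram must have columns onset, duration, label")
  h[need]
}

#' Segment a recording into labeled 30-second epochs
#'
#' Cuts consecutive non-overlapping 30-s epochs from `window` (seconds from
#' recording start; default the whole recording truncated to full epochs),
#' labels each via [map_legacy_stage()] from the covering hypnogram span,
#' and drops epochs whose label maps to `NA`.
#'
#' @param recording an `eeg_recording` (or any list with `samples` and
#'   `sampling_rate`).
#' @param hypnogram data.frame with `onset`, `duration`, `label`.
#' @param window `c(start_s, end_s)`, both multiples of 30.
#' @param epoch_s epoch length in seconds (default 30).
#' @return a `sleep_dataset`: list with `epochs` (matrix, one row per
#'   epoch), `stage` (factor over `sleep_stages()`), `index` (ordinal
#'   epoch positions), `start_s`, `sampling_rate`.
#' @export
segment_epochs <- function(recording, hypnogram, window = NULL, epoch_s = 30) {
  fs <- recording$sampling_rate
  n <- length(recording$samples)
  total_s <- n / fs
  if (is.null(window)) window <- c(0, floor(total_s / epoch_s) * epoch_s)
  if (window[1] %% epoch_s != 0 || window[2] %% epoch_s != 0)
    stop("window must be aligned to the ", epoch_s, "-s epoch grid")
  if (window[1] < 0 || window[2] > total_s || window[1] >= window[2])
    stop("window outside the recording")
  starts <- seq(window[1], window[2] - epoch_s, by = epoch_s)
  spe <- as.integer(epoch_s * fs)
  keep_stage <- character(0); keep_idx <- integer(0); keep_start <- numeric(0)
  rows <- list()
  for (k in seq_along(starts)) {
    t0 <- starts[k]
    cover <- which(hypnogram$onset <= t0 &
                   hypnogram$onset + hypnogram$duration >= t0 + epoch_s)
    if (length(cover) == 0L)
      stop("hypnogram gap: no annotation covers epoch starting at ", t0, " s")
    st <- map_legacy_stage(hypnogram$label[cover[1L]])
    if (is.na(st)) next
    i0 <- as.integer(t0 * fs)
    rows[[length(rows) + 1L]] <- recording$samples[(i0 + 1L):(i0 + spe)]
    keep_stage <- c(keep_stage, st)
    keep_idx <- c(keep_idx, k)
    keep_start <- c(keep_start, t0)
  }
  if (length(rows) == 0L) stop("no scorable epochs in window")
  structure(list(
    epochs = do.call(rbind, rows),
    stage = factor(keep_stage, levels = sleep_stages()),
    index = keep_idx,
    start_s = keep_start,
    sampling_rate = fs
  ), class = "sleep_dataset")
}

#' @export
print.sleep_dataset <- function(x, ...) {
  cat(sprintf("sleep dataset: %d epochs of %d samples at %g Hz\n",
              nrow(x$epochs), ncol(x$epochs), x$sampling_rate))
  print(table(x$stage))
  invisible(x)
}

#' Write epoch labels to the CSV interchange format
#'
#' Columns `epoch_index`, `start_s`, `stage`.
#' @param dataset a `sleep_dataset`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  utils::write.csv(
    data.frame(epoch_index = dataset$index,
               start_s = dataset$start_s,
               stage = as.character(dataset$stage)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read epoch labels from the CSV interchange format
#' @param path CSV written by [write_dataset_csv()].
#' @return data.frame with `epoch_index`, `start_s`, `stage` (factor).
#' @export
read_dataset_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$stage <- factor(d$stage, levels = sleep_stages())
  d
}
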