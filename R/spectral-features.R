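# Song-level spectral trait extraction, including the two complex-vocal-
# mechanism (CVM) indicators. A CVM (two-voice phenomenon or nonlinear
# phenomena of a single syrinx) is indexed indirectly: internote intervals
# shorter than the minimum duration of a minibreath (2 ms) and temporal
# overlap between consecutive notes both imply the bird did not inhale
# between notes.

#' Names of the 14 song-level spectral variables
#' @return Character vector of length 14, in canonical order.
#' @export
feature_names <- function() {
  c("mean_note_length", "sd_note_length",
    "mean_high_freq", "sd_high_freq",
    "mean_low_freq", "sd_low_freq",
    "mean_note_bandwidth", "sd_note_bandwidth",
    "song_bandwidth", "song_duration",
    "n_notes", "delivery_rate",
    "cvm_short_interval_rate", "cvm_overlap_rate")
}

# SD defined as 0 for a single observation so one-note songs stay usable.
.sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

.one_song <- function(notes) {
  ord <- order(notes$start_time, notes$end_time)
  notes[ord, , drop = FALSE]
}

#' Internote intervals of a song
#'
#' Interval i is \code{start_time[i+1] - end_time[i]} for consecutive notes
#' ordered by start time; negative values indicate temporal overlap.
#'
#' @param notes Data frame of the notes of one song.
#' @return Numeric vector of length \code{n_notes - 1} (empty for a
#'   single-note song).
#' @export
internote_intervals <- function(notes) {
  notes <- .one_song(notes)
  n <- nrow(notes)
  if (n < 2) return(numeric(0))
  notes$start_time[-1] - notes$end_time[-n]
}

#' Count CVM-indicative note pairs in a song
#'
#' @param notes Data frame of the notes of one song.
#' @param threshold Minibreath threshold in seconds (default 0.002 = 2 ms).
#' @return Named integer vector: \code{short_interval} = number of internote
#'   intervals in \code{[0, threshold)}; \code{overlap} = number of strictly
#'   negative intervals. A pair contributes to exactly one counter.
#' @export
cvm_counts <- function(notes, threshold = 0.002) {
  iv <- internote_intervals(notes)
  c(short_interval = sum(iv >= 0 & iv < threshold),
    overlap = sum(iv < 0))
}

#' Extract the 14 song-level spectral variables for one song
#'
#' Means and SDs of note length, high/low frequency and note bandwidth;
#' song bandwidth (max high - min low over notes); song duration (max end -
#' min start); number of notes; delivery rate (notes per second of song
#' duration); and the two CVM rates (counts from [cvm_counts()] scaled by
#' the total number of notes in the song, removing bias from
#' population-level differences in notes per song).
#'
#' @param notes Data frame of the notes of one song.
#' @param threshold Minibreath threshold in seconds.
#' @return Named numeric vector over [feature_names()].
#' @export
extract_features <- function(notes, threshold = 0.002) {
  notes <- .one_song(notes)
  n <- nrow(notes)
  dur <- notes$end_time - notes$start_time
  bw <- notes$high_freq - notes$low_freq
  song_duration <- max(notes$end_time) - min(notes$start_time)
  if (song_duration <= 0) {
    stop("degenerate song: non-positive song duration")
  }
  counts <- cvm_counts(notes, threshold)
  c(mean_note_length = mean(dur), sd_note_length = .sd0(dur),
    mean_high_freq = mean(notes$high_freq), sd_high_freq = .sd0(notes$high_freq),
    mean_low_freq = mean(notes$low_freq), sd_low_freq = .sd0(notes$low_freq),
    mean_note_bandwidth = mean(bw), sd_note_bandwidth = .sd0(bw),
    song_bandwidth = max(notes$high_freq) - min(notes$low_freq),
    song_duration = song_duration,
    n_notes = n,
    delivery_rate = n / song_duration,
    cvm_short_interval_rate = counts[["short_interval"]] / n,
    cvm_overlap_rate = counts[["overlap"]] / n)
}

#' Song-level feature table for a whole dataset
#'
#' @param x A \code{song_set} (or note data frame, assembled on the fly).
#' @param cvm_threshold_ms Minibreath threshold in milliseconds (default 2).
#' @return Data frame of class \code{song_features}: one row per song with
#'   label columns \code{song_id, individual_id, population_id} followed by
#'   the 14 feature columns.
#' @export
song_features <- function(x, cvm_threshold_ms = 2) {
  if (!inherits(x, "song_set")) x <- assemble_songs(x)
  thr <- cvm_threshold_ms / 1000
  by_song <- split(x$notes, factor(x$notes$song_id, levels = x$songs$song_id))
  feats <- t(vapply(by_song, extract_features, numeric(14), threshold = thr))
  out <- cbind(x$songs[, c("song_id", "individual_id", "population_id")],
               as.data.frame(feats))
  rownames(out) <- NULL
  class(out) <- c("song_features", "data.frame")
  out
}

#' Numeric feature matrix from a feature table
#' @param features A \code{song_features} data frame.
#' @return Numeric matrix (songs x 14) with song_id rownames.
#' @export
feature_matrix <- function(features) {
  m <- as.matrix(features[, feature_names()])
  rownames(m) <- features$song_id
  m
}

#' Frequency shifts between consecutive notes
#'
#' For each ordered consecutive note pair within a song, the shift is the
#' high frequency of the later note minus the low frequency of the earlier
#' note. Each pair is classed by its internote interval relative to the
#' minibreath threshold: \code{below_2ms} (interval < threshold, including
#' overlaps) or \code{at_or_above_2ms}.
#'
#' @param x A \code{song_set}, note data frame, or the notes of one song.
#' @param threshold Minibreath threshold in seconds.
#' @return Data frame with columns \code{song_id, pair_index, shift,
#'   interval, interval_class}.
#' @export
frequency_shifts <- function(x, threshold = 0.002) {
  if (inherits(x, "song_set")) {
    notes <- x$notes
  } else {
    notes <- x
  }
  res <- lapply(split(notes, notes$song_id), function(sn) {
    sn <- .one_song(sn)
    n <- nrow(sn)
    if (n < 2) return(NULL)
    iv <- sn$start_time[-1] - sn$end_time[-n]
    data.frame(
      song_id = sn$song_id[1],
      pair_index = seq_len(n - 1),
      shift = sn$high_freq[-1] - sn$low_freq[-n],
      interval = iv,
      interval_class = ifelse(iv < threshold, "below_2ms", "at_or_above_2ms"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(song_id = character(), pair_index = integer(),
                      shift = numeric(), interval = numeric(),
                      interval_class = character())
  }
  rownames(out) <- NULL
  out
}

#' Compare frequency-shift distributions across the minibreath boundary
#'
#' Two-sample Kolmogorov-Smirnov test of the pooled frequency shifts of
#' pairs with internote intervals below versus at-or-above the threshold.
#' Larger shifts below the minibreath duration are consistent with complex
#' vocal mechanisms producing notes at widely separated frequencies.
#'
#' @param shifts Output of [frequency_shifts()], pooled over songs.
#' @return List with \code{D}, \code{p}, and the two class sample sizes.
#' @export
ks_compare_shifts <- function(shifts) {
  below <- shifts$shift[shifts$interval_class == "below_2ms"]
  above <- shifts$shift[shifts$interval_class == "at_or_above_2ms"]
  if (length(below) == 0 || length(above) == 0) {
    stop("insufficient data: both interval classes must be non-empty")
  }
  kt <- suppressWarnings(stats::ks.test(below, above, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_below = length(below), n_above = length(above))
}
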