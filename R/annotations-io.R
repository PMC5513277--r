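#' @keywords internal
"_PACKAGE"

# Canonical column order for note tables throughout the package.
NOTE_COLUMNS <- c(
  "population_id", "individual_id", "song_id", "note_index",
  "start_time", "end_time", "low_freq", "high_freq"
)

#' Default column mapping for Raven-style selection tables
#'
#' Maps canonical note fields to the column headers produced by Raven Pro
#' selection tables, plus the three label columns expected alongside them.
#' Override any entry to read tables with different headers.
#'
#' @return Named character vector: canonical field -> column header in file.
#' @export
raven_label_map <- function() {
  c(
    start_time    = "Begin Time (s)",
    end_time      = "End Time (s)",
    low_freq      = "Low Freq (Hz)",
    high_freq     = "High Freq (Hz)",
    population_id = "population",
    individual_id = "individual",
    song_id       = "song"
  )
}

# Validates the per-note invariants. Returns integer row indices of offenders.
.invalid_note_rows <- function(df) {
  num <- c("start_time", "end_time", "low_freq", "high_freq")
  bad <- rep(FALSE, nrow(df))
  for (f in num) {
    v <- df[[f]]
    bad <- bad | !is.finite(v) | v < 0
  }
  ok_num <- !bad
  bad[ok_num] <- bad[ok_num] |
    df$end_time[ok_num] <= df$start_time[ok_num] |
    df$high_freq[ok_num] <= df$low_freq[ok_num]
  which(bad)
}

#' Read a note-annotation selection table
#'
#' Reads a tab-separated selection table (one row per annotated note) into
#' the canonical note data frame used by the rest of the pipeline. Times are
#' taken as seconds and frequencies as Hz, exactly as stored.
#'
#' @param path Path to a TSV file with a header row.
#' @param label_map Named character vector mapping canonical fields
#'   (\code{start_time}, \code{end_time}, \code{low_freq}, \code{high_freq},
#'   \code{population_id}, \code{individual_id}, \code{song_id}) to column
#'   headers in the file. Defaults to [raven_label_map()].
#' @param strict If \code{TRUE} (default), any row violating the note
#'   invariants (end after start, high above low, finite non-negative
#'   numbers) aborts with the offending row numbers. If \code{FALSE}, bad
#'   rows are dropped with a warning listing them.
#' @return A data frame of notes with columns
#'   \code{population_id, individual_id, song_id, start_time, end_time,
#'   low_freq, high_freq}, rows in file order.
#' @export
read_selection_table <- function(path, label_map = raven_label_map(),
                                 strict = TRUE) {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop("empty dataset: no data rows in ", path)
  }
  needed <- c("start_time", "end_time", "low_freq", "high_freq",
              "population_id", "individual_id", "song_id")
  missing_fields <- setdiff(needed, names(label_map))
  if (length(missing_fields)) {
    stop("label_map lacks entries for: ",
         paste(missing_fields, collapse = ", "))
  }
  absent <- setdiff(unname(label_map[needed]), names(raw))
  if (length(absent)) {
    stop("missing column(s) in ", path, ": ",
         paste(absent, collapse = ", "))
  }
  out <- data.frame(
    population_id = as.character(raw[[label_map[["population_id"]]]]),
    individual_id = as.character(raw[[label_map[["individual_id"]]]]),
    song_id       = as.character(raw[[label_map[["song_id"]]]]),
    start_time    = suppressWarnings(as.numeric(raw[[label_map[["start_time"]]]])),
    end_time      = suppressWarnings(as.numeric(raw[[label_map[["end_time"]]]])),
    low_freq      = suppressWarnings(as.numeric(raw[[label_map[["low_freq"]]]])),
    high_freq     = suppressWarnings(as.numeric(raw[[label_map[["high_freq"]]]])),
    stringsAsFactors = FALSE
  )
  nonnum <- which(
    (is.na(out$start_time) & !is.na(raw[[label_map[["start_time"]]]])) |
    (is.na(out$end_time)   & !is.na(raw[[label_map[["end_time"]]]])) |
    (is.na(out$low_freq)   & !is.na(raw[[label_map[["low_freq"]]]])) |
    (is.na(out$high_freq)  & !is.na(raw[[label_map[["high_freq"]]]]))
  )
  if (length(nonnum)) {
    stop("unparseable numeric value(s) at data row(s): ",
         paste(nonnum, collapse = ", "))
  }
  bad <- .invalid_note_rows(out)
  if (length(bad)) {
    if (strict) {
      stop("invalid note row(s) (invariant violation) at data row(s): ",
           paste(bad, collapse = ", "))
    }
    warning("dropping ", length(bad), " invalid note row(s): ",
            paste(bad, collapse = ", "))
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  if (nrow(out) == 0L) stop("empty dataset: all rows invalid in ", path)
  out
}

#' Write notes to a canonical TSV
#'
#' Inverse of [read_selection_table()] under the canonical column names:
#' a write followed by a read with the canonical label map is the identity.
#'
#' @param notes Note data frame (canonical columns).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_notes <- function(notes, path) {
  cols <- intersect(NOTE_COLUMNS, names(notes))
  out <- notes[, cols]
  names(out)[names(out) == "population_id"] <- "population"
  names(out)[names(out) == "individual_id"] <- "individual"
  names(out)[names(out) == "song_id"] <- "song"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Canonical label map for files written by [write_notes()]
#' @return Named character vector suitable for \code{label_map}.
#' @export
canonical_label_map <- function() {
  stats::setNames(
    c("start_time", "end_time", "low_freq", "high_freq",
      "population", "individual", "song"),
    c("start_time", "end_time", "low_freq", "high_freq",
      "population_id", "individual_id", "song_id")
  )
}

#' Group notes into songs ordered within individuals
#'
#' Songs are defined by their \code{song_id} labels (no time-gap
#' segmentation is applied; see [segment_songs_by_gap()] for an optional
#' utility). Notes within a song are sorted by start time, ties broken by
#' end time and then input order, and assigned a dense \code{note_index}
#' from 0. Songs within an individual are ordered by the start time of
#' their first note. The result is permutation-invariant with respect to
#' input row order.
#'
#' @param notes Note data frame (canonical columns).
#' @return An object of class \code{song_set}: a list with
#'   \describe{
#'     \item{notes}{the sorted, indexed note data frame}
#'     \item{songs}{one row per song: labels, first start time,
#'       \code{n_notes}, and \code{song_order} within its individual}
#'   }
#' @export
assemble_songs <- function(notes) {
  if (nrow(notes) == 0L) stop("empty dataset: no notes")
  bad <- .invalid_note_rows(notes)
  if (length(bad)) {
    stop("invalid note row(s): ", paste(bad, collapse = ", "))
  }
  # A song_id must belong to exactly one individual (and one population).
  owners <- unique(notes[, c("song_id", "individual_id", "population_id")])
  dup <- owners$song_id[duplicated(owners$song_id)]
  if (length(dup)) {
    stop("song_id(s) appear under more than one individual/population: ",
         paste(unique(dup), collapse = ", "))
  }
  ord <- order(notes$song_id, notes$start_time, notes$end_time,
               method = "radix")
  notes <- notes[ord, , drop = FALSE]
  rownames(notes) <- NULL
  notes$note_index <- stats::ave(notes$start_time, notes$song_id,
                                 FUN = seq_along) - 1
  first_start <- tapply(notes$start_time, notes$song_id, min)
  n_notes <- tapply(notes$start_time, notes$song_id, length)
  songs <- owners[match(names(first_start), owners$song_id), ]
  songs$first_start <- as.numeric(first_start)
  songs$n_notes <- as.integer(n_notes)
  songs <- songs[order(songs$individual_id, songs$first_start,
                       songs$song_id, method = "radix"), ]
  songs$song_order <- stats::ave(songs$first_start, songs$individual_id,
                                 FUN = seq_along)
  rownames(songs) <- NULL
  notes <- notes[order(match(notes$song_id, songs$song_id),
                       notes$note_index), , drop = FALSE]
  rownames(notes) <- NULL
  structure(list(notes = notes[, NOTE_COLUMNS], songs = songs),
            class = "song_set")
}

#' Segment notes into songs by silence gaps (optional utility)
#'
#' Assigns \code{song_id} within each individual by splitting the note
#' sequence wherever the silence between consecutive notes is at least
#' \code{gap} seconds. Off the main path: the pipeline normally takes
#' song membership from pre-assigned labels.
#'
#' @param notes Note data frame; existing \code{song_id} is overwritten.
#' @param gap Minimum silence (s) separating songs. Default 1.0.
#' @return Note data frame with new \code{song_id} labels
#'   (\code{"<individual>_s<k>"}).
#' @export
segment_songs_by_gap <- function(notes, gap = 1.0) {
  stopifnot(gap > 0)
  notes <- notes[order(notes$individual_id, notes$start_time,
                       notes$end_time, method = "radix"), , drop = FALSE]
  pieces <- split(seq_len(nrow(notes)), notes$individual_id)
  for (idx in pieces) {
    st <- notes$start_time[idx]
    en <- notes$end_time[idx]
    # gap measured from the running maximum end time (notes may overlap)
    run_end <- cummax(en)
    brk <- c(FALSE, st[-1] - run_end[-length(idx)] >= gap)
    k <- cumsum(brk) + 1L
    notes$song_id[idx] <- sprintf("%s_s%d", notes$individual_id[idx], k)
  }
  rownames(notes) <- NULL
  notes
}

#' Summarize a dataset into a manifest
#'
#' Counts populations, individuals, songs and notes, and reports the
#' mean, SD and range of songs per individual.
#'
#' @param x A \code{song_set} (from [assemble_songs()]) or a note data frame.
#' @return An object of class \code{dataset_manifest}.
#' @export
summarize_dataset <- function(x) {
  if (!inherits(x, "song_set")) x <- assemble_songs(x)
  songs <- x$songs
  per_ind <- tapply(songs$song_id, songs$individual_id, length)
  ind_pop <- unique(songs[, c("individual_id", "population_id")])
  per_pop <- tapply(ind_pop$individual_id, ind_pop$population_id, length)
  out <- list(
    populations = sort(unique(songs$population_id)),
    individuals_per_population = c(per_pop[order(names(per_pop))]),
    songs_per_individual = as.integer(per_ind),
    n_populations = length(unique(songs$population_id)),
    n_individuals = nrow(ind_pop),
    n_songs = nrow(songs),
    n_notes = nrow(x$notes),
    songs_per_individual_mean = mean(per_ind),
    songs_per_individual_sd = if (length(per_ind) > 1) stats::sd(per_ind) else 0,
    songs_per_individual_range = range(per_ind)
  )
  class(out) <- "dataset_manifest"
  out
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("Dataset manifest\n")
  cat(sprintf("  populations: %d (%s)\n", x$n_populations,
              paste(x$populations, collapse = ", ")))
  cat(sprintf("  individuals: %d   songs: %d   notes: %d\n",
              x$n_individuals, x$n_songs, x$n_notes))
  cat(sprintf("  songs per individual: %.1f +/- %.1f (range %d-%d)\n",
              x$songs_per_individual_mean, x$songs_per_individual_sd,
              x$songs_per_individual_range[1],
              x$songs_per_individual_range[2]))
  invisible(x)
}

#' Write a dataset manifest as TSV
#' @param manifest A \code{dataset_manifest}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- data.frame(
    quantity = c("n_populations", "n_individuals", "n_songs", "n_notes",
                 "songs_per_individual_mean", "songs_per_individual_sd",
                 "songs_per_individual_min", "songs_per_individual_max"),
    value = c(manifest$n_populations, manifest$n_individuals,
              manifest$n_songs, manifest$n_notes,
              manifest$songs_per_individual_mean,
              manifest$songs_per_individual_sd,
              manifest$songs_per_individual_range)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
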