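# Syntax complexity: song-type identification, the Song Variety Index
# (SVI = distinct song types / songs in a fixed-length bout), bout
# versatility categories (new / mod / old / same), the cross-population
# song-type library, and grouped bootstrap summaries.
#
# Song-type identity operationalizes a visual matching protocol as an
# explicit rule: notes match when their relative differences in duration
# and bandwidth are both within a tolerance; absolute frequency position is
# ignored (a uniform transposition is the same song); a maximal run of >= 2
# consecutive matching notes is a trill and collapses to a single run
# marker, so trill elongation or shortening does not create a new type.

.rel_diff <- function(a, b) abs(a - b) / pmax(a, b)

# Greedy within-song note classing: each note joins the first existing
# class whose exemplar (its first member) matches in both duration and
# bandwidth within `tol`, else founds a new class.
.note_classes <- function(dur, bw, tol) {
  n <- length(dur)
  cls <- integer(n)
  ex_dur <- numeric(0)
  ex_bw <- numeric(0)
  for (i in seq_len(n)) {
    hit <- which(.rel_diff(dur[i], ex_dur) <= tol &
                 .rel_diff(bw[i], ex_bw) <= tol)
    if (length(hit)) {
      cls[i] <- hit[1]
    } else {
      ex_dur <- c(ex_dur, dur[i])
      ex_bw <- c(ex_bw, bw[i])
      cls[i] <- length(ex_dur)
    }
  }
  list(classes = cls, ex_dur = ex_dur, ex_bw = ex_bw)
}

# Collapse runs: returns collapsed local class sequence and trill flags
# (TRUE where a run of length >= 2 was collapsed).
.collapse_runs <- function(cls) {
  r <- rle(cls)
  list(classes = r$values, trill = r$lengths >= 2)
}

#' Compute song-type signatures for all songs of a dataset
#'
#' Assigns every song a note-composition signature comparable across
#' individuals and populations. Notes are clustered into classes by
#' duration and bandwidth (relative tolerance \code{tolerance} on both)
#' by greedy matching of class exemplars in canonical dataset order,
#' which makes the result deterministic. Trills (runs of >= 2 identical
#' classes) collapse to a run marker. Two songs are the same type iff
#' their signatures are equal.
#'
#' @param x A \code{song_set} or note data frame.
#' @param tolerance Maximum relative difference (0-1) in note duration and
#'   bandwidth for two notes to count as the same class. Default 0.2.
#' Note classes are resolved in two stages to keep type identity stable:
#' all of an individual's notes are clustered first (within an individual
#' a note class is a tight cluster, so repeated renditions of a song type
#' resolve to the same classes), then each individual-level class is
#' mapped once onto the global class list, so cross-individual
#' comparisons cannot perturb within-individual identity.
#'
#' @return Data frame of class \code{song_signatures} with columns
#'   \code{song_id, individual_id, population_id, signature}, and
#'   attributes \code{class_seqs} (named list of collapsed global class id
#'   vectors) and \code{trill_seqs} (matching logical vectors).
#' @export
song_signatures <- function(x, tolerance = 0.2) {
  if (!inherits(x, "song_set")) x <- assemble_songs(x)
  stopifnot(tolerance >= 0, tolerance < 1)
  song_ids <- x$songs$song_id
  notes <- x$notes[order(match(x$notes$song_id, song_ids)), ]
  glob_dur <- numeric(0)
  glob_bw <- numeric(0)
  class_seqs <- vector("list", length(song_ids))
  trill_seqs <- vector("list", length(song_ids))
  names(class_seqs) <- names(trill_seqs) <- song_ids
  for (ind in unique(x$songs$individual_id)) {
    sn <- notes[notes$individual_id == ind, , drop = FALSE]
    dur <- sn$end_time - sn$start_time
    bw <- sn$high_freq - sn$low_freq
    loc <- .note_classes(dur, bw, tolerance)
    # map this individual's classes onto the global exemplar list, once
    gmap <- integer(length(loc$ex_dur))
    for (j in seq_along(loc$ex_dur)) {
      hit <- which(.rel_diff(loc$ex_dur[j], glob_dur) <= tolerance &
                   .rel_diff(loc$ex_bw[j], glob_bw) <= tolerance)
      if (length(hit)) {
        gmap[j] <- hit[1]
      } else {
        glob_dur <- c(glob_dur, loc$ex_dur[j])
        glob_bw <- c(glob_bw, loc$ex_bw[j])
        gmap[j] <- length(glob_dur)
      }
    }
    gcls <- gmap[loc$classes]
    for (s in unique(sn$song_id)) {
      col <- .collapse_runs(gcls[sn$song_id == s])
      class_seqs[[s]] <- col$classes
      trill_seqs[[s]] <- col$trill
    }
  }
  sig <- vapply(song_ids, function(s) {
    paste0(class_seqs[[s]], ifelse(trill_seqs[[s]], "*", ""),
           collapse = "-")
  }, character(1))
  out <- data.frame(
    song_id = song_ids,
    individual_id = x$songs$individual_id,
    population_id = x$songs$population_id,
    signature = unname(sig),
    stringsAsFactors = FALSE
  )
  attr(out, "class_seqs") <- class_seqs
  attr(out, "trill_seqs") <- trill_seqs
  class(out) <- c("song_signatures", "data.frame")
  out
}

#' Select fixed-length consecutive song bouts per individual
#'
#' Takes \code{n} consecutive songs (recording order) from each individual;
#' individuals with fewer than \code{n} songs are excluded with a warning.
#' The default start is the first song; \code{start = "random"} draws a
#' reproducible random window per individual, which supports checking that
#' syntax estimates are robust to the choice of start point.
#'
#' @param x A \code{song_set}.
#' @param n Bout length (default 11).
#' @param start \code{"first"} or \code{"random"}.
#' @param seed Seed used when \code{start = "random"}.
#' @return Data frame with columns
#'   \code{individual_id, population_id, position, song_id}.
#' @export
select_bout <- function(x, n = 11, start = c("first", "random"),
                        seed = NULL) {
  start <- match.arg(start)
  if (!inherits(x, "song_set")) x <- assemble_songs(x)
  if (start == "random" && !is.null(seed)) set.seed(seed)
  songs <- x$songs[order(x$songs$individual_id, x$songs$song_order), ]
  res <- lapply(split(songs, songs$individual_id), function(ss) {
    m <- nrow(ss)
    if (m < n) return(NULL)
    s0 <- if (start == "first") 1L else sample.int(m - n + 1L, 1L)
    idx <- seq.int(s0, length.out = n)
    data.frame(individual_id = ss$individual_id[1],
               population_id = ss$population_id[1],
               position = seq_len(n),
               song_id = ss$song_id[idx],
               stringsAsFactors = FALSE)
  })
  dropped <- names(res)[vapply(res, is.null, logical(1))]
  if (length(dropped)) {
    warning("excluding ", length(dropped), " individual(s) with fewer than ",
            n, " songs: ", paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no individual has at least ", n, " songs")
  rownames(out) <- NULL
  out
}

# Ordered bigrams of a collapsed class sequence; empty for length-1 songs.
.bigrams <- function(cls) {
  if (length(cls) < 2) return(character(0))
  paste(cls[-length(cls)], cls[-1], sep = ">")
}

#' Classify songs within bouts and compute the Song Variety Index
#'
#' Walks each individual's bout in order. Song i is \code{"same"} if its
#' signature equals the previous song's; \code{"old"} if it equals an
#' earlier, non-adjacent song's; \code{"mod"} if its signature is novel but
#' shares a contiguous note-class subsequence of length >= 2 (a copied note
#' combination) with an earlier song in the bout; otherwise \code{"new"}.
#' The first song is \code{"new"} by convention.
#' SVI = distinct signatures / bout length, so SVI is in [1/n, 1].
#'
#' @param bouts Output of [select_bout()].
#' @param signatures Output of [song_signatures()] covering the bout songs.
#' @return Data frame of class \code{bout_classification} with columns
#'   \code{individual_id, population_id, position, song_id, signature,
#'   category}; attribute \code{svi} holds one row per individual
#'   (\code{individual_id, population_id, svi, n}).
#' @export
classify_bouts <- function(bouts, signatures) {
  class_seqs <- attr(signatures, "class_seqs")
  sig_of <- stats::setNames(signatures$signature, signatures$song_id)
  missing <- setdiff(bouts$song_id, names(sig_of))
  if (length(missing)) {
    stop("signatures missing for song(s): ", paste(missing, collapse = ", "))
  }
  res <- lapply(split(bouts, bouts$individual_id), function(bb) {
    bb <- bb[order(bb$position), ]
    sigs <- unname(sig_of[bb$song_id])
    n <- nrow(bb)
    cat <- character(n)
    seen_bigrams <- character(0)
    for (i in seq_len(n)) {
      if (i == 1) {
        cat[i] <- "new"
      } else if (sigs[i] == sigs[i - 1]) {
        cat[i] <- "same"
      } else if (sigs[i] %in% sigs[seq_len(i - 1)]) {
        cat[i] <- "old"
      } else if (any(.bigrams(class_seqs[[bb$song_id[i]]]) %in% seen_bigrams)) {
        cat[i] <- "mod"
      } else {
        cat[i] <- "new"
      }
      seen_bigrams <- union(seen_bigrams,
                            .bigrams(class_seqs[[bb$song_id[i]]]))
    }
    bb$signature <- sigs
    bb$category <- cat
    bb
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  svi <- do.call(rbind, lapply(split(out, out$individual_id), function(bb) {
    data.frame(individual_id = bb$individual_id[1],
               population_id = bb$population_id[1],
               svi = length(unique(bb$signature)) / nrow(bb),
               n = nrow(bb), stringsAsFactors = FALSE)
  }))
  rownames(svi) <- NULL
  attr(out, "svi") <- svi
  class(out) <- c("bout_classification", "data.frame")
  out
}

#' Per-individual syntax statistics from a bout classification
#'
#' @param classification Output of [classify_bouts()].
#' @return Data frame with one row per individual: \code{individual_id,
#'   population_id, svi, prop_new, prop_mod, prop_old, prop_same}.
#' @export
bout_syntax_stats <- function(classification) {
  svi <- attr(classification, "svi")
  cats <- c("new", "mod", "old", "same")
  props <- t(vapply(split(classification, classification$individual_id),
    function(bb) {
      tab <- table(factor(bb$category, levels = cats))
      as.numeric(tab) / nrow(bb)
    }, numeric(4)))
  colnames(props) <- paste0("prop_", cats)
  out <- cbind(svi[match(rownames(props), svi$individual_id), ],
               as.data.frame(props))
  rownames(out) <- NULL
  out$n <- NULL
  out
}

#' Build the cross-population song-type library and sharing matrix
#'
#' Groups songs into unique types by signature and counts, for every pair
#' of individuals, the number of distinct types present in both
#' repertoires.
#'
#' @param signatures Output of [song_signatures()].
#' @param bouts Optional [select_bout()] output restricting the library to
#'   analyzed bout songs.
#' @return Object of class \code{song_type_library}: list with
#'   \code{types} (type_id, signature, n_members), \code{members}
#'   (type_id, individual_id, song_id), and \code{sharing} (individual x
#'   individual matrix of shared-type counts, zero diagonal).
#' @export
build_library <- function(signatures, bouts = NULL) {
  df <- as.data.frame(signatures)
  if (!is.null(bouts)) df <- df[df$song_id %in% bouts$song_id, ]
  usig <- unique(df$signature)
  type_id <- sprintf("T%04d", seq_along(usig))
  df$type_id <- type_id[match(df$signature, usig)]
  types <- data.frame(type_id = type_id, signature = usig,
                      n_members = as.integer(table(df$type_id)[type_id]),
                      stringsAsFactors = FALSE)
  inds <- sort(unique(df$individual_id))
  sharing <- matrix(0L, length(inds), length(inds),
                    dimnames = list(inds, inds))
  by_ind <- lapply(split(df$type_id, df$individual_id), unique)
  if (length(inds) > 1) {
    for (i in seq_along(inds)[-1]) {
      for (j in seq_len(i - 1)) {
        k <- length(intersect(by_ind[[inds[i]]], by_ind[[inds[j]]]))
        sharing[i, j] <- sharing[j, i] <- k
      }
    }
  }
  structure(list(
    types = types,
    members = df[, c("type_id", "individual_id", "song_id")],
    sharing = sharing
  ), class = "song_type_library")
}

#' @export
print.song_type_library <- function(x, ...) {
  cat("Song-type library:", nrow(x$types), "unique types from",
      nrow(x$members), "songs of", nrow(x$sharing), "individuals\n")
  shared <- sum(x$sharing[upper.tri(x$sharing)] > 0)
  cat("  individual pairs sharing at least one type:", shared, "\n")
  invisible(x)
}

#' Grouped percentile-bootstrap summary of per-individual statistics
#'
#' For each population and each value column, reports the mean across
#' individuals and a percentile bootstrap confidence interval obtained by
#' resampling individuals (the unit of replication) within the population.
#'
#' @param stats_df Per-individual statistics, e.g. [bout_syntax_stats()]
#'   output; must contain \code{individual_id} and \code{population_id}.
#' @param value_cols Columns to summarize (default: all numeric columns).
#' @param B Bootstrap replications (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for reproducibility.
#' @return Data frame of class \code{syntax_summary}: one row per
#'   population x variable with \code{mean, lower, upper, n_individuals,
#'   ci_available}. Single-individual populations get a point estimate
#'   with \code{ci_available = FALSE}.
#' @export
bootstrap_summary <- function(stats_df, value_cols = NULL, B = 1000,
                              level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(value_cols)) {
    value_cols <- setdiff(names(stats_df)[vapply(stats_df, is.numeric,
                                                 logical(1))],
                          c("n"))
  }
  alpha <- (1 - level) / 2
  rows <- list()
  for (pop in sort(unique(stats_df$population_id))) {
    sub <- stats_df[stats_df$population_id == pop, , drop = FALSE]
    n <- nrow(sub)
    for (v in value_cols) {
      vals <- sub[[v]]
      if (n >= 2) {
        boots <- vapply(seq_len(B), function(b) {
          mean(vals[sample.int(n, n, replace = TRUE)])
        }, numeric(1))
        ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
        ok <- TRUE
      } else {
        ci <- c(NA_real_, NA_real_)
        ok <- FALSE
      }
      rows[[length(rows) + 1]] <- data.frame(
        population_id = pop, variable = v, mean = mean(vals),
        lower = ci[1], upper = ci[2], n_individuals = n,
        ci_available = ok, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "B") <- B
  attr(out, "level") <- level
  class(out) <- c("syntax_summary", "data.frame")
  out
}

#' Correlation of SVI with spectral song characters
#'
#' Pearson correlation (with the t-based two-sided test) between
#' per-individual SVI and per-individual means of song bandwidth and
#' delivery rate.
#'
#' @param svi_df Per-individual SVI (\code{individual_id, svi}), e.g. the
#'   \code{svi} attribute of [classify_bouts()] or [bout_syntax_stats()].
#' @param features A \code{song_features} data frame.
#' @return Data frame: one row per spectral variable with
#'   \code{variable, r, df, p}.
#' @export
svi_spectral_correlation <- function(svi_df, features) {
  if (nrow(svi_df) < 3) stop("need at least 3 individuals")
  vars <- c("song_bandwidth", "delivery_rate")
  rows <- lapply(vars, function(v) {
    ind_mean <- tapply(features[[v]], features$individual_id, mean)
    x <- as.numeric(ind_mean[svi_df$individual_id])
    y <- svi_df$svi
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("undefined correlation: zero variance in ", v, " or svi")
    }
    ct <- stats::cor.test(x, y)
    data.frame(variable = v, r = unname(ct$estimate),
               df = unname(ct$parameter), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
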