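# Hierarchical synthetic song-bout simulator. Generates note-annotation
# datasets with the statistical structure the analysis assumes --
# population-level differences in note length, bandwidth, delivery rate,
# CVM prevalence and repertoire turnover -- together with a ground-truth
# ledger, so that every pipeline stage is testable by parameter recovery.
#
# Generative model (per individual):
#   * a pool of note classes on a duration x bandwidth grid with ratio-1.5
#     spacing (well beyond the default 20% matching tolerance) scaled by
#     the population means and an individual-specific factor;
#   * a repertoire of song types = sequences of pool classes (no immediate
#     repeats except trills), kept unique across ALL individuals via a
#     global registry, reproducing generatively the observation that wild
#     individuals do not share song types;
#   * a bout realized by a 4-state Markov choice among
#     new / mod / old / same driven by the repertoire-turnover parameter;
#   * notes realized with lognormal rendition jitter (2%) around class
#     parameters; internote intervals drawn from U(-10, 2) ms with
#     probability cvm_prob (a CVM pair) and otherwise from a silent-gap
#     window consistent with the population's delivery-rate target.

#' Parameters of one synthetic population
#'
#' @param population_id Label.
#' @param n_individuals Number of individuals.
#' @param songs_range Inclusive range of songs per individual (default
#'   c(11, 30), drawn uniformly).
#' @param note_length Mean note duration (s).
#' @param note_length_sd SD of note duration across an individual's note
#'   classes (s); realized as a lognormal individual factor.
#' @param note_bandwidth Mean note bandwidth (Hz).
#' @param note_bandwidth_sd SD of note bandwidth (Hz).
#' @param base_freq_range Range (Hz) for note low frequencies.
#' @param delivery_rate Target delivery rate (notes/s); sets the silent-gap
#'   window. \code{NULL} uses the generic 10-300 ms window.
#' @param cvm_prob Probability that a consecutive note pair is produced
#'   with a CVM-indicative interval (< 2 ms or overlapping).
#' @param repertoire_turnover Probability mass on introducing novel
#'   material (new or modified song types) at each bout position; drives
#'   the Song Variety Index.
#' @param trill_prob Probability a song type contains a trill.
#' @param trill_length Inclusive range of trill run lengths (redrawn at
#'   each rendition, so trill length varies between renditions of a type).
#' @param lat,lon Population coordinates (decimal degrees).
#' @param barrier_zone Ordinal zone along the mountain chain; consecutive
#'   zones are separated by one dispersal barrier.
#' @param spectral_cluster Planted spectral cluster label (used for
#'   recovery checks of the discriminant analysis).
#' @return List of class \code{population_params}.
#' @export
population_params <- function(population_id, n_individuals,
                              songs_range = c(11, 30),
                              note_length = 0.2, note_length_sd = 0.05,
                              note_bandwidth = 1500,
                              note_bandwidth_sd = 300,
                              base_freq_range = c(1500, 4000),
                              delivery_rate = NULL,
                              cvm_prob = 0.1,
                              repertoire_turnover = 0.5,
                              trill_prob = 0.3, trill_length = c(3, 6),
                              lat = 10, lon = 77, barrier_zone = 0,
                              spectral_cluster = population_id) {
  stopifnot(n_individuals >= 1,
            cvm_prob >= 0, cvm_prob <= 1,
            repertoire_turnover >= 0, repertoire_turnover <= 1,
            trill_prob >= 0, trill_prob <= 1,
            songs_range[1] <= songs_range[2],
            trill_length[1] >= 2, trill_length[1] <= trill_length[2],
            note_length > 0, note_bandwidth > 0,
            base_freq_range[1] >= 0, base_freq_range[1] < base_freq_range[2])
  if (!is.null(delivery_rate) && 1 / delivery_rate <= note_length) {
    stop("infeasible config: delivery rate incompatible with note length")
  }
  structure(as.list(environment()), class = "population_params")
}

#' Default study-shaped simulation configuration
#'
#' Six populations on four sky islands spanning ~600 km, 38 individuals in
#' all (2-10 per population), 11-30 songs each; three planted spectral
#' clusters (simple northern songs, complex central songs, a distinct
#' southern population) and three barrier zones boundaries; repertoire
#' turnover increases with barrier zone so syntax differences track
#' barriers while spectral differences track the geographic gradient.
#'
#' @return List of class \code{simulation_config}: \code{populations}
#'   (list of [population_params()]) plus F_ST synthesis constants
#'   \code{fst_alpha} (per barrier), \code{fst_beta} (per km),
#'   \code{fst_noise_sd}.
#' @export
default_study_config <- function() {
  pops <- list(
    population_params("BRAH", 2, note_length = 0.42, note_length_sd = 0.08,
                      note_bandwidth = 500, note_bandwidth_sd = 100,
                      base_freq_range = c(1500, 3000), delivery_rate = 1.7,
                      cvm_prob = 0.02, repertoire_turnover = 0.20,
                      lat = 13.40, lon = 75.20, barrier_zone = 0,
                      spectral_cluster = "simple"),
    population_params("OOTY", 7, note_length = 0.30, note_length_sd = 0.06,
                      note_bandwidth = 850, note_bandwidth_sd = 170,
                      base_freq_range = c(1600, 3300), delivery_rate = 2.6,
                      cvm_prob = 0.08, repertoire_turnover = 0.45,
                      lat = 11.40, lon = 76.70, barrier_zone = 1,
                      spectral_cluster = "simple"),
    population_params("GRHL", 10, note_length = 0.135, note_length_sd = 0.04,
                      note_bandwidth = 2400, note_bandwidth_sd = 480,
                      base_freq_range = c(2000, 5000), delivery_rate = 5.5,
                      cvm_prob = 0.18, repertoire_turnover = 0.70,
                      lat = 10.33, lon = 77.05, barrier_zone = 2,
                      spectral_cluster = "complex"),
    population_params("KODI", 7, note_length = 0.125, note_length_sd = 0.04,
                      note_bandwidth = 2550, note_bandwidth_sd = 510,
                      base_freq_range = c(2000, 5100), delivery_rate = 5.9,
                      cvm_prob = 0.30, repertoire_turnover = 0.70,
                      lat = 10.23, lon = 77.49, barrier_zone = 2,
                      spectral_cluster = "complex"),
    population_params("HWS", 6, note_length = 0.13, note_length_sd = 0.04,
                      note_bandwidth = 2450, note_bandwidth_sd = 490,
                      base_freq_range = c(2000, 5000), delivery_rate = 5.7,
                      cvm_prob = 0.42, repertoire_turnover = 0.70,
                      lat = 10.28, lon = 76.84, barrier_zone = 2,
                      spectral_cluster = "complex"),
    population_params("PEP", 6, note_length = 0.20, note_length_sd = 0.05,
                      note_bandwidth = 1300, note_bandwidth_sd = 260,
                      base_freq_range = c(3600, 6500), delivery_rate = 3.8,
                      cvm_prob = 0.55, repertoire_turnover = 0.95,
                      lat = 8.55, lon = 77.20, barrier_zone = 3,
                      spectral_cluster = "southern")
  )
  structure(list(populations = pops, fst_alpha = 0.06, fst_beta = 2e-4,
                 fst_noise_sd = 0.015),
            class = "simulation_config")
}

# Bout category chain shared by the generator and expected_svi(): 4-state
# categorical draw with availability constraints (first song "new"; "old"
# needs an earlier type other than the previous one). d = distinct types.
.draw_bout_categories <- function(n, turnover) {
  probs <- c(new = 0.8 * turnover, mod = 0.2 * turnover,
             old = 0.6 * (1 - turnover), same = 0.4 * (1 - turnover))
  cat <- character(n)
  cat[1] <- "new"
  d <- 1L
  for (i in seq_len(n)[-1]) {
    avail <- c(TRUE, TRUE, d >= 2, TRUE)
    pr <- probs * avail
    if (sum(pr) == 0) pr <- c(1, 0, 0, 0)
    cat[i] <- sample(names(probs), 1, prob = pr)
    if (cat[i] %in% c("new", "mod")) d <- d + 1L
  }
  cat
}

#' Expected Song Variety Index implied by a turnover parameter
#'
#' Monte-Carlo expectation of SVI for a bout of length \code{n} under the
#' simulator's 4-state bout Markov chain.
#'
#' @param turnover Repertoire-turnover parameter in [0, 1].
#' @param n Bout length (default 11).
#' @param reps Monte-Carlo replications (default 4000).
#' @param seed Optional seed.
#' @return Expected SVI (scalar).
#' @export
expected_svi <- function(turnover, n = 11, reps = 4000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(reps), function(i) {
    cats <- .draw_bout_categories(n, turnover)
    (1 + sum(cats[-1] %in% c("new", "mod"))) / n
  }, numeric(1)))
}

# --- internal type machinery ----------------------------------------------

# Collision check against types of other individuals: same collapsed
# length and every class matching in duration and bandwidth within a
# safety margin above the analysis tolerance.
.registry_collision <- function(reg, dur, bw, margin = 0.25) {
  for (t in reg) {
    if (length(t$dur) != length(dur)) next
    if (all(.rel_diff(t$dur, dur) <= margin & .rel_diff(t$bw, bw) <= margin)) {
      return(TRUE)
    }
  }
  FALSE
}

# sample() treats a length-1 vector as 1:n; draw from an integer range
# safely even when it is degenerate.
.sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1)

# Random class sequence over the pool with no immediate repeats.
.random_seq <- function(n_pool, len) {
  idx <- integer(len)
  idx[1] <- sample.int(n_pool, 1)
  for (i in seq_len(len)[-1]) {
    idx[i] <- sample(setdiff(seq_len(n_pool), idx[i - 1]), 1)
  }
  idx
}

.type_bigrams <- function(idx) {
  if (length(idx) < 2) return(character(0))
  paste(idx[-length(idx)], idx[-1], sep = ">")
}

#' Simulate a study-shaped note-annotation dataset
#'
#' @param config A \code{simulation_config}, e.g. [default_study_config()].
#' @param seed Master seed (mandatory; the same seed reproduces the
#'   dataset exactly).
#' @return Object of class \code{songdiff_sim}: list with
#'   \describe{
#'     \item{notes}{note data frame (canonical columns)}
#'     \item{populations}{metadata: population_id, lat, lon, barrier_zone,
#'       spectral_cluster, n_individuals, and the generating parameters}
#'     \item{fst}{synthetic genetic-differentiation \code{labeled_dist}
#'       (F_ST = alpha x barriers + beta x km + noise, clipped to [0, 0.5])}
#'     \item{truth}{ground-truth ledger: per-song type id, bout category,
#'       CVM pair count; per-individual repertoire; the config; the seed}
#'   }
#' @export
simulate_dataset <- function(config = default_study_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  ids <- vapply(config$populations, `[[`, character(1), "population_id")
  if (anyDuplicated(ids)) stop("population ids must be unique")
  set.seed(seed)
  registry <- list()       # realized class sequences of all types
  notes_list <- list()
  truth_songs <- list()
  repertoires <- list()
  for (pp in config$populations) {
    gap_window <- if (!is.null(pp$delivery_rate)) {
      gstar <- max(0.012, 1 / pp$delivery_rate - pp$note_length)
      c(0.5 * gstar, 1.5 * gstar)
    } else {
      c(0.010, 0.300)
    }
    for (j in seq_len(pp$n_individuals)) {
      ind_id <- sprintf("%s_i%02d", pp$population_id, j)
      f_dur <- exp(stats::rnorm(1, 0, min(pp$note_length_sd / pp$note_length, 0.08)))
      f_bw <- exp(stats::rnorm(1, 0, min(pp$note_bandwidth_sd / pp$note_bandwidth, 0.08)))
      dur_levels <- pp$note_length * f_dur * 1.5^((1:4) - 2.5)
      bw_levels <- pp$note_bandwidth * f_bw * 1.5^((1:4) - 2.5)
      cells <- expand.grid(d = 1:4, b = 1:4)
      pool_cells <- cells[sample.int(16, 10), ]
      pool <- data.frame(
        dur = dur_levels[pool_cells$d],
        bw = bw_levels[pool_cells$b],
        low = stats::runif(10, pp$base_freq_range[1], pp$base_freq_range[2])
      )
      # type factory: unique across individuals, optionally avoiding
      # within-bout bigram overlap so planted "new" songs classify as new
      make_type <- function(forbidden_bigrams, base_idx = NULL) {
        for (att in seq_len(200)) {
          if (is.null(base_idx)) {
            idx <- .random_seq(10, sample(4:9, 1))
          } else {
            # "mod": copy a contiguous block of >= 2 classes, then add
            # 1-3 fresh classes around it (note insertion/deletion)
            blen <- sample(2:min(3, length(base_idx)), 1)
            bstart <- sample.int(length(base_idx) - blen + 1, 1)
            block <- base_idx[bstart:(bstart + blen - 1)]
            extra <- sample(setdiff(seq_len(10), block[length(block)]),
                            sample(1:3, 1))
            idx <- c(block, extra)
            if (any(idx[-1] == idx[-length(idx)])) next
          }
          if (is.null(base_idx) &&
              any(.type_bigrams(idx) %in% forbidden_bigrams)) next
          dur <- pool$dur[idx]; bw <- pool$bw[idx]
          if (.registry_collision(registry, dur, bw)) next
          trill <- rep(FALSE, length(idx))
          if (stats::runif(1) < pp$trill_prob) {
            trill[sample.int(length(idx), 1)] <- TRUE
          }
          type <- list(idx = idx, dur = dur, bw = bw, low = pool$low[idx],
                       trill = trill)
          registry[[length(registry) + 1]] <<- list(dur = dur, bw = bw)
          return(type)
        }
        NULL
      }
      n_songs <- .sample_range(pp$songs_range[1], pp$songs_range[2])
      cats <- .draw_bout_categories(n_songs, pp$repertoire_turnover)
      types <- list()       # this individual's repertoire, in creation order
      bout_types <- integer(n_songs)
      bout_bigrams <- character(0)
      for (k in seq_len(n_songs)) {
        cat_k <- cats[k]
        if (cat_k == "same") {
          bout_types[k] <- bout_types[k - 1]
        } else if (cat_k == "old") {
          prev <- bout_types[k - 1]
          choices <- setdiff(unique(bout_types[seq_len(k - 1)]), prev)
          bout_types[k] <- if (length(choices) == 1) choices else
            sample(choices, 1)
        } else {
          base_idx <- NULL
          if (cat_k == "mod") {
            parent <- types[[bout_types[sample.int(k - 1, 1)]]]
            base_idx <- parent$idx
          }
          t_new <- make_type(bout_bigrams, base_idx)
          if (is.null(t_new)) {          # fall back to an unconstrained new
            t_new <- make_type(character(0))
            cats[k] <- "new"
          }
          types[[length(types) + 1]] <- t_new
          bout_types[k] <- length(types)
        }
        bout_bigrams <- union(bout_bigrams,
                              .type_bigrams(types[[bout_types[k]]]$idx))
      }
      # realize the notes of each song
      for (k in seq_len(n_songs)) {
        tp <- types[[bout_types[k]]]
        reps <- ifelse(tp$trill,
                       vapply(tp$trill, function(z)
                         .sample_range(pp$trill_length[1], pp$trill_length[2]),
                         numeric(1)),
                       1)
        pos <- rep(seq_along(tp$idx), reps)
        n <- length(pos)
        dur <- tp$dur[pos] * exp(stats::rnorm(n, 0, 0.02))
        bw <- tp$bw[pos] * exp(stats::rnorm(n, 0, 0.02))
        transpose <- exp(stats::rnorm(1, 0, 0.05))
        low <- tp$low[pos] * transpose * exp(stats::rnorm(n, 0, 0.02))
        n_cvm <- 0L
        starts <- numeric(n)
        starts[1] <- (k - 1) * 60
        if (n > 1) {
          for (i in seq_len(n - 1)) {
            if (stats::runif(1) < pp$cvm_prob) {
              gap <- stats::runif(1, max(-0.010, -0.8 * dur[i]), 0.002)
              n_cvm <- n_cvm + 1L
            } else {
              gap <- stats::runif(1, gap_window[1], gap_window[2])
            }
            starts[i + 1] <- starts[i] + dur[i] + gap
          }
        }
        song_id <- sprintf("%s_sg%02d", ind_id, k)
        notes_list[[length(notes_list) + 1]] <- data.frame(
          population_id = pp$population_id, individual_id = ind_id,
          song_id = song_id, start_time = starts,
          end_time = starts + dur, low_freq = low, high_freq = low + bw,
          stringsAsFactors = FALSE)
        truth_songs[[length(truth_songs) + 1]] <- data.frame(
          population_id = pp$population_id, individual_id = ind_id,
          song_id = song_id, song_order = k,
          type_id = sprintf("%s_t%02d", ind_id, bout_types[k]),
          true_category = cats[k], n_notes = n, n_cvm_pairs = n_cvm,
          stringsAsFactors = FALSE)
      }
      repertoires[[ind_id]] <- types
    }
  }
  notes <- do.call(rbind, notes_list)
  rownames(notes) <- NULL
  pops_df <- do.call(rbind, lapply(config$populations, function(pp) {
    data.frame(population_id = pp$population_id, lat = pp$lat,
               lon = pp$lon, barrier_zone = pp$barrier_zone,
               spectral_cluster = pp$spectral_cluster,
               n_individuals = pp$n_individuals,
               note_length = pp$note_length,
               note_bandwidth = pp$note_bandwidth,
               delivery_rate = if (is.null(pp$delivery_rate)) NA_real_
                               else pp$delivery_rate,
               cvm_prob = pp$cvm_prob,
               repertoire_turnover = pp$repertoire_turnover,
               stringsAsFactors = FALSE)
  }))
  geo <- geographic_distances(pops_df)
  bar <- barrier_distances(data.frame(population_id = pops_df$population_id,
                                      zone = pops_df$barrier_zone))
  n_pop <- nrow(pops_df)
  noise <- matrix(stats::rnorm(n_pop^2, 0, config$fst_noise_sd), n_pop)
  noise <- (noise + t(noise)) / 2
  fst_m <- pmin(pmax(config$fst_alpha * bar$matrix +
                     config$fst_beta * geo$matrix + noise, 0), 0.5)
  diag(fst_m) <- 0
  fst <- labeled_dist(fst_m, pops_df$population_id, kind = "fst")
  truth <- list(songs = do.call(rbind, truth_songs),
                repertoires = repertoires, config = config, seed = seed)
  rownames(truth$songs) <- NULL
  structure(list(notes = notes, populations = pops_df, fst = fst,
                 truth = truth),
            class = "songdiff_sim")
}

#' @export
print.songdiff_sim <- function(x, ...) {
  cat(sprintf("Synthetic song dataset: %d notes, %d songs, %d individuals, %d populations (seed %d)\n",
              nrow(x$notes), length(unique(x$notes$song_id)),
              length(unique(x$notes$individual_id)),
              nrow(x$populations), x$truth$seed))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' @param sim A \code{songdiff_sim}.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    notes = file.path(dir, "notes.tsv"),
    populations = file.path(dir, "populations.tsv"),
    fst = file.path(dir, "fst.tsv"),
    truth = file.path(dir, "truth_songs.tsv")
  )
  write_notes(sim$notes, paths["notes"])
  utils::write.table(sim$populations, paths["populations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_distance_matrix(sim$fst, paths["fst"])
  utils::write.table(sim$truth$songs, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Qualitative reconstruction of the study design
#'
#' Simulates \code{replicates} datasets from the default study-shaped
#' configuration and summarizes the three structural findings the design
#' plants: near-zero discriminant confusion between the planted spectral
#' clusters, syntax distances more strongly Mantel-associated with barrier
#' counts than spectral distances are, and zero cross-individual song-type
#' sharing. Replicates are aggregated (pooled confusion, mean Mantel r)
#' because population-level distance matrices from 2-10 individuals per
#' population are noisy in any single draw.
#'
#' @param seed Master seed; replicate r uses \code{seed + r}.
#' @param replicates Number of replicate simulations (default 3).
#' @param config Simulation configuration (default study-shaped).
#' @param permutations Mantel permutations per test.
#' @return List with \code{between_cluster_confusion} (pooled rate),
#'   \code{mean_r} (named: syntax_barrier, spectral_barrier,
#'   spectral_geographic, syntax_geographic), \code{r} (per-replicate data
#'   frame), \code{sharing_total}, \code{classification_rate} (mean DFA
#'   resubstitution rate).
#' @export
reconstruct_study <- function(seed, replicates = 3,
                              config = default_study_config(),
                              permutations = 999) {
  rr <- NULL
  conf_between <- 0
  conf_total <- 0
  sharing <- 0
  rates <- numeric(0)
  for (r in seq_len(replicates)) {
    sim <- simulate_dataset(config, seed = seed + r)
    ss <- assemble_songs(sim$notes)
    feats <- song_features(ss)
    pca <- pca_reduce(feats)
    sigs <- song_signatures(ss)
    bouts <- suppressWarnings(select_bout(ss))
    st <- bout_syntax_stats(classify_bouts(bouts, sigs))
    lib <- build_library(sigs, bouts)
    sharing <- sharing + sum(lib$sharing[upper.tri(lib$sharing)])
    dfa <- discriminant_analysis(pca$scores, feats$population_id)
    cl_true <- sim$populations$spectral_cluster[
      match(rownames(dfa$confusion), sim$populations$population_id)]
    cl_pred <- sim$populations$spectral_cluster[
      match(colnames(dfa$confusion), sim$populations$population_id)]
    conf_between <- conf_between +
      sum(dfa$confusion[outer(cl_true, cl_pred, "!=")])
    conf_total <- conf_total + sum(dfa$confusion)
    rates <- c(rates, dfa$rate)
    dm <- song_distance_matrices(pca, st)
    geo <- geographic_distances(sim$populations)
    bar <- barrier_distances(data.frame(
      population_id = sim$populations$population_id,
      zone = sim$populations$barrier_zone))
    rr <- rbind(rr, data.frame(
      replicate = r,
      syntax_barrier = mantel(dm$syntax, bar, permutations, seed = seed)$r,
      spectral_barrier = mantel(dm$spectral, bar, permutations, seed = seed)$r,
      spectral_geographic = mantel(dm$spectral, geo, permutations, seed = seed)$r,
      syntax_geographic = mantel(dm$syntax, geo, permutations, seed = seed)$r))
  }
  list(between_cluster_confusion = conf_between / conf_total,
       mean_r = colMeans(rr[, -1]),
       r = rr,
       sharing_total = sharing,
       classification_rate = mean(rates))
}

#' Parameter-recovery report for a simulated dataset
#'
#' Runs the analysis pipeline on a simulated dataset and compares what it
#' measures against the generating parameters: extracted CVM rates against
#' cvm_prob x (n-1)/n, measured population SVI against the Monte-Carlo
#' expectation of the bout chain, discriminant between-cluster confusion
#' against the planted spectral clusters, and song-type sharing against
#' the disjoint-repertoire construction.
#'
#' @param sim A \code{songdiff_sim}.
#' @param report Optional precomputed [run_pipeline()] report for
#'   \code{sim} (computed if missing).
#' @param cvm_se_mult CVM check passes when |observed - expected| is at
#'   most this many standard errors (default 2).
#' @param svi_tol Absolute tolerance on population mean SVI (default 0.1).
#' @param cluster_tol Maximum between-cluster confusion rate (default 0.05).
#' @return Data frame of class \code{recovery_report}: one row per check
#'   with \code{check, population, expected, observed, pass}.
#' @export
recover_parameters <- function(sim, report = NULL, cvm_se_mult = 2,
                               svi_tol = 0.1, cluster_tol = 0.05) {
  if (is.null(sim$truth)) stop("cannot score: ground-truth ledger missing")
  if (is.null(report)) report <- run_pipeline(sim, seed = sim$truth$seed)
  feats <- report$features
  rows <- list()
  for (i in seq_len(nrow(sim$populations))) {
    pop <- sim$populations$population_id[i]
    sub <- feats[feats$population_id == pop, ]
    rate <- sub$cvm_short_interval_rate + sub$cvm_overlap_rate
    expected <- sim$populations$cvm_prob[i] *
      mean((sub$n_notes - 1) / sub$n_notes)
    se <- if (nrow(sub) > 1) stats::sd(rate) / sqrt(nrow(sub)) else NA
    pass <- if (expected == 0) all(rate == 0) else
      abs(mean(rate) - expected) <= cvm_se_mult * se
    rows[[length(rows) + 1]] <- data.frame(
      check = "cvm_rate", population = pop, expected = expected,
      observed = mean(rate), pass = pass, stringsAsFactors = FALSE)
  }
  svi <- attr(report$classification, "svi")
  for (i in seq_len(nrow(sim$populations))) {
    pop <- sim$populations$population_id[i]
    expected <- expected_svi(sim$populations$repertoire_turnover[i],
                             n = report$params$bout_size,
                             seed = sim$truth$seed + 7)
    observed <- mean(svi$svi[svi$population_id == pop])
    rows[[length(rows) + 1]] <- data.frame(
      check = "svi", population = pop, expected = expected,
      observed = observed, pass = abs(observed - expected) <= svi_tol,
      stringsAsFactors = FALSE)
  }
  cl <- sim$populations$spectral_cluster[
    match(rownames(report$dfa$confusion), sim$populations$population_id)]
  cl_pred <- sim$populations$spectral_cluster[
    match(colnames(report$dfa$confusion), sim$populations$population_id)]
  conf <- report$dfa$confusion
  between <- sum(conf[outer(cl, cl_pred, "!=")]) / sum(conf)
  rows[[length(rows) + 1]] <- data.frame(
    check = "dfa_between_cluster_confusion", population = NA,
    expected = 0, observed = between, pass = between <= cluster_tol,
    stringsAsFactors = FALSE)
  off <- sum(report$library$sharing[upper.tri(report$library$sharing)])
  rows[[length(rows) + 1]] <- data.frame(
    check = "song_type_sharing", population = NA, expected = 0,
    observed = off, pass = off == 0, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("recovery_report", "data.frame")
  out
}
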