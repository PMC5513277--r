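# Small in-code fixtures shared across test files.

make_notes <- function(start, end, low, high,
                       song = "s1", ind = "i1", pop = "p1") {
  data.frame(population_id = pop, individual_id = ind, song_id = song,
             start_time = start, end_time = end,
             low_freq = low, high_freq = high,
             stringsAsFactors = FALSE)
}

# A song specified by note durations and the silent gaps between them.
make_song <- function(durations, gaps = NULL, lows = NULL, bws = NULL,
                      t0 = 0, ...) {
  n <- length(durations)
  if (is.null(gaps)) gaps <- rep(0.05, max(n - 1, 0))
  if (is.null(lows)) lows <- rep(2000, n)
  if (is.null(bws)) bws <- rep(1000, n)
  starts <- numeric(n)
  starts[1] <- t0
  if (n > 1) {
    for (i in 2:n) starts[i] <- starts[i - 1] + durations[i - 1] + gaps[i - 1]
  }
  make_notes(starts, starts + durations, lows, lows + bws, ...)
}

# A song built from integer note-class ids: class k has duration
# 0.1 * 1.6^k s and bandwidth 500 * 1.6^k Hz (1.6 spacing, i.e. 37.5%
# relative difference, well beyond the 20% matching tolerance).
class_song <- function(classes, song = "s1", ind = "i1", pop = "p1",
                       low = 2000, t0 = 0, low_mult = 1) {
  make_song(0.1 * 1.6^classes, lows = rep(low * low_mult, length(classes)),
            bws = 500 * 1.6^classes, t0 = t0,
            song = song, ind = ind, pop = pop)
}

# A bout: list of class vectors -> one notes data frame for one individual.
class_bout <- function(class_list, ind = "i1", pop = "p1", low_mults = NULL) {
  if (is.null(low_mults)) low_mults <- rep(1, length(class_list))
  do.call(rbind, lapply(seq_along(class_list), function(k) {
    class_song(class_list[[k]], song = sprintf("%s_s%02d", ind, k),
               ind = ind, pop = pop, t0 = (k - 1) * 60,
               low_mult = low_mults[k])
  }))
}

random_valid_notes <- function(n_songs = 4, notes_per_song = 5, seed = 1,
                               ind = "i1", pop = "p1") {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_songs), function(s) {
    n <- notes_per_song
    dur <- runif(n, 0.05, 0.3)
    gaps <- runif(n - 1, -0.02, 0.3)
    low <- runif(n, 1000, 4000)
    bw <- runif(n, 200, 2000)
    make_song(dur, gaps = gaps, lows = low, bws = bw, t0 = (s - 1) * 30,
              song = sprintf("%s_s%02d", ind, s), ind = ind, pop = pop)
  }))
}

# A compact two-population configuration for fast simulations.
small_config <- function(n_individuals = c(4, 4), songs_range = c(11, 14),
                         cvm = c(0.05, 0.3), turnover = c(0.3, 0.8)) {
  structure(list(populations = list(
    population_params("P1", n_individuals[1], songs_range = songs_range,
                      note_length = 0.30, note_length_sd = 0.06,
                      note_bandwidth = 800, note_bandwidth_sd = 160,
                      base_freq_range = c(1500, 3000), delivery_rate = 2.5,
                      cvm_prob = cvm[1], repertoire_turnover = turnover[1],
                      lat = 11, lon = 76, barrier_zone = 0,
                      spectral_cluster = "a"),
    population_params("P2", n_individuals[2], songs_range = songs_range,
                      note_length = 0.12, note_length_sd = 0.03,
                      note_bandwidth = 2500, note_bandwidth_sd = 500,
                      base_freq_range = c(2000, 5000), delivery_rate = 5.5,
                      cvm_prob = cvm[2], repertoire_turnover = turnover[2],
                      lat = 10, lon = 77, barrier_zone = 1,
                      spectral_cluster = "b")),
    fst_alpha = 0.06, fst_beta = 2e-4, fst_noise_sd = 0.015),
    class = "simulation_config")
}

# A single-population configuration (for recovery experiments).
one_pop_config <- function(n_individuals = 10, songs_range = c(11, 11),
                           cvm = 0.1, turnover = 0.6) {
  structure(list(populations = list(
    population_params("P1", n_individuals, songs_range = songs_range,
                      note_length = 0.15, note_length_sd = 0.03,
                      note_bandwidth = 2000, note_bandwidth_sd = 400,
                      base_freq_range = c(2000, 5000), delivery_rate = 5,
                      cvm_prob = cvm, repertoire_turnover = turnover,
                      lat = 10, lon = 77, barrier_zone = 0)),
    fst_alpha = 0.06, fst_beta = 2e-4, fst_noise_sd = 0.015),
    class = "simulation_config")
}

# Random symmetric zero-diagonal distance matrix from points on a line.
random_dist <- function(n, seed, kind = "other") {
  set.seed(seed)
  x <- runif(n, 0, 10)
  labeled_dist(as.matrix(dist(x)), labels = paste0("P", seq_len(n)),
               kind = kind)
}
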