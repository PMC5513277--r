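test_that("internote intervals follow the start-minus-previous-end convention", {
  notes <- make_notes(c(0.5, 1.05), c(1.0, 1.3), c(1000, 1000), c(2000, 2000))
  expect_equal(internote_intervals(notes), 0.05)
  over <- make_notes(c(0.5, 0.99), c(1.0, 1.3), c(1000, 1000), c(2000, 2000))
  expect_equal(internote_intervals(over), -0.01)
  expect_length(internote_intervals(make_notes(0, 1, 1000, 2000)), 0)
})

test_that("intervals match brute-force recomputation on random songs", {
  for (seed in 1:5) {
    notes <- random_valid_notes(n_songs = 1, notes_per_song = 12, seed = seed)
    iv <- internote_intervals(notes)
    ord <- order(notes$start_time, notes$end_time)
    st <- notes$start_time[ord]; en <- notes$end_time[ord]
    brute <- vapply(2:12, function(i) st[i] - en[i - 1], numeric(1))
    expect_equal(iv, brute)
  }
})

test_that("CVM counters split pairs into short-interval and overlap exclusively", {
  # gaps 1 ms (short), -3 ms (overlap), 500 ms (neither)
  notes <- make_song(rep(0.1, 4), gaps = c(0.001, -0.003, 0.5))
  expect_equal(cvm_counts(notes), c(short_interval = 1, overlap = 1))
  none <- make_song(rep(0.1, 4), gaps = rep(0.05, 3))
  expect_equal(unname(cvm_counts(none)), c(0, 0))
  # boundary: exactly 2 ms is not a short interval
  boundary <- make_song(rep(0.1, 2), gaps = 0.002)
  expect_equal(unname(cvm_counts(boundary)), c(0, 0))
  just_below <- make_song(rep(0.1, 2), gaps = 0.0019999)
  expect_equal(unname(cvm_counts(just_below)), c(1, 0))
})

test_that("the extractor emits the documented values on degenerate songs", {
  one <- make_notes(0, 0.2, 2000, 4000)
  f <- extract_features(one)
  expect_equal(unname(f["mean_note_length"]), 0.2)
  expect_equal(unname(f["song_bandwidth"]), 2000)
  expect_equal(unname(f["sd_note_length"]), 0)
  expect_equal(unname(f["cvm_short_interval_rate"]), 0)
  expect_equal(unname(f["delivery_rate"]), 1 / 0.2)

  two <- make_song(c(0.2, 0.2), gaps = 0.1)
  f2 <- extract_features(two)
  expect_equal(unname(f2["sd_note_length"]), 0)
  expect_equal(unname(f2["sd_high_freq"]), 0)
  expect_equal(unname(f2["delivery_rate"]), 2 / unname(f2["song_duration"]))
})

test_that("all 14 features equal an independent recomputation on a random song", {
  notes <- random_valid_notes(n_songs = 1, notes_per_song = 20, seed = 42)
  f <- extract_features(notes)
  ord <- order(notes$start_time, notes$end_time)
  sn <- notes[ord, ]
  dur <- sn$end_time - sn$start_time
  bw <- sn$high_freq - sn$low_freq
  iv <- sn$start_time[-1] - sn$end_time[-20]
  expect_equal(unname(f["mean_note_length"]), mean(dur))
  expect_equal(unname(f["sd_note_length"]), sd(dur))
  expect_equal(unname(f["mean_high_freq"]), mean(sn$high_freq))
  expect_equal(unname(f["sd_high_freq"]), sd(sn$high_freq))
  expect_equal(unname(f["mean_low_freq"]), mean(sn$low_freq))
  expect_equal(unname(f["sd_low_freq"]), sd(sn$low_freq))
  expect_equal(unname(f["mean_note_bandwidth"]), mean(bw))
  expect_equal(unname(f["sd_note_bandwidth"]), sd(bw))
  expect_equal(unname(f["song_bandwidth"]),
               max(sn$high_freq) - min(sn$low_freq))
  expect_equal(unname(f["song_duration"]),
               max(sn$end_time) - min(sn$start_time))
  expect_equal(unname(f["n_notes"]), 20)
  expect_equal(unname(f["delivery_rate"]), 20 / unname(f["song_duration"]))
  expect_equal(unname(f["cvm_short_interval_rate"]),
               sum(iv >= 0 & iv < 0.002) / 20)
  expect_equal(unname(f["cvm_overlap_rate"]), sum(iv < 0) / 20)
  expect_true(unname(f["song_bandwidth"]) >= max(bw))
})

test_that("CVM rates are invariant to time translation and frequency shifts", {
  notes <- random_valid_notes(n_songs = 1, notes_per_song = 10, seed = 3)
  f0 <- extract_features(notes)
  shifted <- notes
  shifted$start_time <- shifted$start_time + 100
  shifted$end_time <- shifted$end_time + 100
  shifted$low_freq <- shifted$low_freq + 500
  shifted$high_freq <- shifted$high_freq + 500
  f1 <- extract_features(shifted)
  expect_equal(f1["cvm_short_interval_rate"], f0["cvm_short_interval_rate"])
  expect_equal(f1["cvm_overlap_rate"], f0["cvm_overlap_rate"])
  # and extraction is row-order invariant
  f2 <- extract_features(notes[sample.int(10), ])
  expect_equal(f2, f0)
})

test_that("frequency shifts equal high of current minus low of previous", {
  notes <- make_notes(c(0, 1), c(0.5, 1.5), c(2000, 3000), c(2500, 4000))
  fs <- frequency_shifts(notes)
  expect_equal(fs$shift, 4000 - 2000)
  # all-identical notes: every shift equals the note bandwidth
  same <- make_song(rep(0.1, 5), lows = rep(2000, 5), bws = rep(800, 5))
  expect_equal(frequency_shifts(same)$shift, rep(800, 4))
  # brute force on a random song
  rn <- random_valid_notes(1, 8, seed = 9)
  ord <- order(rn$start_time, rn$end_time)
  sn <- rn[ord, ]
  expect_equal(frequency_shifts(rn)$shift,
               sn$high_freq[-1] - sn$low_freq[-8])
})

test_that("shift interval classes use the same boundary as the CVM counters", {
  notes <- make_song(rep(0.1, 4), gaps = c(0.001, 0.002, 0.5))
  fs <- frequency_shifts(notes)
  expect_equal(fs$interval_class,
               c("below_2ms", "at_or_above_2ms", "at_or_above_2ms"))
})

test_that("KS statistic behaves at the trivial extremes", {
  shifts <- data.frame(
    shift = c(1, 2, 3, 1, 2, 3),
    interval_class = rep(c("below_2ms", "at_or_above_2ms"), each = 3))
  expect_equal(ks_compare_shifts(shifts)$D, 0)
  disjoint <- data.frame(
    shift = c(1, 2, 3, 4, 5, 6),
    interval_class = rep(c("below_2ms", "at_or_above_2ms"), each = 3))
  expect_equal(ks_compare_shifts(disjoint)$D, 1)
  only_one <- disjoint[disjoint$interval_class == "below_2ms", ]
  expect_error(ks_compare_shifts(only_one), "insufficient")
})

test_that("KS D matches the exhaustive ECDF step-point supremum", {
  set.seed(7)
  for (i in 1:30) {
    x <- round(rnorm(sample(5:30, 1)), 1)   # rounding forces ties
    y <- round(rnorm(sample(5:30, 1), mean = runif(1, -1, 1)), 1)
    shifts <- data.frame(shift = c(x, y),
                         interval_class = c(rep("below_2ms", length(x)),
                                            rep("at_or_above_2ms", length(y))))
    D <- ks_compare_shifts(shifts)$D
    steps <- sort(unique(c(x, y)))
    brute <- max(abs(ecdf(x)(steps) - ecdf(y)(steps)))
    expect_equal(D, brute, tolerance = 1e-12)
  }
})

test_that("adding identical observations to equal-sized samples shrinks D predictably", {
  # With n-point samples and k common extra points, the ECDF difference is
  # diluted by exactly n / (n + k); in particular D never increases.
  set.seed(8)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  base <- data.frame(shift = c(x, y),
                     interval_class = rep(c("below_2ms", "at_or_above_2ms"),
                                          each = 15))
  D0 <- ks_compare_shifts(base)$D
  extra <- rnorm(5)
  aug <- data.frame(shift = c(x, extra, y, extra),
                    interval_class = rep(c("below_2ms", "at_or_above_2ms"),
                                         each = 20))
  D1 <- ks_compare_shifts(aug)$D
  expect_equal(D1, D0 * 15 / 20, tolerance = 1e-10)
})
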