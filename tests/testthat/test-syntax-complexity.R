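# Signature and bout-classification rules. class_song()/class_bout() build
# songs from integer note-class ids spaced far beyond the matching
# tolerance, so the intended classes are unambiguous.

sig_of <- function(notes) {
  s <- song_signatures(assemble_songs(notes))
  stats::setNames(s$signature, s$song_id)
}

test_that("trill elongation does not create a new song type, note addition does", {
  notes <- rbind(
    class_song(c(1, 2, 3, 3, 3), song = "abccc"),
    class_song(c(1, 2, 3, 3), song = "abcc", t0 = 60),
    class_song(c(1, 2, 3), song = "abc", t0 = 120),
    class_song(c(1, 2, 3, 4), song = "abcd", t0 = 180))
  s <- sig_of(notes)
  expect_equal(unname(s["abccc"]), unname(s["abcc"]))    # trill collapsed
  expect_false(s["abc"] == s["abcd"])                    # note added
  expect_false(s["abc"] == s["abcc"])
})

test_that("a uniform frequency transposition is the same song type", {
  notes <- rbind(
    class_song(c(2, 4, 1), song = "orig"),
    class_song(c(2, 4, 1), song = "transposed", t0 = 60, low_mult = 1.6))
  s <- sig_of(notes)
  expect_equal(unname(s["orig"]), unname(s["transposed"]))
})

test_that("note matching respects the relative tolerance", {
  # durations differing by 10% match at the default 20% tolerance,
  # durations differing by 60% do not
  a <- make_song(c(0.10, 0.11), lows = c(2000, 2000), bws = c(1000, 1050),
                 song = "close")
  b <- make_song(c(0.10, 0.16), lows = c(2000, 2000), bws = c(1000, 1600),
                 song = "far", t0 = 60)
  s <- sig_of(rbind(a, b))
  expect_equal(length(strsplit(s[["close"]], "-")[[1]]), 1)  # run collapsed
  expect_equal(length(strsplit(s[["far"]], "-")[[1]]), 2)
})

test_that("bout classification reproduces the hand-enumerated example", {
  # A, B, A, AB' (novel, copies the 1-2 block of A), B, B
  bout_notes <- class_bout(list(
    c(1, 2, 3),        # A     -> new
    c(4, 5),           # B     -> new
    c(1, 2, 3),        # A     -> old
    c(1, 2, 6),        # AB'   -> mod (shares contiguous 1,2 with A)
    c(4, 5),           # B     -> old
    c(4, 5)))          # B     -> same
  ss <- assemble_songs(bout_notes)
  sigs <- song_signatures(ss)
  bouts <- data.frame(individual_id = "i1", population_id = "p1",
                      position = 1:6, song_id = ss$songs$song_id)
  cls <- classify_bouts(bouts, sigs)
  expect_equal(cls$category, c("new", "new", "old", "mod", "old", "same"))
  svi <- attr(cls, "svi")
  expect_equal(svi$svi, 3 / 6)   # distinct signatures: A, B, AB'
})

test_that("all-distinct and all-identical bouts hit the SVI extremes", {
  distinct <- class_bout(lapply(1:11, function(k) {
    c(1 + (k - 1) %/% 4, 5 + (k - 1) %% 4, 9)
  }))
  ss <- assemble_songs(distinct)
  sigs <- song_signatures(ss)
  bouts <- data.frame(individual_id = "i1", population_id = "p1",
                      position = 1:11, song_id = ss$songs$song_id)
  cls <- classify_bouts(bouts, sigs)
  expect_equal(attr(cls, "svi")$svi, 1)

  identical_bout <- class_bout(rep(list(c(1, 2, 3)), 11))
  ss2 <- assemble_songs(identical_bout)
  bouts2 <- data.frame(individual_id = "i1", population_id = "p1",
                       position = 1:11, song_id = ss2$songs$song_id)
  cls2 <- classify_bouts(bouts2, song_signatures(ss2))
  expect_equal(cls2$category, c("new", rep("same", 10)))
  expect_equal(attr(cls2, "svi")$svi, 1 / 11)
})

test_that("SVI always equals the brute-force distinct-signature count", {
  set.seed(21)
  pool <- list(c(1, 2, 3), c(2, 3), c(4, 5, 1), c(1, 3, 2, 4), c(5, 2),
               c(3, 1), c(2, 4, 5), c(1, 2, 3, 3))
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    picks <- sample(length(pool), n, replace = TRUE)
    bout_notes <- class_bout(pool[picks])
    ss <- assemble_songs(bout_notes)
    sigs <- song_signatures(ss)
    bouts <- data.frame(individual_id = "i1", population_id = "p1",
                        position = seq_len(n), song_id = ss$songs$song_id)
    cls <- classify_bouts(bouts, sigs)
    expect_equal(attr(cls, "svi")$svi,
                 length(unique(cls$signature)) / n)
    counts <- table(factor(cls$category,
                           levels = c("new", "mod", "old", "same")))
    expect_equal(sum(counts), n)
    expect_equal(cls$category[1], "new")
  }
})

test_that("bout selection takes consecutive songs and excludes short individuals", {
  notes <- rbind(random_valid_notes(11, seed = 1, ind = "full"),
                 random_valid_notes(10, seed = 2, ind = "short"))
  ss <- assemble_songs(notes)
  expect_warning(b <- select_bout(ss, n = 11), "short")
  expect_equal(unique(b$individual_id), "full")
  expect_equal(nrow(b), 11)
  # recording order preserved
  ord <- ss$songs[ss$songs$individual_id == "full", ]
  expect_equal(b$song_id, ord$song_id[order(ord$song_order)])
})

test_that("random bout starts are reproducible and stay within range", {
  notes <- random_valid_notes(30, seed = 3, ind = "i1")
  ss <- assemble_songs(notes)
  b1 <- select_bout(ss, n = 11, start = "random", seed = 5)
  b2 <- select_bout(ss, n = 11, start = "random", seed = 5)
  expect_equal(b1, b2)
  ord <- ss$songs$song_id[order(ss$songs$song_order)]
  idx <- match(b1$song_id, ord)
  expect_equal(idx, seq(idx[1], length.out = 11))
})

test_that("the library counts shared types and a planted shared song is found", {
  i1 <- class_bout(list(c(1, 2, 3), c(4, 5, 6)), ind = "i1")
  i2 <- class_bout(list(c(1, 2, 3), c(2, 4, 1)), ind = "i2")
  ss <- assemble_songs(rbind(i1, i2))
  lib <- build_library(song_signatures(ss))
  expect_equal(nrow(lib$types), 3)
  expect_equal(lib$sharing["i1", "i2"], 1)
  expect_equal(diag(lib$sharing), c(i1 = 0, i2 = 0))

  # disjoint repertoires: zero sharing
  j2 <- class_bout(list(c(7, 8), c(8, 7, 8)), ind = "i2")
  ss2 <- assemble_songs(rbind(i1, j2))
  lib2 <- build_library(song_signatures(ss2))
  expect_equal(lib2$sharing["i1", "i2"], 0)
})

test_that("library size equals the brute-force distinct-signature count", {
  sim <- simulate_dataset(small_config(), seed = 17)
  ss <- assemble_songs(sim$notes)
  sigs <- song_signatures(ss)
  bouts <- select_bout(ss, n = 11)
  lib <- build_library(sigs, bouts)
  in_bouts <- sigs$signature[sigs$song_id %in% bouts$song_id]
  expect_equal(nrow(lib$types), length(unique(in_bouts)))
  expect_true(all(table(lib$members$song_id) == 1))
})

test_that("grouped bootstrap is seeded, ordered and degenerate-safe", {
  df <- data.frame(individual_id = paste0("i", 1:6),
                   population_id = rep(c("A", "B"), each = 3),
                   svi = c(0.5, 0.5, 0.5, 0.4, 0.6, 0.8))
  s1 <- bootstrap_summary(df, value_cols = "svi", B = 200, seed = 9)
  s2 <- bootstrap_summary(df, value_cols = "svi", B = 200, seed = 9)
  expect_equal(s1, s2)
  a <- s1[s1$population_id == "A", ]
  expect_equal(a$lower, 0.5)
  expect_equal(a$upper, 0.5)
  b <- s1[s1$population_id == "B", ]
  expect_true(b$lower <= b$mean && b$mean <= b$upper)

  single <- data.frame(individual_id = "i1", population_id = "A", svi = 0.7)
  s3 <- bootstrap_summary(single, value_cols = "svi", B = 50, seed = 1)
  expect_false(s3$ci_available)
  expect_equal(s3$mean, 0.7)
})

test_that("SVI-spectral correlation reports r, df and p", {
  set.seed(4)
  feats <- do.call(rbind, lapply(1:10, function(i) {
    f <- song_features(assemble_songs(
      random_valid_notes(3, seed = 100 + i, ind = paste0("i", i))))
    f
  }))
  ind_bw <- tapply(feats$song_bandwidth, feats$individual_id, mean)
  svi_df <- data.frame(individual_id = names(ind_bw),
                       svi = as.numeric(scale(ind_bw)) * 0.1 + 0.5)
  res <- svi_spectral_correlation(svi_df, feats)
  bwrow <- res[res$variable == "song_bandwidth", ]
  expect_equal(bwrow$r, 1, tolerance = 1e-8)
  expect_equal(bwrow$df, 8)
  constant <- svi_df; constant$svi <- 0.5
  expect_error(svi_spectral_correlation(constant, feats), "zero variance")
})
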