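sim_features <- function(seed = 13) {
  song_features(assemble_songs(simulate_dataset(small_config(), seed = seed)$notes))
}

test_that("PCA on perfectly correlated variables retains one component", {
  set.seed(1)
  base <- rnorm(40)
  X <- outer(base, seq_len(6)) + matrix(rep(seq_len(6) * 10, each = 40), 40)
  p <- pca_reduce(X)
  expect_equal(p$k, 1)
  expect_equal(p$var_frac[1], 1, tolerance = 1e-8)
  expect_equal(unname(p$eigenvalues[1]), 6, tolerance = 1e-8)
})

test_that("PCA agrees with prcomp and the basis is complete", {
  feats <- sim_features()
  X <- feature_matrix(feats)
  p <- pca_reduce(feats, eigenvalue_cutoff = 0)   # retain everything positive
  pr <- prcomp(X, scale. = TRUE)
  expect_equal(abs(p$loadings[, 1]), abs(pr$rotation[, 1]), tolerance = 1e-8)
  expect_equal(p$eigenvalues[seq_len(p$k)], unname(pr$sdev[seq_len(p$k)]^2),
               tolerance = 1e-8)
  # reconstruction: scores %*% t(loadings) recovers the standardized data
  Z <- scale(X)
  expect_equal(p$scores %*% t(p$loadings), unclass(Z),
               ignore_attr = TRUE, tolerance = 1e-6)
  # scores centred; retained variance fraction consistent
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
  expect_equal(p$cum_var_frac,
               sum(p$eigenvalues[seq_len(p$k)]) / ncol(X), tolerance = 1e-12)
})

test_that("PCA sign convention is deterministic and constant columns are dropped", {
  feats <- sim_features()
  X <- feature_matrix(feats)
  p1 <- pca_reduce(X)
  p2 <- pca_reduce(X)
  expect_equal(p1$loadings, p2$loadings)
  for (j in seq_len(p1$k)) {
    expect_true(p1$loadings[which.max(abs(p1$loadings[, j])), j] > 0)
  }
  Xc <- cbind(X, const = 5)
  expect_warning(p3 <- pca_reduce(Xc), "constant")
  expect_false("const" %in% rownames(p3$loadings))
})

test_that("univariate nested F matches hand-computed sums of squares", {
  # balanced 2 populations x 2 individuals x 3 songs
  y <- c(1, 2, 3,   4, 5, 6,   10, 11, 12,   13, 14, 15)
  pop <- rep(c("A", "B"), each = 6)
  ind <- rep(c("a1", "a2", "b1", "b2"), each = 3)
  res <- nested_anova_per_pc(matrix(y, ncol = 1), pop, ind)
  grand <- mean(y)
  mpop <- tapply(y, pop, mean)
  mind <- tapply(y, ind, mean)
  ss_pop <- 6 * sum((mpop - grand)^2)
  ss_ind <- 3 * sum((mind - rep(mpop, each = 2))^2)
  ss_res <- sum((y - rep(mind, each = 3))^2)
  f_pop <- (ss_pop / 1) / (ss_ind / 2)
  f_ind <- (ss_ind / 2) / (ss_res / 8)
  expect_equal(res$F[res$effect == "population"], f_pop)
  expect_equal(res$F[res$effect == "individual_within_population"], f_ind)
  expect_equal(res$df1, c(1, 2))
  expect_equal(res$df2, c(2, 8))
})

test_that("nested MANOVA individual effect matches summary.manova Wilks", {
  feats <- sim_features(seed = 31)
  p <- pca_reduce(feats)
  Y <- p$scores
  pop <- factor(feats$population_id)
  ind <- factor(feats$individual_id)
  mine <- nested_manova(Y, pop, ind)
  fit <- manova(Y ~ pop + ind)   # ind nested: each individual in one pop
  sm <- summary(fit, test = "Wilks")$stats
  expect_equal(mine$lambda[2], unname(sm["ind", "Wilks"]), tolerance = 1e-6)
  expect_equal(mine$F[2], unname(sm["ind", "approx F"]), tolerance = 1e-6)
  expect_true(mine$F[1] > mine$F[2])   # planted population effect dominates
  expect_true(all(mine$p_value >= 0 & mine$p_value <= 1))
})

test_that("nested tests hold their size under a permutation null", {
  set.seed(55)
  n_rej <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    # null: no population structure; 6 pops x 3 inds x 4 songs
    pop <- rep(paste0("P", 1:6), each = 12)
    ind <- rep(paste0("i", 1:18), each = 4)
    y <- rnorm(72)
    res <- nested_anova_per_pc(matrix(y, ncol = 1), pop, ind)
    if (res$p_value[res$effect == "population"] < 0.05) n_rej <- n_rej + 1
  }
  expect_gt(n_rej / reps, 0.005)
  expect_lt(n_rej / reps, 0.105)
})

test_that("DFA separates separated clouds and matches lda classification", {
  set.seed(2)
  X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(100, mean = 8), 50))
  g <- rep(c("A", "B"), each = 50)
  d <- discriminant_analysis(X, g)
  expect_equal(d$rate, 1)
  expect_gt(d$canonical_correlations[1], 0.95)
  expect_equal(ncol(d$axes), 1)   # min(p, groups - 1)
  expect_equal(sum(d$confusion), 100)
})

test_that("shuffled labels classify at chance on balanced data", {
  set.seed(3)
  X <- matrix(rnorm(300 * 3), 300)
  g <- sample(rep(c("A", "B", "C"), each = 100))
  d <- discriminant_analysis(X, g)
  expect_lt(d$rate, 0.55)   # chance is 1/3; resubstitution inflates a bit
})

test_that("canonical correlations are invariant under affine transforms", {
  feats <- sim_features(seed = 77)
  p <- pca_reduce(feats)
  X <- p$scores
  g <- feats$population_id
  d0 <- discriminant_analysis(X, g)
  set.seed(10)
  A <- matrix(rnorm(ncol(X)^2), ncol(X))
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(ncol(X)^2), ncol(X))
  Xt <- X %*% A + matrix(rep(rnorm(ncol(X)), each = nrow(X)), nrow(X))
  d1 <- discriminant_analysis(Xt, g)
  expect_equal(d0$canonical_correlations, d1$canonical_correlations,
               tolerance = 1e-6)
})

test_that("leave-one-individual-out classification is available", {
  feats <- sim_features(seed = 19)
  p <- pca_reduce(feats)
  d <- discriminant_analysis(p$scores, feats$population_id,
                             individual = feats$individual_id,
                             cv = "individual")
  expect_true(d$rate >= 0 && d$rate <= 1)
  expect_equal(d$cv, "individual")
})

test_that("NMDS recovers planar data with near-zero stress, deterministically", {
  set.seed(6)
  X <- cbind(rnorm(30), rnorm(30))
  # monoMDS warns that the stress of an exact embedding is ~0; expected here
  o1 <- suppressWarnings(nmds(X, restarts = 5, seed = 4))
  expect_lt(o1$stress, 0.01)
  o2 <- suppressWarnings(nmds(X, restarts = 5, seed = 4))
  expect_equal(o1$points, o2$points)
  expect_equal(o1$stress, o2$stress)
})

test_that("degenerate equal-distance input yields the flagged trivial solution", {
  # rows of the identity matrix form a regular simplex: all pairwise
  # distances equal, also after per-column standardization
  simplex <- diag(4)
  expect_warning(o <- nmds(simplex, restarts = 2, seed = 1), "trivial")
  expect_true(o$trivial)
  expect_equal(o$stress, 0)
})

test_that("Kruskal-Wallis with Dunn matches hand-ranked arithmetic", {
  values <- 1:9
  groups <- rep(c("A", "B", "C"), each = 3)
  res <- kruskal_dunn(values, groups)
  # ranks are 1..9; mean ranks 2, 5, 8; KW = 12/(9*10) * 3*((2-5)^2+0+(8-5)^2)
  expect_equal(res$chi_square, 7.2, tolerance = 1e-10)
  expect_equal(res$df, 2)
  # Dunn: se = sqrt((9*10/12) * (1/3+1/3)) = sqrt(5)
  z_ab <- (2 - 5) / sqrt(5)
  ab <- res$pairwise[res$pairwise$group1 == "A" & res$pairwise$group2 == "B", ]
  expect_equal(ab$z, z_ab, tolerance = 1e-10)
  expect_equal(ab$p_adjusted, min(1, 3 * 2 * pnorm(-abs(z_ab))),
               tolerance = 1e-10)
  expect_equal(res$p_value, unname(kruskal.test(values, factor(groups))$p.value))
})

test_that("tied and degenerate rank data are handled", {
  allsame <- kruskal_dunn(rep(1, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(allsame$chi_square, 0)
  expect_equal(allsame$p_value, 1)
  withties <- kruskal_dunn(c(1, 1, 2, 2, 3, 3), rep(c("A", "B"), 3))
  kw <- kruskal.test(c(1, 1, 2, 2, 3, 3), factor(rep(c("A", "B"), 3)))
  expect_equal(withties$chi_square, unname(kw$statistic))
})

test_that("six groups give five degrees of freedom", {
  set.seed(12)
  res <- kruskal_dunn(rnorm(60), rep(paste0("P", 1:6), each = 10))
  expect_equal(res$df, 5)
  expect_equal(nrow(res$pairwise), choose(6, 2))
})
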