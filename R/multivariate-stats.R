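# Population-differentiation battery: PCA reduction of the 14 spectral
# variables, nested MANOVA/ANOVA (songs within individuals within
# populations), canonical discriminant analysis, NMDS ordination, and
# Kruskal-Wallis with Dunn-Bonferroni post hoc comparisons.

#' Principal component reduction of the spectral variables
#'
#' Variables are z-standardized (PCA on the correlation matrix, since the
#' inputs mix Hz, seconds, counts and proportions) and components with
#' eigenvalue above the cutoff are retained. Component signs are fixed
#' deterministically: the loading with the largest absolute value on each
#' component is made positive.
#'
#' @param features A \code{song_features} data frame or numeric matrix.
#' @param eigenvalue_cutoff Retention threshold on eigenvalues of the
#'   correlation matrix (default 1, the Kaiser rule).
#' @return Object of class \code{pca_model}: list with \code{loadings}
#'   (p x k), \code{eigenvalues} (all p), \code{var_frac} (per retained
#'   component), \code{cum_var_frac}, \code{k}, \code{scores} (n x k,
#'   columns PRIN1..PRINk), \code{center}, \code{scale},
#'   \code{dropped} (constant columns removed), and the label columns of
#'   the input if it was a feature table.
#' @export
pca_reduce <- function(features, eigenvalue_cutoff = 1) {
  labels <- NULL
  if (is.data.frame(features)) {
    labels <- features[, intersect(c("song_id", "individual_id",
                                     "population_id"), names(features)),
                       drop = FALSE]
    X <- feature_matrix(features)
  } else {
    X <- as.matrix(features)
  }
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (nrow(X) < ncol(X) + 1) {
    warning("fewer songs than variables + 1: component retention capped at rank")
  }
  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  evals <- eig$values
  rank <- sum(evals > sqrt(.Machine$double.eps) * evals[1])
  k <- min(sum(evals > eigenvalue_cutoff), rank)
  k <- max(k, 1L)
  V <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive per component
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PRIN", seq_len(k))
  scores <- Z %*% V
  out <- list(loadings = V, eigenvalues = evals,
              var_frac = evals[seq_len(k)] / ncol(X),
              cum_var_frac = sum(evals[seq_len(k)]) / ncol(X),
              k = k, scores = scores,
              center = attr(Z, "scaled:center"),
              scale = attr(Z, "scaled:scale"),
              dropped = dropped, labels = labels)
  class(out) <- "pca_model"
  out
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: retained %d component(s) (eigenvalue > cutoff), %.1f%% of variation\n",
              x$k, 100 * x$cum_var_frac))
  print(round(x$eigenvalues, 3))
  invisible(x)
}

# Wilks' lambda with Rao's F approximation. H, E: hypothesis and error
# SSCP matrices; q, v: their df; p: number of response variables.
.wilks_rao <- function(H, E, q, v, p) {
  L <- det(E) / det(H + E)
  tt <- if (p^2 + q^2 - 5 > 0) {
    sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5))
  } else 1
  w <- v + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * tt - (p * q - 2) / 2
  Lt <- L^(1 / tt)
  Fstat <- (1 - Lt) / Lt * df2 / df1
  list(lambda = L, F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# Hierarchical SSCP decomposition for songs nested in individuals nested
# in populations. Returns H_pop, H_ind, E and their df.
.nested_sscp <- function(Y, population, individual) {
  Y <- as.matrix(Y)
  population <- as.character(population)
  individual <- as.character(individual)
  N <- nrow(Y)
  grand <- colMeans(Y)
  pops <- unique(population)
  inds <- unique(individual)
  a <- length(pops)
  I <- length(inds)
  if (a < 2) stop("design error: need at least 2 populations")
  if (I <= a) stop("design error: individual-within-population effect unestimable")
  if (N <= I) stop("design error: need replicate songs within individuals")
  p <- ncol(Y)
  Hp <- matrix(0, p, p)
  Hi <- matrix(0, p, p)
  E <- matrix(0, p, p)
  ind_pop <- tapply(population, individual, function(z) z[1])
  for (g in pops) {
    idx <- population == g
    m <- colMeans(Y[idx, , drop = FALSE])
    d <- m - grand
    Hp <- Hp + sum(idx) * tcrossprod(d)
  }
  for (ind in inds) {
    idx <- individual == ind
    m <- colMeans(Y[idx, , drop = FALSE])
    gp <- population == ind_pop[[ind]]
    mp <- colMeans(Y[gp, , drop = FALSE])
    d <- m - mp
    Hi <- Hi + sum(idx) * tcrossprod(d)
    resid <- sweep(Y[idx, , drop = FALSE], 2, m)
    E <- E + crossprod(resid)
  }
  list(H_pop = Hp, H_ind = Hi, E = E,
       df_pop = a - 1, df_ind = I - a, df_res = N - I, p = p)
}

#' Nested MANOVA of song scores within individuals within populations
#'
#' Tests the population effect against individual-within-population
#' variation and the individual effect against the song-level residual,
#' using Wilks' lambda with Rao's F approximation. This matches the
#' hierarchical sampling design: songs are replicates of individuals,
#' individuals are replicates of populations, so the population test uses
#' the individual stratum as its error term.
#'
#' @param scores Numeric matrix (songs x variables), e.g. PCA scores.
#' @param population,individual Grouping labels per song.
#' @return Data frame of class \code{nested_manova}: one row per effect
#'   with \code{effect, lambda, F, df1, df2, p_value}.
#' @export
nested_manova <- function(scores, population, individual) {
  s <- .nested_sscp(scores, population, individual)
  r_pop <- .wilks_rao(s$H_pop, s$H_ind, s$df_pop, s$df_ind, s$p)
  r_ind <- .wilks_rao(s$H_ind, s$E, s$df_ind, s$df_res, s$p)
  out <- data.frame(
    effect = c("population", "individual_within_population"),
    lambda = c(r_pop$lambda, r_ind$lambda),
    F = c(r_pop$F, r_ind$F),
    df1 = c(r_pop$df1, r_ind$df1),
    df2 = c(r_pop$df2, r_ind$df2),
    p_value = c(r_pop$p_value, r_ind$p_value),
    stringsAsFactors = FALSE
  )
  class(out) <- c("nested_manova", "data.frame")
  out
}

#' Nested ANOVA per principal component
#'
#' Univariate version of [nested_manova()] applied to each column
#' separately: the classical nested F tests
#' (MS_population / MS_individual and MS_individual / MS_residual).
#'
#' @inheritParams nested_manova
#' @return Data frame: one row per variable x effect with \code{variable,
#'   effect, F, df1, df2, p_value}.
#' @export
nested_anova_per_pc <- function(scores, population, individual) {
  scores <- as.matrix(scores)
  cols <- colnames(scores)
  if (is.null(cols)) cols <- paste0("V", seq_len(ncol(scores)))
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    s <- .nested_sscp(scores[, j, drop = FALSE], population, individual)
    ms_pop <- s$H_pop[1, 1] / s$df_pop
    ms_ind <- s$H_ind[1, 1] / s$df_ind
    ms_res <- s$E[1, 1] / s$df_res
    data.frame(
      variable = cols[j],
      effect = c("population", "individual_within_population"),
      F = c(ms_pop / ms_ind, ms_ind / ms_res),
      df1 = c(s$df_pop, s$df_ind),
      df2 = c(s$df_ind, s$df_res),
      p_value = c(
        stats::pf(ms_pop / ms_ind, s$df_pop, s$df_ind, lower.tail = FALSE),
        stats::pf(ms_ind / ms_res, s$df_ind, s$df_res, lower.tail = FALSE)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Canonical discriminant analysis of songs by population
#'
#' Canonical axes maximize the between- to within-population variance
#' ratio (eigen decomposition of W^-1 B on the pooled within-group SSCP W
#' and between-group SSCP B); canonical correlation of axis i is
#' sqrt(lambda_i / (1 + lambda_i)). Classification is by linear
#' discriminant analysis; the default rate is resubstitution, with
#' leave-one-individual-out cross-validation available.
#'
#' @param scores Numeric matrix (songs x variables).
#' @param population Population label per song.
#' @param individual Optional individual labels, required for
#'   \code{cv = "individual"}.
#' @param cv \code{"none"} (resubstitution, default) or
#'   \code{"individual"} (leave-one-individual-out).
#' @param ridge Ridge added to W (as a fraction of mean diagonal) when W
#'   is singular; applied automatically with a message.
#' @return Object of class \code{dfa_model}: list with \code{axes}
#'   (canonical coefficients), \code{canonical_correlations},
#'   \code{var_explained} (per axis, of the discriminant eigenvalues),
#'   \code{canonical_scores}, \code{predicted}, \code{rate},
#'   \code{confusion} (true x predicted counts), \code{cv}.
#' @export
discriminant_analysis <- function(scores, population, individual = NULL,
                                  cv = c("none", "individual"),
                                  ridge = 1e-8) {
  cv <- match.arg(cv)
  X <- as.matrix(scores)
  g <- factor(population)
  if (nlevels(g) < 2) stop("need at least 2 populations")
  grand <- colMeans(X)
  p <- ncol(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(g)) {
    idx <- g == lev
    if (sum(idx) < 2) stop("each population needs at least 2 songs")
    m <- colMeans(X[idx, , drop = FALSE])
    B <- B + sum(idx) * tcrossprod(m - grand)
    W <- W + crossprod(sweep(X[idx, , drop = FALSE], 2, m))
  }
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-10) {
    message("within-group SSCP singular; adding ridge epsilon = ",
            format(ridge * mean(diag(W))))
    W <- W + diag(ridge * mean(diag(W)), p)
  }
  # symmetric eigenproblem via whitening: W^(-1/2) B W^(-1/2)
  Weig <- eigen(W, symmetric = TRUE)
  Whalf_inv <- Weig$vectors %*% diag(1 / sqrt(Weig$values), p) %*%
    t(Weig$vectors)
  M <- Whalf_inv %*% B %*% Whalf_inv
  Meig <- eigen(M, symmetric = TRUE)
  n_axes <- min(p, nlevels(g) - 1)
  lambda <- pmax(Meig$values[seq_len(n_axes)], 0)
  A <- Whalf_inv %*% Meig$vectors[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(n_axes)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  rownames(A) <- colnames(X)
  colnames(A) <- paste0("Can", seq_len(n_axes))
  can_scores <- sweep(X, 2, grand) %*% A
  fit <- MASS::lda(X, grouping = g)
  if (cv == "none") {
    pred <- stats::predict(fit, X)$class
  } else {
    if (is.null(individual)) stop("individual labels required for cv = 'individual'")
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(g))
    for (ind in unique(individual)) {
      hold <- individual == ind
      f <- MASS::lda(X[!hold, , drop = FALSE], grouping = g[!hold])
      pred[hold] <- stats::predict(f, X[hold, , drop = FALSE])$class
    }
  }
  confusion <- table(true = g, predicted = pred)
  out <- list(axes = A,
              canonical_correlations = sqrt(lambda / (1 + lambda)),
              var_explained = if (sum(lambda) > 0) lambda / sum(lambda)
                              else rep(NA_real_, n_axes),
              canonical_scores = can_scores,
              predicted = pred,
              rate = mean(pred == g),
              confusion = confusion,
              cv = cv, lda_fit = fit)
  class(out) <- "dfa_model"
  out
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf("Canonical discriminant analysis: %d axes, correct classification %.1f%% (%s)\n",
              ncol(x$axes), 100 * x$rate,
              if (x$cv == "none") "resubstitution" else "leave-one-individual-out"))
  cat("  canonical correlations:",
      paste(sprintf("%.2f", x$canonical_correlations), collapse = ", "), "\n")
  invisible(x)
}

#' Nonmetric multidimensional scaling of songs
#'
#' NMDS (monotone-regression stress minimization, best of \code{restarts}
#' random starts) on Euclidean distances between z-standardized feature
#' vectors; suited to variables on heterogeneous scales.
#'
#' @param features A \code{song_features} data frame or numeric matrix.
#' @param dims Embedding dimension (default 2).
#' @param restarts Random restarts (default 20).
#' @param seed Seed for reproducibility.
#' @return Object of class \code{ordination_result}: list with
#'   \code{points} (n x dims), \code{stress}, \code{converged},
#'   \code{trivial} (TRUE when all distances are equal).
#' @export
nmds <- function(features, dims = 2, restarts = 20, seed = NULL) {
  X <- if (is.data.frame(features)) feature_matrix(features) else
    as.matrix(features)
  if (nrow(X) < dims + 2) stop("need at least dims + 2 songs")
  keep <- apply(X, 2, stats::sd) > 0
  Z <- scale(X[, keep, drop = FALSE])
  d <- stats::dist(Z)
  if (stats::sd(d) == 0) {
    warning("all pairwise distances equal: trivial zero-stress solution")
    pts <- matrix(0, nrow(X), dims,
                  dimnames = list(rownames(X), paste0("NMDS", seq_len(dims))))
    return(structure(list(points = pts, stress = 0, converged = TRUE,
                          trivial = TRUE), class = "ordination_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = dims, try = restarts, trymax = restarts,
                        autotransform = FALSE, wascores = FALSE, trace = 0)
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(dims))
  conv <- fit$converged
  converged <- length(conv) == 1 &&
    ((is.logical(conv) && isTRUE(conv)) || (is.numeric(conv) && conv > 0))
  structure(list(points = pts, stress = fit$stress,
                 converged = converged, trivial = FALSE),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress = %.4f\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn-Bonferroni pairwise follow-up
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across groups, followed by
#' Dunn's z tests on mean ranks for every group pair with Bonferroni
#' adjustment over all pairs.
#'
#' @param values Numeric vector (e.g. per-song CVM rate).
#' @param groups Group label per value (e.g. population).
#' @return Object of class \code{rank_test_result}: list with
#'   \code{chi_square, df, p_value} and \code{pairwise} (data frame:
#'   group1, group2, z, p_raw, p_adjusted).
#' @export
kruskal_dunn <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) == 0)) stop("empty group")
  if (length(unique(values)) == 1) {
    pairs <- t(utils::combn(levels(g), 2))
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     z = 0, p_raw = 1, p_adjusted = 1,
                     stringsAsFactors = FALSE)
    return(structure(list(chi_square = 0, df = nlevels(g) - 1,
                          p_value = 1, pairwise = pw),
                     class = "rank_test_result"))
  }
  kw <- stats::kruskal.test(values, g)
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- t(utils::combn(levels(g), 2))
  z <- apply(pairs, 1, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / ng[[pr[1]]] + 1 / ng[[pr[2]]]))
    (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  m <- nrow(pairs)
  pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                   z = z, p_raw = p_raw,
                   p_adjusted = pmin(1, p_raw * m),
                   stringsAsFactors = FALSE)
  structure(list(chi_square = unname(kw$statistic),
                 df = unname(kw$parameter),
                 p_value = kw$p.value, pairwise = pw),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-square = %.2f, df = %d, p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  sig <- sum(x$pairwise$p_adjusted < 0.05)
  cat(sprintf("  Dunn-Bonferroni: %d of %d pairs significant at 0.05\n",
              sig, nrow(x$pairwise)))
  invisible(x)
}
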