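# Isolation analysis: labeled population-level distance matrices
# (geographic km, barrier counts, genetic F_ST, song spectral, song
# syntax) and Mantel / partial Mantel permutation tests of matrix
# correlation, the standard machinery for isolation-by-distance and
# isolation-by-barrier hypotheses.

#' Construct a labeled distance matrix
#'
#' @param m Square numeric matrix (symmetric, zero diagonal).
#' @param labels Population labels (unique); default from dimnames.
#' @param kind One of \code{geographic_km, barrier_count, fst,
#'   song_spectral, song_syntax, other}.
#' @return Object of class \code{labeled_dist}.
#' @export
labeled_dist <- function(m, labels = rownames(m),
                         kind = c("other", "geographic_km", "barrier_count",
                                  "fst", "song_spectral", "song_syntax")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (is.null(labels)) stop("labels required")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (nrow(m) != ncol(m) || nrow(m) != length(labels)) {
    stop("matrix must be square with one row per label")
  }
  if (any(m < 0)) stop("distances must be non-negative")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12)) stop("diagonal must be zero")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  structure(list(matrix = m, labels = labels, kind = kind),
            class = "labeled_dist")
}

#' @export
print.labeled_dist <- function(x, ...) {
  cat(sprintf("Labeled distance matrix (%s), %d populations\n",
              x$kind, length(x$labels)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Great-circle distances between populations
#'
#' Haversine great-circle distances, in kilometres, from decimal-degree
#' coordinates.
#'
#' @param coords Data frame with columns \code{population_id, lat, lon}.
#' @return A \code{labeled_dist} of kind \code{geographic_km}.
#' @export
geographic_distances <- function(coords) {
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    stop("latitude must be in [-90, 90] and longitude in [-180, 180]")
  }
  n <- nrow(coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        m[i, j] <- m[j, i] <- geosphere::distHaversine(
          c(coords$lon[i], coords$lat[i]),
          c(coords$lon[j], coords$lat[j])) / 1000
      }
    }
  }
  labeled_dist(m, coords$population_id, kind = "geographic_km")
}

#' Barrier distances between populations
#'
#' Populations are assigned to ordered zones along the mountain chain,
#' with successive zones separated by one barrier (ancient valley or
#' river). The distance between two populations is the number of barriers
#' between their zones (\code{count}, default) or the presence of any
#' barrier (\code{binary}).
#'
#' @param zones Data frame with columns \code{population_id, zone}
#'   (integer ordinal along the chain).
#' @param encoding \code{"count"} or \code{"binary"}.
#' @return A \code{labeled_dist} of kind \code{barrier_count}.
#' @export
barrier_distances <- function(zones, encoding = c("count", "binary")) {
  encoding <- match.arg(encoding)
  if (anyNA(zones$zone)) stop("unassigned population zone")
  m <- abs(outer(zones$zone, zones$zone, "-"))
  if (encoding == "binary") m <- (m > 0) + 0
  labeled_dist(m, zones$population_id, kind = "barrier_count")
}

#' Population-level song distance matrices
#'
#' Spectral: Euclidean distance between population centroids in retained
#' principal-component space. Syntax: Euclidean distance between
#' population vectors of (mean SVI, mean category proportions).
#'
#' @param pca A \code{pca_model} fitted on song features (with label
#'   columns), for the spectral matrix; or \code{NULL} to skip.
#' @param syntax_stats [bout_syntax_stats()] output for the syntax matrix;
#'   or \code{NULL} to skip.
#' @return Named list with elements \code{spectral} and/or \code{syntax},
#'   each a \code{labeled_dist}.
#' @export
song_distance_matrices <- function(pca = NULL, syntax_stats = NULL) {
  out <- list()
  if (!is.null(pca)) {
    if (is.null(pca$labels) || is.null(pca$labels$population_id)) {
      stop("pca must carry population labels (fit it on a song_features table)")
    }
    pops <- sort(unique(pca$labels$population_id))
    cent <- t(vapply(pops, function(pp) {
      colMeans(pca$scores[pca$labels$population_id == pp, , drop = FALSE])
    }, numeric(ncol(pca$scores))))
    out$spectral <- labeled_dist(as.matrix(stats::dist(cent)), pops,
                                 kind = "song_spectral")
  }
  if (!is.null(syntax_stats)) {
    pops <- sort(unique(syntax_stats$population_id))
    vars <- c("svi", "prop_new", "prop_mod", "prop_old", "prop_same")
    cent <- t(vapply(pops, function(pp) {
      colMeans(as.matrix(
        syntax_stats[syntax_stats$population_id == pp, vars, drop = FALSE]))
    }, numeric(length(vars))))
    out$syntax <- labeled_dist(as.matrix(stats::dist(cent)), pops,
                               kind = "song_syntax")
  }
  out
}

#' Read / write a square labeled distance matrix (TSV)
#'
#' Square matrix with labels as the first column and the header row
#' (PHYLIP-style square matrices with a header are also accepted by
#' \code{read_distance_matrix} when \code{header = FALSE}).
#'
#' @param x A \code{labeled_dist}.
#' @param path File path.
#' @param kind Kind tag for the matrix read back.
#' @param header Whether the file has a header row of labels.
#' @return \code{write_distance_matrix}: \code{path}, invisibly.
#'   \code{read_distance_matrix}: a \code{labeled_dist}.
#' @export
write_distance_matrix <- function(x, path) {
  df <- data.frame(label = x$labels, x$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, kind = "other", header = TRUE) {
  raw <- utils::read.delim(path, header = header, check.names = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  mode(m) <- "numeric"
  labeled_dist(m, labels, kind = kind)
}

# Align two or more labeled_dist objects on their common labels, in the
# order of the first.
.align_dists <- function(...) {
  ds <- list(...)
  labs <- Reduce(intersect, lapply(ds, `[[`, "labels"))
  if (length(labs) < 3) stop("fewer than 3 common populations after alignment")
  lapply(ds, function(d) d$matrix[labs, labs])
}

.upper <- function(m) m[upper.tri(m)]

# All permutations of 1..n (n small), for exact Mantel enumeration.
.all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      k <- k + 1L
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      out[[k]] <- v
    }
  }
  out
}

#' Mantel test of matrix correlation
#'
#' Pearson correlation between the upper triangles of two aligned distance
#' matrices, with significance by joint row/column permutation of the
#' second matrix. When the number of populations is small enough that all
#' n! relabelings fit within \code{permutations}, the exact permutation
#' distribution is enumerated; otherwise random permutations are sampled
#' and the add-one correction \code{p = (1 + extreme) / (1 + B)} is used.
#' The default tail is one-sided positive (the isolation hypothesis);
#' \code{tail = "two-sided"} compares |r|.
#'
#' @param a,b \code{labeled_dist} objects (aligned on common labels).
#' @param permutations Number of permutations (default 9999).
#' @param seed Optional seed.
#' @param tail \code{"greater"} (default) or \code{"two-sided"}.
#' @return Object of class \code{mantel_result}: list with \code{r, p,
#'   permutations, exact, tail, partial, control_kind, kinds}.
#' @export
mantel <- function(a, b, permutations = 9999, seed = NULL,
                   tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  al <- .align_dists(a, b)
  n <- nrow(al[[1]])
  if (n < 4) stop("need at least 4 populations")
  x <- .upper(al[[1]])
  y <- .upper(al[[2]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant distance matrix")
  }
  r_obs <- stats::cor(x, y)
  stat <- function(pm) stats::cor(x, .upper(al[[2]][pm, pm]))
  exact <- factorial(n) <= permutations
  if (exact) {
    rs <- vapply(.all_perms(n), stat, numeric(1))
    nperm <- length(rs)
    p <- if (tail == "greater") mean(rs >= r_obs - 1e-12) else
      mean(abs(rs) >= abs(r_obs) - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rs <- vapply(seq_len(permutations), function(i) {
      stat(sample.int(n))
    }, numeric(1))
    nperm <- permutations
    p <- if (tail == "greater") (1 + sum(rs >= r_obs - 1e-12)) / (1 + nperm)
         else (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (1 + nperm)
  }
  structure(list(r = r_obs, p = p, permutations = nperm, exact = exact,
                 tail = tail, partial = FALSE, control_kind = NULL,
                 kinds = c(a$kind, b$kind)),
            class = "mantel_result")
}

#' Partial Mantel test controlling for a third matrix
#'
#' Correlation between the upper triangles of \code{a} and \code{b} after
#' removing (by linear regression) the effect of control matrix \code{c};
#' significance by joint row/column permutation of \code{a} with residual
#' recomputation.
#'
#' @param a,b \code{labeled_dist} objects of interest.
#' @param control Control \code{labeled_dist}.
#' @inheritParams mantel
#' @return A \code{mantel_result} with \code{partial = TRUE}.
#' @export
partial_mantel <- function(a, b, control, permutations = 9999, seed = NULL,
                           tail = c("greater", "two-sided")) {
  tail <- match.arg(tail)
  al <- .align_dists(a, b, control)
  n <- nrow(al[[1]])
  if (n < 4) stop("need at least 4 populations")
  zc <- .upper(al[[3]])
  if (stats::sd(zc) == 0) {
    warning("constant control matrix: reduces to a simple Mantel test")
    return(mantel(a, b, permutations = permutations, seed = seed,
                  tail = tail))
  }
  resid_on <- function(v) stats::lm.fit(cbind(1, zc), v)$residuals
  ry <- resid_on(.upper(al[[2]]))
  if (stats::sd(ry) < 1e-12) {
    warning("control absorbs all variation in b: partial r undefined")
    return(structure(list(r = NA_real_, p = NA_real_,
                          permutations = 0, exact = FALSE, tail = tail,
                          partial = TRUE, control_kind = control$kind,
                          kinds = c(a$kind, b$kind)),
                     class = "mantel_result"))
  }
  stat <- function(pm) {
    rx <- resid_on(.upper(al[[1]][pm, pm]))
    if (stats::sd(rx) < 1e-12) return(NA_real_)
    stats::cor(rx, ry)
  }
  r_obs <- stat(seq_len(n))
  if (is.na(r_obs)) {
    warning("control absorbs all variation in a: partial r undefined")
    return(structure(list(r = NA_real_, p = NA_real_,
                          permutations = 0, exact = FALSE, tail = tail,
                          partial = TRUE, control_kind = control$kind,
                          kinds = c(a$kind, b$kind)),
                     class = "mantel_result"))
  }
  exact <- factorial(n) <= permutations
  if (exact) {
    rs <- vapply(.all_perms(n), stat, numeric(1))
    rs <- rs[!is.na(rs)]
    nperm <- length(rs)
    p <- if (tail == "greater") mean(rs >= r_obs - 1e-12) else
      mean(abs(rs) >= abs(r_obs) - 1e-12)
  } else {
    if (!is.null(seed)) set.seed(seed)
    rs <- vapply(seq_len(permutations), function(i) stat(sample.int(n)),
                 numeric(1))
    rs <- rs[!is.na(rs)]
    nperm <- length(rs)
    p <- if (tail == "greater") (1 + sum(rs >= r_obs - 1e-12)) / (1 + nperm)
         else (1 + sum(abs(rs) >= abs(r_obs) - 1e-12)) / (1 + nperm)
  }
  structure(list(r = r_obs, p = p, permutations = nperm, exact = exact,
                 tail = tail, partial = TRUE, control_kind = control$kind,
                 kinds = c(a$kind, b$kind)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  lab <- if (x$partial) {
    sprintf("Partial Mantel (%s ~ %s | %s)", x$kinds[1], x$kinds[2],
            x$control_kind)
  } else {
    sprintf("Mantel (%s ~ %s)", x$kinds[1], x$kinds[2])
  }
  cat(sprintf("%s: r = %.3f, p = %.4g (%s, %d permutations%s)\n",
              lab, x$r, x$p, x$tail, x$permutations,
              if (x$exact) ", exact" else ""))
  invisible(x)
}
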