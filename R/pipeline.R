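# End-to-end orchestration: ingest -> spectral features -> syntax ->
# multivariate battery -> isolation analysis, with a single master seed
# fanned out to per-stage seeds (seed + fixed offsets, so any stage can be
# rerun in isolation reproducibly).

#' Run the full song-differentiation pipeline
#'
#' @param x Input data: a note data frame (canonical columns), a
#'   \code{song_set}, or a \code{songdiff_sim} (in which case population
#'   coordinates, barrier zones and the synthetic F_ST matrix are taken
#'   from the simulation).
#' @param coords Optional data frame \code{population_id, lat, lon}.
#' @param zones Optional data frame \code{population_id, zone}.
#' @param fst Optional genetic-differentiation \code{labeled_dist} (F_ST
#'   is always consumed as an input, never estimated). When absent, the
#'   isolation section is limited to distance/barrier tests and says so.
#' @param bout_size Songs per analyzed bout (default 11).
#' @param cvm_threshold_ms Minibreath threshold in ms (default 2).
#' @param note_tolerance Note-matching tolerance for signatures (default 0.2).
#' @param eigenvalue_cutoff PCA retention cutoff (default 1).
#' @param bootstrap_reps Bootstrap replications (default 1000).
#' @param permutations Mantel permutations (default 9999).
#' @param nmds_restarts NMDS random restarts (default 20).
#' @param seed Master seed (default 1).
#' @return Object of class \code{songdiff_report}: list with elements
#'   \code{manifest, features, shifts, ks, bouts, signatures,
#'   classification, syntax_stats, library, syntax_summary, svi_correlation,
#'   pca, manova, anova_per_pc, dfa, nmds, kw_short, kw_overlap,
#'   distances, mantel, notices, params}.
#' @export
run_pipeline <- function(x, coords = NULL, zones = NULL, fst = NULL,
                         bout_size = 11, cvm_threshold_ms = 2,
                         note_tolerance = 0.2, eigenvalue_cutoff = 1,
                         bootstrap_reps = 1000, permutations = 9999,
                         nmds_restarts = 20, seed = 1) {
  notices <- character(0)
  if (inherits(x, "songdiff_sim")) {
    coords <- x$populations[, c("population_id", "lat", "lon")]
    zones <- data.frame(population_id = x$populations$population_id,
                        zone = x$populations$barrier_zone)
    fst <- x$fst
    x <- x$notes
  }
  ss <- if (inherits(x, "song_set")) x else assemble_songs(x)
  manifest <- summarize_dataset(ss)

  features <- song_features(ss, cvm_threshold_ms = cvm_threshold_ms)
  shifts <- frequency_shifts(ss, threshold = cvm_threshold_ms / 1000)
  ks <- tryCatch(ks_compare_shifts(shifts), error = function(e) {
    notices <<- c(notices, paste("KS comparison skipped:",
                                 conditionMessage(e)))
    NULL
  })

  bouts <- withCallingHandlers(
    select_bout(ss, n = bout_size),
    warning = function(w) {
      notices <<- c(notices, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  signatures <- song_signatures(ss, tolerance = note_tolerance)
  classification <- classify_bouts(bouts, signatures)
  syntax_stats <- bout_syntax_stats(classification)
  library <- build_library(signatures, bouts)
  syntax_summary <- bootstrap_summary(syntax_stats, B = bootstrap_reps,
                                      seed = seed + 1)
  svi_corr <- tryCatch(
    svi_spectral_correlation(attr(classification, "svi"), features),
    error = function(e) {
      notices <<- c(notices, paste("SVI correlation skipped:",
                                   conditionMessage(e)))
      NULL
    })

  pca <- withCallingHandlers(
    pca_reduce(features, eigenvalue_cutoff = eigenvalue_cutoff),
    warning = function(w) {
      notices <<- c(notices, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  pop <- features$population_id
  ind <- features$individual_id
  man <- tryCatch(nested_manova(pca$scores, pop, ind), error = function(e) {
    notices <<- c(notices, paste("nested MANOVA skipped:",
                                 conditionMessage(e)))
    NULL
  })
  anovas <- tryCatch(nested_anova_per_pc(pca$scores, pop, ind),
                     error = function(e) NULL)
  dfa <- tryCatch(discriminant_analysis(pca$scores, pop),
                  error = function(e) {
                    notices <<- c(notices, paste("DFA skipped:",
                                                 conditionMessage(e)))
                    NULL
                  })
  ord <- nmds(features, restarts = nmds_restarts, seed = seed + 2)
  kw_short <- tryCatch(
    kruskal_dunn(features$cvm_short_interval_rate, pop),
    error = function(e) NULL)
  kw_overlap <- tryCatch(
    kruskal_dunn(features$cvm_overlap_rate, pop),
    error = function(e) NULL)

  distances <- song_distance_matrices(pca, syntax_stats)
  if (!is.null(coords)) distances$geographic <- geographic_distances(coords)
  if (!is.null(zones)) distances$barrier <- barrier_distances(zones)
  if (!is.null(fst)) {
    distances$fst <- fst
  } else {
    notices <- c(notices,
                 "no F_ST matrix supplied: isolation section limited to distance/barrier tests")
  }
  mantel_tab <- .mantel_battery(distances, permutations, seed + 3)

  out <- list(manifest = manifest, features = features, shifts = shifts,
              ks = ks, bouts = bouts, signatures = signatures,
              classification = classification, syntax_stats = syntax_stats,
              library = library, syntax_summary = syntax_summary,
              svi_correlation = svi_corr, pca = pca, manova = man,
              anova_per_pc = anovas, dfa = dfa, nmds = ord,
              kw_short = kw_short, kw_overlap = kw_overlap,
              distances = distances, mantel = mantel_tab,
              notices = notices,
              params = list(bout_size = bout_size,
                            cvm_threshold_ms = cvm_threshold_ms,
                            note_tolerance = note_tolerance,
                            eigenvalue_cutoff = eigenvalue_cutoff,
                            bootstrap_reps = bootstrap_reps,
                            permutations = permutations,
                            nmds_restarts = nmds_restarts, seed = seed))
  class(out) <- "songdiff_report"
  out
}

# All Mantel and partial Mantel tests the available matrices permit.
.mantel_battery <- function(distances, permutations, seed) {
  rows <- list()
  add <- function(name, res) {
    if (is.null(res)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      test = name, r = res$r, p = res$p, permutations = res$permutations,
      partial = res$partial, stringsAsFactors = FALSE)
  }
  try_mantel <- function(a, b) {
    tryCatch(mantel(distances[[a]], distances[[b]],
                    permutations = permutations, seed = seed),
             error = function(e) NULL)
  }
  try_partial <- function(a, b, ctrl) {
    tryCatch(suppressWarnings(
      partial_mantel(distances[[a]], distances[[b]], distances[[ctrl]],
                     permutations = permutations, seed = seed)),
      error = function(e) NULL)
  }
  for (song in intersect(c("spectral", "syntax"), names(distances))) {
    for (pred in intersect(c("geographic", "barrier", "fst"),
                           names(distances))) {
      add(paste(song, pred, sep = "~"), try_mantel(song, pred))
    }
    if (all(c("fst", "geographic", "barrier") %in% names(distances))) {
      add(paste0(song, "~fst|geographic"),
          try_partial(song, "fst", "geographic"))
      add(paste0(song, "~fst|barrier"),
          try_partial(song, "fst", "barrier"))
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(test = character(), r = numeric(), p = numeric(),
                      permutations = integer(), partial = logical())
  }
  rownames(out) <- NULL
  out
}

#' @export
print.songdiff_report <- function(x, ...) {
  cat("== Song differentiation report ==\n")
  print(x$manifest)
  cat(sprintf("Syntax stage: %d songs in %d bouts of %d; %d unique song types\n",
              nrow(x$classification),
              length(unique(x$classification$individual_id)),
              x$params$bout_size, nrow(x$library$types)))
  shared <- sum(x$library$sharing[upper.tri(x$library$sharing)])
  cat(sprintf("Cross-individual shared song types: %d\n", shared))
  print(x$pca)
  if (!is.null(x$manova)) {
    cat(sprintf("Nested MANOVA: population F = %.2f (p = %.3g), individual F = %.2f (p = %.3g)\n",
                x$manova$F[1], x$manova$p_value[1],
                x$manova$F[2], x$manova$p_value[2]))
  }
  if (!is.null(x$dfa)) print(x$dfa)
  print(x$nmds)
  if (!is.null(x$kw_short)) {
    cat("CVM short-interval rate by population: ")
    print(x$kw_short)
  }
  if (!is.null(x$ks)) {
    cat(sprintf("Frequency shifts across minibreath boundary: KS D = %.3f, p = %.3g\n",
                x$ks$D, x$ks$p))
  }
  if (nrow(x$mantel)) {
    cat("Mantel battery:\n")
    print(cbind(x$mantel[, c("test", "partial")],
                r = round(x$mantel$r, 3), p = round(x$mantel$p, 4)))
  }
  if (length(x$notices)) {
    cat("Notices:\n")
    for (n in x$notices) cat(" -", n, "\n")
  }
  invisible(x)
}

#' Write the report's tabular outputs to a directory
#'
#' @param report A \code{songdiff_report}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(as.data.frame(report$features), "features.tsv")
  wt(report$shifts, "shifts.tsv")
  wt(as.data.frame(report$classification), "bout_classification.tsv")
  wt(report$library$types, "song_type_library.tsv")
  utils::write.table(report$library$sharing, file.path(dir, "sharing_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  wt(as.data.frame(report$syntax_summary), "syntax_summary.tsv")
  wt(data.frame(song_id = rownames(report$pca$scores), report$pca$scores),
     "pca_scores.tsv")
  wt(data.frame(variable = rownames(report$pca$loadings),
                report$pca$loadings), "pca_loadings.tsv")
  if (!is.null(report$manova)) wt(report$manova, "manova.tsv")
  if (!is.null(report$anova_per_pc)) wt(report$anova_per_pc, "anova_per_pc.tsv")
  if (!is.null(report$dfa)) {
    utils::write.table(report$dfa$confusion, file.path(dir, "dfa_confusion.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  wt(data.frame(song_id = rownames(report$nmds$points), report$nmds$points),
     "nmds_points.tsv")
  wt(report$mantel, "mantel.tsv")
  for (nm in names(report$distances)) {
    write_distance_matrix(report$distances[[nm]],
                          file.path(dir, paste0("dist_", nm, ".tsv")))
  }
  invisible(dir)
}
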