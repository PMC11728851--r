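#' Assemble a combined session report
#'
#' Joins per-animal microstructure summaries (and, optionally, the spatial
#' quadrant table) into one wide table, one row per animal x session, plus
#' group means with standard errors. No inferential statistics are computed
#' here; the table is the export surface for external stats tooling.
#'
#' @param summaries Microstructure summaries, rows as produced by
#'   [summarize_session()]; an optional `group` column drives the grouping
#'   of the means (falling back to a single overall group).
#' @param quadrant_summary Optional output of [quadrant_distance_summary()];
#'   its `session` values must all appear in `summaries$session_index`.
#' @return A list of class `session_report`: `by_animal` (sorted wide
#'   table), `group_means` (`group` x `measure` with `mean`, `se`, `n`), and
#'   `quadrants` (the table passed in, or `NULL`).
#' @export
session_report <- function(summaries, quadrant_summary = NULL) {
  stopifnot(is.data.frame(summaries),
            all(c("animal_id", "session_index") %in% names(summaries)))
  if (!is.null(quadrant_summary)) {
    extra <- setdiff(unique(quadrant_summary$session),
                     unique(summaries$session_index))
    if (length(extra))
      stop("quadrant_summary sessions absent from summaries: ",
           paste(extra, collapse = ", "))
  }
  by_animal <- summaries[order(summaries$animal_id,
                               summaries$session_index), , drop = FALSE]
  rownames(by_animal) <- NULL
  grp <- if ("group" %in% names(by_animal)) by_animal$group else
    rep("all", nrow(by_animal))
  measures <- intersect(
    c("active_licks", "inactive_licks", "log10_active_licks", "rewards",
      "intake_ml_per_kg", "n_clusters", "mean_cluster_size", "mean_ili_ms",
      "latency_ms"),
    names(by_animal))
  gm <- list()
  for (g in unique(grp)) {
    sub <- by_animal[grp == g, , drop = FALSE]
    for (m in measures) {
      v <- sub[[m]]
      v <- v[is.finite(v)]
      gm[[length(gm) + 1L]] <- data.frame(
        group = g, measure = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(by_animal = by_animal,
                 group_means = do.call(rbind, gm),
                 quadrants = quadrant_summary),
            class = "session_report")
}

#' Write a session report to disk
#'
#' @param report A [session_report()].
#' @param dir Output directory; writes `report.csv` (per-animal rows),
#'   `group_means.csv` and a short `report.md`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "session_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$by_animal, file.path(dir, "report.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(report$group_means, file.path(dir, "group_means.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  md <- c("# Session report", "",
          sprintf("Animals x sessions: %d rows", nrow(report$by_animal)),
          "", "## Group means (mean +/- SE)", "")
  gm <- report$group_means
  md <- c(md, sprintf("- %s / %s: %.4g +/- %.2g (n=%d)", gm$group,
                      gm$measure, gm$mean, gm$se, gm$n))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
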