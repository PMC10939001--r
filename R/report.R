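# Run diagnostics and persistence: predicted-vs-relaxed energy correlation,
# per-minimum relaxation accounting, and the run-directory layout.

#' Rank and correlate predicted against relaxed energies
#'
#' Shifts each energy set to its own minimum (relative energies), then
#' reports the coefficient of determination of relaxed on predicted
#' energies, the Spearman rank correlation, and the joined table.  Constant
#' predictions give an R-squared of zero by convention.
#'
#' @param predicted data frame with columns `index`, `E_pred` (eV).
#' @param relaxed data frame with columns `index`, `E_relaxed` (eV).
#' @return list with `table` (relative energies, matched by index),
#'   `r_squared`, and `rank_correlation`.
#' @export
rank_and_correlate <- function(predicted, relaxed) {
  tab <- merge(predicted, relaxed, by = "index")
  if (!nrow(tab)) stop("no common indices between the two sets")
  tab$E_pred_rel <- tab$E_pred - min(tab$E_pred)
  tab$E_relaxed_rel <- tab$E_relaxed - min(tab$E_relaxed)
  r2 <- if (stats::var(tab$E_pred_rel) < 1e-300 ||
            stats::var(tab$E_relaxed_rel) < 1e-300) {
    0
  } else {
    stats::cor(tab$E_pred_rel, tab$E_relaxed_rel)^2
  }
  rho <- if (nrow(tab) > 2 && stats::var(tab$E_pred_rel) > 1e-300 &&
             stats::var(tab$E_relaxed_rel) > 1e-300) {
    stats::cor(tab$E_pred_rel, tab$E_relaxed_rel, method = "spearman")
  } else NA_real_
  tab <- tab[order(tab$E_pred_rel), ]
  rownames(tab) <- NULL
  list(table = tab, r_squared = r2, rank_correlation = rho)
}

#' Summarize a search run against its relaxed minima
#'
#' The per-minimum accounting table: predicted energy, relaxed energy,
#' RMSD from the realized to the relaxed structure, and the number of
#' relaxation steps, plus their averages.
#'
#' @param minima deduplicated minima list (each with `x`, `E_pred`,
#'   `structure`).
#' @param relaxed list of [relax()] results matching `minima`.
#' @param rmsd_fn RMSD function (default [kabsch_rmsd()]; use
#'   [adsorption_rmsd()] for adsorbate+slab systems).
#' @return list with `table` (one row per minimum) and `averages`.
#' @export
summarize_run <- function(minima, relaxed, rmsd_fn = kabsch_rmsd) {
  stopifnot(length(minima) == length(relaxed))
  rows <- lapply(seq_along(minima), function(i) {
    m <- minima[[i]]; r <- relaxed[[i]]
    data.frame(rank = i,
               E_pred = if (!is.null(m$E_pred)) m$E_pred else NA_real_,
               E_relaxed = r$energy,
               rmsd = rmsd_fn(m$structure, r$structure),
               n_steps = r$n_steps,
               converged = r$converged)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       averages = c(n_steps = mean(tab$n_steps), rmsd = mean(tab$rmsd)))
}

#' Write a search run directory
#'
#' Persists a run in the standard layout: `dataset.csv` (reduced vectors,
#' raw and transformed energies, provenance), `model.json` (GP
#' hyperparameters), `minima/min_<rank>.xyz` (extended XYZ), `config.yaml`
#' (settings snapshot) and `run.log`.
#'
#' @param result a `surfbo_result`.
#' @param dir output directory (created if needed).
#' @param minima optional deduplicated minima (with structures) to write.
#' @return `dir`, invisibly.
#' @export
write_run_dir <- function(result, dir, minima = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- cbind(as.data.frame(result$X), result$data)
  names(df)[seq_len(ncol(result$X))] <- result$space$vars$label
  utils::write.csv(df, file.path(dir, "dataset.csv"), row.names = FALSE)
  gp_to_json(result$model, file.path(dir, "model.json"))
  cfg <- result$settings
  cfg$transform <- unclass(cfg$transform)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(minima) && length(minima)) {
    dir.create(file.path(dir, "minima"), showWarnings = FALSE)
    for (i in seq_along(minima)) {
      m <- minima[[i]]
      if (is.null(m$structure)) next
      s <- m$structure
      s$energy <- m$E_pred
      write_xyz(s, file.path(dir, "minima",
                             sprintf("min_%02d.xyz", i)))
    }
  }
  log_lines <- c(
    sprintf("surfbo run: %s", result$objective$label),
    sprintf("observations: %d (%d sampled, %d augmented, %d capped)",
            nrow(result$X), sum(result$data$provenance == "sampled"),
            sum(result$data$provenance == "augmented"),
            sum(result$data$provenance == "capped")),
    sprintf("termination: %s", result$termination),
    sprintf("best transformed energy: %.6f eV", min(result$data$y)),
    sprintf("seed: %d", result$settings$seed))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' Read a configuration file
#'
#' Flat YAML schema for command-line runs; unknown keys are passed through.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
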