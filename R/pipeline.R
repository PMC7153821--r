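# End-to-end orchestration: simulate (or load) -> featurize -> tICA -> MSM
# (+ validation) -> PCCA+ -> landscape -> kinetic grouping -> report, behind
# one configuration object with recorded seeds.

#' Pipeline configuration
#'
#' Collects every stage's settings in one provenance record. Defaults follow
#' the analysis conventions used throughout: 10 ns MSM/tICA lag, 150 k-means
#' microstates, 300 K, 100x100 landscape bins; microstate clustering runs on
#' `tica_dim` tICs (default 3) while surfaces use tIC1/tIC2.
#'
#' @param lag_ns tICA and MSM lag time in ns.
#' @param k microstate count.
#' @param n_macro macrostate count, or `"auto"` for the spectral-gap rule
#'   ([choose_n_macro()]).
#' @param tica_dim number of tICs used for microstate clustering.
#' @param bins landscape bins per axis.
#' @param temperature Kelvin for kcal/mol conversion.
#' @param ck_factors lag multiples for the Chapman-Kolmogorov test.
#' @param kmeans_seed recorded k-means seed.
#' @param reweight logical: stationary-reweight the free-energy surface
#'   (default TRUE; seeded short trajectories are not equilibrium samples).
#' @param synthetic optional [synthetic_spec()] to generate input data.
#' @param out_dir optional directory for artifacts (CSV/JSON).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(lag_ns = 10, k = 150, n_macro = "auto",
                            tica_dim = 3, bins = 100, temperature = 300,
                            ck_factors = 2:4, kmeans_seed = 42L,
                            reweight = TRUE, synthetic = NULL, out_dir = NULL) {
  structure(list(lag_ns = lag_ns, k = k, n_macro = n_macro,
                 tica_dim = tica_dim, bins = bins, temperature = temperature,
                 ck_factors = ck_factors, kmeans_seed = kmeans_seed,
                 reweight = reweight, synthetic = synthetic, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full loop-kinetics pipeline
#'
#' Executes: data generation (if `config$synthetic` is set) or use of the
#' supplied trajectories; sin/cos featurization; tICA at the configured lag;
#' k-means microstate discretization; reversible MSM with connectivity
#' trimming; implied timescales and Chapman-Kolmogorov validation; PCCA+
#' macrostates with probabilities and MFPTs; the free-energy surface; and,
#' when references are given, their projection and kinetic grouping plus the
#' nearest-neighbor distance report.
#'
#' @param config a [pipeline_config()].
#' @param trajectories list of [torsion_trajectory()] (ignored if
#'   `config$synthetic` is given).
#' @param references optional list of [reference_conformation()].
#' @return a `run_report` list with all fitted models and summary tables.
#' @export
run_pipeline <- function(config, trajectories = NULL, references = NULL) {
  stage <- "input"
  res <- list(config = config)
  tryCatch({
    if (!is.null(config$synthetic)) {
      stage <- "simulate"
      sim <- generate_torsion_ensemble(config$synthetic)
      trajectories <- sim$trajectories
      res$ground_truth <- sim$ground_truth
    }
    if (is.null(trajectories) || length(trajectories) == 0) {
      stop("no input trajectories")
    }
    frame_dt <- trajectories[[1]]$frame_dt
    lag_frames <- max(1L, as.integer(round(config$lag_ns / frame_dt)))
    min_len <- min(vapply(trajectories, function(t) nrow(t$angles), integer(1)))
    if (lag_frames >= min_len) {
      stop(sprintf("msm stage: lag (%d frames) is not shorter than the shortest trajectory (%d frames)",
                   lag_frames, min_len))
    }

    stage <- "featurize"
    feats <- lapply(trajectories, featurize)

    stage <- "tica"
    res$tica <- estimate_tica(feats, lag = lag_frames,
                              n_components = max(2, config$tica_dim))
    res$projection <- tica_project(res$tica, feats)

    stage <- "msm"
    res$micro <- kmeans_discretize(res$projection, k = min(config$k, nrow(res$projection$coords)),
                                   seed = config$kmeans_seed)
    Cmat <- count_transitions(res$micro$dtrajs, lag_frames, n_states = res$micro$k)
    res$msm <- estimate_reversible_T(Cmat, frame_dt = frame_dt)
    res$implied_timescales_ns <- suppressWarnings(
      implied_timescales(res$msm, min(10, nrow(res$msm$T) - 1)))
    res$ck <- tryCatch(ck_test(res$micro$dtrajs, res$msm, factors = config$ck_factors),
                       warning = function(w) suppressWarnings(
                         ck_test(res$micro$dtrajs, res$msm, factors = config$ck_factors)))

    stage <- "pcca"
    n_macro <- if (identical(config$n_macro, "auto")) {
      choose_n_macro(res$msm)
    } else config$n_macro
    res$macro <- pcca_plus(res$msm, n_macro)
    res$macro_table <- macrostate_statistics(res$macro, res$msm, res$micro,
                                             res$projection)
    # re-run CK aggregated over macrostates (the standard validation view)
    res$ck_macro <- tryCatch(
      ck_test(res$micro$dtrajs, res$msm, factors = config$ck_factors,
              macro_sets = res$macro$macro_sets),
      error = function(e) NULL)

    stage <- "landscape"
    w <- if (config$reweight) {
      stationary_frame_weights(res$msm, res$micro, res$projection)
    } else NULL
    res$fes <- free_energy_surface(res$projection, weights = w,
                                   bins = config$bins,
                                   temperature = config$temperature)

    if (!is.null(references)) {
      stage <- "grouping"
      res$ref_coords <- project_references(references, res$tica)
      res$grouping <- assign_references_to_kinetics(res$ref_coords, res$micro,
                                                    res$macro, res$fes)
      res$nn_report <- nearest_neighbor_report(references, trajectories)
    }

    stage <- "report"
    res$summary <- list(
      n_trajectories = length(trajectories),
      n_frames = nrow(res$projection$coords),
      lag_ns = lag_frames * frame_dt,
      k_microstates = res$micro$k,
      fraction_retained = res$msm$fraction_retained,
      n_macrostates = res$macro$n_macro,
      macro_probabilities = res$macro$macro_pi,
      mfpt_ns = res$macro$mfpt_matrix,
      implied_timescales_ns = res$implied_timescales_ns,
      ck_max_deviation = if (!is.null(res$ck_macro)) res$ck_macro$max_abs_deviation
                         else res$ck$max_abs_deviation,
      kinetic_groups = if (!is.null(res$grouping)) res$grouping$groups else NULL
    )
    class(res) <- "run_report"
    if (!is.null(config$out_dir)) write_report(res, config$out_dir)
    res
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Write a machine- and human-readable run report
#'
#' Emits `report.json` (summary, macrostate table, MFPT matrix in ns,
#' implied timescales in ns, CK deviations, kinetic grouping) and
#' `report.txt` (formatted summary with units), plus the macrostate and
#' MFPT tables as CSV.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  jpath <- file.path(out_dir, "report.json")
  jsonlite::write_json(s, jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$macro_table, file.path(out_dir, "macrostates.csv"),
                   row.names = FALSE)
  M <- s$mfpt_ns
  utils::write.csv(as.data.frame(M), file.path(out_dir, "mfpt_ns.csv"),
                   row.names = FALSE)
  tpath <- file.path(out_dir, "report.txt")
  con <- file(tpath, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("loop kinetics run report")
  w("  trajectories: %d (%d frames total)", s$n_trajectories, s$n_frames)
  w("  lag time: %.4g ns; microstates: %d; counts retained: %.1f%%",
    s$lag_ns, s$k_microstates, 100 * s$fraction_retained)
  w("  macrostates: %d", s$n_macrostates)
  for (m in seq_along(s$macro_probabilities)) {
    w("    state %d: probability %.3f", m, s$macro_probabilities[m])
  }
  w("  implied timescales (ns): %s",
    paste(sprintf("%.4g", s$implied_timescales_ns), collapse = ", "))
  if (length(s$ck_max_deviation) > 0) {
    w("  Chapman-Kolmogorov max deviation: %s",
      paste(sprintf("%.4f", s$ck_max_deviation), collapse = ", "))
  }
  if (!is.null(s$kinetic_groups)) {
    w("  kinetic grouping of reference conformations:")
    for (g in seq_along(s$kinetic_groups)) {
      w("    minimum %s: %s", names(s$kinetic_groups)[g],
        paste(s$kinetic_groups[[g]], collapse = ", "))
    }
  }
  invisible(c(jpath, tpath))
}
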