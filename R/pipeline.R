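#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis with explicit
#' seeds. Defaults reproduce the analysis settings: Dunnett-style
#' responsiveness at alpha 0.01, 4th-order 81-point Savitzky-Golay
#' baseline, 500 ms lag cutoff, 50-graph ER ensembles, 5-fold LASSO CV.
#'
#' @param n_neurons,n_blocks,frame_rate_hz synthetic recording geometry
#'   (used when the simulate stage is enabled).
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param stages character vector of stages to run, in pipeline order.
#' @param sim named list of [sim_config()] overrides.
#' @param alpha_responsive,alpha_tuning,n_perm,n_restarts tuning-stage
#'   parameters.
#' @param sg_order,sg_window baseline-stage parameters.
#' @param lag_cutoff_s,max_lag_s,weight_floor,frame_filter graph-stage
#'   parameters.
#' @param er_graphs motif-stage ER ensemble size.
#' @param n_folds LASSO cross-validation folds.
#' @param run_lasso,run_crossval heavier reconstruction benchmarks on/off.
#' @param lasso_neurons optional neuron subset for the LASSO benchmark.
#' @param out_dir optional output directory for delimited/JSON artifacts.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_neurons = 100, n_blocks = 8,
                            frame_rate_hz = 30, seed = 1,
                            stages = c("simulate", "preprocess", "tune",
                                       "graph", "motifs", "reconstruct",
                                       "report"),
                            sim = list(),
                            alpha_responsive = 0.01, alpha_tuning = 0.05,
                            n_perm = 1000, n_restarts = 20,
                            sg_order = 4, sg_window = 81,
                            lag_cutoff_s = 0.5, max_lag_s = 1.5,
                            weight_floor = 0, frame_filter = "all",
                            er_graphs = 50, n_folds = 5,
                            run_lasso = FALSE, run_crossval = FALSE,
                            lasso_neurons = NULL, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]  # paths are not content
  rlang::hash(cfg[order(names(cfg))])
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, tune,
#' graph, motifs, reconstruct, report) with the seeds in the
#' configuration; reruns with the same configuration produce identical
#' outputs. When `out_dir` is set, edge lists, per-neuron tables and a
#' JSON report carrying the configuration hash are written there.
#'
#' @param config a [pipeline_config()].
#' @param recording optional `ca_recording` input; required when the
#'   simulate stage is disabled.
#' @return a report list with the intermediate objects, stage timings, and
#'   `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), recording = NULL) {
  hash <- config_hash(config)
  res <- list(config = config, config_hash = hash)
  timings <- list()
  on_stage <- function(s) s %in% config$stages
  tic <- function() Sys.time()
  took <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))
  log_stage <- function(s, secs, what = "") {
    message(sprintf("[peernet %s] %-11s %6.1fs %s", hash, s, secs, what))
  }

  if (on_stage("simulate")) {
    t0 <- tic()
    schedule <- make_schedule(config$n_blocks,
                              frame_rate_hz = config$frame_rate_hz,
                              seed = config$seed)
    cfg <- do.call(sim_config,
                   c(list(n_neurons = config$n_neurons), config$sim))
    sim <- simulate_population(cfg, schedule, seed = config$seed + 1)
    recording <- sim$recording
    res$ground_truth <- sim$ground_truth
    timings$simulate <- took(t0)
    log_stage("simulate", timings$simulate,
              sprintf("%d neurons x %d frames", config$n_neurons,
                      schedule$n_frames))
  }
  if (is.null(recording)) abort("no recording: enable 'simulate' or supply one")
  res$recording <- recording
  schedule <- recording$schedule

  dff <- NULL; trm <- NULL
  if (on_stage("preprocess")) {
    t0 <- tic()
    dff <- compute_dff(recording, sg_order = config$sg_order,
                       sg_window = config$sg_window)
    trm <- trial_means(dff, schedule)
    res$dff <- dff; res$trial_responses <- trm
    timings$preprocess <- took(t0)
    log_stage("preprocess", timings$preprocess)
  }

  classes <- rep("unclassified", nrow(recording$raw_f))
  if (on_stage("tune")) {
    if (is.null(trm)) abort("tune stage needs the preprocess stage")
    t0 <- tic()
    tuning <- tune_neurons(trm, alpha_responsive = config$alpha_responsive,
                           alpha_tuning = config$alpha_tuning,
                           n_perm = config$n_perm,
                           n_restarts = config$n_restarts,
                           seed = config$seed + 2)
    classes <- ifelse(tuning$tuning_class == "untuned", "untuned", "tuned")
    res$tuning <- tuning
    res$condition_correlations <- condition_correlations(
      trm, classes = classes, theta_p_deg = tuning$theta_p_deg)
    timings$tune <- took(t0)
    log_stage("tune", timings$tune,
              sprintf("%d responsive, %d tuned", sum(tuning$responsive),
                      sum(classes == "tuned")))
  }
  res$classes <- classes

  g <- NULL; xcorr <- NULL
  if (on_stage("graph")) {
    if (is.null(dff)) abort("graph stage needs the preprocess stage")
    t0 <- tic()
    pcm <- block_partial_matrix(dff, schedule,
                                frame_filter = config$frame_filter)
    xcorr <- block_correlograms(dff, schedule, config$max_lag_s)
    lags <- edge_lag(xcorr, cutoff_s = config$lag_cutoff_s)
    g <- build_graph(pcm, lags, weight_floor = config$weight_floor,
                     positions_um = dff$positions_um, classes = classes)
    res$graph <- g
    res$graph_stats <- graph_stats(g)
    timings$graph <- took(t0)
    log_stage("graph", timings$graph,
              sprintf("pair density %.2f", glance(g)$pair_density))
  }

  if (on_stage("motifs")) {
    if (is.null(g)) abort("motifs stage needs the graph stage")
    t0 <- tic()
    adj <- (g$W != 0) * 1
    res$clustering <- directed_clustering(adj)
    q <- sum(adj) / (nrow(adj) * (nrow(adj) - 1))
    res$er_null <- er_null(nrow(adj), q, n_graphs = config$er_graphs,
                           seed = config$seed + 3)
    timings$motifs <- took(t0)
    log_stage("motifs", timings$motifs, sprintf("ER p = %.3f", q))
  }

  if (on_stage("reconstruct")) {
    if (is.null(g)) abort("reconstruct stage needs the graph stage")
    t0 <- tic()
    rec <- reconstruct_population(g, dff)
    res$reconstruction <- rec
    if (!is.null(res$clustering)) {
      res$clustering_vs_ve <- clustering_vs_performance(
        res$clustering, rec$neurons$ve)
    }
    if (config$run_lasso) {
      res$lasso <- lasso_reconstruction(
        g, dff, neurons = config$lasso_neurons,
        n_folds = config$n_folds, seed = config$seed + 4)
    }
    if (config$run_crossval && schedule$n_blocks >= 3) {
      res$crossval <- crossval_reconstruction(
        dff, schedule, xcorr = xcorr,
        weight_floor = config$weight_floor,
        cutoff_s = config$lag_cutoff_s, max_lag_s = config$max_lag_s)
    }
    timings$reconstruct <- took(t0)
    log_stage("reconstruct", timings$reconstruct,
              sprintf("population VE %.3f", rec$population_ve))
  }

  res$timings <- timings
  if (on_stage("report")) res$report <- pipeline_report(res)
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

# compact numeric summary of a pipeline result
pipeline_report <- function(res) {
  rep <- list(config_hash = res$config_hash,
              n_neurons = nrow(res$recording$raw_f),
              n_frames = ncol(res$recording$raw_f))
  if (!is.null(res$tuning)) {
    rep$n_responsive <- sum(res$tuning$responsive)
    rep$n_tuned <- sum(res$classes == "tuned")
  }
  if (!is.null(res$graph)) {
    gl <- glance(res$graph)
    rep$pair_density <- gl$pair_density
    rep$zero_edge_fraction <- gl$zero_edge_fraction
    rep$bidir_fraction <- gl$bidir_fraction
  }
  if (!is.null(res$reconstruction)) {
    rep$population_ve <- res$reconstruction$population_ve
    rep$mean_neuron_ve <- mean(res$reconstruction$neurons$ve, na.rm = TRUE)
    if (!is.null(res$classes) && !is.null(res$tuning)) {
      for (cl in unique(res$classes)) {
        rep[[paste0("mean_ve_", cl)]] <-
          mean(res$reconstruction$neurons$ve[res$classes == cl], na.rm = TRUE)
      }
    }
  }
  if (!is.null(res$lasso)) rep$population_ve_lasso <- res$lasso$population_ve
  if (!is.null(res$crossval)) {
    rep$population_ve_crossval <- res$crossval$population_ve
  }
  rep
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  if (!is.null(res$graph)) wcsv(tidy(res$graph), "edges.csv")
  if (!is.null(res$graph)) {
    write_graphml(res$graph, file.path(out_dir, "graph.graphml"))
  }
  if (!is.null(res$tuning)) {
    wcsv(as_tibble(res$tuning), "tuning.csv")
  }
  if (!is.null(res$trial_responses)) {
    wcsv(tidy(res$trial_responses), "trial_responses.csv")
  }
  if (!is.null(res$reconstruction)) {
    wcsv(res$reconstruction$neurons, "reconstruction.csv")
  }
  if (!is.null(res$clustering)) wcsv(res$clustering, "clustering.csv")
  if (!is.null(res$report)) {
    jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
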