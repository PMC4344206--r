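# Run configuration and end-to-end pipeline -----------------------------

#' Build a run configuration
#'
#' A flat, human-readable configuration (serializable as YAML) for the
#' design -> simulate -> preprocess -> train -> predict -> synergy chain.
#' Defaults mirror the standard assay: 2.5 s raw reads resampled to a 1 s
#' model grid, 20 s baseline, 210 s post-dispense window, 780 s sequential
#' horizon with a second dispense at 300 s.
#'
#' @param overrides named list of fields to override.
#' @return A list of class `pas_config`.
#' @export
pas_config <- function(overrides = list()) {
  cfg <- list(
    doses = c(0.1, 1, 10),
    design = "pairwise",
    holdout_design = "trinary",
    holdout_doses = c(0.1, 1),
    dt_raw_s = 2.5, dt_model_s = 1,
    baseline_s = 20, post_dispense_s = 210,
    sequential_horizon_s = 780, second_dispense_s = 300,
    donors = 3, replicates = 2, n_per_donor = 2,
    hidden_nodes = 12, max_epochs = 300, patience = 5, val_fraction = 0.10,
    lags_s = c(1, 2, 4, 8, 16, 32, 64, 128),
    seed = 1L,
    stages = c("design", "simulate", "train", "predict", "synergy")
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  stopifnot(cfg$dt_raw_s > 0, cfg$dt_model_s > 0, cfg$baseline_s > 0,
            cfg$post_dispense_s > 0, cfg$donors >= 1, cfg$replicates >= 1)
  class(cfg) <- c("pas_config", "list")
  cfg
}

#' Read / write a configuration as YAML
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) pas_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param config a `pas_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

design_for <- function(tag, panel, doses) {
  switch(tag,
         pairwise = enumerate_pairwise(panel, dose_grid(doses)),
         trinary  = enumerate_trinary(panel, dose_grid(doses)),
         higher   = enumerate_higher_order(panel, dose_grid(doses)),
         stop("unknown design tag: ", tag))
}

#' Run the configured pipeline
#'
#' Executes the stage chain of a [pas_config()] on synthetic donors and
#' writes all artifacts (condition tables, trace matrices, ensemble
#' archive, predictions, synergy tables, metrics) plus a JSON manifest
#' into `out_dir`. Reruns with the same config and seed reproduce the
#' outputs.
#'
#' @param config a `pas_config`.
#' @param out_dir output directory (created if needed).
#' @param population donor population parameters; default
#'   [default_donor_params()].
#' @return Invisibly, a list of in-memory results (`design`, `experiments`,
#'   `ensemble`, `prediction`, `synergy`, `metrics`).
#' @export
run_pipeline <- function(config, out_dir,
                         population = default_donor_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config.yaml"))
  panel <- population$panel
  manifest <- list(seed = config$seed, stages = config$stages,
                   artifacts = character(0))
  add_artifact <- function(f) manifest$artifacts <<- c(manifest$artifacts, f)
  results <- list()
  time_s <- model_time_grid(config$baseline_s, config$post_dispense_s,
                            config$dt_model_s)

  if ("design" %in% config$stages) {
    design <- design_for(config$design, panel, config$doses)
    write_conditions(design, file.path(out_dir, "conditions.tsv"))
    add_artifact("conditions.tsv")
    results$design <- design
  }
  if ("simulate" %in% config$stages) {
    schedules <- design_schedules(results$design, panel,
                                  horizon_s = config$post_dispense_s)
    experiments <- lapply(seq_len(config$donors), function(i) {
      donor <- sample_donor(population, seed = derive_seed(config$seed, "donor", i))
      ex <- simulate_experiment(donor, schedules, time_s,
                                replicates = config$replicates,
                                seed = derive_seed(config$seed, "noise", i),
                                donor_id = sprintf("D%02d", i),
                                design_tag = config$design,
                                design = results$design)
      average_experiment(ex)
    })
    for (ex in experiments) {
      f <- sprintf("traces_%s.csv", ex$donor_id)
      write_traces(ex, file.path(out_dir, f)); add_artifact(f)
    }
    results$experiments <- experiments
  }
  if ("train" %in% config$stages) {
    spec <- nn_spec(n_inputs = nrow(panel), lags_s = config$lags_s,
                    hidden_nodes = config$hidden_nodes,
                    max_epochs = config$max_epochs,
                    patience = config$patience,
                    val_fraction = config$val_fraction,
                    dt_s = config$dt_model_s)
    ensemble <- train_ensemble(results$experiments, config$n_per_donor,
                               base_seed = config$seed, spec = spec)
    write_ensemble(ensemble, file.path(out_dir, "ensemble"))
    add_artifact("ensemble/manifest.tsv")
    results$ensemble <- ensemble
  }
  if ("predict" %in% config$stages) {
    holdout <- design_for(config$holdout_design, panel, config$holdout_doses)
    schedules <- design_schedules(holdout, panel,
                                  horizon_s = config$post_dispense_s)
    pred <- predict_ensemble(results$ensemble, schedules, time_s)
    pred_exp <- pas_experiment("ensemble", config$holdout_design, holdout,
                               schedules, time_s, pred$mean)
    write_traces(pred_exp, file.path(out_dir, "predictions.csv"))
    add_artifact("predictions.csv")
    results$holdout <- holdout
    results$prediction <- pred
    results$prediction_experiment <- pred_exp
  }
  if ("synergy" %in% config$stages) {
    syn <- synergy_vector(results$prediction_experiment)
    write_synergy(syn, file.path(out_dir, "synergy.tsv"))
    add_artifact("synergy.tsv")
    results$synergy <- syn
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
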