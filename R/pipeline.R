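#' End-to-end pipeline
#'
#' Runs the full study on a synthetic world: generate the benchmark, train
#' the PoE-VAE and the diagnostic model, train the inquiry agent with PPO,
#' then evaluate the trained agent solo, a random-legal-action agent at the
#' same budget, the physician-agent collaboration, and full-information
#' references. Every stage's seed is derived deterministically from one
#' root seed (fixed offsets), so a run is reproducible from its manifest.
#'
#' @name pipeline
NULL

derive_seed <- function(root, offset) as.integer((as.numeric(root) + offset) %% 2147483647)

#' Run the complete pipeline on a synthetic world
#'
#' @param world_cfg a [world_config()] (its `seed` is overridden by
#'   `seed`).
#' @param n_records benchmark size.
#' @param reward_cfg a [reward_config()]; presets via [reward_preset()].
#' @param ppo_cfg a [ppo_config()] (its `seed` is overridden).
#' @param net architecture widths: list with `d_z`, `d_e`, `hidden`
#'   (VAE), `d_hidden` (diagnosis), `head_hidden`, `critic_hidden`.
#' @param vae_epochs,d_epochs training lengths for the pretrained parts.
#' @param seed root seed.
#' @param n_boot bootstrap replicates for the reports.
#' @param out optional directory for artifacts (manifest + report JSON).
#' @param verbose print stage progress.
#' @return list with `world`, `splits`, `vae`, `D`, `baseline`, `train`
#'   (agent training result), `reports` (solo/random/collaboration/
#'   full-information), `manifest`.
#' @export
run_pipeline <- function(world_cfg = world_config(), n_records = 2000L,
                         reward_cfg = reward_config(n_t_max = 8L),
                         ppo_cfg = ppo_config(epochs = 300L,
                                              episodes_per_epoch = 96L),
                         net = list(d_z = 16L, d_e = 16L, hidden = 32L,
                                    d_hidden = 64L, head_hidden = 32L,
                                    critic_hidden = 32L),
                         vae_epochs = 10L, d_epochs = 25L,
                         seed = 1L, n_boot = 200L, out = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  world_cfg$seed <- derive_seed(seed, 0L)

  say("generate: world + %d records", n_records)
  bench <- make_benchmark(world_cfg, n_records)
  world <- bench$world
  cat_ <- world$catalog
  splits <- bench$splits
  n_classes <- nrow(world$labels)

  say("train-vae")
  vae <- train_vae(splits$train, cat_, d_z = net$d_z, d_e = net$d_e,
                   hidden = net$hidden, epochs = vae_epochs,
                   seed = derive_seed(seed, 10L))

  say("train-diagnosis")
  D <- train_diagnosis_model(splits$train, cat_, n_classes,
                             hidden = net$d_hidden, epochs = d_epochs,
                             val_records = splits$validation,
                             seed = derive_seed(seed, 20L))
  baseline <- train_physician_baseline(splits$train, splits$validation,
                                       cat_, n_classes,
                                       seed = derive_seed(seed, 25L))

  say("train-agent (%d epochs x %d episodes)", ppo_cfg$epochs,
      ppo_cfg$episodes_per_epoch)
  ppo_cfg$seed <- derive_seed(seed, 30L)
  trained <- train_agent(splits$train, cat_, D, vae, n_classes, reward_cfg,
                         ppo_cfg, head_hidden = net$head_hidden,
                         critic_hidden = net$critic_hidden, verbose = verbose)

  say("evaluate")
  reports <- evaluate_pipeline(trained$agent, trained$D, baseline, world,
                               splits$test, reward_cfg,
                               seed = derive_seed(seed, 40L), n_boot = n_boot)

  manifest <- list(
    root_seed = seed, n_records = n_records,
    world_cfg = unclass(world_cfg), reward_cfg = unclass(reward_cfg),
    ppo_cfg = unclass(ppo_cfg), net = net,
    stage_seeds = list(world = world_cfg$seed, vae = derive_seed(seed, 10L),
                       diagnosis = derive_seed(seed, 20L),
                       baseline = derive_seed(seed, 25L),
                       agent = derive_seed(seed, 30L),
                       evaluate = derive_seed(seed, 40L)),
    baseline_family = baseline$family)
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(report_summary(reports), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(world = world, splits = splits, vae = vae, D = trained$D,
       baseline = baseline, train = trained, reports = reports,
       manifest = manifest)
}

#' Evaluate a trained agent against references on test records
#'
#' @param agent,D trained agent and (fine-tuned) diagnostic model.
#' @param baseline the physician-baseline classifier (or NULL).
#' @param world the `SyntheticWorld`; `test_records` held-out records.
#' @param reward_cfg budget/reward settings used at evaluation.
#' @param seed evaluation seed; `n_boot` bootstrap replicates.
#' @return list of `EvaluationReport`s: `solo`, `random`, `collaboration`,
#'   plus `full_info` (AUROC of D and of the baseline on complete
#'   observations).
#' @export
evaluate_pipeline <- function(agent, D, baseline, world, test_records,
                              reward_cfg, seed = 1L, n_boot = 200L) {
  cat_ <- world$catalog
  n_classes <- nrow(world$labels)
  layout <- state_layout(cat_)

  set.seed(seed)
  solo <- collect_rollouts(agent, D, test_records, cat_, reward_cfg,
                           deterministic = TRUE, collect_transitions = FALSE)
  solo_rep <- evaluation_report(solo$traces, test_records, cat_, world$labels,
                                n_classes, n_boot = n_boot, seed = seed)

  set.seed(seed + 1L)
  rand_traces <- lapply(seq_along(test_records), function(i) {
    ro <- random_rollout(test_records[[i]], cat_, reward_cfg$n_t_max)
    term <- encode_state(ro$state$observations, ro$state$demo, cat_, layout)
    p <- predict_proba(D, term)[1, ]
    structure(list(record = i, steps = ro$steps, asked = ro$asked,
                   terminal_probs = p, predicted_class = which.max(p),
                   forced = ro$state$forced, total_reward = NA_real_),
              class = "EpisodeTrace")
  })
  rand_rep <- evaluation_report(rand_traces, test_records, cat_, world$labels,
                                n_classes, n_boot = n_boot, seed = seed + 1L)

  collab <- collaborate_rollouts(agent, D, test_records, cat_, reward_cfg,
                                 seed = seed + 2L)
  collab_rep <- evaluation_report(collab, test_records, cat_, world$labels,
                                  n_classes, n_boot = n_boot, seed = seed + 2L)

  td <- records_design(test_records, cat_, layout)
  full_d <- macro_auroc(predict_proba(D, td$X), td$y, n_classes)
  full_base <- if (!is.null(baseline)) {
    macro_auroc(baseline$predict(td$X), td$y, n_classes)
  } else NA_real_

  list(solo = solo_rep, random = rand_rep, collaboration = collab_rep,
       full_info = list(diagnosis_model = full_d, baseline = full_base))
}

#' Flat summary of pipeline reports (for JSON export)
#' @param reports output of [evaluate_pipeline()].
#' @export
report_summary <- function(reports) {
  flat <- function(r) {
    list(auroc = r$auroc, f1 = r$f1, accuracy = r$accuracy,
         general_accuracy = r$general_accuracy,
         mean_inquiries = unname(r$inquiry[["n_inquiries"]]),
         mean_matching = unname(r$inquiry[["n_matching"]]),
         mean_physician = unname(r$inquiry[["n_physician"]]),
         mean_recalled = unname(r$inquiry[["n_recalled"]]))
  }
  list(solo = flat(reports$solo), random = flat(reports$random),
       collaboration = flat(reports$collaboration),
       full_info = reports$full_info)
}

#' Save a model object (agent, VAE or diagnosis model) to disk
#'
#' The object is self-describing: it carries its architecture, weights and
#' the hash of the catalog it was built for.
#' @param model object; `path` file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with [save_model()], checking the catalog hash
#' @param path file path; `cat` optional catalog to check against.
#' @export
load_model <- function(path, cat = NULL) {
  model <- readRDS(path)
  if (!is.null(cat) && !is.null(model$catalog_hash) &&
      !identical(model$catalog_hash, catalog_hash(cat))) {
    stop("model was built for a different catalog")
  }
  model
}
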