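# End-to-end demo pipeline: fixture -> stimuli -> lists -> responses ->
# scores -> model fit, with a manifest recording seeds and file hashes.

#' Default pipeline configuration
#'
#' Nested list with blocks `fixture`, `stimuli`, `design` and `cohort`
#' mirroring [fixture_config()], [filter_criteria()]/[similarity_bands()],
#' [design_config()] and [response_model_params()]. Any block may be
#' overridden by the YAML file given to [run_pipeline()].
#'
#' @param seed Master seed propagated to every block.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    fixture = list(n_nouns = 1000L, n_adjectives = 2000L, dim = 64L,
                   n_clusters = 30L, cluster_spread = 0.8,
                   zipf_exponent = 1.1, seed = seed),
    stimuli = list(n_triplets = 100L, n_foils = 125L, n_fillers = 100L,
                   seed = seed),
    design = list(n_participants = 40L, seed = seed),
    cohort = list(n_young = 20L, n_old = 20L, seed = seed)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Blocks missing from the file fall back to [default_pipeline_config()].
#'
#' @param path YAML file path.
#' @param seed Master seed for the defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  cfg <- default_pipeline_config(seed)
  user <- yaml::read_yaml(path)
  for (block in intersect(names(user), names(cfg))) {
    cfg[[block]] <- utils::modifyList(cfg[[block]], user[[block]])
  }
  cfg
}

#' Run the full sMST demo pipeline
#'
#' Executes, in order: synthetic fixture generation (embedding + lexicon),
#' stimulus-set construction, rotation + list generation, cohort
#' simulation, signal-detection scoring, and the probit similarity-by-age
#' fit. Every intermediate is written under `out_dir` and a
#' `manifest.json` records the configuration, seeds, per-stage outputs and
#' their MD5 hashes, so a rerun with the same seeds is byte-identical.
#' Any stage failure halts the pipeline with an error naming the stage.
#'
#' @param config Nested configuration list (see
#'   [default_pipeline_config()]) or a path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed used for any block that does not set its own.
#' @param quiet Suppress per-stage log lines (default `FALSE`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(seed), out_dir,
                         seed = 1L, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, msg) {
    if (!quiet) message(sprintf("[smst] stage=%s %s", stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline halted at stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("smst")),
                   seed = seed, config = config, stages = list())

  # 1. fixture ---------------------------------------------------------
  fx <- run_stage("fixture", {
    fc <- do.call(fixture_config, config$fixture)
    out <- generate_fixture_embedding(fc)
    write_word2vec(out$space, file.path(out_dir, "embedding.w2v.txt"))
    write_lexicon(out$lexicon, file.path(out_dir, "lexicon.tsv"))
    out
  })
  log_line("fixture", sprintf("seed=%d tokens=%d", config$fixture$seed,
                              length(embedding_tokens(fx$space))))
  manifest$stages$fixture <- list(files = c("embedding.w2v.txt", "lexicon.tsv"))

  # 2. build-stimuli ----------------------------------------------------
  stim <- run_stage("build-stimuli", {
    s <- build_stimulus_set(
      fx$lexicon, fx$space,
      n_triplets = config$stimuli$n_triplets,
      n_foils = config$stimuli$n_foils,
      n_fillers = config$stimuli$n_fillers,
      seed = config$stimuli$seed
    )
    write_stimulus_set(s, file.path(out_dir, "stimuli"))
    s
  })
  log_line("build-stimuli", sprintf("seed=%d triplets=%d foils=%d",
                                    config$stimuli$seed, nrow(stim$triplets),
                                    nrow(stim$foils)))
  manifest$stages$`build-stimuli` <- list(
    files = file.path("stimuli", c("triplets.tsv", "foils.tsv", "fillers.tsv"))
  )

  # 3. make-lists -------------------------------------------------------
  schedules <- run_stage("make-lists", {
    dc <- do.call(design_config, config$design)
    plan <- make_rotation_plan(dc, stim)
    sch <- generate_all_schedules(plan, stim)
    write_schedules(sch, file.path(out_dir, "lists.csv"))
    sch
  })
  log_line("make-lists", sprintf("participants=%d", length(schedules)))
  manifest$stages$`make-lists` <- list(files = "lists.csv")

  # 4. simulate ---------------------------------------------------------
  responses <- run_stage("simulate", {
    n <- length(schedules)
    ny <- config$cohort$n_young %||% ceiling(n / 2)
    ages <- rep(c("young", "old"), c(ny, n - ny))
    params_fields <- setdiff(names(config$cohort), c("n_young", "n_old", "seed"))
    params <- do.call(response_model_params, config$cohort[params_fields])
    resp <- simulate_cohort(schedules, ages, params, seed = config$cohort$seed)
    write_responses(resp, file.path(out_dir, "responses.csv"))
    resp
  })
  log_line("simulate", sprintf("seed=%d trials=%d", config$cohort$seed,
                               nrow(responses)))
  manifest$stages$simulate <- list(files = "responses.csv")

  # 5. score ------------------------------------------------------------
  scores <- run_stage("score", {
    sc <- score_responses(responses)
    utils::write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE,
                     quote = FALSE)
    sc
  })
  log_line("score", sprintf("participants=%d", nrow(scores)))
  manifest$stages$score <- list(files = "scores.csv")

  # 6. fit --------------------------------------------------------------
  fit <- run_stage("fit", {
    f <- fit_probit_similarity_model(responses)
    jsonlite::write_json(
      list(coefficients = as.list(f$coefficients),
           standard_errors = as.list(f$standard_errors),
           exp_estimates = as.list(f$exp_estimates),
           ci95 = list(lower = as.list(f$ci95[, "lower"]),
                       upper = as.list(f$ci95[, "upper"])),
           n_obs = f$n_obs, converged = f$converged,
           iterations = f$iterations),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA
    )
    f
  })
  log_line("fit", sprintf("n_obs=%d converged=%s", fit$n_obs, fit$converged))
  manifest$stages$fit <- list(files = "fit.json")

  # manifest with hashes ------------------------------------------------
  for (stage in names(manifest$stages)) {
    files <- manifest$stages[[stage]]$files
    files <- files[file.exists(file.path(out_dir, files))]
    hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(hashes) <- files
    manifest$stages[[stage]] <- list(files = files, md5 = hashes)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
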