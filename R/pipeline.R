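# End-to-end pipeline: schedule -> simulated cohort -> scoring ->
# SWAN factors -> correlation report, with a checksummed manifest.

#' Pipeline configuration
#'
#' Collects everything one reproducible run needs: the schedule design,
#' cohort size, simulator parameters, scoring thresholds, correlation
#' method, seed and output directory. The output directory must be
#' supplied up front; a missing one is a validation error raised before
#' any work happens.
#'
#' @param out_dir Directory the run writes into (created if absent).
#' @param n_participants Cohort size (default 30).
#' @param design Schedule preset, `"revised-60"` or `"legacy-360"`.
#' @param seed Integer master seed recorded in every output.
#' @param method Correlation method, `"pearson"` or `"spearman"`.
#' @param sim A [sim_config()].
#' @param onset An [onset_params()].
#' @param classify A [class_params()].
#' @param trait_dist A [trait_distribution()].
#' @return A list of class `cpt_run_config`.
#' @export
pipeline_config <- function(out_dir, n_participants = 30, design = "revised-60",
                            seed = 1L, method = "pearson",
                            sim = sim_config(seed = seed),
                            onset = onset_params(),
                            classify = class_params(),
                            trait_dist = trait_distribution()) {
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir)) {
    cpt_abort("`out_dir` must be supplied before a run can start.", "cpt_invalid_config")
  }
  if (!is_scalar_number(n_participants) || n_participants < 1) {
    cpt_abort("`n_participants` must be a positive count.", "cpt_invalid_config")
  }
  structure(
    list(
      out_dir = out_dir, n_participants = as.integer(n_participants),
      design = design, seed = as.integer(seed), method = method,
      sim = sim, onset = onset, classify = classify,
      trait_dist = trait_dist
    ),
    class = "cpt_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `sim`,
#' `onset`, `classify` and `trait_dist` may be nested mappings whose
#' entries override the corresponding defaults.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `cpt_run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  raw <- yaml::read_yaml(path)
  seed <- as.integer(raw$seed %||% 1L)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  sim_args <- raw$sim %||% list()
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  pipeline_config(
    out_dir = out_dir %||% raw$out_dir,
    n_participants = raw$n_participants %||% 30,
    design = raw$design %||% "revised-60",
    seed = seed,
    method = raw$method %||% "pearson",
    sim = build(sim_config, sim_args),
    onset = build(onset_params, raw$onset),
    classify = build(class_params, raw$classify),
    trait_dist = build(trait_distribution, raw$trait_dist)
  )
}

config_hash <- function(config) {
  # the hash identifies the run's parameters, not where it was written
  plain <- unclass(config)
  plain$out_dir <- NULL
  plain <- rapply(plain, function(x) x, how = "replace")
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = I(10), force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes schedule generation, cohort simulation, per-participant
#' scoring, SWAN factor scoring and the correlation report, writing
#' every artifact under `config$out_dir` and recording each file's MD5
#' checksum in `manifest.json`. Identical configuration and seed
#' reproduce byte-identical artifacts and therefore identical manifest
#' checksums. On a stage failure the manifest still records the
#' completed stages together with the failing stage's error message.
#'
#' @param config A `cpt_run_config` from [pipeline_config()] or
#'   [read_run_config()].
#' @return The manifest, invisibly: a list with the run metadata,
#'   completed `stages`, per-file `artifacts` (path + md5) and `error`
#'   (`NULL` on success).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "cpt_run_config")) {
    cpt_abort("`config` must come from pipeline_config().", "cpt_invalid_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "trajectories"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "trial_results"), showWarnings = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("kinectcpt")),
    seed = config$seed,
    config_md5 = config_hash(config),
    stages = character(0),
    artifacts = list(),
    error = NULL
  )
  add_artifact <- function(path) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <<- list(
      path = sub(paste0("^", config$out_dir, "/?"), "", path),
      md5 = unname(tools::md5sum(path))
    )
  }
  finish_stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
  }
  write_manifest <- function() {
    json <- jsonlite::toJSON(manifest,
      auto_unbox = TRUE, digits = I(10),
      pretty = TRUE, null = "null"
    )
    writeLines(json, file.path(config$out_dir, "manifest.json"))
  }

  result <- tryCatch(
    {
      sched <- cpt_schedule(config$design, seed = config$seed)
      write_schedule(sched, file.path(config$out_dir, "schedule.json"))
      add_artifact(file.path(config$out_dir, "schedule.json"))
      finish_stage("schedule")

      local_cpt_seed(config$seed + 1L)
      part_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)

      summaries <- vector("list", config$n_participants)
      swans <- vector("list", config$n_participants)
      traits_log <- vector("list", config$n_participants)
      for (i in seq_len(config$n_participants)) {
        tr <- trait_profile(
          draw_trait(config$trait_dist$mean[1], config$trait_dist$sd[1]),
          draw_trait(config$trait_dist$mean[2], config$trait_dist$sd[2]),
          draw_trait(config$trait_dist$mean[3], config$trait_dist$sd[3])
        )
        sim <- simulate_participant(sched, tr, config$sim, seed = part_seeds[i])
        pid <- sprintf("P%03d", i)

        traj_path <- file.path(config$out_dir, "trajectories", paste0(pid, ".csv"))
        write_trajectory(sim$trajectory, traj_path)
        add_artifact(traj_path)

        res <- score_session(sim$trajectory, sched,
          onset = config$onset, classify = config$classify
        )
        res_path <- file.path(config$out_dir, "trial_results", paste0(pid, ".csv"))
        readr::write_csv(tibble::as_tibble(res), res_path, progress = FALSE)
        add_artifact(res_path)

        summaries[[i]] <- dplyr::bind_cols(
          tibble::tibble(participant_id = pid),
          tibble::as_tibble(summarize_participant(res))
        )
        swans[[i]] <- dplyr::bind_cols(
          tibble::tibble(participant_id = pid), sim$swan
        )
        traits_log[[i]] <- dplyr::bind_cols(
          tibble::tibble(participant_id = pid), tibble::as_tibble(tr)
        )
      }
      finish_stage("simulate")

      summaries <- dplyr::bind_rows(summaries)
      swan_items <- dplyr::bind_rows(swans)
      traits_df <- dplyr::bind_rows(traits_log)

      for (nm in c("summaries", "swan", "traits")) {
        df <- switch(nm,
          summaries = summaries, swan = swan_items, traits = traits_df
        )
        p <- file.path(config$out_dir, paste0(nm, ".csv"))
        readr::write_csv(df, p, progress = FALSE)
        add_artifact(p)
      }
      finish_stage("score")

      swan_scored <- score_swan(swan_items)
      report <- correlate_traits(summaries, swan_scored, method = config$method)
      render_report(report, "markdown", file.path(config$out_dir, "report.md"))
      render_report(report, "csv", file.path(config$out_dir, "report.csv"))
      render_report(report, "json", file.path(config$out_dir, "report.json"))
      for (f in c("report.md", "report.csv", "report.json")) {
        add_artifact(file.path(config$out_dir, f))
      }
      finish_stage("correlate")
      report
    },
    error = function(e) {
      manifest$error <<- conditionMessage(e)
      NULL
    }
  )

  write_manifest()
  manifest$report <- result
  invisible(manifest)
}
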