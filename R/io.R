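trial_table_columns <- function() {
  c("participant_id", "study_arm", "environment", "harshness",
    "block_position", "trial", "choice", "reward", "tube_after",
    "rain_triggered", "schedule_set_id")
}

#' Validate a canonical trial table
#'
#' Checks the exact column set, closed label vocabularies, value ranges,
#' uniqueness of (participant, block, trial), and block completeness
#' (contiguous trials 1..`n_trials` in every block). Violations are reported
#' with the offending rows or trials.
#'
#' @param table data.frame to validate.
#' @param n_trials required trials per block.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_trial_table <- function(table, n_trials = 75L) {
  need <- trial_table_columns()
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    stop("trial table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!table$study_arm %in% c("none", "monetary"))
  if (length(bad)) stop("out-of-vocabulary study_arm at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!table$environment %in% c("stable", "variable"))
  if (length(bad)) stop("out-of-vocabulary environment at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!table$harshness %in% c("not_harsh", "harsh"))
  if (length(bad)) stop("out-of-vocabulary harshness at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!table$choice %in% 1:4)
  if (length(bad)) stop("choice outside 1..4 at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(table$reward < 1 | table$reward > 100)
  if (length(bad)) stop("reward outside [1, 100] at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!table$block_position %in% 1:4)
  if (length(bad)) stop("block_position outside 1..4 at rows: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(table$participant_id, table$block_position, table$trial)
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate (participant, block, trial) keys at rows: ",
                        paste(utils::head(dup, 5), collapse = ", "))
  for (g in split(table, interaction(table$participant_id,
                                     table$block_position, drop = TRUE))) {
    have <- sort(g$trial)
    want <- seq_len(n_trials)
    if (!identical(as.integer(have), as.integer(want))) {
      gap <- setdiff(want, have)
      stop(sprintf(
        "incomplete block for participant %s, block %s: missing trial(s) %s",
        g$participant_id[1], g$block_position[1],
        paste(utils::head(gap, 5), collapse = ", ")))
    }
  }
  invisible(table)
}

#' Read / write the canonical trial table CSV
#'
#' UTF-8 CSV with the exact canonical header; round-trips losslessly and is
#' validated on both ends.
#'
#' @param table canonical trial table.
#' @param path CSV file path.
#' @param n_trials required trials per block.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns the validated data.frame.
#' @export
write_trial_table <- function(table, path, n_trials = 75L) {
  validate_trial_table(table, n_trials)
  utils::write.csv(table[, trial_table_columns()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path, n_trials = 75L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("rain_triggered" %in% names(df)) {
    df$rain_triggered <- as.logical(df$rain_triggered)
  }
  validate_trial_table(df, n_trials)
  df
}

#' Run the end-to-end pipeline
#'
#' Schedules -> synthetic cohort (+ stress ratings) -> switching ladder with
#' WAIC and posterior contrasts -> hierarchical RL fit with recovery report
#' -> outcome statistics. Every stage derives its own named substream from
#' the root seed and logs what it did; outputs land in a deterministic
#' layout under `out_dir`. A failing stage stops the pipeline with the stage
#' name while files from completed stages remain on disk.
#'
#' @param config named list (or path to a JSON file) with any of:
#'   `n_agents` (default 100), `incentive` ("none"/"monetary"),
#'   `n_schedule_sets` (5), `ladder` (model ids, default the 1.x ladder),
#'   `n_draws` (posterior draws, default 1000), `fit_rl` (logical, default
#'   TRUE), `stress_effect` (latent SD, default 2.19).
#' @param seed root seed.
#' @param out_dir output directory (created if needed).
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = tempfile("bj_run_")) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(n_agents = 100L, incentive = "none", n_schedule_sets = 5L,
         ladder = c("1.0", "1.1", "1.2", "1.3"), n_draws = 1000L,
         fit_rl = TRUE, stress_effect = 2.19),
    config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                                append = TRUE)
  stage <- function(name, expr) {
    log_line("[%s] stage %s: seed substream %d", format(Sys.time()), name,
             substream_seed(seed, name))
    tryCatch(expr, error = function(e) {
      log_line("[%s] stage %s FAILED: %s", format(Sys.time()), name,
               conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()

  results$schedules <- stage("schedules", {
    sets <- generate_study_sets(cfg$n_schedule_sets,
                                seed = substream_seed(seed, "schedules"))
    write_schedules(sets, file.path(out_dir, "schedules.csv"))
    sets
  })

  results$cohort <- stage("cohort", {
    ccfg <- cohort_config(n_agents = cfg$n_agents, incentive = cfg$incentive,
                          n_schedule_sets = cfg$n_schedule_sets,
                          stress_effect = cfg$stress_effect)
    cohort <- simulate_cohort(ccfg, seed = seed,
                              schedule_sets = results$schedules)
    write_trial_table(cohort$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(cohort$params, file.path(out_dir, "agent_params.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$ratings, file.path(out_dir, "stress_ratings.csv"),
                     row.names = FALSE)
    cohort
  })

  results$switching <- stage("switching", {
    records <- code_switches(results$cohort$trials)
    fits <- lapply(cfg$ladder, function(id) {
      fit_switch_model(records, id, n_draws = cfg$n_draws,
                       seed = substream_seed(seed, paste0("switch", id)))
    })
    names(fits) <- cfg$ladder
    wt <- waic_table(fits)
    best <- fits[[attr(wt, "best_model")]]
    contrasts <- list(
      variable_elective = posterior_switch_contrast(
        best, list(V = 1, H = 0), list(V = 1, H = 1), "elective",
        label = "Variable: NotHarsh - Harsh, elective"),
      variable_responsive = posterior_switch_contrast(
        best, list(V = 1, H = 0), list(V = 1, H = 1), "responsive",
        label = "Variable: NotHarsh - Harsh, responsive"),
      stable_elective = posterior_switch_contrast(
        best, list(V = 0, H = 0), list(V = 0, H = 1), "elective",
        label = "Stable: NotHarsh - Harsh, elective"),
      stable_responsive = posterior_switch_contrast(
        best, list(V = 0, H = 0), list(V = 0, H = 1), "responsive",
        label = "Stable: NotHarsh - Harsh, responsive")
    )
    summary_json <- list(
      waic = as.data.frame(wt), best_model = attr(wt, "best_model"),
      contrasts = lapply(contrasts, function(ct)
        list(label = ct$label, mean = ct$mean,
             hpdi = as.numeric(ct$hpdi)))
    )
    jsonlite::write_json(summary_json,
                         file.path(out_dir, "switching_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(waic = wt, contrasts = contrasts, best = best)
  })

  if (isTRUE(cfg$fit_rl)) {
    results$rl <- stage("rl", {
      fit <- fit_rl(results$cohort$trials, n_draws = cfg$n_draws,
                    seed = substream_seed(seed, "rl"))
      rec <- recovery_report(results$cohort$params, fit,
                             file = file.path(out_dir, "recovery"))
      jsonlite::write_json(
        list(population = summary(fit), recovery = rec$summary),
        file.path(out_dir, "rl_summary.json"), auto_unbox = TRUE, digits = NA)
      list(fit = fit, recovery = rec)
    })
  }

  results$outcomes <- stage("outcomes", {
    oc <- optimal_choice_summary(results$cohort$trials, results$schedules,
                                 n_draws = cfg$n_draws,
                                 seed = substream_seed(seed, "optimal"))
    st <- score_trend(results$cohort$trials,
                      seed = substream_seed(seed, "trend"))
    se <- stress_effect(results$cohort$ratings,
                        seed = substream_seed(seed, "stress_fit"))
    jsonlite::write_json(
      list(optimal_choice = oc, score_trend = st,
           stress = list(effect = se$effect,
                         interval = as.numeric(se$interval),
                         tally = as.list(se$tally))),
      file.path(out_dir, "outcomes_summary.json"), auto_unbox = TRUE,
      digits = NA)
    list(optimal_choice = oc, score_trend = st, stress = se)
  })

  log_line("[%s] pipeline complete", format(Sys.time()))
  invisible(results)
}
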