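stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline aborted at stage `", stage, "`: ",
                 conditionMessage(e)))
  })
}

#' Run the full burden pipeline
#'
#' Executes the five estimation steps in order: (1) malnutrition
#' prevalence within each disease from the examination survey, (2)
#' disease prevalence from the declared survey per disease, (3) state
#' population table, (4) cost parameters, (5) the attributable-cost
#' equation over states x diseases x cells; optionally followed by the
#' probabilistic sensitivity analysis. Inputs can be file paths (read via
#' the package readers) or already-loaded tibbles. Per-step row counts
#' and pooling events are logged with `message()`; the first failing
#' stage aborts with a stage-named error. When `out_dir` is given, the
#' burden tables and a run manifest are written there.
#'
#' @param exam,interview Survey tables or CSV paths.
#' @param population Population table or CSV path.
#' @param costs `dam_cost_params` or YAML path.
#' @param states Optional state subset.
#' @param psa `NULL` for a deterministic run, or a list of arguments for
#'   [run_psa()] (e.g. `list(n_reps = 1000, seed = 7)`).
#' @param out_dir Optional output directory.
#' @param min_cell_n,exclude_children Passed to [estimate_pmn()].
#' @param seed Seed recorded in the manifest and used as the PSA default.
#' @param quiet Suppress progress messages.
#' @return A `dam_burden`, or a `dam_psa` when `psa` is given.
#' @export
dam_pipeline <- function(exam, interview, population, costs,
                         states = NULL, psa = NULL, out_dir = NULL,
                         min_cell_n = 10, exclude_children = FALSE,
                         seed = 1L, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  input_paths <- character()
  grab <- function(x, reader, nm) {
    if (is.character(x)) {
      input_paths[[nm]] <<- x
      reader(x)
    } else x
  }
  exam_t <- stage_try("1-malnutrition-prevalence",
                      grab(exam, \(p) read_survey_table(p, "examination"), "exam"))
  pmn <- stage_try("1-malnutrition-prevalence",
                   estimate_pmn(exam_t, min_cell_n = min_cell_n,
                                exclude_children = exclude_children))
  say("step 1: PMN estimated from ", nrow(exam_t), " examination records; ",
      sum(pmn$pooling != "none"), " of ", nrow(pmn), " entries pooled; ",
      sum(pmn$empty), " flagged empty")

  interview_t <- stage_try("2-disease-prevalence",
                           grab(interview, \(p) read_survey_table(p, "interview"),
                                "interview"))
  rho <- stage_try("2-disease-prevalence",
                   estimate_rho(interview_t, exam_t))
  say("step 2: disease prevalence from ", nrow(interview_t),
      " interview + ", nrow(exam_t), " examination records; ",
      sum(rho$empty), " empty cells")

  pop <- stage_try("3-state-population",
                   grab(population, read_population_table, "population"))
  say("step 3: population table covers ", dplyr::n_distinct(pop$state), " states")

  cp <- stage_try("4-cost-parameters", grab(costs, read_cost_config, "costs"))
  say("step 4: cost parameters for ", nrow(cp$costs), " diseases; delta_mn = ",
      cp$delta_mn$value, if (cp$delta_mn$global) " (global)" else "")

  result <- stage_try("5-burden",
                      compute_burden(pmn, rho, pop, cp, states = states))
  say("step 5: burden over ", nrow(result$state), " states; national total ",
      format(round(result$national$cost_total), big.mark = ","), " USD/yr")

  if (!is.null(psa)) {
    psa_args <- utils::modifyList(
      list(exam_records = exam_t, interview_records = interview_t,
           population = pop, cost_params = cp, states = states,
           min_cell_n = min_cell_n, exclude_children = exclude_children,
           seed = seed),
      psa)
    result <- stage_try("psa", do.call(run_psa, psa_args))
    say("psa: ", result$n_used, " replicates used")
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    burden <- if (inherits(result, "dam_psa")) result$point else result
    write_burden_tables(burden, out_dir)
    write_run_manifest(out_dir, seed = seed, inputs = input_paths,
                       config = list(states = states, min_cell_n = min_cell_n,
                                     exclude_children = exclude_children,
                                     psa = psa))
  }
  result
}

#' Render report tables from a burden or PSA result
#'
#' Writes three CSVs to `out_dir`: a per-capita state ranking
#' (descending), the national per-disease decomposition, and a one-row
#' summary of the 65+ versus all-ages burden. Output is deterministic;
#' re-rendering identical inputs yields identical files.
#'
#' @param result `dam_burden` or `dam_psa`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
dam_report <- function(result, out_dir) {
  burden <- if (inherits(result, "dam_psa")) result$point else result
  stopifnot(inherits(burden, "dam_burden"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  ranking <- burden$state |>
    arrange(dplyr::desc(.data$per_capita), .data$state) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "state", "per_capita", "cost_total")
  decomposition <- burden$national_disease |>
    mutate(disease = as.character(.data$disease),
           share = .data$cost_total / sum(.data$cost_total))
  elderly <- burden$national |>
    select("cost_total", "cost_65plus", "share_65plus",
           "per_capita", "per_capita_65plus")

  paths <- c(
    ranking = file.path(out_dir, "per_capita_ranking.csv"),
    decomposition = file.path(out_dir, "disease_decomposition.csv"),
    elderly = file.path(out_dir, "elderly_share.csv")
  )
  readr::write_csv(ranking, paths[["ranking"]], progress = FALSE)
  readr::write_csv(decomposition, paths[["decomposition"]], progress = FALSE)
  readr::write_csv(elderly, paths[["elderly"]], progress = FALSE)
  invisible(paths)
}
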