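#' Cost-attributable fraction of malnutrition
#'
#' The share of a disease's direct medical spending attributable to
#' malnutrition: `PMN * dMN / (1 + PMN * dMN)`, where `PMN` is the
#' prevalence of malnutrition among patients and `dMN` the proportional
#' excess annual cost of a malnourished patient (a malnourished patient
#' costs `(1 + dMN)` times a non-malnourished one). Strictly increasing in
#' both arguments, zero iff either is zero, and always below 1.
#'
#' @param pmn Malnutrition prevalence within disease, in `[0, 1]`.
#' @param delta_mn Proportional excess cost, `>= 0`.
#' @return Fraction in `[0, 1)`.
#' @export
#' @examples
#' attributable_fraction(0.5, 1)  # 1/3: half of patients cost double
attributable_fraction <- function(pmn, delta_mn) {
  if (any(pmn < 0 | pmn > 1, na.rm = TRUE)) abort("pmn outside [0, 1]")
  if (any(delta_mn < 0, na.rm = TRUE)) abort("delta_mn must be >= 0")
  pmn * delta_mn / (1 + pmn * delta_mn)
}

#' Attributable cost of one disease x cell x state
#'
#' `C * AF(PMN, dMN) * rho * POP`: mean annual per-patient cost, times the
#' attributable fraction, times disease prevalence in the cell, times the
#' cell's population. Vectorized; equals the individual-level enumeration
#' in which each of the `rho * POP` patients costs either `c` or
#' `c * (1 + dMN)`, with `c` calibrated so the average is `C`.
#'
#' @param C Mean annual direct medical cost per patient (USD/year).
#' @param pmn,delta_mn See [attributable_fraction()].
#' @param rho Disease prevalence in the cell, in `[0, 1]`.
#' @param pop Cell population (persons, `>= 0`).
#' @return USD/year.
#' @export
cell_cost <- function(C, pmn, delta_mn, rho, pop) {
  if (any(C <= 0, na.rm = TRUE)) abort("C must be positive")
  if (any(rho < 0 | rho > 1, na.rm = TRUE)) abort("rho outside [0, 1]")
  if (any(pop < 0, na.rm = TRUE)) abort("pop must be >= 0")
  C * attributable_fraction(pmn, delta_mn) * rho * pop
}

# Accept a prevalence table from estimate_*() (column `estimate`) or a
# ground-truth table (column `pmn` / `rho`).
prev_values <- function(tbl, what) {
  tbl <- as_tibble(tbl)
  col <- intersect(c("estimate", what), names(tbl))[1]
  if (is.na(col)) abort(paste0("prevalence table needs an `estimate` or `",
                               what, "` column"))
  as_cell_cols(tbl) |>
    mutate(disease = factor(as.character(.data$disease), levels = DISEASES)) |>
    select("disease", "age_band", "sex", "race", value = dplyr::all_of(col))
}

#' Compute the state-level burden of disease-associated malnutrition
#'
#' Applies the attributable-cost equation over every state x disease x
#' demographic cell and rolls the results up: per-state and national
#' totals, per-capita costs, and the 65+ subset (costs restricted to the
#' 65+ cells, per-capita over the 65+ population). Summation order is
#' fixed (cells in canonical order within disease, diseases in reporting
#' order, states alphabetical) so results are bit-reproducible.
#'
#' @param pmn Malnutrition-within-disease prevalence per (disease, cell):
#'   output of [estimate_pmn()] or a ground-truth table with a `pmn` column.
#' @param rho Disease prevalence per (disease, cell): output of
#'   [estimate_rho()] or a table with a `rho` column.
#' @param population State population table: `state`, `age_band`, `sex`,
#'   `race`, `count`.
#' @param cost_params `dam_cost_params` from [read_cost_config()].
#' @param states States to compute, default all in `population`. A state
#'   absent from the table is an error.
#' @param costs Optional tibble (`disease`, `mean_annual_cost`) overriding
#'   `cost_params$costs` (used by the sensitivity analysis).
#' @param delta_mn Optional named vector over diseases (or scalar)
#'   overriding the config's malnutrition multiplier.
#' @return Object of class `dam_burden`: list with tibbles `cell`
#'   (state x disease x cell costs), `state_disease`, `state` (totals,
#'   per-capita, 65+ columns), `national_disease` and `national`.
#' @export
compute_burden <- function(pmn, rho, population, cost_params,
                           states = NULL, costs = NULL, delta_mn = NULL) {
  stopifnot(inherits(cost_params, "dam_cost_params"))
  pmn_t <- prev_values(pmn, "pmn") |> rename(pmn = "value")
  rho_t <- prev_values(rho, "rho") |> rename(rho = "value")
  pop <- as_cell_cols(as_tibble(population))
  if (!is.null(states)) {
    missing_states <- setdiff(states, unique(pop$state))
    if (length(missing_states))
      abort(paste0("state(s) absent from population table: ",
                   toString(missing_states)))
    pop <- filter(pop, .data$state %in% states)
  }
  if (nrow(pop) == 0) abort("no states to compute")

  cost_tbl <- if (is.null(costs)) cost_params$costs else
    as_tibble(costs) |>
      mutate(disease = factor(as.character(.data$disease), levels = DISEASES))
  dmn <- delta_mn %||% delta_mn_by_disease(cost_params)
  if (length(dmn) == 1 && is.null(names(dmn)))
    dmn <- setNames(rep(dmn, 8), DISEASES)

  grid <- pop |>
    tidyr::crossing(disease = factor(DISEASES, levels = DISEASES)) |>
    inner_join(pmn_t, by = c("disease", "age_band", "sex", "race")) |>
    inner_join(rho_t, by = c("disease", "age_band", "sex", "race")) |>
    inner_join(cost_tbl |> select("disease", "mean_annual_cost"),
               by = "disease") |>
    mutate(delta_mn = unname(dmn[as.character(.data$disease)]))

  bad <- grid |>
    filter((is.na(.data$pmn) | is.na(.data$rho)) & .data$count > 0)
  if (nrow(bad))
    abort(paste0("missing prevalence for ", nrow(bad),
                 " populated (disease, cell) entries, e.g. ",
                 bad$disease[1], " / ", bad$age_band[1], " / ",
                 bad$sex[1], " / ", bad$race[1]))

  cell <- grid |>
    mutate(
      pmn = if_else(is.na(.data$pmn), 0, .data$pmn),
      rho = if_else(is.na(.data$rho), 0, .data$rho),
      cost = cell_cost(.data$mean_annual_cost, .data$pmn, .data$delta_mn,
                       .data$rho, .data$count)
    ) |>
    arrange(.data$state, .data$disease, .data$age_band, .data$sex, .data$race) |>
    select("state", "disease", "age_band", "sex", "race",
           "count", "pmn", "rho", "mean_annual_cost", "delta_mn", "cost")

  state_disease <- cell |>
    group_by(.data$state, .data$disease) |>
    summarise(cost_total = sum(.data$cost),
              cost_65plus = sum(.data$cost[.data$age_band == "65+"]),
              .groups = "drop") |>
    arrange(.data$state, .data$disease)

  pop_sum <- pop |>
    group_by(.data$state) |>
    summarise(population = sum(.data$count),
              population_65plus = sum(.data$count[.data$age_band == "65+"]),
              .groups = "drop")

  state <- state_disease |>
    group_by(.data$state) |>
    summarise(cost_total = sum(.data$cost_total),
              cost_65plus = sum(.data$cost_65plus), .groups = "drop") |>
    left_join(pop_sum, by = "state") |>
    mutate(per_capita = .data$cost_total / .data$population,
           per_capita_65plus = .data$cost_65plus / .data$population_65plus) |>
    arrange(.data$state) |>
    select("state", "cost_total", "per_capita", "cost_65plus",
           "per_capita_65plus", "population", "population_65plus")

  national_disease <- state_disease |>
    group_by(.data$disease) |>
    summarise(cost_total = sum(.data$cost_total),
              cost_65plus = sum(.data$cost_65plus), .groups = "drop") |>
    arrange(.data$disease)

  national <- tibble(
    cost_total = sum(state$cost_total),
    cost_65plus = sum(state$cost_65plus),
    population = sum(state$population),
    population_65plus = sum(state$population_65plus)
  ) |>
    mutate(per_capita = .data$cost_total / .data$population,
           per_capita_65plus = .data$cost_65plus / .data$population_65plus,
           share_65plus = .data$cost_65plus / .data$cost_total)

  structure(list(cell = cell, state_disease = state_disease, state = state,
                 national_disease = national_disease, national = national),
            class = "dam_burden")
}

#' @export
print.dam_burden <- function(x, ...) {
  cat("Disease-associated malnutrition burden\n")
  cat("  states:", nrow(x$state), "  national total (USD/yr):",
      format(x$national$cost_total, big.mark = ","), "\n")
  cat("  per capita:", round(x$national$per_capita, 2),
      "  65+ share:", sprintf("%.1f%%", 100 * x$national$share_65plus), "\n")
  invisible(x)
}
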