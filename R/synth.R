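# Measurement bands used to realize a latent malnutrition label. They
# straddle the diagnostic thresholds (0.90 IBW, 3.5 g/dL) with a margin
# wide enough that 0.1-unit rounding of stored measurements can never flip
# a classification, so the classifier recovers the latent label exactly.
ALB_LOW  <- c(2.5, 3.4)
ALB_OK   <- c(3.6, 5.0)
FRAC_LOW <- c(0.75, 0.89)
FRAC_OK  <- c(0.95, 1.30)

HEIGHT_NORM <- list(male = c(mean = 175.7, sd = 7.4),
                    female = c(mean = 162.1, sd = 6.9))
AGE_RANGES <- list("0-18" = c(0, 18), "19-45" = c(19, 45), "46-55" = c(46, 55),
                   "56-64" = c(56, 64), "65+" = c(65, 90))

#' Construct a synthetic-world ground truth
#'
#' Bundles everything the generators need: per-cell disease prevalence
#' (`rho`), malnutrition-given-disease prevalence (`pmn`), the cell mix of
#' the sampled population, the survey design (strata, clusters, weight
#' dispersion), state population counts and cost parameters. Defaults
#' emulate plausible U.S. epidemiology: strongly age-graded chronic
#' disease prevalence (dementia reaching 12.5% at 65+), malnutrition
#' prevalence of 5-10% within disease, a two-cluster-per-stratum masked
#' design and log-normal sampling weights.
#'
#' @param rho Tibble (`disease`, `age_band`, `sex`, `race`, `rho`) or NULL
#'   for the defaults. Probabilities in `[0, 1]`.
#' @param pmn Tibble (`disease`, `age_band`, `sex`, `race`, `pmn`) or NULL.
#' @param cell_probs Tibble (`age_band`, `sex`, `race`, `prob`) summing to
#'   1, or NULL for a census-like mix.
#' @param design List: `n_strata`, `clusters_per_stratum`,
#'   `weight_log_sd` (log-normal dispersion of cluster weights),
#'   `cluster_effect_sd` (SD of a per-cluster random effect on the logit
#'   of disease prevalence; 0 disables it).
#' @param states Tibble (`state`, `age_band`, `sex`, `race`, `count`) or
#'   NULL for three synthetic states.
#' @param cost_params `dam_cost_params`, default from the bundled config.
#' @param pmn_background Malnutrition probability for persons with no
#'   study disease.
#' @return Object of class `dam_truth`.
#' @export
synth_truth <- function(rho = NULL, pmn = NULL, cell_probs = NULL,
                        design = list(), states = NULL, cost_params = NULL,
                        pmn_background = 0.05) {
  cells <- dam_cells()
  if (is.null(rho)) rho <- default_rho()
  if (is.null(pmn)) pmn <- default_pmn()
  rho <- as_cell_cols(as_tibble(rho)) |>
    mutate(disease = factor(as.character(.data$disease), levels = DISEASES))
  pmn <- as_cell_cols(as_tibble(pmn)) |>
    mutate(disease = factor(as.character(.data$disease), levels = DISEASES))
  if (nrow(rho) != 8 * 30 || anyNA(rho$disease))
    abort("rho must cover all 8 diseases x 30 cells")
  if (nrow(pmn) != 8 * 30 || anyNA(pmn$disease))
    abort("pmn must cover all 8 diseases x 30 cells")
  if (any(rho$rho < 0 | rho$rho > 1)) abort("rho outside [0, 1]")
  if (any(pmn$pmn < 0 | pmn$pmn > 1)) abort("pmn outside [0, 1]")
  if (pmn_background < 0 || pmn_background > 1) abort("pmn_background outside [0, 1]")

  if (is.null(cell_probs)) cell_probs <- default_cell_probs()
  cell_probs <- as_cell_cols(as_tibble(cell_probs))
  if (abs(sum(cell_probs$prob) - 1) > 1e-8) abort("cell_probs must sum to 1")
  if (any(cell_probs$prob < 0)) abort("cell_probs must be non-negative")

  design <- utils::modifyList(
    list(n_strata = 15L, clusters_per_stratum = 2L,
         weight_log_sd = 0.5, cluster_effect_sd = 0), design)
  if (design$n_strata < 1 || design$clusters_per_stratum < 1)
    abort("design counts must be >= 1")

  if (is.null(states)) {
    states <- synth_states(c("Alpha", "Beta", "Gamma"),
                           c(4e6, 1.5e6, 8e5), cell_probs)
  }
  states <- as_cell_cols(as_tibble(states))
  if (any(states$count < 0)) abort("state counts must be non-negative")

  if (is.null(cost_params)) cost_params <- default_cost_params()
  stopifnot(inherits(cost_params, "dam_cost_params"))

  structure(list(rho = arrange(rho, .data$disease, .data$age_band, .data$sex, .data$race),
                 pmn = arrange(pmn, .data$disease, .data$age_band, .data$sex, .data$race),
                 cell_probs = arrange(cell_probs, .data$age_band, .data$sex, .data$race),
                 design = design,
                 states = arrange(states, .data$state, .data$age_band, .data$sex, .data$race),
                 cost_params = cost_params,
                 pmn_background = pmn_background),
            class = "dam_truth")
}

#' Build state population counts from a cell mix
#'
#' @param names State identifiers.
#' @param totals Total population per state.
#' @param cell_probs Cell mix (defaults to the standard synthetic mix).
#' @return Tibble (`state`, `age_band`, `sex`, `race`, `count`).
#' @export
synth_states <- function(names, totals, cell_probs = default_cell_probs()) {
  stopifnot(length(names) == length(totals))
  purrr::map2(names, totals, function(nm, tot) {
    cell_probs |> mutate(state = nm, count = round(tot * .data$prob)) |>
      select("state", "age_band", "sex", "race", "count")
  }) |> purrr::list_rbind()
}

default_cell_probs <- function() {
  age_p <- c("0-18" = 0.24, "19-45" = 0.35, "46-55" = 0.14,
             "56-64" = 0.12, "65+" = 0.15)
  race_p <- c(white = 0.64, black = 0.13, other = 0.23)
  dam_cells() |>
    mutate(prob = unname(age_p[as.character(.data$age_band)]) * 0.5 *
             unname(race_p[as.character(.data$race)]))
}

# Age-graded prevalence per disease (rows: the five age bands). Breast
# cancer applies to females only; the male column is zeroed below.
default_rho <- function() {
  by_age <- list(
    stroke            = c(0.001, 0.005, 0.020, 0.040, 0.080),
    copd              = c(0.002, 0.010, 0.040, 0.070, 0.100),
    chf               = c(0.001, 0.003, 0.015, 0.030, 0.080),
    colorectal_cancer = c(0.0005, 0.001, 0.004, 0.010, 0.030),
    breast_cancer     = c(0.000, 0.002, 0.010, 0.020, 0.040),
    dementia          = c(0.001, 0.002, 0.010, 0.030, 0.125),
    musculoskeletal   = c(0.010, 0.040, 0.080, 0.100, 0.120),
    depression        = c(0.020, 0.060, 0.080, 0.080, 0.070)
  )
  purrr::imap(by_age, function(p, d) {
    dam_cells() |>
      mutate(disease = d, rho = p[as.integer(.data$age_band)])
  }) |>
    purrr::list_rbind() |>
    mutate(rho = if_else(.data$disease == "breast_cancer" & .data$sex == "male",
                         0, .data$rho)) |>
    select("disease", "age_band", "sex", "race", "rho")
}

default_pmn <- function() {
  base <- c(stroke = 0.08, copd = 0.07, chf = 0.09, colorectal_cancer = 0.10,
            breast_cancer = 0.06, dementia = 0.07, musculoskeletal = 0.05,
            depression = 0.06)
  purrr::imap(base, function(p, d) {
    dam_cells() |> mutate(disease = d, pmn = p)
  }) |>
    purrr::list_rbind() |>
    select("disease", "age_band", "sex", "race", "pmn")
}

default_cost_params <- function() {
  read_cost_config(system.file("extdata", "cost_parameters_synthetic.yaml",
                               package = "damcost"))
}

# Shared scaffolding: cells, ages, design labels, weights, disease flags.
synth_core <- function(truth, n, prefix) {
  cp <- truth$cell_probs
  idx <- sample.int(nrow(cp), n, replace = TRUE, prob = cp$prob)
  core <- cp[idx, c("age_band", "sex", "race")]
  rng <- purrr::map(AGE_RANGES, identity)
  lo <- vapply(rng, `[`, numeric(1), 1)[as.integer(core$age_band)]
  hi <- vapply(rng, `[`, numeric(1), 2)[as.integer(core$age_band)]
  core$age <- floor(runif(n, lo, hi + 1))

  d <- truth$design
  k <- (seq_len(n) - 1) %% (d$n_strata * d$clusters_per_stratum)
  core$stratum_id <- sprintf("S%02d", k %/% d$clusters_per_stratum + 1)
  core$cluster_id <- sprintf("%s-C%d", core$stratum_id,
                             k %% d$clusters_per_stratum + 1)
  clus <- sort(unique(core$cluster_id))
  w_clus <- setNames(100 * exp(rnorm(length(clus), 0, d$weight_log_sd)), clus)
  core$sample_weight <- round(unname(w_clus[core$cluster_id]), 3)
  core$person_id <- sprintf("%s%06d", prefix, seq_len(n))

  # disease flags: Bernoulli(rho) per disease, optional per-cluster effect
  # on the logit shared across diseases
  u_clus <- if (d$cluster_effect_sd > 0)
    setNames(rnorm(length(clus), 0, d$cluster_effect_sd), clus)
  else setNames(rep(0, length(clus)), clus)
  u <- unname(u_clus[core$cluster_id])
  rho_wide <- truth$rho |>
    tidyr::pivot_wider(names_from = "disease", values_from = "rho")
  core_join <- core |>
    left_join(rho_wide, by = c("age_band", "sex", "race"))
  for (dis in DISEASES) {
    p <- core_join[[dis]]
    p_adj <- stats::plogis(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) + u)
    p_adj[p == 0] <- 0
    core[[paste0("flag_", dis)]] <- as.logical(rbinom(n, 1, p_adj))
  }
  core
}

latent_malnutrition <- function(core, truth) {
  pmn_wide <- truth$pmn |>
    tidyr::pivot_wider(names_from = "disease", values_from = "pmn")
  pm <- core |>
    left_join(pmn_wide, by = c("age_band", "sex", "race")) |>
    select(dplyr::all_of(DISEASES)) |> as.matrix()
  fl <- core |> select(dplyr::all_of(paste0("flag_", DISEASES))) |> as.matrix()
  nd <- rowSums(fl)
  p <- ifelse(nd > 0, rowSums(pm * fl) / pmax(nd, 1), truth$pmn_background)
  as.logical(rbinom(nrow(core), 1, p))
}

#' Generate an examination-style synthetic survey
#'
#' Person-level records with demographics, disease flags, body
#' measurements and serum albumin under a stratified-cluster design.
#' Disease flags are drawn independently per disease from the ground-truth
#' cell prevalences; each diseased person's malnutrition status is drawn
#' from the cell's malnutrition-given-disease probability and then
#' realized through measurements: a malnourished person receives either
#' low albumin (uniform 2.5-3.4 g/dL) or low weight (uniform 75-89% of
#' Hamwi ideal weight), each with probability 1/2; a non-malnourished
#' person receives albumin 3.6-5.0 g/dL and weight 95-130% of ideal.
#' Measurements are stored rounded to 0.1 units; the bands are disjoint
#' from the diagnostic thresholds so classification recovers the latent
#' label exactly. The latent label is returned in column
#' `latent_malnourished` for validation; the estimation pipeline never
#' reads it.
#'
#' @param truth A `dam_truth` object.
#' @param n Number of records, `>= 1`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return Tibble of examination survey records.
#' @export
generate_examination_survey <- function(truth, n, seed) {
  stopifnot(inherits(truth, "dam_truth"))
  if (n < 1) abort("n must be >= 1")
  set.seed(seed)
  core <- synth_core(truth, n, "E")
  core$latent_malnourished <- latent_malnutrition(core, truth)

  hp <- HEIGHT_NORM[as.character(core$sex)]
  height <- round(rnorm(n, purrr::map_dbl(hp, "mean"), purrr::map_dbl(hp, "sd")), 1)
  height <- pmax(height, 120)  # adult-formula floor; children share the mechanism
  ibw_kg <- hamwi_ideal_weight(as.character(core$sex), height) / LB_PER_KG

  route_albumin <- as.logical(rbinom(n, 1, 0.5))
  mal <- core$latent_malnourished
  albumin <- round(ifelse(mal & route_albumin,
                          runif(n, ALB_LOW[1], ALB_LOW[2]),
                          runif(n, ALB_OK[1], ALB_OK[2])), 1)
  frac <- ifelse(mal & !route_albumin,
                 runif(n, FRAC_LOW[1], FRAC_LOW[2]),
                 runif(n, FRAC_OK[1], FRAC_OK[2]))
  weight <- round(frac * ibw_kg, 1)

  core$height <- height
  core$weight <- weight
  core$serum_albumin <- albumin
  as_tibble(core) |>
    relocate("person_id", "age", "age_band", "sex", "race", "height",
             "weight", "serum_albumin", "sample_weight", "stratum_id",
             "cluster_id")
}

#' Generate an interview-style synthetic survey
#'
#' As [generate_examination_survey()] but without body measurements or
#' albumin: demographics, disease flags, weights and design identifiers
#' only. Interview surveys are typically larger than examination surveys.
#'
#' @inheritParams generate_examination_survey
#' @return Tibble of interview survey records.
#' @export
generate_interview_survey <- function(truth, n, seed) {
  stopifnot(inherits(truth, "dam_truth"))
  if (n < 1) abort("n must be >= 1")
  set.seed(seed)
  core <- synth_core(truth, n, "I")
  as_tibble(core) |>
    relocate("person_id", "age", "age_band", "sex", "race",
             "sample_weight", "stratum_id", "cluster_id")
}

#' Emit the state population table of a synthetic world
#'
#' Counts are fixed inputs of the ground truth, reproduced exactly with no
#' sampling noise, so the output is deterministic across seeds.
#'
#' @param truth A `dam_truth` object.
#' @return Tibble (`state`, `age_band`, `sex`, `race`, `count`).
#' @export
generate_population <- function(truth) {
  stopifnot(inherits(truth, "dam_truth"))
  if (nrow(truth$states) == 0) abort("truth has no states")
  truth$states
}

#' Serialize / restore a ground truth
#'
#' JSON round-trip of a `dam_truth` object for parameter-recovery tests
#' and run provenance.
#'
#' @param truth A `dam_truth` object.
#' @param path File path.
#' @return `write_ground_truth()` returns the path invisibly;
#'   `read_ground_truth()` returns a `dam_truth`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "dam_truth"))
  payload <- list(
    rho = truth$rho, pmn = truth$pmn, cell_probs = truth$cell_probs,
    design = truth$design, states = truth$states,
    pmn_background = truth$pmn_background,
    cost_params = list(
      costs = truth$cost_params$costs,
      delta_mn = truth$cost_params$delta_mn
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", factor = "string")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp_cfg <- list(
    diseases = split(p$cost_params$costs, p$cost_params$costs$disease) |>
      purrr::map(\(r) list(mean_annual_cost = r$mean_annual_cost,
                           distribution = r$distribution,
                           se = if (is.na(r$se)) NULL else r$se)),
    delta_mn = p$cost_params$delta_mn
  )
  synth_truth(rho = p$rho, pmn = p$pmn, cell_probs = p$cell_probs,
              design = p$design, states = p$states,
              cost_params = new_cost_params(cp_cfg),
              pmn_background = p$pmn_background)
}
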