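# Required columns per survey schema. Examination records carry body
# measurements; interview records need not.
SCHEMA_COLS <- list(
  examination = c("person_id", "age", "sex", "race", "height", "weight",
                  "serum_albumin", "sample_weight", "stratum_id", "cluster_id"),
  interview = c("person_id", "age", "sex", "race",
                "sample_weight", "stratum_id", "cluster_id")
)

#' Read survey microdata
#'
#' Reads a delimited person-level table, validates it against the
#' examination or interview schema, derives the demographic cell
#' (`age_band`, collapsed `race`) and returns a tibble of survey records.
#' Disease indicator columns are any columns named `flag_<disease>`;
#' missing flags and missing albumin stay `NA`, never silently 0.
#'
#' @param path Path to a CSV (or TSV) file with a header row.
#' @param schema `"examination"` or `"interview"`.
#' @param delim Field delimiter, `","` by default; pass `"\t"` for TSV.
#' @param race_mapping Passed to [assign_race()].
#' @return A tibble of validated survey records with factor `age_band`,
#'   `sex`, `race` columns and logical `flag_*` columns.
#' @export
read_survey_table <- function(path, schema = c("examination", "interview"),
                              delim = ",",
                              race_mapping = c(white = "white", black = "black")) {
  schema <- rlang::arg_match(schema)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  required <- SCHEMA_COLS[[schema]]
  if (schema == "interview") required <- setdiff(required, "serum_albumin")
  miss <- setdiff(required, names(df))
  if (length(miss))
    abort(paste0("schema error: missing required column(s): ", toString(miss)))
  validate_survey_records(df, schema, race_mapping)
}

validate_survey_records <- function(df, schema, race_mapping) {
  bad_w <- which(is.na(df$sample_weight) | df$sample_weight < 0)
  if (length(bad_w))
    abort(paste0("validation error: negative or missing sample_weight in row(s): ",
                 toString(head(bad_w, 20))))
  if (schema == "examination") {
    bad_h <- which(!is.na(df$height) & df$height <= 0)
    bad_m <- which(!is.na(df$weight) & df$weight <= 0)
    if (length(c(bad_h, bad_m)))
      abort(paste0("validation error: nonpositive height/weight in row(s): ",
                   toString(head(sort(unique(c(bad_h, bad_m))), 20))))
  }
  out <- as_tibble(df) |>
    mutate(
      sex = factor(tolower(as.character(.data$sex)), levels = SEXES),
      race = assign_race(.data$race, race_mapping),
      age_band = assign_age_band(.data$age)
    )
  if (anyNA(out$sex)) abort("validation error: unknown sex label")
  flags <- grep("^flag_", names(out), value = TRUE)
  out |> mutate(across(dplyr::all_of(flags), \(x) as.logical(x)))
}

#' Read a state population table
#'
#' One count per (state, age band, sex, race). Cells absent for a state
#' are zero-filled with a warning; duplicated cells are an error.
#'
#' @param path CSV with columns `state`, `age_band`, `sex`, `race`, `count`.
#' @param delim Field delimiter.
#' @return Tibble with one row per state x cell (30 rows per state).
#' @export
read_population_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("state", "age_band", "sex", "race", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("schema error: missing column(s): ", toString(miss)))
  df <- as_cell_cols(df)
  if (any(is.na(df$count) | df$count < 0)) abort("counts must be non-negative")
  dup <- df |> count(.data$state, .data$age_band, .data$sex, .data$race) |>
    filter(.data$n > 1)
  if (nrow(dup))
    abort(paste0("duplicate (state, cell) rows, e.g. ", dup$state[1], " / ",
                 dup$age_band[1], " / ", dup$sex[1], " / ", dup$race[1]))
  full <- tidyr::crossing(state = sort(unique(df$state)), dam_cells())
  out <- full |>
    left_join(df, by = c("state", "age_band", "sex", "race"))
  n_fill <- sum(is.na(out$count))
  if (n_fill > 0)
    warn(paste0(n_fill, " absent (state, cell) combination(s) zero-filled"))
  out |>
    mutate(count = if_else(is.na(.data$count), 0, as.numeric(.data$count))) |>
    arrange(.data$state, .data$age_band, .data$sex, .data$race)
}

#' Read a cost-parameter configuration
#'
#' YAML config supplying, for each of the eight diseases, the mean annual
#' direct medical cost per patient (USD/year) and its uncertainty
#' distribution (`gamma` with a standard error, or `uniform` meaning
#' +/-20% of the mean), plus the malnutrition cost multiplier `delta_mn`
#' (proportional excess annual cost of a malnourished patient) with its
#' own distribution and a `global` flag.
#'
#' @param path YAML file; see the bundled default
#'   `system.file("extdata", "cost_parameters_synthetic.yaml", package = "damcost")`.
#' @return Object of class `dam_cost_params`: list with `costs` (tibble:
#'   `disease`, `mean_annual_cost`, `distribution`, `se`) and `delta_mn`
#'   (list: `value`, `distribution`, `se`, `global`, optional per-disease
#'   `overrides`).
#' @export
read_cost_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  cfg <- yaml::read_yaml(path)
  new_cost_params(cfg)
}

new_cost_params <- function(cfg) {
  if (is.null(cfg$diseases)) abort("config needs a `diseases` block")
  miss <- setdiff(DISEASES, names(cfg$diseases))
  if (length(miss)) abort(paste0("disease(s) missing from config: ", toString(miss)))
  costs <- purrr::imap(cfg$diseases[DISEASES], function(d, nm) {
    if (is.null(d$mean_annual_cost) || d$mean_annual_cost <= 0)
      abort(paste0("mean_annual_cost must be positive for ", nm))
    dist <- d$distribution %||% "uniform"
    if (!dist %in% c("gamma", "uniform", "fixed"))
      abort(paste0("unknown distribution for ", nm, ": ", dist))
    se <- d$se %||% NA_real_
    if (dist == "gamma" && (is.na(se) || se <= 0))
      abort(paste0("gamma distribution for ", nm, " needs a positive se"))
    tibble(disease = nm, mean_annual_cost = as.numeric(d$mean_annual_cost),
           distribution = dist, se = as.numeric(se))
  }) |> purrr::list_rbind() |>
    mutate(disease = factor(.data$disease, levels = DISEASES))
  dm <- cfg$delta_mn
  if (is.null(dm) || is.null(dm$value)) abort("config needs delta_mn with a value")
  if (dm$value < 0) abort("delta_mn must be non-negative")
  delta <- list(
    value = as.numeric(dm$value),
    distribution = dm$distribution %||% "fixed",
    se = as.numeric(dm$se %||% NA_real_),
    global = isTRUE(dm$global %||% TRUE),
    overrides = dm$overrides
  )
  if (delta$distribution == "gamma" && (is.na(delta$se) || delta$se <= 0))
    abort("gamma delta_mn needs a positive se")
  structure(list(costs = costs, delta_mn = delta), class = "dam_cost_params")
}

#' Resolve the malnutrition multiplier per disease
#'
#' @param params A `dam_cost_params` object.
#' @return Named numeric vector over the eight diseases: the global
#'   `delta_mn` value, with per-disease overrides applied when the config
#'   is not global.
#' @export
delta_mn_by_disease <- function(params) {
  stopifnot(inherits(params, "dam_cost_params"))
  dm <- params$delta_mn
  out <- setNames(rep(dm$value, length(DISEASES)), DISEASES)
  if (!dm$global && !is.null(dm$overrides)) {
    ov <- unlist(dm$overrides)
    out[names(ov)] <- as.numeric(ov)
  }
  out
}

#' Write burden result tables
#'
#' Emits two CSVs into `out_dir`: `state_burden.csv` (per-state totals,
#' per-capita, 65+ totals and per-capita, plus interval columns when
#' present) and `state_disease_burden.csv` (state x disease totals). Row
#' order is deterministic: states alphabetical, diseases in reporting
#' order. Values are plain decimals.
#'
#' @param result A `dam_burden` object from [compute_burden()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_burden_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "dam_burden"))
  if (nrow(result$state) == 0) abort("empty result: no states to write")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", out_dir))
  }
  p1 <- file.path(out_dir, "state_burden.csv")
  p2 <- file.path(out_dir, "state_disease_burden.csv")
  readr::write_csv(result$state |> arrange(.data$state), p1, progress = FALSE)
  readr::write_csv(
    result$state_disease |>
      arrange(.data$state, .data$disease) |>
      mutate(disease = as.character(.data$disease)),
    p2, progress = FALSE)
  invisible(c(state = p1, state_disease = p2))
}

#' Write a run manifest
#'
#' Records what produced an output directory: the seed(s), the
#' configuration digest, digests of the input files, package version and
#' timestamp. One manifest per output directory makes every number in the
#' emitted tables reproducible.
#'
#' @param out_dir Directory the manifest describes.
#' @param seed Integer seed(s) used.
#' @param inputs Named character vector of input file paths (digested).
#' @param config Arbitrary configuration list (digested, also stored).
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(out_dir, seed = NA_integer_, inputs = character(),
                               config = list()) {
  digests <- purrr::map_chr(inputs, \(p)
    if (file.exists(p)) digest::digest(file = p, algo = "sha256") else NA_character_)
  manifest <- list(
    package = "damcost",
    version = as.character(utils::packageVersion("damcost")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_digest = digest::digest(config, algo = "sha256"),
    config = config,
    inputs = as.list(digests)
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
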