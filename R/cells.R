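#' @importFrom rlang .data %||% abort warn
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows across n distinct rename count
#'   if_else pull relocate semi_join
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif rbinom rgamma quantile setNames
#' @importFrom utils head
NULL

# Canonical factor levels. Order is fixed so every roll-up and file is
# bit-reproducible: age bands young to old, diseases in the conventional
# reporting order (stroke ... depression).
AGE_BANDS <- c("0-18", "19-45", "46-55", "56-64", "65+")
SEXES     <- c("male", "female")
RACES     <- c("white", "black", "other")

#' The 30 demographic cells
#'
#' All prevalence and population quantities in the model are indexed by 30
#' demographic cells: 5 age bands (0-18, 19-45, 46-55, 56-64, 65+) x
#' 2 sexes x 3 race groups.
#'
#' @return A 30-row tibble with factor columns `age_band`, `sex`, `race` in
#'   canonical order.
#' @export
#' @examples
#' dam_cells()
dam_cells <- function() {
  grid <- expand.grid(race = RACES, sex = SEXES, age_band = AGE_BANDS,
                      stringsAsFactors = FALSE)
  tibble(
    age_band = factor(grid$age_band, levels = AGE_BANDS),
    sex      = factor(grid$sex, levels = SEXES),
    race     = factor(grid$race, levels = RACES)
  ) |>
    arrange(.data$age_band, .data$sex, .data$race)
}

#' Assign ages to age bands
#'
#' Band edges are inclusive as written: 18 falls in the youngest band,
#' 19 in the second, 65 in the oldest. Ages are whole years.
#'
#' @param age Numeric vector of ages in years (non-negative).
#' @return Factor with levels `r toString(AGE_BANDS)`.
#' @export
#' @examples
#' assign_age_band(c(18, 19, 46, 64, 65))
assign_age_band <- function(age) {
  if (any(age < 0, na.rm = TRUE)) abort("ages must be non-negative")
  cut(age, breaks = c(-Inf, 18, 45, 55, 64, Inf), labels = AGE_BANDS)
}

#' Collapse race labels to the three-level coding
#'
#' Any label not mapped to "white" or "black" becomes "other". The mapping
#' can be extended, e.g. `c(caucasian = "white", aa = "black")`.
#'
#' @param race Character vector of input race labels.
#' @param mapping Named character vector from input label to one of
#'   `"white"`, `"black"`, `"other"`.
#' @return Factor with levels white, black, other.
#' @export
assign_race <- function(race, mapping = c(white = "white", black = "black")) {
  if (!all(mapping %in% RACES)) abort("mapping targets must be white/black/other")
  out <- unname(mapping[tolower(as.character(race))])
  out[is.na(out)] <- "other"
  factor(out, levels = RACES)
}

#' The eight study diseases
#'
#' The model covers eight conditions chosen to limit double counting of
#' malnourished individuals across diseases: stroke, COPD, CHF, colorectal
#' cancer, breast cancer, dementia, musculoskeletal disorders and
#' depression. Each declares which survey supplies its disease prevalence:
#' the larger interview survey where its definition matches, otherwise the
#' examination survey (dementia and depression).
#'
#' @return Tibble with columns `disease` (ordered factor, reporting order)
#'   and `prevalence_source` (`"interview"` or `"examination"`).
#' @export
dam_diseases <- function() {
  tibble(
    disease = factor(DISEASES, levels = DISEASES),
    prevalence_source = if_else(DISEASES %in% c("dementia", "depression"),
                                "examination", "interview")
  )
}

DISEASES <- c("stroke", "copd", "chf", "colorectal_cancer", "breast_cancer",
              "dementia", "musculoskeletal", "depression")

# Validate that a data frame carries proper cell columns; coerce to factors.
as_cell_cols <- function(df, call = rlang::caller_env()) {
  need <- c("age_band", "sex", "race")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("missing cell columns: ", toString(miss)), call = call)
  bad_band <- setdiff(unique(as.character(df$age_band)), AGE_BANDS)
  if (length(bad_band)) abort(paste0("unknown age-band label: ", toString(bad_band)), call = call)
  bad_sex <- setdiff(unique(as.character(df$sex)), SEXES)
  if (length(bad_sex)) abort(paste0("unknown sex label: ", toString(bad_sex)), call = call)
  bad_race <- setdiff(unique(as.character(df$race)), RACES)
  if (length(bad_race)) abort(paste0("unknown race label: ", toString(bad_race)), call = call)
  df |>
    mutate(age_band = factor(as.character(.data$age_band), levels = AGE_BANDS),
           sex = factor(as.character(.data$sex), levels = SEXES),
           race = factor(as.character(.data$race), levels = RACES))
}
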