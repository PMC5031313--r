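CM_PER_INCH <- 2.54
LB_PER_KG <- 1 / 0.45359237

#' Hamwi ideal body weight
#'
#' The traditional Hamwi rule: 106 lb plus 6 lb per inch over five feet for
#' men, 100 lb plus 5 lb per inch over five feet for women. Heights below
#' five feet extrapolate the same slope downward, floored at
#' `floor_lb` so the result stays positive for short adults.
#'
#' @param sex Character vector, `"male"` or `"female"` (recycled).
#' @param height_cm Heights in centimetres, must be positive.
#' @param floor_lb Minimum ideal weight returned (lb), default 50.
#' @return Ideal body weight in pounds.
#' @export
#' @examples
#' hamwi_ideal_weight("male", 60 * 2.54)    # 106
#' hamwi_ideal_weight("female", 60 * 2.54)  # 100
#' hamwi_ideal_weight("male", 72 * 2.54)    # 178
hamwi_ideal_weight <- function(sex, height_cm, floor_lb = 50) {
  if (any(!is.finite(height_cm) | height_cm <= 0))
    abort("height must be positive and finite")
  sex <- as.character(sex)
  bad <- setdiff(unique(sex), SEXES)
  if (length(bad)) abort(paste0("unknown sex label: ", toString(bad)))
  inches <- height_cm / CM_PER_INCH
  base  <- if_else(sex == "male", 106, 100)
  slope <- if_else(sex == "male", 6, 5)
  pmax(base + slope * (inches - 60), floor_lb)
}

#' Classify malnutrition from anthropometry and serum albumin
#'
#' A person is malnourished when their weight is below 90% of Hamwi ideal
#' body weight and/or their serum albumin is below 3.5 g/dL. Both
#' thresholds are strict: exactly 90% IBW or exactly 3.5 g/dL is not
#' malnourished. Missing albumin makes the albumin criterion unknown; the
#' overall status is then `TRUE` if the weight criterion already fires,
#' `NA` otherwise. Rows with missing height or weight cannot be assessed
#' and are dropped with a warning naming them.
#'
#' @param records Data frame with columns `sex`, `height` (cm), `weight`
#'   (kg) and optionally `serum_albumin` (g/dL, may be `NA`).
#' @param pct_ibw_threshold Fraction of ideal body weight below which the
#'   weight criterion fires. Default 0.90.
#' @param albumin_threshold Serum albumin (g/dL) below which the albumin
#'   criterion fires. Default 3.5.
#' @param ibw_floor_lb Floor passed to [hamwi_ideal_weight()].
#' @return The input tibble with columns `ideal_weight_lb`, `percent_ibw`,
#'   `low_weight`, `low_albumin`, `malnourished` appended. Rows lacking
#'   height or weight are excluded.
#' @export
#' @examples
#' recs <- tibble::tibble(sex = "male", height = 175.3,
#'                        weight = c(70, 55), serum_albumin = c(3.4, NA))
#' classify_malnutrition(recs)[, c("percent_ibw", "malnourished")]
classify_malnutrition <- function(records,
                                  pct_ibw_threshold = 0.90,
                                  albumin_threshold = 3.5,
                                  ibw_floor_lb = 50) {
  records <- as_tibble(records)
  if (!all(c("sex", "height", "weight") %in% names(records)))
    abort("records need sex, height and weight columns")
  if (!"serum_albumin" %in% names(records)) records$serum_albumin <- NA_real_

  unmeasured <- is.na(records$height) | is.na(records$weight)
  if (any(unmeasured)) {
    warn(paste0(sum(unmeasured), " record(s) excluded from classification: ",
                "missing height or weight (rows ",
                toString(head(which(unmeasured), 10)), ")"))
    records <- records[!unmeasured, , drop = FALSE]
  }
  if (any(records$height <= 0 | records$weight <= 0))
    abort("height and weight must be positive")

  records |>
    mutate(
      ideal_weight_lb = hamwi_ideal_weight(.data$sex, .data$height, ibw_floor_lb),
      percent_ibw = .data$weight * LB_PER_KG / .data$ideal_weight_lb,
      low_weight = .data$percent_ibw < pct_ibw_threshold,
      low_albumin = .data$serum_albumin < albumin_threshold,
      malnourished = if_else(
        .data$low_weight | (!is.na(.data$low_albumin) & .data$low_albumin),
        TRUE,
        if_else(is.na(.data$low_albumin), NA, FALSE)
      )
    )
}
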