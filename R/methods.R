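#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_pointrange coord_flip
#'   labs scale_y_continuous
#' @export
ggplot2::autoplot

#' Tidy a burden result
#'
#' @param x A `dam_burden`.
#' @param level `"state_disease"` (default), `"state"`, or
#'   `"national_disease"`.
#' @param ... Unused.
#' @return A tibble of the requested roll-up.
#' @method tidy dam_burden
#' @export
tidy.dam_burden <- function(x, level = c("state_disease", "state",
                                         "national_disease"), ...) {
  level <- rlang::arg_match(level)
  as_tibble(x[[level]])
}

#' @rdname tidy.dam_burden
#' @method glance dam_burden
#' @export
glance.dam_burden <- function(x, ...) as_tibble(x$national)

#' Tidy a PSA result
#'
#' @param x A `dam_psa`.
#' @param level `"state"` (default), `"state_disease"`,
#'   `"national_disease"`, or `"replicates"`.
#' @param ... Unused.
#' @return Tibble with point estimates and interval bounds (or the
#'   per-replicate long table).
#' @method tidy dam_psa
#' @export
tidy.dam_psa <- function(x, level = c("state", "state_disease",
                                      "national_disease", "replicates"), ...) {
  level <- rlang::arg_match(level)
  as_tibble(x[[level]])
}

#' @rdname tidy.dam_psa
#' @method glance dam_psa
#' @export
glance.dam_psa <- function(x, ...) {
  x$national |>
    mutate(n_reps = x$n_reps, n_used = x$n_used, n_failed = x$n_failed,
           ci_level = x$config$ci_level)
}

#' Plot per-capita state burden
#'
#' Horizontal bar chart of per-capita DAM cost by state, highest first.
#'
#' @param object A `dam_burden`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dam_burden
#' @export
autoplot.dam_burden <- function(object, ...) {
  df <- object$state |>
    mutate(state = stats::reorder(.data$state, .data$per_capita))
  ggplot(df, aes(x = .data$state, y = .data$per_capita)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(x = NULL, y = "DAM cost per capita (USD/year)",
         title = "Direct medical cost of disease-associated malnutrition")
}

#' Plot PSA intervals for state totals
#'
#' Point estimates with percentile interval bars per state.
#'
#' @param object A `dam_psa`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dam_psa
#' @export
autoplot.dam_psa <- function(object, ...) {
  df <- object$state |>
    mutate(state = stats::reorder(.data$state, .data$cost_total))
  ggplot(df, aes(x = .data$state, y = .data$cost_total,
                 ymin = .data$cost_total_lower, ymax = .data$cost_total_upper)) +
    geom_pointrange() +
    coord_flip() +
    scale_y_continuous(labels = \(x) format(x, big.mark = ",",
                                            scientific = FALSE)) +
    labs(x = NULL, y = "DAM cost (USD/year)",
         title = sprintf("State DAM burden with %.0f%% Monte Carlo intervals",
                         100 * object$config$ci_level))
}

#' Plot the national disease decomposition
#'
#' @param result `dam_burden` or `dam_psa`.
#' @return A ggplot: national DAM cost by disease, largest first.
#' @export
plot_disease_decomposition <- function(result) {
  burden <- if (inherits(result, "dam_psa")) result$point else result
  stopifnot(inherits(burden, "dam_burden"))
  df <- burden$national_disease |>
    mutate(disease = stats::reorder(.data$disease, .data$cost_total))
  ggplot(df, aes(x = .data$disease, y = .data$cost_total)) +
    geom_col(fill = "darkred") +
    coord_flip() +
    scale_y_continuous(labels = \(x) format(x, big.mark = ",",
                                            scientific = FALSE)) +
    labs(x = NULL, y = "national DAM cost (USD/year)")
}
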