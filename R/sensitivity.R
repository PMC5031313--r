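# Rao-Wu rescaling bootstrap weights per cluster.
#
# Within each stratum of n_h clusters, n_h - 1 clusters are drawn with
# replacement; a record's weight is multiplied by m_c * n_h / (n_h - 1)
# where m_c is the number of times its cluster was drawn. The record set
# never changes, only the weights, so domain structure is preserved and
# E(bootstrap weight) equals the original weight.

merge_singleton_strata <- function(design) {
  # design: tibble(stratum_id, cluster_id), distinct. Strata with a single
  # cluster are merged into the next stratum in identifier order (the
  # previous one for the last stratum) so every stratum has >= 2 clusters.
  sizes <- design |> count(.data$stratum_id, name = "n_clus") |>
    arrange(.data$stratum_id)
  strata <- sizes$stratum_id
  merged <- setNames(as.character(strata), as.character(strata))
  for (i in seq_along(strata)) {
    if (sizes$n_clus[i] == 1) {
      target <- if (i < length(strata)) strata[i + 1] else strata[i - 1]
      if (length(target) == 0 || is.na(target))
        abort("stratum with a single cluster and no adjacent stratum to merge with")
      merged[as.character(strata[i])] <- merged[as.character(target)]
    }
  }
  merged
}

#' Rao-Wu rescaling bootstrap of a survey
#'
#' Returns the records with bootstrap-rescaled sampling weights,
#' preserving the stratified-cluster design. Strata with a single cluster
#' are first merged into the adjacent stratum in identifier order; a
#' merged stratum still holding one cluster is an error. Draws come from
#' the current RNG state, so seed handling is the caller's.
#'
#' @param records Survey records with `sample_weight`, `stratum_id`,
#'   `cluster_id`.
#' @return The same tibble with `sample_weight` replaced by the bootstrap
#'   weight (possibly zero for undrawn clusters).
#' @export
bootstrap_resample_survey <- function(records) {
  records <- as_tibble(records)
  factor_by_cluster <- bootstrap_factors(records$stratum_id, records$cluster_id)
  records |>
    mutate(sample_weight = .data$sample_weight *
             unname(factor_by_cluster[as.character(.data$cluster_id)]))
}

# Precomputed design structure: record -> cluster index, clusters grouped
# by (merged) stratum in deterministic order. Built once; each replicate
# then only draws multiplicities.
design_prep <- function(stratum_id, cluster_id) {
  design <- distinct(tibble(stratum_id = as.character(stratum_id),
                            cluster_id = as.character(cluster_id)))
  merged <- merge_singleton_strata(design)
  design$stratum_eff <- unname(merged[design$stratum_id])
  groups <- split(seq_len(nrow(design)), design$stratum_eff)
  groups <- lapply(groups, \(ix) ix[order(design$cluster_id[ix])])
  for (h in names(groups)) {
    if (length(groups[[h]]) < 2)
      abort(paste0("stratum ", h, " has a single cluster after merging"))
  }
  list(rec_idx = match(as.character(cluster_id), design$cluster_id),
       cluster_levels = design$cluster_id,
       groups = groups)
}

# One Rao-Wu draw: weight multiplier per cluster (order = cluster_levels).
draw_factors <- function(dp) {
  f <- numeric(length(dp$cluster_levels))
  for (g in dp$groups) {
    n_h <- length(g)
    m <- tabulate(sample.int(n_h, n_h - 1, replace = TRUE), n_h)
    f[g] <- m * n_h / (n_h - 1)
  }
  f
}

# Named vector of weight multipliers per cluster id.
bootstrap_factors <- function(stratum_id, cluster_id) {
  dp <- design_prep(stratum_id, cluster_id)
  setNames(draw_factors(dp), dp$cluster_levels)
}

#' Draw cost parameters for one PSA replicate
#'
#' Each disease's mean annual cost is redrawn from its declared
#' uncertainty: a gamma distribution parameterized by method of moments
#' (shape `(mean/se)^2`, scale `se^2/mean`) when a standard error is
#' available, a uniform on `[0.8 mean, 1.2 mean]` otherwise; `fixed`
#' parameters stay at their mean. The malnutrition multiplier `delta_mn`
#' is redrawn only when `vary_global_delta` is `TRUE`, else held at its
#' point value. Uses the current RNG state.
#'
#' @param params `dam_cost_params`.
#' @param vary_global_delta Redraw `delta_mn` from its distribution?
#' @return A `dam_cost_params` with realized values (all distributions
#'   marked `fixed`).
#' @export
draw_cost_parameters <- function(params, vary_global_delta = FALSE) {
  stopifnot(inherits(params, "dam_cost_params"))
  draw1 <- function(mean, dist, se) {
    switch(dist,
      gamma = rgamma(1, shape = (mean / se)^2, scale = se^2 / mean),
      uniform = runif(1, 0.8 * mean, 1.2 * mean),
      fixed = mean,
      abort(paste0("unknown distribution: ", dist)))
  }
  costs <- params$costs |>
    mutate(mean_annual_cost = purrr::pmap_dbl(
      list(.data$mean_annual_cost, .data$distribution, .data$se), draw1),
      distribution = "fixed")
  dm <- params$delta_mn
  if (vary_global_delta && dm$distribution != "fixed") {
    dm$value <- draw1(dm$value, dm$distribution, dm$se)
  }
  dm$distribution <- "fixed"
  structure(list(costs = costs, delta_mn = dm), class = "dam_cost_params")
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of survey sampling and cost-parameter
#' uncertainty through the whole pipeline. Each replicate (i) reweights
#' both surveys with an independent Rao-Wu rescaling bootstrap, (ii)
#' redraws the cost parameters, (iii) re-estimates both prevalence tables
#' and recomputes the burden. Intervals are empirical percentiles of the
#' replicate outputs at `(1 - ci_level)/2` and `1 - (1 - ci_level)/2`
#' (0.05/0.95 for the default 90% level). The point estimate is the
#' unresampled run; the replicate mean is reported alongside. Two modes
#' mirror the usual reporting convention: holding the global multiplier
#' `delta_mn` fixed (so states can be compared to each other) or letting
#' it vary with the other parameters.
#'
#' Replicate seeds are derived from the master seed by a fixed counter
#' scheme (`(seed + 99991 * r) mod (2^31 - 1)`), so any replicate can be
#' reproduced in isolation. A failing replicate is dropped and counted;
#' more than 1% failures aborts.
#'
#' @param exam_records,interview_records Survey microdata tibbles.
#' @param population State population table.
#' @param cost_params `dam_cost_params`.
#' @param n_reps Number of Monte Carlo replicates (conventionally 1000).
#' @param ci_level Interval level, default 0.90.
#' @param vary_global_delta Redraw `delta_mn` per replicate?
#' @param seed Master seed.
#' @param bootstrap Resample the surveys? (FALSE isolates cost-parameter
#'   uncertainty.)
#' @param vary_costs Redraw cost parameters? (FALSE isolates survey
#'   uncertainty.)
#' @param states Subset of states, default all.
#' @param min_cell_n,exclude_children Passed to the prevalence step.
#' @return Object of class `dam_psa`: the point `dam_burden`, interval
#'   tibbles `state`, `state_disease`, `national`, `national_disease`
#'   (point, lower, upper, replicate mean), the per-replicate long tibble
#'   `replicates`, and bookkeeping (`n_reps`, `n_failed`, `config`).
#' @export
run_psa <- function(exam_records, interview_records, population, cost_params,
                    n_reps = 1000, ci_level = 0.90, vary_global_delta = FALSE,
                    seed = 1, bootstrap = TRUE, vary_costs = TRUE,
                    states = NULL, min_cell_n = 10, exclude_children = FALSE) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)")

  pmn_pt <- estimate_pmn(exam_records, min_cell_n = min_cell_n,
                         exclude_children = exclude_children)
  rho_pt <- estimate_rho(interview_records, exam_records)
  point <- compute_burden(pmn_pt, rho_pt, population, cost_params,
                          states = states)

  prep <- prev_prep(exam_records, interview_records,
                    min_cell_n = min_cell_n,
                    exclude_children = exclude_children)
  pop <- as_cell_cols(as_tibble(population))
  if (!is.null(states)) pop <- filter(pop, .data$state %in% states)
  state_names <- sort(unique(as.character(pop$state)))
  popmat <- vapply(state_names, function(s) {
    sub <- pop |> filter(.data$state == s) |>
      arrange(.data$age_band, .data$sex, .data$race)
    v <- numeric(30)
    v[cell_index(sub)] <- sub$count
    v
  }, numeric(30))
  is65 <- dam_cells()$age_band == "65+"

  w_ex0 <- prep$cl$sample_weight
  w_iv0 <- prep$iv$sample_weight
  dp_ex <- design_prep(prep$cl$stratum_id, prep$cl$cluster_id)
  dp_iv <- design_prep(prep$iv$stratum_id, prep$iv$cluster_id)
  reps <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- (seed + 99991 * r) %% 2147483647
    set.seed(rep_seed)
    res <- tryCatch({
      w_ex <- w_ex0
      w_iv <- w_iv0
      if (bootstrap) {
        w_ex <- w_ex0 * draw_factors(dp_ex)[dp_ex$rec_idx]
        w_iv <- w_iv0 * draw_factors(dp_iv)[dp_iv$rec_idx]
      }
      cp <- if (vary_costs) draw_cost_parameters(cost_params, vary_global_delta)
            else cost_params
      tabs <- prev_point_tables(prep, w_ex, w_iv)
      pmn <- tabs$pmn
      rho <- tabs$rho
      need <- popmat > 0
      if (any(is.na(pmn[rowSums(need) > 0, ])) ||
          any(is.na(rho[rowSums(need) > 0, ])))
        stop("unestimable prevalence cell in replicate")
      Cvec <- cp$costs$mean_annual_cost
      dvec <- delta_mn_by_disease(cp)
      af <- sweep(pmn, 2, dvec, \(p, d) p * d / (1 + p * d))
      contrib <- sweep(af * rho, 2, Cvec, `*`)        # 30 x 8 cost per person
      sd_mat <- crossprod(popmat, contrib)            # states x diseases
      sd65 <- crossprod(popmat[is65, , drop = FALSE],
                        contrib[is65, , drop = FALSE])
      list(sd = sd_mat, sd65 = sd65)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[[r]] <- res
  }
  if (n_failed > max(1, 0.01 * n_reps))
    abort(paste0(n_failed, " of ", n_reps, " PSA replicates failed"))
  reps <- reps[!vapply(reps, is.null, logical(1))]
  n_used <- length(reps)

  sd_arr <- array(unlist(purrr::map(reps, "sd")),
                  dim = c(length(state_names), 8, n_used))
  sd65_arr <- array(unlist(purrr::map(reps, "sd65")),
                    dim = c(length(state_names), 8, n_used))
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)

  q_over <- function(x) quantile(x, probs, names = FALSE, type = 7)
  state_tot <- apply(sd_arr, c(1, 3), sum)    # states x reps
  state_65 <- apply(sd65_arr, c(1, 3), sum)
  nat_tot <- colSums(state_tot)
  nat_65 <- colSums(state_65)
  nat_dis <- apply(sd_arr, c(2, 3), sum)      # diseases x reps

  pop_tot <- colSums(popmat)[state_names]
  pop_65 <- colSums(popmat[is65, , drop = FALSE])[state_names]

  state_iv <- purrr::map(seq_along(state_names), function(s) {
    qt <- q_over(state_tot[s, ]); q6 <- q_over(state_65[s, ])
    tibble(state = state_names[s],
           cost_total_lower = qt[1], cost_total_upper = qt[2],
           cost_total_mean = mean(state_tot[s, ]),
           per_capita_lower = qt[1] / pop_tot[s],
           per_capita_upper = qt[2] / pop_tot[s],
           cost_65plus_lower = q6[1], cost_65plus_upper = q6[2],
           per_capita_65plus_lower = q6[1] / pop_65[s],
           per_capita_65plus_upper = q6[2] / pop_65[s])
  }) |> purrr::list_rbind()
  state_out <- point$state |> left_join(state_iv, by = "state")

  sd_iv <- tidyr::crossing(state = state_names,
                           disease = factor(DISEASES, levels = DISEASES)) |>
    arrange(.data$state, .data$disease)
  sd_iv$cost_total_lower <- NA_real_
  sd_iv$cost_total_upper <- NA_real_
  sd_iv$cost_total_mean <- NA_real_
  for (s in seq_along(state_names)) for (d in 1:8) {
    qq <- q_over(sd_arr[s, d, ])
    row <- (s - 1) * 8 + d
    sd_iv$cost_total_lower[row] <- qq[1]
    sd_iv$cost_total_upper[row] <- qq[2]
    sd_iv$cost_total_mean[row] <- mean(sd_arr[s, d, ])
  }
  state_disease_out <- point$state_disease |>
    left_join(sd_iv, by = c("state", "disease"))

  nd_iv <- purrr::map(1:8, function(d) {
    qq <- q_over(nat_dis[d, ])
    tibble(disease = factor(DISEASES[d], levels = DISEASES),
           cost_total_lower = qq[1], cost_total_upper = qq[2],
           cost_total_mean = mean(nat_dis[d, ]))
  }) |> purrr::list_rbind()
  national_disease_out <- point$national_disease |>
    left_join(nd_iv, by = "disease")

  qn <- q_over(nat_tot); qn6 <- q_over(nat_65)
  national_out <- point$national |>
    mutate(cost_total_lower = qn[1], cost_total_upper = qn[2],
           cost_total_mean = mean(nat_tot),
           per_capita_lower = qn[1] / sum(pop_tot),
           per_capita_upper = qn[2] / sum(pop_tot),
           cost_65plus_lower = qn6[1], cost_65plus_upper = qn6[2])

  replicates <- tibble(
    replicate = rep(seq_len(n_used), each = length(state_names)),
    state = rep(state_names, times = n_used),
    cost_total = c(state_tot),
    cost_65plus = c(state_65)
  )

  # percentile intervals from resampled data need not bracket the point
  # estimate; flag it when they genuinely do not (beyond float noise)
  slack <- 1e-9 * abs(national_out$cost_total)
  not_bracketing <- with(national_out,
                         cost_total < cost_total_lower - slack |
                           cost_total > cost_total_upper + slack)
  if (isTRUE(not_bracketing))
    warn("the national 90% interval does not bracket the point estimate")

  structure(list(point = point, state = state_out,
                 state_disease = state_disease_out,
                 national = national_out,
                 national_disease = national_disease_out,
                 replicates = replicates,
                 n_reps = n_reps, n_used = n_used, n_failed = n_failed,
                 config = list(ci_level = ci_level, seed = seed,
                               vary_global_delta = vary_global_delta,
                               bootstrap = bootstrap, vary_costs = vary_costs,
                               min_cell_n = min_cell_n,
                               exclude_children = exclude_children)),
            class = "dam_psa")
}

#' @export
print.dam_psa <- function(x, ...) {
  cat("DAM probabilistic sensitivity analysis\n")
  cat("  replicates:", x$n_used, "used /", x$n_reps,
      "requested (", x$n_failed, "failed )\n")
  ci <- x$config$ci_level * 100
  cat(sprintf("  national total: %s  (%.0f%% CI %s - %s)\n",
              format(round(x$national$cost_total), big.mark = ","), ci,
              format(round(x$national$cost_total_lower), big.mark = ","),
              format(round(x$national$cost_total_upper), big.mark = ",")))
  invisible(x)
}
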