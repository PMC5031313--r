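# Design-based ratio estimation of domain prevalences.
#
# Point estimator: p = sum(w * y) / sum(w) over in-domain records with a
# known indicator. Standard error by Taylor linearization of the ratio
# within strata/clusters: the linearized variate z_k = w_k (y_k - p) for
# in-domain records (0 otherwise) is totalled per cluster, and the
# variance is sum_h n_h/(n_h - 1) * sum_c (t_hc - tbar_h)^2 / W^2 over
# strata with >= 2 clusters. When every stratum is degenerate (a single
# cluster) the SE falls back to the weighted SRS binomial form.

ratio_point <- function(w, y, dom) {
  keep <- dom & !is.na(y) & !is.na(w)
  W <- sum(w[keep])
  if (W <= 0 || !any(keep)) return(NA_real_)
  sum(w[keep] * y[keep]) / W
}

ratio_se <- function(w, y, dom, stratum, cluster, p) {
  keep <- dom & !is.na(y) & !is.na(w)
  if (is.na(p) || !any(keep)) return(NA_real_)
  W <- sum(w[keep])
  z <- numeric(length(w))
  z[keep] <- w[keep] * (y[keep] - p)
  sc <- paste(stratum, cluster, sep = "\r")
  t_hc <- rowsum(z, sc, reorder = TRUE)
  strat_of <- sub("\r.*$", "", rownames(t_hc))
  n_h <- table(strat_of)
  ok <- strat_of %in% names(n_h)[n_h >= 2]
  if (!any(ok)) {
    # degenerate design: weighted SRS binomial fallback
    return(sqrt(max(p * (1 - p), 0) * sum(w[keep]^2)) / W)
  }
  v <- 0
  for (h in names(n_h)[n_h >= 2]) {
    t_h <- t_hc[strat_of == h, 1]
    nh <- length(t_h)
    v <- v + nh / (nh - 1) * sum((t_h - mean(t_h))^2)
  }
  sqrt(v) / W
}

#' Design-weighted domain prevalence
#'
#' Estimates the prevalence of a binary indicator within a domain of a
#' complex survey: the weighted proportion over in-domain records with a
#' known indicator, with a Taylor-linearized standard error that respects
#' the stratum/cluster design (falling back to the weighted binomial SE
#' when no stratum has two clusters). Records with an unknown indicator
#' are excluded from numerator and denominator (complete case).
#'
#' @param records Data frame with `sample_weight`, `stratum_id`,
#'   `cluster_id` columns.
#' @param indicator Expression (evaluated in `records`) giving the 0/1 or
#'   logical indicator; may contain `NA` (unknown).
#' @param domain Expression giving the domain membership (logical);
#'   defaults to all records.
#' @return One-row tibble: `estimate`, `se`, `n_effective` (count of
#'   contributing records), `empty` (TRUE when no record contributes).
#' @export
#' @examples
#' df <- tibble::tibble(y = c(1, 0, 1, 0), sample_weight = c(3, 1, 1, 1),
#'                      stratum_id = 1, cluster_id = 1:4)
#' weighted_domain_prevalence(df, y)                     # 5/6
#' weighted_domain_prevalence(df, y, sample_weight > 2)  # weight-3 record only
weighted_domain_prevalence <- function(records, indicator, domain = NULL) {
  y <- as.numeric(rlang::eval_tidy(rlang::enquo(indicator), records))
  dq <- rlang::enquo(domain)
  dom <- if (rlang::quo_is_null(dq)) rep(TRUE, nrow(records))
         else as.logical(rlang::eval_tidy(dq, records))
  dom[is.na(dom)] <- FALSE
  w <- records$sample_weight
  if (any(w < 0, na.rm = TRUE)) abort("sample weights must be non-negative")
  p <- ratio_point(w, y, dom)
  se <- ratio_se(w, y, dom, records$stratum_id, records$cluster_id, p)
  n <- sum(dom & !is.na(y) & !is.na(w))
  tibble(estimate = p, se = se, n_effective = n, empty = n == 0)
}

cell_index <- function(df) {
  (as.integer(df$age_band) - 1L) * 6L + (as.integer(df$sex) - 1L) * 3L +
    as.integer(df$race)
}

# Pooling ladder for sparse malnutrition-within-disease cells: a cell with
# fewer than min_cell_n contributing diseased records is estimated from
# progressively wider domains -- all races within (age band, sex), then
# both sexes within the age band, then the disease-wide marginal. The
# ladder is chosen once from unweighted counts, so it is deterministic and
# invariant under bootstrap reweighting.
POOL_LEVELS <- c("none", "race", "sex", "marginal")

pool_level_for <- function(n_cell, n_agesex, n_age, n_marg, min_cell_n) {
  dplyr::case_when(
    n_cell >= min_cell_n ~ "none",
    n_agesex >= min_cell_n ~ "race",
    n_age >= min_cell_n ~ "sex",
    .default = "marginal"
  )
}

#' Estimate malnutrition prevalence within each disease and cell
#'
#' For every (disease, demographic cell): the design-weighted prevalence
#' of malnutrition (per [classify_malnutrition()]) among persons carrying
#' that disease flag. Records with unknown malnutrition status or unknown
#' disease flag are excluded from that estimate (complete case). Cells
#' with fewer than `min_cell_n` contributing records are filled by a
#' deterministic pooling ladder (race, then sex, then the disease-wide
#' marginal), recorded in the `pooling` column.
#'
#' @param exam_records Examination survey records (see
#'   [read_survey_table()] or [generate_examination_survey()]).
#' @param min_cell_n Minimum contributing records before pooling, default 10.
#' @param exclude_children Drop the 0-18 band from estimation (the adult
#'   ideal-body-weight rule is not validated for children); their entries
#'   are then pooled from adult data. Default FALSE.
#' @inheritParams classify_malnutrition
#' @return A prevalence table: tibble keyed by `disease`, `age_band`,
#'   `sex`, `race` with `estimate`, `se`, `n_effective`, `source`,
#'   `pooling`, `empty`.
#' @export
estimate_pmn <- function(exam_records, min_cell_n = 10,
                         exclude_children = FALSE,
                         pct_ibw_threshold = 0.90, albumin_threshold = 3.5) {
  cl <- classify_malnutrition(exam_records,
                              pct_ibw_threshold = pct_ibw_threshold,
                              albumin_threshold = albumin_threshold)
  if (exclude_children) cl <- filter(cl, .data$age_band != "0-18")
  y <- as.numeric(cl$malnourished)
  w <- cl$sample_weight
  cells <- dam_cells()
  ci <- cell_index(cl)

  purrr::map(DISEASES, function(dis) {
    fl <- cl[[paste0("flag_", dis)]]
    if (is.null(fl)) abort(paste0("missing disease flag column: flag_", dis))
    dom_base <- !is.na(fl) & fl
    known <- dom_base & !is.na(y)
    n_cell <- tabulate(ci[known], 30)
    grid <- cells |>
      mutate(cell = dplyr::row_number(), n_cell = n_cell) |>
      group_by(.data$age_band, .data$sex) |>
      mutate(n_agesex = sum(.data$n_cell)) |>
      group_by(.data$age_band) |>
      mutate(n_age = sum(.data$n_cell)) |>
      ungroup() |>
      mutate(n_marg = sum(n_cell),
             pooling = pool_level_for(.data$n_cell, .data$n_agesex,
                                      .data$n_age, .data$n_marg, min_cell_n))
    est <- purrr::pmap(grid, function(age_band, sex, race, cell, pooling, ...) {
      dom <- dom_base & switch(pooling,
        none = ci == cell,
        race = cl$age_band == age_band & cl$sex == sex,
        sex = cl$age_band == age_band,
        marginal = TRUE)
      p <- ratio_point(w, y, dom)
      tibble(estimate = p,
             se = ratio_se(w, y, dom, cl$stratum_id, cl$cluster_id, p),
             n_effective = sum(dom & !is.na(y)))
    }) |> purrr::list_rbind()
    grid |>
      mutate(disease = dis) |>
      select("disease", "age_band", "sex", "race", "pooling") |>
      dplyr::bind_cols(est)
  }) |>
    purrr::list_rbind() |>
    mutate(disease = factor(.data$disease, levels = DISEASES),
           source = "examination",
           empty = .data$n_effective == 0) |>
    select("disease", "age_band", "sex", "race", "estimate", "se",
           "n_effective", "source", "pooling", "empty")
}

#' Estimate disease prevalence per cell
#'
#' For every (disease, cell): the design-weighted prevalence of the
#' disease flag among all survey records in that cell. Each disease
#' declares which survey supplies it (`prevalence_source` in `diseases`);
#' for interview-sourced diseases the 0-18 cells fall back to the
#' examination survey, whose condition definitions cover children.
#' Records with an unknown flag are excluded from that disease's
#' denominator.
#'
#' @param interview_records Interview survey records.
#' @param exam_records Examination survey records.
#' @param diseases Routing table as from [dam_diseases()].
#' @return Prevalence table shaped as in [estimate_pmn()] (the `pooling`
#'   column is always `"none"`; `source` names the survey used per entry).
#' @export
estimate_rho <- function(interview_records, exam_records,
                         diseases = dam_diseases()) {
  cells <- dam_cells()
  surveys <- list(interview = as_tibble(interview_records),
                  examination = as_tibble(exam_records))
  idx <- purrr::map(surveys, cell_index)

  purrr::pmap(diseases, function(disease, prevalence_source) {
    dis <- as.character(disease)
    per_cell <- function(src, cell_set) {
      df <- surveys[[src]]
      fl <- df[[paste0("flag_", dis)]]
      if (is.null(fl)) abort(paste0("missing disease flag column: flag_", dis))
      y <- as.numeric(fl)
      purrr::map(cell_set, function(cell) {
        dom <- idx[[src]] == cell
        p <- ratio_point(df$sample_weight, y, dom)
        tibble(cell = cell, estimate = p,
               se = ratio_se(df$sample_weight, y, dom,
                             df$stratum_id, df$cluster_id, p),
               n_effective = sum(dom & !is.na(y)), source = src)
      }) |> purrr::list_rbind()
    }
    child_cells <- which(cells$age_band == "0-18")
    out <- if (prevalence_source == "interview") {
      bind_rows(per_cell("examination", child_cells),
                per_cell("interview", setdiff(1:30, child_cells)))
    } else {
      per_cell("examination", 1:30)
    }
    cells |>
      mutate(cell = dplyr::row_number(), disease = dis) |>
      inner_join(out, by = "cell") |>
      select(-"cell")
  }) |>
    purrr::list_rbind() |>
    mutate(disease = factor(.data$disease, levels = DISEASES),
           pooling = "none", empty = .data$n_effective == 0) |>
    select("disease", "age_band", "sex", "race", "estimate", "se",
           "n_effective", "source", "pooling", "empty") |>
    arrange(.data$disease, .data$age_band, .data$sex, .data$race)
}

# ---- fast point-estimate path (used by the PSA replicates) -----------------
#
# The bootstrap changes only the weights, never the record set, so domain
# membership, complete-case masks and the pooling ladder are fixed. We
# precompute indicator matrices once and per replicate do a handful of
# rowsum() aggregations.

prev_prep <- function(exam_records, interview_records, diseases = dam_diseases(),
                      min_cell_n = 10, exclude_children = FALSE,
                      pct_ibw_threshold = 0.90, albumin_threshold = 3.5) {
  cl <- classify_malnutrition(exam_records,
                              pct_ibw_threshold = pct_ibw_threshold,
                              albumin_threshold = albumin_threshold)
  if (exclude_children) cl <- filter(cl, .data$age_band != "0-18")
  iv <- as_tibble(interview_records)
  flag_mat <- function(df) {
    m <- vapply(DISEASES, \(d) as.numeric(df[[paste0("flag_", d)]]),
                numeric(nrow(df)))
    colnames(m) <- DISEASES
    m
  }
  ex_fl <- flag_mat(cl); iv_fl <- flag_mat(iv)
  y <- as.numeric(cl$malnourished)

  # pmn: contribution mask per disease = diseased & known status
  pmn_known <- ex_fl == 1 & !is.na(ex_fl) & !is.na(y)
  pmn_known[is.na(pmn_known)] <- FALSE
  ci_ex <- cell_index(cl); ci_iv <- cell_index(iv)
  n_cell <- vapply(DISEASES, \(d) tabulate(ci_ex[pmn_known[, d]], 30),
                   numeric(30))
  agg <- function(m, map) rowsum(m, map, reorder = TRUE)  # over 30 cells
  cells <- dam_cells()
  map_agesex <- (as.integer(cells$age_band) - 1L) * 2L + as.integer(cells$sex)
  map_age <- as.integer(cells$age_band)
  n_agesex <- agg(n_cell, map_agesex)[map_agesex, , drop = FALSE]
  n_age <- agg(n_cell, map_age)[map_age, , drop = FALSE]
  n_marg <- matrix(colSums(n_cell), 30, 8, byrow = TRUE)
  pool <- matrix(pool_level_for(c(n_cell), c(n_agesex), c(n_age), c(n_marg),
                                min_cell_n), 30, 8,
                 dimnames = list(NULL, DISEASES))

  rho_known <- !is.na(iv_fl)
  rho_known_ex <- !is.na(ex_fl)
  # replicate-invariant matrices, precomputed so each bootstrap replicate
  # only rescales by its weight vector
  y0 <- ifelse(is.na(y), 0, y)
  list(cl = cl, iv = iv, y = y, ci_ex = ci_ex, ci_iv = ci_iv,
       ex_fl = ex_fl, iv_fl = iv_fl, pmn_known = pmn_known,
       rho_known = rho_known, rho_known_ex = rho_known_ex,
       pmn_num_mat = y0 * pmn_known, pmn_den_mat = pmn_known * 1,
       iv_fl0 = ifelse(rho_known, iv_fl, 0), iv_known0 = rho_known * 1,
       ex_fl0 = ifelse(rho_known_ex, ex_fl, 0), ex_known0 = rho_known_ex * 1,
       pool = pool, map_agesex = map_agesex, map_age = map_age,
       child = cells$age_band == "0-18",
       src_interview = setNames(diseases$prevalence_source == "interview",
                                as.character(diseases$disease)))
}

prev_point_tables <- function(prep, w_exam, w_int) {
  num <- rowsum(w_exam * prep$pmn_num_mat, prep$ci_ex, reorder = TRUE)
  den <- rowsum(w_exam * prep$pmn_den_mat, prep$ci_ex, reorder = TRUE)
  # rowsum drops absent levels; re-expand to 30
  expand30 <- function(m, idx_present) {
    out <- matrix(0, 30, ncol(m))
    out[idx_present, ] <- m
    out
  }
  pres <- as.integer(rownames(num))
  num <- expand30(num, pres); den <- expand30(den, pres)
  lvl <- list(
    none = list(num, den),
    race = list(rowsum(num, prep$map_agesex)[prep$map_agesex, , drop = FALSE],
                rowsum(den, prep$map_agesex)[prep$map_agesex, , drop = FALSE]),
    sex = list(rowsum(num, prep$map_age)[prep$map_age, , drop = FALSE],
               rowsum(den, prep$map_age)[prep$map_age, , drop = FALSE]),
    marginal = list(matrix(colSums(num), 30, 8, byrow = TRUE),
                    matrix(colSums(den), 30, 8, byrow = TRUE))
  )
  # fill each entry from its assigned ladder rung; when bootstrap
  # reweighting empties that domain (total weight 0), climb further up the
  # ladder for this replicate -- with original weights the assigned rung is
  # never empty, so the deterministic path is unchanged
  pmn <- matrix(NA_real_, 30, 8, dimnames = list(NULL, DISEASES))
  rank_assigned <- matrix(match(prep$pool, POOL_LEVELS), 30, 8)
  for (l in seq_along(POOL_LEVELS)) {
    nm <- lvl[[POOL_LEVELS[l]]][[1]]; dn <- lvl[[POOL_LEVELS[l]]][[2]]
    sel <- rank_assigned <= l & is.na(pmn) & dn > 0
    pmn[sel] <- nm[sel] / dn[sel]
  }

  rho_from <- function(fl0, known0, ci, w) {
    num <- rowsum(w * fl0, ci, reorder = TRUE)
    den <- rowsum(w * known0, ci, reorder = TRUE)
    pres <- as.integer(rownames(num))
    num <- expand30(num, pres); den <- expand30(den, pres)
    out <- matrix(NA_real_, 30, 8, dimnames = list(NULL, DISEASES))
    ok <- den > 0
    out[ok] <- num[ok] / den[ok]
    out
  }
  rho_iv <- rho_from(prep$iv_fl0, prep$iv_known0, prep$ci_iv, w_int)
  rho_ex <- rho_from(prep$ex_fl0, prep$ex_known0, prep$ci_ex, w_exam)
  rho <- rho_ex
  for (d in DISEASES) {
    if (prep$src_interview[[d]]) rho[!prep$child, d] <- rho_iv[!prep$child, d]
  }
  list(pmn = pmn, rho = rho)
}

# long-format tibble from a 30 x 8 matrix
prev_mat_to_tbl <- function(m, value_name) {
  out <- dam_cells() |>
    tidyr::crossing(disease = factor(DISEASES, levels = DISEASES)) |>
    arrange(.data$disease, .data$age_band, .data$sex, .data$race) |>
    relocate("disease")
  out[[value_name]] <- c(m)
  out
}
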