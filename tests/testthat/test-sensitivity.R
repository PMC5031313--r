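two_cluster_survey <- function(n_strata = 4, per_cluster = 5) {
  tidyr::crossing(stratum_id = sprintf("S%d", seq_len(n_strata)),
                  cluster = c("c1", "c2"), rep = seq_len(per_cluster)) |>
    dplyr::mutate(cluster_id = paste(stratum_id, cluster, sep = "-"),
                  sample_weight = 10) |>
    dplyr::select(-cluster, -rep)
}

test_that("a two-cluster stratum yields weights x2 and x0", {
  df <- two_cluster_survey(n_strata = 1)
  set.seed(10)
  out <- bootstrap_resample_survey(df)
  by_cl <- tapply(out$sample_weight, out$cluster_id, unique)
  expect_setequal(as.numeric(by_cl), c(0, 20))
  expect_equal(sum(out$sample_weight), sum(df$sample_weight))  # n_h = 2 exactly preserves the total
})

test_that("bootstrap weights are unbiased for the original total", {
  df <- two_cluster_survey(n_strata = 6)
  set.seed(20)
  tots <- replicate(400, sum(bootstrap_resample_survey(df)$sample_weight))
  expect_equal(mean(tots), sum(df$sample_weight), tolerance = 0.02)
  # record set never changes, only weights
  out <- bootstrap_resample_survey(df)
  expect_equal(nrow(out), nrow(df))
  expect_identical(out$cluster_id, df$cluster_id)
})

test_that("singleton strata merge deterministically; unmergeable designs error", {
  df <- tibble::tibble(
    stratum_id = c("S1", "S1", "S2"),
    cluster_id = c("a", "b", "c"),
    sample_weight = 1
  )
  # S2 has one cluster: merged into the adjacent stratum, so resampling
  # operates on one 3-cluster stratum and every draw takes 2 of 3 clusters
  set.seed(30)
  for (i in 1:20) {
    out <- bootstrap_resample_survey(df)
    m <- out$sample_weight / df$sample_weight / (3 / 2)
    expect_equal(sum(m), 2)
  }
  solo <- tibble::tibble(stratum_id = "S1", cluster_id = "only", sample_weight = 1)
  expect_error(bootstrap_resample_survey(solo), "single cluster")
})

test_that("cost draws follow the declared distributions", {
  cfg <- list(
    diseases = setNames(lapply(damcost:::DISEASES, function(d)
      list(mean_annual_cost = 100, distribution = "gamma", se = 10)),
      damcost:::DISEASES),
    delta_mn = list(value = 0.5, distribution = "gamma", se = 0.1, global = TRUE)
  )
  cfg$diseases$stroke <- list(mean_annual_cost = 50, distribution = "uniform")
  cfg$diseases$copd <- list(mean_annual_cost = 70, distribution = "fixed")
  cp <- damcost:::new_cost_params(cfg)

  # draws happen in disease order: stroke (uniform) first
  set.seed(40)
  d1 <- draw_cost_parameters(cp)
  set.seed(40)
  u <- runif(1, 0.8 * 50, 1.2 * 50)
  g <- rgamma(1, shape = (100 / 10)^2, scale = 10^2 / 100)  # chf, method of moments
  expect_equal(d1$costs$mean_annual_cost[d1$costs$disease == "stroke"], u)
  expect_equal(d1$costs$mean_annual_cost[d1$costs$disease == "chf"], g)

  # uniform draws bounded 20% around the mean; fixed stays put
  set.seed(41)
  draws <- replicate(300, {
    dd <- draw_cost_parameters(cp)
    dd$costs$mean_annual_cost[dd$costs$disease == "stroke"]
  })
  expect_true(all(draws >= 40 & draws <= 60))
  expect_gt(max(draws), 58)
  expect_lt(min(draws), 42)
  dd <- draw_cost_parameters(cp)
  expect_equal(dd$costs$mean_annual_cost[dd$costs$disease == "copd"], 70)

  # gamma draws have roughly the declared mean and se
  set.seed(42)
  gdraws <- replicate(2000, {
    dd <- draw_cost_parameters(cp)
    dd$costs$mean_annual_cost[dd$costs$disease == "dementia"]
  })
  expect_equal(mean(gdraws), 100, tolerance = 0.02)
  expect_equal(sd(gdraws), 10, tolerance = 0.1)

  # delta only moves when vary_global_delta is TRUE
  set.seed(43)
  expect_equal(draw_cost_parameters(cp)$delta_mn$value, 0.5)
  set.seed(43)
  expect_false(draw_cost_parameters(cp, vary_global_delta = TRUE)$delta_mn$value == 0.5)

  bad <- cfg
  bad$diseases$chf$se <- -1
  expect_error(damcost:::new_cost_params(bad), "positive se")
})

test_that("bootstrap SE tracks the true sampling SE on a clustered survey", {
  # truth: clustered design with a real cluster effect; the Monte Carlo SE
  # over independent surveys is the target the bootstrap must approximate
  t_dep <- flat_truth(0.3, 0.25,
                      design = list(n_strata = 10, clusters_per_stratum = 4,
                                    cluster_effect_sd = 0.6))
  prev_of <- function(survey) {
    weighted_domain_prevalence(survey, flag_musculoskeletal)$estimate
  }
  mc <- vapply(1:150, function(s)
    prev_of(generate_interview_survey(t_dep, 1500, seed = 1000 + s)), numeric(1))
  mc_se <- sd(mc)

  one <- generate_interview_survey(t_dep, 1500, seed = 999)
  set.seed(7)
  boot <- vapply(1:200, function(r) prev_of(bootstrap_resample_survey(one)),
                 numeric(1))
  expect_lt(abs(sd(boot) - mc_se) / mc_se, 0.30)

  # and the analytic linearized SE agrees with the same target
  lin_se <- weighted_domain_prevalence(one, flag_musculoskeletal)$se
  expect_lt(abs(lin_se - mc_se) / mc_se, 0.30)
})

test_that("the PSA is deterministic in its seed and collapses without randomness", {
  w <- tiny_world(n_exam = 2000, n_int = 3000)
  a <- run_psa(w$exam, w$interview, w$population, w$costs, n_reps = 30, seed = 5)
  b <- run_psa(w$exam, w$interview, w$population, w$costs, n_reps = 30, seed = 5)
  expect_identical(a$national, b$national)
  expect_identical(a$state, b$state)
  expect_equal(a$n_failed, 0)

  frozen <- w$costs
  frozen$costs$distribution <- "fixed"
  frozen$delta_mn$distribution <- "fixed"
  c1 <- run_psa(w$exam, w$interview, w$population, frozen, n_reps = 1,
                seed = 5, bootstrap = FALSE)
  expect_equal(c1$national$cost_total_lower, c1$national$cost_total, tolerance = 1e-12)
  expect_equal(c1$national$cost_total_upper, c1$national$cost_total, tolerance = 1e-12)
  # turning off all randomness reproduces the deterministic pipeline
  det <- compute_burden(estimate_pmn(w$exam), estimate_rho(w$interview, w$exam),
                        w$population, w$costs)
  expect_equal(c1$national$cost_total, det$national$cost_total, tolerance = 1e-12)
})

test_that("varying the global multiplier widens the national interval", {
  w <- tiny_world(n_exam = 2000, n_int = 3000)
  held <- run_psa(w$exam, w$interview, w$population, w$costs, n_reps = 80,
                  seed = 9, vary_global_delta = FALSE)
  varied <- run_psa(w$exam, w$interview, w$population, w$costs, n_reps = 80,
                    seed = 9, vary_global_delta = TRUE)
  width <- function(x) x$national$cost_total_upper - x$national$cost_total_lower
  expect_gt(width(varied), width(held))
})

test_that("interval width shrinks as the examination survey grows", {
  widths <- vapply(c(3000, 12000), function(n) {
    truth <- synth_truth(states = synth_states("Solo", 1e6))
    exam <- generate_examination_survey(truth, n, seed = 60)
    intv <- generate_interview_survey(truth, 12000, seed = 61)
    p <- run_psa(exam, intv, generate_population(truth), truth$cost_params,
                 n_reps = 60, seed = 62, vary_costs = FALSE)
    p$national$cost_total_upper - p$national$cost_total_lower
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("PSA results expose tidy and glance views", {
  w <- tiny_world(n_exam = 1500, n_int = 2000)
  p <- run_psa(w$exam, w$interview, w$population, w$costs, n_reps = 10, seed = 3)
  expect_s3_class(tidy(p), "tbl_df")
  expect_true(all(c("cost_total_lower", "cost_total_upper") %in% names(tidy(p))))
  expect_equal(nrow(tidy(p, "replicates")), 10 * 2)
  expect_equal(glance(p)$n_used, 10)
  expect_s3_class(autoplot(p), "ggplot")
})
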