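srs_records <- function(y, w = rep(1, length(y)), dom = rep(TRUE, length(y))) {
  tibble::tibble(y = y, sample_weight = w, dom = dom,
                 stratum_id = "S1", cluster_id = seq_along(y))
}

test_that("weighted prevalence equals hand-computed ratios on small inputs", {
  expect_equal(weighted_domain_prevalence(srs_records(c(1, 0, 1, 0)), y)$estimate, 0.5)
  expect_equal(weighted_domain_prevalence(srs_records(c(1, 0), w = c(3, 1)), y)$estimate, 0.75)

  # brute force on random <= 12-record inputs, full precision
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    y <- sample(c(0, 1, NA), n, replace = TRUE, prob = c(.4, .4, .2))
    w <- round(runif(n, 0.5, 5), 2)
    dom <- sample(c(TRUE, FALSE), n, replace = TRUE)
    est <- weighted_domain_prevalence(srs_records(y, w, dom), y, dom)
    keep <- dom & !is.na(y)
    if (any(keep)) {
      expect_identical(est$estimate, sum(w[keep] * y[keep]) / sum(w[keep]))
      expect_equal(est$n_effective, sum(keep))
    } else {
      expect_true(est$empty)
      expect_true(is.na(est$estimate))
    }
  }
})

test_that("estimates are weight-scale invariant and confined to [0, 1]", {
  truth <- synth_truth()
  exam <- generate_examination_survey(truth, 3000, seed = 41)
  cl <- classify_malnutrition(exam)
  a <- weighted_domain_prevalence(cl, malnourished, flag_dementia)
  cl2 <- dplyr::mutate(cl, sample_weight = sample_weight * 773.1)
  b <- weighted_domain_prevalence(cl2, malnourished, flag_dementia)
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_true(a$estimate >= 0 && a$estimate <= 1)

  pmn <- estimate_pmn(exam)
  pmn2 <- estimate_pmn(dplyr::mutate(exam, sample_weight = sample_weight * 10))
  expect_equal(pmn$estimate, pmn2$estimate, tolerance = 1e-12)
  expect_true(all(pmn$estimate >= 0 & pmn$estimate <= 1, na.rm = TRUE))
})

test_that("empty domains are flagged, never silent zeros", {
  r <- srs_records(c(1, 0, 1))
  out <- weighted_domain_prevalence(r, y, sample_weight > 99)
  expect_true(out$empty)
  expect_true(is.na(out$estimate))
  expect_equal(out$n_effective, 0)
})

test_that("linearized SE matches the stratified two-cluster hand formula", {
  # 2 strata x 2 clusters, computed by hand from the linearization:
  # z_k = w_k (y_k - p); cluster totals t_hc; var = sum_h 2 * sum_c (t_hc - mean)^2 / W^2
  df <- tibble::tibble(
    y = c(1, 0, 1, 1, 0, 0, 1, 0),
    sample_weight = c(2, 1, 1, 2, 1, 1, 2, 2),
    stratum_id = rep(c("a", "b"), each = 4),
    cluster_id = rep(c("c1", "c2", "c3", "c4"), each = 2)
  )
  got <- weighted_domain_prevalence(df, y)
  p <- sum(df$sample_weight * df$y) / sum(df$sample_weight)
  z <- df$sample_weight * (df$y - p)
  t_hc <- tapply(z, df$cluster_id, sum)
  v <- 0
  for (h in c("a", "b")) {
    cl <- if (h == "a") c("c1", "c2") else c("c3", "c4")
    v <- v + 2 * sum((t_hc[cl] - mean(t_hc[cl]))^2)
  }
  expect_equal(got$estimate, p)
  expect_equal(got$se, sqrt(v) / sum(df$sample_weight), tolerance = 1e-12)
})

test_that("degenerate designs fall back to the weighted binomial SE", {
  df <- tibble::tibble(y = c(1, 0, 1, 0, 1), sample_weight = c(1, 2, 3, 1, 1),
                       stratum_id = 1:5, cluster_id = 1)
  got <- weighted_domain_prevalence(df, y)
  p <- got$estimate
  expect_equal(got$se, sqrt(p * (1 - p) * sum(df$sample_weight^2)) /
                 sum(df$sample_weight), tolerance = 1e-12)
})

test_that("sparse PMN cells climb the pooling ladder deterministically", {
  truth <- synth_truth()
  exam <- generate_examination_survey(truth, 3000, seed = 44)
  pmn <- estimate_pmn(exam, min_cell_n = 10)
  expect_true(all(pmn$pooling %in% c("none", "race", "sex", "marginal")))
  # colorectal cancer in children is absent: those cells must be pooled
  child_crc <- dplyr::filter(pmn, disease == "colorectal_cancer", age_band == "0-18")
  expect_true(all(child_crc$pooling != "none"))
  # a pooled estimate equals the estimate over its pooled domain, by hand
  cl <- classify_malnutrition(exam)
  row <- dplyr::filter(pmn, pooling == "sex")[1, ]
  if (nrow(row) == 1 && !is.na(row$estimate)) {
    dom <- cl[[paste0("flag_", row$disease)]] & cl$age_band == row$age_band
    hand <- weighted_domain_prevalence(cl, malnourished, !!dom)
    expect_equal(row$estimate, hand$estimate, tolerance = 1e-12)
  }
  # with everything present at pmn 0, all estimates are exactly 0
  t0 <- flat_truth(pmn_value = 0, rho_value = 0.3)
  e0 <- generate_examination_survey(t0, 2000, seed = 45)
  pmn0 <- estimate_pmn(e0)
  expect_true(all(pmn0$estimate == 0, na.rm = TRUE))
})

test_that("disease prevalence routes by declared source with child fallback", {
  truth <- synth_truth()
  exam <- generate_examination_survey(truth, 4000, seed = 47)
  intv <- generate_interview_survey(truth, 4000, seed = 48)

  # an interview table where dementia flags are all TRUE must not affect
  # dementia estimates (dementia is examination-sourced)
  intv_poison <- dplyr::mutate(intv, flag_dementia = TRUE)
  rho_a <- estimate_rho(intv, exam)
  rho_b <- estimate_rho(intv_poison, exam)
  dem_a <- dplyr::filter(rho_a, disease == "dementia")
  dem_b <- dplyr::filter(rho_b, disease == "dementia")
  expect_equal(dem_a$estimate, dem_b$estimate)
  expect_true(all(dem_a$source == "examination"))

  # interview-sourced diseases use the exam survey for child cells only
  stroke <- dplyr::filter(rho_a, disease == "stroke")
  expect_true(all(stroke$source[stroke$age_band == "0-18"] == "examination"))
  expect_true(all(stroke$source[stroke$age_band != "0-18"] == "interview"))

  # identical surveys passed as both sources: routing cannot matter
  exam_as_both <- dplyr::select(exam, -dplyr::any_of("latent_malnourished"))
  rho_same <- estimate_rho(exam_as_both, exam_as_both)
  rho_swap <- estimate_rho(exam_as_both,
                           dplyr::mutate(exam_as_both, person_id = paste0("X", person_id)))
  expect_equal(rho_same$estimate, rho_swap$estimate)
})

test_that("excluding children removes the 0-18 band from PMN estimation", {
  truth <- synth_truth()
  exam <- generate_examination_survey(truth, 4000, seed = 49)
  pmn <- estimate_pmn(exam, exclude_children = TRUE)
  kids <- dplyr::filter(pmn, age_band == "0-18")
  # child entries exist but are pooled from adult data
  expect_true(all(kids$pooling == "marginal" | kids$n_effective == 0 |
                    kids$pooling %in% c("race", "sex")))
  cl <- classify_malnutrition(exam)
  adult_dom <- cl$flag_copd & cl$age_band != "0-18"
  hand <- weighted_domain_prevalence(dplyr::filter(cl, age_band != "0-18"),
                                     malnourished, flag_copd)
  marg <- dplyr::filter(pmn, disease == "copd", pooling == "marginal")
  if (nrow(marg)) expect_equal(marg$estimate[1], hand$estimate, tolerance = 1e-12)
})
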