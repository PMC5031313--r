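test_that("attributable fraction matches its closed form and limits", {
  expect_equal(attributable_fraction(0, 2.0), 0)
  expect_equal(attributable_fraction(0.7, 0), 0)
  # half of patients cost double: a third of spending is attributable
  expect_equal(attributable_fraction(0.5, 1.0), 1 / 3, tolerance = 1e-12)
  # approaches 1 from below as the excess cost grows
  expect_lt(attributable_fraction(1.0, 1e9), 1)
  expect_gt(attributable_fraction(1.0, 1e9), 0.999999)
  # strictly increasing in each argument
  expect_gt(attributable_fraction(0.4, 1), attributable_fraction(0.3, 1))
  expect_gt(attributable_fraction(0.4, 2), attributable_fraction(0.4, 1))
  expect_error(attributable_fraction(1.2, 1), "\\[0, 1\\]")
  expect_error(attributable_fraction(0.5, -1), ">= 0")
})

test_that("cell cost equals the individual-level enumeration", {
  # 100 patients, half malnourished at double cost, average 1000:
  # baseline c = 666.67, excess = 50 * c = 33,333.33
  expect_equal(cell_cost(1000, 0.5, 1, 0.1, 1000),
               oracle_micro_cell(1000, 1, 1000, 100, 50), tolerance = 1e-12)
  expect_equal(cell_cost(1000, 0.5, 1, 0.1, 1000), 100000 / 3, tolerance = 1e-12)
  expect_equal(cell_cost(1000, 0.5, 1, 0, 1000), 0)
  expect_equal(cell_cost(1000, 0.5, 1, 0.1, 0), 0)

  # randomized parameter sets against the enumeration oracle
  set.seed(77)
  for (i in 1:200) {
    pop <- sample(100:50000, 1)
    n_pat <- sample(1:pop, 1)
    n_mal <- sample(0:n_pat, 1)
    C <- runif(1, 500, 60000)
    d <- runif(1, 0, 3)
    expect_equal(cell_cost(C, n_mal / n_pat, d, n_pat / pop, pop),
                 oracle_micro_cell(C, d, pop, n_pat, n_mal),
                 tolerance = 1e-12)
  }
})

test_that("a single nonzero cell reduces compute_burden to cell_cost", {
  truth <- synth_truth(states = synth_states("Solo", 0))
  pop <- truth$states
  pop$count <- ifelse(pop$age_band == "65+" & pop$sex == "female" &
                        pop$race == "white", 10000, 0)
  b <- compute_burden(truth$pmn, truth$rho, pop, truth$cost_params)
  pmn_v <- truth$pmn$pmn[truth$pmn$disease == "dementia" &
                           truth$pmn$age_band == "65+" &
                           truth$pmn$sex == "female" & truth$pmn$race == "white"]
  rho_v <- truth$rho$rho[truth$rho$disease == "dementia" &
                           truth$rho$age_band == "65+" &
                           truth$rho$sex == "female" & truth$rho$race == "white"]
  dem <- dplyr::filter(b$state_disease, disease == "dementia")
  expect_equal(dem$cost_total, cell_cost(36397, pmn_v, 0.5, rho_v, 10000),
               tolerance = 1e-12)
})

test_that("burden is homogeneous in population and conserves across roll-ups", {
  w <- tiny_world()
  b <- compute_burden(w$truth$pmn, w$truth$rho, w$population, w$costs)
  doubled <- dplyr::mutate(w$population, count = count * 2)
  b2 <- compute_burden(w$truth$pmn, w$truth$rho, doubled, w$costs)
  expect_equal(b2$national$cost_total, 2 * b$national$cost_total, tolerance = 1e-12)
  expect_equal(b2$state$per_capita, b$state$per_capita, tolerance = 1e-12)

  # conservation: national = sum of states = sum of diseases = sum of cells
  expect_equal(b$national$cost_total, sum(b$state$cost_total), tolerance = 1e-12)
  expect_equal(b$national$cost_total, sum(b$national_disease$cost_total),
               tolerance = 1e-12)
  expect_equal(b$national$cost_total, sum(b$cell$cost), tolerance = 1e-12)
  expect_equal(b$state$cost_total,
               dplyr::summarise(dplyr::group_by(b$state_disease, state),
                                s = sum(cost_total))$s, tolerance = 1e-12)
  expect_true(all(b$state$cost_65plus <= b$state$cost_total))
  expect_true(all(b$cell$cost >= 0))
})

test_that("burden is monotone in every parameter", {
  w <- tiny_world()
  base <- compute_burden(w$truth$pmn, w$truth$rho, w$population, w$costs)
  up_pmn <- compute_burden(dplyr::mutate(w$truth$pmn, pmn = pmin(pmn + 0.1, 1)),
                           w$truth$rho, w$population, w$costs)
  up_rho <- compute_burden(w$truth$pmn,
                           dplyr::mutate(w$truth$rho, rho = pmin(rho + 0.05, 1)),
                           w$population, w$costs)
  costs_up <- w$costs
  costs_up$costs$mean_annual_cost <- costs_up$costs$mean_annual_cost * 1.3
  up_C <- compute_burden(w$truth$pmn, w$truth$rho, w$population, costs_up)
  up_d <- compute_burden(w$truth$pmn, w$truth$rho, w$population, w$costs,
                         delta_mn = 0.9)
  for (b2 in list(up_pmn, up_rho, up_C, up_d)) {
    expect_gt(b2$national$cost_total, base$national$cost_total)
  }
})

test_that("with age-constant prevalences the 65+ cost share equals the population share", {
  t_flat <- flat_truth(pmn_value = 0.1, rho_value = 0.05)
  b <- compute_burden(t_flat$pmn, t_flat$rho, t_flat$states, t_flat$cost_params)
  pop_share <- sum(t_flat$states$count[t_flat$states$age_band == "65+"]) /
    sum(t_flat$states$count)
  expect_equal(b$national$share_65plus, pop_share, tolerance = 1e-9)
})

test_that("missing prevalence entries and unknown states are errors", {
  w <- tiny_world()
  holey <- w$truth$pmn
  holey$pmn[holey$disease == "stroke" & holey$age_band == "65+" &
              holey$sex == "male" & holey$race == "white"] <- NA
  expect_error(compute_burden(holey, w$truth$rho, w$population, w$costs),
               "stroke.*65\\+")
  expect_error(compute_burden(w$truth$pmn, w$truth$rho, w$population, w$costs,
                              states = "Nowhere"), "Nowhere")
})

test_that("tidy, glance and autoplot expose the burden result", {
  w <- tiny_world()
  b <- compute_burden(w$truth$pmn, w$truth$rho, w$population, w$costs)
  expect_s3_class(tidy(b), "tbl_df")
  expect_equal(nrow(tidy(b)), 16)
  expect_equal(nrow(tidy(b, "state")), 2)
  expect_equal(nrow(glance(b)), 1)
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(plot_disease_decomposition(b), "ggplot")
})
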