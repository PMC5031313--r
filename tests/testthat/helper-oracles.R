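# Shared fixtures and independent oracles. Oracles deliberately use plain
# base-R loops / closed forms, never the package's vectorized code paths.

# Closed-form total DAM cost from ground-truth parameter tables:
# sum_states sum_i sum_j C_i * AF(PMN_ij, dMN) * rho_ij * POP_j,
# evaluated entry by entry.
oracle_burden_total <- function(truth, only_65plus = FALSE) {
  st <- as.data.frame(truth$states)
  if (only_65plus) st <- st[st$age_band == "65+", ]
  pm <- as.data.frame(truth$pmn)
  rh <- as.data.frame(truth$rho)
  cc <- as.data.frame(truth$cost_params$costs)
  dmn <- delta_mn_by_disease(truth$cost_params)
  total <- 0
  for (k in seq_len(nrow(st))) {
    for (i in seq_len(nrow(cc))) {
      d <- as.character(cc$disease[i])
      sel <- pm$disease == d & pm$age_band == as.character(st$age_band[k]) &
        pm$sex == as.character(st$sex[k]) & pm$race == as.character(st$race[k])
      pmn <- pm$pmn[sel]
      rho <- rh$rho[rh$disease == d & rh$age_band == as.character(st$age_band[k]) &
                      rh$sex == as.character(st$sex[k]) &
                      rh$race == as.character(st$race[k])]
      af <- pmn * dmn[[d]] / (1 + pmn * dmn[[d]])
      total <- total + cc$mean_annual_cost[i] * af * rho * st$count[k]
    }
  }
  total
}

# Individual-level enumeration oracle for one cell: n_pat diseased persons
# in a population of pop, n_mal of them malnourished; the per-person cost c
# is calibrated so that mean spending equals C; the malnutrition-attributable
# excess is the total spent above what the same patients would cost
# non-malnourished.
oracle_micro_cell <- function(C, d_mn, pop, n_pat, n_mal) {
  stopifnot(n_mal <= n_pat, n_pat <= pop)
  c_base <- C * n_pat / ((n_pat - n_mal) + n_mal * (1 + d_mn))
  n_mal * c_base * d_mn
}

# A small, fully materialized world shared by several tests.
tiny_world <- function(seed = 11, n_exam = 4000, n_int = 6000,
                       states = synth_states(c("Alpha", "Beta"), c(5e5, 2e5))) {
  truth <- synth_truth(states = states)
  list(truth = truth,
       exam = generate_examination_survey(truth, n_exam, seed = seed),
       interview = generate_interview_survey(truth, n_int, seed = seed + 1),
       population = generate_population(truth),
       costs = truth$cost_params)
}

# Ground truth with a single constant PMN / rho for sharp recovery checks.
flat_truth <- function(pmn_value, rho_value, states = synth_states("Solo", 1e6),
                       design = list()) {
  cells <- dam_cells()
  pmn <- do.call(rbind, lapply(damcost:::DISEASES, function(d)
    cbind(cells, disease = d, pmn = pmn_value)))
  rho <- do.call(rbind, lapply(damcost:::DISEASES, function(d)
    cbind(cells, disease = d, rho = rho_value)))
  synth_truth(rho = rho, pmn = pmn, states = states, design = design)
}
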