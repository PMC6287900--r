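test_that("expenditure decomposition reproduces the published increments", {
  expect_equal(round(cost_decomposition(359, 0.61)), 136)  # national
  expect_equal(round(cost_decomposition(977, 0.61)), 370)  # high-expenditure
  expect_equal(round(cost_decomposition(243, 0.61)), 92)   # low-expenditure
  expect_equal(cost_decomposition(500, 0), 0)
  expect_error(cost_decomposition(0, 0.61), "he1")
  expect_error(cost_decomposition(359, -1), "growth rate")
})

test_that("mortality and incidence adjustments clamp to the probability scale", {
  expect_equal(adjusted_mortality(0.005, -0.10), 0.0049)
  expect_equal(adjusted_mortality(0.0005, -1.0), 0)
  q <- c(0, 0.2, 0.97, 1)
  expect_equal(adjusted_mortality(q, 0), q)
  expect_equal(adjusted_mortality(0.9995, 40), 1)
  expect_error(adjusted_mortality(1.2, 0), "\\[0, 1\\]")

  expect_equal(adjusted_incidence(0.10, 0.98, "NCMS"), 0.098)
  expect_equal(adjusted_incidence(0.10, 0.98, "no-NCMS"), 0.10)
  expect_equal(adjusted_incidence(0.9, 1.5, "NCMS"), 1.0)
  expect_error(adjusted_incidence(-0.1, 0.98, "NCMS"), "\\[0, 1\\]")
  expect_error(adjusted_incidence(0.1, 0, "NCMS"), "rr")
})

test_that("labor gain follows the band-specific monetization", {
  labor <- default_parameters()$labor
  expect_equal(labor_gain(25, labor), 0)
  expect_equal(labor_gain(35, labor), 0.13 * 1029 + 1.10 * 1.44)  # 135.354
  expect_equal(labor_gain(55, labor), 0.07 * 1029 + 1.28 * 1.44)  # 73.8732
  expect_equal(labor_gain(c(20, 30, 49, 50, 99), labor),
               c(0, 135.354, 135.354, 73.8732, 73.8732))
})

test_that("per-cycle rewards honour state occupancies and arm", {
  p <- default_parameters()
  dead <- cycle_rewards(c(0, 0, 1), 40, "NCMS", p)
  expect_equal(dead$qaly, 0)
  expect_equal(unname(dead$costs), c(0, 0, 0))

  norm <- cycle_rewards(c(1, 0, 0), 25, "no-NCMS", p)
  expect_equal(norm$qaly, 0.98)
  expect_equal(unname(norm$costs), c(0, 0, 0))

  hyp <- cycle_rewards(c(0, 1, 0), 40, "no-NCMS", p)
  expect_equal(hyp$qaly, 0.92)
  expect_equal(hyp$costs[["htn_medical"]], 392)
  expect_equal(hyp$costs[["extra_health_expenditure"]], 0)

  hyp_ncms <- cycle_rewards(c(0, 1, 0), 40, "NCMS", p)
  expect_equal(hyp_ncms$costs[["extra_health_expenditure"]],
               cost_decomposition(359, 0.61))
  expect_equal(hyp_ncms$costs[["labor_benefit"]], -labor_gain(40, p$labor))
})

test_that("an immortal cohort earns the annuity of its utility", {
  p80 <- tiny_params(q = 0, inc = 0, n_cycles = 80, u_n = 1, r = 0)
  out <- run_cohort(p80, "no-NCMS", "male")$outcome
  expect_equal(out$qalys, 80)

  p80d <- tiny_params(q = 0, inc = 0, n_cycles = 80, u_n = 1, r = 0.03)
  outd <- run_cohort(p80d, "no-NCMS", "male")$outcome
  expect_equal(outd$qalys, sum(1.03^-(0:79)))   # ~33.666
})

test_that("the engine matches the transition-matrix oracle to 1e-12", {
  # 3-cycle miniature from first principles: q = 0.1 flat, incidence 0.2
  # flat, utilities (1, 0.9), expenditure increment 100, hypertension
  # cost 50, no discounting
  p <- tiny_params(q = 0.1, inc = 0.2, n_cycles = 3, u_n = 1, u_h = 0.9,
                   r = 0, dhe = 100, htn_cost = 50)
  for (timing in c("start", "end", "half")) {
    conv <- cycle_conventions(timing)
    got <- run_cohort(p, "no-NCMS", "male", conv)
    want <- oracle_run(rep(0.1, 3), rep(0.2, 3), 1, 0.9, 0,
                       dhe = 0, htn_cost = 50, timing = timing)
    expect_equal(got$outcome$qalys, want$qalys, tolerance = 1e-12)
    expect_equal(got$outcome$cost_total, want$cost_total, tolerance = 1e-12)
    expect_equal(as.matrix(got$trace[, 3:5]), want$trace,
                 tolerance = 1e-12, ignore_attr = TRUE)

    gotn <- run_cohort(p, "NCMS", "male", conv)
    wantn <- oracle_run(rep(0.1, 3), rep(0.2, 3), 1, 0.9, 0,
                        dhe = 100, htn_cost = 50, timing = timing)
    expect_equal(gotn$outcome$qalys, wantn$qalys, tolerance = 1e-12)
    expect_equal(gotn$outcome$cost_total, wantn$cost_total, tolerance = 1e-12)
  }
})

test_that("program-arm adjustments match the oracle on a 5-cycle model", {
  # nonzero mortality effect (-5 per 1,000), risk ratio 0.9, discounting
  p <- tiny_params(q = 0.05, inc = 0.1, n_cycles = 5, u_n = 0.98, u_h = 0.92,
                   r = 0.03, eff = -5, rr = 0.9, dhe = 40, htn_cost = 25)
  got <- run_cohort(p, "NCMS", "female")
  want <- oracle_run(rep(0.05 - 5 / 1000, 5), rep(0.1 * 0.9, 5), 0.98, 0.92,
                     0.03, dhe = 40, htn_cost = 25)
  expect_equal(got$outcome$qalys, want$qalys, tolerance = 1e-12)
  expect_equal(got$outcome$cost_total, want$cost_total, tolerance = 1e-12)
  expect_equal(got$outcome$cost_components[["htn_medical"]], want$htn,
               tolerance = 1e-12)
  expect_equal(got$outcome$cost_components[["extra_health_expenditure"]],
               want$ehe, tolerance = 1e-12)
})

test_that("traces conserve occupancy and deaths never decrease", {
  p <- default_parameters()
  for (arm in c("NCMS", "no-NCMS")) {
    for (sex in c("male", "female")) {
      tr <- run_cohort(p, arm, sex)$trace
      occ <- tr$occ_normotensive + tr$occ_hypertensive + tr$occ_dead
      expect_true(all(abs(occ - 1) < 1e-12))
      expect_true(all(diff(tr$occ_dead) > 0))   # positive mortality everywhere
      expect_true(all(tr$occ_normotensive >= 0 & tr$occ_hypertensive >= 0))
    }
  }
})

test_that("discounting is monotone for nonnegative reward streams", {
  qalys_at <- function(r) {
    p <- default_parameters()
    p$econ$discount_rate <- uv0(r)
    m <- run_model(p)
    c(q_c = m$control$qalys, q_n = m$ncms$qalys,
      htn = m$control$cost_components[["htn_medical"]])
  }
  v0 <- qalys_at(0); v3 <- qalys_at(0.03); v5 <- qalys_at(0.05)
  expect_true(all(v0 >= v3) && all(v3 >= v5))
})

test_that("beneficial effects push program-arm QALYs above the comparator", {
  p <- default_parameters()
  for (s in c("male", "female")) {
    for (b in c("b20_44", "b45_59", "b60p")) {
      p$effects$mortality[[s]][[b]] <- uncertain_value(-0.2, -0.3, -0.1)
    }
  }
  p$effects$rr_hypertension <- uncertain_value(0.95, 0.95, 0.98)
  m <- run_model(p)
  expect_gt(m$ncms$qalys, m$control$qalys)
})

test_that("costs scale with currency while QALYs are invariant", {
  k <- 2.5
  p <- default_parameters()
  pk <- p
  for (id in c("he1", "htn_annual_cost", "annual_wage", "agri_hourly")) {
    uv <- get_param(p, id)
    pk <- ncmscea:::.poke(pk, ncmscea:::.uv_paths[[id]],
                          uncertain_value(uv$base * k, uv$low * k, uv$high * k))
  }
  m <- run_model(p); mk <- run_model(pk)
  expect_equal(mk$ncms$cost_total, k * m$ncms$cost_total)
  expect_equal(mk$control$cost_total, k * m$control$cost_total)
  expect_equal(mk$incremental$d_cost, k * m$incremental$d_cost)
  expect_equal(mk$ncms$qalys, m$ncms$qalys)
  expect_equal(mk$incremental$d_qaly, m$incremental$d_qaly)
})

test_that("arm outcomes reconcile: total equals the sum of components", {
  m <- run_model(default_parameters())
  for (arm in list(m$ncms, m$control)) {
    expect_equal(arm$cost_total, sum(arm$cost_components), tolerance = 1e-9)
    expect_gte(arm$qalys, 0)
  }
  expect_lte(m$ncms$cost_components[["labor_benefit"]], 0)
  expect_equal(m$control$cost_components[["extra_health_expenditure"]], 0)
})
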