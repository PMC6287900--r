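test_that("triangular inverse-CDF sampling matches the closed form", {
  expect_equal(sample_triangular(c(0, 1, 2), 0.5), 1)      # symmetric median
  expect_equal(sample_triangular(c(5, 5, 5), 0.123), 5)    # point mass
  expect_equal(sample_triangular(c(0, 0, 1), 0.25), 1 - sqrt(0.75))
  expect_equal(sample_triangular(c(0, 1, 1), 0.25), sqrt(0.25))
  expect_equal(sample_triangular(uncertain_value(0.98, 0.95, 1.00), 0), 0.95)
  expect_equal(sample_triangular(uncertain_value(0.98, 0.95, 1.00), 1), 1.00)
  expect_error(sample_triangular(c(2, 1, 0), 0.5), "low <= mode <= high")
  expect_error(sample_triangular(c(0, 1, 2), 1.5), "\\[0, 1\\]")
})

test_that("the sampler's empirical mean and support agree with theory", {
  set.seed(101)
  n <- 1e5
  for (spec in list(c(-3.01, 0.36, 3.73), c(0.95, 0.98, 1.00),
                    c(243, 359, 977))) {
    x <- sample_triangular(spec, stats::runif(n))
    a <- spec[1]; cc <- spec[2]; b <- spec[3]
    expect_true(all(x >= a & x <= b))
    mu <- (a + b + cc) / 3
    sigma <- sqrt((a^2 + b^2 + cc^2 - a * b - a * cc - b * cc) / 18)
    expect_lt(abs(mean(x) - mu), 3 * sigma / sqrt(n))
  }
})

test_that("one-way analysis pins a single parameter at its bounds", {
  p <- default_parameters()
  base <- run_model(p)$incremental

  # degenerate parameter: both endpoints reproduce the base case
  ow <- one_way(p, "u_normotensive")
  expect_equal(ow$at_low$incremental$icer, base$icer)
  expect_equal(ow$at_high$incremental$icer, base$icer)

  # lower expenditure growth means a smaller program increment
  owg <- one_way(p, "growth_rate")
  expect_lt(owg$at_low$incremental$d_cost, base$d_cost)
  expect_gt(owg$at_high$incremental$d_cost, base$d_cost)
  expect_equal(owg$at_low$incremental$d_cost,
               run_model(set_param(p, "growth_rate", 0.50))$incremental$d_cost)
  expect_error(one_way(p, "nonexistent"), "unknown parameter")
})

test_that("tornado ranking matches spans computed by direct model calls", {
  p <- default_parameters()
  tn <- tornado(p)
  expect_setequal(tn$summary$parameter, param_ids())
  expect_false(is.unsorted(rev(tn$summary$span)))   # descending (Inf-safe)

  # independent span computation for two parameters by direct model calls
  for (id in c("he1", "u_hypertensive")) {
    uv <- get_param(p, id)
    lo <- run_model(set_param(p, id, uv$low))$incremental
    hi <- run_model(set_param(p, id, uv$high))$incremental
    row <- tn$summary[tn$summary$parameter == id, ]
    expect_equal(row$icer_low, lo$icer)
    expect_equal(row$icer_high, hi$icer)
    if (is.finite(row$span)) {
      expect_equal(row$span, abs(hi$icer - lo$icer))
    }
  }

  # degenerate parameters have zero span and sink to the bottom
  expect_equal(tn$summary$span[tn$summary$parameter == "u_normotensive"], 0)
})

test_that("PSA is deterministic in its seed and degenerate without uncertainty", {
  p <- default_parameters()
  a <- run_psa(p, n = 150, seed = 11)
  b <- run_psa(p, n = 150, seed = 11)
  expect_identical(a, b)
  c <- run_psa(p, n = 150, seed = 12)
  expect_false(identical(a$draws$d_cost, c$draws$d_cost))

  pd <- p   # collapse every triangular to a point mass at base
  for (id in param_ids()) {
    uv <- get_param(pd, id)
    pd <- ncmscea:::.poke(pd, ncmscea:::.uv_paths[[id]], uv0(uv$base))
  }
  base <- run_model(pd)$incremental
  psa <- run_psa(pd, n = 25, seed = 5)
  expect_equal(psa$draws$d_cost, rep(base$d_cost, 25))
  expect_equal(psa$draws$d_qaly, rep(base$d_qaly, 25))
  cls <- classify(base$d_cost, psa$wtp, d_qaly = base$d_qaly)
  expect_equal(unname(psa$quadrant_probs[cls]), 1)
})

test_that("quadrant probabilities are empirical fractions summing to one", {
  wtp <- 37059
  expect_equal(
    unname(quadrant_probabilities(list(d_cost = -1, d_qaly = 0.1), wtp)),
    c(1, 0, 0, 0))
  expect_equal(
    unname(quadrant_probabilities(list(d_cost = c(-1, 1),
                                       d_qaly = c(0.1, -0.1)), wtp)),
    c(0.5, 0, 0, 0.5))
  # one hand-placed draw per category
  qp <- quadrant_probabilities(
    list(d_cost = c(-10, 100, 10000, 50), d_qaly = c(0.5, 0.5, 0.01, -0.2)),
    wtp)
  expect_equal(unname(qp), c(0.25, 0.25, 0.25, 0.25))
  expect_equal(sum(qp), 1)
  expect_error(quadrant_probabilities(list(d_cost = numeric(0),
                                           d_qaly = numeric(0)), wtp),
               "no draws")
})

test_that("the acceptability curve counts positive net benefit", {
  expect_equal(ceac(list(d_cost = 0, d_qaly = 1), 1)$acceptability, 1)
  expect_equal(ceac(list(d_cost = 10, d_qaly = 0),
                    c(0, 37059, 1e6))$acceptability, c(0, 0, 0))
  # non-decreasing in wtp when all draws gain QALYs
  set.seed(3)
  draws <- list(d_cost = stats::rnorm(500, 500, 800),
                d_qaly = stats::runif(500, 0.001, 0.05))
  acc <- ceac(draws, seq(0, 1e5, 5000))$acceptability
  expect_true(all(diff(acc) >= 0))
  expect_true(all(acc >= 0 & acc <= 1))
})

test_that("CEAC at the threshold agrees with the quadrant split", {
  psa <- run_psa(default_parameters(), n = 400, seed = 99)
  wtp <- psa$wtp
  at_wtp <- psa$ceac$acceptability[psa$ceac$wtp == wtp]
  qp <- psa$quadrant_probs
  expect_equal(sum(qp), 1)

  # On the QALY-gain half-plane, positive net benefit coincides with the
  # {dominant, cost-effective} classes (up to exact-boundary ties). Draws
  # losing QALYs can still carry positive net benefit when they save
  # enough cost, so the full identity adds that overlap.
  d <- psa$draws
  nmb <- net_monetary_benefit(d$d_cost, wtp, d_qaly = d$d_qaly)
  gain <- d$d_qaly > 0
  agree <- (nmb > 0) == (d$classification %in% c("dominant", "cost_effective"))
  expect_true(all(agree[gain & nmb != 0]))
  expect_equal(at_wtp,
               unname(qp["dominant"] + qp["cost_effective"]) +
                 mean(!gain & nmb > 0))
})
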