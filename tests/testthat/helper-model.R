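# Miniature parameter sets and an independent transition-matrix oracle,
# used to cross-check the cycle engine against explicit matrix powering.

uv0 <- function(x) uncertain_value(x, x, x)

# A tiny cohort world: flat annual death probability `q`, flat annual
# hypertension incidence `inc`, `n_cycles` one-year cycles, degenerate
# (point-mass) uncertainty everywhere. `eff` is the mortality effect
# (deaths per 1,000) applied in the program arm at every age; `dhe_g`
# with he1 = 2 * dhe gives an expenditure increment of exactly `dhe`.
tiny_params <- function(q = 0.1, inc = 0.2, n_cycles = 3, u_n = 1, u_h = 0.9,
                        r = 0, eff = 0, rr = 1, dhe = 0, htn_cost = 0,
                        wage = 0, agri = 0) {
  p <- default_parameters()
  ages <- seq.int(20L, 20L + n_cycles - 1L)
  p$econ$end_age <- 20L + n_cycles
  p$mortality <- data.frame(age = ages, male = q, female = q)
  p$incidence <- data.frame(age = ages, male = inc, female = inc)
  p$utilities$u_normotensive <- uv0(u_n)
  p$utilities$u_hypertensive <- uv0(u_h)
  p$econ$discount_rate <- uv0(r)
  for (s in c("male", "female")) {
    for (b in c("b20_44", "b45_59", "b60p")) {
      p$effects$mortality[[s]][[b]] <- uv0(eff)
    }
  }
  p$effects$rr_hypertension <- uv0(rr)
  if (dhe > 0) {
    p$costs$he1 <- uv0(2 * dhe)        # he1 - he1/(1+1) = he1/2
    p$costs$growth_rate <- uv0(1)
  } else {
    p$costs$he1 <- uv0(100)
    p$costs$growth_rate <- uv0(0)      # increment 0
  }
  p$costs$htn_annual_cost <- uv0(htn_cost)
  p$labor$annual_wage <- uv0(wage)
  p$labor$agri_hourly <- uv0(agri)
  validate_params(p)
}

# Independent oracle: explicit 3x3 transition matrices multiplied onto the
# occupancy row vector, rewards on the convention's occupancy basis.
# States: 1 normotensive, 2 hypertensive, 3 dead. Death first, then onset.
oracle_run <- function(qs, ps, u_n, u_h, r, dhe = 0, htn_cost = 0,
                       lg = rep(0, length(qs)), timing = "start") {
  n_cycles <- length(qs)
  occ <- c(1, 0, 0)
  trace <- matrix(NA_real_, n_cycles, 3)
  qaly <- ehe <- htn <- lab <- 0
  for (t in seq_len(n_cycles)) {
    q <- qs[t]; pinc <- ps[t]
    P <- rbind(c((1 - q) * (1 - pinc), (1 - q) * pinc, q),
               c(0, 1 - q, q),
               c(0, 0, 1))
    occ_end <- as.numeric(occ %*% P)
    basis <- switch(timing,
                    start = occ, end = occ_end,
                    half = (occ + occ_end) / 2)
    df <- if (timing == "end") (1 + r)^(-t) else (1 + r)^(-(t - 1))
    qaly <- qaly + df * (basis[1] * u_n + basis[2] * u_h)
    htn <- htn + df * basis[2] * htn_cost
    ehe <- ehe + df * (basis[1] + basis[2]) * dhe
    lab <- lab - df * (basis[1] + basis[2]) * lg[t]
    trace[t, ] <- occ
    occ <- occ_end
  }
  list(trace = trace, qalys = qaly, ehe = ehe, htn = htn, labor = lab,
       cost_total = ehe + htn + lab)
}
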