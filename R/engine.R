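#' Additional annual health expenditure attributable to the program
#'
#' Decomposes the observed post-program total health expenditure per rural
#' resident, `HE1`, into its pre-program level and the increment caused by
#' the program, using the expenditure growth rate `g` attributable to the
#' insurance scheme: the increment is `HE1 - HE1 / (1 + g)`. With the 2013
#' national figure of Int$359 and a 61% growth rate this gives about
#' Int$136 per resident-year (Int$370 for the Beijing expenditure level,
#' Int$92 for Guizhou).
#'
#' @param he1 Post-program total health expenditure per rural resident per
#'   year (Int$); must be positive.
#' @param g Growth rate attributable to the program (dimensionless, > -1).
#' @return Increment in Int$ per person-year. Vectorized.
#' @examples
#' cost_decomposition(359, 0.61) # ~136
#' @export
cost_decomposition <- function(he1, g) {
  stopifnot(is.numeric(he1), is.numeric(g))
  if (any(he1 <= 0)) stop("cost_decomposition: he1 must be > 0", call. = FALSE)
  if (any(g <= -1)) stop("cost_decomposition: growth rate must be > -1", call. = FALSE)
  he1 - he1 / (1 + g)
}

#' Apply the program's mortality effect to a background death probability
#'
#' The program's effect on mortality is published as a signed change in the
#' age-standardized mortality rate per 1,000 population per year. It is
#' applied additively on the annual probability scale and clamped to
#' `[0, 1]`. The comparator arm passes `effect = 0`.
#'
#' @param q Annual background death probability in `[0, 1]`.
#' @param effect Signed change in deaths per 1,000 population per year.
#' @return Adjusted probability. Vectorized.
#' @examples
#' adjusted_mortality(0.005, -0.10) # 0.0049
#' @export
adjusted_mortality <- function(q, effect) {
  if (any(q < 0 | q > 1)) stop("adjusted_mortality: q must lie in [0, 1]",
                               call. = FALSE)
  pmin(pmax(q + effect / 1000, 0), 1)
}

#' Apply the program's hypertension risk ratio to an annual incidence
#'
#' In the program arm the annual probability of becoming hypertensive is
#' multiplied by the risk ratio and clamped to `[0, 1]`; the comparator arm
#' is unchanged.
#'
#' @param p Annual incidence probability in `[0, 1]`.
#' @param rr Risk ratio (> 0).
#' @param arm `"NCMS"` or `"no-NCMS"`.
#' @return Adjusted probability. Vectorized over `p` and `rr`.
#' @examples
#' adjusted_incidence(0.10, 0.98, "NCMS") # 0.098
#' @export
adjusted_incidence <- function(p, rr, arm = c("NCMS", "no-NCMS")) {
  arm <- match.arg(arm)
  if (any(p < 0 | p > 1)) stop("adjusted_incidence: p must lie in [0, 1]",
                               call. = FALSE)
  if (any(rr <= 0)) stop("adjusted_incidence: rr must be > 0", call. = FALSE)
  if (arm == "NCMS") pmin(pmax(rr * p, 0), 1) else p
}

#' Annual labor-productivity gain attributable to the program
#'
#' Monetizes the program's labor effects for one person-year: the increase
#' in the probability of off-farm work times the annual wage, plus the
#' increase in agricultural hours times the hourly agricultural income.
#' The published labor effects cover two age bands (30-49 and 50+); ages
#' below 30 receive no labor benefit.
#'
#' @param age Age in years (vectorized).
#' @param labor The `labor` component of a parameter set (base values used).
#' @return Int$ per person-year.
#' @examples
#' labor_gain(35, default_parameters()$labor) # 0.13*1029 + 1.10*1.44
#' @export
labor_gain <- function(age, labor) {
  g1 <- labor$d_offfarm_p$b30_49$base * labor$annual_wage$base +
    labor$d_farm_hours$b30_49$base * labor$agri_hourly$base
  g2 <- labor$d_offfarm_p$b50p$base * labor$annual_wage$base +
    labor$d_farm_hours$b50p$base * labor$agri_hourly$base
  ifelse(age < 30, 0, ifelse(age < 50, g1, g2))
}

# Age-band indices used by the engine: mortality-effect bands (20-44,
# 45-59, 60+) and labor bands (<30 none, 30-49, 50+). Bands are
# channel-specific: age 45-49 sits in the 30-49 labor band but the 45-59
# mortality band.
.mort_band <- function(age) ifelse(age <= 44, 1L, ifelse(age <= 59, 2L, 3L))
.labor_band <- function(age) ifelse(age < 30, 0L, ifelse(age <= 49, 1L, 2L))

#' Cycle accounting conventions
#'
#' The reward-accrual convention of the annual-cycle cohort model. The
#' default (`"start"`) accrues rewards on start-of-cycle occupancies with
#' discount exponent `t` (t = 0 in the first cycle); `"end"` accrues on
#' end-of-cycle occupancies with exponent `t + 1`; `"half"` applies a
#' half-cycle correction (mean of start and end occupancies, exponent `t`).
#' Within every cycle death is applied first, from both living states with
#' the same probability, then hypertension onset among survivors; the newly
#' hypertensive earn hypertensive utility and cost from the next cycle on.
#'
#' @param timing One of `"start"`, `"end"`, `"half"`.
#' @return A list of class `cycle_conventions`.
#' @export
cycle_conventions <- function(timing = c("start", "end", "half")) {
  structure(list(timing = match.arg(timing)), class = "cycle_conventions")
}

#' Undiscounted per-cycle rewards for given state occupancies
#'
#' Returns the QALY increment and the cost increment by component for one
#' cycle spent at the given occupancies: utility-weighted life-years;
#' hypertension medical cost on the hypertensive occupancy (both arms);
#' and, in the program arm only, the per-resident expenditure increment on
#' all alive occupancy plus the labor-productivity gain (entered as a
#' negative cost).
#'
#' @param occ Numeric vector `c(normotensive, hypertensive, dead)` of
#'   cohort fractions (non-negative, summing to 1).
#' @param age Age at the cycle (years).
#' @param arm `"NCMS"` or `"no-NCMS"`.
#' @param p A parameter set (base values used).
#' @return List with `qaly` and `costs`, the latter a named vector
#'   `extra_health_expenditure`, `htn_medical`, `labor_benefit`.
#' @export
cycle_rewards <- function(occ, age, arm = c("NCMS", "no-NCMS"), p) {
  arm <- match.arg(arm)
  stopifnot(length(occ) == 3L, all(occ >= 0), abs(sum(occ) - 1) < 1e-9)
  alive <- occ[1L] + occ[2L]
  qaly <- occ[1L] * p$utilities$u_normotensive$base +
    occ[2L] * p$utilities$u_hypertensive$base
  htn <- occ[2L] * p$costs$htn_annual_cost$base
  if (arm == "NCMS") {
    ehe <- alive * cost_decomposition(p$costs$he1$base, p$costs$growth_rate$base)
    lab <- -alive * labor_gain(age, p$labor)
  } else {
    ehe <- 0
    lab <- 0
  }
  list(qaly = qaly,
       costs = c(extra_health_expenditure = ehe, htn_medical = htn,
                 labor_benefit = lab))
}

# Core cohort engine, vectorized over m parameter scenarios. Scalar
# arguments are the per-cycle schedules; everything in `pv` may be a
# length-m vector (PSA draws) or length-1 (base case). Death is applied
# first, then onset among survivors; rewards follow `timing`.
.cohort_engine <- function(qs, ps, band, lband, pv, ncms, timing,
                           trace = FALSE, start_age = 20L) {
  n_cycles <- length(qs)
  m <- length(pv$r)
  occ_n <- rep(1, m)
  occ_h <- numeric(m)
  qaly <- c_ehe <- c_htn <- c_lab <- numeric(m)
  effs <- pv$effs     # list of 3 vectors, per mortality band
  lgs <- list(0, pv$lg1, pv$lg2)
  if (trace) {
    tr <- matrix(NA_real_, n_cycles, 8L,
                 dimnames = list(NULL, c("occ_normotensive", "occ_hypertensive",
                                         "occ_dead", "qaly_disc",
                                         "cost_disc_extra_health_expenditure",
                                         "cost_disc_htn_medical",
                                         "cost_disc_labor_benefit",
                                         "cost_disc_total")))
  }
  for (t in seq_len(n_cycles)) {
    q <- if (ncms) pmin(pmax(qs[t] + effs[[band[t]]] / 1000, 0), 1) else qs[t]
    pinc <- if (ncms) pmin(pmax(pv$rr * ps[t], 0), 1) else ps[t]
    surv_n <- occ_n * (1 - q)
    n_end <- surv_n * (1 - pinc)
    h_end <- occ_h * (1 - q) + surv_n * pinc
    if (timing == "start") {
      b_n <- occ_n; b_h <- occ_h; df <- (1 + pv$r)^(-(t - 1))
    } else if (timing == "end") {
      b_n <- n_end; b_h <- h_end; df <- (1 + pv$r)^(-t)
    } else {
      b_n <- (occ_n + n_end) / 2; b_h <- (occ_h + h_end) / 2
      df <- (1 + pv$r)^(-(t - 1))
    }
    alive_b <- b_n + b_h
    dq <- df * (b_n * pv$u_n + b_h * pv$u_h)
    dhtn <- df * b_h * pv$htn_cost
    qaly <- qaly + dq
    c_htn <- c_htn + dhtn
    if (ncms) {
      dehe <- df * alive_b * pv$dhe
      dlab <- -df * alive_b * lgs[[lband[t] + 1L]]
      c_ehe <- c_ehe + dehe
      c_lab <- c_lab + dlab
    } else {
      dehe <- dlab <- 0
    }
    if (trace) {
      tr[t, ] <- c(occ_n[1L], occ_h[1L], 1 - occ_n[1L] - occ_h[1L],
                   dq[1L], dehe[1L], dhtn[1L], dlab[1L],
                   dehe[1L] + dhtn[1L] + dlab[1L])
    }
    occ_n <- n_end
    occ_h <- h_end
  }
  out <- list(qalys = qaly, ehe = c_ehe, htn = c_htn, labor = c_lab,
              surv = occ_n + occ_h)
  if (trace) {
    out$trace <- data.frame(cycle = seq_len(n_cycles) - 1L,
                            age = start_age + seq_len(n_cycles) - 1L,
                            tr, check.names = FALSE)
  }
  out
}

# Base-case parameter vectors (length 1 each) in the engine's layout.
.base_pv <- function(p) {
  b <- function(id) get_param(p, id)$base
  list(
    rr = b("rr_hypertension"),
    u_n = b("u_normotensive"),
    u_h = b("u_hypertensive"),
    dhe = cost_decomposition(b("he1"), b("growth_rate")),
    htn_cost = b("htn_annual_cost"),
    lg1 = b("d_offfarm_p_30_49") * b("annual_wage") +
      b("d_farm_hours_30_49") * b("agri_hourly"),
    lg2 = b("d_offfarm_p_50p") * b("annual_wage") +
      b("d_farm_hours_50p") * b("agri_hourly"),
    r = b("discount_rate"),
    eff = list(
      male = list(b("mort_male_20_44"), b("mort_male_45_59"), b("mort_male_60p")),
      female = list(b("mort_female_20_44"), b("mort_female_45_59"),
                    b("mort_female_60p"))))
}

.sex_schedules <- function(p, sex) {
  ages <- seq.int(p$econ$start_age, p$econ$end_age - 1L)
  list(ages = ages,
       qs = p$mortality[[sex]][match(ages, p$mortality$age)],
       ps = p$incidence[[sex]][match(ages, p$incidence$age)],
       band = .mort_band(ages),
       lband = .labor_band(ages))
}

.run_engine_sex <- function(p, pv, sex, ncms, conventions, trace = FALSE) {
  s <- .sex_schedules(p, sex)
  pv$effs <- pv$eff[[sex]]
  .cohort_engine(s$qs, s$ps, s$band, s$lband, pv, ncms, conventions$timing,
                 trace = trace, start_age = p$econ$start_age)
}

.arm_outcome <- function(eng) {
  cc <- c(extra_health_expenditure = eng$ehe, htn_medical = eng$htn,
          labor_benefit = eng$labor)
  structure(list(cost_total = sum(cc), qalys = eng$qalys,
                 cost_components = cc), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("Arm outcome: cost Int$%.2f, %.4f QALYs\n", x$cost_total, x$qalys))
  cc <- x$cost_components
  for (k in names(cc)) cat(sprintf("  %-25s %10.2f\n", k, cc[[k]]))
  invisible(x)
}

#' Run the cohort model for one arm and one sex
#'
#' Simulates the closed cohort through the three health states
#' (normotensive, hypertensive, dead) in annual cycles from `start_age`
#' until everyone has died or reached `end_age`, and accumulates discounted
#' QALYs and costs. Within each cycle death is applied first, from both
#' living states with the same probability (hypertension carries no excess
#' mortality), then hypertension onset among the surviving normotensives;
#' hypertension is absorbing among the living.
#'
#' @param p A validated parameter set.
#' @param arm `"NCMS"` (program arm: mortality effects, risk ratio, extra
#'   health expenditure and labor benefit all active) or `"no-NCMS"`.
#' @param sex `"male"` or `"female"`.
#' @param conventions A [cycle_conventions()] object.
#' @return A list with `trace` (one row per cycle: occupancies at cycle
#'   start plus discounted per-cycle rewards) and `outcome` (an
#'   `arm_outcome`: discounted totals and cost components).
#' @examples
#' res <- run_cohort(default_parameters(), "no-NCMS", "female")
#' head(res$trace)
#' @export
run_cohort <- function(p, arm = c("NCMS", "no-NCMS"),
                       sex = c("male", "female"),
                       conventions = cycle_conventions()) {
  arm <- match.arg(arm)
  sex <- match.arg(sex)
  validate_params(p)
  eng <- .run_engine_sex(p, .base_pv(p), sex, arm == "NCMS", conventions,
                         trace = TRUE)
  list(trace = eng$trace, outcome = .arm_outcome(eng))
}

# Sex-weighted arm totals for m scenarios; returns per-component vectors.
.eval_arms <- function(p, pv, conventions) {
  w <- p$econ$sex_weight_male
  out <- list()
  for (arm in c("ncms", "control")) {
    ncms <- arm == "ncms"
    em <- .run_engine_sex(p, pv, "male", ncms, conventions)
    ef <- .run_engine_sex(p, pv, "female", ncms, conventions)
    out[[arm]] <- list(
      qalys = w * em$qalys + (1 - w) * ef$qalys,
      ehe = w * em$ehe + (1 - w) * ef$ehe,
      htn = w * em$htn + (1 - w) * ef$htn,
      labor = w * em$labor + (1 - w) * ef$labor)
  }
  out$d_cost <- with(out, (ncms$ehe + ncms$htn + ncms$labor) -
                       (control$ehe + control$htn + control$labor))
  out$d_qaly <- out$ncms$qalys - out$control$qalys
  out
}

#' Run the full two-arm model
#'
#' Runs both arms for both sexes at base-case parameter values, averages the
#' sexes with the configured weights, and returns per-arm outcomes together
#' with the incremental comparison against the willingness-to-pay threshold.
#'
#' @inheritParams run_cohort
#' @return An object of class `ncms_cea`: `ncms` and `control`
#'   (`arm_outcome`s), `incremental` (see [incremental()]), `wtp`, and the
#'   conventions used.
#' @examples
#' run_model(default_parameters())
#' @export
run_model <- function(p, conventions = cycle_conventions()) {
  validate_params(p)
  ev <- .eval_arms(p, .base_pv(p), conventions)
  ncms <- .arm_outcome(ev$ncms)
  control <- .arm_outcome(ev$control)
  wtp <- wtp_threshold(p)
  structure(list(ncms = ncms, control = control,
                 incremental = incremental(ncms, control, wtp),
                 wtp = wtp, conventions = conventions),
            class = "ncms_cea")
}

#' @export
print.ncms_cea <- function(x, ...) {
  inc <- x$incremental
  cat("Two-arm cost-effectiveness analysis (lifetime, discounted)\n")
  cat(sprintf("  %-10s cost Int$%9.0f   QALYs %6.2f\n", "no-NCMS",
              x$control$cost_total, x$control$qalys))
  cat(sprintf("  %-10s cost Int$%9.0f   QALYs %6.2f\n", "NCMS",
              x$ncms$cost_total, x$ncms$qalys))
  cat(sprintf("  incremental: Int$%.0f, %.2f QALYs, ICER %s\n",
              inc$d_cost, inc$d_qaly,
              if (is.na(inc$icer)) "undefined"
              else sprintf("Int$%.0f/QALY", inc$icer)))
  cat(sprintf("  vs WTP Int$%s/QALY: %s\n",
              format(x$wtp, big.mark = ","), inc$classification))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param trace The `trace` data frame from [run_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
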