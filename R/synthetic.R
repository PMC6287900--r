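#' Specification of the synthetic demographic stand-ins
#'
#' The original analysis drew its background mortality from the 2013 China
#' life table and its hypertension onset probabilities from supplementary
#' schedules that are not redistributed with this package. This spec
#' parameterizes the synthetic stand-ins: a Gompertz-Makeham mortality
#' hazard `lambda + alpha * exp(beta * age)` (with a multiplicative female
#' hazard ratio) and a logistic annual hypertension incidence
#' `max_level / (1 + exp(-steepness * (age - midpoint)))`, the minimal
#' parametric shapes matching a national life table's age pattern and the
#' age-rising risk of hypertension. Defaults are tuned only so that life
#' expectancy at age 20 is demographically plausible for rural China in
#' 2013 (mid-50s of remaining years); they are not calibrated to any
#' published model output.
#'
#' @param lambda Age-independent (Makeham) hazard component, per year.
#' @param alpha Gompertz level parameter (> 0).
#' @param beta Gompertz slope, per year of age (> 0).
#' @param sex_gap Multiplicative female/male hazard ratio (> 0).
#' @param inc_max Asymptotic annual hypertension incidence in `[0, 1]`.
#' @param inc_mid Age at which incidence reaches half its maximum.
#' @param inc_steep Logistic steepness (> 0), per year of age.
#' @param seed Integer seed carried for downstream jittering.
#' @return An object of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(lambda = 1e-4, alpha = 3e-5, beta = 0.09,
                                  sex_gap = 0.8, inc_max = 0.05,
                                  inc_mid = 55, inc_steep = 0.08, seed = 0L) {
  stopifnot(lambda >= 0, alpha > 0, beta > 0, sex_gap > 0,
            inc_max >= 0, inc_max <= 1, inc_steep > 0)
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 sex_gap = sex_gap, inc_max = inc_max, inc_mid = inc_mid,
                 inc_steep = inc_steep, seed = as.integer(seed)),
            class = "cohort_spec")
}

.gompertz_q <- function(spec, age, sex) {
  hz <- spec$lambda + spec$alpha * exp(spec$beta * age)
  if (sex == "female") hz <- hz * spec$sex_gap
  1 - exp(-hz)
}

#' Generate a synthetic annual-mortality schedule
#'
#' Annual death probabilities `q(age) = 1 - exp(-h(age))` from the
#' Gompertz-Makeham hazard of the spec, for ages 20-99; females get the
#' spec's multiplicative hazard ratio. Probabilities are monotone
#' non-decreasing in age and must stay below 1 through age 99.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param sex `"male"` or `"female"`.
#' @param ages Integer ages covered (default 20-99).
#' @return Data frame `age`, `q`.
#' @export
generate_life_table <- function(spec, sex = c("male", "female"),
                                ages = 20:99) {
  sex <- match.arg(sex)
  q <- .gompertz_q(spec, ages, sex)
  if (any(q >= 1)) {
    stop("generate_life_table: parameters imply q >= 1 before the terminal age",
         call. = FALSE)
  }
  data.frame(age = as.integer(ages), q = q)
}

#' Generate a synthetic hypertension-incidence schedule
#'
#' Annual probability of transitioning from the normotensive to the
#' hypertensive state, as a logistic function of age: increasing, bounded
#' by the spec's `inc_max`, equal to `inc_max / 2` at the midpoint age.
#' The same curve is used for both sexes (a documented simplification of
#' the stand-in).
#'
#' @inheritParams generate_life_table
#' @return Data frame `age`, `p`.
#' @export
generate_incidence <- function(spec, sex = c("male", "female"), ages = 20:99) {
  sex <- match.arg(sex)
  p <- spec$inc_max / (1 + exp(-spec$inc_steep * (ages - spec$inc_mid)))
  data.frame(age = as.integer(ages), p = p)
}

.schedules_from_spec <- function(spec, ages = 20:99) {
  list(
    mortality = data.frame(
      age = as.integer(ages),
      male = generate_life_table(spec, "male", ages)$q,
      female = generate_life_table(spec, "female", ages)$q),
    incidence = data.frame(
      age = as.integer(ages),
      male = generate_incidence(spec, "male", ages)$p,
      female = generate_incidence(spec, "female", ages)$p))
}

#' Synthesize a complete, valid parameter set
#'
#' Combines the synthetic demographic schedules with the published
#' model-input values, optionally perturbed by seeded jitter: each
#' uncertain input's base value is shifted by a uniform offset of at most
#' `jitter` times its low-high width and clamped into `[low, high]`, which
#' preserves every ordering invariant by construction. With `jitter = 0`
#' the result equals the bundled base-case fixture exactly. Deterministic
#' in `seed`.
#'
#' @param seed Integer seed.
#' @param jitter Fraction of each parameter's low-high width used as the
#'   maximum perturbation of its base value (default 0.1).
#' @param spec A [synthetic_cohort_spec()] for the schedules.
#' @return A validated `ncms_params` object.
#' @examples
#' identical(synthesize_parameter_set(1, jitter = 0),
#'           synthesize_parameter_set(1, jitter = 0))
#' @export
synthesize_parameter_set <- function(seed, jitter = 0.1,
                                     spec = synthetic_cohort_spec(seed = seed)) {
  stopifnot(jitter >= 0)
  p <- default_parameters()
  sched <- .schedules_from_spec(spec, seq.int(p$econ$start_age,
                                              p$econ$end_age - 1L))
  p$mortality <- sched$mortality
  p$incidence <- sched$incidence
  set.seed(seed)
  for (id in param_ids()) {
    uv <- get_param(p, id)
    width <- uv$high - uv$low
    z <- stats::runif(1, -1, 1)        # drawn even when width is 0, to keep
    if (width > 0 && jitter > 0) {     # the stream alignment independent of
      value <- uv$base + jitter * width * z   # which parameters are degenerate
      p <- set_param(p, id, min(max(value, uv$low), uv$high))
    }
  }
  validate_params(p)
  p
}

#' Write a synthetic configuration to a directory
#'
#' Materializes [synthesize_parameter_set()] as the on-disk configuration
#' formats consumed by [load_parameters()]: `params.json` plus the two
#' schedule CSVs.
#'
#' @inheritParams synthesize_parameter_set
#' @param dir Output directory (created if needed).
#' @return Path to the written JSON configuration, invisibly.
#' @export
synthesize_to_dir <- function(dir, seed, jitter = 0.1,
                              spec = synthetic_cohort_spec(seed = seed)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- synthesize_parameter_set(seed, jitter, spec)
  save_parameters(p, file.path(dir, "params.json"))
}
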