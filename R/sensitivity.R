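#' Inverse-CDF sampling from a triangular distribution
#'
#' All parameter uncertainty in the probabilistic sensitivity analysis is
#' expressed as triangular distributions with the low/base/high values of
#' the model-input table as support and mode. Sampling uses the closed-form
#' inverse CDF: for `u <= (c - a) / (b - a)` return
#' `a + sqrt(u (b - a)(c - a))`, otherwise `b - sqrt((1 - u)(b - a)(b - c))`;
#' a degenerate spec (`a == b`) is a point mass at `a`.
#'
#' @param spec An [uncertain_value()] (low = a, base = mode c, high = b) or
#'   a numeric vector `c(low, mode, high)`.
#' @param u Uniform(0, 1) variates (vectorized).
#' @return Sampled values, same length as `u`.
#' @examples
#' sample_triangular(c(0, 1, 2), 0.5) # 1
#' @export
sample_triangular <- function(spec, u) {
  if (is_uv(spec)) {
    a <- spec$low; cc <- spec$base; b <- spec$high
  } else {
    stopifnot(is.numeric(spec), length(spec) == 3L)
    a <- spec[1L]; cc <- spec[2L]; b <- spec[3L]
  }
  if (!(a <= cc && cc <= b)) {
    stop(sprintf("sample_triangular: need low <= mode <= high, got (%g, %g, %g)",
                 a, cc, b), call. = FALSE)
  }
  if (any(u < 0 | u > 1)) stop("sample_triangular: u must lie in [0, 1]",
                               call. = FALSE)
  if (a == b) return(rep(a, length(u)))
  fc <- (cc - a) / (b - a)
  ifelse(u <= fc,
         a + sqrt(u * (b - a) * (cc - a)),
         b - sqrt((1 - u) * (b - a) * (b - cc)))
}

#' One-way sensitivity analysis for a single parameter
#'
#' Reruns the full two-arm model twice with the named parameter pinned at
#' its low and at its high bound, all other inputs at base.
#'
#' @param p A validated parameter set.
#' @param id One of [param_ids()].
#' @param conventions A [cycle_conventions()] object.
#' @return An object of class `one_way_result`: `parameter`, `at_low`,
#'   `at_high` (each an `ncms_cea` from [run_model()]).
#' @examples
#' ow <- one_way(default_parameters(), "growth_rate")
#' ow$at_low$incremental$icer
#' @export
one_way <- function(p, id, conventions = cycle_conventions()) {
  uv <- get_param(p, id)
  structure(list(parameter = id,
                 at_low = run_model(set_param(p, id, uv$low), conventions),
                 at_high = run_model(set_param(p, id, uv$high), conventions)),
            class = "one_way_result")
}

# Sort value of an ICER for tornado ordering: cost-saving (dominant)
# endpoints count as -Inf, QALY-losing endpoints as +Inf ("dominated"), so
# parameters whose range crosses either extreme rank as maximally influential.
.icer_sort_value <- function(inc) {
  cls <- inc$classification
  if (identical(cls, "dominant")) return(-Inf)
  if (identical(cls, "qaly_loss")) return(Inf)
  inc$icer
}

#' Tornado analysis over every uncertain input
#'
#' Runs [one_way()] for every parameter and orders the results by
#' descending ICER span, the customary tornado-diagram ranking. Endpoints
#' that are cost-saving or QALY-losing are treated as infinite for the
#' ordering.
#'
#' @inheritParams one_way
#' @return An object of class `tornado_result`: `summary`, a data frame
#'   with one row per parameter (`parameter`, `icer_low`, `icer_high`,
#'   `class_low`, `class_high`, `span`), sorted by descending span with the
#'   original enumeration as a stable tie-break; and `results`, the named
#'   list of `one_way_result`s.
#' @export
tornado <- function(p, conventions = cycle_conventions()) {
  ids <- param_ids()
  results <- lapply(ids, function(id) one_way(p, id, conventions))
  names(results) <- ids
  rows <- lapply(ids, function(id) {
    ow <- results[[id]]
    lo <- ow$at_low$incremental
    hi <- ow$at_high$incremental
    slo <- .icer_sort_value(lo)
    shi <- .icer_sort_value(hi)
    span <- abs(shi - slo)
    if (!is.finite(span)) span <- if (identical(slo, shi)) 0 else Inf
    data.frame(parameter = id, icer_low = lo$icer, icer_high = hi$icer,
               class_low = lo$classification, class_high = hi$classification,
               span = span, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  ord <- order(-summary$span)   # radix order is stable; ties keep table order
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary, results = results[summary$parameter]),
            class = "tornado_result")
}

#' @export
print.tornado_result <- function(x, ...) {
  cat("One-way sensitivity (tornado) ranking by ICER span\n")
  print(x$summary, digits = 6)
  invisible(x)
}

#' Empirical quadrant probabilities of PSA draws
#'
#' Classifies every draw on the cost-effectiveness plane with [classify()]
#' and returns the empirical fraction in each of the four categories.
#'
#' @param draws Data frame (or list) with numeric `d_cost` and `d_qaly`.
#' @param wtp Willingness-to-pay threshold (Int$/QALY).
#' @return Named numeric vector over `dominant`, `cost_effective`,
#'   `not_cost_effective`, `qaly_loss`; sums to 1.
#' @export
quadrant_probabilities <- function(draws, wtp) {
  if (length(draws$d_cost) == 0L) {
    stop("quadrant_probabilities: no draws", call. = FALSE)
  }
  cls <- classify(draws$d_cost, wtp, d_qaly = draws$d_qaly)
  tab <- table(factor(cls, levels = .cea_classes))
  as.numeric(tab) / length(cls) -> fr
  stats::setNames(fr, .cea_classes)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value in the grid, the fraction of PSA draws
#' with strictly positive net monetary benefit.
#'
#' @param draws Data frame (or list) with numeric `d_cost` and `d_qaly`.
#' @param wtp_grid Numeric vector of thresholds (Int$/QALY).
#' @return Data frame with columns `wtp`, `acceptability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (length(draws$d_cost) == 0L || length(wtp_grid) == 0L) {
    stop("ceac: draws and wtp_grid must be nonempty", call. = FALSE)
  }
  acc <- vapply(wtp_grid, function(w) {
    mean(w * draws$d_qaly - draws$d_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, acceptability = acc)
}

# Sample every uncertain input from its triangular distribution, consuming
# the RNG stream parameter-by-parameter in param_ids() order (the documented
# reproducibility contract; R's default Mersenne-Twister generator).
.sample_params <- function(p, n) {
  s <- list()
  for (id in param_ids()) {
    u <- stats::runif(n)
    s[[id]] <- sample_triangular(get_param(p, id), u)
  }
  s
}

.pv_from_samples <- function(s) {
  list(
    rr = s$rr_hypertension,
    u_n = s$u_normotensive,
    u_h = s$u_hypertensive,
    dhe = cost_decomposition(s$he1, s$growth_rate),
    htn_cost = s$htn_annual_cost,
    lg1 = s$d_offfarm_p_30_49 * s$annual_wage +
      s$d_farm_hours_30_49 * s$agri_hourly,
    lg2 = s$d_offfarm_p_50p * s$annual_wage +
      s$d_farm_hours_50p * s$agri_hourly,
    r = s$discount_rate,
    eff = list(
      male = list(s$mort_male_20_44, s$mort_male_45_59, s$mort_male_60p),
      female = list(s$mort_female_20_44, s$mort_female_45_59,
                    s$mort_female_60p)))
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws `n` parameter vectors — every uncertain input sampled
#' independently from its triangular distribution (low, base, high) with a
#' seeded generator — reruns both arms for every draw, and summarizes the
#' incremental cost/QALY cloud: means, equal-tailed 95% percentile
#' intervals, quadrant probabilities at the willingness-to-pay threshold,
#' and the acceptability curve. Negative sampled values are deliberately
#' allowed wherever a triangular support includes them (the mortality-effect
#' intervals span zero); truncating at zero would bias the ICER.
#'
#' The summary ICER is reported as the ratio of mean incremental cost to
#' mean incremental QALYs (never the unstable mean of per-draw ratios),
#' alongside the percentile interval of the incremental pair.
#'
#' @param p A validated parameter set.
#' @param n Number of Monte Carlo draws (>= 1); the published analysis used
#'   10,000.
#' @param seed Integer seed; identical `(p, n, seed)` give bit-identical
#'   results.
#' @param wtp Willingness-to-pay threshold; defaults to [wtp_threshold()].
#' @param wtp_grid Thresholds for the acceptability curve; defaults to
#'   Int$0-150,000 in steps of 2,500 with `wtp` inserted.
#' @param conventions A [cycle_conventions()] object.
#' @return An object of class `psa_result`; see Details.
#' @examples
#' psa <- run_psa(default_parameters(), n = 100, seed = 1)
#' psa$quadrant_probs
#' @export
run_psa <- function(p, n, seed, wtp = wtp_threshold(p), wtp_grid = NULL,
                    conventions = cycle_conventions()) {
  validate_params(p)
  stopifnot(n >= 1)
  if (is.null(wtp_grid)) wtp_grid <- sort(unique(c(seq(0, 150000, 2500), wtp)))
  set.seed(seed)
  s <- .sample_params(p, n)
  ev <- .eval_arms(p, .pv_from_samples(s), conventions)
  draws <- data.frame(draw = seq_len(n), d_cost = ev$d_cost, d_qaly = ev$d_qaly)
  draws$classification <- classify(draws$d_cost, wtp, d_qaly = draws$d_qaly)
  q <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  mean_d_cost <- mean(draws$d_cost)
  mean_d_qaly <- mean(draws$d_qaly)
  structure(list(
    n_draws = n, seed = seed, wtp = wtp, draws = draws,
    mean_d_cost = mean_d_cost, mean_d_qaly = mean_d_qaly,
    ci95_d_cost = q(draws$d_cost), ci95_d_qaly = q(draws$d_qaly),
    icer_ratio_of_means = if (mean_d_qaly == 0) NA_real_
      else mean_d_cost / mean_d_qaly,
    quadrant_probs = quadrant_probabilities(draws, wtp),
    ceac = ceac(draws, wtp_grid),
    rng = RNGkind()[1L]), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws (seed %d, %s)\n",
              x$n_draws, x$seed, x$rng))
  cat(sprintf("  mean dCost Int$%.0f (95%% PI %.0f, %.0f)\n",
              x$mean_d_cost, x$ci95_d_cost[1], x$ci95_d_cost[2]))
  cat(sprintf("  mean dQALY %.4f (95%% PI %.4f, %.4f)\n",
              x$mean_d_qaly, x$ci95_d_qaly[1], x$ci95_d_qaly[2]))
  cat(sprintf("  ICER (ratio of means) %s\n",
              if (is.na(x$icer_ratio_of_means)) "undefined"
              else sprintf("Int$%.0f/QALY", x$icer_ratio_of_means)))
  cat(sprintf("  at WTP Int$%s/QALY:\n", format(x$wtp, big.mark = ",")))
  qp <- x$quadrant_probs
  for (k in names(qp)) cat(sprintf("    %-20s %5.1f%%\n", k, 100 * qp[[k]]))
  invisible(x)
}
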