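#' Base-case report
#'
#' Runs the two-arm model and assembles a publication-style base-case
#' table: per-arm discounted cost and QALYs, incremental cost and
#' effectiveness, ICER and classification against the willingness-to-pay
#' threshold. All quantities are carried unrounded; the print method
#' rounds only at display (costs to Int$1, QALYs to 0.01, ICER to Int$1),
#' which is why a displayed pair like Int$825 / 0.01 QALYs can correspond
#' to an ICER that is not their rounded quotient.
#'
#' @param x A validated `ncms_params` object, or a path to a JSON
#'   configuration for [load_parameters()].
#' @param conventions A [cycle_conventions()] object.
#' @return An object of class `base_case_report`.
#' @examples
#' run_base_case(default_parameters())
#' @export
run_base_case <- function(x, conventions = cycle_conventions()) {
  p <- if (inherits(x, "ncms_params")) x else load_parameters(x)
  m <- run_model(p, conventions)
  structure(list(model = m, params = p), class = "base_case_report")
}

#' @export
print.base_case_report <- function(x, ...) {
  m <- x$model
  inc <- m$incremental
  fmt_c <- function(v) formatC(round(v), big.mark = ",", format = "d")
  cat("Base-case cost-effectiveness analysis\n")
  cat(sprintf("  %-8s  cost Int$%8s   effectiveness %5.2f QALYs\n",
              "no-NCMS", fmt_c(m$control$cost_total), m$control$qalys))
  cat(sprintf("  %-8s  cost Int$%8s   effectiveness %5.2f QALYs\n",
              "NCMS", fmt_c(m$ncms$cost_total), m$ncms$qalys))
  cat(sprintf("  incremental cost Int$%s, incremental effectiveness %.2f QALYs\n",
              fmt_c(inc$d_cost), inc$d_qaly))
  cat(sprintf("  ICER %s, WTP Int$%s/QALY -> %s\n",
              if (is.na(inc$icer)) "undefined"
              else paste0("Int$", fmt_c(inc$icer), "/QALY"),
              fmt_c(m$wtp), inc$classification))
  invisible(x)
}

#' Sweep the unpublished accounting conventions
#'
#' The published analysis does not state its reward-timing convention
#' (start-of-cycle, end-of-cycle, or half-cycle corrected) nor how the
#' sex-specific inputs were combined into one cohort. This sweep reruns the
#' base case under each timing convention and a grid of male cohort
#' weights, so the convention closest to a reference result can be
#' identified.
#'
#' @param p A validated parameter set.
#' @param sex_weights Male-cohort weights to sweep.
#' @return Data frame with one row per (timing, sex weight): `d_cost`,
#'   `d_qaly`, `icer`, `classification`.
#' @export
convention_sweep <- function(p, sex_weights = c(0, 0.5, 1)) {
  rows <- list()
  for (timing in c("start", "half", "end")) {
    for (w in sex_weights) {
      pw <- p
      pw$econ$sex_weight_male <- w
      inc <- run_model(pw, cycle_conventions(timing))$incremental
      rows[[length(rows) + 1L]] <- data.frame(
        timing = timing, sex_weight_male = w, d_cost = inc$d_cost,
        d_qaly = inc$d_qaly, icer = inc$icer,
        classification = inc$classification, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.write_stage <- function(manifest, stage, fn) {
  out <- tryCatch(list(ok = TRUE, value = fn()),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  manifest$stages[[stage]] <- if (out$ok) "completed" else
    paste("failed:", out$error)
  list(manifest = manifest, ok = out$ok,
       value = if (out$ok) out$value else NULL)
}

#' Run the full analysis pipeline to a directory
#'
#' Base case, tornado (one-way sensitivity for every parameter), and the
#' Monte Carlo probabilistic sensitivity analysis, written as
#' plotting-ready CSV/JSON files: `base_case.json`, `tornado.csv`,
#' `psa_scatter.csv` (the incremental cloud with classifications),
#' `ceac.csv`, `quadrants.csv`, `trace_<arm>_<sex>.csv`, plus a
#' `manifest.json` recording the command, seed, package version, parameter
#' hash and produced files. The manifest is written even when a stage
#' fails, with the failure recorded per stage. Given the same
#' configuration, version and seed the outputs are byte-stable (the
#' manifest timestamp aside).
#'
#' @param x Parameter set or config path, as in [run_base_case()].
#' @param n Number of PSA draws (>= 1).
#' @param seed Integer seed for the PSA.
#' @param out_dir Output directory (created if needed).
#' @param conventions A [cycle_conventions()] object.
#' @return The manifest, invisibly. Signals an error after writing the
#'   manifest if any stage failed.
#' @export
run_full_analysis <- function(x, n, seed, out_dir,
                              conventions = cycle_conventions()) {
  stopifnot(is.numeric(n), length(n) == 1L)
  if (n < 1) stop("run_full_analysis: n must be >= 1", call. = FALSE)
  p <- if (inherits(x, "ncms_params")) x else load_parameters(x)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(command = "full", n = n, seed = seed,
                   package_version = as.character(utils::packageVersion("ncmscea")),
                   param_hash = .param_hash(p),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = list(), outputs = character())
  add_out <- function(f) manifest$outputs <<- c(manifest$outputs, f)

  st <- .write_stage(manifest, "base_case", function() {
    m <- run_model(p, conventions)
    write_incremental_json(m$incremental, m$wtp,
                           file.path(out_dir, "base_case.json"))
    for (arm in c("NCMS", "no-NCMS")) {
      for (sex in c("male", "female")) {
        f <- sprintf("trace_%s_%s.csv", gsub("-", "_", arm), sex)
        export_trace(run_cohort(p, arm, sex, conventions)$trace,
                     file.path(out_dir, f))
        add_out(f)
      }
    }
    add_out("base_case.json")
    m
  })
  manifest <- st$manifest

  st <- .write_stage(manifest, "tornado", function() {
    tn <- tornado(p, conventions)
    utils::write.csv(tn$summary, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
    add_out("tornado.csv")
    tn
  })
  manifest <- st$manifest

  st <- .write_stage(manifest, "psa", function() {
    psa <- run_psa(p, n = n, seed = seed, conventions = conventions)
    utils::write.csv(psa$draws, file.path(out_dir, "psa_scatter.csv"),
                     row.names = FALSE)
    utils::write.csv(psa$ceac, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
    qp <- psa$quadrant_probs
    utils::write.csv(data.frame(classification = names(qp),
                                probability = as.numeric(qp)),
                     file.path(out_dir, "quadrants.csv"), row.names = FALSE)
    add_out(c("psa_scatter.csv", "ceac.csv", "quadrants.csv"))
    psa
  })
  manifest <- st$manifest

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  failed <- vapply(manifest$stages, function(s) startsWith(s, "failed"),
                   logical(1))
  if (any(failed)) {
    stop(sprintf("pipeline stage(s) failed: %s",
                 paste(names(manifest$stages)[failed], collapse = ", ")),
         call. = FALSE)
  }
  invisible(manifest)
}

# Provenance hash of a parameter set: stable digest of its serialized form.
.param_hash <- function(p) {
  txt <- jsonlite::toJSON(list(table = param_table(p),
                               mortality = p$mortality,
                               incidence = p$incidence,
                               econ = p$econ[c("gdp_per_capita",
                                               "wtp_multiplier", "start_age",
                                               "end_age", "sex_weight_male")]),
                          digits = NA)
  # djb2 string hash; cheap, dependency-free, stable across platforms
  h <- 5381
  for (b in utf8ToInt(as.character(txt))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}
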