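#' Incremental comparison of two arm outcomes
#'
#' Computes the incremental cost and effectiveness of the program arm over
#' the comparator and their ratio (the ICER), always on unrounded values;
#' any rounding happens only at display. The ICER is undefined (`NA`) when
#' the QALY difference is exactly zero.
#'
#' @param ncms,control `arm_outcome` objects from the same parameter set.
#' @param wtp Optional willingness-to-pay threshold (Int$/QALY); when given,
#'   the outcome is classified with [classify()].
#' @return An object of class `incremental_outcome` with fields `d_cost`,
#'   `d_qaly`, `icer`, `classification` (`NA` if no `wtp` supplied).
#' @examples
#' a <- structure(list(cost_total = 1100, qalys = 14.5), class = "arm_outcome")
#' b <- structure(list(cost_total = 1000, qalys = 14.0), class = "arm_outcome")
#' incremental(a, b, wtp = 37059)
#' @export
incremental <- function(ncms, control, wtp = NULL) {
  d_cost <- ncms$cost_total - control$cost_total
  d_qaly <- ncms$qalys - control$qalys
  icer <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  o <- structure(list(d_cost = d_cost, d_qaly = d_qaly, icer = icer,
                      classification = NA_character_),
                 class = "incremental_outcome")
  if (!is.null(wtp)) o$classification <- classify(o, wtp)
  o
}

#' @export
print.incremental_outcome <- function(x, ...) {
  cat(sprintf("dCost Int$%.2f, dQALY %.5f, ICER %s%s\n", x$d_cost, x$d_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("%.0f", x$icer),
              if (is.na(x$classification)) ""
              else paste0(" (", x$classification, ")")))
  invisible(x)
}

#' Cost-effectiveness classification labels
#' @keywords internal
.cea_classes <- c("dominant", "cost_effective", "not_cost_effective", "qaly_loss")

#' Classify incremental cost-effectiveness pairs
#'
#' Partition of the cost-effectiveness plane used throughout: a QALY gain
#' at non-positive incremental cost is *dominant* (cost-saving); a QALY gain
#' bought at an ICER at or below the threshold is *cost-effective*
#' (boundary inclusive); above the threshold *not cost-effective*; and any
#' non-positive QALY change is pooled as *qaly_loss* regardless of cost,
#' matching the four-way reporting convention of the underlying analysis.
#'
#' @param o An `incremental_outcome`, or a numeric vector of incremental
#'   costs (in which case `d_qaly` must be given).
#' @param wtp Willingness-to-pay threshold, Int$/QALY (> 0).
#' @param d_qaly Incremental QALYs (vectorized with `o` when numeric).
#' @return Character vector of classifications.
#' @examples
#' classify(-1, 37059, d_qaly = 0.1) # dominant
#' @export
classify <- function(o, wtp, d_qaly = NULL) {
  stopifnot(wtp > 0)
  if (inherits(o, "incremental_outcome")) {
    d_cost <- o$d_cost
    d_qaly <- o$d_qaly
  } else {
    d_cost <- o
    if (is.null(d_qaly)) stop("classify: d_qaly required", call. = FALSE)
  }
  out <- rep("qaly_loss", length(d_cost))
  gain <- d_qaly > 0
  out[gain & d_cost <= 0] <- "dominant"
  ce <- gain & d_cost > 0 & d_cost / d_qaly <= wtp
  out[ce] <- "cost_effective"
  out[gain & d_cost > 0 & d_cost / d_qaly > wtp] <- "not_cost_effective"
  out
}

#' Net monetary benefit
#'
#' `wtp * d_qaly - d_cost`: positive exactly when the program is dominant
#' or cost-effective at the threshold (for positive QALY gains).
#'
#' @param o An `incremental_outcome`, or numeric incremental costs.
#' @param wtp Willingness-to-pay threshold (Int$/QALY, >= 0).
#' @param d_qaly Incremental QALYs when `o` is numeric.
#' @return Net monetary benefit in Int$. Vectorized.
#' @examples
#' net_monetary_benefit(0, 10, d_qaly = 1) # 10
#' @export
net_monetary_benefit <- function(o, wtp, d_qaly = NULL) {
  stopifnot(wtp >= 0)
  if (inherits(o, "incremental_outcome")) {
    d_cost <- o$d_cost
    d_qaly <- o$d_qaly
  } else {
    d_cost <- o
    if (is.null(d_qaly)) stop("net_monetary_benefit: d_qaly required", call. = FALSE)
  }
  wtp * d_qaly - d_cost
}

#' Serialize an incremental outcome to a JSON report
#'
#' @param o An `incremental_outcome`.
#' @param wtp Willingness-to-pay threshold used for the classification and
#'   net monetary benefit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incremental_json <- function(o, wtp, path) {
  jsonlite::write_json(
    list(d_cost = o$d_cost, d_qaly = o$d_qaly,
         icer = if (is.na(o$icer)) NULL else o$icer,
         classification = classify(o, wtp),
         nmb_at_wtp = net_monetary_benefit(o, wtp), wtp = wtp),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
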