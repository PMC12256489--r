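#' Incremental cost-effectiveness of one strategy against a comparator
#'
#' Computes incremental cost and QALYs, the ICER (from the unrounded
#' increments) and a dominance / willingness-to-pay classification:
#' `DOMINANT` when the new strategy is cheaper and more effective,
#' `DOMINATED` when it is dearer and less effective, otherwise the ICER is
#' compared against the thresholds (`HIGHLY_CE` strictly below the low
#' threshold, `INTERMEDIATELY_CE` from the low threshold up to but not
#' including the high one, `NOT_CE` otherwise). When the QALY increment is
#' zero the ICER is flagged undefined rather than reported as infinite.
#'
#' @param cost_new,qaly_new discounted totals of the evaluated strategy.
#' @param cost_ref,qaly_ref discounted totals of the comparator.
#' @param thresholds `c(low, high)` USD/QALY.
#' @return a `ce_result` list: per-arm totals, `incremental_cost`,
#'   `incremental_qaly`, `icer` (`NA` when undefined or dominance applies),
#'   `icer_defined`, `classification`.
#' @examples
#' icer(12590.69, 9.09, 12275.89, 8.66)
#' @export
icer <- function(cost_new, qaly_new, cost_ref, qaly_ref,
                 thresholds = c(12814, 38442)) {
  vals <- c(cost_new, qaly_new, cost_ref, qaly_ref)
  .assert(all(is.finite(vals)), "all inputs must be finite (no NaN/NA)")
  dc <- cost_new - cost_ref
  de <- qaly_new - qaly_ref
  ic <- if (de != 0) dc / de else NA_real_
  res <- structure(list(
    cost_new = cost_new, qaly_new = qaly_new,
    cost_ref = cost_ref, qaly_ref = qaly_ref,
    incremental_cost = dc, incremental_qaly = de,
    icer = ic, icer_defined = de != 0,
    thresholds = thresholds, classification = NA_character_),
    class = "ce_result")
  res$classification <- classify_cost_effectiveness(res, thresholds)
  res
}

#' Classify a cost-effectiveness result against thresholds
#'
#' @param result a `ce_result` from [icer] (or a list with
#'   `incremental_cost`, `incremental_qaly`, `icer`, `icer_defined`).
#' @param thresholds `c(low, high)` with low < high.
#' @return one of `"DOMINANT"`, `"HIGHLY_CE"`, `"INTERMEDIATELY_CE"`,
#'   `"NOT_CE"`, `"DOMINATED"`, or `NA` when the ICER is undefined and no
#'   dominance quadrant applies.
#' @export
classify_cost_effectiveness <- function(result, thresholds = c(12814, 38442)) {
  .assert(length(thresholds) == 2L && thresholds[1] < thresholds[2],
          "thresholds must be increasing (low, high)")
  dc <- result$incremental_cost; de <- result$incremental_qaly
  if (dc < 0 && de > 0) return("DOMINANT")
  if (dc > 0 && de < 0) return("DOMINATED")
  # equal effects: classification rests on cost alone
  if (!isTRUE(result$icer_defined)) return(NA_character_)
  ic <- result$icer
  if (ic < thresholds[1]) "HIGHLY_CE"
  else if (ic < thresholds[2]) "INTERMEDIATELY_CE"
  else "NOT_CE"
}

#' Net monetary benefit
#'
#' `wtp * incremental_qalys - incremental_cost`. Positive exactly when the
#' ICER lies below the willingness-to-pay (for a positive QALY increment);
#' this identity is what turns probabilistic draws into the acceptability
#' curve.
#'
#' @param incremental_cost,incremental_qaly increments versus comparator.
#' @param wtp willingness to pay, USD/QALY (>= 0).
#' @export
net_monetary_benefit <- function(incremental_cost, incremental_qaly, wtp) {
  .assert(all(wtp >= 0), "wtp must be >= 0")
  wtp * incremental_qaly - incremental_cost
}

# Table 6 style: negative monetary values in parentheses
.fmt_money <- function(x, digits = 2) {
  s <- formatC(abs(x), format = "f", digits = digits, big.mark = ",")
  ifelse(x < 0, paste0("(", s, ")"), s)
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("  incremental: cost %s USD, %s QALYs\n",
              .fmt_money(x$incremental_cost), .fmt_money(x$incremental_qaly, 4)))
  if (isTRUE(x$icer_defined))
    cat(sprintf("  ICER %s USD/QALY -> %s\n", .fmt_money(x$icer), x$classification))
  else
    cat(sprintf("  ICER undefined (zero QALY increment) -> %s\n",
                ifelse(is.na(x$classification), "unclassified", x$classification)))
  invisible(x)
}

#' @export
as.data.frame.ce_result <- function(x, ...) {
  data.frame(cost_ref = x$cost_ref, cost_new = x$cost_new,
             qaly_ref = x$qaly_ref, qaly_new = x$qaly_new,
             incremental_cost = x$incremental_cost,
             incremental_qaly = x$incremental_qaly,
             icer = x$icer, classification = x$classification)
}
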