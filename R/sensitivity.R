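#' One-way deterministic sensitivity analysis
#'
#' Varies one cost input at a time between a lower and an upper bound —
#' explicit bounds where known, a symmetric +/-20% spread otherwise — and
#' records the resulting per-patient delivery cost, producing a tornado
#' ranking of the most influential parameters and the overall cost range.
#'
#' @name sensitivity
NULL

#' Define a sensitivity parameter
#'
#' @param name display name.
#' @param target what the parameter drives: the `component` id of one
#'   delivery component, or `"total"` for the overall package cost (a
#'   multiplicative factor on the reported per-patient total).
#' @param base_value base value in INR; if `NULL`, taken from the breakdown
#'   at analysis time (the component's per-patient cost, or the reported
#'   total).
#' @param low,high explicit bounds in INR; if absent, resolved as
#'   `base * (1 -/+ spread)`.
#' @param spread symmetric spread used when explicit bounds are absent
#'   (default 0.20).
#' @return a `dsa_parameter` list.
#' @export
dsa_parameter <- function(name, target = name, base_value = NULL,
                          low = NULL, high = NULL, spread = 0.20) {
  if (!is.null(low) && !is.null(high) && low > high) {
    stop("explicit lower bound exceeds upper bound for parameter '", name,
         "'", call. = FALSE)
  }
  structure(list(name = name, target = target, base_value = base_value,
                 low = low, high = high, spread = spread),
            class = "dsa_parameter")
}

#' Resolve the bounds of a sensitivity parameter
#'
#' Explicit bounds pass through unchanged; otherwise the bounds are
#' `base * (1 - spread)` and `base * (1 + spread)`.
#'
#' @param param a [dsa_parameter()].
#' @param base_value base value to use when the parameter carries none.
#' @return named numeric vector `c(low = , high = )`.
#' @examples
#' resolve_bounds(dsa_parameter("sms", base_value = 160))  # 128, 192
#' @export
resolve_bounds <- function(param, base_value = param$base_value) {
  if (is.null(base_value)) {
    stop("parameter '", param$name, "' has no base value", call. = FALSE)
  }
  assert_scalar_num(base_value, "base_value", min = 0)
  low <- param$low %||% (base_value * (1 - param$spread))
  high <- param$high %||% (base_value * (1 + param$spread))
  if (low > high) {
    stop("lower bound exceeds upper bound for parameter '", param$name,
         "'", call. = FALSE)
  }
  c(low = low, high = high)
}

#' Run the one-way sensitivity analysis
#'
#' For each parameter independently, the unit delivery cost is recomputed
#' with that parameter at its lower and upper bound and all others at base.
#' A component parameter replaces its component's per-patient cost; the
#' `"total"` parameter scales the reported (integer-rounded) per-patient
#' total. Outputs are reported as integer INR (half-up); exact pre-rounding
#' outputs are retained for diagnostics.
#'
#' @param ledger a [cost_ledger()].
#' @param params list of [dsa_parameter()] objects.
#' @return a `dsa_result`: list with `entries` (data frame `parameter`,
#'   `low`, `high`, `output_at_low`, `output_at_high`, `range`, plus exact
#'   columns), `base_output`, `overall_min`, `overall_max`, `ranking`
#'   (parameter names by descending range, ties broken lexicographically).
#' @examples
#' res <- one_way_dsa(table2_fixture(),
#'                    list(dsa_parameter("Overall package cost", "total")))
#' res$overall_max  # 326
#' @export
one_way_dsa <- function(ledger, params) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (inherits(params, "dsa_parameter")) params <- list(params)
  if (length(params) == 0) stop("no parameters supplied", call. = FALSE)
  bd <- unit_delivery_cost(ledger)
  base_output <- bd$total_reported
  comp_cost <- stats::setNames(bd$components$cost, bd$components$component)

  eval_at <- function(target, value) {
    if (identical(target, "total")) {
      # multiplicative factor on the reported overall package cost
      value
    } else {
      sum(comp_cost[setdiff(names(comp_cost), target)]) + value
    }
  }

  rows <- lapply(params, function(p) {
    base <- p$base_value %||% (
      if (identical(p$target, "total")) base_output else {
        if (!p$target %in% names(comp_cost)) {
          stop("parameter '", p$name, "' targets unknown component '",
               p$target, "'", call. = FALSE)
        }
        unname(comp_cost[p$target])
      })
    b <- resolve_bounds(p, base)
    out_lo <- eval_at(p$target, b[["low"]])
    out_hi <- eval_at(p$target, b[["high"]])
    data.frame(parameter = p$name, low = b[["low"]], high = b[["high"]],
               output_at_low = round_half_up(out_lo),
               output_at_high = round_half_up(out_hi),
               output_at_low_exact = out_lo, output_at_high_exact = out_hi,
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries$range <- abs(entries$output_at_high - entries$output_at_low)
  ord <- order(-entries$range, entries$parameter)
  structure(
    list(entries = entries,
         base_output = base_output,
         overall_min = min(entries$output_at_low, entries$output_at_high,
                           base_output),
         overall_max = max(entries$output_at_low, entries$output_at_high,
                           base_output),
         ranking = entries$parameter[ord]),
    class = "dsa_result"
  )
}

#' @export
print.dsa_result <- function(x, ...) {
  cat(sprintf("<dsa_result> base %s, overall range [%s, %s]\n",
              format(x$base_output), format(x$overall_min),
              format(x$overall_max)))
  print(tornado_table(x))
  invisible(x)
}

#' Tornado table
#'
#' Rows of a one-way sensitivity analysis ordered by descending output
#' range (ties broken lexicographically by parameter name), truncated to
#' the `top_n` most influential parameters — the data behind a tornado
#' diagram.
#'
#' @param result a `dsa_result`.
#' @param top_n number of rows to keep (default all, >= 1).
#' @return data frame `parameter`, `output_at_low`, `output_at_high`,
#'   `range`, sorted.
#' @export
tornado_table <- function(result, top_n = nrow(result$entries)) {
  stopifnot(inherits(result, "dsa_result"))
  if (nrow(result$entries) == 0) stop("empty DSA result", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  e <- result$entries
  e <- e[order(-e$range, e$parameter), , drop = FALSE]
  e <- e[seq_len(min(top_n, nrow(e))),
         c("parameter", "output_at_low", "output_at_high", "range")]
  rownames(e) <- NULL
  e
}

#' Tornado diagram
#'
#' Horizontal bar chart of the DSA output ranges around the base-case
#' per-patient cost, widest bar on top.
#'
#' @param result a `dsa_result`.
#' @param top_n bars to show (default all).
#' @param main plot title.
#' @return the tornado table, invisibly.
#' @export
plot_tornado <- function(result, top_n = nrow(result$entries),
                         main = "One-way sensitivity analysis") {
  tt <- tornado_table(result, top_n)
  tt <- tt[rev(seq_len(nrow(tt))), ]  # widest on top
  n <- nrow(tt)
  xlim <- range(tt$output_at_low, tt$output_at_high, result$base_output)
  graphics::plot(NULL, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "Per-patient delivery cost (INR)", ylab = "",
                 main = main)
  graphics::axis(2, at = seq_len(n), labels = tt$parameter, las = 1,
                 cex.axis = 0.8)
  for (i in seq_len(n)) {
    graphics::rect(min(tt$output_at_low[i], tt$output_at_high[i]), i - 0.3,
                   max(tt$output_at_low[i], tt$output_at_high[i]), i + 0.3,
                   col = "steelblue", border = "grey30")
  }
  graphics::abline(v = result$base_output, lty = 2)
  invisible(tt)
}
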