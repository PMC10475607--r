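#' Costing engine
#'
#' Aggregates a validated cost ledger into the study's headline outputs:
#' phase totals with proportional breakdowns (top-down, financial view),
#' the per-patient unit cost of service delivery decomposed into named
#' components (bottom-up, activity-based view), and USD conversion.
#'
#' @name costing_engine
NULL

# undiscounted financial cost of one ledger line
item_cost <- function(items) {
  items$unit_price * items$quantity * items$apportionment_fraction
}

#' Phase cost summary (top-down view)
#'
#' Sums item costs (unit price x quantity x apportionment fraction) for one
#' phase, with each line's proportion of the phase total and the unit cost
#' per patient in the cohort.
#'
#' @param ledger a [cost_ledger()].
#' @param phase one of `"development"`, `"pretest"`, `"training"`,
#'   `"delivery"`.
#' @param include_pretest if `TRUE` and `phase = "development"`, pretest
#'   items are folded into the development summary (the published
#'   development total includes the pretest line; the abstract's headline
#'   development cost excludes it — both views are available here).
#' @return a `phase_cost_summary`: list with `phase`, `line_items` (data
#'   frame `label`, `cost`, `proportion`), `total` (exact INR),
#'   `unit_cost` (integer INR per patient, half-up), `total_usd` (2 dp).
#' @examples
#' s <- phase_summary(table2_fixture(), "development", include_pretest = TRUE)
#' s$total      # 659444
#' s$unit_cost  # 6594
#' @export
phase_summary <- function(ledger, phase = LEDGER_PHASES,
                          include_pretest = FALSE) {
  stopifnot(inherits(ledger, "cost_ledger"))
  phase <- match.arg(tolower(phase), LEDGER_PHASES)
  keep <- ledger$items$phase == phase
  if (phase == "development" && include_pretest) {
    keep <- keep | ledger$items$phase == "pretest"
  }
  it <- ledger$items[keep, , drop = FALSE]
  costs <- item_cost(it)
  total <- sum(costs)
  prop <- if (total > 0) round_half_up(costs / total * 100, 2) else
    rep(NA_real_, nrow(it))
  structure(
    list(phase = phase,
         line_items = data.frame(label = it$label, cost = costs,
                                 proportion = prop,
                                 stringsAsFactors = FALSE),
         total = total,
         unit_cost = round_half_up(total / ledger$cohort_size),
         total_usd = convert_currency(total, ledger$exchange_rate)),
    class = "phase_cost_summary"
  )
}

#' @export
print.phase_cost_summary <- function(x, ...) {
  cat(sprintf("<phase_cost_summary> %s: total INR %s (USD %.2f), unit cost %s\n",
              x$phase, format(x$total, big.mark = ""), x$total_usd,
              format(x$unit_cost)))
  print(x$line_items)
  invisible(x)
}

#' Per-patient unit cost of service delivery (bottom-up view)
#'
#' Resolves every delivery-phase item to a per-patient cost and sums them.
#' Items flagged `per_patient` contribute `unit_price x quantity x
#' apportionment_fraction` directly. Other delivery items are resolved
#' through the annualization path: a capital purchase is annualized over its
#' useful life at the ledger's discount rate, a recurrent item's unit price
#' is taken as its annual cost; the annual cost is converted to a per-minute
#' rate over the ledger's annual operational minutes and multiplied by the
#' item's minutes per patient.
#'
#' Component proportions are computed against the integer-rounded total
#' (the reported per-patient figure), which is the report convention the
#' published proportions follow.
#'
#' @param ledger a [cost_ledger()].
#' @return a `unit_cost_breakdown`: list with `components` (data frame
#'   `component`, `label`, `cost`, `proportion`), `total` (exact INR per
#'   patient), `total_reported` (integer INR, half-up), `total_usd` (2 dp,
#'   from the reported total).
#' @examples
#' b <- unit_delivery_cost(table2_fixture())
#' b$total_reported              # 272
#' b$components$proportion       # 27.94 9.56 3.68 58.82 0.06
#' @export
unit_delivery_cost <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  it <- ledger$items[ledger$items$phase == "delivery", , drop = FALSE]
  costs <- numeric(nrow(it))
  for (i in seq_len(nrow(it))) {
    r <- it[i, ]
    base <- item_cost(r)
    if (isTRUE(r$per_patient)) {
      costs[i] <- base
      next
    }
    if (is.na(r$staff_minutes_per_patient)) {
      stop(sprintf(
        paste0("delivery item '%s' has neither a per-patient price nor ",
               "staff_minutes_per_patient; cannot resolve its per-patient ",
               "cost"), r$item_id), call. = FALSE)
    }
    annual <- if (identical(r$cost_class, "capital")) {
      annualize_capital(base, r$useful_life_years, ledger$discount_rate)
    } else {
      base
    }
    costs[i] <- per_minute_cost(annual, ledger$annual_operational_minutes) *
      r$staff_minutes_per_patient
  }
  total <- sum(costs)
  reported <- round_half_up(total)
  prop <- if (reported > 0) round_half_up(costs / reported * 100, 2) else
    rep(NA_real_, nrow(it))
  structure(
    list(components = data.frame(component = it$item_id, label = it$label,
                                 cost = costs, proportion = prop,
                                 stringsAsFactors = FALSE),
         total = total,
         total_reported = reported,
         total_usd = convert_currency(reported, ledger$exchange_rate)),
    class = "unit_cost_breakdown"
  )
}

#' @export
print.unit_cost_breakdown <- function(x, ...) {
  cat(sprintf("<unit_cost_breakdown> total INR %.2f, reported %s (USD %.2f)\n",
              x$total, format(x$total_reported), x$total_usd))
  print(x$components)
  invisible(x)
}

#' Convert INR to USD
#'
#' @param amount_inr amount in INR.
#' @param exchange_rate INR per USD (> 0).
#' @return amount in USD, rounded to 2 decimal places (half-up).
#' @export
convert_currency <- function(amount_inr, exchange_rate) {
  assert_scalar_num(exchange_rate, "exchange_rate", min = 0,
                    strict_min = TRUE)
  round2(amount_inr / exchange_rate)
}

#' Render a plain-text cost report
#'
#' Deterministic fixed-width table of phase summaries and the delivery
#' unit-cost breakdown, in the layout of the study's published cost table:
#' label, cost in INR with the USD equivalent in parentheses, proportion.
#'
#' @param summaries a list of `phase_cost_summary` objects (may be empty).
#' @param breakdown optionally, a `unit_cost_breakdown`.
#' @param exchange_rate INR per USD used for the parenthetical USD column.
#' @return a character vector of report lines.
#' @export
render_report <- function(summaries = list(), breakdown = NULL,
                          exchange_rate = 74) {
  if (inherits(summaries, "phase_cost_summary")) summaries <- list(summaries)
  lines <- c(sprintf("%-55s %18s %10s", "Cost Components of Intervention",
                     "Cost INR (USD)", "Prop (%)"),
             strrep("-", 85))
  money <- function(x) {
    # sub-rupee cells (e.g. a 0.15 INR phone-bill share) keep 2 dp
    inr <- if (abs(x) < 1 && x != 0) sprintf("%.2f", x) else
      format(round_half_up(x), big.mark = "", scientific = FALSE)
    sprintf("%s (%s)", inr,
            format(convert_currency(x, exchange_rate), nsmall = 2))
  }
  for (s in summaries) {
    lines <- c(lines, sprintf("[%s]", toupper(s$phase)))
    for (i in seq_len(nrow(s$line_items))) {
      li <- s$line_items[i, ]
      lines <- c(lines, sprintf("%-55s %18s %10.2f", li$label,
                                money(li$cost), li$proportion))
    }
    lines <- c(lines, sprintf("%-55s %18s %10s", "Total", money(s$total),
                              "100"))
    lines <- c(lines, sprintf("%-55s %18s", "Unit Cost",
                              format(s$unit_cost)))
  }
  if (!is.null(breakdown)) {
    lines <- c(lines, "[UNIT COST OF SERVICE DELIVERY]")
    for (i in seq_len(nrow(breakdown$components))) {
      co <- breakdown$components[i, ]
      lines <- c(lines, sprintf("%-55s %18s %10.2f", co$label,
                                money(co$cost), co$proportion))
    }
    lines <- c(lines, sprintf("%-55s %18s %10s", "Overall Cost",
                              sprintf("%s (%s)",
                                      format(breakdown$total_reported),
                                      format(breakdown$total_usd,
                                             nsmall = 2)),
                              "100"))
  }
  lines
}
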