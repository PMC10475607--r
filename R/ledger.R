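#' Cost-ledger data model
#'
#' A cost ledger is the package's central input: one row per priced resource
#' item, plus the global parameters every downstream computation needs (the
#' annual discount rate, the patient denominator for unit costs, the INR/USD
#' exchange rate, and the annual operational minutes of a facility resource).
#'
#' Items are classified three ways, following standard micro-costing practice:
#' by *phase* (development, pretest, training, delivery), by *cost class*
#' (capital purchases with a useful life vs. recurrent expenditure), and by
#' *cost behavior* (fixed vs. variable with patient volume). Shared resources
#' carry an `apportionment_fraction`, the share of the resource attributable
#' to the intervention. Delivery items may either be expressed directly per
#' patient served (`per_patient = TRUE`) or be resolved to a per-patient cost
#' through annualization and per-minute costing (see
#' [unit_delivery_cost()]).
#'
#' @name cost_ledger_model
NULL

LEDGER_PHASES  <- c("development", "pretest", "training", "delivery")
COST_CLASSES   <- c("capital", "recurrent")
COST_BEHAVIORS <- c("fixed", "variable")

ITEM_COLUMNS <- c("item_id", "label", "phase", "cost_class", "cost_behavior",
                  "unit_price", "quantity", "useful_life_years",
                  "apportionment_fraction", "staff_minutes_per_patient",
                  "per_patient")

#' Create a single cost item
#'
#' @param item_id short unique identifier.
#' @param label free-text description.
#' @param phase one of `"development"`, `"pretest"`, `"training"`,
#'   `"delivery"` (case-insensitive).
#' @param cost_class `"capital"` or `"recurrent"`.
#' @param cost_behavior `"fixed"` or `"variable"`.
#' @param unit_price price in INR (>= 0). For non-per-patient delivery items
#'   this is the *annual* cost of the resource (a capital item's purchase
#'   price is first annualized).
#' @param quantity count of units (>= 1).
#' @param useful_life_years useful life in years; required for (and only
#'   allowed on) capital purchases that still need annualizing.
#' @param apportionment_fraction fraction in (0, 1] of the resource
#'   attributable to the intervention.
#' @param staff_minutes_per_patient minutes of the resource consumed per
#'   patient; only meaningful on delivery items.
#' @param per_patient `TRUE` if `unit_price` is already expressed per patient
#'   served.
#' @return a one-row `data.frame` with the ledger item columns.
#' @export
cost_item <- function(item_id, label, phase, cost_class, cost_behavior,
                      unit_price, quantity = 1,
                      useful_life_years = NA_real_,
                      apportionment_fraction = 1,
                      staff_minutes_per_patient = NA_real_,
                      per_patient = FALSE) {
  phase <- match.arg(tolower(phase), LEDGER_PHASES)
  cost_class <- match.arg(tolower(cost_class), COST_CLASSES)
  cost_behavior <- match.arg(tolower(cost_behavior), COST_BEHAVIORS)
  data.frame(
    item_id = as.character(item_id), label = as.character(label),
    phase = phase, cost_class = cost_class, cost_behavior = cost_behavior,
    unit_price = as.numeric(unit_price), quantity = as.numeric(quantity),
    useful_life_years = as.numeric(useful_life_years),
    apportionment_fraction = as.numeric(apportionment_fraction),
    staff_minutes_per_patient = as.numeric(staff_minutes_per_patient),
    per_patient = as.logical(per_patient),
    stringsAsFactors = FALSE
  )
}

#' Assemble a cost ledger
#'
#' @param items a `data.frame` of ledger items (rows from [cost_item()], or
#'   any data frame with the same columns). Item order is preserved.
#' @param discount_rate annual discount rate as a fraction in \[0, 0.2\]
#'   (default 0.03, the HTAIn reference-case rate).
#' @param cohort_size patient denominator for unit costs (default 100, the
#'   per-clinic cohort implied by the built-in fixture's unit costs).
#' @param exchange_rate INR per USD (default 74).
#' @param annual_operational_minutes minutes per year a facility resource is
#'   available for service delivery; default 240 working days x 480 minutes.
#' @return an object of class `cost_ledger`.
#' @seealso [validate_ledger()], [read_ledger()], [table2_fixture()]
#' @export
cost_ledger <- function(items = empty_items(), discount_rate = 0.03,
                        cohort_size = 100, exchange_rate = 74,
                        annual_operational_minutes = 240 * 480) {
  if (is.null(items)) items <- empty_items()
  if (nrow(items) > 0) {
    missing <- setdiff(ITEM_COLUMNS, names(items))
    if (length(missing) > 0) {
      stop("ledger items are missing required field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  items <- if (nrow(items) > 0) items[, ITEM_COLUMNS] else empty_items()
  rownames(items) <- NULL
  assert_scalar_num(discount_rate, "discount_rate", min = 0, max = 0.2)
  assert_scalar_num(cohort_size, "cohort_size", min = 1)
  assert_scalar_num(exchange_rate, "exchange_rate", min = 0, strict_min = TRUE)
  assert_scalar_num(annual_operational_minutes, "annual_operational_minutes",
                    min = 0, strict_min = TRUE)
  if (anyDuplicated(items$item_id)) {
    stop("duplicate item_id: ",
         paste(unique(items$item_id[duplicated(items$item_id)]),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(items = items,
         discount_rate = discount_rate,
         cohort_size = cohort_size,
         exchange_rate = exchange_rate,
         annual_operational_minutes = annual_operational_minutes),
    class = "cost_ledger"
  )
}

empty_items <- function() {
  data.frame(
    item_id = character(), label = character(), phase = character(),
    cost_class = character(), cost_behavior = character(),
    unit_price = numeric(), quantity = numeric(),
    useful_life_years = numeric(), apportionment_fraction = numeric(),
    staff_minutes_per_patient = numeric(), per_patient = logical(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("<cost_ledger> %d item(s)\n", nrow(x$items)))
  tab <- table(factor(x$items$phase, levels = LEDGER_PHASES))
  cat("  phases:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf(
    "  discount_rate=%.3f cohort_size=%g exchange_rate=%.2f INR/USD\n",
    x$discount_rate, x$cohort_size, x$exchange_rate))
  invisible(x)
}

#' Validate a cost ledger
#'
#' Checks every item invariant (price, quantity, apportionment range, the
#' capital/useful-life correspondence, staff minutes restricted to the
#' delivery phase) and the ledger-level invariants (unique ids, parameter
#' ranges). Violations are returned, not thrown.
#'
#' @param ledger a [cost_ledger()].
#' @return a `validation_report`: list with `ok` (logical) and `issues`
#'   (data frame with `item_id`, `severity`, `message`). `ok` is `TRUE` iff
#'   there is no issue of severity `"error"`.
#' @examples
#' rep <- validate_ledger(table2_fixture())
#' rep$ok
#' @export
validate_ledger <- function(ledger) {
  stopifnot(inherits(ledger, "cost_ledger"))
  issues <- list()
  add <- function(id, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      item_id = id, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }
  it <- ledger$items
  for (i in seq_len(nrow(it))) {
    r <- it[i, ]
    id <- r$item_id
    if (is.na(id) || !nzchar(id)) add("", "error", "item_id must be non-empty")
    if (!r$phase %in% LEDGER_PHASES)
      add(id, "error", sprintf("unknown phase '%s'", r$phase))
    if (!r$cost_class %in% COST_CLASSES)
      add(id, "error", sprintf("unknown cost_class '%s'", r$cost_class))
    if (!r$cost_behavior %in% COST_BEHAVIORS)
      add(id, "error", sprintf("unknown cost_behavior '%s'", r$cost_behavior))
    if (is.na(r$unit_price) || r$unit_price < 0)
      add(id, "error", "unit_price must be >= 0")
    if (is.na(r$quantity) || r$quantity < 1)
      add(id, "error", "quantity must be >= 1")
    if (is.na(r$apportionment_fraction) ||
        r$apportionment_fraction <= 0 || r$apportionment_fraction > 1)
      add(id, "error", "apportionment_fraction must be in (0, 1]")
    capital_purchase <- identical(r$cost_class, "capital") && !isTRUE(r$per_patient)
    if (capital_purchase && is.na(r$useful_life_years))
      add(id, "error", "useful_life_years required for capital items")
    if (!is.na(r$useful_life_years)) {
      if (!identical(r$cost_class, "capital"))
        add(id, "error", "useful_life_years only allowed on capital items")
      else if (r$useful_life_years < 1)
        add(id, "error", "useful_life_years must be >= 1")
    }
    if (!is.na(r$staff_minutes_per_patient) && r$phase != "delivery")
      add(id, "error", "staff_minutes_per_patient only allowed on delivery items")
    if (!is.na(r$staff_minutes_per_patient) && r$staff_minutes_per_patient < 0)
      add(id, "error", "staff_minutes_per_patient must be >= 0")
  }
  dup <- unique(it$item_id[duplicated(it$item_id)])
  for (d in dup) add(d, "error", "duplicate item_id")
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(item_id = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok = %s, %d issue(s)\n", x$ok,
              nrow(x$issues)))
  if (nrow(x$issues) > 0) print(x$issues)
  invisible(x)
}

#' Built-in cost ledger of the tobacco-cessation costing study
#'
#' The complete published cost ledger of a culturally tailored tobacco
#' cessation package delivered at two district NCD clinics in Punjab, India:
#' four development-phase lines (stakeholder meetings, program-manager
#' workshop and meeting, advocacy workshop), a pretest line, the
#' health-system cost of training healthcare providers, and the five
#' per-patient service-delivery components (human resource time, annualized
#' capital share, pamphlets, SMS & follow-up calls, dedicated phone bill).
#'
#' All delivery components are stored as already-resolved per-patient
#' charges (`per_patient = TRUE`), exactly as published. Global parameters:
#' 3% discount rate, per-clinic cohort of 100 patients (the denominator
#' reproducing the published unit costs of 6,594 INR for development and
#' 1,340 INR for training), exchange rate 74 INR/USD.
#'
#' @return a validated [cost_ledger()].
#' @examples
#' led <- table2_fixture()
#' unit_delivery_cost(led)$total_reported  # 272
#' @export
table2_fixture <- function() {
  items <- rbind(
    cost_item("dev_civil_meetings", "Meetings with civil society (n = 2)",
              "development", "recurrent", "variable", 9396),
    cost_item("dev_pm_workshop", "Workshop with Program Manager (n = 1)",
              "development", "recurrent", "variable", 491040),
    cost_item("dev_pm_meeting", "Meeting with Program Manager (n = 1)",
              "development", "recurrent", "variable", 93795),
    cost_item("dev_advocacy", "Advocacy Workshop (n = 1)",
              "development", "recurrent", "variable", 53593),
    cost_item("pretest", "Cost of doing a pre-test",
              "pretest", "recurrent", "variable", 11620),
    cost_item("training_hcp", "Total Health System Cost of Training of HCP",
              "training", "recurrent", "fixed", 134002),
    cost_item("human_resource", "Human Resource",
              "delivery", "recurrent", "variable", 76, per_patient = TRUE),
    cost_item("capital", "Capital Cost (Building, Furniture, Equipment)",
              "delivery", "recurrent", "fixed", 26, per_patient = TRUE),
    cost_item("pamphlets", "Pamphlets (IEC)",
              "delivery", "recurrent", "variable", 10, per_patient = TRUE),
    cost_item("sms_calls", "SMS and Follow-up calls (HR)",
              "delivery", "recurrent", "fixed", 160, per_patient = TRUE),
    cost_item("phone_bill", "Dedicated Phone Bill",
              "delivery", "recurrent", "fixed", 0.15, per_patient = TRUE)
  )
  cost_ledger(items, discount_rate = 0.03, cohort_size = 100,
              exchange_rate = 74)
}
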