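#' Scale-up scenario models
#'
#' Four scenario families quantify how the per-patient cost falls when the
#' intervention is rolled out at scale: (I) disease-specific group
#' counseling, which shares the counselor's time, capital, and the dedicated
#' phone line across a group; (II) bulk procurement of pamphlets and of the
#' SMS & follow-up call package at a negotiated discount; (III) integrating
#' provider training into routine in-service programs, modelled as a
#' discount on the unit training cost; and (IV) the cumulative combination
#' of group counseling and bulk procurement.
#'
#' @name scenarios
NULL

#' Scenario configuration
#'
#' Partitions delivery components into a *shareable* pool (divided across a
#' counseling group) and a *discountable* pool (subject to bulk-procurement
#' discounts). The default partition — shareable = human resource, capital,
#' dedicated phone bill; discountable = pamphlets, SMS & follow-up calls —
#' reproduces every published scenario figure exactly and is fully
#' overridable for other ledgers.
#'
#' @param shareable component ids divided across a counseling group.
#' @param discountable component ids subject to bulk discounts.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(shareable = c("human_resource", "capital",
                                          "phone_bill"),
                            discountable = c("pamphlets", "sms_calls")) {
  structure(list(shareable = shareable, discountable = discountable),
            class = "scenario_config")
}

pool_sum <- function(breakdown, ids) {
  sum(breakdown$components$cost[breakdown$components$component %in% ids])
}

scenario_result <- function(scenario, axis_value, exact, components = NULL) {
  structure(list(scenario = scenario, axis_value = axis_value,
                 per_patient_cost = round_half_up(exact),
                 exact = exact, components = components),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s @ %s: INR %s/patient (exact %.4f)\n",
              x$scenario, format(x$axis_value), format(x$per_patient_cost),
              x$exact))
  invisible(x)
}

#' Scenario I: group counseling
#'
#' Per-patient delivery cost when counseling is delivered to groups of
#' `group_size` patients: the shareable pool is divided by the group size,
#' non-shareable components are unchanged; half-up rounding at the final
#' figure only.
#'
#' @param breakdown a `unit_cost_breakdown` (see [unit_delivery_cost()]).
#' @param group_size patients per counseling group (>= 1).
#' @param config a [scenario_config()].
#' @return a `scenario_result` with `per_patient_cost` in integer INR.
#' @examples
#' b <- unit_delivery_cost(table2_fixture())
#' group_counseling_cost(b, 10)$per_patient_cost  # 180
#' @export
group_counseling_cost <- function(breakdown, group_size,
                                  config = scenario_config()) {
  stopifnot(inherits(breakdown, "unit_cost_breakdown"))
  assert_scalar_num(group_size, "group_size", min = 1)
  shareable <- pool_sum(breakdown, config$shareable)
  rest <- breakdown$total - shareable
  exact <- rest + shareable / group_size
  scenario_result("group", group_size, exact,
                  components = c(shareable = shareable / group_size,
                                 non_shareable = rest))
}

#' Scenario II: bulk procurement discount
#'
#' Per-patient cost when the discountable pool (pamphlets, SMS & calls) is
#' procured in bulk at a fractional `discount`.
#'
#' @param breakdown a `unit_cost_breakdown`.
#' @param discount fraction in \[0, 1).
#' @param config a [scenario_config()].
#' @return a `scenario_result`.
#' @examples
#' b <- unit_delivery_cost(table2_fixture())
#' bulk_discount_cost(b, 0.30)$per_patient_cost  # 221
#' @export
bulk_discount_cost <- function(breakdown, discount,
                               config = scenario_config()) {
  stopifnot(inherits(breakdown, "unit_cost_breakdown"))
  if (discount < 0 || discount >= 1) {
    stop("discount must be in [0, 1)", call. = FALSE)
  }
  pool <- pool_sum(breakdown, config$discountable)
  exact <- breakdown$total - discount * pool
  scenario_result("bulk", discount, exact,
                  components = c(discountable = (1 - discount) * pool,
                                 other = breakdown$total - pool))
}

#' Scenario III: integrated training discount
#'
#' Per-patient training cost when provider training is folded into routine
#' in-service programs, abstracted as a fractional discount on the unit
#' training cost.
#'
#' @param unit_training_cost training cost per patient, INR (>= 0).
#' @param discount fraction in \[0, 1).
#' @return a `scenario_result`.
#' @examples
#' training_discount_cost(1340, 0.20)$per_patient_cost  # 1072
#' @export
training_discount_cost <- function(unit_training_cost, discount) {
  assert_scalar_num(unit_training_cost, "unit_training_cost", min = 0)
  if (discount < 0 || discount >= 1) {
    stop("discount must be in [0, 1)", call. = FALSE)
  }
  exact <- unit_training_cost * (1 - discount)
  scenario_result("training", discount, exact)
}

#' Scenario IV: cumulative (group counseling + bulk discount)
#'
#' Implementation cost = shareable pool / group size + (1 - discount) x
#' discountable pool (+ any component in neither pool at base), rounded
#' half-up; total = implementation + discounted unit training cost (sum of
#' the two rounded figures, as reported).
#'
#' @param breakdown a `unit_cost_breakdown`.
#' @param unit_training_cost training cost per patient, INR.
#' @param group_size patients per counseling group (>= 1).
#' @param discount fraction in \[0, 1) applied to both the discountable
#'   pool and the training cost.
#' @param config a [scenario_config()].
#' @return list with `implementation` and `total_with_training`, both
#'   `scenario_result` objects.
#' @examples
#' b <- unit_delivery_cost(table2_fixture())
#' r <- cumulative_scenario(b, 1340, group_size = 5, discount = 0.10)
#' r$implementation$per_patient_cost      # 173
#' r$total_with_training$per_patient_cost # 1379
#' @export
cumulative_scenario <- function(breakdown, unit_training_cost, group_size,
                                discount, config = scenario_config()) {
  stopifnot(inherits(breakdown, "unit_cost_breakdown"))
  assert_scalar_num(group_size, "group_size", min = 1)
  if (discount < 0 || discount >= 1) {
    stop("discount must be in [0, 1)", call. = FALSE)
  }
  shareable <- pool_sum(breakdown, config$shareable)
  discountable <- pool_sum(breakdown, config$discountable)
  other <- breakdown$total - shareable - discountable
  impl_exact <- shareable / group_size + (1 - discount) * discountable + other
  impl <- scenario_result("cumulative", c(group_size = group_size,
                                          discount = discount), impl_exact)
  training <- training_discount_cost(unit_training_cost, discount)
  total <- scenario_result(
    "cumulative_total", c(group_size = group_size, discount = discount),
    impl$per_patient_cost + training$per_patient_cost)
  list(implementation = impl, total_with_training = total)
}

#' Scenario grid
#'
#' Convenience sweep producing the published scenario table layout: group
#' sizes for Scenario I, discounts for Scenarios II and III.
#'
#' @param ledger a [cost_ledger()].
#' @param group_sizes group sizes for Scenario I (default 5, 10, 15, 20).
#' @param discounts discounts for Scenarios II/III (default 10–40%).
#' @param config a [scenario_config()].
#' @return data frame `scenario`, `axis`, `per_patient_cost`.
#' @export
scenario_grid <- function(ledger, group_sizes = c(5, 10, 15, 20),
                          discounts = c(0.10, 0.20, 0.30, 0.40),
                          config = scenario_config()) {
  bd <- unit_delivery_cost(ledger)
  unit_training <- phase_summary(ledger, "training")$unit_cost
  rows <- list()
  for (g in group_sizes) {
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = "I_group", axis = g,
      per_patient_cost = group_counseling_cost(bd, g, config)$per_patient_cost)
  }
  for (d in discounts) {
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = "II_bulk", axis = d,
      per_patient_cost = bulk_discount_cost(bd, d, config)$per_patient_cost)
  }
  for (d in discounts) {
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = "III_training", axis = d,
      per_patient_cost = training_discount_cost(unit_training,
                                                d)$per_patient_cost)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
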