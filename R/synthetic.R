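#' Synthetic cost ledgers with known ground truth
#'
#' Generates randomized multi-phase cost ledgers that emulate the resource
#' structure of a clinic-based intervention — development and training
#' lines, capital goods with useful lives and per-patient usage minutes,
#' salaried staff with per-patient contact minutes, and per-patient
#' consumable/communication items — together with analytically computed
#' ground-truth totals. The ground truth is computed at generation time
#' with its own explicit arithmetic (loop-based discount sums, no shared
#' aggregation code), so it serves as an independent oracle for the
#' costing pipeline.
#'
#' @name synthetic_data
NULL

#' Synthetic-ledger configuration
#'
#' Prices are drawn log-uniformly over `price_range` (development, training,
#' capital and staff lines) to mimic the wide span of real ledgers;
#' per-patient consumable prices are drawn log-uniformly over
#' `price_range / 1000` (floored at 0.05 INR). All drawn money values are
#' rounded to 2 decimal places so ledgers survive CSV serialization
#' losslessly.
#'
#' @param seed integer seed; the same seed always yields the identical
#'   ledger.
#' @param n_capital_items delivery-phase capital goods (annualized path).
#' @param n_staff_roles delivery-phase salaried roles (per-minute path).
#' @param n_consumables delivery-phase per-patient items.
#' @param n_development_items development-phase lines (plus one pretest
#'   line whenever > 0).
#' @param price_range c(min, max) INR for drawn prices.
#' @param life_range c(min, max) years for capital useful lives (integers).
#' @param minutes_range c(min, max) minutes per patient (integers).
#' @param cohort_size patient denominator.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1, n_capital_items = 2, n_staff_roles = 3,
                         n_consumables = 3, n_development_items = 4,
                         price_range = c(100, 500000),
                         life_range = c(3, 10), minutes_range = c(2, 20),
                         cohort_size = 100) {
  stopifnot(length(price_range) == 2, length(life_range) == 2,
            length(minutes_range) == 2)
  if (price_range[1] <= 0 || diff(price_range) < 0 || diff(life_range) < 0 ||
      diff(minutes_range) < 0) {
    stop("degenerate range(s) in synth_config", call. = FALSE)
  }
  if (life_range[1] < 1) stop("life_range must start at >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_capital_items = n_capital_items,
                 n_staff_roles = n_staff_roles,
                 n_consumables = n_consumables,
                 n_development_items = n_development_items,
                 price_range = price_range, life_range = life_range,
                 minutes_range = minutes_range, cohort_size = cohort_size),
            class = "synth_config")
}

rlogunif2 <- function(n, lo, hi) {
  round(exp(stats::runif(n, log(lo), log(hi))), 2)
}

# annuity factor by explicit discount-sum loop: deliberately separate from
# annuity_factor() so ground truth does not share the closed form it checks
loop_annuity <- function(rate, life) {
  if (rate == 0) return(life)
  s <- 0
  for (t in seq_len(life)) s <- s + (1 + rate)^(-t)
  s
}

#' Generate a synthetic ledger with ground truth
#'
#' @param config a [synth_config()].
#' @return list with `ledger` (a validated [cost_ledger()]) and `truth`,
#'   which holds `unit_cost` (exact per-patient delivery total),
#'   `component_costs` (named, exact), `phase_totals` (named),
#'   `scenario_config` (capital + staff shareable, consumables
#'   discountable), `group_costs` (exact per-patient cost at group sizes
#'   1/5/10/20), `bulk_costs` (exact at 10–40% discounts) and `dsa_ranges`
#'   (0.4 x component, the exact one-way range under a +/-20% spread).
#' @export
generate_ledger <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  pr <- config$price_range
  items <- list()
  add <- function(x) items[[length(items) + 1L]] <<- x

  n_dev <- config$n_development_items
  if (n_dev > 0) {
    for (i in seq_len(n_dev)) {
      add(cost_item(sprintf("dev_%02d", i), sprintf("Development line %d", i),
                    "development", "recurrent", "variable",
                    rlogunif2(1, pr[1], pr[2]),
                    apportionment_fraction = sample(seq(20, 100, 5), 1) / 100))
    }
    add(cost_item("pretest_01", "Pretest", "pretest", "recurrent",
                  "variable", rlogunif2(1, pr[1], pr[2])))
    add(cost_item("train_01", "Provider training", "training", "recurrent",
                  "fixed", rlogunif2(1, pr[1], pr[2])))
  }
  for (i in seq_len(config$n_capital_items)) {
    add(cost_item(sprintf("cap_%02d", i), sprintf("Capital good %d", i),
                  "delivery", "capital", "fixed",
                  rlogunif2(1, pr[1], pr[2]),
                  quantity = sample(1:3, 1),
                  useful_life_years = sample(config$life_range[1]:
                                             config$life_range[2], 1),
                  apportionment_fraction = sample(seq(20, 100, 5), 1) / 100,
                  staff_minutes_per_patient =
                    sample(config$minutes_range[1]:config$minutes_range[2],
                           1)))
  }
  for (i in seq_len(config$n_staff_roles)) {
    add(cost_item(sprintf("staff_%02d", i), sprintf("Staff role %d", i),
                  "delivery", "recurrent", "variable",
                  rlogunif2(1, pr[1], pr[2]),
                  apportionment_fraction = sample(seq(20, 100, 5), 1) / 100,
                  staff_minutes_per_patient =
                    sample(config$minutes_range[1]:config$minutes_range[2],
                           1)))
  }
  for (i in seq_len(config$n_consumables)) {
    add(cost_item(sprintf("cons_%02d", i), sprintf("Consumable %d", i),
                  "delivery", "recurrent", "variable",
                  rlogunif2(1, max(pr[1] / 1000, 0.05),
                            max(pr[2] / 1000, 0.10)),
                  per_patient = TRUE))
  }
  items <- if (length(items)) do.call(rbind, items) else empty_items()
  ledger <- cost_ledger(items, discount_rate = 0.03,
                        cohort_size = config$cohort_size)
  list(ledger = ledger, truth = compute_truth(ledger))
}

# independent ground-truth arithmetic: per-item loops, loop-based annuity
compute_truth <- function(ledger) {
  it <- ledger$items
  M <- ledger$annual_operational_minutes
  comp <- numeric(0)
  shareable <- character(0)
  discountable <- character(0)
  for (i in seq_len(nrow(it))) {
    r <- it[i, ]
    if (r$phase != "delivery") next
    base <- r$unit_price * r$quantity * r$apportionment_fraction
    if (isTRUE(r$per_patient)) {
      pp <- base
      discountable <- c(discountable, r$item_id)
    } else if (identical(r$cost_class, "capital")) {
      pp <- base / loop_annuity(ledger$discount_rate, r$useful_life_years) /
        M * r$staff_minutes_per_patient
      shareable <- c(shareable, r$item_id)
    } else {
      pp <- base / M * r$staff_minutes_per_patient
      shareable <- c(shareable, r$item_id)
    }
    comp[r$item_id] <- pp
  }
  unit_cost <- sum(comp)
  phase_totals <- vapply(LEDGER_PHASES, function(ph) {
    s <- 0
    for (i in seq_len(nrow(it))) {
      if (it$phase[i] == ph) {
        s <- s + it$unit_price[i] * it$quantity[i] *
          it$apportionment_fraction[i]
      }
    }
    s
  }, numeric(1))
  share_sum <- sum(comp[shareable])
  disc_sum <- sum(comp[discountable])
  groups <- c(1, 5, 10, 20)
  bulk <- c(0.10, 0.20, 0.30, 0.40)
  list(
    unit_cost = unit_cost,
    component_costs = comp,
    phase_totals = phase_totals,
    scenario_config = scenario_config(shareable = shareable,
                                      discountable = discountable),
    group_costs = stats::setNames(
      (unit_cost - share_sum) + share_sum / groups, groups),
    bulk_costs = stats::setNames(unit_cost - bulk * disc_sum, bulk),
    dsa_ranges = 0.4 * comp
  )
}

#' End-to-end recovery suite on synthetic ledgers
#'
#' For each seed, generates a ledger and runs the costing engine, scenario
#' models and one-way DSA against the
#' analytically computed ground truth (relative tolerance `tol`). Failures
#' are reported, not thrown.
#'
#' @param n_seeds number of seeds to run (seeds are `1:n_seeds`).
#' @param config a [synth_config()] used as the template (its `seed` is
#'   overridden).
#' @param tol relative tolerance (default 1e-9).
#' @return a `recovery_report`: list with `per_seed` (logical data frame,
#'   one row per seed), `n_pass`, `n_fail`.
#' @export
recovery_suite <- function(n_seeds = 100, config = synth_config(),
                           tol = 1e-9) {
  stopifnot(n_seeds >= 1)
  rel_ok <- function(a, b) {
    all(abs(a - b) <= tol * pmax(abs(b), 1))
  }
  rows <- lapply(seq_len(n_seeds), function(s) {
    config$seed <- s
    gen <- generate_ledger(config)
    led <- gen$ledger
    tr <- gen$truth
    bd <- unit_delivery_cost(led)
    comp <- stats::setNames(bd$components$cost, bd$components$component)
    sc <- tr$scenario_config
    groups <- as.numeric(names(tr$group_costs))
    grp <- vapply(groups, function(g)
      group_counseling_cost(bd, g, sc)$exact, numeric(1))
    bulks <- as.numeric(names(tr$bulk_costs))
    blk <- vapply(bulks, function(d)
      bulk_discount_cost(bd, d, sc)$exact, numeric(1))
    dsa_ok <- TRUE
    if (length(comp) > 0) {
      params <- lapply(names(comp), function(id) dsa_parameter(id, id))
      res <- one_way_dsa(led, params)
      got <- abs(res$entries$output_at_high_exact -
                 res$entries$output_at_low_exact)
      dsa_ok <- rel_ok(got, unname(tr$dsa_ranges[res$entries$parameter]))
    }
    data.frame(
      seed = s,
      valid = validate_ledger(led)$ok,
      unit_cost = rel_ok(bd$total, tr$unit_cost),
      components = rel_ok(unname(comp[names(tr$component_costs)]),
                          unname(tr$component_costs)),
      phases = rel_ok(
        vapply(LEDGER_PHASES,
               function(ph) phase_summary(led, ph)$total, numeric(1)),
        unname(tr$phase_totals[LEDGER_PHASES])),
      groups = rel_ok(grp, unname(tr$group_costs)),
      bulk = rel_ok(blk, unname(tr$bulk_costs)),
      dsa = dsa_ok
    )
  })
  per_seed <- do.call(rbind, rows)
  ok <- apply(per_seed[, -1, drop = FALSE], 1, all)
  structure(list(per_seed = per_seed, n_pass = sum(ok),
                 n_fail = sum(!ok)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d/%d seed(s) pass\n", x$n_pass,
              x$n_pass + x$n_fail))
  if (x$n_fail > 0) print(x$per_seed[!apply(x$per_seed[, -1], 1, all), ])
  invisible(x)
}
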