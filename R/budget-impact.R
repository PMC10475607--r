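#' Budget-impact projection
#'
#' Projects the total program cost of one clinic over a multi-year horizon:
#' initial provider training in year 1, refresher training at a stated
#' interval thereafter, and annual service delivery at the clinic's patient
#' capacity, with each year's cost discounted to present value. Costs are
#' booked at the start of the year, so year 1 is undiscounted and year t
#' carries the factor (1 + r)^-(t - 1).
#'
#' @name budget_impact
NULL

#' Budget-impact configuration
#'
#' @param horizon_years projection horizon in years (>= 1, default 10).
#' @param annual_patients patients served per year (>= 0).
#' @param unit_delivery_cost per-patient delivery cost, INR.
#' @param initial_training_cost training cost incurred in year 1, INR.
#' @param refresher_training_cost cost of each refresher training, INR.
#' @param refresher_interval_years years between refresher trainings
#'   (>= 1); a refresher falls in every year t > 1 with
#'   (t - 1) divisible by the interval.
#' @param discount_rate annual discount rate (default 0.03).
#' @return a `bia_config` list.
#' @export
bia_config <- function(horizon_years = 10, annual_patients,
                       unit_delivery_cost, initial_training_cost = 0,
                       refresher_training_cost = 0,
                       refresher_interval_years = 1,
                       discount_rate = 0.03) {
  assert_scalar_num(horizon_years, "horizon_years", min = 1)
  assert_scalar_num(annual_patients, "annual_patients", min = 0)
  assert_scalar_num(unit_delivery_cost, "unit_delivery_cost", min = 0)
  assert_scalar_num(initial_training_cost, "initial_training_cost", min = 0)
  assert_scalar_num(refresher_training_cost, "refresher_training_cost",
                    min = 0)
  assert_scalar_num(refresher_interval_years, "refresher_interval_years",
                    min = 1)
  assert_scalar_num(discount_rate, "discount_rate", min = 0)
  structure(list(horizon_years = horizon_years,
                 annual_patients = annual_patients,
                 unit_delivery_cost = unit_delivery_cost,
                 initial_training_cost = initial_training_cost,
                 refresher_training_cost = refresher_training_cost,
                 refresher_interval_years = refresher_interval_years,
                 discount_rate = discount_rate),
            class = "bia_config")
}

#' Project multi-year program costs
#'
#' @param config a [bia_config()].
#' @return a `bia_result`: list with `yearly` (data frame `year`,
#'   `training`, `delivery`, `total`, `discounted`), `undiscounted_sum`,
#'   `discounted_sum`.
#' @examples
#' cfg <- bia_config(horizon_years = 1, annual_patients = 100,
#'                   unit_delivery_cost = 272,
#'                   initial_training_cost = 134002)
#' project_costs(cfg)$undiscounted_sum  # 161202
#' @export
project_costs <- function(config) {
  stopifnot(inherits(config, "bia_config"))
  years <- seq_len(config$horizon_years)
  training <- numeric(length(years))
  training[1] <- config$initial_training_cost
  refresher <- years > 1 &
    (years - 1) %% config$refresher_interval_years == 0
  training[refresher] <- training[refresher] + config$refresher_training_cost
  delivery <- rep(config$annual_patients * config$unit_delivery_cost,
                  length(years))
  total <- training + delivery
  disc <- total * (1 + config$discount_rate)^(-(years - 1))
  structure(
    list(yearly = data.frame(year = years, training = training,
                             delivery = delivery, total = total,
                             discounted = disc),
         undiscounted_sum = sum(total),
         discounted_sum = sum(disc)),
    class = "bia_result"
  )
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf(
    "<bia_result> %d year(s): undiscounted INR %.2f, discounted INR %.2f\n",
    nrow(x$yearly), x$undiscounted_sum, x$discounted_sum))
  print(x$yearly)
  invisible(x)
}
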