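#' Annuity factor
#'
#' Present value of one currency unit paid at the end of each year for
#' `life` years, discounted at annual rate `rate`:
#' \deqn{A(r, L) = \frac{1 - (1+r)^{-L}}{r}, \qquad A(0, L) = L.}
#' This is the standard health-economics annualization convention (payments
#' in arrears). `A` is strictly increasing in `life` and strictly decreasing
#' in `rate`.
#'
#' @param rate annual discount rate (fraction, >= 0).
#' @param life useful life in years (>= 1).
#' @return the dimensionless annuity factor.
#' @examples
#' annuity_factor(0.03, 7)  # 6.23028...
#' annuity_factor(0, 7)     # 7
#' @export
annuity_factor <- function(rate, life) {
  assert_scalar_num(rate, "rate", min = 0)
  assert_scalar_num(life, "life", min = 1)
  if (rate == 0) return(life)
  (1 - (1 + rate)^(-life)) / rate
}

#' Annualize a capital purchase
#'
#' Converts a capital purchase price into the equivalent annual cost over
#' the asset's useful life: the constant annual amount whose discounted
#' stream over the life sums back to the purchase price.
#'
#' @param purchase_price purchase price in INR (>= 0).
#' @param useful_life_years useful life in years (>= 1).
#' @param discount_rate annual discount rate (default 0.03).
#' @param method `"annuity"` (default; purchase_price / [annuity_factor()])
#'   or `"straight_line"` (purchase_price / life, no discounting), kept for
#'   comparison.
#' @return annual cost in INR per year.
#' @examples
#' annualize_capital(6230.28, 7, 0.03)  # ~1000 INR/year
#' @export
annualize_capital <- function(purchase_price, useful_life_years,
                              discount_rate = 0.03,
                              method = c("annuity", "straight_line")) {
  method <- match.arg(method)
  assert_scalar_num(purchase_price, "purchase_price", min = 0)
  if (method == "straight_line") {
    assert_scalar_num(useful_life_years, "useful_life_years", min = 1)
    return(purchase_price / useful_life_years)
  }
  purchase_price / annuity_factor(discount_rate, useful_life_years)
}

#' Per-minute cost of an annual resource
#'
#' @param annual_cost cost in INR per year.
#' @param annual_operational_minutes minutes per year the resource is
#'   available for service delivery (> 0); the package default is 240
#'   working days x 480 minutes = 115,200.
#' @return cost in INR per minute.
#' @export
per_minute_cost <- function(annual_cost, annual_operational_minutes) {
  assert_scalar_num(annual_cost, "annual_cost", min = 0)
  assert_scalar_num(annual_operational_minutes,
                    "annual_operational_minutes", min = 0, strict_min = TRUE)
  annual_cost / annual_operational_minutes
}

#' Opportunity cost of staff time per patient
#'
#' Values a staff member's contact time at their gross salary rate: the
#' per-minute salary (gross monthly salary over working days times working
#' minutes per day) multiplied by the minutes dedicated to one patient.
#'
#' @param gross_salary_per_month gross salary in INR/month (> 0).
#' @param working_days_per_month working days per month (> 0).
#' @param working_minutes_per_day working minutes per day (> 0).
#' @param minutes_per_patient contact minutes per patient (>= 0).
#' @return cost in INR per patient.
#' @examples
#' staff_cost_per_patient(48000, 20, 480, 10)  # 50
#' @export
staff_cost_per_patient <- function(gross_salary_per_month,
                                   working_days_per_month,
                                   working_minutes_per_day,
                                   minutes_per_patient) {
  assert_scalar_num(gross_salary_per_month, "gross_salary_per_month",
                    min = 0, strict_min = TRUE)
  assert_scalar_num(working_days_per_month, "working_days_per_month",
                    min = 0, strict_min = TRUE)
  assert_scalar_num(working_minutes_per_day, "working_minutes_per_day",
                    min = 0, strict_min = TRUE)
  assert_scalar_num(minutes_per_patient, "minutes_per_patient", min = 0)
  gross_salary_per_month /
    (working_days_per_month * working_minutes_per_day) * minutes_per_patient
}

#' Apportion a shared resource
#'
#' Assigns the share of a shared resource's cost attributable to the
#' intervention. Shares across users whose fractions sum to one conserve
#' the total exactly.
#'
#' @param total_cost cost in INR.
#' @param fraction fraction in \[0, 1\].
#' @return apportioned cost in INR.
#' @export
apportion <- function(total_cost, fraction) {
  assert_scalar_num(fraction, "fraction", min = 0, max = 1)
  total_cost * fraction
}
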