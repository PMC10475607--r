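fixture_breakdown <- function() unit_delivery_cost(table2_fixture())

test_that("group counseling reproduces all published Scenario I cells", {
  b <- fixture_breakdown()
  got <- vapply(c(5, 10, 15, 20),
                function(g) group_counseling_cost(b, g)$per_patient_cost,
                numeric(1))
  expect_equal(got, c(190, 180, 177, 175))
  expect_equal(group_counseling_cost(b, 1)$per_patient_cost, 272)
  expect_error(group_counseling_cost(b, 0), "group_size")
})

test_that("group counseling is monotone and converges to the fixed floor", {
  b <- fixture_breakdown()
  sizes <- 1:40
  costs <- vapply(sizes,
                  function(g) group_counseling_cost(b, g)$exact, numeric(1))
  expect_true(all(diff(costs) < 0))
  # limit = non-shareable pool (pamphlets + SMS/calls = 170)
  expect_equal(group_counseling_cost(b, 1e9)$exact, 170, tolerance = 1e-6)
})

test_that("bulk discount reproduces Scenario II and is affine in discount", {
  b <- fixture_breakdown()
  got <- vapply(c(0.10, 0.20, 0.30, 0.40),
                function(d) bulk_discount_cost(b, d)$per_patient_cost,
                numeric(1))
  expect_equal(got, c(255, 238, 221, 204))
  expect_equal(bulk_discount_cost(b, 0)$per_patient_cost, 272)
  # slope = -sum(discountable pool) pre-rounding
  d <- seq(0, 0.9, 0.1)
  exact <- vapply(d, function(x) bulk_discount_cost(b, x)$exact, numeric(1))
  expect_equal(diff(exact) / 0.1, rep(-170, length(d) - 1),
               tolerance = 1e-9)
  expect_error(bulk_discount_cost(b, 1), "discount")
})

test_that("integrated training reproduces Scenario III", {
  got <- vapply(c(0.10, 0.20, 0.30, 0.40),
                function(d) training_discount_cost(1340, d)$per_patient_cost,
                numeric(1))
  expect_equal(got, c(1206, 1072, 938, 804))
  expect_equal(training_discount_cost(1340, 0)$per_patient_cost, 1340)
  expect_error(training_discount_cost(-1, 0.1), "unit_training_cost")
})

test_that("cumulative scenario reproduces the published minimal/optimistic cells", {
  b <- fixture_breakdown()
  minimal <- cumulative_scenario(b, 1340, group_size = 5, discount = 0.10)
  expect_equal(minimal$implementation$per_patient_cost, 173)
  expect_equal(minimal$total_with_training$per_patient_cost, 1379)
  optimistic <- cumulative_scenario(b, 1340, group_size = 20,
                                    discount = 0.40)
  expect_equal(optimistic$implementation$per_patient_cost, 107)
  expect_equal(optimistic$total_with_training$per_patient_cost, 911)
  # degenerate settings recover the base case
  base <- cumulative_scenario(b, 1340, group_size = 1, discount = 0)
  expect_equal(base$implementation$per_patient_cost, 272)
  expect_equal(base$total_with_training$per_patient_cost, 272 + 1340)
})

test_that("cumulative never exceeds either single scenario at the same settings", {
  b <- fixture_breakdown()
  for (g in c(2, 5, 10, 20)) {
    for (d in c(0.1, 0.25, 0.4)) {
      cum <- cumulative_scenario(b, 1340, g, d)$implementation$exact
      expect_lte(cum, group_counseling_cost(b, g)$exact + 1e-12)
      expect_lte(cum, bulk_discount_cost(b, d)$exact + 1e-12)
    }
  }
})

test_that("scenario grid emits the published table layout", {
  grid <- scenario_grid(table2_fixture())
  expect_equal(grid$per_patient_cost[grid$scenario == "I_group"],
               c(190, 180, 177, 175))
  expect_equal(grid$per_patient_cost[grid$scenario == "II_bulk"],
               c(255, 238, 221, 204))
  expect_equal(grid$per_patient_cost[grid$scenario == "III_training"],
               c(1206, 1072, 938, 804))
})

test_that("the scenario partition is overridable for other ledgers", {
  b <- fixture_breakdown()
  cfg <- scenario_config(shareable = "sms_calls", discountable = "pamphlets")
  # 272.15 - 160 + 160/10 = 128.15 -> 128
  expect_equal(group_counseling_cost(b, 10, cfg)$per_patient_cost, 128)
  # 272.15 - 0.5 * 10 = 267.15 -> 267
  expect_equal(bulk_discount_cost(b, 0.5, cfg)$per_patient_cost, 267)
})
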