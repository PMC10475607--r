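test_that("bounds resolve to +-20% by default and pass explicit bounds", {
  expect_equal(resolve_bounds(dsa_parameter("sms", base_value = 160)),
               c(low = 128, high = 192))
  expect_equal(resolve_bounds(dsa_parameter("overall", base_value = 272)),
               c(low = 217.6, high = 326.4))
  expect_equal(resolve_bounds(dsa_parameter("overall", base_value = 272,
                                            low = 184, high = 326)),
               c(low = 184, high = 326))
  expect_error(dsa_parameter("bad", base_value = 10, low = 20, high = 5),
               "bound")
})

test_that("the overall-package parameter reproduces the published range top", {
  led <- table2_fixture()
  res <- one_way_dsa(led, dsa_parameter("Overall package cost", "total"))
  expect_equal(res$base_output, 272)
  expect_equal(res$entries$output_at_low, 218)
  expect_equal(res$entries$output_at_high, 326)
  expect_equal(res$overall_max, 326)
})

test_that("component perturbations match a brute-force rebuild", {
  led <- table2_fixture()
  b <- unit_delivery_cost(led)
  comp <- setNames(as.list(b$components$cost), b$components$component)
  params <- lapply(names(comp), function(id) dsa_parameter(id, id))
  res <- one_way_dsa(led, params)
  for (i in seq_len(nrow(res$entries))) {
    id <- res$entries$parameter[i]
    base <- comp[[id]]
    expect_equal(res$entries$output_at_low_exact[i],
                 brute_force_total(comp, id, 0.8 * base), tolerance = 1e-12)
    expect_equal(res$entries$output_at_high_exact[i],
                 brute_force_total(comp, id, 1.2 * base), tolerance = 1e-12)
    # symmetric +-20% on an additive component: exact range = 0.4 x base
    expect_equal(res$entries$output_at_high_exact[i] -
                   res$entries$output_at_low_exact[i],
                 0.4 * base, tolerance = 1e-12)
    # outputs bracket the base output
    expect_lte(res$entries$output_at_low[i], res$base_output)
    expect_gte(res$entries$output_at_high[i], res$base_output)
  }
  expect_lte(res$overall_min, res$base_output)
  expect_gte(res$overall_max, res$base_output)
  # the largest component (SMS & calls) dominates the component ranking
  expect_equal(res$ranking[1], "sms_calls")
})

test_that("degenerate and misconfigured parameters behave", {
  led <- table2_fixture()
  res <- one_way_dsa(led, dsa_parameter("fixed sms", "sms_calls",
                                        low = 160, high = 160))
  expect_equal(res$entries$range, 0)
  expect_equal(res$entries$output_at_low, res$base_output)
  expect_error(one_way_dsa(led, dsa_parameter("ghost", "no_such")),
               "unknown component")
})

test_that("tornado table sorts by range with lexicographic tie-breaks", {
  led <- table2_fixture()
  params <- c(lapply(c("human_resource", "capital", "pamphlets", "sms_calls",
                       "phone_bill"), function(id) dsa_parameter(id, id)),
              list(dsa_parameter("Overall package cost", "total")))
  res <- one_way_dsa(led, params)
  tt <- tornado_table(res, top_n = 6)
  # the whole-package parameter outranks every single component
  expect_equal(tt$parameter[1], "Overall package cost")
  expect_equal(tt$parameter[2], "sms_calls")
  expect_true(all(diff(tt$range) <= 0))
  expect_equal(nrow(tornado_table(res, top_n = 3)), 3)
  expect_error(tornado_table(res, top_n = 0), "top_n")
  # tie-break: equal-range parameters come out in lexicographic order
  tie <- one_way_dsa(led, list(dsa_parameter("b_param", "sms_calls"),
                               dsa_parameter("a_param", "sms_calls")))
  expect_equal(tornado_table(tie)$parameter, c("a_param", "b_param"))
  single <- one_way_dsa(led, dsa_parameter("solo", "pamphlets"))
  expect_equal(nrow(tornado_table(single)), 1)
})
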