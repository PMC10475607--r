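test_that("development phase summary reproduces the published totals", {
  led <- table2_fixture()
  with_pre <- phase_summary(led, "development", include_pretest = TRUE)
  expect_equal(with_pre$total, 659444)        # printed total 659447, +-3 slack
  expect_lte(abs(with_pre$total - 659447), 3)
  expect_equal(with_pre$unit_cost, 6594)
  # the workshop line dominates the development phase
  workshop <- with_pre$line_items[grepl("Workshop with Program Manager",
                                        with_pre$line_items$label), ]
  expect_equal(workshop$proportion, 74.46)
  # headline development cost excludes the pretest line
  without <- phase_summary(led, "development")
  expect_equal(without$total, 647824)         # printed 647827, +-3 slack
  expect_lte(abs(without$total - 647827), 3)
  expect_equal(phase_summary(led, "training")$total, 134002)
  expect_equal(phase_summary(led, "training")$unit_cost, 1340)
})

test_that("proportions normalize and sum to 100 within rounding slack", {
  led <- table2_fixture()
  for (ph in c("development", "training", "delivery")) {
    s <- phase_summary(led, ph, include_pretest = TRUE)
    expect_lte(abs(sum(s$line_items$proportion) - 100), 0.05)
  }
  one <- cost_ledger(cost_item("only", "sole line", "training",
                               "recurrent", "fixed", 4321))
  expect_equal(phase_summary(one, "training")$line_items$proportion, 100)
  # absent phase: empty summary, zero total
  s <- phase_summary(one, "delivery")
  expect_equal(s$total, 0)
  expect_equal(nrow(s$line_items), 0)
})

test_that("phase totals are invariant under item permutation", {
  led <- table2_fixture()
  set.seed(3)
  shuffled <- cost_ledger(led$items[sample(nrow(led$items)), ],
                          discount_rate = led$discount_rate,
                          cohort_size = led$cohort_size,
                          exchange_rate = led$exchange_rate)
  for (ph in c("development", "training", "delivery")) {
    expect_equal(phase_summary(shuffled, ph)$total,
                 phase_summary(led, ph)$total)
  }
  expect_equal(unit_delivery_cost(shuffled)$total,
               unit_delivery_cost(led)$total)
})

test_that("unit delivery cost reproduces every published panel cell", {
  b <- unit_delivery_cost(table2_fixture())
  expect_equal(b$components$cost, c(76, 26, 10, 160, 0.15))
  expect_equal(b$total, 272.15)
  expect_equal(b$total_reported, 272)
  # proportions are taken against the integer-rounded total
  expect_equal(b$components$proportion, c(27.94, 9.56, 3.68, 58.82, 0.06))
  expect_equal(b$components$proportion[b$components$component == "sms_calls"],
               58.82)
  # conservation: reported total is the rounded exact component sum
  expect_equal(b$total, sum(b$components$cost))
})

test_that("non-per-patient delivery items resolve via the annualization path", {
  led <- mini_ledger()
  b <- unit_delivery_cost(led)
  # capital desk: 115200 / A(0.03, 5) / 115200 min * 10 min
  desk <- 115200 / loop_annuity_oracle(0.03, 5) / 115200 * 10
  # counselor: 576000 INR/year / 115200 min * 12 min = 60
  expect_equal(b$components$cost[b$components$component == "c1"], desk,
               tolerance = 1e-12)
  expect_equal(b$components$cost[b$components$component == "s1"], 60)
  expect_equal(b$components$cost[b$components$component == "p1"], 8)
  expect_equal(b$total, desk + 60 + 8, tolerance = 1e-12)
  # an unresolvable delivery item names itself in the error
  bad <- cost_ledger(cost_item("orphan", "x", "delivery", "recurrent",
                               "fixed", 100))
  expect_error(unit_delivery_cost(bad), "orphan")
})

test_that("single-component breakdown normalizes to 100%", {
  led <- cost_ledger(cost_item("only", "x", "delivery", "recurrent",
                               "fixed", 55, per_patient = TRUE))
  b <- unit_delivery_cost(led)
  expect_equal(b$total, 55)
  expect_equal(b$components$proportion, 100)
})

test_that("currency conversion rounds to two decimals", {
  expect_equal(convert_currency(272, 74), 3.68)
  expect_equal(convert_currency(0, 74), 0)
  expect_equal(convert_currency(134002, 74), 1810.84)
  expect_error(convert_currency(100, 0), "exchange_rate")
})

test_that("rendered report is deterministic and carries the headline cells", {
  led <- table2_fixture()
  sums <- list(phase_summary(led, "development", include_pretest = TRUE),
               phase_summary(led, "training"))
  b <- unit_delivery_cost(led)
  r1 <- render_report(sums, b, exchange_rate = led$exchange_rate)
  r2 <- render_report(sums, b, exchange_rate = led$exchange_rate)
  expect_identical(r1, r2)
  expect_true(any(grepl("Overall Cost", r1) & grepl("272", r1)))
  expect_true(any(grepl("659444", r1)))
  # empty inputs -> header-only table
  expect_equal(length(render_report(list(), NULL)), 2)
})
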