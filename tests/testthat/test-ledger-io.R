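expect_ledger_equal <- function(a, b) {
  expect_equal(a$items, b$items)
  expect_equal(a$discount_rate, b$discount_rate)
  expect_equal(a$cohort_size, b$cohort_size)
  expect_equal(a$exchange_rate, b$exchange_rate)
  expect_equal(a$annual_operational_minutes, b$annual_operational_minutes)
}

test_that("fixture ledger round-trips through CSV and JSON", {
  led <- table2_fixture()
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_ledger(led, path, fmt)
    expect_ledger_equal(read_ledger(path, fmt), led)
  }
})

test_that("randomized synthetic ledgers round-trip losslessly", {
  for (seed in 1:10) {
    led <- generate_ledger(synth_config(seed = seed, n_capital_items = 4,
                                        n_staff_roles = 4,
                                        n_consumables = 4))$ledger
    path <- withr::local_tempfile(fileext = ".csv")
    write_ledger(led, path)
    expect_ledger_equal(read_ledger(path), led)
    path2 <- withr::local_tempfile(fileext = ".json")
    write_ledger(led, path2)
    expect_ledger_equal(read_ledger(path2), led)
  }
})

test_that("an empty ledger with a valid header round-trips to identity", {
  led <- cost_ledger()
  expect_equal(nrow(led$items), 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, path)
  back <- read_ledger(path)
  expect_equal(nrow(back$items), 0)
  expect_ledger_equal(back, led)
})

test_that("Indian digit grouping is accepted on input, never emitted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("item_id,label,phase,cost_class,cost_behavior,unit_price,quantity,",
          "useful_life_years,apportionment_fraction,",
          "staff_minutes_per_patient,per_patient", sep = ""),
    'w1,"Workshop",development,recurrent,variable,"4,91,040",1,,1.00,,false'
  ), path)
  led <- read_ledger(path)
  expect_equal(led$items$unit_price, 491040)
  out <- withr::local_tempfile(fileext = ".csv")
  write_ledger(led, out)
  expect_false(any(grepl("4,91,040|491,040", readLines(out))))
  expect_true(any(grepl("491040.00", readLines(out), fixed = TRUE)))
})

test_that("money and fractions serialize with two decimal places", {
  it <- cost_item("a", "half room", "development", "recurrent", "fixed",
                  100, apportionment_fraction = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ledger(cost_ledger(it), path)
  expect_true(any(grepl('"0.50"', readLines(path), fixed = TRUE)))
})

test_that("missing columns and unreadable files raise named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("item_id,label,phase", "a,x,delivery"), path)
  expect_error(read_ledger(path), "cost_class")
  expect_error(read_ledger(file.path(tempdir(), "nope.csv")), "no such file")
})

test_that("enum fields are normalized case-insensitively on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste0("item_id,label,phase,cost_class,cost_behavior,unit_price,",
           "quantity,useful_life_years,apportionment_fraction,",
           "staff_minutes_per_patient,per_patient"),
    "a,x,Delivery,RECURRENT,Fixed,10,1,,1,,TRUE"
  ), path)
  led <- read_ledger(path)
  expect_equal(led$items$phase, "delivery")
  expect_equal(led$items$cost_class, "recurrent")
  expect_true(led$items$per_patient)
})

test_that("writing an invalid ledger is refused", {
  it <- cost_item("a", "x", "delivery", "capital", "fixed", 10)  # no life
  led <- cost_ledger(it)
  expect_error(write_ledger(led, withr::local_tempfile(fileext = ".csv")),
               "invalid ledger")
})
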