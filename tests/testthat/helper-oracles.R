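# independent oracles used across test files; deliberately written as
# explicit loops / from-scratch sums, not calls into the package internals

# present value of 1/year for `life` years at `rate`, by explicit loop
loop_annuity_oracle <- function(rate, life) {
  if (rate == 0) return(life)
  s <- 0
  for (t in seq_len(life)) s <- s + (1 + rate)^(-t)
  s
}

# rebuild a perturbed per-patient delivery total from a component vector
brute_force_total <- function(components, replace_id, value) {
  s <- 0
  for (id in names(components)) {
    s <- s + if (id == replace_id) value else components[[id]]
  }
  s
}

# a small hand-built ledger with one item per phase, resolvable delivery
mini_ledger <- function() {
  items <- rbind(
    cost_item("d1", "design meeting", "development", "recurrent",
              "variable", 1000),
    cost_item("t1", "training day", "training", "recurrent", "fixed", 500),
    cost_item("c1", "counseling desk", "delivery", "capital", "fixed",
              unit_price = 115200, useful_life_years = 5,
              staff_minutes_per_patient = 10),
    cost_item("s1", "counselor", "delivery", "recurrent", "variable",
              unit_price = 576000, staff_minutes_per_patient = 12),
    cost_item("p1", "leaflet", "delivery", "recurrent", "variable",
              unit_price = 8, per_patient = TRUE)
  )
  cost_ledger(items, discount_rate = 0.03, cohort_size = 50)
}
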