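# shared fixtures: everything is generated in code at test time

toy <- make_toy_fixture()
toy_cd <- compute_intakes(toy$recall, toy$foods)
milks_tbl <- load_milks()
refs_tbl <- load_references()

# small generated survey reused across tests
small_survey <- function(n = 1000, seed = 101, ...) {
  generate_survey(population_spec(n_children = n, seed = seed, ...))
}

# independent spreadsheet-style recomputation of per-child totals:
# plain loops over rows, no package internals
hand_totals <- function(recall, foods, nutrient) {
  out <- numeric(0)
  for (id in unique(recall$child_id)) {
    rows <- recall[recall$child_id == id, ]
    tot <- 0
    for (k in seq_len(nrow(rows))) {
      comp <- foods[foods$food_code == rows$food_code[k], nutrient][[1]]
      tot <- tot + rows$grams[k] / 100 * comp
    }
    out[id] <- tot
  }
  out
}
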