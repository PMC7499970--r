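# Small in-code fixtures shared across test files. Contents echo published
# per-100 g magnitudes (white bread, wheat flour, crispbread, chickpeas) so
# worked examples stay on a realistic scale.

toy_db <- function() {
  fodmap_db(tibble::tibble(
    id = c("white_bread", "crispbread_rye", "wheat_flour", "milk", "cheese",
           "apple", "chickpeas_canned", "water", "beef"),
    name = c("white bread", "air-leavened rye crispbread", "wheat flour",
             "milk", "hard cheese", "apple", "canned chickpeas", "water",
             "beef"),
    category = c("cereal_grain", "cereal_grain", "cereal_grain", "dairy",
                 "dairy", "fruit_berry", "vegetable_root_legume",
                 "non_carbohydrate", "non_carbohydrate"),
    water_fraction = c(0.38, 0.06, 0.13, 0.88, 0.37, 0.85, 0.70, 1, 0.65),
    energy_kj_100g = c(1100, 1500, 1450, 190, 1600, 220, 500, 0, 900),
    fructose_g_100g = c(0.27, NA, NA, NA, NA, 6.0, NA, NA, NA),
    glucose_g_100g = c(0.30, NA, NA, NA, NA, 2.5, NA, NA, NA),
    fructan_g_100g = c(1.02, 4.40, 1.30, NA, NA, NA, NA, NA, NA),
    lactose_g_100g = c(NA, NA, NA, 4.8, 0.1, NA, NA, NA, NA),
    gos_g_100g = c(0.20, NA, NA, NA, NA, NA, 0.19, NA, NA),
    polyols_g_100g = c(NA, NA, NA, NA, NA, 0.5, NA, NA, NA),
    rye_wheat_based = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                        FALSE, FALSE)))
}

toy_recipes <- function(yield = 1) {
  tibble::tibble(
    composite_id = "dough",
    ingredient_id = c("wheat_flour", "water"),
    mass_fraction = c(0.6, 0.4),
    yield_factor = yield)
}

toy_diary_row <- function(person_id = "p1", day_index = 1L, food_id,
                          amount_g) {
  tibble::tibble(person_id = person_id, day_index = day_index,
                 food_id = food_id, amount_g = amount_g)
}

# database with randomly present values for property tests on the census
random_db <- function(n_items = 40) {
  cats <- sample(setdiff(food_categories(), "non_carbohydrate"), n_items,
                 replace = TRUE)
  items <- tibble::tibble(
    id = sprintf("f%03d", seq_len(n_items)),
    name = sprintf("food %03d", seq_len(n_items)),
    category = cats,
    water_fraction = runif(n_items, 0.05, 0.95),
    energy_kj_100g = runif(n_items, 50, 2000))
  for (comp in fodmap_components()) {
    vals <- ifelse(runif(n_items) < 0.4, rlnorm(n_items, 0, 1), NA_real_)
    items[[paste0(comp, "_g_100g")]] <- vals
    items[[paste0(comp, "_provenance")]] <-
      ifelse(is.na(vals), NA_character_,
             sample(provenance_classes(), n_items, replace = TRUE))
  }
  fodmap_db(items)
}

# fast small simulation config for tests that loop
small_sim_config <- function(...) {
  sim_config(
    n_persons = 40, n_days = 4, items_per_day = 8,
    foods_per_category = c(cereal_grain = 8, vegetable_root_legume = 6,
                           fruit_berry = 6, dairy = 5,
                           dessert_snack_candy = 4, composite_other = 3,
                           non_carbohydrate = 4),
    ...)
}

count_census_values <- function(db) {
  sum(vapply(fodmap_groups(),
             function(g) sum(!is.na(db[[paste0(g, "_g_100g")]])), integer(1)))
}
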