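#' Configuration for the synthetic dietary-survey generator
#'
#' Bundles every tunable of the simulated study: population size and diary
#' length, the category-structured food list, per-100 g content
#' distributions, the consumption model, calibration targets for the
#' expected daily intakes, under-reporting, and demographics.
#'
#' The defaults emulate a national-survey-style design: 117 persons keeping
#' four-day diaries, about 12 recorded items per person-day (Poisson),
#' gamma-distributed portion sizes with category-level means, and log-normal
#' per-100 g contents. After drawing contents, a single deterministic scale
#' factor per component calibrates the closed-form expected intakes to the
#' `target_mean_intake` values (defaults: fructose 15.2, glucose 15.5,
#' fructan 3.46, lactose 14.2, GOS 0.43, polyols 1.31 g/day; energy
#' 8.1 MJ/day). Lactose is confined to the dairy category. Weekday and
#' season labels cycle over persons so that, at group level, all weekdays
#' and seasons are covered.
#'
#' @param n_persons Number of persons (default 117).
#' @param n_days Diary length in days (default 4).
#' @param items_per_day Poisson mean of recorded items per person-day.
#' @param portion_shape Gamma shape of portion sizes (mean set per category).
#' @param foods_per_category Named integer vector of food counts per
#'   category.
#' @param category_weights Named selection probabilities per category
#'   (normalised internally).
#' @param portion_mean_g Named mean portion size (grams) per category.
#' @param content_spec Tibble (`category`, `component`, `presence_prob`,
#'   `meanlog`, `sdlog`) giving, per category, the probability that a food
#'   carries the component and the log-normal of its per-100 g content
#'   before calibration.
#' @param glucose_ratio_sdlog Log-normal sd of the per-food glucose:fructose
#'   ratio (glucose is drawn only where fructose is present).
#' @param energy_mean_kj Named mean energy (kJ/100 g) per category, before
#'   calibration.
#' @param water_mean Named mean water fraction per category.
#' @param target_mean_intake Named calibration targets, expected g/day per
#'   component.
#' @param target_energy_mj Expected energy intake, MJ/day.
#' @param provenance_mix Named sampling weights over provenance labels for
#'   generated base-food values.
#' @param under_report_fraction Fraction of persons whose recorded amounts
#'   are scaled down (default 0).
#' @param under_report_multiplier Scaling applied to under-reporters'
#'   amounts (default 0.7).
#' @param female_share,age_range,weight_mean,weight_sd,pal_mean,pal_sd
#'   Demographic distributions (weight means/sds are named by sex).
#' @return A list of class `fodmap_sim_config`.
#' @export
sim_config <- function(
    n_persons = 117,
    n_days = 4,
    items_per_day = 12,
    portion_shape = 4,
    foods_per_category = c(cereal_grain = 30, vegetable_root_legume = 25,
                           fruit_berry = 20, dairy = 15,
                           dessert_snack_candy = 12, composite_other = 8,
                           non_carbohydrate = 10),
    category_weights = c(cereal_grain = 0.25, vegetable_root_legume = 0.15,
                         fruit_berry = 0.15, dairy = 0.20,
                         dessert_snack_candy = 0.10, composite_other = 0.05,
                         non_carbohydrate = 0.10),
    portion_mean_g = c(cereal_grain = 80, vegetable_root_legume = 90,
                       fruit_berry = 120, dairy = 150,
                       dessert_snack_candy = 50, composite_other = 250,
                       non_carbohydrate = 120),
    content_spec = default_content_spec(),
    glucose_ratio_sdlog = 0.35,
    energy_mean_kj = c(cereal_grain = 1100, vegetable_root_legume = 180,
                       fruit_berry = 220, dairy = 350,
                       dessert_snack_candy = 1600, composite_other = 650,
                       non_carbohydrate = 800),
    water_mean = c(cereal_grain = 0.35, vegetable_root_legume = 0.90,
                   fruit_berry = 0.85, dairy = 0.88,
                   dessert_snack_candy = 0.30, composite_other = 0.70,
                   non_carbohydrate = 0.70),
    target_mean_intake = c(fructose = 15.2, glucose = 15.5, fructan = 3.46,
                           lactose = 14.2, gos = 0.43, polyols = 1.31),
    target_energy_mj = 8.1,
    provenance_mix = c(direct_measurement = 0.75, similarity_assigned = 0.15,
                       component_sum = 0.05, dry_weight_converted = 0.05),
    under_report_fraction = 0,
    under_report_multiplier = 0.7,
    female_share = 0.76,
    age_range = c(18, 70),
    weight_mean = c(female = 67, male = 82),
    weight_sd = c(female = 10, male = 12),
    pal_mean = 1.7,
    pal_sd = 0.15) {
  cats <- food_categories()
  for (nm in c("foods_per_category", "category_weights", "portion_mean_g",
               "energy_mean_kj", "water_mean")) {
    v <- get(nm)
    if (!all(cats %in% names(v))) {
      stop_invalid("`%s` must be named with every food category", nm)
    }
  }
  if (any(foods_per_category < 1)) {
    stop_invalid("`foods_per_category` entries must be >= 1")
  }
  if (n_persons < 1 || n_days < 1 || items_per_day <= 0 ||
      portion_shape <= 0) {
    stop_invalid("population and consumption parameters must be positive")
  }
  if (under_report_fraction < 0 || under_report_fraction > 1 ||
      under_report_multiplier <= 0) {
    stop_invalid("invalid under-reporting parameters")
  }
  if (any(content_spec$presence_prob < 0 | content_spec$presence_prob > 1) ||
      any(content_spec$sdlog < 0)) {
    stop_invalid("invalid content_spec distribution parameters")
  }
  structure(list(
    n_persons = n_persons, n_days = n_days,
    items_per_day = items_per_day, portion_shape = portion_shape,
    foods_per_category = foods_per_category[cats],
    category_weights = category_weights[cats] / sum(category_weights[cats]),
    portion_mean_g = portion_mean_g[cats],
    content_spec = tibble::as_tibble(content_spec),
    glucose_ratio_sdlog = glucose_ratio_sdlog,
    energy_mean_kj = energy_mean_kj[cats],
    water_mean = water_mean[cats],
    target_mean_intake = target_mean_intake,
    target_energy_mj = target_energy_mj,
    provenance_mix = provenance_mix,
    under_report_fraction = under_report_fraction,
    under_report_multiplier = under_report_multiplier,
    female_share = female_share, age_range = age_range,
    weight_mean = weight_mean, weight_sd = weight_sd,
    pal_mean = pal_mean, pal_sd = pal_sd
  ), class = "fodmap_sim_config")
}

#' Default per-category content distributions for the generator
#'
#' Which FODMAP components foods of each category can carry, with what
#' probability, and the log-normal parameters of the per-100 g content
#' before calibration. Cereals always carry fructan and often GOS; fruits
#' always carry fructose (with glucose) and often polyols; lactose appears
#' only in dairy; composites derive everything from their recipes.
#'
#' @return A tibble with columns `category`, `component`, `presence_prob`,
#'   `meanlog`, `sdlog`.
#' @export
default_content_spec <- function() {
  tibble::tribble(
    ~category,               ~component, ~presence_prob, ~meanlog, ~sdlog,
    "cereal_grain",          "fructan",  1.0,  log(1.2), 0.5,
    "cereal_grain",          "gos",      0.6,  log(0.2), 0.5,
    "cereal_grain",          "fructose", 0.4,  log(0.5), 0.5,
    "vegetable_root_legume", "fructose", 0.8,  log(1.0), 0.5,
    "vegetable_root_legume", "fructan",  0.5,  log(0.6), 0.6,
    "vegetable_root_legume", "gos",      0.4,  log(0.3), 0.7,
    "vegetable_root_legume", "polyols",  0.3,  log(0.3), 0.7,
    "fruit_berry",           "fructose", 1.0,  log(3.0), 0.5,
    "fruit_berry",           "polyols",  0.5,  log(0.5), 0.8,
    "fruit_berry",           "fructan",  0.2,  log(0.3), 0.6,
    "dairy",                 "lactose",  0.9,  log(4.0), 0.4,
    "dessert_snack_candy",   "fructose", 0.7,  log(3.0), 0.6,
    "dessert_snack_candy",   "fructan",  0.2,  log(0.5), 0.5,
    "dessert_snack_candy",   "polyols",  0.3,  log(1.0), 0.8
  )
}

## expected grams of each food eaten per person-day under the consumption
## model: items/day x P(food chosen) x mean portion
expected_food_grams <- function(db, config) {
  n_cat <- config$foods_per_category[db$category]
  p_food <- config$category_weights[db$category] / n_cat
  as.numeric(config$items_per_day * p_food * config$portion_mean_g[db$category])
}

## effective per-100 g contents with composites resolved through recipes
effective_contents <- function(db, recipes) {
  eff <- add_recipe_profiles(db, recipes)
  m <- sapply(fodmap_components(), function(comp) {
    dplyr::coalesce(eff[[db_value_col(comp)]], 0)
  })
  matrix(m, nrow = nrow(db),
         dimnames = list(db$id, fodmap_components()))
}

#' Generate a synthetic composition database and recipe table
#'
#' Draws a category-structured food list with log-normal per-100 g contents
#' (see [default_content_spec()]), glucose tied to fructose by a log-normal
#' ratio, category-level energy and water fractions, and composite foods
#' defined purely by recipes over the base foods (so the recipe machinery is
#' exercised downstream). Contents and energies are then rescaled by one
#' deterministic factor per component so the closed-form expected intakes
#' under the consumption model equal the configured targets. Provenance
#' labels for base-food values are sampled from `provenance_mix`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the output is a deterministic function of
#'   (config, seed).
#' @return A list with elements `db` (a `fodmap_db`; composites carry no
#'   stored profile) and `recipes`.
#' @export
generate_composition_db <- function(config, seed) {
  stopifnot(inherits(config, "fodmap_sim_config"))
  withr::with_seed(seed, generate_composition_db_impl(config))
}

generate_composition_db_impl <- function(config) {
  cats <- food_categories()
  counts <- config$foods_per_category
  category <- rep(cats, counts[cats])
  n <- length(category)
  idx_in_cat <- unlist(lapply(counts[cats], seq_len), use.names = FALSE)
  db <- tibble::tibble(
    id = sprintf("%s_%02d", category, idx_in_cat),
    name = sprintf("%s %02d", gsub("_", " ", category), idx_in_cat),
    category = category,
    water_fraction = pmin(0.97, pmax(0.02, rnorm(
      n, config$water_mean[category], 0.05))),
    energy_kj_100g = rlnorm(n, log(config$energy_mean_kj[category]), 0.3),
    fermented_bread = FALSE,
    rye_wheat_based = category == "cereal_grain")
  db <- fodmap_db(db)

  is_base <- category != "composite_other"
  for (comp in setdiff(fodmap_components(), "glucose")) {
    spec <- config$content_spec[config$content_spec$component == comp, ]
    if (nrow(spec) == 0) next
    vc <- db_value_col(comp)
    for (j in seq_len(nrow(spec))) {
      rows <- which(db$category == spec$category[j])
      carry <- rows[runif(length(rows)) < spec$presence_prob[j]]
      db[[vc]][carry] <- rlnorm(length(carry), spec$meanlog[j], spec$sdlog[j])
    }
  }
  ## glucose accompanies fructose with a log-normal ratio around 1
  has_fru <- which(!is.na(db$fructose_g_100g))
  db$glucose_g_100g[has_fru] <- db$fructose_g_100g[has_fru] *
    rlnorm(length(has_fru), 0, config$glucose_ratio_sdlog)

  ## composite recipes over base foods (2-4 ingredients, fractions < 1,
  ## remainder water)
  comp_ids <- db$id[category == "composite_other"]
  base_ids <- db$id[is_base]
  recipes <- purrr::map_dfr(comp_ids, function(cid) {
    k <- sample(2:4, 1)
    ing <- sample(base_ids, k)
    w <- rgamma(k, 2, 1)
    tibble::tibble(composite_id = cid, ingredient_id = ing,
                   mass_fraction = 0.9 * w / sum(w), yield_factor = 1)
  })

  ## calibrate: one scale factor per component so that the closed-form
  ## expected intake equals the target; composites follow linearly since
  ## their contents are mass-fraction-weighted sums of base contents
  e_grams <- expected_food_grams(db, config)
  contents <- effective_contents(db, recipes)
  for (comp in fodmap_components()) {
    raw <- sum(e_grams * contents[, comp]) / 100
    target <- config$target_mean_intake[[comp]]
    if (is.null(target) || is.na(target)) target <- 0
    if (raw == 0) {
      if (target > 0) {
        stop_invalid(paste0("configuration gives zero expected `%s` intake ",
                            "but a positive target"), comp)
      }
      next
    }
    vc <- db_value_col(comp)
    db[[vc]] <- db[[vc]] * (target / raw)
  }
  raw_energy <- sum(e_grams * ifelse(is.na(db$energy_kj_100g), 0,
                                     db$energy_kj_100g)) / 100 / 1000
  ## composite energy is the recipe-weighted ingredient energy, filled after
  ## scaling so the stored value matches the mix
  db$energy_kj_100g <- db$energy_kj_100g * (config$target_energy_mj / raw_energy)
  for (cid in comp_ids) {
    rec <- recipes[recipes$composite_id == cid, ]
    ing_idx <- match(rec$ingredient_id, db$id)
    db$energy_kj_100g[match(cid, db$id)] <-
      sum(rec$mass_fraction * db$energy_kj_100g[ing_idx]) / rec$yield_factor[1]
  }
  ## recompute energy calibration including composites
  raw_energy <- sum(expected_food_grams(db, config) * db$energy_kj_100g) /
    100 / 1000
  db$energy_kj_100g <- db$energy_kj_100g * (config$target_energy_mj / raw_energy)

  ## provenance labels for the generated base-food values
  provs <- names(config$provenance_mix)
  for (comp in fodmap_components()) {
    vc <- db_value_col(comp)
    pc <- db_prov_col(comp)
    sc <- db_source_col(comp)
    present <- which(!is.na(db[[vc]]))
    if (length(present) == 0) next
    db[[pc]][present] <- sample(provs, length(present), replace = TRUE,
                                prob = config$provenance_mix)
    db[[sc]][present] <- "synthetic"
  }
  list(db = db, recipes = recipes)
}

#' Generate synthetic multi-day diaries and a persons table
#'
#' Simulates `n_persons x n_days` person-days. Each day records a
#' Poisson-distributed number of items; foods are drawn with
#' category-weighted probabilities and portions from a gamma distribution
#' with category-level means. Start weekdays cycle over persons (days are
#' consecutive) so all seven weekdays appear at group level, as do the four
#' seasons. An optional fraction of persons under-reports: all their
#' recorded amounts are multiplied by `under_report_multiplier`.
#'
#' @param db,recipes Output of [generate_composition_db()].
#' @param config The same [sim_config()].
#' @param seed Integer seed.
#' @return A list with `diary` (person_id, day_index, weekday, season,
#'   food_id, amount_g) and `persons` (person_id, sex, age, weight_kg, pal,
#'   under_reporter).
#' @export
generate_population_diaries <- function(db, recipes, config, seed) {
  stopifnot(inherits(config, "fodmap_sim_config"))
  withr::with_seed(seed, generate_population_diaries_impl(db, config))
}

generate_population_diaries_impl <- function(db, config) {
  np <- config$n_persons
  nd <- config$n_days
  seasons <- c("winter", "spring", "summer", "autumn")
  sex <- ifelse(runif(np) < config$female_share, "female", "male")
  persons <- tibble::tibble(
    person_id = sprintf("p%03d", seq_len(np)),
    sex = sex,
    age = round(runif(np, config$age_range[1], config$age_range[2])),
    weight_kg = round(pmax(40, rnorm(np, config$weight_mean[sex],
                                     config$weight_sd[sex])), 1),
    pal = round(pmax(1.2, rnorm(np, config$pal_mean, config$pal_sd)), 2),
    under_reporter = runif(np) < config$under_report_fraction,
    start_weekday = ((seq_len(np) - 1L) %% 7L) + 1L,
    season = seasons[((seq_len(np) - 1L) %% 4L) + 1L])

  grid <- tidyr::expand_grid(person_id = persons$person_id,
                             day_index = seq_len(nd)) |>
    dplyr::left_join(dplyr::select(persons, "person_id", "start_weekday",
                                   "season", "under_reporter"),
                     by = "person_id") |>
    dplyr::mutate(weekday = ((.data$start_weekday + .data$day_index - 2L) %%
                               7L) + 1L)
  n_items <- rpois(nrow(grid), config$items_per_day)
  diary <- grid[rep(seq_len(nrow(grid)), n_items), ]
  p_food <- config$category_weights[db$category] /
    config$foods_per_category[db$category]
  pick <- sample.int(nrow(db), nrow(diary), replace = TRUE, prob = p_food)
  diary$food_id <- db$id[pick]
  cat_mean <- config$portion_mean_g[db$category[pick]]
  shape <- config$portion_shape
  diary$amount_g <- rgamma(nrow(diary), shape = shape,
                           scale = cat_mean / shape)
  diary$amount_g <- pmax(diary$amount_g, 0.1)
  diary$amount_g[diary$under_reporter] <-
    diary$amount_g[diary$under_reporter] * config$under_report_multiplier
  diary <- dplyr::select(diary, "person_id", "day_index", "weekday",
                         "season", "food_id", "amount_g")
  persons$start_weekday <- NULL
  list(diary = diary, persons = persons)
}

#' Closed-form expected daily intakes of a synthetic study
#'
#' By linearity of expectation, the expected daily intake of a component is
#' `sum over foods of E[items/day] x P(food) x E[portion] x content / 100`,
#' with composite contents resolved through their recipes, scaled by the
#' expected under-reporting factor
#' `1 - under_report_fraction x (1 - under_report_multiplier)`. Excess
#' fructose and total FODMAP are day-level, non-linear quantities and have
#' no closed form here; the five component means and glucose and energy do.
#'
#' @param db,recipes Output of [generate_composition_db()].
#' @param config The same [sim_config()].
#' @return A named list: expected g/day for the six components and
#'   `energy_mj` (MJ/day).
#' @export
ground_truth <- function(db, recipes, config) {
  stopifnot(inherits(config, "fodmap_sim_config"))
  e_grams <- expected_food_grams(db, config)
  contents <- effective_contents(db, recipes)
  ur <- 1 - config$under_report_fraction * (1 - config$under_report_multiplier)
  out <- lapply(fodmap_components(), function(comp) {
    ur * sum(e_grams * contents[, comp]) / 100
  })
  names(out) <- paste0(fodmap_components(), "_g")
  out$energy_mj <- ur * sum(e_grams * db$energy_kj_100g) / 100 / 1000
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: composition database + recipes, diaries + persons,
#' and the closed-form ground truth, all from one config and seed. The
#' database and the diaries use independent streams derived from `seed`, so
#' diary replicates can be drawn against a fixed database.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `db`, `recipes`, `diary`, `persons`, `truth` and
#'   `config`.
#' @export
generate_study <- function(config = sim_config(), seed = 1) {
  gen <- generate_composition_db(config, seed)
  pop <- generate_population_diaries(gen$db, gen$recipes, config, seed + 1)
  list(db = gen$db, recipes = gen$recipes, diary = pop$diary,
       persons = pop$persons,
       truth = ground_truth(gen$db, gen$recipes, config),
       config = config)
}
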