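#' Read recipe definitions from delimited text
#'
#' A recipe file has one row per ingredient with columns `composite_id`,
#' `ingredient_id`, `mass_fraction` and optionally `yield_factor` (mass of
#' finished food per unit mass of raw mix; repeated per row or given on any
#' row of the recipe; default 1).
#'
#' @inheritParams read_composition_db
#' @return A tibble with one row per (composite, ingredient) pair.
#' @export
read_recipes <- function(path, delim = NULL, decimal_comma = FALSE) {
  raw <- read_delimited(path, delim = delim, decimal_comma = decimal_comma)
  names(raw) <- tolower(names(raw))
  req <- c("composite_id", "ingredient_id", "mass_fraction")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop_invalid("recipes file is missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  if (!"yield_factor" %in% names(raw)) raw$yield_factor <- NA_real_
  raw$composite_id <- as.character(raw$composite_id)
  raw$ingredient_id <- as.character(raw$ingredient_id)
  validate_recipes(tibble::as_tibble(raw))
}

validate_recipes <- function(recipes) {
  recipes <- tibble::as_tibble(recipes)
  if (!"yield_factor" %in% names(recipes)) recipes$yield_factor <- NA_real_
  recipes <- recipes |>
    dplyr::group_by(.data$composite_id) |>
    dplyr::mutate(yield_factor = {
      y <- unique(.data$yield_factor[!is.na(.data$yield_factor)])
      if (length(y) > 1) {
        stop_invalid("recipe `%s` has conflicting yield factors",
                     .data$composite_id[1])
      }
      if (length(y) == 0) 1 else y
    }) |>
    dplyr::ungroup()
  if (any(recipes$mass_fraction <= 0)) {
    stop_invalid("recipe mass fractions must be > 0")
  }
  if (any(recipes$yield_factor <= 0)) {
    stop_invalid("recipe yield factors must be > 0")
  }
  frac_sums <- tapply(recipes$mass_fraction, recipes$composite_id, sum)
  over <- names(frac_sums)[frac_sums > 1 + 1e-8]
  if (length(over) > 0) {
    stop_invalid("recipe(s) with ingredient fractions summing above 1: %s",
                 paste(over, collapse = ", "))
  }
  recipes
}

## Recursively resolve the per-100 g component contents of a food id.
## Returns a named numeric over fodmap_components(); NA = absent in every
## ingredient along the way. `partial` attribute lists components absent in
## some (but not all) ingredients, which are treated as 0 there.
resolve_contents <- function(id, recipes, db, depth, max_depth, visiting) {
  idx <- match(id, db$id)
  has_profile <- FALSE
  if (!is.na(idx)) {
    vals <- vapply(fodmap_components(),
                   function(comp) db[[db_value_col(comp)]][idx], numeric(1))
    has_profile <- any(!is.na(vals))
  }
  in_recipes <- id %in% recipes$composite_id
  if (has_profile || (!in_recipes && !is.na(idx))) {
    ## a stored profile wins; foods without values contribute nothing
    attr(vals, "partial") <- character(0)
    return(vals)
  }
  if (!in_recipes) {
    stop_invalid("food `%s` is absent from both the database and the recipes",
                 id)
  }
  if (id %in% visiting) {
    stop_invalid("recipe cycle detected at `%s` (chain: %s)", id,
                 paste(c(visiting, id), collapse = " -> "))
  }
  if (depth > max_depth) {
    stop_invalid("recipe recursion deeper than %d at `%s`", max_depth, id)
  }
  rec <- recipes[recipes$composite_id == id, ]
  yield <- rec$yield_factor[1]
  acc <- setNames(rep(0, length(fodmap_components())), fodmap_components())
  seen <- setNames(rep(FALSE, length(fodmap_components())),
                   fodmap_components())
  missing_some <- character(0)
  for (i in seq_len(nrow(rec))) {
    ing <- resolve_contents(rec$ingredient_id[i], recipes, db, depth + 1,
                            max_depth, c(visiting, id))
    missing_some <- union(missing_some, attr(ing, "partial"))
    present <- !is.na(ing)
    seen <- seen | present
    acc[present] <- acc[present] + rec$mass_fraction[i] * ing[present]
    absent_here <- names(ing)[!present]
    missing_some <- union(missing_some, absent_here)
  }
  out <- acc / yield
  out[!seen] <- NA_real_
  attr(out, "partial") <- intersect(missing_some, names(seen)[seen])
  out
}

#' Derive a composite food's FODMAP profile from its recipe
#'
#' Each per-100 g value of the composite is the mass-fraction-weighted sum of
#' the ingredient values, divided by the cooking yield factor (finished mass
#' per unit raw mass; 1 means no change). Ingredients may themselves be
#' composites with recipes; cycles are an error. A component absent from
#' every ingredient is absent from the composite; a component absent from
#' only some ingredients is treated as 0 for those and listed in the result's
#' `partial` attribute.
#'
#' @param composite_id Id of the composite food.
#' @param recipes A recipes tibble (see [read_recipes()]).
#' @param db A `fodmap_db` supplying ingredient profiles.
#' @param max_depth Maximum recipe nesting depth (default 10).
#' @return A named numeric vector over the six stored components (g/100 g),
#'   with attribute `partial` naming components computed from incomplete
#'   ingredient data.
#' @export
#' @examples
#' db <- fodmap_db(tibble::tibble(
#'   id = c("wheat_flour", "water"), name = c("wheat flour", "water"),
#'   category = c("cereal_grain", "non_carbohydrate"),
#'   water_fraction = c(0.13, 1), energy_kj_100g = c(1450, 0),
#'   fructan_g_100g = c(1.3, NA)))
#' recipes <- tibble::tibble(composite_id = "dough",
#'   ingredient_id = c("wheat_flour", "water"),
#'   mass_fraction = c(0.6, 0.4), yield_factor = 1)
#' resolve_recipe("dough", recipes, db)["fructan"] # 0.78
resolve_recipe <- function(composite_id, recipes, db, max_depth = 10) {
  recipes <- validate_recipes(recipes)
  if (!composite_id %in% recipes$composite_id) {
    stop_invalid("no recipe found for `%s`", composite_id)
  }
  ## force the recipe path even if the composite already has a stored profile
  idx <- match(composite_id, db$id)
  if (!is.na(idx)) {
    for (comp in fodmap_components()) {
      db[[db_value_col(comp)]][idx] <- NA_real_
    }
  }
  resolve_contents(composite_id, recipes, db, 1, max_depth, character(0))
}

#' Fill recipe-derived profiles into a database
#'
#' For every composite that appears in `recipes`, exists in the database and
#' has no stored FODMAP value, computes its profile via [resolve_recipe()]
#' and stores it with provenance `recipe_derived`. Composites with a stored
#' profile are left untouched (a measured value beats a recipe estimate).
#' A warning is raised when a recipe-derived profile is created for an item
#' flagged `fermented_bread`, since yeast fermentation degrades fructan and a
#' recipe estimate from flour overstates it.
#'
#' @inheritParams resolve_recipe
#' @return The database with recipe-derived profiles filled in.
#' @export
add_recipe_profiles <- function(db, recipes, max_depth = 10) {
  recipes <- validate_recipes(recipes)
  targets <- intersect(unique(recipes$composite_id), db$id)
  for (id in targets) {
    idx <- match(id, db$id)
    existing <- vapply(fodmap_components(),
                       function(comp) db[[db_value_col(comp)]][idx],
                       numeric(1))
    if (any(!is.na(existing))) next
    contents <- resolve_contents(id, recipes, db, 1, max_depth, character(0))
    if (isTRUE(db$fermented_bread[idx]) && !is.na(contents[["fructan"]])) {
      warning(sprintf(paste0("recipe-derived fructan for fermented bread ",
                             "`%s`: yeast fermentation degradation is not ",
                             "modelled; prefer a measured value"), id),
              call. = FALSE)
    }
    partial <- attr(contents, "partial")
    for (comp in fodmap_components()) {
      if (is.na(contents[[comp]])) next
      db[[db_value_col(comp)]][idx] <- contents[[comp]]
      db[[db_prov_col(comp)]][idx] <- "recipe_derived"
      db[[db_source_col(comp)]][idx] <- paste0(
        "recipe calculation",
        if (comp %in% partial) " (some ingredients lacked a value)")
    }
  }
  db
}

#' Break a diary entry for a composite down to ingredient-level entries
#'
#' Used when a composite eaten in a diary has a recipe but no stored profile.
#' Each ingredient receives `amount_g * mass_fraction / yield_factor` grams
#' (the raw ingredient mass behind the eaten portion), preserving the entry's
#' person, day and label columns. Intake computed from the decomposition
#' equals intake computed from the resolved composite profile.
#'
#' @param entry A one-row diary tibble with at least `food_id` and
#'   `amount_g`.
#' @param recipes A recipes tibble.
#' @return A tibble with one row per ingredient.
#' @export
decompose_entry <- function(entry, recipes) {
  recipes <- validate_recipes(recipes)
  if (nrow(entry) != 1) stop_invalid("`entry` must be a single diary row")
  rec <- recipes[recipes$composite_id == entry$food_id, ]
  if (nrow(rec) == 0) {
    stop_invalid("no recipe for unresolved food `%s`", entry$food_id)
  }
  out <- entry[rep(1, nrow(rec)), ]
  out$food_id <- rec$ingredient_id
  out$amount_g <- entry$amount_g * rec$mass_fraction / rec$yield_factor
  out
}

## Decompose all diary rows whose food has no stored profile but a recipe,
## repeating until every row resolves or no rule applies. Rows for foods
## absent from both db and recipes are returned in `unresolved`.
decompose_entries <- function(diary, recipes, db, max_depth = 10) {
  recipes <- if (is.null(recipes)) {
    tibble::tibble(composite_id = character(), ingredient_id = character(),
                   mass_fraction = numeric(), yield_factor = numeric())
  } else {
    validate_recipes(recipes)
  }
  has_profile <- rep(FALSE, nrow(db))
  for (comp in fodmap_components()) {
    has_profile <- has_profile | !is.na(db[[db_value_col(comp)]])
  }
  profiled_ids <- db$id[has_profile]
  for (step in seq_len(max_depth + 1)) {
    needs <- !(diary$food_id %in% profiled_ids) &
      diary$food_id %in% recipes$composite_id
    if (!any(needs)) break
    if (step > max_depth) {
      stop_invalid("recipe recursion deeper than %d while decomposing diary",
                   max_depth)
    }
    keep <- diary[!needs, ]
    expand <- diary[needs, ] |>
      dplyr::left_join(recipes, by = c(food_id = "composite_id"),
                       relationship = "many-to-many") |>
      dplyr::mutate(food_id = .data$ingredient_id,
                    amount_g = .data$amount_g * .data$mass_fraction /
                      .data$yield_factor) |>
      dplyr::select(-"ingredient_id", -"mass_fraction", -"yield_factor")
    diary <- dplyr::bind_rows(keep, expand)
  }
  unresolved <- !(diary$food_id %in% db$id)
  list(resolved = diary[!unresolved, ],
       unresolved = diary[unresolved, ])
}
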