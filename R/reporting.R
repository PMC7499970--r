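rank_types <- function() c(fodmap_groups(), "any")
content_types <- function() c(fodmap_groups(), "excess_fructose")

## per-100 g content of a (possibly derived) component for every food
db_content <- function(db, fodmap_type) {
  if (fodmap_type == "excess_fructose") {
    excess_fructose(dplyr::coalesce(db[[db_value_col("fructose")]], 0),
                    dplyr::coalesce(db[[db_value_col("glucose")]], 0))
  } else {
    dplyr::coalesce(db[[db_value_col(fodmap_type)]], 0)
  }
}

#' Rank the most commonly eaten foods containing a FODMAP
#'
#' Restricts the database to foods with a positive stored content of the
#' requested FODMAP group (or any group, for the combined list), then ranks
#' them by the population mean grams of the food eaten per day: each person's
#' mean daily grams (zero for days without the food), averaged over all
#' persons — so rarely-but-heavily eaten foods rank below staples. Ties are
#' broken alphabetically by name, making the order invariant to row
#' shuffling of the diary.
#'
#' @param db A `fodmap_db` (apply [add_recipe_profiles()] first if composite
#'   foods should qualify through their recipe-derived content).
#' @param diary Diary tibble.
#' @param fodmap_type One of the five FODMAP groups (`"fructose"`,
#'   `"fructan"`, `"lactose"`, `"gos"`, `"polyols"`) or `"any"` for the
#'   combined list of foods containing any FODMAP.
#' @param top_n Number of rows to keep (default 10).
#' @param consumer_only If `TRUE`, average grams per day over consumers of
#'   the food only, instead of over all persons (default `FALSE`).
#' @return A tibble ordered by `mean_amount_g_per_day` descending, with
#'   columns `rank`, `food_id`, `name`, `category`,
#'   `mean_amount_g_per_day`, `content_g_per_100g` (NA for `"any"`) and
#'   `mean_fodmap_g_per_day` (`mean_amount x content / 100`).
#' @export
rank_sources <- function(db, diary, fodmap_type, top_n = 10,
                         consumer_only = FALSE) {
  if (!fodmap_type %in% rank_types()) {
    stop_invalid("unknown fodmap_type `%s`; expected one of %s", fodmap_type,
                 paste(rank_types(), collapse = ", "))
  }
  if (nrow(diary) == 0) stop_invalid("diary is empty")
  if (top_n < 1) stop_invalid("`top_n` must be >= 1")

  qualifies <- if (fodmap_type == "any") {
    Reduce(`|`, lapply(fodmap_groups(), function(g) db_content(db, g) > 0))
  } else {
    db_content(db, fodmap_type) > 0
  }
  foods <- tibble::tibble(
    food_id = db$id, name = db$name, category = db$category,
    content_g_per_100g = if (fodmap_type == "any") NA_real_ else
      db_content(db, fodmap_type))[qualifies, ]
  if (nrow(foods) == 0) return(foods[0, ])

  person_days <- diary |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day_index),
                     .groups = "drop")
  n_persons <- nrow(person_days)

  per_person <- diary |>
    dplyr::filter(.data$food_id %in% foods$food_id) |>
    dplyr::group_by(.data$person_id, .data$food_id) |>
    dplyr::summarise(total_g = sum(.data$amount_g), .groups = "drop") |>
    dplyr::left_join(person_days, by = "person_id") |>
    dplyr::mutate(g_per_day = .data$total_g / .data$n_days)

  means <- per_person |>
    dplyr::group_by(.data$food_id) |>
    dplyr::summarise(
      mean_amount_g_per_day = if (consumer_only) mean(.data$g_per_day) else
        sum(.data$g_per_day) / n_persons,
      .groups = "drop")

  foods |>
    dplyr::inner_join(means, by = "food_id") |>
    dplyr::mutate(mean_fodmap_g_per_day =
                    .data$mean_amount_g_per_day * .data$content_g_per_100g / 100) |>
    dplyr::arrange(dplyr::desc(.data$mean_amount_g_per_day), .data$name,
                   .data$food_id) |>
    head(top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
}

#' Rank foods by stored FODMAP content per 100 g
#'
#' Orders all foods by their per-100 g content of the requested group,
#' descending, dropping foods with no (or zero) content; ties alphabetical
#' by name. The `"excess_fructose"` variant ranks by
#' `max(0, fructose - glucose)` per 100 g, so foods whose glucose meets or
#' exceeds their fructose are excluded.
#'
#' @param db A `fodmap_db`.
#' @param fodmap_type One of the five FODMAP groups or `"excess_fructose"`.
#' @param top_n Number of rows to keep (default 20).
#' @return A tibble with `rank`, `food_id`, `name`, `category`,
#'   `content_g_per_100g`, ordered descending.
#' @export
top_content <- function(db, fodmap_type, top_n = 20) {
  if (!fodmap_type %in% content_types()) {
    stop_invalid("unknown fodmap_type `%s`; expected one of %s", fodmap_type,
                 paste(content_types(), collapse = ", "))
  }
  if (top_n < 1) stop_invalid("`top_n` must be >= 1")
  content <- db_content(db, fodmap_type)
  keep <- content > 0
  tibble::tibble(food_id = db$id, name = db$name, category = db$category,
                 content_g_per_100g = content)[keep, ] |>
    dplyr::arrange(dplyr::desc(.data$content_g_per_100g), .data$name,
                   .data$food_id) |>
    head(top_n) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::relocate("rank")
}

#' Category breakdown of a ranked food list
#'
#' Counts the list's entries per value of a grouping column (the food
#' `category` by default, or any other column such as a `rye_wheat_based`
#' flag) and reports integer percentage shares (rounded half up), which
#' therefore sum to 100 within rounding.
#'
#' @param ranked A nonempty ranked tibble (from [rank_sources()] or
#'   [top_content()], possibly joined with extra metadata).
#' @param column Name of the column to break down by (default
#'   `"category"`).
#' @return A tibble with the grouping value, `n` and `share_pct`, ordered by
#'   descending count.
#' @export
#' @examples
#' lst <- tibble::tibble(category = rep(c("cereal_grain", "fruit_berry"),
#'                                      c(19, 31)))
#' category_breakdown(lst) # cereals 38%, fruits 62%
category_breakdown <- function(ranked, column = "category") {
  if (nrow(ranked) == 0) stop_invalid("ranked list is empty")
  if (!column %in% names(ranked)) {
    stop_invalid("column `%s` not found in the ranked list", column)
  }
  ranked |>
    dplyr::count(.data[[column]], name = "n") |>
    dplyr::mutate(share_pct = round_half_up(100 * .data$n / nrow(ranked))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data[[column]])
}
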