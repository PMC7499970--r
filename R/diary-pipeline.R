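#' Read a multi-day food diary from delimited text
#'
#' Required columns: `person_id`, `day_index`, `food_id`, `amount_g`. An
#' optional ISO `date` column is used to derive `weekday` (1 = Monday) and
#' `season` (winter = Dec-Feb, spring = Mar-May, summer = Jun-Aug,
#' autumn = Sep-Nov); explicit `weekday`/`season` columns are kept as given.
#'
#' @inheritParams read_composition_db
#' @return A tibble with one row per consumed item.
#' @export
read_diary <- function(path, delim = NULL, decimal_comma = FALSE) {
  raw <- read_delimited(path, delim = delim, decimal_comma = decimal_comma)
  names(raw) <- tolower(names(raw))
  req <- c("person_id", "day_index", "food_id", "amount_g")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) {
    stop_invalid("diary file is missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  raw$person_id <- as.character(raw$person_id)
  raw$food_id <- as.character(raw$food_id)
  if ("date" %in% names(raw) && !"weekday" %in% names(raw)) {
    d <- as.Date(raw$date)
    raw$weekday <- as.integer(format(d, "%u"))
    if (!"season" %in% names(raw)) {
      m <- as.integer(format(d, "%m"))
      raw$season <- c("winter", "winter", "spring", "spring", "spring",
                      "summer", "summer", "summer", "autumn", "autumn",
                      "autumn", "winter")[m]
    }
  }
  if (any(is.na(raw$amount_g)) || any(raw$amount_g <= 0)) {
    stop_invalid("diary `amount_g` must be present and > 0")
  }
  if (any(is.na(raw$day_index)) || any(raw$day_index < 1)) {
    stop_invalid("diary `day_index` must be an integer >= 1")
  }
  tibble::as_tibble(raw)
}

#' Read a persons table (demographics for the energy screen)
#'
#' Expected columns: `person_id`, `sex` (`"female"`/`"male"`), `age` (years),
#' `weight_kg`, and optionally `pal` (physical activity level).
#'
#' @inheritParams read_composition_db
#' @return A tibble with one row per person.
#' @export
read_persons <- function(path, delim = NULL, decimal_comma = FALSE) {
  raw <- read_delimited(path, delim = delim, decimal_comma = decimal_comma)
  names(raw) <- tolower(names(raw))
  miss <- setdiff(c("person_id", "sex", "age", "weight_kg"), names(raw))
  if (length(miss) > 0) {
    stop_invalid("persons file is missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  raw$person_id <- as.character(raw$person_id)
  tibble::as_tibble(raw)
}

intake_value_cols <- function() {
  c("fructose_g", "glucose_g", "fructan_g", "gos_g", "lactose_g",
    "polyols_g", "excess_fructose_g", "total_oligo_g", "total_fodmap_g",
    "energy_mj")
}

#' Summarise a food diary into per person-day FODMAP intakes
#'
#' Joins every diary entry to its food's per-100 g profile (decomposing
#' composites with recipes but no stored profile via [decompose_entry()]
#' semantics), scales to the recorded portion with [portion_grams()], and
#' sums per person-day. Absent component values contribute 0 grams. Excess
#' fructose is computed from the day totals of fructose and glucose
#' (`mode = "day_level"`, the default) or summed per item
#' (`mode = "item_level"`); aggregation before the max(0, f - g) floor makes
#' the day-level figure never larger than the item-level one.
#'
#' @param diary Diary tibble (see [read_diary()]).
#' @param db A `fodmap_db`.
#' @param recipes Optional recipes tibble for decomposing composites.
#' @param mode `"day_level"` (default) or `"item_level"` excess-fructose
#'   accounting.
#' @param permissive If `FALSE` (default) a food absent from both the
#'   database and the recipes is an error listing the offending ids; if
#'   `TRUE` such entries are skipped and the affected person-days get
#'   `completeness_flag = TRUE`.
#' @return A tibble with one row per person-day: the six component totals in
#'   grams, `excess_fructose_g`, `total_oligo_g`, `total_fodmap_g`,
#'   `energy_mj` and `completeness_flag`.
#' @export
compute_daily_intakes <- function(diary, db, recipes = NULL,
                                  mode = c("day_level", "item_level"),
                                  permissive = FALSE) {
  mode <- match.arg(mode)
  req <- c("person_id", "day_index", "food_id", "amount_g")
  miss <- setdiff(req, names(diary))
  if (length(miss) > 0) {
    stop_invalid("diary is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (nrow(diary) > 0 && (anyNA(diary$amount_g) || any(diary$amount_g <= 0))) {
    stop_invalid("diary `amount_g` must be present and > 0")
  }

  days <- dplyr::distinct(diary, .data$person_id, .data$day_index)
  if (nrow(diary) == 0) {
    out <- days
    for (col in intake_value_cols()) out[[col]] <- numeric(0)
    out$completeness_flag <- logical(0)
    return(out)
  }

  dec <- decompose_entries(diary, recipes, db)
  if (nrow(dec$unresolved) > 0) {
    bad <- sort(unique(dec$unresolved$food_id))
    if (!permissive) {
      stop_invalid("unresolved food id(s) absent from database and recipes: %s",
                   paste(bad, collapse = ", "))
    }
  }
  flagged_days <- dplyr::distinct(dec$unresolved, .data$person_id,
                                  .data$day_index)
  flagged_days$completeness_flag <- TRUE

  profile <- tibble::tibble(food_id = db$id)
  for (comp in fodmap_components()) {
    profile[[comp]] <- dplyr::coalesce(db[[db_value_col(comp)]], 0)
  }
  profile$energy_kj <- dplyr::coalesce(db$energy_kj_100g, 0)

  entries <- dec$resolved |>
    dplyr::inner_join(profile, by = "food_id") |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(c(fodmap_components(), "energy_kj")),
      ~ portion_grams(.x, amount_g)))

  daily <- entries |>
    dplyr::group_by(.data$person_id, .data$day_index) |>
    dplyr::summarise(
      fructose_g = sum(.data$fructose),
      glucose_g = sum(.data$glucose),
      fructan_g = sum(.data$fructan),
      gos_g = sum(.data$gos),
      lactose_g = sum(.data$lactose),
      polyols_g = sum(.data$polyols),
      excess_item = sum(pmax(0, .data$fructose - .data$glucose)),
      energy_mj = sum(.data$energy_kj) / 1000,
      .groups = "drop")

  daily$excess_fructose_g <- if (mode == "day_level") {
    excess_fructose(daily$fructose_g, daily$glucose_g)
  } else {
    daily$excess_item
  }
  daily$excess_item <- NULL
  daily$total_oligo_g <- total_oligosaccharides(daily$fructan_g, daily$gos_g)
  daily$total_fodmap_g <- total_fodmap(daily$excess_fructose_g,
                                       daily$fructan_g, daily$gos_g,
                                       daily$lactose_g, daily$polyols_g)

  out <- days |>
    dplyr::left_join(daily, by = c("person_id", "day_index")) |>
    dplyr::left_join(flagged_days, by = c("person_id", "day_index")) |>
    dplyr::mutate(
      completeness_flag = dplyr::coalesce(.data$completeness_flag, FALSE),
      dplyr::across(dplyr::all_of(intake_value_cols()),
                    ~ dplyr::coalesce(.x, 0)))
  dplyr::relocate(out, dplyr::all_of(c("person_id", "day_index",
                                       intake_value_cols(),
                                       "completeness_flag")))
}

#' Summarise one person-day of diary entries
#'
#' Convenience wrapper around [compute_daily_intakes()] for the entries of a
#' single person-day; an empty set of entries yields an all-zero vector.
#'
#' @param entries Diary rows for one person-day (may be empty but needs the
#'   diary columns).
#' @inheritParams compute_daily_intakes
#' @return A one-row intake tibble (see [compute_daily_intakes()]).
#' @export
compute_daily_intake <- function(entries, db, recipes = NULL,
                                 mode = c("day_level", "item_level"),
                                 permissive = FALSE) {
  mode <- match.arg(mode)
  if (nrow(entries) == 0) {
    zero <- tibble::as_tibble(setNames(as.list(rep(0, length(intake_value_cols()))),
                                       intake_value_cols()))
    return(dplyr::bind_cols(tibble::tibble(person_id = NA_character_,
                                           day_index = NA_integer_),
                            zero, tibble::tibble(completeness_flag = FALSE)))
  }
  key <- dplyr::distinct(entries, .data$person_id, .data$day_index)
  if (nrow(key) != 1) {
    stop_invalid("`entries` must belong to a single person-day")
  }
  compute_daily_intakes(entries, db, recipes, mode = mode,
                        permissive = permissive)
}

#' Per-person mean daily intake over recorded days
#'
#' @param daily_intakes Output of [compute_daily_intakes()].
#' @return One row per person: the arithmetic mean of each intake column
#'   over that person's recorded days, `n_days`, and `any_incomplete`.
#' @export
person_means <- function(daily_intakes) {
  if (nrow(daily_intakes) == 0) {
    stop_invalid("no recorded days: cannot compute person means")
  }
  daily_intakes |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(intake_value_cols()), mean),
      n_days = dplyr::n(),
      any_incomplete = any(.data$completeness_flag),
      .groups = "drop")
}

#' Population mean daily intake with confidence intervals
#'
#' The population mean of each intake component is the arithmetic mean of the
#' per-person means; the confidence interval is Student-t based,
#' `mean +/- t(1 - alpha/2, n - 1) * sd / sqrt(n)`.
#'
#' @param person_means Output of [person_means()].
#' @param conf_level Confidence level in (0, 1); default 0.95.
#' @return A tibble with one row per component: `component`, `n_persons`,
#'   `mean_g_day`, `sd_g_day`, `ci_low`, `ci_high` (energy rows are MJ/day).
#' @export
population_summary <- function(person_means, conf_level = 0.95) {
  n <- nrow(person_means)
  if (n < 2) {
    stop_invalid("insufficient sample: need at least 2 persons for a CI")
  }
  if (conf_level <= 0 || conf_level >= 1) {
    stop_invalid("`conf_level` must be in (0, 1)")
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  person_means |>
    tidyr::pivot_longer(dplyr::all_of(intake_value_cols()),
                        names_to = "component", values_to = "value") |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      mean_g_day = mean(.data$value),
      sd_g_day = sd(.data$value),
      ci_low = .data$mean_g_day - tcrit * .data$sd_g_day / sqrt(.data$n_persons),
      ci_high = .data$mean_g_day + tcrit * .data$sd_g_day / sqrt(.data$n_persons),
      .groups = "drop") |>
    dplyr::arrange(match(.data$component, intake_value_cols()))
}

#' Sample size for estimating a mean intake to a given precision
#'
#' Inverts the normal-approximation confidence half-width: the number of
#' persons needed so that `z * sd / sqrt(n) <= margin` is
#' `n = ceiling((z * sd / margin)^2)`. The margin can be given directly in
#' g/day or as a relative fraction of an expected mean.
#'
#' @param z Standard-normal quantile (1.96 for a 95% interval).
#' @param sd Anticipated between-person standard deviation, g/day.
#' @param margin Absolute half-width target, g/day.
#' @param relative_margin,expected_mean Alternative margin specification:
#'   `margin = relative_margin * expected_mean`.
#' @return The required number of persons (integer, >= 1).
#' @export
#' @examples
#' sample_size(1.96, 1.0, 0.196)  # 100
#' sample_size(1.96, 2.5, 0.47)   # about 110 persons for a fructan survey
sample_size <- function(z, sd, margin = NULL, relative_margin = NULL,
                        expected_mean = NULL) {
  if (is.null(margin)) {
    if (is.null(relative_margin) || is.null(expected_mean)) {
      stop_invalid(paste0("supply `margin`, or `relative_margin` together ",
                          "with `expected_mean`"))
    }
    margin <- relative_margin * expected_mean
  }
  if (any(c(z, sd, margin) <= 0)) {
    stop_invalid("`z`, `sd` and `margin` must all be > 0")
  }
  max(1L, as.integer(ceiling((z * sd / margin)^2)))
}

#' Default basal-metabolic-rate coefficient table
#'
#' The standard sex- and age-band linear equations (`BMR = slope * weight_kg
#' + intercept`, MJ/day) of the FAO/WHO/UNU style, shipped as a data file so
#' alternative coefficient sets can be substituted.
#'
#' @return A tibble with columns `sex`, `age_min`, `age_max` (band covers
#'   `age_min <= age < age_max`), `slope_mj_per_kg`, `intercept_mj`.
#' @export
default_bmr_coefficients <- function() {
  path <- system.file("extdata", "bmr_coefficients.csv", package = "fodmapr",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Basal metabolic rate from a sex/age-band coefficient table
#'
#' @param sex `"female"` or `"male"`. Vectorised.
#' @param age_years Age in years, > 0. Vectorised.
#' @param weight_kg Body weight in kg, > 0. Vectorised.
#' @param coefficients Coefficient table, see [default_bmr_coefficients()].
#' @return BMR in MJ/day.
#' @export
#' @examples
#' bmr("female", 40, 65) # 0.034 * 65 + 3.538 = 5.748
bmr <- function(sex, age_years, weight_kg,
                coefficients = default_bmr_coefficients()) {
  if (any(is.na(age_years)) || any(age_years <= 0)) {
    stop_invalid("`age_years` must be > 0")
  }
  if (any(is.na(weight_kg)) || any(weight_kg <= 0)) {
    stop_invalid("`weight_kg` must be > 0")
  }
  n <- max(length(sex), length(age_years), length(weight_kg))
  sex <- rep_len(tolower(as.character(sex)), n)
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    band <- which(coefficients$sex == sex[i] &
                    coefficients$age_min <= age_years[i] &
                    age_years[i] < coefficients$age_max)
    if (length(band) == 0) {
      stop_invalid("no BMR coefficient band covers sex `%s`, age %g",
                   sex[i], age_years[i])
    }
    out[i] <- coefficients$slope_mj_per_kg[band[1]] * weight_kg[i] +
      coefficients$intercept_mj[band[1]]
  }
  out
}

#' Energy intake to energy expenditure ratio
#'
#' @param mean_ei_mj Reported mean energy intake, MJ/day, >= 0.
#' @param mean_ee_mj Estimated mean energy expenditure (BMR x PAL), MJ/day,
#'   > 0.
#' @return The dimensionless ratio EI / EE (unrounded; round only for
#'   presentation). Vectorised.
#' @export
#' @examples
#' round(ei_ee_ratio(8.1, 11.2), 2) # 0.72
ei_ee_ratio <- function(mean_ei_mj, mean_ee_mj) {
  check_nonnegative(mean_ei_mj, "mean_ei_mj")
  if (any(is.na(mean_ee_mj)) || any(mean_ee_mj <= 0)) {
    stop_invalid("`mean_ee_mj` must be > 0")
  }
  mean_ei_mj / mean_ee_mj
}

#' Flag possible under-reporting from an EI:EE ratio
#'
#' @param ratio EI:EE ratio(s).
#' @param cutoff Screening cutoff; a ratio strictly below it is flagged.
#'   Default 0.76, a conventional Goldberg-type bound.
#' @return Logical, `TRUE` where `ratio < cutoff`.
#' @export
underreport_flag <- function(ratio, cutoff = 0.76) {
  if (any(is.na(cutoff)) || any(cutoff <= 0)) {
    stop_invalid("`cutoff` must be > 0")
  }
  ratio < cutoff
}

#' Energy-based under-reporting screen for a diary population
#'
#' For each person, compares mean reported energy intake (EI) against
#' estimated energy expenditure EE = BMR x PAL, where BMR comes from the
#' sex/age-band coefficient table and PAL from the persons table (default
#' `pal_default` when missing). Reports per-person ratios and flags, plus
#' population means: the ratio of mean EI to mean EE, and the mean of the
#' per-person ratios with a t-based confidence interval.
#'
#' @param person_means Output of [person_means()] (uses `energy_mj`).
#' @param persons Persons tibble with `person_id`, `sex`, `age`, `weight_kg`
#'   and optionally `pal`.
#' @param coefficients BMR coefficient table.
#' @param pal_default PAL used for persons without one (default 1.6).
#' @param cutoff Under-reporting cutoff passed to [underreport_flag()].
#' @param conf_level Confidence level for the mean-ratio interval.
#' @return A list of class `energy_assessment`: `per_person` tibble
#'   (`person_id`, `ei_mj`, `bmr_mj`, `pal`, `ee_mj`, `ratio`, `flagged`)
#'   and `population` list (`n`, `mean_ei_mj`, `mean_ee_mj`,
#'   `ratio_of_means`, `mean_ratio`, `ci_low`, `ci_high`, `cutoff`,
#'   `n_flagged`).
#' @export
energy_assessment <- function(person_means, persons,
                              coefficients = default_bmr_coefficients(),
                              pal_default = 1.6, cutoff = 0.76,
                              conf_level = 0.95) {
  miss <- setdiff(c("person_id", "sex", "age", "weight_kg"), names(persons))
  if (length(miss) > 0) {
    stop_invalid("persons table is missing column(s): %s",
                 paste(miss, collapse = ", "))
  }
  pp <- person_means |>
    dplyr::select("person_id", ei_mj = "energy_mj") |>
    dplyr::inner_join(tibble::as_tibble(persons), by = "person_id")
  if (nrow(pp) == 0) stop_invalid("no persons match the diary")
  if (!"pal" %in% names(pp)) pp$pal <- NA_real_
  n_missing_pal <- sum(is.na(pp$pal))
  if (n_missing_pal > 0) {
    message(sprintf("using default PAL %.2f for %d person(s) without one",
                    pal_default, n_missing_pal))
    pp$pal[is.na(pp$pal)] <- pal_default
  }
  pp$bmr_mj <- bmr(pp$sex, pp$age, pp$weight_kg, coefficients)
  pp$ee_mj <- pp$bmr_mj * pp$pal
  pp$ratio <- ei_ee_ratio(pp$ei_mj, pp$ee_mj)
  pp$flagged <- underreport_flag(pp$ratio, cutoff)
  per_person <- dplyr::select(pp, "person_id", "ei_mj", "bmr_mj", "pal",
                              "ee_mj", "ratio", "flagged")
  n <- nrow(per_person)
  mean_ratio <- mean(per_person$ratio)
  ci <- if (n >= 2) {
    tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
    se <- sd(per_person$ratio) / sqrt(n)
    c(mean_ratio - tcrit * se, mean_ratio + tcrit * se)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(
    per_person = per_person,
    population = list(
      n = n,
      mean_ei_mj = mean(per_person$ei_mj),
      mean_ee_mj = mean(per_person$ee_mj),
      ratio_of_means = mean(per_person$ei_mj) / mean(per_person$ee_mj),
      mean_ratio = mean_ratio,
      ci_low = ci[1], ci_high = ci[2],
      cutoff = cutoff,
      n_flagged = sum(per_person$flagged))
  ), class = "energy_assessment")
}

#' @export
print.energy_assessment <- function(x, ...) {
  p <- x$population
  cat("Energy-based under-reporting screen\n")
  cat(sprintf("  persons: %d\n", p$n))
  cat(sprintf("  mean EI: %.2f MJ/day; mean EE: %.2f MJ/day\n",
              p$mean_ei_mj, p$mean_ee_mj))
  cat(sprintf("  EI:EE ratio of means: %.2f\n", p$ratio_of_means))
  cat(sprintf("  mean per-person ratio: %.2f (95%% CI %.2f-%.2f)\n",
              p$mean_ratio, p$ci_low, p$ci_high))
  cat(sprintf("  flagged below cutoff %.2f: %d\n", p$cutoff, p$n_flagged))
  invisible(x)
}
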