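## A composition database is a tibble with one row per food item and, for each
## carbohydrate component c in fodmap_components(), a column triple
## <c>_g_100g / <c>_provenance / <c>_source. NA in <c>_g_100g means the value
## is absent (unknown), which is distinct from a stored 0.

db_required_cols <- function() {
  c("id", "name", "category", "water_fraction", "energy_kj_100g")
}

db_value_col <- function(component) paste0(component, "_g_100g")
db_prov_col <- function(component) paste0(component, "_provenance")
db_source_col <- function(component) paste0(component, "_source")

#' Construct a FODMAP composition database from a data frame
#'
#' Ensures the required identity columns are present, creates any missing
#' component value/provenance/source columns (as absent), and defaults the
#' provenance of present values to `direct_measurement`.
#'
#' @param items A data frame with columns `id`, `name`, `category`,
#'   `water_fraction`, `energy_kj_100g`, optionally `fermented_bread`,
#'   `rye_wheat_based`, and per-component triples such as `fructan_g_100g`,
#'   `fructan_provenance`, `fructan_source`.
#' @return A tibble of class `fodmap_db`.
#' @seealso [read_composition_db()] for loading from delimited text with
#'   component-sum and dry-weight handling.
#' @export
fodmap_db <- function(items) {
  items <- tibble::as_tibble(items)
  missing_cols <- setdiff(db_required_cols(), names(items))
  if (length(missing_cols) > 0) {
    stop_invalid("composition table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  items$id <- as.character(items$id)
  items$name <- as.character(items$name)
  items$category <- as.character(items$category)
  if (!"fermented_bread" %in% names(items)) items$fermented_bread <- FALSE
  if (!"rye_wheat_based" %in% names(items)) items$rye_wheat_based <- FALSE
  for (comp in fodmap_components()) {
    vc <- db_value_col(comp)
    pc <- db_prov_col(comp)
    sc <- db_source_col(comp)
    if (!vc %in% names(items)) items[[vc]] <- NA_real_
    items[[vc]] <- as.numeric(items[[vc]])
    if (!pc %in% names(items)) items[[pc]] <- NA_character_
    if (!sc %in% names(items)) items[[sc]] <- NA_character_
    has_val <- !is.na(items[[vc]])
    items[[pc]][has_val & is.na(items[[pc]])] <- "direct_measurement"
    items[[pc]][!has_val] <- NA_character_
  }
  class(items) <- c("fodmap_db", class(items))
  items
}

#' Convert a dry-matter value to fresh-weight basis
#'
#' Analytical values reported per 100 g dry matter are converted to the
#' fresh-weight ("as eaten") basis used throughout the database, using the
#' food's water fraction: `fresh = dry * (1 - water_fraction)`.
#'
#' @param value_dry Content in g per 100 g dry matter. Vectorised.
#' @param water_fraction Mass fraction of water in the fresh food, in
#'   `[0, 1)`. Vectorised.
#' @return Content in g per 100 g fresh weight; never larger than the input.
#' @export
#' @examples
#' dry_to_fresh(2.0, 0.5)    # 1.0
#' dry_to_fresh(1.494, 0.13) # ~1.30, a typical wheat-flour fructan value
dry_to_fresh <- function(value_dry, water_fraction) {
  check_nonnegative(value_dry, "value_dry")
  if (!is.numeric(water_fraction) || anyNA(water_fraction) ||
      any(water_fraction < 0) || any(water_fraction >= 1)) {
    stop_invalid("`water_fraction` must be in [0, 1)")
  }
  value_dry * (1 - water_fraction)
}

#' Galacto-oligosaccharides from separately analysed components
#'
#' GOS is operationalised as the sum of raffinose and stachyose, which are
#' typically reported separately by HPLC analyses.
#'
#' @param raffinose,stachyose Contents in g per 100 g. Vectorised.
#' @return The GOS content (`raffinose + stachyose`).
#' @export
#' @examples
#' gos_from_components(0.1, 0.3) # 0.4
gos_from_components <- function(raffinose, stachyose) {
  check_nonnegative(raffinose, "raffinose")
  check_nonnegative(stachyose, "stachyose")
  raffinose + stachyose
}

#' Polyols from separately analysed components
#'
#' The polyol total is operationalised as sorbitol + mannitol.
#'
#' @param sorbitol,mannitol Contents in g per 100 g. Vectorised.
#' @return The polyol content (`sorbitol + mannitol`).
#' @export
polyols_from_components <- function(sorbitol, mannitol) {
  check_nonnegative(sorbitol, "sorbitol")
  check_nonnegative(mannitol, "mannitol")
  sorbitol + mannitol
}

#' Approximate total fructan by summing oligomer analyses
#'
#' Where no enzymatic total-fructan analysis exists, separate analyses of the
#' main fructo-oligosaccharides (e.g. the kestose/nystose GF2-GF4 series) can
#' be summed to approximate the total. The result should be stored with
#' provenance `component_sum` and flagged as an approximation.
#'
#' @param oligomer_amounts Numeric vector of oligomer contents, g per 100 g.
#'   Must be non-empty.
#' @return The summed fructan approximation.
#' @export
#' @examples
#' fructan_from_oligomers(c(0.3, 0.2, 0.1)) # 0.6
fructan_from_oligomers <- function(oligomer_amounts) {
  if (length(oligomer_amounts) == 0) {
    stop_invalid("`oligomer_amounts` must contain at least one value")
  }
  check_nonnegative(oligomer_amounts, "oligomer_amounts")
  sum(oligomer_amounts)
}

## Collapse duplicate ids: for each component, take the value from the
## highest-precedence row that has one (a source that detected the analyte
## beats one that did not); item metadata comes from the highest-precedence
## row overall. Default precedence is row order, so later rows win.
merge_duplicate_ids <- function(items) {
  if (!"precedence" %in% names(items)) items$precedence <- seq_len(nrow(items))
  if (!anyDuplicated(items$id)) {
    return(dplyr::select(items, -"precedence"))
  }
  meta_cols <- setdiff(names(items), "precedence")
  items <- dplyr::arrange(items, .data$id, .data$precedence)
  merged <- items |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(rows, key) {
      out <- rows[nrow(rows), meta_cols[meta_cols != "id"]]
      for (comp in fodmap_components()) {
        vc <- db_value_col(comp)
        present <- which(!is.na(rows[[vc]]))
        if (length(present) > 0) {
          pick <- present[length(present)]
          out[[vc]] <- rows[[vc]][pick]
          out[[db_prov_col(comp)]] <- rows[[db_prov_col(comp)]][pick]
          out[[db_source_col(comp)]] <- rows[[db_source_col(comp)]][pick]
        }
      }
      out
    }) |>
    dplyr::ungroup()
  merged
}

#' Read a FODMAP composition table from delimited text
#'
#' Reads a comma- or tab-delimited table with one row per food item, then
#' applies the standard loading transformations:
#'
#' * component sums: where a GOS value is absent but `raffinose_g_100g` /
#'   `stachyose_g_100g` are present they are summed (likewise sorbitol +
#'   mannitol for polyols, and any `oligomer_*` columns for fructan), stored
#'   with provenance `component_sum`;
#' * dry-weight conversion: rows with `dry_weight = TRUE` have all component
#'   values converted to fresh weight via [dry_to_fresh()] using the row's
#'   `water_fraction`;
#' * duplicate ids are merged with last-writer-wins semantics, ordered by an
#'   optional numeric `precedence` column (higher wins; default row order),
#'   taking each component value from the highest-precedence source that
#'   reports one.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @param decimal_comma If `TRUE`, parse numbers with a decimal comma (then
#'   the field delimiter must be tab or semicolon).
#' @return A `fodmap_db` tibble.
#' @export
read_composition_db <- function(path, delim = NULL, decimal_comma = FALSE) {
  raw <- read_delimited(path, delim = delim, decimal_comma = decimal_comma)
  if (nrow(raw) == 0) {
    stop_invalid("composition file `%s` contains no rows", path)
  }
  names(raw) <- tolower(names(raw))
  if ("dry_weight" %in% names(raw)) raw$dry_weight <- as.logical(raw$dry_weight)

  ## component sums from raw analyte columns
  sum_into <- function(items, comp, part_cols, note) {
    have <- intersect(part_cols, names(items))
    if (length(have) == 0) return(items)
    vc <- db_value_col(comp)
    if (!vc %in% names(items)) items[[vc]] <- NA_real_
    parts <- as.matrix(items[have])
    n_present <- rowSums(!is.na(parts))
    total <- rowSums(parts, na.rm = TRUE)
    fill <- is.na(items[[vc]]) & n_present > 0
    items[[vc]][fill] <- total[fill]
    pc <- db_prov_col(comp)
    sc <- db_source_col(comp)
    if (!pc %in% names(items)) items[[pc]] <- NA_character_
    if (!sc %in% names(items)) items[[sc]] <- NA_character_
    items[[pc]][fill] <- "component_sum"
    items[[sc]][fill] <- note
    items
  }
  raw <- sum_into(raw, "gos", c("raffinose_g_100g", "stachyose_g_100g"),
                  "component_sum: raffinose + stachyose")
  raw <- sum_into(raw, "polyols", c("sorbitol_g_100g", "mannitol_g_100g"),
                  "component_sum: sorbitol + mannitol")
  oligo_cols <- grep("^oligomer", names(raw), value = TRUE)
  raw <- sum_into(raw, "fructan", oligo_cols,
                  "component_sum: fructo-oligomer sum (approximation)")

  db <- fodmap_db(raw)

  ## dry-weight rows: convert every present component value to fresh weight
  if ("dry_weight" %in% names(raw)) {
    dry <- which(!is.na(raw$dry_weight) & raw$dry_weight)
    for (comp in fodmap_components()) {
      vc <- db_value_col(comp)
      pc <- db_prov_col(comp)
      rows <- dry[!is.na(db[[vc]][dry])]
      if (length(rows) == 0) next
      db[[vc]][rows] <- dry_to_fresh(db[[vc]][rows], db$water_fraction[rows])
      plain <- rows[db[[pc]][rows] == "direct_measurement"]
      db[[pc]][plain] <- "dry_weight_converted"
    }
    db$dry_weight <- NULL
  }

  db <- merge_duplicate_ids(db)
  class(db) <- c("fodmap_db", setdiff(class(db), "fodmap_db"))
  db
}

#' Copy FODMAP values from a similar food item
#'
#' When no analytical data exist for a food, its values can be assigned from
#' a similar item (e.g. frozen broccoli from fresh broccoli, bulgur from
#' couscous). Each value present on the source and absent on the target is
#' copied with provenance `similarity_assigned` and a source label naming the
#' source item. Values the target already carries are never overwritten.
#'
#' @param db A `fodmap_db`.
#' @param target_id,source_id Item ids in `db`.
#' @param mapping_note Optional free text appended to the source label.
#' @return The updated database.
#' @export
assign_by_similarity <- function(db, target_id, source_id,
                                 mapping_note = NULL) {
  ti <- match(target_id, db$id)
  si <- match(source_id, db$id)
  if (is.na(ti)) stop_invalid("unknown target id `%s`", target_id)
  if (is.na(si)) stop_invalid("unknown source id `%s`", source_id)
  src_vals <- vapply(fodmap_components(),
                     function(comp) db[[db_value_col(comp)]][si], numeric(1))
  if (all(is.na(src_vals))) {
    warning(sprintf("source `%s` has an empty profile; nothing to assign",
                    source_id), call. = FALSE)
    return(db)
  }
  label <- paste0("assigned from ", source_id,
                  if (!is.null(mapping_note)) paste0(" (", mapping_note, ")"))
  for (comp in fodmap_components()) {
    vc <- db_value_col(comp)
    if (!is.na(db[[vc]][si]) && is.na(db[[vc]][ti])) {
      db[[vc]][ti] <- db[[vc]][si]
      db[[db_prov_col(comp)]][ti] <- "similarity_assigned"
      db[[db_source_col(comp)]][ti] <- label
    }
  }
  db
}

#' Apply a similarity mapping table
#'
#' @param db A `fodmap_db`.
#' @param map A data frame with columns `target_id` and `source_id` (and an
#'   optional `note`), applied row by row via [assign_by_similarity()].
#' @return The updated database.
#' @export
apply_similarity_map <- function(db, map) {
  map <- tibble::as_tibble(map)
  if (!all(c("target_id", "source_id") %in% names(map))) {
    stop_invalid("similarity map needs columns `target_id` and `source_id`")
  }
  for (i in seq_len(nrow(map))) {
    note <- if ("note" %in% names(map)) map$note[i] else NULL
    db <- assign_by_similarity(db, map$target_id[i], map$source_id[i], note)
  }
  db
}

#' Census of stored FODMAP values by group and provenance
#'
#' Counts every present value of the five FODMAP groups (glucose is excluded:
#' it is carried only for the excess-fructose rule), broken down by group and
#' by provenance class, and reports the share of values that came from direct
#' measurement, rounded half-up to an integer percent.
#'
#' @param db A `fodmap_db`.
#' @return A list of class `provenance_census` with elements `per_fodmap`
#'   (named counts, `fructose_n` ... `polyols_n`), `per_provenance`,
#'   `total_n`, `direct_n`, `direct_share` (integer percent; 0 with
#'   `empty = TRUE` for a database holding no values), `n_items` and
#'   `n_items_with_values`.
#' @export
provenance_census <- function(db) {
  per_fodmap <- integer(0)
  prov_counts <- setNames(integer(length(provenance_classes())),
                          provenance_classes())
  any_value <- rep(FALSE, nrow(db))
  for (comp in fodmap_groups()) {
    present <- !is.na(db[[db_value_col(comp)]])
    per_fodmap[[paste0(comp, "_n")]] <- sum(present)
    any_value <- any_value | present
    provs <- db[[db_prov_col(comp)]][present]
    tab <- table(factor(provs, levels = provenance_classes()))
    prov_counts <- prov_counts + as.integer(tab)
  }
  total_n <- sum(per_fodmap)
  direct_n <- prov_counts[["direct_measurement"]]
  empty <- total_n == 0
  structure(list(
    per_fodmap = per_fodmap,
    per_provenance = as.list(prov_counts),
    total_n = total_n,
    direct_n = direct_n,
    direct_share = if (empty) 0 else round_half_up(100 * direct_n / total_n),
    empty = empty,
    n_items = nrow(db),
    n_items_with_values = sum(any_value)
  ), class = "provenance_census")
}

#' @export
print.provenance_census <- function(x, ...) {
  cat("FODMAP value census\n")
  cat(sprintf("  items: %d (%d with at least one value)\n",
              x$n_items, x$n_items_with_values))
  cat("  values by FODMAP group:\n")
  for (nm in names(x$per_fodmap)) {
    cat(sprintf("    %-12s %6d\n", sub("_n$", "", nm), x$per_fodmap[[nm]]))
  }
  cat(sprintf("  total values: %d\n", x$total_n))
  cat("  values by provenance:\n")
  for (nm in names(x$per_provenance)) {
    cat(sprintf("    %-22s %6d\n", nm, x$per_provenance[[nm]]))
  }
  if (x$empty) {
    cat("  direct-measurement share: undefined (empty database)\n")
  } else {
    cat(sprintf("  direct-measurement share: %d%%\n", x$direct_share))
  }
  invisible(x)
}

#' Validate a composition database
#'
#' Runs structural checks and returns findings as data rather than raising
#' errors: negative amounts, water fractions outside `[0, 1]`, negative
#' energy, duplicate ids, unknown categories or provenance labels,
#' non-carbohydrate items carrying FODMAP values, and glucose stored without
#' fructose (a warning, since the excess-fructose rule then has nothing to
#' offset).
#'
#' @param db A `fodmap_db`.
#' @return A tibble with columns `level` (`"error"` or `"warning"`), `id`,
#'   `field`, `message`; zero rows for a clean database.
#' @export
validate_db <- function(db) {
  findings <- list()
  add <- function(level, id, field, message) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(level = level, id = id, field = field, message = message)
  }
  dup <- unique(db$id[duplicated(db$id)])
  for (d in dup) add("error", d, "id", "duplicate food id")
  bad_w <- which(is.na(db$water_fraction) | db$water_fraction < 0 |
                   db$water_fraction > 1)
  for (i in bad_w) {
    add("error", db$id[i], "water_fraction",
        "water_fraction missing or outside [0, 1]")
  }
  bad_e <- which(!is.na(db$energy_kj_100g) & db$energy_kj_100g < 0)
  for (i in bad_e) add("error", db$id[i], "energy_kj_100g", "negative energy")
  bad_cat <- which(!db$category %in% food_categories())
  for (i in bad_cat) {
    add("warning", db$id[i], "category",
        sprintf("unknown category `%s`", db$category[i]))
  }
  for (comp in fodmap_components()) {
    vc <- db_value_col(comp)
    pc <- db_prov_col(comp)
    neg <- which(!is.na(db[[vc]]) & db[[vc]] < 0)
    for (i in neg) add("error", db$id[i], vc, "negative amount")
    bad_p <- which(!is.na(db[[vc]]) & !db[[pc]] %in% provenance_classes())
    for (i in bad_p) {
      add("warning", db$id[i], pc,
          sprintf("unrecognised provenance `%s`", db[[pc]][i]))
    }
    noncarb <- which(db$category == "non_carbohydrate" & !is.na(db[[vc]]))
    for (i in noncarb) {
      add("error", db$id[i], vc,
          "non-carbohydrate item should carry no FODMAP values")
    }
  }
  glc_only <- which(!is.na(db[[db_value_col("glucose")]]) &
                      is.na(db[[db_value_col("fructose")]]))
  for (i in glc_only) {
    add("warning", db$id[i], "glucose_g_100g",
        "glucose stored without fructose; excess-fructose rule cannot apply")
  }
  if (length(findings) == 0) {
    return(tibble::tibble(level = character(), id = character(),
                          field = character(), message = character()))
  }
  dplyr::bind_rows(findings)
}

## shared delimited-text reader: comma default, tab accepted; optional
## decimal-comma locale (Swedish sources)
read_delimited <- function(path, delim = NULL, decimal_comma = FALSE) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    if (length(header) == 0) stop_invalid("file `%s` is empty", path)
    delim <- if (grepl("\t", header)) "\t" else if (!grepl(",", header) &&
                                                    grepl(";", header)) ";" else ","
  }
  if (decimal_comma && delim == ",") {
    stop_invalid("decimal_comma = TRUE requires a tab or semicolon delimiter")
  }
  loc <- readr::locale(decimal_mark = if (decimal_comma) "," else ".",
                       grouping_mark = if (decimal_comma) "." else ",")
  readr::read_delim(path, delim = delim, locale = loc, na = c("", "NA"),
                    show_col_types = FALSE, progress = FALSE)
}
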