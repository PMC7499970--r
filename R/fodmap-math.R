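#' Fructose in excess of glucose
#'
#' Fructose is co-absorbed with glucose, so only fructose in excess of glucose
#' is counted toward the FODMAP total. When glucose meets or exceeds fructose
#' the excess is zero.
#'
#' @param fructose_g Fructose in grams (per day, portion, or 100 g). Vectorised.
#' @param glucose_g Glucose in grams on the same basis. Vectorised.
#' @return `pmax(0, fructose_g - glucose_g)`, in the same units as the inputs.
#' @export
#' @examples
#' excess_fructose(15.2, 15.5) # 0: glucose exceeds fructose
#' excess_fructose(5, 2)       # 3
excess_fructose <- function(fructose_g, glucose_g) {
  check_nonnegative(fructose_g, "fructose_g")
  check_nonnegative(glucose_g, "glucose_g")
  pmax(0, fructose_g - glucose_g)
}

#' Total oligosaccharides
#'
#' The oligosaccharide total is the sum of fructans and
#' galacto-oligosaccharides (GOS).
#'
#' @param fructan_g Fructan in grams. Vectorised.
#' @param gos_g GOS in grams. Vectorised.
#' @return `fructan_g + gos_g`.
#' @export
#' @examples
#' total_oligosaccharides(3.46, 0.43) # 3.89
total_oligosaccharides <- function(fructan_g, gos_g) {
  check_nonnegative(fructan_g, "fructan_g")
  check_nonnegative(gos_g, "gos_g")
  fructan_g + gos_g
}

#' Total FODMAP
#'
#' Total FODMAP = excess fructose + total oligosaccharides (fructan + GOS) +
#' lactose + polyols. Glucose enters only through the excess-fructose term.
#'
#' @param excess_fructose_g Fructose in excess of glucose, grams.
#' @param fructan_g,gos_g,lactose_g,polyols_g Component amounts in grams.
#' @return The total in grams. All arguments vectorised.
#' @export
#' @examples
#' total_fodmap(0, 3.46, 0.43, 14.2, 1.31) # 19.4
total_fodmap <- function(excess_fructose_g, fructan_g, gos_g, lactose_g,
                         polyols_g) {
  check_nonnegative(excess_fructose_g, "excess_fructose_g")
  check_nonnegative(fructan_g, "fructan_g")
  check_nonnegative(gos_g, "gos_g")
  check_nonnegative(lactose_g, "lactose_g")
  check_nonnegative(polyols_g, "polyols_g")
  excess_fructose_g + total_oligosaccharides(fructan_g, gos_g) +
    lactose_g + polyols_g
}

#' Scale a per-100 g content to a recorded portion
#'
#' @param value_per_100g Content in g per 100 g of food.
#' @param amount_g Portion mass in grams.
#' @return Grams of the component in the portion. Vectorised.
#' @export
#' @examples
#' portion_grams(1.02, 100) # 1.02 g fructan in 100 g white bread
#' portion_grams(0.20, 250) # 0.50
portion_grams <- function(value_per_100g, amount_g) {
  check_nonnegative(value_per_100g, "value_per_100g")
  check_nonnegative(amount_g, "amount_g")
  value_per_100g * amount_g / 100
}

#' Build a FODMAP vector with its derived totals
#'
#' Collects component amounts (grams per day or per portion) into a one-row
#' tibble and appends the derived fields: excess fructose, total
#' oligosaccharides and total FODMAP. All inputs are vectorised, giving one
#' row per element.
#'
#' @param fructose_g,glucose_g,fructan_g,gos_g,lactose_g,polyols_g Component
#'   amounts in grams; default 0.
#' @return A tibble with the six component columns plus `excess_fructose_g`,
#'   `total_oligo_g` and `total_fodmap_g`.
#' @export
#' @examples
#' fodmap_vector(fructose_g = 15.2, glucose_g = 15.5, fructan_g = 3.46,
#'               gos_g = 0.43, lactose_g = 14.2, polyols_g = 1.31)
fodmap_vector <- function(fructose_g = 0, glucose_g = 0, fructan_g = 0,
                          gos_g = 0, lactose_g = 0, polyols_g = 0) {
  ex <- excess_fructose(fructose_g, glucose_g)
  tibble::tibble(
    fructose_g = fructose_g,
    glucose_g = glucose_g,
    fructan_g = fructan_g,
    gos_g = gos_g,
    lactose_g = lactose_g,
    polyols_g = polyols_g,
    excess_fructose_g = ex,
    total_oligo_g = total_oligosaccharides(fructan_g, gos_g),
    total_fodmap_g = total_fodmap(ex, fructan_g, gos_g, lactose_g, polyols_g)
  )
}
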