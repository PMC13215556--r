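# Diet intake: daily food logs plus a per-100 g composition table become
# per-nutrient gross COD entering the mouth (COD_g^UGI).

#' Gross COD contributed by one nutrient of one food
#'
#' `amt_food * f_nutrient * cod_specific`: grams of food per day, the mass
#' fraction of the nutrient in the food, and the nutrient's specific COD.
#'
#' @param amt_food g wet weight of food per day.
#' @param f_nutrient g nutrient per g food wet weight, in `[0, 1]`.
#' @param spec A [nutrient_spec()] or bare specific COD (gCOD/g).
#' @return gCOD/d.
#' @export
nutrient_gross_cod <- function(amt_food, f_nutrient, spec) {
  if (amt_food < 0) stop("amt_food must be non-negative", call. = FALSE)
  if (f_nutrient < 0 || f_nutrient > 1)
    stop("f_nutrient must lie in [0, 1]", call. = FALSE)
  cod_of_mass(amt_food * f_nutrient, spec)
}

#' Read a diet log CSV
#'
#' Columns: `participant_id`, `diet_label`, `food_id`, `grams_per_day`.
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_diet_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "diet_label", "food_id", "grams_per_day")
  if (!all(needed %in% names(d)))
    stop("diet CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(d$grams_per_day < 0))
    stop("grams_per_day must be non-negative", call. = FALSE)
  d
}

#' Read a food-composition CSV
#'
#' Columns: `food_id`, `nutrient_id`, `g_per_100g` (USDA-style, per 100 g
#' wet weight; converted to mass fractions at load).
#' @param path CSV file path.
#' @return A data frame with columns `food_id`, `nutrient_id`, `fraction`.
#' @export
read_composition_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("food_id", "nutrient_id", "g_per_100g")
  if (!all(needed %in% names(d)))
    stop("composition CSV needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  d$fraction <- d$g_per_100g / 100
  d[c("food_id", "nutrient_id", "fraction")]
}

validate_composition <- function(composition, tol = 0.01) {
  if (any(composition$fraction < 0 | composition$fraction > 1))
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  sums <- tapply(composition$fraction, composition$food_id, sum)
  bad <- names(sums)[sums > 1 + tol]
  if (length(bad))
    stop("composition fractions sum to more than 1 for food(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Aggregate a food log into per-nutrient gross COD
#'
#' Sums, across all foods eaten in a day, each nutrient's gross COD. The
#' result is order-independent and additive in the food list.
#'
#' @param foods Data frame with columns `food_id`, `grams_per_day` (one row
#'   per food eaten; repeated foods accumulate).
#' @param composition Data frame with columns `food_id`, `nutrient_id`,
#'   `fraction` (g nutrient per g food), e.g. from [read_composition_csv()].
#' @param registry A `nutrient_registry`.
#' @param tol Tolerance on per-food fraction sums above 1 (water and ash make
#'   up the remainder below 1).
#' @return A `diet_intake`: list with `cod` (named gCOD/d per nutrient,
#'   registry order) and `total` (gCOD/d).
#' @export
aggregate_diet <- function(foods, composition, registry, tol = 0.01) {
  validate_composition(composition, tol = tol)
  unknown <- setdiff(composition$nutrient_id, registry$id)
  if (length(unknown))
    stop("composition refers to unknown nutrient(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  food_ids <- if (nrow(foods)) unique(foods$food_id) else character(0)
  missing_comp <- setdiff(food_ids, composition$food_id)
  if (length(missing_comp))
    stop("no composition for food(s): ",
         paste(missing_comp, collapse = ", "), call. = FALSE)
  nutrient_ids <- registry$id[
    registry$nutrient_class %in% c("amino_acid", "sugar", "starch",
                                   "fiber", "fat")]
  cod <- stats::setNames(numeric(length(nutrient_ids)), nutrient_ids)
  if (nrow(foods)) {
    m <- merge(foods, composition, by = "food_id")
    m$gcod <- m$grams_per_day * m$fraction *
      registry_cod(registry, m$nutrient_id)
    sums <- tapply(m$gcod, m$nutrient_id, sum)
    cod[names(sums)] <- sums
  }
  structure(list(cod = cod, total = sum(cod)), class = "diet_intake")
}

#' @export
print.diet_intake <- function(x, ...) {
  cat(sprintf("<diet_intake> total %.1f gCOD/d over %d nutrients (%d nonzero)\n",
              x$total, length(x$cod), sum(x$cod > 0)))
  invisible(x)
}

#' Macronutrient grams of a food log
#'
#' Total grams per day of protein (amino acids), carbohydrate (sugars, starch
#' and fiber; the classic Atwater convention counts fiber as carbohydrate)
#' and fat, for use with the Atwater baseline.
#'
#' @inheritParams aggregate_diet
#' @return Named numeric: `protein_g`, `carb_g`, `fat_g`.
#' @export
diet_macronutrient_grams <- function(foods, composition, registry) {
  if (!nrow(foods))
    return(c(protein_g = 0, carb_g = 0, fat_g = 0))
  m <- merge(foods, composition, by = "food_id")
  m$grams <- m$grams_per_day * m$fraction
  cls <- registry_class(registry, m$nutrient_id)
  c(protein_g = sum(m$grams[cls == "amino_acid"]),
    carb_g = sum(m$grams[cls %in% c("sugar", "starch", "fiber")]),
    fat_g = sum(m$grams[cls == "fat"]))
}
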