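#' Nutrient panels
#'
#' A nutrient panel is the ordered list of nutrients a recall table carries,
#' together with the unit each nutrient is expressed in and the set of
#' "nutrients to limit" that are reverse scored when a total nutrient index is
#' computed. Units are metadata only: no function in the package ever converts
#' a unit implicitly.
#'
#' @param nutrients Character vector of unique nutrient names. These become the
#'   nutrient amount columns of a recall table.
#' @param units Named character vector of units, one per nutrient. Defaults to
#'   `"unit"` for every nutrient.
#' @param reverse Character vector of nutrients to limit (reverse scored in the
#'   total nutrient index); must be a subset of `nutrients`.
#'
#' @return An object of class `nutrient_panel`: a list with elements
#'   `nutrients`, `units` and `reverse`.
#' @examples
#' nutrient_panel(c("energy", "sodium"), reverse = "sodium")
#' @export
nutrient_panel <- function(nutrients, units = NULL, reverse = character()) {
  if (!is.character(nutrients) || length(nutrients) == 0) {
    abort("`nutrients` must be a non-empty character vector.")
  }
  if (anyDuplicated(nutrients)) {
    abort("nutrient names must be unique.")
  }
  if (is.null(units)) {
    units <- setNames(rep("unit", length(nutrients)), nutrients)
  }
  if (is.null(names(units)) || !all(names(units) %in% nutrients)) {
    abort("`units` must be named by nutrients in the panel.")
  }
  units <- units[nutrients]
  names(units) <- nutrients
  units[is.na(units)] <- "unit"
  if (!all(reverse %in% nutrients)) {
    abort(paste0(
      "reverse-scored nutrients not in the panel: ",
      paste(setdiff(reverse, nutrients), collapse = ", ")
    ))
  }
  structure(
    list(nutrients = nutrients, units = units, reverse = reverse),
    class = "nutrient_panel"
  )
}

#' @export
print.nutrient_panel <- function(x, ...) {
  cat("<nutrient_panel> ", length(x$nutrients), " nutrients\n", sep = "")
  cat("  ", paste(x$nutrients, " (", x$units, ")", sep = "", collapse = ", "),
      "\n", sep = "")
  if (length(x$reverse)) {
    cat("  reverse scored:", paste(x$reverse, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default 32-nutrient panel
#'
#' Energy, the three macronutrients, the 16 nutrients carrying an intake
#' recommendation (14 with an Estimated Average Requirement, sodium with an
#' Upper Limit, saturated fat with a percent-of-energy guideline) and the 12
#' commonly reported nutrients without one. Sodium and saturated fat are
#' reverse scored.
#'
#' @return A [nutrient_panel()].
#' @export
default_nutrient_panel <- function() {
  units <- c(
    energy = "kcal", protein = "g", carbohydrate = "g", total_fat = "g",
    saturated_fat = "g", vitamin_a = "ug_rae", vitamin_c = "mg",
    vitamin_d = "ug", vitamin_e = "mg", thiamin = "mg", riboflavin = "mg",
    niacin = "mg", vitamin_b6 = "mg", folate = "ug_dfe", vitamin_b12 = "ug",
    calcium = "mg", iron = "mg", magnesium = "mg", sodium = "mg", zinc = "mg",
    fiber = "g", epa = "g", dha = "g", alpha_linolenic_acid = "g",
    vitamin_k = "ug", choline = "mg", potassium = "mg", alpha_carotene = "ug",
    beta_carotene = "ug", beta_cryptoxanthin = "ug", lutein_zeaxanthin = "ug",
    lycopene = "ug"
  )
  nutrient_panel(names(units), units,
                 reverse = c("sodium", "saturated_fat"))
}

#' Dish taxonomy
#'
#' The shipped taxonomy of 17 main-dish categories and 6 egg-dish categories
#' used to classify foods reported at breakfast, lunch and dinner. Mapping raw
#' food codes onto these categories is the user's responsibility (a
#' `dish_category` column on the recall table); the names here are the default
#' vocabulary.
#'
#' @return Character vector of category names.
#' @export
main_dish_categories <- function() {
  c("beef_dishes", "pork_dishes", "bacon", "poultry_dishes",
    "other_meat_dishes", "seafood_dishes", "sandwiches", "sausages", "soups",
    "breads", "sweet_baked_goods", "pancakes_waffles", "oatmeal",
    "breakfast_cereal", "pasta", "mexican_dishes", "pizzas_calzones")
}

#' @rdname main_dish_categories
#' @export
egg_dish_categories <- function() {
  c("whole_eggs", "scrambled_eggs_omelets", "egg_sandwiches", "egg_soups",
    "frozen_egg_dishes", "quiches")
}

#' Intake recommendations
#'
#' A recommendation table has one row per nutrient x sex x age band with the
#' rule deciding what "not meeting" means:
#' \describe{
#'   \item{`EAR_below`}{usual intake strictly below the threshold
#'     (Estimated Average Requirement cut-point method).}
#'   \item{`UL_above`}{usual intake strictly above the threshold
#'     (Tolerable Upper Intake Level, e.g. sodium).}
#'   \item{`PCT_ENERGY_above`}{the nutrient's share of usual energy intake
#'     strictly above the threshold, in percent (e.g. saturated fat under the
#'     Dietary Guidelines' 10%-of-energy line).}
#' }
#' `default_recommendations()` ships adult (19+ y) thresholds transcribed from
#' the Institute of Medicine Dietary Reference Intakes and the 2015-2020
#' Dietary Guidelines; rows use `sex = "all"` where the threshold does not
#' differ by sex. Users may edit or replace the table freely.
#'
#' @return A tibble with columns `nutrient`, `rule`, `sex` (`"male"`,
#'   `"female"` or `"all"`), `age_min`, `age_max`, `threshold`.
#' @export
default_recommendations <- function() {
  r <- function(nutrient, rule, sex, age_min, age_max, threshold) {
    tibble(nutrient = nutrient, rule = rule, sex = sex,
           age_min = age_min, age_max = age_max, threshold = threshold)
  }
  bind_rows(
    r("vitamin_a", "EAR_below", "male", 19, Inf, 625),
    r("vitamin_a", "EAR_below", "female", 19, Inf, 500),
    r("vitamin_c", "EAR_below", "male", 19, Inf, 75),
    r("vitamin_c", "EAR_below", "female", 19, Inf, 60),
    r("vitamin_d", "EAR_below", "all", 19, Inf, 10),
    r("vitamin_e", "EAR_below", "all", 19, Inf, 12),
    r("thiamin", "EAR_below", "male", 19, Inf, 1.0),
    r("thiamin", "EAR_below", "female", 19, Inf, 0.9),
    r("riboflavin", "EAR_below", "male", 19, Inf, 1.1),
    r("riboflavin", "EAR_below", "female", 19, Inf, 0.9),
    r("niacin", "EAR_below", "male", 19, Inf, 12),
    r("niacin", "EAR_below", "female", 19, Inf, 11),
    r("vitamin_b6", "EAR_below", "male", 19, 50, 1.1),
    r("vitamin_b6", "EAR_below", "female", 19, 50, 1.0),
    r("vitamin_b6", "EAR_below", "male", 51, Inf, 1.4),
    r("vitamin_b6", "EAR_below", "female", 51, Inf, 1.3),
    r("folate", "EAR_below", "all", 19, Inf, 320),
    r("vitamin_b12", "EAR_below", "all", 19, Inf, 2.0),
    r("calcium", "EAR_below", "all", 19, 50, 800),
    r("calcium", "EAR_below", "male", 51, 70, 800),
    r("calcium", "EAR_below", "female", 51, 70, 1000),
    r("calcium", "EAR_below", "all", 71, Inf, 1000),
    r("iron", "EAR_below", "male", 19, Inf, 6),
    r("iron", "EAR_below", "female", 19, 50, 8.1),
    r("iron", "EAR_below", "female", 51, Inf, 5),
    r("magnesium", "EAR_below", "male", 19, 30, 330),
    r("magnesium", "EAR_below", "female", 19, 30, 255),
    r("magnesium", "EAR_below", "male", 31, Inf, 350),
    r("magnesium", "EAR_below", "female", 31, Inf, 265),
    r("zinc", "EAR_below", "male", 19, Inf, 9.4),
    r("zinc", "EAR_below", "female", 19, Inf, 6.8),
    r("sodium", "UL_above", "all", 19, Inf, 2300),
    r("saturated_fat", "PCT_ENERGY_above", "all", 19, Inf, 10)
  )
}

validate_recommendations <- function(rec) {
  needed <- c("nutrient", "rule", "sex", "age_min", "age_max", "threshold")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) {
    abort(paste0("recommendation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_rule <- setdiff(unique(rec$rule),
                      c("EAR_below", "UL_above", "PCT_ENERGY_above"))
  if (length(bad_rule)) {
    abort(paste0("unknown recommendation rule(s): ",
                 paste(bad_rule, collapse = ", ")))
  }
  if (any(rec$threshold <= 0)) abort("recommendation thresholds must be > 0.")
  multi <- rec |>
    distinct(.data$nutrient, .data$rule) |>
    dplyr::count(.data$nutrient) |>
    filter(.data$n > 1)
  if (nrow(multi)) {
    abort(paste0("nutrient with more than one rule: ",
                 paste(multi$nutrient, collapse = ", ")))
  }
  invisible(rec)
}

#' Read and write configuration tables as YAML
#'
#' Nutrient panels and recommendation tables are serialized to YAML so they
#' can be edited by hand and versioned alongside an analysis.
#'
#' @param panel A [nutrient_panel()].
#' @param rec A recommendation table (see [default_recommendations()]).
#' @param path File path.
#' @return `read_panel()` returns a [nutrient_panel()];
#'   `read_recommendations()` returns a recommendation tibble. The writers
#'   return their input invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "nutrient_panel"))
  yaml::write_yaml(
    list(nutrients = as.list(panel$units), reverse = panel$reverse),
    path
  )
  invisible(panel)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- yaml::read_yaml(path)
  units <- unlist(x$nutrients)
  nutrient_panel(names(units), units,
                 reverse = as.character(unlist(x$reverse)))
}

#' @rdname write_panel
#' @export
write_recommendations <- function(rec, path) {
  validate_recommendations(rec)
  yaml::write_yaml(
    purrr::pmap(rec, \(...) {
      row <- list(...)
      row$age_max <- if (is.infinite(row$age_max)) "Inf" else row$age_max
      row
    }),
    path
  )
  invisible(rec)
}

#' @rdname write_panel
#' @export
read_recommendations <- function(path) {
  rows <- yaml::read_yaml(path)
  rec <- purrr::map_dfr(rows, \(row) {
    row$age_max <- as.numeric(row$age_max)
    as_tibble(row)
  })
  validate_recommendations(rec)
  rec
}

# Threshold for each person under one nutrient's recommendation rows.
# Errors (naming the stratum) when a person's sex x age stratum has no row.
lookup_thresholds <- function(rec, persons) {
  stopifnot(nrow(rec) > 0)
  out <- rep(NA_real_, nrow(persons))
  for (i in seq_len(nrow(rec))) {
    hit <- (rec$sex[i] == "all" | persons$sex == rec$sex[i]) &
      persons$age >= rec$age_min[i] & persons$age <= rec$age_max[i]
    out[hit & is.na(out)] <- rec$threshold[i]
  }
  if (anyNA(out)) {
    j <- which(is.na(out))[1]
    abort(paste0(
      "no ", rec$nutrient[1], " threshold for stratum sex=", persons$sex[j],
      ", age=", persons$age[j]
    ))
  }
  out
}
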