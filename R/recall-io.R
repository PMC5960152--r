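#' Recall and person tables
#'
#' The package's canonical data model is two tibbles.
#'
#' A *recall table* has one row per food eaten by one person on one recall day
#' at one eating occasion, with columns `person_id`, `day` (1 or 2), `weekday`
#' (logical), `occasion` (`"breakfast"`, `"lunch"`, `"dinner"` or `"other"`),
#' `dish_category`, `dish_kind` (`"main"`, `"egg"` or `"other"`), `grams`
#' (> 0) and one column per nutrient holding the food's total nutrient amount
#' (per-gram density times grams, already applied). An optional `food_code`
#' column identifies distinct foods within a category.
#'
#' A *person table* has one row per respondent: `person_id`, `group` (one of
#' `"snap"`, `"wic"`, `"fi_nonpart"`, `"fs_nonpart"`), `age`, `sex`, any
#' categorical covariates, a positive survey `weight`, and optional balanced
#' repeated replication weights `repw_1` ... `repw_R`.
#'
#' `validate_recalls()`/`validate_persons()` check the invariants and fail
#' with the offending column or row; the readers validate after parsing, and
#' writing then reading a table is lossless (readr serializes doubles with
#' round-trip precision).
#'
#' @param recalls,persons Tibbles as described above.
#' @param panel A [nutrient_panel()] naming the expected nutrient columns.
#' @param path File path of a comma-separated text file with a header row.
#' @name recall_tables
NULL

occasion_levels <- function() c("breakfast", "lunch", "dinner", "other")
dish_kinds <- function() c("main", "egg", "other")
group_levels <- function() c("snap", "wic", "fi_nonpart", "fs_nonpart")

#' @rdname recall_tables
#' @return `validate_recalls()` and `validate_persons()` return their input
#'   invisibly.
#' @export
validate_recalls <- function(recalls, panel) {
  stopifnot(inherits(panel, "nutrient_panel"))
  needed <- c("person_id", "day", "weekday", "occasion", "dish_category",
              "dish_kind", "grams", panel$nutrients)
  missing <- setdiff(needed, names(recalls))
  if (length(missing)) {
    abort(paste0("recall table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!(recalls$day %in% c(1L, 2L)))
  if (length(bad)) {
    abort(paste0("`day` must be 1 or 2 (first offending row: ", bad[1], ")."))
  }
  bad <- which(!(recalls$occasion %in% occasion_levels()))
  if (length(bad)) {
    abort(paste0("unknown occasion in row ", bad[1], ": ",
                 recalls$occasion[bad[1]]))
  }
  bad <- which(!(recalls$dish_kind %in% dish_kinds()))
  if (length(bad)) {
    abort(paste0("unknown dish_kind in row ", bad[1], ": ",
                 recalls$dish_kind[bad[1]]))
  }
  bad <- which(!is.finite(recalls$grams) | recalls$grams <= 0)
  if (length(bad)) {
    abort(paste0("`grams` must be > 0; violated in row ", bad[1], "."))
  }
  for (nut in panel$nutrients) {
    bad <- which(!is.finite(recalls[[nut]]) | recalls[[nut]] < 0)
    if (length(bad)) {
      abort(paste0("nutrient `", nut, "` must be >= 0; violated in row ",
                   bad[1], "."))
    }
  }
  invisible(recalls)
}

#' @rdname recall_tables
#' @export
validate_persons <- function(persons) {
  needed <- c("person_id", "group", "weight")
  missing <- setdiff(needed, names(persons))
  if (length(missing)) {
    abort(paste0("person table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(persons$person_id)) {
    abort("`person_id` must be unique in the person table.")
  }
  bad <- which(!(persons$group %in% group_levels()))
  if (length(bad)) {
    abort(paste0("unknown group in row ", bad[1], ": ", persons$group[bad[1]]))
  }
  bad <- which(!is.finite(persons$weight) | persons$weight <= 0)
  if (length(bad)) {
    abort(paste0("`weight` must be > 0; violated in row ", bad[1], "."))
  }
  rep_cols <- replicate_weight_cols(persons)
  for (col in rep_cols) {
    if (any(persons[[col]] < 0)) {
      abort(paste0("replicate weight `", col, "` has negative entries."))
    }
  }
  invisible(persons)
}

replicate_weight_cols <- function(persons) {
  grep("^repw_[0-9]+$", names(persons), value = TRUE)
}

#' @rdname recall_tables
#' @return `read_recalls()` and `read_persons()` return validated tibbles;
#'   `write_recalls()` and `write_persons()` return their input invisibly.
#' @export
read_recalls <- function(path, panel) {
  recalls <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("weekday" %in% names(recalls)) {
    recalls$weekday <- as.logical(recalls$weekday)
  }
  if ("day" %in% names(recalls)) recalls$day <- as.integer(recalls$day)
  validate_recalls(recalls, panel)
}

#' @rdname recall_tables
#' @export
write_recalls <- function(recalls, path) {
  readr::write_csv(recalls, path, progress = FALSE)
  invisible(recalls)
}

#' @rdname recall_tables
#' @export
read_persons <- function(path) {
  persons <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_persons(persons)
}

#' @rdname recall_tables
#' @export
write_persons <- function(persons, path) {
  readr::write_csv(persons, path, progress = FALSE)
  invisible(persons)
}

#' Classify respondents into study groups
#'
#' Assigns each respondent to one of four mutually exclusive groups from their
#' food-assistance participation and food-security status. WIC participation
#' dominates SNAP (a respondent reporting both is a WIC participant);
#' non-participants with low or very low food security are food insecure
#' non-participants, and non-participants with marginal or full security are
#' food secure non-participants.
#'
#' @param snap,wic Logical vectors: currently participating in SNAP / WIC.
#' @param food_security Character vector with levels `"full"`, `"marginal"`,
#'   `"low"`, `"very_low"`.
#' @return Character vector with values `"snap"`, `"wic"`, `"fi_nonpart"` or
#'   `"fs_nonpart"`.
#' @examples
#' assign_group(snap = TRUE, wic = TRUE, food_security = "low")    # "wic"
#' assign_group(snap = FALSE, wic = FALSE, food_security = "low")  # "fi_nonpart"
#' @export
assign_group <- function(snap, wic, food_security) {
  n <- max(length(snap), length(wic), length(food_security))
  snap <- rep_len(as.logical(snap), n)
  wic <- rep_len(as.logical(wic), n)
  food_security <- rep_len(as.character(food_security), n)
  bad <- setdiff(unique(food_security), c("full", "marginal", "low", "very_low"))
  if (length(bad)) {
    abort(paste0("unknown food security level(s): ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::case_when(
    wic ~ "wic",
    snap ~ "snap",
    food_security %in% c("low", "very_low") ~ "fi_nonpart",
    TRUE ~ "fs_nonpart"
  )
}
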