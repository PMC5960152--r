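#' Percent of individuals consuming each dish
#'
#' Tabulates, per group x occasion x kind, the percent of individuals who
#' reported a dish category at least once over their recalls. A person counts
#' at most once per category regardless of how many records they have, so the
#' percentages over categories can exceed 100 when summed. Ranking is by
#' unweighted person counts by default; `weighted = TRUE` uses survey weights.
#'
#' @param recalls Recall table.
#' @param persons Person table (defines group membership and denominators).
#' @param occasions,kinds Occasions and dish kinds to tabulate.
#' @param groups Groups to include; defaults to all groups present.
#' @param weighted Use survey weights for the percentages.
#' @return Tibble with columns `group`, `occasion`, `kind`, `category`,
#'   `n_persons`, `pct`.
#' @export
consumption_frequency <- function(recalls, persons,
                                  occasions = c("breakfast", "lunch", "dinner"),
                                  kinds = c("main", "egg"),
                                  groups = NULL,
                                  weighted = FALSE) {
  validate_persons(persons)
  groups <- groups %||% unique(persons$group)
  pop <- persons |> filter(.data$group %in% groups)
  if (nrow(pop) == 0) abort("no persons in the requested group(s).")
  denom <- pop |>
    group_by(.data$group) |>
    summarise(n_group = n(), w_group = sum(.data$weight), .groups = "drop")
  eaten <- recalls |>
    inner_join(pop |> select("person_id", "group", "weight"),
               by = "person_id") |>
    filter(.data$occasion %in% occasions, .data$dish_kind %in% kinds) |>
    distinct(.data$group, .data$occasion, .data$dish_kind,
             .data$dish_category, .data$person_id, .data$weight) |>
    group_by(.data$group, .data$occasion,
             kind = .data$dish_kind, category = .data$dish_category) |>
    summarise(n_persons = n(), w_persons = sum(.data$weight),
              .groups = "drop") |>
    left_join(denom, by = "group")
  eaten |>
    mutate(pct = if (weighted) 100 * .data$w_persons / .data$w_group
           else 100 * .data$n_persons / .data$n_group) |>
    select("group", "occasion", "kind", "category", "n_persons", "pct") |>
    arrange(.data$group, .data$occasion, .data$kind,
            dplyr::desc(.data$pct), .data$category)
}

#' Most commonly consumed dish
#'
#' Picks the category with the highest percent of individuals from a
#' frequency table, within each group x occasion x kind; ties are broken by
#' lexicographic category name so the choice is deterministic.
#'
#' @param freq Frequency table from [consumption_frequency()].
#' @return One row per group x occasion x kind with the winning `category`.
#' @export
select_most_common <- function(freq) {
  if (nrow(freq) == 0) abort("frequency table is empty.")
  freq |>
    group_by(.data$group, .data$occasion, .data$kind) |>
    arrange(dplyr::desc(.data$pct), .data$category, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
}

#' Composite per-gram nutrient profile of a dish category
#'
#' Averages the per-gram nutrient content (`amount / grams`) over the
#' distinct foods observed in a category, unweighted. A food is a distinct
#' `food_code` when the recall table carries that column, otherwise each
#' record counts as a food (with per-code averaging applied first when codes
#' are present).
#'
#' @param recalls Recall table.
#' @param category Dish category name.
#' @param panel [nutrient_panel()] naming the nutrient columns.
#' @return Object of class `dish_profile`: list with `category`, `kind`,
#'   `density` (named per-gram vector) and `n_foods`.
#' @export
composite_profile <- function(recalls, category, panel) {
  rows <- recalls |> filter(.data$dish_category == category)
  if (nrow(rows) == 0) {
    abort(paste0("no foods found in category `", category, "`."))
  }
  dens <- as.matrix(rows[panel$nutrients]) / rows$grams
  if ("food_code" %in% names(rows)) {
    dens <- rowsum(dens, rows$food_code) /
      as.vector(table(rows$food_code)[sort(unique(rows$food_code))])
  }
  structure(
    list(category = category,
         kind = rows$dish_kind[1],
         density = colMeans(dens),
         n_foods = nrow(dens)),
    class = "dish_profile"
  )
}

#' @export
print.dish_profile <- function(x, ...) {
  cat("<dish_profile> ", x$category, " (", x$kind, "), averaged over ",
      x$n_foods, " food(s)\n", sep = "")
  print(round(x$density, 6))
  invisible(x)
}

#' Build a substitution plan
#'
#' For each group, identifies the most commonly consumed main dish and the
#' most commonly consumed egg dish at the given occasion; the plan replaces
#' the former with the latter. The constructor refuses the degenerate case in
#' which the most common main dish *is* an egg-dish category.
#'
#' @param recalls,persons Recall and person tables.
#' @param occasion One of `"breakfast"`, `"lunch"`, `"dinner"`.
#' @param basis `"gram"` (replacement keeps the record's gram weight) or
#'   `"calorie"` (replacement keeps the record's energy).
#' @param weighted Rank dishes by survey-weighted percentages.
#' @return Tibble of class `substitution_plan` with columns `group`,
#'   `occasion`, `source_category`, `replacement_category`, `basis`.
#' @export
substitution_plan <- function(recalls, persons, occasion,
                              basis = c("gram", "calorie"),
                              weighted = FALSE) {
  basis <- match.arg(basis)
  if (!occasion %in% c("breakfast", "lunch", "dinner")) {
    abort("substitution occasion must be breakfast, lunch or dinner.")
  }
  freq <- consumption_frequency(recalls, persons, occasions = occasion,
                                kinds = c("main", "egg"), weighted = weighted)
  top <- select_most_common(freq)
  plan <- top |>
    tidyr::pivot_wider(id_cols = c("group", "occasion"),
                       names_from = "kind", values_from = "category")
  if (!all(c("main", "egg") %in% names(plan))) {
    abort(paste0("no main or egg dish reported at ", occasion,
                 "; cannot build a plan."))
  }
  plan <- plan |>
    rename(source_category = "main", replacement_category = "egg")
  if (anyNA(plan$source_category) || anyNA(plan$replacement_category)) {
    abort(paste0("no main or egg dish reported at ", occasion,
                 " for some group; cannot build a plan."))
  }
  bad <- plan$source_category == plan$replacement_category
  if (any(bad)) {
    abort(paste0("most common main dish equals the egg dish (",
                 plan$source_category[bad][1], "); refusing the plan."))
  }
  plan$basis <- basis
  class(plan) <- c("substitution_plan", class(plan))
  plan
}

#' Apply a dish substitution to recall records
#'
#' For every record of a group's source category at the plan's occasion, the
#' nutrient vector is replaced by the replacement dish's composite per-gram
#' profile times the record's grams (gram basis), or times adjusted grams
#' `grams * source_energy_density / replacement_energy_density` (calorie
#' basis, which preserves the record's energy). Substituted records are
#' relabeled to the replacement category and kind, which makes the operation
#' idempotent and auditable; all other records are untouched.
#'
#' @param recalls Recall table.
#' @param persons Person table (for group membership).
#' @param plan [substitution_plan()].
#' @param profiles Named list of `dish_profile`s keyed by replacement
#'   category; defaults to composites computed from `recalls`.
#' @param panel [nutrient_panel()].
#' @param energy_nutrient Energy column used by the calorie basis.
#' @return The modified recall table (same row order).
#' @export
apply_substitution <- function(recalls, persons, plan, panel,
                               profiles = NULL,
                               energy_nutrient = "energy") {
  stopifnot(inherits(plan, "substitution_plan"))
  validate_recalls(recalls, panel)
  if (is.null(profiles)) {
    profiles <- purrr::map(
      setNames(unique(plan$replacement_category),
               unique(plan$replacement_category)),
      \(cat) composite_profile(recalls, cat, panel)
    )
  }
  person_group <- setNames(persons$group, persons$person_id)
  out <- recalls
  for (i in seq_len(nrow(plan))) {
    src <- plan$source_category[i]
    rep_cat <- plan$replacement_category[i]
    prof <- profiles[[rep_cat]]
    if (is.null(prof)) {
      abort(paste0("no profile supplied for replacement category `",
                   rep_cat, "`."))
    }
    dens <- prof$density[panel$nutrients]
    idx <- which(
      out$dish_category == src &
        out$occasion == plan$occasion[i] &
        person_group[out$person_id] == plan$group[i]
    )
    if (length(idx) == 0) next
    g <- out$grams[idx]
    if (plan$basis[i] == "calorie") {
      src_energy <- recalls[[energy_nutrient]][idx] / g
      if (dens[[energy_nutrient]] <= 0) {
        abort("replacement energy density is 0; calorie basis undefined.")
      }
      g <- g * src_energy / dens[[energy_nutrient]]
      out$grams[idx] <- g
    }
    nut <- outer(g, dens)
    out[idx, panel$nutrients] <- as_tibble(nut)
    out$dish_category[idx] <- rep_cat
    out$dish_kind[idx] <- prof$kind
  }
  out
}

#' Daily nutrient totals
#'
#' Sums nutrient amounts over all records (all occasions, including snacks)
#' per person-day. By default only person-days present in `recalls` appear;
#' pass `person_days` (the universe of completed recall days, e.g.
#' `person_id` x `day`) to emit an all-zero row for a completed day on which
#' no food was recorded.
#'
#' @param recalls Recall table.
#' @param panel [nutrient_panel()].
#' @param person_days Optional tibble with columns `person_id`, `day` and
#'   optionally `weekday` listing every completed recall day.
#' @return Tibble with `person_id`, `day`, `weekday` and one total column per
#'   nutrient (amount/day).
#' @export
daily_totals <- function(recalls, panel, person_days = NULL) {
  totals <- recalls |>
    group_by(.data$person_id, .data$day) |>
    summarise(
      weekday = first(.data$weekday),
      across(all_of(panel$nutrients), sum),
      .groups = "drop"
    )
  if (!is.null(person_days)) {
    if (!("weekday" %in% names(person_days))) person_days$weekday <- NA
    empty <- person_days |>
      dplyr::anti_join(totals, by = c("person_id", "day")) |>
      select("person_id", "day", "weekday")
    if (nrow(empty)) {
      zeros <- as_tibble(matrix(0, nrow(empty), length(panel$nutrients),
                                dimnames = list(NULL, panel$nutrients)))
      totals <- bind_rows(totals, bind_cols(empty, zeros))
    }
  }
  totals |> arrange(.data$person_id, .data$day)
}
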