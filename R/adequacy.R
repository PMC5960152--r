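#' Prevalence of not meeting a recommendation
#'
#' Applies a recommendation rule to every usual-intake draw against the
#' draw's person-specific (sex and age band) threshold and reports the
#' survey-weighted percent of draws failing it, per group: the EAR cut-point
#' method for `EAR_below`, exceedance for `UL_above`, and the nutrient's
#' share of usual energy for `PCT_ENERGY_above` (which requires energy draws
#' jointly simulated with the nutrient, see [simulate_usual_joint()]).
#' Inequalities are strict.
#'
#' @param draws `usual_intake_draws` for the nutrient under the rule.
#' @param rec Recommendation table rows for that single nutrient (see
#'   [default_recommendations()]).
#' @param persons Person table.
#' @param groups Groups to estimate; default all present.
#' @param energy_draws `usual_intake_draws` for energy from the same joint
#'   draw (percent-of-energy rule only).
#' @param energy_kcal_per_g kcal per gram of the nutrient for the
#'   percent-of-energy rule (default 9, the fat factor).
#' @param se Attach BRR standard errors.
#' @param fay Fay coefficient of the replicate weights.
#' @return Tibble with columns `nutrient`, `rule`, `group`, `estimate`
#'   (percent in `[0, 100]`), `se`, `n`.
#' @export
prevalence_not_meeting <- function(draws, rec, persons, groups = NULL,
                                   energy_draws = NULL,
                                   energy_kcal_per_g = 9,
                                   se = FALSE, fay = 0) {
  validate_recommendations(rec)
  nutrient <- unique(rec$nutrient)
  if (length(nutrient) != 1) abort("`rec` must describe a single nutrient.")
  rule <- rec$rule[1]
  if (rule == "PCT_ENERGY_above" && is.null(energy_draws)) {
    abort("the percent-of-energy rule needs jointly simulated energy draws.")
  }
  pm <- prevalence_person_fail(draws, rec, persons, energy_draws,
                               energy_kcal_per_g)
  groups <- groups %||% unique(persons$group)
  purrr::map_dfr(groups, function(g) {
    pg <- persons |> filter(.data$group == g) |>
      inner_join(pm, by = "person_id")
    if (nrow(pg) == 0) abort(paste0("group `", g, "` has no persons."))
    est <- 100 * weighted.mean(pg$pm, pg$weight)
    se_val <- NA_real_
    if (se) {
      se_val <- brr_se(function(w) 100 * weighted.mean(pg$pm, w), pg,
                       fay = fay)
    }
    tibble(nutrient = nutrient, rule = rule, group = g,
           estimate = est, se = se_val, n = nrow(pg))
  })
}

# Per-person mean failure indicator under a recommendation rule: the share
# of a person's draws that fail the rule. Shared by the prevalence estimator
# and by paired baseline-vs-modeled tests.
prevalence_person_fail <- function(draws, rec, persons, energy_draws = NULL,
                                   energy_kcal_per_g = 9) {
  rule <- rec$rule[1]
  x <- draws$usual
  if (rule == "PCT_ENERGY_above") {
    if (is.null(energy_draws) || nrow(energy_draws) != nrow(draws)) {
      abort("energy draws must align with the nutrient draws.")
    }
    x <- 100 * x * energy_kcal_per_g / energy_draws$usual
  }
  thr_tbl <- persons |> mutate(..thr = lookup_thresholds(rec, persons))
  dat <- tibble(person_id = draws$person_id, x = x) |>
    left_join(thr_tbl |> select("person_id", "..thr"), by = "person_id")
  dat$fail <- switch(rule,
    EAR_below = dat$x < dat$..thr,
    UL_above = dat$x > dat$..thr,
    PCT_ENERGY_above = dat$x > dat$..thr
  )
  dat |>
    group_by(.data$person_id) |>
    summarise(pm = mean(.data$fail), .groups = "drop")
}

#' Percent change from baseline
#'
#' @param baseline,modeled Numeric vectors, or estimate tables with
#'   `estimate` columns matched by position.
#' @return `100 * (modeled - baseline) / baseline`; errors when a baseline
#'   value is zero (the change is undefined).
#' @examples
#' percent_change(200, 220)  # +10
#' @export
percent_change <- function(baseline, modeled) {
  b <- if (is.data.frame(baseline)) baseline$estimate else baseline
  m <- if (is.data.frame(modeled)) modeled$estimate else modeled
  if (any(b == 0)) {
    abort("baseline estimate is 0; percent change is undefined.")
  }
  100 * (m - b) / b
}

#' Total nutrient index
#'
#' A scalar summary of how intake of all nutrients changed collectively
#' between baseline and a modeled diet. Nutrients to limit (the `reverse`
#' set) enter with their percent change sign-flipped so that a larger index
#' always reads as more favorable. The default formula is, verbatim,
#' \deqn{TNI = \frac{\sum_{i=1}^N C_i / se_i}{\sum_{i=1}^N se_i},}
#' where `C_i` is nutrient `i`'s percent change and `se_i` its standard
#' error, so more precisely estimated nutrients carry more weight. Note the
#' denominator: the formula is not invariant to rescaling the standard
#' errors (doubling every `se` divides the index by 4); the conventional
#' inverse-variance weighted mean (denominator `sum(1/se_i)`) is available
#' as `mode = "normalized"` but is never the default.
#'
#' @param changes Data frame with columns `nutrient`, `change` (percent) and
#'   `se`, or a numeric vector of changes named by nutrient.
#' @param se Standard errors (same length), when `changes` is a vector. All
#'   must be strictly positive.
#' @param reverse Character vector of reverse-scored nutrients.
#' @param mode `"printed"` (default) or `"normalized"`.
#' @return Object of class `tni`: list with `index`, `table` (per-nutrient
#'   signed changes and weights), `n_nutrients`, `mode`.
#' @examples
#' total_nutrient_index(c(a = 10, b = 20), se = c(1, 1))$index  # 15
#' @export
total_nutrient_index <- function(changes, se = NULL, reverse = character(),
                                 mode = c("printed", "normalized")) {
  mode <- match.arg(mode)
  if (is.data.frame(changes)) {
    tab <- as_tibble(changes)
    stopifnot(all(c("nutrient", "change", "se") %in% names(tab)))
  } else {
    if (is.null(se)) abort("`se` is required when `changes` is a vector.")
    if (length(se) != length(changes)) {
      abort("`changes` and `se` must have the same length.")
    }
    nm <- names(changes) %||% paste0("nutrient_", seq_along(changes))
    tab <- tibble(nutrient = nm, change = as.numeric(changes),
                  se = as.numeric(se))
  }
  if (nrow(tab) < 1) abort("at least one nutrient is required.")
  if (any(!is.finite(tab$se) | tab$se <= 0)) {
    abort("all standard errors must be finite and > 0.")
  }
  tab <- tab |>
    mutate(
      reverse = .data$nutrient %in% reverse,
      signed_change = ifelse(.data$reverse, -.data$change, .data$change)
    )
  index <- switch(mode,
    printed = sum(tab$signed_change / tab$se) / sum(tab$se),
    normalized = sum(tab$signed_change / tab$se) / sum(1 / tab$se)
  )
  structure(
    list(index = index, table = tab, n_nutrients = nrow(tab), mode = mode),
    class = "tni"
  )
}

#' @export
print.tni <- function(x, ...) {
  cat("<total nutrient index> ", format(x$index, digits = 4),
      " (", x$mode, " formula, ", x$n_nutrients, " nutrients)\n", sep = "")
  invisible(x)
}

#' Leave-largest-out sensitivity of the total nutrient index
#'
#' Ranks nutrients by the magnitude of their percent change (ties broken by
#' lexicographic name) and recomputes the index with the top `1..k_max`
#' removed, reporting the full index as the `k = 0` reference row.
#'
#' @inheritParams total_nutrient_index
#' @param k_max Largest number of nutrients to remove (default all but one).
#' @return Tibble with columns `k`, `removed` (the nutrient dropped at step
#'   `k`) and `index`.
#' @export
tni_sensitivity <- function(changes, se = NULL, reverse = character(),
                            mode = c("printed", "normalized"), k_max = NULL) {
  mode <- match.arg(mode)
  full <- total_nutrient_index(changes, se, reverse, mode)
  tab <- full$table
  if (nrow(tab) < 2) abort("sensitivity analysis needs at least 2 nutrients.")
  k_max <- k_max %||% (nrow(tab) - 1)
  k_max <- min(k_max, nrow(tab) - 1)
  ranked <- tab |>
    arrange(dplyr::desc(abs(.data$change)), .data$nutrient)
  out <- tibble(k = 0L, removed = NA_character_, index = full$index)
  for (k in seq_len(k_max)) {
    keep <- ranked[-seq_len(k), ]
    idx <- total_nutrient_index(keep |> select("nutrient", "change", "se"),
                                reverse = reverse, mode = mode)$index
    out <- bind_rows(out, tibble(k = k, removed = ranked$nutrient[k],
                                 index = idx))
  }
  out
}
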