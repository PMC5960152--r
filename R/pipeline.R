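#' End-to-end substitution analysis
#'
#' Runs the whole modeling chain for one eating occasion: identify each
#' group's most commonly consumed main and egg dishes, substitute the former
#' with the latter on the chosen basis, estimate baseline and modeled usual
#' intake for every nutrient with the measurement-error model, attach
#' balanced repeated replication standard errors, compute prevalences of not
#' meeting recommendations (with a paired BRR z-test on the change), and
#' summarize the percent changes with the total nutrient index per group.
#'
#' The baseline and modeled scenarios are simulated from the *same*
#' person-effect draws (same seed), so within-person comparisons are paired;
#' the prevalence change test uses the BRR standard error of the difference
#' directly, while mean-intake contrasts are also reported with the
#' independent-z convention via [compare_estimates()].
#'
#' @param recalls Recall table.
#' @param persons Person table with replicate weights (see
#'   [simulate_replicate_weights()]).
#' @param panel [nutrient_panel()].
#' @param occasion `"breakfast"`, `"lunch"` or `"dinner"`.
#' @param recommendations Recommendation table (may cover a subset of the
#'   panel); `NULL` skips prevalence estimation.
#' @param nutrients Nutrients to model; default the whole panel.
#' @param covariates Person-table covariates to adjust for.
#' @param basis `"gram"` or `"calorie"`.
#' @param lambda_grid Box-Cox grid for [fit_amount_model()].
#' @param n_mc Monte-Carlo draws per person.
#' @param seed Integer seed shared by both scenarios.
#' @param fay Fay coefficient of the replicate weights.
#' @param alpha,m Significance level and Bonferroni divisor for the tests.
#' @param energy_nutrient Energy column name (calorie basis and
#'   percent-of-energy rules).
#' @return Object of class `substitution_analysis`: list with `plan`,
#'   `estimates` (nutrient x group x scenario means with BRR SEs), `changes`
#'   (percent change per nutrient x group, with the independent z-test),
#'   `prevalence` (per rule-carrying nutrient, both scenarios, with the
#'   paired z-test on the change), and `tni` (per-group [tni] objects built
#'   from the changes and baseline SEs).
#' @export
substitution_analysis <- function(recalls, persons, panel, occasion,
                                  recommendations = NULL,
                                  nutrients = NULL,
                                  covariates = character(),
                                  basis = c("gram", "calorie"),
                                  lambda_grid = seq(0, 1, by = 0.1),
                                  n_mc = 100, seed = 1, fay = 0,
                                  alpha = 0.05, m = 3,
                                  energy_nutrient = "energy") {
  basis <- match.arg(basis)
  validate_recalls(recalls, panel)
  validate_persons(persons)
  nutrients <- nutrients %||% panel$nutrients
  if (!is.null(recommendations)) validate_recommendations(recommendations)

  plan <- substitution_plan(recalls, persons, occasion, basis = basis)
  modeled <- apply_substitution(recalls, persons, plan, panel,
                                energy_nutrient = energy_nutrient)
  person_days <- recalls |> distinct(.data$person_id, .data$day, .data$weekday)
  totals0 <- daily_totals(recalls, panel, person_days)
  totals1 <- daily_totals(modeled, panel, person_days)

  fit_all <- function(totals) {
    purrr::map(
      setNames(nutrients, nutrients),
      \(nut) fit_usual_intake(totals, persons, nut, covariates, lambda_grid)
    )
  }
  fits0 <- fit_all(totals0)
  fits1 <- fit_all(totals1)
  draws0 <- simulate_usual_joint(fits0, persons, n_mc = n_mc, seed = seed)
  draws1 <- simulate_usual_joint(fits1, persons, n_mc = n_mc, seed = seed)

  est <- purrr::map_dfr(nutrients, function(nut) {
    bind_rows(
      group_mean(draws0[[nut]], persons, se = TRUE, fay = fay) |>
        mutate(scenario = "baseline"),
      group_mean(draws1[[nut]], persons, se = TRUE, fay = fay) |>
        mutate(scenario = "modeled")
    )
  })

  wide <- est |>
    tidyr::pivot_wider(id_cols = c("nutrient", "group"),
                       names_from = "scenario",
                       values_from = c("estimate", "se"))
  cmp <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    compare_estimates(
      list(estimate = wide$estimate_modeled[i], se = wide$se_modeled[i],
           label = "modeled"),
      list(estimate = wide$estimate_baseline[i], se = wide$se_baseline[i],
           label = "baseline"),
      alpha = alpha, m = m
    )
  })
  changes <- wide |>
    mutate(
      change = percent_change(.data$estimate_baseline,
                              .data$estimate_modeled),
      z = cmp$z, p = cmp$p, significant = cmp$significant
    )

  prevalence <- NULL
  if (!is.null(recommendations)) {
    rec_nuts <- intersect(nutrients, unique(recommendations$nutrient))
    prevalence <- purrr::map_dfr(rec_nuts, function(nut) {
      rec <- recommendations |> filter(.data$nutrient == nut)
      e0 <- if (rec$rule[1] == "PCT_ENERGY_above") draws0[[energy_nutrient]]
      e1 <- if (rec$rule[1] == "PCT_ENERGY_above") draws1[[energy_nutrient]]
      pm0 <- prevalence_person_fail(draws0[[nut]], rec, persons, e0)
      pm1 <- prevalence_person_fail(draws1[[nut]], rec, persons, e1)
      purrr::map_dfr(unique(persons$group), function(g) {
        pg <- persons |> filter(.data$group == g) |>
          inner_join(pm0 |> rename(pm0 = "pm"), by = "person_id") |>
          inner_join(pm1 |> rename(pm1 = "pm"), by = "person_id")
        cmp <- compare_paired(
          function(w) 100 * weighted.mean(pg$pm1, w),
          function(w) 100 * weighted.mean(pg$pm0, w),
          pg, fay = fay, alpha = alpha, m = m
        )
        tibble(
          nutrient = nut, rule = rec$rule[1], group = g,
          baseline = 100 * weighted.mean(pg$pm0, pg$weight),
          modeled = 100 * weighted.mean(pg$pm1, pg$weight),
          change_pp = cmp$difference,
          z = cmp$z, p = cmp$p, significant = cmp$significant,
          n = nrow(pg)
        )
      })
    })
  }

  tni_by_group <- purrr::map(
    setNames(unique(persons$group), unique(persons$group)),
    function(g) {
      tab <- changes |>
        filter(.data$group == g) |>
        select("nutrient", "change", se = "se_baseline")
      total_nutrient_index(tab, reverse = panel$reverse)
    }
  )

  structure(
    list(plan = plan, estimates = est, changes = changes,
         prevalence = prevalence, tni = tni_by_group,
         occasion = occasion, basis = basis,
         fits_baseline = fits0, fits_modeled = fits1,
         n_mc = n_mc, seed = seed),
    class = "substitution_analysis"
  )
}

#' @export
print.substitution_analysis <- function(x, ...) {
  cat("<substitution_analysis> ", x$basis, "-basis substitution at ",
      x$occasion, "\n", sep = "")
  cat("  plan:\n")
  for (i in seq_len(nrow(x$plan))) {
    cat("    ", x$plan$group[i], ": ", x$plan$source_category[i], " -> ",
        x$plan$replacement_category[i], "\n", sep = "")
  }
  cat("  total nutrient index by group:\n")
  for (g in names(x$tni)) {
    cat(sprintf("    %s: %.4g\n", g, x$tni[[g]]$index))
  }
  if (!is.null(x$prevalence)) {
    sig <- x$prevalence |> filter(.data$significant)
    cat("  significant prevalence changes: ", nrow(sig), " of ",
        nrow(x$prevalence), "\n", sep = "")
  }
  invisible(x)
}
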