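#' Configure a synthetic two-day recall simulation
#'
#' Defines the generative model for an NHANES-like recall dataset with fully
#' known ground truth. Each dish row describes one dish category at one eating
#' occasion: on every recall day a person consumes it with probability
#' `plogis(qlogis(prob) + b_i)`, where `b_i ~ N(0, sd_logit^2)` is a
#' person-level heterogeneity offset, and when consumed the amount is
#' `exp(mean_log_grams + u_i + e_{id})` grams with a person effect
#' `u_i ~ N(0, sd_person^2)` and day-level noise `e ~ N(0, sd_day^2)`.
#' Nutrient amounts are grams times the category's per-gram density.
#'
#' @param n_persons Named integer vector of persons per group; names must be
#'   among `"snap"`, `"wic"`, `"fi_nonpart"`, `"fs_nonpart"`.
#' @param dishes Tibble with columns `category`, `kind` (`"main"`, `"egg"` or
#'   `"other"`), `occasion`, `prob` (per-day consumption probability in
#'   `[0, 1]`), `mean_log_grams`, `sd_person`, `sd_day` and optionally
#'   `sd_logit` (default 0). One row per category x occasion.
#' @param densities Tibble with a `category` column and one non-negative
#'   per-gram density column per nutrient.
#' @param panel Optional [nutrient_panel()]; defaults to one built from the
#'   density columns.
#' @param n_reps Number of balanced repeated replication weights to attach; a
#'   Hadamard-constructible multiple of 4 (see [hadamard_matrix()]).
#' @param fay Fay coefficient in `[0, 1)` for the replicate weights.
#' @param single_day_fraction Fraction of persons completing only the first
#'   recall (the survey's telephone follow-up is missed by some respondents);
#'   default 0.
#' @return An object of class `simulation_config`.
#' @seealso [simulate_population()], [simulate_recalls()],
#'   [default_simulation_config()]
#' @export
simulation_config <- function(n_persons, dishes, densities, panel = NULL,
                              n_reps = 16, fay = 0,
                              single_day_fraction = 0) {
  if (is.null(names(n_persons)) || !all(names(n_persons) %in% group_levels())) {
    abort("invalid config field `n_persons`: must be named by study groups.")
  }
  if (any(n_persons < 1)) {
    abort("invalid config field `n_persons`: counts must be >= 1.")
  }
  dishes <- as_tibble(dishes)
  if (!("sd_logit" %in% names(dishes))) dishes$sd_logit <- 0
  needed <- c("category", "kind", "occasion", "prob", "mean_log_grams",
              "sd_person", "sd_day", "sd_logit")
  missing <- setdiff(needed, names(dishes))
  if (length(missing)) {
    abort(paste0("invalid config field `dishes`: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  if (any(dishes$prob < 0 | dishes$prob > 1)) {
    abort("invalid config field `dishes$prob`: probabilities must be in [0, 1].")
  }
  for (col in c("sd_person", "sd_day", "sd_logit")) {
    if (any(dishes[[col]] < 0)) {
      abort(paste0("invalid config field `dishes$", col,
                   "`: variances must be >= 0."))
    }
  }
  if (!all(dishes$kind %in% dish_kinds())) {
    abort("invalid config field `dishes$kind`.")
  }
  if (!all(dishes$occasion %in% occasion_levels())) {
    abort("invalid config field `dishes$occasion`.")
  }
  densities <- as_tibble(densities)
  if (!("category" %in% names(densities))) {
    abort("invalid config field `densities`: needs a `category` column.")
  }
  nut_cols <- setdiff(names(densities), "category")
  if (any(as.matrix(densities[nut_cols]) < 0)) {
    abort("invalid config field `densities`: densities must be >= 0.")
  }
  if (!all(dishes$category %in% densities$category)) {
    abort("invalid config field `densities`: every dish category needs a row.")
  }
  if (is.null(panel)) panel <- nutrient_panel(nut_cols)
  if (!all(panel$nutrients %in% nut_cols)) {
    abort("invalid config field `panel`: nutrients missing from `densities`.")
  }
  if (n_reps %% 4 != 0 && !(n_reps %in% c(1, 2))) {
    abort("invalid config field `n_reps`: must be a multiple of 4.")
  }
  if (fay < 0 || fay >= 1) {
    abort("invalid config field `fay`: must be in [0, 1).")
  }
  if (single_day_fraction < 0 || single_day_fraction > 1) {
    abort("invalid config field `single_day_fraction`: must be in [0, 1].")
  }
  structure(
    list(n_persons = n_persons, dishes = dishes, densities = densities,
         panel = panel, n_reps = n_reps, fay = fay,
         single_day_fraction = single_day_fraction),
    class = "simulation_config"
  )
}

#' Default simulation conditions
#'
#' A modest four-group configuration emulating the structure of the national
#' survey the package targets: group sizes in roughly the survey's relative
#' proportions (down-scaled to desk size, with the WIC group raised enough to
#' remain estimable), a small dish library covering a main and an egg dish at
#' each named meal plus an untouched snack occasion, and a six-nutrient panel.
#' Densities are plausible per-gram values for the categories involved.
#'
#' @param n_scale Multiplier on the default group sizes.
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(n_scale = 1) {
  dishes <- tibble::tribble(
    ~category,                ~kind,   ~occasion,   ~prob, ~mean_log_grams, ~sd_person, ~sd_day, ~sd_logit,
    "breakfast_cereal",       "main",  "breakfast", 0.50,  log(60),         0.40,       0.30,    0.8,
    "scrambled_eggs_omelets", "egg",   "breakfast", 0.18,  log(120),        0.35,       0.30,    0.8,
    "sandwiches",             "main",  "lunch",     0.45,  log(220),        0.35,       0.30,    0.8,
    "scrambled_eggs_omelets", "egg",   "lunch",     0.06,  log(120),        0.35,       0.30,    0.8,
    "poultry_dishes",         "main",  "dinner",    0.40,  log(250),        0.35,       0.30,    0.8,
    "whole_eggs",             "egg",   "dinner",    0.05,  log(100),        0.35,       0.30,    0.8,
    "sweet_baked_goods",      "other", "other",     0.60,  log(80),         0.40,       0.40,    0.8
  )
  densities <- tibble::tribble(
    ~category,                ~energy, ~protein, ~vitamin_d, ~folate, ~sodium, ~saturated_fat,
    "breakfast_cereal",       3.80,    0.070,    0.033,      6.00,    5.0,     0.004,
    "scrambled_eggs_omelets", 1.66,    0.110,    0.021,      0.40,    2.9,     0.033,
    "sandwiches",             2.50,    0.110,    0.003,      0.45,    5.6,     0.022,
    "poultry_dishes",         1.90,    0.150,    0.002,      0.12,    3.6,     0.014,
    "whole_eggs",             1.43,    0.126,    0.020,      0.47,    1.4,     0.031,
    "sweet_baked_goods",      4.00,    0.050,    0.001,      0.50,    3.0,     0.025
  )
  units <- c(energy = "kcal", protein = "g", vitamin_d = "ug",
             folate = "ug_dfe", sodium = "mg", saturated_fat = "g")
  panel <- nutrient_panel(names(units), units,
                          reverse = c("sodium", "saturated_fat"))
  n <- round(n_scale * c(snap = 400, wic = 100, fi_nonpart = 360,
                         fs_nonpart = 1200))
  simulation_config(n, dishes, densities, panel = panel, n_reps = 16)
}

#' Generate a synthetic study population
#'
#' Draws persons with group labels, demographics, covariates and positive
#' survey weights. WIC participants are women of childbearing age (the
#' program's categorical eligibility); other groups are half female with ages
#' 20-80. Weights are lognormal around 1 so that no design information is
#' implied beyond mild unequal weighting.
#'
#' @param config A [simulation_config()].
#' @param seed Integer random seed; the same config and seed give an
#'   identical population.
#' @return A person table (see [validate_persons()]).
#' @export
simulate_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  groups <- rep(names(config$n_persons), config$n_persons)
  n <- length(groups)
  wic <- groups == "wic"
  age <- numeric(n)
  age[wic] <- runif(sum(wic), 20, 44)
  age[!wic] <- runif(sum(!wic), 20, 80)
  sex <- ifelse(wic, "female",
                ifelse(runif(n) < 0.5, "female", "male"))
  race_ethnicity <- sample(c("nh_white", "nh_black", "mexican_american"),
                           n, replace = TRUE, prob = c(0.6, 0.2, 0.2))
  education <- sample(c("lt_hs", "hs", "some_college", "college"),
                      n, replace = TRUE, prob = c(0.25, 0.3, 0.3, 0.15))
  weight <- exp(rnorm(n, 0, 0.25))
  persons <- tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    group = groups,
    age = round(age, 1),
    sex = sex,
    race_ethnicity = race_ethnicity,
    education = education,
    weight = weight
  )
  validate_persons(persons)
}

#' Generate two-day recall records with known ground truth
#'
#' Simulates the recall table implied by the configuration for the given
#' persons and returns it together with the ground truth the draws were built
#' from: each person's true usual intake of every nutrient (the long-run
#' expectation of their daily total), the true percent of individuals in each
#' group expected to report each dish over their recall window, and the true
#' most common dish per group x occasion x kind.
#'
#' @param persons Person table from [simulate_population()].
#' @param config The matching [simulation_config()].
#' @param seed Integer random seed.
#' @return A list with elements `recalls` (a recall table) and `truth` (class
#'   `recall_truth`: list of `usual`, `dish_prevalence`, `most_common`).
#' @export
simulate_recalls <- function(persons, config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  validate_persons(persons)
  set.seed(seed)
  dishes <- config$dishes
  n <- nrow(persons)
  D <- nrow(dishes)
  nutrients <- config$panel$nutrients

  # density matrix aligned with dish rows (D x K)
  dens <- as.matrix(config$densities[match(dishes$category,
                                           config$densities$category),
                                     nutrients, drop = FALSE])

  # person-level effects, one per person x dish row
  u <- matrix(rnorm(n * D), n, D) * rep(dishes$sd_person, each = n)
  b <- matrix(rnorm(n * D), n, D) * rep(dishes$sd_logit, each = n)
  p_pers <- plogis(sweep(b, 2, qlogis(dishes$prob), "+"))
  # qlogis(0)/qlogis(1) are -Inf/Inf; adding a finite offset keeps them exact
  p_pers[, dishes$prob == 0] <- 0
  p_pers[, dishes$prob == 1] <- 1

  n_days <- ifelse(runif(n) < config$single_day_fraction, 1L, 2L)

  day_tables <- vector("list", 2L)
  for (d in 1:2) {
    active <- n_days >= d
    weekday <- runif(n) < 5 / 7
    cons <- matrix(runif(n * D), n, D) < p_pers
    e <- matrix(rnorm(n * D), n, D) * rep(dishes$sd_day, each = n)
    grams <- exp(sweep(u + e, 2, dishes$mean_log_grams, "+"))
    hit <- which(cons & active, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    g <- grams[hit]
    tab <- tibble(
      person_id = persons$person_id[hit[, 1]],
      day = d,
      weekday = weekday[hit[, 1]],
      occasion = dishes$occasion[hit[, 2]],
      dish_category = dishes$category[hit[, 2]],
      dish_kind = dishes$kind[hit[, 2]],
      grams = g
    )
    nut <- dens[hit[, 2], , drop = FALSE] * g
    colnames(nut) <- nutrients
    day_tables[[d]] <- bind_cols(tab, as_tibble(nut))
  }
  recalls <- bind_rows(day_tables) |>
    arrange(.data$person_id, .data$day)
  recalls$day <- as.integer(recalls$day)

  # ground truth: long-run expectations under the parameters actually drawn
  usual_dish <- p_pers * exp(sweep(u, 2,
                                   dishes$mean_log_grams + dishes$sd_day^2 / 2,
                                   "+"))
  usual <- usual_dish %*% dens
  colnames(usual) <- nutrients
  usual_tbl <- bind_cols(tibble(person_id = persons$person_id),
                         as_tibble(usual))

  report_prob <- 1 - (1 - p_pers)^n_days
  prev <- tibble(
    group = rep(persons$group, times = D),
    occasion = rep(dishes$occasion, each = n),
    kind = rep(dishes$kind, each = n),
    category = rep(dishes$category, each = n),
    p = as.vector(report_prob)
  ) |>
    group_by(.data$group, .data$occasion, .data$kind, .data$category) |>
    summarise(pct = 100 * mean(.data$p), .groups = "drop")
  most_common <- prev |>
    group_by(.data$group, .data$occasion, .data$kind) |>
    arrange(dplyr::desc(.data$pct), .data$category, .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  truth <- structure(
    list(usual = usual_tbl, dish_prevalence = prev, most_common = most_common),
    class = "recall_truth"
  )
  list(recalls = validate_recalls(recalls, config$panel), truth = truth)
}

#' Attach balanced repeated replication weights
#'
#' Assigns persons to paired pseudo-strata in enumeration order (the last
#' stratum may be a singleton, whose weight is never perturbed) and builds
#' `n_reps` replicate weight columns from a Hadamard sign matrix: in replicate
#' `r`, the half-sample member selected by the stratum's Hadamard column gets
#' weight `base * (2 - fay)` and the other member gets `base * fay`. With a
#' balanced design the mean of a person's replicate weights equals their base
#' weight exactly.
#'
#' @param persons Person table.
#' @param n_reps Number of replicates; must be Hadamard-constructible (see
#'   [hadamard_matrix()]) and at least the number of strata plus one.
#' @param fay Fay coefficient in `[0, 1)`; 0 gives classic BRR (weights 0 and
#'   2 times base).
#' @return The person table with columns `repw_1` ... `repw_<n_reps>` added
#'   (existing replicate columns are replaced).
#' @export
simulate_replicate_weights <- function(persons, n_reps, fay = 0) {
  validate_persons(persons)
  if (fay < 0 || fay >= 1) abort("`fay` must be in [0, 1).")
  n <- nrow(persons)
  stratum <- (seq_len(n) - 1L) %/% 2L + 1L
  member <- (seq_len(n) - 1L) %% 2L + 1L
  n_strata <- max(stratum)
  H <- hadamard_matrix(n_reps)   # errors if not constructible
  if (n_strata > n_reps - 1) {
    abort(paste0("need n_reps >= ", n_strata + 1, " replicates for ",
                 n_strata, " paired strata; got ", n_reps, "."))
  }
  # singleton stratum: factor 1 in every replicate
  singleton <- stratum == n_strata & sum(stratum == n_strata) == 1
  fac <- matrix(1, n, n_reps)
  sel <- H[, stratum + 1L, drop = FALSE]           # n_reps x n
  up <- t(sel) == ifelse(member == 1L, 1L, -1L)    # n x n_reps
  fac[!singleton, ] <- ifelse(up[!singleton, , drop = FALSE], 2 - fay, fay)
  repw <- fac * persons$weight
  colnames(repw) <- paste0("repw_", seq_len(n_reps))
  persons <- persons |> select(-any_of(replicate_weight_cols(persons)))
  bind_cols(persons, as_tibble(repw))
}

#' True prevalence of not meeting a recommendation
#'
#' Computes, from the generator's own ground truth, the survey-weighted
#' percent of persons in each group whose *true* usual intake fails a
#' recommendation — the quantity the estimation pipeline is trying to
#' recover.
#'
#' @param truth `recall_truth` from [simulate_recalls()].
#' @param persons The matching person table.
#' @param rec Recommendation table rows (a single nutrient).
#' @param energy_nutrient Name of the energy column used by the
#'   percent-of-energy rule.
#' @param energy_kcal_per_g Energy conversion factor for the
#'   percent-of-energy rule (default 9 kcal/g, the fat factor).
#' @return Tibble with columns `group`, `nutrient`, `prevalence` (percent).
#' @export
true_prevalence <- function(truth, persons, rec,
                            energy_nutrient = "energy",
                            energy_kcal_per_g = 9) {
  stopifnot(inherits(truth, "recall_truth"))
  validate_recommendations(rec)
  nutrient <- unique(rec$nutrient)
  if (length(nutrient) != 1) abort("`rec` must describe a single nutrient.")
  rule <- rec$rule[1]
  dat <- persons |>
    inner_join(truth$usual, by = "person_id")
  thr <- lookup_thresholds(rec, dat)
  x <- dat[[nutrient]]
  fail <- switch(rule,
    EAR_below = x < thr,
    UL_above = x > thr,
    PCT_ENERGY_above =
      100 * x * energy_kcal_per_g / dat[[energy_nutrient]] > thr
  )
  dat |>
    mutate(fail = fail) |>
    group_by(.data$group) |>
    summarise(
      nutrient = nutrient,
      prevalence = 100 * weighted.mean(.data$fail, .data$weight),
      .groups = "drop"
    )
}

#' Write and read ground truth
#'
#' Serializes a `recall_truth` object to a structured YAML file (intended for
#' desk-scale simulations).
#'
#' @param truth `recall_truth` from [simulate_recalls()].
#' @param path File path.
#' @return `read_ground_truth()` returns a `recall_truth`; the writer returns
#'   its input invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "recall_truth"))
  yaml::write_yaml(
    list(
      usual = lapply(seq_len(nrow(truth$usual)),
                     function(i) as.list(truth$usual[i, ])),
      dish_prevalence = lapply(seq_len(nrow(truth$dish_prevalence)),
                               function(i) as.list(truth$dish_prevalence[i, ])),
      most_common = lapply(seq_len(nrow(truth$most_common)),
                           function(i) as.list(truth$most_common[i, ]))
    ),
    path,
    precision = 15
  )
  invisible(truth)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- yaml::read_yaml(path)
  structure(
    list(
      usual = purrr::map_dfr(x$usual, as_tibble),
      dish_prevalence = purrr::map_dfr(x$dish_prevalence, as_tibble),
      most_common = purrr::map_dfr(x$most_common, as_tibble)
    ),
    class = "recall_truth"
  )
}

#' A designed vitamin-D substitution scenario
#'
#' Builds a single-group configuration in which everyone eats a fortified
#' breakfast-cereal main dish at lunch (lognormal grams) plus a small fixed
#' egg side, vitamin D comes only from those two dishes, and the egg dish's
#' vitamin-D density is solved in closed form so that replacing the cereal
#' with the egg dish moves the true EAR-below prevalence down by exactly
#' `shift_pp` percentage points.
#'
#' With cereal grams `exp(mu_g + u + e)`, `u ~ N(0, sd_person^2)`,
#' `e ~ N(0, sd_day^2)`, a person's true usual vitamin D is
#' `d * exp(mu_g + u + sd_day^2/2) + d_egg * egg_grams`, so the population
#' prevalence below the EAR `t` is
#' `pnorm((log((t - c)/d) - mu_g - sd_day^2/2) / sd_person)`; the constructor
#' inverts this for the two densities.
#'
#' @param n_persons Persons in the (single) group.
#' @param group Group label.
#' @param baseline_prevalence True baseline EAR-below prevalence (fraction).
#' @param shift_pp Designed true reduction, in percentage points.
#' @param ear EAR threshold (ug/day; the adult vitamin-D EAR is 10).
#' @param mu_g,sd_person,sd_day Log-gram parameters of the cereal dish.
#' @param egg_grams Fixed grams of the egg side dish.
#' @param n_reps Replicate weights to attach downstream; default is the
#'   smallest power of two exceeding the number of paired strata.
#' @return List with `config` (a [simulation_config()]), `recommendation`
#'   (a one-row vitamin-D EAR table) and `truth` (closed-form baseline and
#'   modeled prevalences in percent, and the two densities).
#' @export
scenario_vitamin_d_substitution <- function(n_persons = 800,
                                            group = "fi_nonpart",
                                            baseline_prevalence = 0.50,
                                            shift_pp = 3,
                                            ear = 10,
                                            mu_g = log(250),
                                            sd_person = 0.5,
                                            sd_day = 0.3,
                                            egg_grams = 10,
                                            n_reps = NULL) {
  z0 <- qnorm(baseline_prevalence)
  z1 <- qnorm(baseline_prevalence - shift_pp / 100)
  k <- exp(sd_person * (z0 - z1))     # egg / cereal density ratio
  d_cereal <- ear / (exp(mu_g + sd_day^2 / 2 + sd_person * z0) + k * egg_grams)
  d_egg <- k * d_cereal
  if (is.null(n_reps)) {
    n_strata <- ceiling(n_persons / 2)
    n_reps <- 2^ceiling(log2(n_strata + 1))
  }
  dishes <- tibble::tribble(
    ~category,                ~kind,  ~occasion, ~prob, ~mean_log_grams, ~sd_person, ~sd_day, ~sd_logit,
    "breakfast_cereal",       "main", "lunch",   1,     mu_g,            sd_person,  sd_day,  0,
    "scrambled_eggs_omelets", "egg",  "lunch",   1,     log(egg_grams),  0,          0,       0
  )
  densities <- tibble::tribble(
    ~category,                ~energy, ~vitamin_d,
    "breakfast_cereal",       3.8,     d_cereal,
    "scrambled_eggs_omelets", 1.66,    d_egg
  )
  cfg <- simulation_config(setNames(n_persons, group), dishes, densities,
                           n_reps = n_reps)
  rec <- tibble(nutrient = "vitamin_d", rule = "EAR_below", sex = "all",
                age_min = 0, age_max = Inf, threshold = ear)
  list(
    config = cfg,
    recommendation = rec,
    truth = list(
      prevalence_baseline = 100 * baseline_prevalence,
      prevalence_modeled = 100 * baseline_prevalence - shift_pp,
      density_cereal = d_cereal,
      density_egg = d_egg,
      ear = ear
    )
  )
}
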