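# Small in-code fixtures shared across the suite.

# Two-nutrient panel used by hand-built recall tables.
tiny_panel <- function() {
  nutrient_panel(c("energy", "vitamin_d"),
                 units = c(energy = "kcal", vitamin_d = "ug"))
}

# Hand-built three-record recall table exercising every column.
tiny_recalls <- function() {
  tibble::tibble(
    person_id = c("P1", "P1", "P2"),
    day = c(1L, 2L, 1L),
    weekday = c(TRUE, FALSE, TRUE),
    occasion = c("breakfast", "lunch", "breakfast"),
    dish_category = c("breakfast_cereal", "sandwiches", "whole_eggs"),
    dish_kind = c("main", "main", "egg"),
    grams = c(50, 150, 100 / 3),
    energy = c(100, 375, 50.123456789012),
    vitamin_d = c(1 / 3, 0.45, 2.2)
  )
}

tiny_persons <- function(n = 2, group = "snap") {
  tibble::tibble(
    person_id = paste0("P", seq_len(n)),
    group = rep_len(group, n),
    age = rep_len(c(35, 62), n),
    sex = rep_len(c("female", "male"), n),
    weight = 1
  )
}

# Minimal two-dish, two-nutrient simulation configuration.
tiny_config <- function(n_persons = c(snap = 10, fi_nonpart = 10),
                        prob = c(1, 0.5),
                        sd_day = c(0.2, 0.2),
                        sd_person = c(0.3, 0.3),
                        sd_logit = c(0, 0),
                        n_reps = 16, ...) {
  dishes <- tibble::tibble(
    category = c("breakfast_cereal", "sandwiches"),
    kind = c("main", "main"),
    occasion = c("breakfast", "lunch"),
    prob = prob,
    mean_log_grams = c(log(60), log(200)),
    sd_person = sd_person,
    sd_day = sd_day,
    sd_logit = sd_logit
  )
  densities <- tibble::tibble(
    category = c("breakfast_cereal", "sandwiches"),
    energy = c(3.8, 2.5),
    vitamin_d = c(0.03, 0.004)
  )
  simulation_config(n_persons, dishes, densities, panel = tiny_panel(),
                    n_reps = n_reps, ...)
}

# Daily-totals table simulated directly from the measurement-error model
# y_ij = g^-1(mu + u_i + e_ij) (identity or log link), bypassing the dish
# machinery; used for parameter-recovery tests.
simulate_totals <- function(n, mu, sigma_u2, sigma_e2, seed,
                            log_scale = TRUE, nutrient = "y",
                            weight = NULL) {
  set.seed(seed)
  u <- rnorm(n, 0, sqrt(sigma_u2))
  e <- matrix(rnorm(2 * n, 0, sqrt(sigma_e2)), n, 2)
  m <- mu + u + e
  y <- if (log_scale) exp(m) else m
  persons <- tibble::tibble(
    person_id = sprintf("P%05d", seq_len(n)),
    group = "snap",
    age = 40,
    sex = "female",
    weight = weight %||% rep(1, n)
  )
  totals <- tibble::tibble(
    person_id = rep(persons$person_id, 2),
    day = rep(1:2, each = n),
    weekday = TRUE,
    y = as.vector(y)
  )
  names(totals)[names(totals) == "y"] <- nutrient
  list(persons = persons, totals = totals, u = u)
}
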