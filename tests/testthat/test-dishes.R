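make_freq_recalls <- function() {
  # 10 snap persons; 3 ever eat cereal at breakfast (one of them twice)
  tibble::tibble(
    person_id = c("P1", "P1", "P2", "P3", "P4"),
    day = c(1L, 1L, 1L, 2L, 1L),
    weekday = TRUE,
    occasion = "breakfast",
    dish_category = c("breakfast_cereal", "breakfast_cereal",
                      "breakfast_cereal", "breakfast_cereal", "oatmeal"),
    dish_kind = "main",
    grams = 50,
    energy = 100,
    vitamin_d = 1
  )
}

test_that("consumption frequency counts each person once per category", {
  recalls <- make_freq_recalls()
  persons <- tiny_persons(10)
  freq <- consumption_frequency(recalls, persons, occasions = "breakfast")
  cereal <- freq |> dplyr::filter(category == "breakfast_cereal")
  expect_equal(cereal$pct, 30)          # 3 of 10, double report counts once
  expect_equal(cereal$n_persons, 3L)
  oat <- freq |> dplyr::filter(category == "oatmeal")
  expect_equal(oat$pct, 10)
  # percentages are per category, not exclusive: they can sum past 100
  everyone_two_dishes <- dplyr::bind_rows(
    dplyr::mutate(tiny_persons(10)[, "person_id"], day = 1L, weekday = TRUE,
                  occasion = "breakfast", dish_category = "breakfast_cereal",
                  dish_kind = "main", grams = 50, energy = 100, vitamin_d = 1),
    dplyr::mutate(tiny_persons(10)[, "person_id"], day = 1L, weekday = TRUE,
                  occasion = "breakfast", dish_category = "oatmeal",
                  dish_kind = "main", grams = 40, energy = 60, vitamin_d = 0.5)
  )
  freq2 <- consumption_frequency(everyone_two_dishes, persons,
                                 occasions = "breakfast")
  expect_equal(sum(freq2$pct), 200)
  expect_error(consumption_frequency(recalls, persons, groups = "wic"),
               "group")
})

test_that("survey-weighted frequencies use the weights", {
  recalls <- make_freq_recalls()
  persons <- tiny_persons(10)
  persons$weight <- c(10, rep(1, 9))    # person 1 dominates
  freq <- consumption_frequency(recalls, persons, occasions = "breakfast",
                                weighted = TRUE)
  cereal <- freq |> dplyr::filter(category == "breakfast_cereal")
  expect_equal(cereal$pct, 100 * 12 / 19)
})

test_that("most common dish is the argmax with lexicographic ties", {
  freq <- tibble::tibble(
    group = "snap", occasion = "breakfast", kind = "main",
    category = c("b_dish", "a_dish", "c_dish"),
    n_persons = c(3L, 3L, 2L),
    pct = c(25, 25, 20)
  )
  expect_equal(select_most_common(freq)$category, "a_dish")
  one <- freq[3, ]
  expect_equal(select_most_common(one)$category, "c_dish")
  expect_error(select_most_common(freq[0, ]), "empty")
})

test_that("composite profiles average per-gram densities over foods", {
  panel <- tiny_panel()
  recalls <- tibble::tibble(
    person_id = c("P1", "P2"),
    day = 1L, weekday = TRUE, occasion = "breakfast",
    dish_category = "breakfast_cereal", dish_kind = "main",
    grams = c(50, 100),
    energy = c(50, 300),     # 1 and 3 kcal/g -> mean 2
    vitamin_d = c(0.5, 1.0)  # 0.01 per g both
  )
  prof <- composite_profile(recalls, "breakfast_cereal", panel)
  expect_equal(unname(prof$density["energy"]), 2)
  expect_equal(unname(prof$density["vitamin_d"]), 0.01)
  expect_equal(prof$n_foods, 2)
  # one food, 50 g with 100 kcal -> 2 kcal/g
  prof1 <- composite_profile(recalls[1, ] |> dplyr::mutate(energy = 100),
                             "breakfast_cereal", panel)
  expect_equal(unname(prof1$density["energy"]), 2)
  expect_error(composite_profile(recalls, "soups", panel), "soups")
  # distinct foods by code: replicate records of one food count once
  coded <- dplyr::bind_rows(recalls, recalls[1, ]) |>
    dplyr::mutate(food_code = c("f1", "f2", "f1"))
  prof2 <- composite_profile(coded, "breakfast_cereal", panel)
  expect_equal(unname(prof2$density["energy"]), 2)
  expect_equal(prof2$n_foods, 2)
})

substitution_fixture <- function() {
  panel <- tiny_panel()
  recalls <- tibble::tibble(
    person_id = c("P1", "P1", "P1", "P2", "P2"),
    day = 1L,
    weekday = TRUE,
    occasion = c("lunch", "lunch", "other", "lunch", "breakfast"),
    dish_category = c("sandwiches", "scrambled_eggs_omelets",
                      "sweet_baked_goods", "scrambled_eggs_omelets",
                      "sandwiches"),
    dish_kind = c("main", "egg", "other", "egg", "main"),
    grams = c(100, 40, 30, 40, 80),
    energy = c(250, 66.4, 120, 66.4, 200),        # eggs: 1.66 kcal/g
    vitamin_d = c(0.3, 0.84, 0.03, 0.84, 0.24)    # eggs: 0.021 ug/g
  )
  persons <- tiny_persons(2)
  list(panel = panel, recalls = recalls, persons = persons)
}

test_that("gram-basis substitution preserves grams and is local", {
  fx <- substitution_fixture()
  plan <- substitution_plan(fx$recalls, fx$persons, "lunch")
  expect_equal(plan$source_category, "sandwiches")
  expect_equal(plan$replacement_category, "scrambled_eggs_omelets")
  out <- apply_substitution(fx$recalls, fx$persons, plan, fx$panel)
  expect_identical(out$grams, fx$recalls$grams)            # bitwise grams
  # untouched rows are bit-identical
  untouched <- c(2, 3, 4, 5)
  expect_identical(as.data.frame(out[untouched, ]),
                   as.data.frame(fx$recalls[untouched, ]))
  # substituted row takes the egg composite density and relabels
  expect_equal(out$energy[1], 100 * 1.66)
  expect_equal(out$vitamin_d[1], 100 * 0.021)
  expect_equal(out$dish_category[1], "scrambled_eggs_omelets")
  expect_equal(out$dish_kind[1], "egg")
  # occasion totals move by grams * (replacement - source density)
  expect_equal(out$energy[1] - fx$recalls$energy[1], 100 * (1.66 - 2.5))
})

test_that("substitution is idempotent after relabeling", {
  fx <- substitution_fixture()
  plan <- substitution_plan(fx$recalls, fx$persons, "lunch")
  once <- apply_substitution(fx$recalls, fx$persons, plan, fx$panel)
  profiles <- list(scrambled_eggs_omelets =
                     composite_profile(fx$recalls, "scrambled_eggs_omelets",
                                       fx$panel))
  twice <- apply_substitution(once, fx$persons, plan, fx$panel,
                              profiles = profiles)
  expect_identical(as.data.frame(twice), as.data.frame(once))
})

test_that("calorie basis rescales grams to preserve record energy", {
  fx <- substitution_fixture()
  plan <- substitution_plan(fx$recalls, fx$persons, "lunch",
                            basis = "calorie")
  out <- apply_substitution(fx$recalls, fx$persons, plan, fx$panel)
  # source 2.5 kcal/g x 100 g = 250 kcal; replacement 1.66 kcal/g
  expect_equal(out$grams[1], 100 * 2.5 / 1.66)
  expect_equal(out$energy[1], fx$recalls$energy[1], tolerance = 1e-9)
  zero_energy <- list(scrambled_eggs_omelets = structure(
    list(category = "scrambled_eggs_omelets", kind = "egg",
         density = c(energy = 0, vitamin_d = 0.021), n_foods = 1),
    class = "dish_profile"
  ))
  expect_error(
    apply_substitution(fx$recalls, fx$persons, plan, fx$panel,
                       profiles = zero_energy),
    "energy density"
  )
})

test_that("persons without source records are untouched", {
  fx <- substitution_fixture()
  plan <- substitution_plan(fx$recalls, fx$persons, "lunch")
  out <- apply_substitution(fx$recalls, fx$persons, plan, fx$panel)
  p2 <- out |> dplyr::filter(person_id == "P2")
  expect_identical(as.data.frame(p2),
                   as.data.frame(fx$recalls |>
                                   dplyr::filter(person_id == "P2")))
})

test_that("degenerate plans are refused", {
  fx <- substitution_fixture()
  # no main dish left at the occasion
  no_main <- fx$recalls |>
    dplyr::mutate(dish_kind = ifelse(dish_category == "sandwiches" &
                                       occasion == "lunch",
                                     "other", dish_kind))
  expect_error(substitution_plan(no_main, fx$persons, "lunch"),
               "main or egg")
  # most common main *is* the egg-dish category
  egg_as_main <- fx$recalls |>
    dplyr::mutate(dish_category = ifelse(dish_category == "sandwiches" &
                                           occasion == "lunch",
                                         "scrambled_eggs_omelets",
                                         dish_category))
  expect_error(substitution_plan(egg_as_main, fx$persons, "lunch"),
               "refusing")
  expect_error(substitution_plan(fx$recalls, fx$persons, "other"),
               "occasion")
})

test_that("daily totals conserve record sums and honor person-days", {
  fx <- substitution_fixture()
  totals <- daily_totals(fx$recalls, fx$panel)
  expect_equal(sum(totals$energy), sum(fx$recalls$energy))
  expect_equal(sum(totals$vitamin_d), sum(fx$recalls$vitamin_d))
  one <- daily_totals(fx$recalls[1, ], fx$panel)
  expect_equal(one$energy, fx$recalls$energy[1])
  # completed person-days without records appear as zero rows
  pd <- tibble::tibble(person_id = c("P1", "P2"), day = 2L, weekday = FALSE)
  padded <- daily_totals(fx$recalls, fx$panel,
                         dplyr::bind_rows(
                           fx$recalls |> dplyr::distinct(person_id, day,
                                                         weekday),
                           pd
                         ))
  expect_equal(nrow(padded), 4)
  expect_equal(padded$energy[padded$day == 2], c(0, 0))
})
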