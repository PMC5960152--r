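test_that("variance components are recovered on the identity scale", {
  sim <- simulate_totals(n = 1000, mu = 50, sigma_u2 = 4, sigma_e2 = 1,
                         seed = 101, log_scale = FALSE)
  fit <- fit_amount_model(sim$totals, sim$persons, "y",
                          lambda_grid = c(0, 0.5, 1))
  expect_equal(fit$lambda, 1)
  expect_lt(abs(fit$sigma_u2 - 4) / 4, 0.15)
  expect_lt(abs(fit$sigma_e2 - 1) / 1, 0.15)
})

test_that("zero within-person variance is recognized", {
  sim <- simulate_totals(n = 300, mu = 50, sigma_u2 = 4, sigma_e2 = 0,
                         seed = 102, log_scale = FALSE)
  fit <- fit_amount_model(sim$totals, sim$persons, "y",
                          lambda_grid = c(1))
  expect_lte(fit$sigma_e2, 0.01 * fit$sigma_u2)
})

test_that("a null covariate is estimated near zero", {
  sim <- simulate_totals(n = 600, mu = 50, sigma_u2 = 4, sigma_e2 = 1,
                         seed = 103, log_scale = FALSE)
  set.seed(104)
  sim$persons$xcov <- rnorm(600)
  fit <- fit_amount_model(sim$totals, sim$persons, "y",
                          covariates = "xcov", lambda_grid = c(1))
  expect_lt(abs(fit$beta[["xcov"]]) / fit$beta_se[["xcov"]], 3)
})

test_that("degenerate amount inputs raise the specified errors", {
  sim <- simulate_totals(n = 50, mu = 2, sigma_u2 = 0.3, sigma_e2 = 0.1,
                         seed = 105)
  single <- sim$totals |> dplyr::filter(day == 1)
  expect_error(fit_amount_model(single, sim$persons, "y"), "single recall")
  zero <- sim$totals |> dplyr::mutate(y = 0)
  expect_error(fit_amount_model(zero, sim$persons, "y"), "zero")
})

test_that("the probability submodel recovers a constant consumption rate", {
  n <- 800
  set.seed(106)
  persons <- tibble::tibble(person_id = sprintf("P%04d", 1:n),
                            group = "snap", age = 40, sex = "female",
                            weight = 1)
  totals <- tibble::tibble(
    person_id = rep(persons$person_id, 2),
    day = rep(1:2, each = n), weekday = TRUE,
    y = as.numeric(runif(2 * n) < 0.5)
  )
  fit <- fit_probability_model(totals, persons, "y")
  expect_lt(abs(fit$gamma[["(Intercept)"]]) / fit$gamma_se[["(Intercept)"]],
            3)
  expect_lt(fit$tau_u2, 0.2)
})

test_that("the person random-intercept variance is recovered", {
  n <- 2000
  set.seed(107)
  v <- rnorm(n, 0, 1)
  persons <- tibble::tibble(person_id = sprintf("P%04d", 1:n),
                            group = "snap", age = 40, sex = "female",
                            weight = 1)
  totals <- tibble::tibble(
    person_id = rep(persons$person_id, 2),
    day = rep(1:2, each = n), weekday = TRUE,
    y = as.numeric(runif(2 * n) < plogis(rep(v, 2)))
  )
  fit <- fit_probability_model(totals, persons, "y")
  expect_lt(abs(fit$tau_u2 - 1), 0.25)
})

test_that("ubiquitous nutrients refuse the probability path", {
  sim <- simulate_totals(n = 100, mu = 2, sigma_u2 = 0.3, sigma_e2 = 0.1,
                         seed = 108)
  expect_error(fit_probability_model(sim$totals, sim$persons, "y"),
               class = "mealswap_ubiquitous")
  # the orchestrator falls back to amount-only
  fit <- fit_usual_intake(sim$totals, sim$persons, "y", episodic = TRUE,
                          lambda_grid = c(0, 1))
  expect_false(fit$episodic)
})

test_that("group mean matches the closed-form lognormal usual mean", {
  mu <- 1.5; su2 <- 0.25; se2 <- 0.09
  sim <- simulate_totals(n = 1000, mu = mu, sigma_u2 = su2, sigma_e2 = se2,
                         seed = 109)
  fit <- fit_usual_intake(sim$totals, sim$persons, "y",
                          lambda_grid = c(0, 0.25, 0.5, 1))
  expect_equal(fit$amount$lambda, 0)
  draws <- simulate_usual_intake(fit, sim$persons, n_mc = 300, seed = 110)
  est <- group_mean(draws, sim$persons)
  truth <- exp(mu + su2 / 2 + se2 / 2)
  expect_lt(abs(est$estimate - truth) / truth, 0.02)
})

test_that("draws are deterministic given the seed", {
  sim <- simulate_totals(n = 100, mu = 2, sigma_u2 = 0.3, sigma_e2 = 0.1,
                         seed = 111)
  fit <- fit_usual_intake(sim$totals, sim$persons, "y", lambda_grid = c(0, 1))
  d1 <- simulate_usual_intake(fit, sim$persons, n_mc = 100, seed = 7)
  d2 <- simulate_usual_intake(fit, sim$persons, n_mc = 100, seed = 7)
  expect_identical(d1$usual, d2$usual)
  d3 <- simulate_usual_intake(fit, sim$persons, n_mc = 100, seed = 8)
  expect_false(identical(d3$usual, d1$usual))
  expect_warning(simulate_usual_intake(fit, sim$persons, n_mc = 50, seed = 7),
                 "100")
})

test_that("usual-intake draws shrink relative to observed two-day means", {
  configs <- list(c(su2 = 0.25, se2 = 0.16), c(su2 = 0.4, se2 = 0.36),
                  c(su2 = 0.1, se2 = 0.25))
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    sim <- simulate_totals(n = 500, mu = 1.5, sigma_u2 = cf[["su2"]],
                           sigma_e2 = cf[["se2"]], seed = 120 + i)
    fit <- fit_usual_intake(sim$totals, sim$persons, "y",
                            lambda_grid = c(0, 0.5, 1))
    draws <- simulate_usual_intake(fit, sim$persons, n_mc = 200,
                                   seed = 130 + i)
    pm <- draws |> dplyr::group_by(person_id) |>
      dplyr::summarise(m = mean(usual))
    obs <- sim$totals |> dplyr::group_by(person_id) |>
      dplyr::summarise(m = mean(y))
    expect_lt(var(pm$m), var(obs$m))
  }
})

test_that("without day-to-day noise the draws reproduce person means exactly", {
  sim <- simulate_totals(n = 200, mu = 50, sigma_u2 = 4, sigma_e2 = 0,
                         seed = 140, log_scale = FALSE,
                         weight = exp(rnorm(200, 0, 0.3)))
  fit <- fit_usual_intake(sim$totals, sim$persons, "y", lambda_grid = c(1))
  draws <- simulate_usual_intake(fit, sim$persons, n_mc = 50, seed = 141) |>
    suppressWarnings()
  est <- group_mean(draws, sim$persons)
  naive <- sim$totals |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(m = mean(y)) |>
    dplyr::inner_join(sim$persons, by = "person_id") |>
    dplyr::summarise(m = weighted.mean(m, weight)) |>
    dplyr::pull(m)
  expect_equal(est$estimate, naive, tolerance = 1e-6)
})

test_that("the two-part model matches an independence oracle for the mean", {
  n <- 800
  set.seed(150)
  mu <- 1.5; su2 <- 0.25; se2 <- 0.09; g0 <- 0.4; tau2 <- 0.5
  u <- rnorm(n, 0, sqrt(su2))
  v <- rnorm(n, 0, sqrt(tau2))          # independent of u: rho = 0 in truth
  persons <- tibble::tibble(person_id = sprintf("P%04d", 1:n),
                            group = "snap", age = 40, sex = "female",
                            weight = 1)
  amount <- exp(mu + rep(u, 2) + rnorm(2 * n, 0, sqrt(se2)))
  consumed <- runif(2 * n) < plogis(g0 + rep(v, 2))
  totals <- tibble::tibble(
    person_id = rep(persons$person_id, 2),
    day = rep(1:2, each = n), weekday = TRUE,
    y = amount * consumed
  )
  fit <- fit_usual_intake(totals, persons, "y", lambda_grid = c(0, 0.5))
  expect_true(fit$episodic)
  expect_equal(fit$amount$lambda, 0)
  expect_lt(abs(fit$rho), 0.35)
  draws <- simulate_usual_intake(fit, persons, n_mc = 300, seed = 151)
  est <- group_mean(draws, persons)
  p_bar <- stats::integrate(function(x) plogis(g0 + x) * dnorm(x, 0, sqrt(tau2)),
                            -Inf, Inf)$value
  truth <- p_bar * exp(mu + su2 / 2 + se2 / 2)
  expect_lt(abs(est$estimate - truth) / truth, 0.05)
})

test_that("Gauss-Hermite back-transformation matches the log-scale closed form", {
  m <- c(-1, 0, 1.3)
  s2 <- 0.09
  gh <- mealswap:::backtransform_mean(m, 0, s2, "gauss-hermite")
  expect_equal(gh, exp(m + s2 / 2), tolerance = 1e-8)
  taylor <- mealswap:::backtransform_mean(m, 0, s2, "taylor")
  expect_equal(taylor, exp(m) * (1 + s2 / 2))
  # identity scale needs no correction
  expect_equal(mealswap:::backtransform_mean(m, 1, s2, "taylor"), m + 1)
})

test_that("group means respect weights and reject empty groups", {
  sim <- simulate_totals(n = 60, mu = 2, sigma_u2 = 0.3, sigma_e2 = 0.1,
                         seed = 160)
  fit <- fit_usual_intake(sim$totals, sim$persons, "y", lambda_grid = c(0))
  draws <- simulate_usual_intake(fit, sim$persons, n_mc = 100, seed = 161)
  est1 <- group_mean(draws, sim$persons)
  doubled <- sim$persons |> dplyr::mutate(weight = 2 * weight)
  est2 <- group_mean(draws, doubled)
  expect_equal(est1$estimate, est2$estimate)
  expect_error(group_mean(draws, sim$persons, groups = "wic"), "wic")
})
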