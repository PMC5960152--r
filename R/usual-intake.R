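#' Box-Cox power transform
#'
#' `boxcox_transform()` maps positive amounts to the transformed scale the
#' mixed model is fitted on (`lambda = 0` means the natural log);
#' `boxcox_inverse()` maps back.
#'
#' @param y Positive amounts.
#' @param z Transformed values.
#' @param lambda Power parameter.
#' @return Numeric vector.
#' @keywords internal
boxcox_transform <- function(y, lambda) {
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @keywords internal
boxcox_inverse <- function(z, lambda) {
  if (lambda == 0) exp(z) else pmax(lambda * z + 1, 0)^(1 / lambda)
}

# Mean of the back-transformed daily amount given the person-level mean m on
# the transformed scale and within-person variance s2e: E[g^-1(m + e)].
# "taylor" is the second-order correction g^-1(m) + g^-1''(m) * s2e / 2 (the
# usual-intake macros' approach); "gauss-hermite" integrates with 9 nodes.
backtransform_mean <- function(m, lambda, s2e,
                               method = c("taylor", "gauss-hermite")) {
  method <- match.arg(method)
  if (method == "taylor") {
    if (lambda == 0) return(exp(m) * (1 + s2e / 2))
    base <- pmax(lambda * m + 1, 0)
    corr <- 0.5 * s2e * (1 - lambda) * base^(1 / lambda - 2)
    corr[base == 0] <- 0
    return(base^(1 / lambda) + corr)
  }
  gh <- pracma::gaussHermite(9)
  out <- 0
  s <- sqrt(2 * s2e)
  for (j in seq_along(gh$x)) {
    out <- out + gh$w[j] * boxcox_inverse(m + s * gh$x[j], lambda)
  }
  out / sqrt(pi)
}

prep_covariates <- function(dat, covariates, xlev = NULL) {
  for (cv in covariates) {
    if (!cv %in% names(dat)) {
      abort(paste0("covariate `", cv, "` not found."))
    }
    if (is.character(dat[[cv]]) || is.factor(dat[[cv]])) {
      lv <- xlev[[cv]] %||% sort(unique(as.character(dat[[cv]])))
      dat[[cv]] <- factor(as.character(dat[[cv]]), levels = lv)
    }
  }
  dat
}

stored_xlev <- function(dat, covariates) {
  xlev <- list()
  for (cv in covariates) {
    if (is.factor(dat[[cv]])) xlev[[cv]] <- levels(dat[[cv]])
  }
  xlev
}

modeling_frame <- function(totals, persons, nutrient, covariates) {
  if (!nutrient %in% names(totals)) {
    abort(paste0("nutrient `", nutrient, "` not found in the totals table."))
  }
  dat <- totals |>
    inner_join(persons, by = "person_id") |>
    mutate(
      day2 = as.numeric(.data$day == 2),
      weekend = as.numeric(!.data$weekday),
      ..y = .data[[nutrient]]
    )
  dat <- prep_covariates(dat, covariates)
  dat
}

extract_blups <- function(fit) {
  re <- lme4::ranef(fit, condVar = TRUE)$person_id
  tibble(
    person_id = rownames(re),
    blup = re[, 1],
    condvar = as.vector(attr(re, "postVar"))
  )
}

#' Fit the amount part of the usual-intake model
#'
#' Fits a linear mixed model with a person random intercept to Box-Cox
#' transformed daily totals,
#' `g(y) = X beta + u_i + e`, with `u_i ~ N(0, sigma_u2)` (between-person) and
#' `e ~ N(0, sigma_e2)` (within-person, the day-to-day measurement
#' variation). The power `lambda` is chosen from `lambda_grid` by maximum
#' profile likelihood (ML fit plus the transform's Jacobian); variance
#' components at the chosen `lambda` are then re-estimated by REML. Fixed
#' effects always include a second-recall indicator and a weekend indicator
#' in addition to `covariates` drawn from the person table.
#'
#' When zeros are present in an amount-only fit, a small positive offset
#' (half the smallest positive observed value) is added before transforming
#' and subtracted after back-transformation; the episodic path
#' (`positive_only = TRUE`) models positive amounts only and leaves zeros to
#' the probability submodel.
#'
#' @param totals Daily totals from [daily_totals()].
#' @param persons Person table with covariate columns.
#' @param nutrient Nutrient column to model.
#' @param covariates Character vector of person-table covariate names.
#' @param lambda_grid Candidate Box-Cox powers (0 = log).
#' @param positive_only Drop zero days instead of shifting.
#' @return Object of class `amount_model` with elements `lambda`, `beta`,
#'   `sigma_u2`, `sigma_e2`, `epsilon_shift`, `blups`, `profile` (the
#'   per-lambda profile log-likelihoods) and design metadata.
#' @export
fit_amount_model <- function(totals, persons, nutrient,
                             covariates = character(),
                             lambda_grid = seq(0, 1, by = 0.1),
                             positive_only = FALSE) {
  dat <- modeling_frame(totals, persons, nutrient, covariates)
  if (all(dat$..y == 0)) {
    abort(paste0("nutrient `", nutrient, "` is zero on every person-day; ",
                 "nothing to model."))
  }
  shift <- 0
  if (positive_only) {
    dat <- dat |> filter(.data$..y > 0)
  } else if (any(dat$..y == 0)) {
    shift <- min(dat$..y[dat$..y > 0]) / 2
  }
  if (!any(duplicated(dat$person_id))) {
    abort("every person has a single recall; within-person variance is not identifiable.")
  }
  y <- dat$..y + shift
  rhs <- c("day2", "weekend", covariates)
  fml <- as.formula(paste("..z ~", paste(rhs, collapse = " + "),
                          "+ (1 | person_id)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  jac <- sum(log(y))
  prof <- purrr::map_dbl(lambda_grid, function(lam) {
    dat$..z <- boxcox_transform(y, lam)
    fit <- suppressMessages(
      lme4::lmer(fml, data = dat, REML = FALSE, control = ctrl)
    )
    as.numeric(logLik(fit)) + (lam - 1) * jac
  })
  lambda <- lambda_grid[which.max(prof)]
  dat$..z <- boxcox_transform(y, lambda)
  fit <- suppressMessages(
    lme4::lmer(fml, data = dat, REML = TRUE, control = ctrl)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      nutrient = nutrient,
      lambda = lambda,
      beta = lme4::fixef(fit),
      beta_se = sqrt(diag(as.matrix(stats::vcov(fit)))),
      sigma_u2 = vc$vcov[vc$grp == "person_id"][1],
      sigma_e2 = sigma(fit)^2,
      epsilon_shift = shift,
      covariates = covariates,
      xlev = stored_xlev(dat, covariates),
      blups = extract_blups(fit),
      profile = tibble(lambda = lambda_grid, loglik = prof),
      n_persons = dplyr::n_distinct(dat$person_id),
      n_obs = nrow(dat)
    ),
    class = "amount_model"
  )
}

#' Fit the consumption-probability submodel
#'
#' Logistic mixed model for the probability that a nutrient is consumed at
#' all on a recall day, with a person random intercept estimated by adaptive
#' Gauss-Hermite quadrature. Refuses with a `mealswap_ubiquitous` condition
#' when every person-day shows consumption (the amount-only model applies).
#'
#' @inheritParams fit_amount_model
#' @param nagq Quadrature points for the marginal likelihood.
#' @return Object of class `probability_model` with elements `gamma` (fixed
#'   effects on the logit scale), `tau_u2` (person random-intercept variance)
#'   and `blups`.
#' @export
fit_probability_model <- function(totals, persons, nutrient,
                                  covariates = character(), nagq = 7) {
  dat <- modeling_frame(totals, persons, nutrient, covariates)
  dat$..c <- as.numeric(dat$..y > 0)
  if (all(dat$..c == 1)) {
    abort(paste0("nutrient `", nutrient, "` is consumed on every person-day; ",
                 "use the amount-only model."),
          class = "mealswap_ubiquitous")
  }
  if (all(dat$..c == 0)) {
    abort(paste0("nutrient `", nutrient, "` is never consumed."))
  }
  rhs <- c("day2", "weekend", covariates)
  fml <- as.formula(paste("..c ~", paste(rhs, collapse = " + "),
                          "+ (1 | person_id)"))
  fit <- suppressMessages(
    lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nagq,
                control = lme4::glmerControl(check.conv.singular = "ignore"))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      nutrient = nutrient,
      gamma = lme4::fixef(fit),
      tau_u2 = vc$vcov[vc$grp == "person_id"][1],
      gamma_se = sqrt(diag(as.matrix(stats::vcov(fit)))),
      covariates = covariates,
      xlev = stored_xlev(dat, covariates),
      blups = extract_blups(fit),
      n_persons = dplyr::n_distinct(dat$person_id)
    ),
    class = "probability_model"
  )
}

#' Fit the usual-intake measurement-error model
#'
#' Orchestrates the amount and (when needed) consumption-probability
#' submodels for one nutrient. A nutrient is treated as *episodic* when more
#' than `episodic_threshold` of person-days report zero intake, in which case
#' positive amounts and the consumption indicator are modeled separately and
#' the person effects of the two submodels are linked through their
#' correlation `rho` (estimated from the two sets of conditional modes);
#' otherwise the amount-only model is used.
#'
#' @inheritParams fit_amount_model
#' @param episodic Force the two-part (`TRUE`) or amount-only (`FALSE`) path;
#'   `NULL` applies the zero-share rule.
#' @param episodic_threshold Zero share above which the two-part model is
#'   used.
#' @return Object of class `usual_intake_fit`: list with `nutrient`,
#'   `episodic`, `amount` ([fit_amount_model()] result), `prob`
#'   ([fit_probability_model()] result or `NULL`) and `rho`.
#' @examples
#' cfg <- default_simulation_config(n_scale = 0.1)
#' persons <- simulate_population(cfg, seed = 1)
#' sim <- simulate_recalls(persons, cfg, seed = 2)
#' totals <- daily_totals(sim$recalls, cfg$panel)
#' fit <- fit_usual_intake(totals, persons, "energy",
#'                         lambda_grid = c(0, 0.5, 1))
#' glance(fit)
#' @export
fit_usual_intake <- function(totals, persons, nutrient,
                             covariates = character(),
                             lambda_grid = seq(0, 1, by = 0.1),
                             episodic = NULL, episodic_threshold = 0.05) {
  y <- totals[[nutrient]]
  if (is.null(y)) {
    abort(paste0("nutrient `", nutrient, "` not found in the totals table."))
  }
  zero_share <- mean(y == 0)
  episodic <- episodic %||% (zero_share > episodic_threshold)
  prob <- NULL
  rho <- NA_real_
  if (episodic) {
    prob <- tryCatch(
      fit_probability_model(totals, persons, nutrient, covariates),
      mealswap_ubiquitous = function(cnd) NULL
    )
    if (is.null(prob)) episodic <- FALSE
  }
  amount <- fit_amount_model(totals, persons, nutrient, covariates,
                             lambda_grid, positive_only = episodic)
  if (episodic) {
    both <- inner_join(amount$blups, prob$blups, by = "person_id",
                       suffix = c("_a", "_p"))
    rho <- if (nrow(both) > 2 &&
               sd(both$blup_a) > 0 && sd(both$blup_p) > 0) {
      max(-1, min(1, stats::cor(both$blup_a, both$blup_p)))
    } else {
      0
    }
  }
  structure(
    list(nutrient = nutrient, episodic = episodic, amount = amount,
         prob = prob, rho = rho, zero_share = zero_share),
    class = "usual_intake_fit"
  )
}

#' @export
print.usual_intake_fit <- function(x, ...) {
  cat("<usual_intake_fit> ", x$nutrient,
      if (x$episodic) " (two-part)" else " (amount-only)", "\n", sep = "")
  cat(sprintf("  lambda = %.2f, sigma_u2 = %.4g, sigma_e2 = %.4g\n",
              x$amount$lambda, x$amount$sigma_u2, x$amount$sigma_e2))
  if (x$episodic) {
    cat(sprintf("  tau_u2 = %.4g, rho = %.3f\n", x$prob$tau_u2, x$rho))
  }
  invisible(x)
}

# Fixed-effect linear predictor for each person at the usual-intake
# reference: first recall day, weekend indicator at its long-run share 2/7.
predict_eta <- function(coefs, covariates, xlev, persons,
                        weekend_value = 2 / 7) {
  nd <- persons
  nd$day2 <- 0
  nd$weekend <- weekend_value
  nd <- prep_covariates(nd, covariates, xlev)
  X <- model.matrix(stats::reformulate(c("day2", "weekend", covariates)), nd)
  drop(X[, names(coefs), drop = FALSE] %*% coefs)
}

#' Simulate the usual-intake distribution
#'
#' The DISTRIB-style step: for each person, draws `n_mc` person effects from
#' their conditional (posterior) distribution given the data — conditional
#' mode plus conditional standard deviation from the mixed model — adds the
#' fixed-effect predictor, back-transforms the Box-Cox mean with the
#' within-person variance correction (see [fit_amount_model()]), removes the
#' zero-offset and clamps at zero. For an episodic nutrient the consumption
#' probability is computed from correlated person-effect draws
#' (`rho`-coupled standard normals) and multiplies the amount.
#'
#' Persons absent from the fitting data draw from the population distribution
#' `N(0, sigma_u2)`.
#'
#' @param fit A [fit_usual_intake()] result.
#' @param persons Person table (covariates must be present).
#' @param n_mc Monte-Carlo draws per person; fewer than 100 triggers a
#'   warning about unstable tails.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param backtransform `"taylor"` (default) or `"gauss-hermite"`.
#' @param z,z2 Optional pre-drawn standard-normal matrices
#'   (`nrow(persons)` x `n_mc`) for the amount and probability person
#'   effects; supply shared draws to couple several nutrients (see
#'   [simulate_usual_joint()]).
#' @return A tibble of class `usual_intake_draws` with columns `person_id`,
#'   `draw`, `usual`; attributes `nutrient` and `n_mc`.
#' @export
simulate_usual_intake <- function(fit, persons, n_mc = 100, seed = 1,
                                  backtransform = c("taylor", "gauss-hermite"),
                                  z = NULL, z2 = NULL) {
  stopifnot(inherits(fit, "usual_intake_fit"))
  backtransform <- match.arg(backtransform)
  if (n_mc < 100) {
    warn("fewer than 100 Monte-Carlo draws per person: distribution tails will be unstable.")
  }
  n <- nrow(persons)
  if (is.null(z) || (fit$episodic && is.null(z2))) {
    set.seed(seed)
    if (is.null(z)) z <- matrix(rnorm(n * n_mc), n, n_mc)
    if (fit$episodic && is.null(z2)) z2 <- matrix(rnorm(n * n_mc), n, n_mc)
  }
  am <- fit$amount
  eta <- predict_eta(am$beta, am$covariates, am$xlev, persons)
  bl <- persons |>
    left_join(am$blups, by = "person_id")
  b <- ifelse(is.na(bl$blup), 0, bl$blup)
  v <- ifelse(is.na(bl$condvar), am$sigma_u2, bl$condvar)
  m <- eta + b + sqrt(v) * z
  usual <- backtransform_mean(m, am$lambda, am$sigma_e2, backtransform)
  usual <- pmax(usual - am$epsilon_shift, 0)
  if (fit$episodic) {
    pr <- fit$prob
    eta_p <- predict_eta(pr$gamma, pr$covariates, pr$xlev, persons)
    blp <- persons |> left_join(pr$blups, by = "person_id")
    bp <- ifelse(is.na(blp$blup), 0, blp$blup)
    vp <- ifelse(is.na(blp$condvar), pr$tau_u2, blp$condvar)
    rho <- if (is.na(fit$rho)) 0 else fit$rho
    w <- rho * z + sqrt(1 - rho^2) * z2
    p <- plogis(eta_p + bp + sqrt(vp) * w)
    usual <- p * usual
  }
  out <- tibble(
    person_id = rep(persons$person_id, times = n_mc),
    draw = rep(seq_len(n_mc), each = n),
    usual = as.vector(usual)
  )
  structure(out, class = c("usual_intake_draws", class(out)),
            nutrient = fit$nutrient, n_mc = n_mc)
}

#' Jointly simulate several nutrients from shared person-effect draws
#'
#' Runs [simulate_usual_intake()] for each fit with the *same* underlying
#' standard-normal draws, rank-coupling the nutrients through their person
#' effects. Required for ratio quantities such as saturated fat as a percent
#' of energy, where the numerator and denominator must move together within a
#' person.
#'
#' @param fits Named list of [fit_usual_intake()] results.
#' @inheritParams simulate_usual_intake
#' @return Named list of `usual_intake_draws`.
#' @export
simulate_usual_joint <- function(fits, persons, n_mc = 100, seed = 1,
                                 backtransform = "taylor") {
  n <- nrow(persons)
  set.seed(seed)
  z <- matrix(rnorm(n * n_mc), n, n_mc)
  z2 <- matrix(rnorm(n * n_mc), n, n_mc)
  purrr::map(fits, simulate_usual_intake, persons = persons, n_mc = n_mc,
             backtransform = backtransform, z = z, z2 = z2)
}

#' Survey-weighted group mean of usual intake
#'
#' Averages the usual-intake draws within person, then takes the
#' survey-weighted mean per group. With `se = TRUE` the balanced repeated
#' replication standard error is attached (the statistic is re-evaluated
#' under every replicate weight column).
#'
#' @param draws `usual_intake_draws` from [simulate_usual_intake()].
#' @param persons Person table; must carry replicate weights when
#'   `se = TRUE`.
#' @param groups Groups to estimate; default all present. Errors if a
#'   requested group has no persons.
#' @param se Attach BRR standard errors.
#' @param fay Fay coefficient of the replicate weights.
#' @return Tibble with columns `nutrient`, `group`, `estimate`, `se` (NA
#'   unless requested), `n`.
#' @export
group_mean <- function(draws, persons, groups = NULL, se = FALSE, fay = 0) {
  pm <- draws |>
    group_by(.data$person_id) |>
    summarise(pm = mean(.data$usual), .groups = "drop")
  groups <- groups %||% unique(persons$group)
  out <- purrr::map_dfr(groups, function(g) {
    pg <- persons |> filter(.data$group == g)
    if (nrow(pg) == 0) abort(paste0("group `", g, "` has no persons."))
    pg <- pg |> inner_join(pm, by = "person_id")
    if (nrow(pg) == 0) abort(paste0("group `", g, "` has no draws."))
    est <- weighted.mean(pg$pm, pg$weight)
    se_val <- NA_real_
    if (se) {
      se_val <- brr_se(function(w) weighted.mean(pg$pm, w), pg, fay = fay)
    }
    tibble(nutrient = attr(draws, "nutrient") %||% NA_character_,
           group = g, estimate = est, se = se_val, n = nrow(pg))
  })
  out
}
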