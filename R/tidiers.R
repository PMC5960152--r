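#' Tidy a fitted usual-intake model
#'
#' @param x A `usual_intake_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: `part` (`"amount"` or
#'   `"probability"`), `effect` (`"fixed"` or `"variance"`), `term`,
#'   `estimate`.
#' @method tidy usual_intake_fit
#' @export
tidy.usual_intake_fit <- function(x, ...) {
  am <- x$amount
  out <- bind_rows(
    tibble(part = "amount", effect = "fixed",
           term = names(am$beta), estimate = unname(am$beta)),
    tibble(part = "amount", effect = "variance",
           term = c("sigma_u2", "sigma_e2"),
           estimate = c(am$sigma_u2, am$sigma_e2))
  )
  if (x$episodic) {
    out <- bind_rows(
      out,
      tibble(part = "probability", effect = "fixed",
             term = names(x$prob$gamma), estimate = unname(x$prob$gamma)),
      tibble(part = "probability", effect = "variance",
             term = c("tau_u2", "rho"), estimate = c(x$prob$tau_u2, x$rho))
    )
  }
  out
}

#' @rdname tidy.usual_intake_fit
#' @return `glance()` returns a one-row summary: nutrient, path, `lambda`,
#'   variance components, zero share, persons and observations.
#' @method glance usual_intake_fit
#' @export
glance.usual_intake_fit <- function(x, ...) {
  tibble(
    nutrient = x$nutrient,
    episodic = x$episodic,
    lambda = x$amount$lambda,
    sigma_u2 = x$amount$sigma_u2,
    sigma_e2 = x$amount$sigma_e2,
    tau_u2 = if (x$episodic) x$prob$tau_u2 else NA_real_,
    rho = x$rho,
    zero_share = x$zero_share,
    epsilon_shift = x$amount$epsilon_shift,
    n_persons = x$amount$n_persons,
    n_obs = x$amount$n_obs
  )
}

#' Tidy a total nutrient index
#'
#' @param x A `tni` object.
#' @param ... Unused.
#' @return Per-nutrient table with the signed change and its index weight.
#' @method tidy tni
#' @export
tidy.tni <- function(x, ...) {
  x$table |>
    mutate(weight = 1 / .data$se)
}

#' @rdname tidy.tni
#' @method glance tni
#' @export
glance.tni <- function(x, ...) {
  tibble(index = x$index, n_nutrients = x$n_nutrients, mode = x$mode)
}
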