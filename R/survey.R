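#' Balanced repeated replication standard error
#'
#' Re-evaluates a weight-dependent statistic under each replicate weight
#' column of the person table and combines the deviations with the BRR
#' formula
#' \deqn{se^2 = \frac{1}{R (1 - f)^2} \sum_{r=1}^{R} (\theta_r - \theta)^2,}
#' where \eqn{f} is the Fay coefficient (0 for classic BRR, in which each
#' replicate zeroes one half-sample and doubles the other).
#'
#' @param statistic Function taking a numeric weight vector (aligned with the
#'   rows of `persons`) and returning a scalar.
#' @param persons Person table carrying `weight` and `repw_1` ... `repw_R`
#'   columns (see [simulate_replicate_weights()]).
#' @param fay Fay coefficient in `[0, 1)` used when the replicate weights were
#'   built.
#' @return The BRR standard error (scalar).
#' @examples
#' persons <- simulate_replicate_weights(
#'   tibble::tibble(person_id = sprintf("P%02d", 1:8),
#'                  group = "snap", weight = 1),
#'   n_reps = 8
#' )
#' x <- rnorm(8)
#' brr_se(function(w) weighted.mean(x, w), persons)
#' @export
brr_se <- function(statistic, persons, fay = 0) {
  rep_cols <- replicate_weight_cols(persons)
  if (length(rep_cols) == 0) {
    abort("person table carries no replicate weight columns (repw_*).")
  }
  if (fay < 0 || fay >= 1) abort("`fay` must be in [0, 1).")
  theta <- statistic(persons$weight)
  theta_r <- purrr::map_dbl(seq_along(rep_cols), function(r) {
    out <- tryCatch(statistic(persons[[rep_cols[r]]]), error = function(e) {
      abort(paste0("statistic failed under replicate ", r, ": ",
                   conditionMessage(e)))
    })
    out
  })
  R <- length(rep_cols)
  sqrt(sum((theta_r - theta)^2) / (R * (1 - fay)^2))
}

#' z-test between two estimates
#'
#' Compares two estimates carrying standard errors with a two-sided z-test
#' assuming independence, flagging significance against a Bonferroni-adjusted
#' threshold. For baseline-versus-modeled contrasts that share persons, the
#' independence assumption is conservative when the estimates are positively
#' correlated; [compare_paired()] computes the BRR standard error of the
#' difference directly instead.
#'
#' @param e1,e2 One-row data frames (or lists) with elements `estimate` and
#'   `se`, optionally `label`.
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons the Bonferroni adjustment divides by.
#' @return A tibble with columns `label1`, `label2`, `difference`, `z`, `p`,
#'   `threshold`, `significant`.
#' @examples
#' compare_estimates(list(estimate = 10, se = 1), list(estimate = 13, se = 1))
#' @export
compare_estimates <- function(e1, e2, alpha = 0.05, m = 3) {
  v1 <- e1$estimate
  v2 <- e2$estimate
  se1 <- e1$se
  se2 <- e2$se
  if (se1 < 0 || se2 < 0) abort("standard errors must be >= 0.")
  denom <- sqrt(se1^2 + se2^2)
  if (denom == 0) {
    z <- if (v1 == v2) 0 else sign(v1 - v2) * Inf
  } else {
    z <- (v1 - v2) / denom
  }
  p <- 2 * pnorm(-abs(z))
  thr <- bonferroni_threshold(alpha, m)
  tibble(
    label1 = (e1$label %||% "estimate1")[1],
    label2 = (e2$label %||% "estimate2")[1],
    difference = v1 - v2,
    z = z,
    p = p,
    threshold = thr,
    significant = p < thr
  )
}

#' @rdname compare_estimates
#' @param f1,f2 Functions of a weight vector returning the two statistics,
#'   evaluated on the same persons (paired design); the BRR standard error of
#'   `f1 - f2` is used in the denominator.
#' @param persons Person table with replicate weights.
#' @param fay Fay coefficient of the replicate weights.
#' @export
compare_paired <- function(f1, f2, persons, fay = 0, alpha = 0.05, m = 3) {
  diff_stat <- function(w) f1(w) - f2(w)
  d <- diff_stat(persons$weight)
  se <- brr_se(diff_stat, persons, fay = fay)
  z <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else {
    d / se
  }
  p <- 2 * pnorm(-abs(z))
  thr <- bonferroni_threshold(alpha, m)
  tibble(label1 = "statistic1", label2 = "statistic2", difference = d,
         z = z, p = p, threshold = thr, significant = p < thr)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 3)  # 0.0167
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  if (!is.numeric(m) || m < 1) abort("`m` must be >= 1.")
  alpha / m
}
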