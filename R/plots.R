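#' Plot a usual-intake distribution
#'
#' Weighted density of the usual-intake draws, optionally split by group when
#' a person table is supplied.
#'
#' @param object `usual_intake_draws` from [simulate_usual_intake()].
#' @param persons Optional person table for group coloring and weights.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot usual_intake_draws
#' @export
autoplot.usual_intake_draws <- function(object, persons = NULL, ...) {
  nutrient <- attr(object, "nutrient") %||% "usual intake"
  dat <- as_tibble(object)
  if (!is.null(persons)) {
    dat <- dat |>
      inner_join(persons |> select("person_id", "group", "weight"),
                 by = "person_id")
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$usual,
                                           colour = .data$group,
                                           weight = .data$weight))
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$usual))
  }
  p +
    ggplot2::geom_density() +
    ggplot2::labs(x = paste0("usual ", nutrient, " intake (amount/day)"),
                  y = "density",
                  title = paste0("Usual ", nutrient, " intake distribution"))
}

#' Plot a total nutrient index
#'
#' Bar chart of the per-nutrient SE-weighted contributions `C_i / se_i`
#' (sign-flipped for reverse-scored nutrients), annotated with the scalar
#' index.
#'
#' @param object A `tni` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tni
#' @export
autoplot.tni <- function(object, ...) {
  dat <- object$table |>
    mutate(contribution = .data$signed_change / .data$se)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$nutrient,
                                                       .data$contribution),
                                    y = .data$contribution,
                                    fill = .data$reverse)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "SE-weighted percent change (C / se)",
      fill = "reverse scored",
      title = sprintf("Total nutrient index = %.3g", object$index)
    )
}

#' Plot dish consumption frequencies
#'
#' @param freq Frequency table from [consumption_frequency()].
#' @param top_n Categories to show per panel.
#' @return A ggplot faceted by group and occasion.
#' @export
plot_consumption_frequency <- function(freq, top_n = 8) {
  dat <- freq |>
    group_by(.data$group, .data$occasion, .data$kind) |>
    arrange(dplyr::desc(.data$pct), .by_group = TRUE) |>
    slice(seq_len(min(top_n, n()))) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pct, y = .data$category,
                                    fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(group ~ occasion) +
    ggplot2::labs(x = "% of individuals reporting the dish", y = NULL,
                  fill = "dish kind")
}
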