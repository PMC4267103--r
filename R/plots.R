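#' Plot a projection's death series
#'
#' One line per cause plus the total, over the horizon.
#'
#' @param object An `lst_projection`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lst_projection <- function(object, ...) {
  df <- bind_rows(
    object$deaths |> rename(series = "cause_id"),
    object$total_deaths |> mutate(series = "total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$deaths,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "Predicted deaths",
                  colour = NULL,
                  title = paste0("Projected deaths: ", object$scenario_name)) +
    ggplot2::theme_minimal()
}

#' Plot an observed-vs-counterfactual comparison
#'
#' Two total-death series — observed and the no-community-change
#' counterfactual; the vertical gap between them is the program's impact.
#' If the counterfactual line lies above the observed one the program is
#' saving lives, even when both series rise.
#'
#' @param object An `lst_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lst_comparison <- function(object, ...) {
  df <- bind_rows(
    object$difference |>
      select("year", deaths = "deaths_a") |>
      mutate(scenario = object$scenario_a),
    object$difference |>
      select("year", deaths = "deaths_b") |>
      mutate(scenario = object$scenario_b))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$deaths,
                                   colour = .data$scenario)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "Predicted deaths", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
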