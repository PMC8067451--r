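#' Plot PCS trajectories with fitted growth curves
#'
#' @param pcs_long Long PCS table (`species`, `ppfd`, `block`, `day`,
#'   `pcs_cm2_per_plant` or `pcs`).
#' @param fits Optional [fit_sigmoids()] result; when given, fitted daily
#'   curves are overlaid.
#' @param harvest_days Harvest days used to extend the fitted curves.
#' @return A ggplot object: one panel per PPFD, colour by species.
#' @export
plot_trajectories <- function(pcs_long, fits = NULL,
                              harvest_days = c(mizuna = 27, lettuce = 28)) {
  df <- tibble::as_tibble(pcs_long)
  if (!"pcs" %in% names(df) && "pcs_cm2_per_plant" %in% names(df)) {
    df$pcs <- df$pcs_cm2_per_plant
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(day, pcs, colour = species)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ppfd, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Days after seeding",
                  y = expression(PCS ~ (cm^2 ~ plant^-1))) +
    ggplot2::theme_bw()
  if (!is.null(fits)) {
    curves <- predict_daily_all(fits, harvest_days)
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(day, pcs, colour = species,
                   group = interaction(species, block)),
      linewidth = 0.4)
  }
  p
}

#' Plot a trait against PPFD by species
#'
#' @param traits Trait table from [compute_traits()] (or any tibble with
#'   `ppfd`, `species` and the trait column).
#' @param trait Trait column (tidy-evaluated), e.g. `lue_g_mol`.
#' @return A ggplot object.
#' @export
plot_trait_response <- function(traits, trait) {
  ggplot2::ggplot(traits,
                  ggplot2::aes(ppfd, {{ trait }}, colour = species)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = expression(PPFD ~ (mu * mol ~ m^-2 ~ s^-1))) +
    ggplot2::theme_bw()
}

#' @rdname fit_sigmoid
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(day = seq(min(object$data$day),
                                   max(object$data$day), length.out = 200))
  grid$pcs <- sigmoid(grid$day, object$a, object$x0, object$b)
  ggplot2::ggplot(object$data, ggplot2::aes(day, pcs)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Days after seeding",
                  y = expression(PCS ~ (cm^2 ~ plant^-1)),
                  title = sprintf("a = %.1f, x0 = %.1f, b = %.2f (R2 = %.4f)",
                                  object$a, object$x0, object$b,
                                  object$r_squared)) +
    ggplot2::theme_bw()
}

#' @rdname fit_species_ppfd_model
#' @export
autoplot.species_ppfd_fit <- function(object, ...) {
  if (is.null(object$model)) abort("degenerate fit has nothing to plot")
  d <- object$model$model
  names(d)[1] <- "response"
  d$fitted <- stats::fitted(object$model)
  ggplot2::ggplot(d, ggplot2::aes(ppfd, response, colour = species)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = fitted)) +
    ggplot2::labs(x = expression(PPFD ~ (mu * mol ~ m^-2 ~ s^-1)),
                  y = object$response,
                  subtitle = sprintf("interaction %s (p = %s)",
                                     if (object$interaction_dropped)
                                       "dropped" else "retained",
                                     format(object$interaction_p,
                                            digits = 3))) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
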