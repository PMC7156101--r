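#' Plot the metapopulation selection gradient against investment
#'
#' Draws [metapop_gradient()] as a function of resident investment for one
#' or both selection regimes, with the zero crossing (the ESS) marked.
#'
#' @param dist A [resource_atoms()] / [resource_density()] object.
#' @param model A [trait_model()].
#' @param regimes Character vector among `"soft"`, `"hard"`.
#' @param n Curve resolution. Default 200.
#' @return A ggplot object.
#' @export
plot_gradient <- function(dist, model, regimes = c("soft", "hard"), n = 200) {
  zmax <- model$r * dist$Rmax^model$a
  if (zmax <= 0) zmax <- 1
  grid <- tidyr::expand_grid(regime = regimes,
                             z = seq(0, zmax, length.out = n)) |>
    dplyr::group_by(.data$regime) |>
    dplyr::mutate(gradient = metapop_gradient(dist, model, .data$z,
                                              .data$regime[1])) |>
    dplyr::ungroup()
  roots <- purrr::map_dfr(regimes, function(rg) {
    fit <- ess_solve(dist, model, rg)
    tibble::tibble(regime = rg, z_star = fit$z_star)
  })
  ggplot2::ggplot(grid, ggplot2::aes(.data$z, .data$gradient,
                                     colour = .data$regime)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = roots,
                        ggplot2::aes(xintercept = .data$z_star,
                                     colour = .data$regime),
                        linetype = 3) +
    ggplot2::labs(x = "resident investment z",
                  y = "ancestry-weighted selection gradient",
                  colour = "selection") +
    ggplot2::theme_minimal()
}

#' Plot cooperator frequency trajectories
#'
#' @param frequency Output of [metapop_frequency()], optionally with extra
#'   grouping columns (e.g. `group`).
#' @param colour Optional column name (string) to colour lines by.
#' @return A ggplot object.
#' @export
plot_metapop_frequency <- function(frequency, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(.data$transfer, .data$frequency,
                 group = .data$replicate)
  } else {
    ggplot2::aes(.data$transfer, .data$frequency,
                 group = interaction(.data$replicate, .data[[colour]]),
                 colour = .data[[colour]])
  }
  ggplot2::ggplot(frequency, aes) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "transfer", y = "cooperator frequency") +
    ggplot2::theme_minimal()
}

#' Plot relative fitness by media
#'
#' Replicate-level cooperator relative fitness with group means, against the
#' neutral line `W = 1`.
#'
#' @param fitness Output of [competition_fitness()].
#' @return A ggplot object.
#' @export
plot_fitness_by_media <- function(fitness) {
  means <- fitness |>
    dplyr::group_by(.data$media) |>
    dplyr::summarise(W = mean(.data$W), .groups = "drop")
  ggplot2::ggplot(fitness, ggplot2::aes(.data$media, .data$W)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.5) +
    ggplot2::geom_point(data = means, colour = "red", size = 3, shape = 18) +
    ggplot2::labs(x = "media", y = "cooperator relative fitness W") +
    ggplot2::theme_minimal()
}
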