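#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline labs
#'   facet_wrap theme_minimal autoplot scale_y_log10
NULL

#' Plot a Start-model trajectory
#'
#' Concentration time courses (nM) of the Start-model control proteins.
#'
#' @param traj Tibble from [simulate_start()] or [simulate_multip()].
#' @return A ggplot.
#' @export
plot_start_trajectory <- function(traj) {
  d <- traj %>%
    mutate(Cln3 = number_to_concentration(.data$cln3, .data$v),
           ClbS = number_to_concentration(.data$clbs, .data$v),
           SBF = .data$sbf_nm,
           Whi5_active = number_to_concentration(.data$whi5_a, .data$v)) %>%
    select("t", "Cln3", "ClbS", "SBF", "Whi5_active") %>%
    tidyr::pivot_longer(-"t", names_to = "species", values_to = "nM")
  ggplot(d, aes(.data$t, .data$nM, colour = .data$species)) +
    geom_line() +
    labs(x = "time (min)", y = "concentration (nM)") +
    theme_minimal()
}

#' Plot a full-model trajectory
#'
#' Normalized concentrations of selected cell-cycle regulators over time.
#'
#' @param traj Trajectory tibble (e.g. attribute of [simulate_lineage()]).
#' @param species Character vector of columns to show.
#' @return A ggplot.
#' @export
plot_cellcycle_trajectory <- function(traj,
                                      species = c("cln2", "clb5", "clb2",
                                                  "cki_t", "cdh1_a",
                                                  "cdc14", "v_n")) {
  d <- traj %>%
    select("t", dplyr::all_of(species)) %>%
    tidyr::pivot_longer(-"t", names_to = "species", values_to = "value")
  ggplot(d, aes(.data$t, .data$value)) +
    geom_line() +
    facet_wrap(~species, scales = "free_y") +
    labs(x = "time (min)", y = "normalized concentration") +
    theme_minimal()
}

#' @rdname bifurcation_scan
#' @param object A `bifurcation_scan`.
#' @export
autoplot.bifurcation_scan <- function(object, ...) {
  ggplot(object, aes(.data$v, .data$clbs, group = .data$branch)) +
    geom_point() +
    geom_line() +
    scale_y_log10() +
    labs(x = "cell volume (fL)", y = "steady-state ClbS (molecules)",
         title = sprintf("folds at %.1f and %.1f fL",
                         attr(object, "fold_left"),
                         attr(object, "fold_right"))) +
    theme_minimal()
}

#' @rdname size_control_fit
#' @param object A `size_control_fit`.
#' @export
autoplot.size_control_fit <- function(object, ...) {
  g <- ggplot(object$data, aes(.data$x, .data$y)) +
    geom_point(alpha = 0.15, size = 0.5) +
    geom_point(data = object$bins, size = 2, colour = "red") +
    labs(x = expression(ln(V[birth] / bar(V)[m])),
         y = expression(mu %.% T[G1]),
         title = paste(object$role, "cells")) +
    theme_minimal()
  g
}
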