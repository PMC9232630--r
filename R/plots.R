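#' Plot island-by-swarm match proportions
#'
#' Bar chart of the proportion of island genotypes matching the swarm of
#' capture, per chromosome, faceted by species and sex, with Wilson
#' confidence whiskers — the visual summary of the perfect X association
#' and its breakdown on 2L.
#'
#' @param match_table Output of [build_match_table()].
#' @param conf_level Confidence level for the whiskers.
#' @return A ggplot object.
#' @export
plot_match_proportions <- function(match_table, conf_level = 0.95) {
  props <- match_proportions(match_table, conf_level)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$island,
                                      y = .data$prop_match)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       y = 0.05, size = 3) +
    ggplot2::facet_grid(.data$sex ~ .data$species, labeller = ggplot2::label_both) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Island of speciation",
                  y = "Proportion matching swarm type") +
    ggplot2::theme_minimal()
}

#' Plot kdr genotype frequency trajectories
#'
#' Stacked genotype frequencies (RR / RS / SS) over years per village and
#' species, tracking the sweep of the resistant allele.
#'
#' @param kdr_freqs Output of [kdr_frequencies()].
#' @return A ggplot object.
#' @export
plot_kdr_frequencies <- function(kdr_freqs) {
  long <- kdr_freqs |>
    tidyr::pivot_longer(dplyr::starts_with("freq_"), names_to = "genotype",
                        names_prefix = "freq_", values_to = "freq") |>
    dplyr::filter(.data$n > 0)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$freq,
                                     fill = .data$genotype)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$species ~ .data$village) +
    ggplot2::labs(x = "Year", y = "kdr genotype frequency",
                  fill = "kdr") +
    ggplot2::theme_minimal()
}

#' Plot 2L recovery class frequencies by year
#'
#' Frequencies of *An. coluzzii* 2L classes over time: the rise of
#' `COL_RECOVERED_2L` (coluzzii-like pericentromeric loci plus the
#' resistant kdr allele) against `GAM_LIKE_2L` signals the second sweep
#' restoring the species-specific island.
#'
#' @param recovery Output of [classify_2l_recovery()].
#' @return A ggplot object.
#' @export
plot_recovery_classes <- function(recovery) {
  d <- recovery |>
    dplyr::count(.data$village, .data$year, .data$recovery_class) |>
    dplyr::group_by(.data$village, .data$year) |>
    dplyr::mutate(freq = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$freq,
                                  fill = .data$recovery_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~village) +
    ggplot2::labs(x = "Year", y = "Frequency", fill = "2L class") +
    ggplot2::theme_minimal()
}
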