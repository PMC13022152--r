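# ggplot2 views of the main result types.

#' Plot haplotype frequencies by subpopulation
#'
#' @param freq Output of \code{\link{tabulate_frequencies}}.
#' @return A ggplot object (stacked percentage bars).
#' @export
plot_frequency_table <- function(freq) {
  grp <- setdiff(names(freq), c("label", "n", "pct"))[1]
  ggplot2::ggplot(freq, ggplot2::aes(x = .data[[grp]], y = .data$pct,
                                     fill = .data$label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "% of accessions", fill = "haplotype") +
    ggplot2::theme_minimal()
}

#' Plot per-window diversity statistics
#'
#' @param windows Output of \code{\link{window_scan}}.
#' @return A ggplot object comparing pi and Watterson's theta per window.
#' @export
plot_diversity_windows <- function(windows) {
  long <- windows |>
    select("flank", "pi", "theta_w_site") |>
    tidyr::pivot_longer(c("pi", "theta_w_site"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$flank), y = .data$value,
                                     fill = .data$statistic)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "flank (bp)", y = "per-site estimate") +
    ggplot2::theme_minimal()
}

#' Plot group means with compact letter display
#'
#' @param x A \code{group_anova} from \code{\link{anova_letters}}.
#' @return A ggplot object (bars with letters above).
#' @export
plot_anova_letters <- function(x) {
  stopifnot(inherits(x, "group_anova"))
  ggplot2::ggplot(x$letters, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letter),
                       vjust = -0.5) +
    ggplot2::labs(x = NULL, y = "group mean") +
    ggplot2::theme_minimal()
}

#' Plot a tandem-repeat comparison as a banded track
#'
#' Gained loci (present only in the accession) are drawn in red above the
#' axis, lost loci (present only in the reference) in green below, shared
#' loci in grey.
#'
#' @param cmp A \code{tr_comparison} from \code{\link{compare_trs}}.
#' @return A ggplot object.
#' @export
plot_tr_comparison <- function(cmp) {
  stopifnot(inherits(cmp, "tr_comparison"))
  bands <- bind_rows(
    if (nrow(cmp$gained) > 0)
      mutate(cmp$gained, status = "gained", y = 1, x = .data$start),
    if (nrow(cmp$lost) > 0)
      mutate(cmp$lost, status = "lost", y = -1, x = .data$start),
    if (nrow(cmp$shared) > 0)
      mutate(cmp$shared, status = "shared", y = 0, x = .data$ref_start))
  if (is.null(bands) || nrow(bands) == 0) {
    bands <- tibble(x = numeric(), y = numeric(), status = character())
  }
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$status)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = .data$y + 0.8)) +
    ggplot2::scale_colour_manual(values = c(gained = "red", lost = "darkgreen",
                                            shared = "grey50")) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the template-length distribution with the fitted model
#'
#' @param pairs Pairs tibble.
#' @param model Optional \code{insert_size_model}; fitted if omitted.
#' @return A ggplot object.
#' @export
plot_insert_sizes <- function(pairs, model = NULL) {
  model <- model %||% fit_insert_model(pairs)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$template_length)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = model$mean, colour = "blue") +
    ggplot2::geom_vline(xintercept = model$mean + 4 * model$sd,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "template length (bp)", y = "pairs") +
    ggplot2::theme_minimal()
}
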