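#' Free-energy curve across candidate state counts
#'
#' @param object an `hmm_selection`.
#' @param ... unused.
#' @return a ggplot: free energy per K with the selected K highlighted.
#' @export
autoplot.hmm_selection <- function(object, ...) {
  tab <- object$table[!is.na(object$table$free_energy), ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$n_states,
                                    y = .data$free_energy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tab[tab$n_states == object$selected_k, ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "Number of states K", y = "Variational free energy",
                  title = sprintf("Minimum free energy at K = %d",
                                  object$selected_k)) +
    ggplot2::theme_minimal()
}

#' Group differences in temporal metrics
#'
#' Point plot of patient-minus-control estimates per state, faceted by
#' metric family, solid points marking FDR-significant tests.
#'
#' @param object a `group_analysis`.
#' @param ... unused.
#' @export
autoplot.group_analysis <- function(object, ...) {
  d <- object$differences
  d$label <- ifelse(d$family == "transition",
                    paste0(d$from_state, "→", d$to_state),
                    ifelse(is.na(d$state), "all", as.character(d$state)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$estimate,
                                  alpha = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.35, `TRUE` = 1),
                                name = sprintf("p[FDR] < %g", object$alpha)) +
    ggplot2::facet_wrap(~ family, scales = "free") +
    ggplot2::labs(x = "State / transition", y = "Patient - control") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Heatmap of a state's functional-connectivity matrix
#'
#' Regions are ordered by network when a lookup is supplied, reproducing
#' the block structure emphasised in state connectivity figures.
#'
#' @param model a `vbhmm`.
#' @param state state index.
#' @param networks optional region-to-network lookup
#'   ([load_network_table()]).
#' @return a ggplot heatmap.
#' @export
plot_state_fc <- function(model, state, networks = NULL) {
  C <- state_fc_matrix(model, state)
  ord <- seq_len(ncol(C))
  if (!is.null(networks)) {
    tag <- networks$network[match(colnames(C), networks$region_label)]
    ord <- order(tag, colnames(C))
  }
  C <- C[ord, ord]
  df <- tibble::tibble(
    row = factor(rep(rownames(C), ncol(C)), levels = rownames(C)),
    col = factor(rep(colnames(C), each = nrow(C)), levels = colnames(C)),
    fc = as.vector(C))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", limits = c(-1, 1),
                                  name = "r") +
    ggplot2::labs(title = sprintf("State %d functional connectivity", state),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Activation maps of all states
#'
#' Tile plot of each state's mean activation (z-units) across regions.
#'
#' @param model a `vbhmm`.
#' @return a ggplot.
#' @export
plot_activation_maps <- function(model) {
  df <- tidy(model, "states")
  df$region <- factor(df$region, levels = model$region_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region,
                                   y = factor(.data$state),
                                   fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", name = "z") +
    ggplot2::labs(x = NULL, y = "State") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 5))
}

#' Boxplots of a temporal metric by group and state
#'
#' @param metrics tidy tibble from [temporal_metrics()].
#' @param clinical tibble with `subject_id` and `group`.
#' @param metric `"fo"`, `"lt_tr"`, `"lt_s"` or `"sr"`.
#' @return a ggplot.
#' @export
plot_metric_by_group <- function(metrics, clinical, metric = "fo") {
  d <- dplyr::left_join(metrics, clinical, by = "subject_id") |>
    dplyr::filter(.data$metric == .env$metric)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$state),
                                  y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_fill_manual(values = c(patient = "#d6604d",
                                          control = "#4393c3")) +
    ggplot2::labs(x = "State", y = metric) +
    ggplot2::theme_minimal()
}
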