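#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a co-activation solution into a per-reaction table
#'
#' @param x an `icon_solution`.
#' @param ... unused.
#' @return A tibble: reaction, net_flux, f_bound (expression-derived upper
#'   bound of the forward column), q_forward, q_backward, subsystem.
#' @export
tidy.icon_solution <- function(x, ...) {
  tpl <- x$problem$template
  bnd <- x$problem$bounds
  cols <- tpl$columns
  per_rx <- function(rx, field, dir) {
    k <- which(cols$reaction == rx &
                 cols$direction %in% dir)
    if (!length(k)) NA_real_ else field[k[1]]
  }
  ids <- tpl$base$reactions$id
  tibble::tibble(
    reaction = ids,
    net_flux = unname(x$net_flux[ids]),
    f_bound = vapply(ids, per_rx, numeric(1), field = bnd$f,
                     dir = c("irreversible", "forward", "backward")),
    q_forward = vapply(ids, per_rx, numeric(1), field = x$q,
                       dir = c("irreversible", "forward")),
    q_backward = vapply(ids, per_rx, numeric(1), field = x$q,
                        dir = "backward"),
    subsystem = tpl$base$reactions$subsystem
  )
}

#' One-row summary of a co-activation solution
#'
#' @param x an `icon_solution`.
#' @param ... unused.
#' @return A tibble: objective, biomass, z_star, alpha, n_pairs, status.
#' @export
glance.icon_solution <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, biomass = x$biomass, z_star = x$z_star,
    alpha = x$alpha, n_pairs = nrow(x$problem$pairs), status = x$status)
}

#' @rdname tidy.icon_solution
#' @export
tidy.flexibility_report <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a flexibility report
#'
#' @param x a `flexibility_report`.
#' @param ... unused.
#' @return A tibble: n_reactions, mean_F, max_F, n_rigid (F below 1e-6).
#' @export
glance.flexibility_report <- function(x, ...) {
  tibble::tibble(n_reactions = nrow(x), mean_F = mean(x$F),
                 max_F = max(x$F), n_rigid = sum(x$F < 1e-6))
}

#' Threshold-selection diagnostics plot
#'
#' Scale-free fit, mean connectivity and component count across the
#' candidate threshold grid, with the selected threshold marked.
#'
#' @param object a `coexpression_network` from [select_threshold()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coexpression_network <- function(object, ...) {
  if (is.null(object$diagnostics)) {
    stop("this network carries no threshold diagnostics")
  }
  long <- tidyr::pivot_longer(object$diagnostics,
                              c("r2", "mean_connectivity", "n_components"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "correlation threshold", y = NULL,
                  title = "Co-expression threshold diagnostics")
}

#' Flux-solution bar plot
#'
#' Net flux per reaction, colored by subsystem.
#'
#' @param object an `icon_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.icon_solution <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$reaction, y = .data$net_flux,
                                   fill = .data$subsystem)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(y = "net flux", x = NULL,
                  title = "Predicted flux distribution")
}

#' Subsystem flexibility heatmap
#'
#' @param object the normalized tibble from [subsystem_flexibility()].
#' @return A ggplot object.
#' @param ... unused.
#' @export
plot_subsystem_flexibility <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"subsystem",
                              names_to = "condition", values_to = "flexibility")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$subsystem,
                                     fill = .data$flexibility)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = "Normalized subsystem flexibility")
}
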