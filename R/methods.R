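#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("Cross-species scaling factor (%s method)\n", x$method))
  cat(sprintf("  c_opt = %.6g   objective |emp - nominal type-I| = %.4g at alpha = %g\n",
              x$c_opt, x$objective_value, x$alpha))
  if (x$method == "scbn") {
    cat(sprintf("  minimizing plateau: [%.6g, %.6g]   conserved genes: %d\n",
                x$plateau[[1]], x$plateau[[2]], x$m))
  } else {
    cat(sprintf("  conserved genes: %d (IQR-retained: %s)\n", x$m,
                x$n_iqr_retained %||% "?"))
  }
  invisible(x)
}

#' Tidy a fitted scaling factor
#'
#' @param x A `scaling_result` from [scbn_factor()] or [median_factor()].
#' @param ... Unused.
#' @return One-row tibble with `method`, `c_opt`, `objective_value`, `alpha`,
#'   the plateau bounds and the conserved-set size.
#' @export
tidy.scaling_result <- function(x, ...) {
  tibble(method = x$method, c_opt = x$c_opt,
         objective_value = x$objective_value, alpha = x$alpha,
         plateau_lo = x$plateau[[1]], plateau_hi = x$plateau[[2]], m = x$m)
}

#' @rdname tidy.scaling_result
#' @export
glance.scaling_result <- function(x, ...) {
  tidy.scaling_result(x, ...)
}

#' Tidy a pFDR estimate
#'
#' @param x A `pfdr_estimate`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.pfdr_estimate <- function(x, ...) {
  tibble(pfdr = x$value, alpha = x$alpha, prior_h0 = x$prior_h0,
         rejection_rate_h0 = x$rejection_rates[["h0"]],
         rejection_rate_h1 = x$rejection_rates[["h1"]])
}

#' Objective curve of a scaling-factor search
#'
#' Plots the type-I-error deviation against the scaling factor on a log axis,
#' with the chosen `c_opt` marked. Requires the fit to have been run with
#' `keep_grid = TRUE`.
#'
#' @param object A `scaling_result` from [scbn_factor()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_result <- function(object, ...) {
  if (is.null(object$grid)) {
    abort("no grid stored; rerun with keep_grid = TRUE",
          class = "crossnorm_domain_error")
  }
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$c, y = .data$objective,
                               colour = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$c_opt, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "scaling factor c",
                  y = sprintf("|empirical - nominal type-I error| (alpha = %g)",
                              object$alpha),
                  title = sprintf("%s search: c_opt = %.4g",
                                  object$method, object$c_opt)) +
    ggplot2::theme_minimal()
}

#' MA plot of adjusted expressions
#'
#' Scatter of per-gene adjusted M against A (see [ma_values()]) with
#' horizontal reference lines at `M = log2(c)` for one or more scaling
#' factors.
#'
#' @param tab Orthologous table.
#' @param c Named (or unnamed) numeric vector of scaling factors to draw as
#'   reference lines.
#' @param highlight Optional logical vector (aligned with `tab` rows) of genes
#'   to colour, e.g. a truth DE mask.
#' @return A ggplot object.
#' @export
plot_ma <- function(tab, c, highlight = NULL) {
  ma <- ma_values(tab, c[[1]])
  if (!is.null(highlight)) {
    key <- tibble(gene_id = tab$gene_id, highlight = highlight)
    ma <- dplyr::left_join(ma, key, by = "gene_id")
  } else {
    ma$highlight <- FALSE
  }
  lines <- tibble(method = names(c) %||% paste0("c", seq_along(c)),
                  M = log2(unname(c)))
  ggplot2::ggplot(ma, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlight),
                        size = 0.3, alpha = 0.4, show.legend = !is.null(highlight)) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$M,
                                     linetype = .data$method)) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40", "TRUE" = "red")) +
    ggplot2::labs(x = "A (mean log2 adjusted expression)",
                  y = "M (log2 adjusted ratio, species 1 / species 2)") +
    ggplot2::theme_minimal()
}

#' Metric curves of a replicated study
#'
#' Plots the mean of a chosen metric against the swept parameter, one line per
#' normalization method.
#'
#' @param object A `study_result` from [run_study()].
#' @param metric One of `"precision"`, `"sensitivity"`, `"fscore"`,
#'   `"fd_number"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, metric = "precision", ...) {
  metric <- match.arg(metric, c("precision", "sensitivity", "fscore",
                                "fd_number"))
  sm <- study_summary(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$sweep_value,
                                   y = .data[[metric]],
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(sm$sweep_param), y = metric) +
    ggplot2::theme_minimal()
}
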