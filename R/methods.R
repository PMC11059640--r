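#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the scalar trace of an MCMC run
#'
#' @param x A `cn_mcmc` object.
#' @param ... Unused.
#' @return A tibble, one row per logged state.
#' @export
tidy.cn_mcmc <- function(x, ...) x$trace

#' One-row summary of an MCMC run
#'
#' @param x A `cn_mcmc` object.
#' @param ... Unused.
#' @return A tibble with chain length, number of logged states, overall
#'   acceptance rate, and the final log posterior.
#' @export
glance.cn_mcmc <- function(x, ...) {
  acc <- sum(x$acceptance$accepted)
  tot <- acc + sum(x$acceptance$rejected)
  tibble::tibble(chain_length = x$config$chain_length,
                 n_logged = nrow(x$trace),
                 acceptance_rate = if (tot > 0) acc / tot else NA_real_,
                 final_log_posterior = utils::tail(x$trace$log_posterior, 1),
                 seed = x$seed)
}

#' Trace plot of an MCMC run
#'
#' Faceted trace of log posterior and the main scalar parameters.
#'
#' @param object A `cn_mcmc` object.
#' @param parameters Trace columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_mcmc <- function(object,
                             parameters = c("log_posterior", "d", "sigma",
                                            "root_height"), ...) {
  df <- object$trace |>
    dplyr::select(dplyr::all_of(c("iteration", parameters))) |>
    tidyr::pivot_longer(-"iteration", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' Branch-recovery plot by branch-length decile
#'
#' @param tpr Output of [branch_tpr_by_decile()].
#' @return A ggplot object.
#' @export
plot_branch_tpr <- function(tpr) {
  ggplot2::ggplot(tpr, ggplot2::aes(x = .data$decile, y = .data$recovery)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "true branch-length decile",
                  y = "branch recovery rate") +
    ggplot2::theme_minimal()
}

#' Copy-number profile heatmap
#'
#' @param x A [cn_profiles()] object or matrix.
#' @return A ggplot object.
#' @export
plot_profiles <- function(x) {
  values <- if (inherits(x, "cn_profiles")) x$values else x
  df <- tibble::as_tibble(values, rownames = "cell", .name_repair = "minimal")
  names(df)[-1] <- as.character(seq_len(ncol(values)))
  df <- tidyr::pivot_longer(df, -"cell", names_to = "bin",
                            values_to = "copy_number")
  df$bin <- as.integer(df$bin)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$cell,
                                   fill = .data$copy_number)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 2, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "genomic bin", y = NULL, fill = "CN") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
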