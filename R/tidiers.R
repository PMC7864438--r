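#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mini-batch k-means fit
#'
#' One row per cluster: its 1-based id, member count, within-cluster sum of
#' squares, and the fraction of the total WCSS it contributes.
#'
#' @param x an `mbk_fit` from [fit_minibatch()].
#' @param ... unused.
#' @return a tibble with columns `cluster`, `size`, `wcss`, `wcss_frac`.
#' @method tidy mbk_fit
#' @export
tidy.mbk_fit <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$cluster_sizes),
    size = x$cluster_sizes,
    wcss = x$wcss_per_cluster,
    wcss_frac = if (x$wcss_total > 0) x$wcss_per_cluster / x$wcss_total
                else rep(0, length(x$wcss_per_cluster))
  )
}

#' Glance at a mini-batch k-means fit
#'
#' @param x an `mbk_fit` from [fit_minibatch()].
#' @param ... unused.
#' @return a one-row tibble: `k`, `n_obs`, `n_feat`, `b`, `n_iter`,
#'   `converged`, `final_shift`, `wcss_total`, `backend`.
#' @method glance mbk_fit
#' @export
glance.mbk_fit <- function(x, ...) {
  tibble::tibble(
    k = x$config$k,
    n_obs = x$config$n_obs,
    n_feat = x$config$n_feat,
    b = x$config$b,
    n_iter = x$n_iter,
    converged = x$converged,
    final_shift = tail(x$shift_trace, 1L),
    wcss_total = x$wcss_total,
    backend = x$config$backend
  )
}

#' Convergence trace plot for a mini-batch k-means fit
#'
#' Plots the Frobenius centroid shift per iteration on a log scale, with
#' the convergence threshold as a horizontal reference line.
#'
#' @param fit an `mbk_fit` from [fit_minibatch()].
#' @return a ggplot object.
#' @export
plot_convergence <- function(fit) {
  stopifnot(inherits(fit, "mbk_fit"))
  df <- data.frame(iteration = seq_along(fit$shift_trace),
                   shift = fit$shift_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$shift)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = fit$config$tol, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration",
                  y = expression("centroid shift" ~
                                   group("||", hat(mu)^{(t)} -
                                           hat(mu)^{(t - 1)}, "||")[2]),
                  title = sprintf("Mini-batch k-means convergence (k = %d)",
                                  fit$config$k)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_convergence
#' @param object an `mbk_fit`.
#' @param ... unused.
#' @method autoplot mbk_fit
#' @export
autoplot.mbk_fit <- function(object, ...) plot_convergence(object)

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
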