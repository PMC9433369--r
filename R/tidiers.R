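# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted factor model
#'
#' One row per variable x factor, with the loading; communalities and
#' diagonal variances are repeated per variable for convenience.
#'
#' @param x a `compfa_fit`.
#' @param ... unused.
#' @return A tibble with columns `variable`, `factor`, `loading`,
#'   `communality`, `diag_var`, `error_variance`.
#' @export
tidy.compfa_fit <- function(x, ...) {
  L <- x$loadings
  p <- nrow(L)
  m <- ncol(L)
  vars <- rownames(L)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  ev <- if (is.null(x$error_cov)) rep(NA_real_, p) else diag(x$error_cov)
  tibble::tibble(
    variable = rep(vars, m),
    factor = rep(paste0("F", seq_len(m)), each = p),
    loading = as.vector(L),
    communality = rep(communalities(L), m),
    diag_var = rep(x$diag_var, m),
    error_variance = rep(ev, m)
  )
}

#' One-row summary of a fitted factor model
#'
#' @param x a `compfa_fit`.
#' @param ... unused.
#' @return A tibble with `method`, `p`, `m`, `loss`, `iters`, `converged`,
#'   `proper`.
#' @method glance compfa_fit
#' @export
glance.compfa_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    p = nrow(x$loadings),
    m = ncol(x$loadings),
    loss = x$loss,
    iters = x$iters,
    converged = x$converged,
    proper = x$proper
  )
}

#' @method tidy mrfa_fit
#' @export
tidy.mrfa_fit <- function(x, ...) {
  tibble::tibble(
    variable = paste0("V", seq_along(x$theta2)),
    theta2 = x$theta2
  )
}

#' @method glance mrfa_fit
#' @export
glance.mrfa_fit <- function(x, ...) {
  tibble::tibble(
    m = x$m, objective = x$objective, iters = x$iters,
    converged = x$converged
  )
}

#' Loading heatmap for a fitted factor model
#'
#' @param object a `compfa_fit`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot compfa_fit
#' @export
autoplot.compfa_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$factor, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1) *
                                    max(abs(td$loading), 1)) +
    ggplot2::labs(title = paste(object$method, "loadings"),
                  x = NULL, y = NULL)
}

#' Recovery summary plot for a simulation grid
#'
#' Mean recovery error (MAD) per procedure and reference matrix, faceted by
#' error level.
#'
#' @param object a `compfa_grid`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot compfa_grid
#' @export
autoplot.compfa_grid <- function(object, ...) {
  long <- object$results |>
    dplyr::filter(.data$method %in% c("LVFA-ML", "MDFA", "CDFA")) |>
    tidyr::pivot_longer(c("mad_lambda", "mad_theta2", "mad_theta2_dee"),
                        names_to = "matrix", values_to = "mad") |>
    dplyr::group_by(.data$method, .data$matrix, .data$error_level) |>
    dplyr::summarise(mean_mad = mean(.data$mad), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$matrix, y = .data$mean_mad,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~error_level) +
    ggplot2::labs(x = NULL, y = "mean MAD", fill = NULL)
}

#' @importFrom rlang .data
NULL
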