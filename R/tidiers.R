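#' Tidy a sweep fit into a parameter table
#'
#' One row per identified parameter.  For the parameter-scaling norm the
#' per-test absolute linear parameters \eqn{x_i = x^*/\beta_i} are included,
#' keyed by test.
#'
#' @param x A `laos_fit` from [sweep_fit()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and (for per-test
#'   parameters) `test`.
#' @method tidy laos_fit
#' @export
tidy.laos_fit <- function(x, ...) {
  global <- tibble::tibble(
    term = c("alpha", if (!is.na(x$b)) "b",
             if (x$norm == "scaling") paste0(names(x$x_star), "_star")
             else names(x$x)),
    estimate = c(x$alpha, if (!is.na(x$b)) x$b,
                 if (x$norm == "scaling") unname(x$x_star) else unname(x$x)),
    test = NA_integer_
  )
  if (x$norm != "scaling") return(global[, c("term", "estimate", "test")])
  test_id <- if ("test" %in% names(x$tests)) x$tests$test else seq_len(x$n_tests)
  per_test <- dplyr::bind_rows(
    tibble::tibble(term = "beta", estimate = x$beta, test = test_id),
    dplyr::bind_rows(lapply(rownames(x$x_tests), function(nm) {
      tibble::tibble(term = nm, estimate = x$x_tests[nm, ], test = test_id)
    }))
  )
  dplyr::bind_rows(global, per_test)
}

#' One-row summary of a sweep fit
#'
#' @inheritParams tidy.laos_fit
#' @return A one-row tibble: model, norm, argmin `alpha` and `b`, percent
#'   `error`, `iterations` at the argmin, number of tests and grid size.
#' @method glance laos_fit
#' @export
glance.laos_fit <- function(x, ...) {
  tibble::tibble(model = x$model, norm = x$norm, alpha = x$alpha, b = x$b,
                 error = x$error, iterations = x$iterations,
                 n_tests = x$n_tests, n_grid = nrow(x$surface),
                 converged = x$converged %||% TRUE)
}

#' Per-point data with fitted torque attached
#'
#' Rebuilds, for every test, the fitted torque at the argmin node (using the
#' per-test parameters under the scaling norm, the shared ones otherwise)
#' and returns it alongside the observed torque.
#'
#' @inheritParams tidy.laos_fit
#' @return A tibble with columns `test`, `point`, `torque` and `.fitted`
#'   plus the test metadata.
#' @method augment laos_fit
#' @export
augment.laos_fit <- function(x, ...) {
  test_id <- if ("test" %in% names(x$tests)) x$tests$test else seq_len(x$n_tests)
  dplyr::bind_rows(lapply(seq_len(x$n_tests), function(i) {
    xi <- if (x$norm == "scaling") x$x_tests[, i] else x$x
    Ai <- x$A_blocks[[i]]
    meta <- x$tests[i, , drop = FALSE]
    tibble::tibble(meta,
                   point = seq_len(nrow(Ai)),
                   torque = x$b_blocks[[i]],
                   .fitted = as.numeric(Ai %*% xi))
  }))
}

#' Plot methods for fits and traces
#'
#' `autoplot.laos_fit()` draws either the sweep error surface (`"surface"`:
#' percent error against the fractional order, one line per nonlinear power
#' `b`, argmin highlighted) or the data-model overlay (`"fit"`: observed and
#' fitted torque per test).  `autoplot.torque_trace()` draws the Lissajous
#' curve (torque against imposed angle), the standard way of reading
#' nonlinearity and hysteresis off an oscillatory test.
#'
#' @param object A `laos_fit` or `torque_trace`.
#' @param type `"surface"` or `"fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot laos_fit
#' @export
autoplot.laos_fit <- function(object, type = c("surface", "fit"), ...) {
  type <- match.arg(type)
  if (type == "surface") {
    surf <- dplyr::mutate(object$surface,
                          b_label = ifelse(is.na(.data$b), "-",
                                           format(.data$b)))
    ggplot2::ggplot(surf, ggplot2::aes(x = .data$alpha, y = .data$error,
                                       colour = .data$b_label)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::annotate("point", x = object$alpha, y = object$error,
                        size = 3, shape = 1, stroke = 1.2) +
      ggplot2::labs(x = "fractional order α", y = "error (%)",
                    colour = "b",
                    title = sprintf("%s model, %s norm", object$model,
                                    object$norm)) +
      ggplot2::theme_minimal()
  } else {
    aug <- augment(object)
    ggplot2::ggplot(aug, ggplot2::aes(x = .data$point)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$torque), colour = "grey40") +
      ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red",
                         linetype = "dashed") +
      ggplot2::facet_wrap(~test, scales = "free_y") +
      ggplot2::labs(x = "sample", y = "torque (N m)") +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.laos_fit
#' @method autoplot torque_trace
#' @export
autoplot.torque_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$angle, y = .data$tau)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "angular displacement (rad)", y = "torque (N m)") +
    ggplot2::theme_minimal()
}

#' Lissajous curves of a dataset
#'
#' Torque against imposed angle for every test of a dataset, faceted by
#' compression and frequency and coloured by shear amplitude.
#'
#' @param dataset A `laos_dataset`.
#' @return A ggplot object.
#' @export
plot_lissajous <- function(dataset) {
  d <- tidyr::unnest(tibble::as_tibble(dataset), "trace")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$angle, y = .data$torque,
                                  colour = factor(.data$shear_percent))) +
    ggplot2::geom_path() +
    ggplot2::facet_grid(cs_percent ~ freq_hz, labeller = ggplot2::label_both,
                        scales = "free_y") +
    ggplot2::labs(x = "angular displacement (rad)", y = "torque (N m)",
                  colour = "shear (%)") +
    ggplot2::theme_minimal()
}
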