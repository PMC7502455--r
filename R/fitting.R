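#' Nonnegative linear least squares
#'
#' Solves \eqn{\min_{x \ge 0} \|A x - b\|_2}.  The linear material scales
#' (`C_lin`, `delta`) live on the nonnegative orthant, so every norm in the
#' fitting engine solves its linear subproblem in this constrained form.
#' Thin wrapper around an active-set NNLS solver.
#'
#' @param A Design matrix (rows = data points, columns = unit-parameter
#'   torque components).
#' @param b Data vector.
#' @return Numeric vector `x >= 0`.
#' @export
solve_linear_nonneg <- function(A, b) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  if (length(b) == 0L || nrow(A) == 0L || ncol(A) == 0L) {
    abort("empty linear system")
  }
  stopifnot(nrow(A) == length(b))
  as.numeric(pracma::lsqnonneg(A, b)$x)
}

#' Relative L2 fitting error
#'
#' \eqn{J_{lsq} = \|A x - b\|_2 / \|b\|_2}, reported in percent: 0\% for a
#' perfect fit and exactly 100\% when the linear parameters are zero.  This
#' norm weights every residual equally in absolute terms, so tests with
#' larger torque amplitudes dominate it.
#'
#' @inheritParams solve_linear_nonneg
#' @param x Linear parameter vector.
#' @return Percent error (scalar).
#' @export
norm_l2 <- function(A, x, b) {
  A <- as.matrix(A)
  r <- A %*% x - b
  100 * sqrt(sum(r^2)) / sqrt(sum(b^2))
}

.pw_tol <- function(b_i, tol = NULL) tol %||% (1e-3 * max(abs(b_i)))

#' Point-wise scaled fitting error
#'
#' Each residual is scaled by the magnitude of its own data point,
#' \eqn{(a; b)_{pw} = \sum_k (a_k / \max(tol, |b_k|))^2}, and the error is
#' \deqn{J_{pw} = \sqrt{\sum_i (A_i x - b_i; b_i)_{pw}} \; / \;
#'   \sqrt{\sum_i (b_i; b_i)_{pw}},}
#' in percent.  Every point carries equal weight regardless of amplitude, so
#' curve shapes are matched even for the small-torque tests.  The guard
#' `tol` (default `1e-3 * max(abs(b_i))` per test) keeps near-zero-crossing
#' points from dominating.
#'
#' @param A_blocks List of per-test design matrices.
#' @param x Linear parameter vector.
#' @param b_blocks List of per-test data vectors.
#' @param tol Positive scalar guard, or `NULL` for the per-test default.
#' @return Percent error (scalar).
#' @export
norm_pointwise <- function(A_blocks, x, b_blocks, tol = NULL) {
  stopifnot(is.list(A_blocks), is.list(b_blocks),
            length(A_blocks) == length(b_blocks))
  if (!is.null(tol) && tol <= 0) abort("`tol` must be positive.")
  num <- den <- 0
  for (i in seq_along(A_blocks)) {
    bi <- as.numeric(b_blocks[[i]])
    sc <- pmax(.pw_tol(bi, tol), abs(bi))
    ri <- as.matrix(A_blocks[[i]]) %*% x - bi
    num <- num + sum((ri / sc)^2)
    den <- den + sum((bi / sc)^2)
  }
  100 * sqrt(num / den)
}

# Weighted NNLS solve of the point-wise objective.
.solve_pointwise <- function(A_blocks, b_blocks, tol = NULL) {
  W <- unlist(lapply(b_blocks, function(bi) {
    1 / pmax(.pw_tol(as.numeric(bi), tol), abs(as.numeric(bi)))
  }))
  A <- do.call(rbind, lapply(A_blocks, as.matrix))
  b <- unlist(lapply(b_blocks, as.numeric))
  solve_linear_nonneg(A * W, b * W)
}

#' Parameter-scaling fit of shared shape with per-test amplitudes
#'
#' Implements the alternating fit behind the parameter-scaling norm: the
#' nonlinear parameters (fixed upstream by the sweep) and a single set of
#' normalised linear parameters \eqn{x^*} are shared by all tests, while a
#' positive per-test scaling \eqn{\beta_i} absorbs amplitude variability
#' (sample location, strain softening).  The absolute per-test parameters
#' are \eqn{x_i = x^* / \beta_i}.
#'
#' Each test's block is first normalised by \eqn{n_i \|\tau_i^d\|_2}
#' (\eqn{n_i} = points in test \eqn{i}).  Starting from \eqn{\beta_i = 1},
#' the algorithm alternates (a) a stacked nonnegative least-squares solve
#' for \eqn{x^*} with the \eqn{\beta_i} fixed and (b) the per-test
#' closed-form update \eqn{\beta_i = (b_i^{*T} A_i^* x^*) / (b_i^{*T}
#' b_i^*)}, until the error
#' \deqn{J_{sc} = \sqrt{\textstyle\sum_i \|A_i^* x^* / \beta_i -
#'   b_i^*\|_2^2} \; / \; \|b^*\|_2}
#' (percent) changes by less than `tol_rel` in relative terms, or
#' `max_iter` alternations.  The reported gauge is fixed by rescaling so
#' that `mean(beta) = 1`; the absolute \eqn{x_i} are gauge-invariant.
#'
#' @param A_blocks List of per-test design matrices (unit-parameter torque
#'   columns).
#' @param b_blocks List of per-test data vectors.
#' @param tol_rel Relative convergence tolerance on the error (default
#'   1e-10).
#' @param max_iter Maximum alternations (default 200).
#' @return A list of class `scaling_fit`: `x_star`, `beta`, `x_tests`
#'   (matrix, one column per test, \eqn{x_i = x^*/\beta_i}), `error`
#'   (percent), `iterations`, `converged`, `error_path`.
#' @export
fit_parameter_scaling <- function(A_blocks, b_blocks,
                                  tol_rel = 1e-10, max_iter = 200) {
  stopifnot(is.list(A_blocks), is.list(b_blocks),
            length(A_blocks) == length(b_blocks), length(A_blocks) >= 1L)
  N <- length(A_blocks)
  As <- lapply(A_blocks, as.matrix)
  bs <- lapply(b_blocks, as.numeric)
  norms <- vapply(bs, function(bi) sqrt(sum(bi^2)), numeric(1))
  if (any(norms == 0)) {
    abort("a test has an all-zero data block; its scaling beta_i is undefined")
  }
  n_i <- vapply(bs, length, integer(1))
  As <- Map(function(Ai, ni, nb) Ai / (ni * nb), As, n_i, norms)
  bs <- Map(function(bi, ni, nb) bi / (ni * nb), bs, n_i, norms)
  b_norm <- sqrt(sum(unlist(bs)^2))
  beta <- rep(1, N)
  err <- function(x_star, beta) {
    r2 <- sum(vapply(seq_len(N), function(i) {
      sum((As[[i]] %*% x_star / beta[i] - bs[[i]])^2)
    }, numeric(1)))
    100 * sqrt(r2) / b_norm
  }
  J_prev <- Inf
  path <- numeric(0)
  x_star <- rep(0, ncol(As[[1]]))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    A_stack <- do.call(rbind, Map(function(Ai, bi_) Ai / bi_, As, beta))
    x_star <- solve_linear_nonneg(A_stack, unlist(bs))
    beta_new <- vapply(seq_len(N), function(i) {
      mod <- As[[i]] %*% x_star
      sum(bs[[i]] * mod) / sum(bs[[i]]^2)
    }, numeric(1))
    # beta must stay positive; an anti-correlated (degenerate) block is
    # pinned just above zero so its absolute parameters blow up visibly
    # rather than flipping sign.
    beta <- pmax(beta_new, .Machine$double.eps)
    J <- err(x_star, beta)
    path <- c(path, J)
    if (is.finite(J_prev) && abs(J_prev - J) <= tol_rel * max(J_prev, .Machine$double.eps)) {
      converged <- TRUE
      J_prev <- J
      break
    }
    J_prev <- J
  }
  gauge <- mean(beta)
  beta <- beta / gauge
  x_star <- x_star / gauge
  x_tests <- vapply(beta, function(bi_) x_star / bi_, numeric(length(x_star)))
  x_tests <- matrix(x_tests, nrow = length(x_star))
  structure(
    list(x_star = x_star, beta = beta, x_tests = x_tests,
         error = J_prev, iterations = iter, converged = converged,
         error_path = path),
    class = "scaling_fit"
  )
}

#' Default sweep grid for the fractional order
#'
#' The fractional order is swept from 0.05 to 1 in steps of 0.05 (covering
#' the whole elastic-to-viscous spectrum), refined to steps of 0.01 on
#' \[0.15, 0.40\], the range reported for soft tissue in multi-frequency
#' rheometry.
#'
#' @return Sorted numeric vector of alpha values.
#' @export
default_alpha_grid <- function() {
  sort(unique(round(c(seq(0.05, 1, by = 0.05), seq(0.15, 0.40, by = 0.01)), 10)))
}

#' Default sweep grid for the nonlinear power
#'
#' The focused ranges used for parameter isolation: `b` in \[1, 14\] with
#' step 0.5 for the Ogden model and \[1, 1.5\] with step 0.1 for the
#' exponential model (wider coarse ranges, \[0.1, 14\] and \[0.1, 3\], are
#' useful for trend exploration and can be passed explicitly to
#' [sweep_fit()]).  The modified Mooney-Rivlin model has no `b`, encoded as
#' a single `NA`.
#'
#' @param model Model name (`"vmr"`, `"vog"`, `"vexp"`).
#' @return Numeric vector of b values (or `NA` for `"vmr"`).
#' @export
default_b_grid <- function(model) {
  switch(tolower(model),
         vmr = NA_real_,
         vog = seq(1, 14, by = 0.5),
         vexp = round(seq(1, 1.5, by = 0.1), 10),
         abort(sprintf("unknown model '%s'; available models are 'vmr', 'vog', 'vexp'", model)))
}

#' Sweep-fit a fractional viscoelastic model to a torque dataset
#'
#' Identifies material parameters by an exhaustive sweep over the nonlinear
#' parameters: for every node \eqn{(\alpha, b)} of the grid, the forward
#' model is run at unit linear parameters for each test of the dataset, the
#' per-test unit-torque columns are assembled into a block design system,
#' the linear parameters are solved by nonnegative least squares under the
#' chosen norm, and the node is scored.  The reported fit is the grid
#' argmin (ties broken toward the smallest `alpha`, then smallest `b`).
#'
#' Under `norm = "scaling"` the linear parameters float per test through
#' the scalings \eqn{\beta_i} (see [fit_parameter_scaling()]); under
#' `"l2"` and `"pointwise"` a single linear parameter set is shared by all
#' tests in the dataset.
#'
#' @param dataset A `laos_dataset` from [generate_dataset()] /
#'   [read_dataset()], or any tibble with columns `test`, `cs_percent`,
#'   `shear_percent`, `freq_hz`, `height_m`, `radius_m`,
#'   `points_per_period`, `n_burnin`, `n_record` and a `trace` list-column
#'   of tibbles holding a `torque` column for the recorded window.
#' @param model Model name (`"vmr"`, `"vog"`, `"vexp"`).
#' @param norm One of `"l2"`, `"pointwise"`, `"scaling"`.
#' @param alpha_grid,b_grid Sweep grids (defaults: [default_alpha_grid()],
#'   [default_b_grid()]).
#' @param mesh Optional surface mesh passed to the forward model.
#' @param tol Point-wise norm guard (see [norm_pointwise()]).
#' @return An object of class `laos_fit`: list with the argmin `alpha`,
#'   `b`, `error` (percent), linear parameters (`x` for global norms;
#'   `x_star`, `beta` and per-test `x_tests` for the scaling norm), the
#'   full error `surface` (tibble with one row per grid node), fitted
#'   per-test torque columns at the argmin, and the call configuration.
#' @examples
#' \donttest{
#' ds <- generate_dataset(
#'   material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3),
#'   protocol = default_protocol(points_per_period = 100)[1:3, ],
#'   noise_sd = 0, seed = 1)
#' fit <- sweep_fit(ds, "vexp", "l2", alpha_grid = c(0.15, 0.2, 0.25),
#'                  b_grid = c(1.2, 1.3, 1.4))
#' glance(fit)
#' }
#' @export
sweep_fit <- function(dataset, model, norm = c("l2", "pointwise", "scaling"),
                      alpha_grid = default_alpha_grid(),
                      b_grid = default_b_grid(model),
                      mesh = NULL, tol = NULL) {
  model <- tolower(model)
  norm <- match.arg(norm)
  if (length(alpha_grid) == 0L || length(b_grid) == 0L) abort("empty sweep grid")
  tests <- .dataset_tests(dataset)
  b_data <- lapply(tests, function(ti) ti$torque)

  eval_node <- function(hists, alpha) {
    A_blocks <- lapply(hists, function(h) {
      comp <- .torque_components(h, alpha)
      rec <- h$recorded
      if (is.null(comp$tau_e)) {
        matrix(comp$tau_v[rec], ncol = 1,
               dimnames = list(NULL, "tau_v"))
      } else {
        cbind(tau_e = comp$tau_e[rec], tau_v = comp$tau_v[rec])
      }
    })
    A <- do.call(rbind, A_blocks)
    bb <- unlist(b_data)
    if (norm == "l2") {
      x <- solve_linear_nonneg(A, bb)
      list(error = norm_l2(A, x, bb), x = x, iterations = 1L,
           A_blocks = A_blocks)
    } else if (norm == "pointwise") {
      x <- .solve_pointwise(A_blocks, b_data, tol)
      list(error = norm_pointwise(A_blocks, x, b_data, tol), x = x,
           iterations = 1L, A_blocks = A_blocks)
    } else {
      sc <- fit_parameter_scaling(A_blocks, b_data)
      list(error = sc$error, x = sc$x_star, scaling = sc,
           iterations = sc$iterations, A_blocks = A_blocks)
    }
  }

  rows <- list()
  best <- NULL
  for (bv in b_grid) {
    hists <- lapply(tests, function(ti) {
      .torque_histories(model, bv, ti$cond, mesh)
    })
    for (av in alpha_grid) {
      node <- eval_node(hists, av)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        alpha = av, b = bv, error = node$error,
        iterations = node$iterations)
      better <- is.null(best) || node$error < best$error ||
        (node$error == best$error &&
           (av < best$alpha || (av == best$alpha && isTRUE(bv < best$b))))
      if (better) {
        best <- c(list(alpha = av, b = bv), node)
      }
    }
  }
  surface <- dplyr::bind_rows(rows)

  d <- tibble::as_tibble(dataset)
  meta <- d[, intersect(c("test", "cs_percent", "shear_percent", "freq_hz"), names(d))]
  fit <- list(
    model = model, norm = norm, alpha = best$alpha, b = best$b,
    error = best$error, x = best$x,
    iterations = best$iterations, surface = surface,
    alpha_grid = alpha_grid, b_grid = b_grid,
    A_blocks = best$A_blocks, b_blocks = b_data, tests = meta,
    n_tests = length(tests), tol = tol
  )
  if (norm == "scaling") {
    sc <- best$scaling
    fit$x_star <- sc$x_star
    fit$beta <- sc$beta
    fit$x_tests <- sc$x_tests
    fit$converged <- sc$converged
  }
  param_names <- if (model == "vmr") c("C_lin", "delta") else "delta"
  names(fit$x) <- param_names
  if (!is.null(fit$x_star)) {
    names(fit$x_star) <- param_names
    rownames(fit$x_tests) <- param_names
  }
  structure(fit, class = "laos_fit")
}

# Normalise a dataset into a list of per-test lists (cond + recorded torque).
.dataset_tests <- function(dataset) {
  d <- tibble::as_tibble(dataset)
  need <- c("cs_percent", "shear_percent", "freq_hz", "height_m", "radius_m",
            "points_per_period", "n_burnin", "n_record", "trace")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  lapply(seq_len(nrow(d)), function(i) {
    geo <- sample_geometry(d$height_m[i], d$radius_m[i], d$cs_percent[i] / 100)
    cond <- test_condition(geo, d$shear_percent[i] / 100, d$freq_hz[i],
                           d$points_per_period[i], d$n_burnin[i], d$n_record[i])
    tr <- d$trace[[i]]
    torque <- if ("torque" %in% names(tr)) tr$torque else tr$tau
    list(cond = cond, torque = as.numeric(torque))
  })
}

#' @export
print.laos_fit <- function(x, ...) {
  cat(sprintf("<laos_fit> model %s, %s norm: error %.4g%% at alpha = %.3g",
              x$model, x$norm, x$error, x$alpha))
  if (!is.na(x$b)) cat(sprintf(", b = %.3g", x$b))
  cat("\n")
  if (x$norm == "scaling") {
    cat(sprintf("  shared x* = (%s) Pa; per-test beta in [%.3g, %.3g]\n",
                paste(signif(x$x_star, 4), collapse = ", "),
                min(x$beta), max(x$beta)))
  } else {
    cat(sprintf("  linear parameters: (%s) Pa\n",
                paste(signif(x$x, 4), collapse = ", ")))
  }
  invisible(x)
}
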