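#' Write / read a torque trace as CSV with a JSON metadata sidecar
#'
#' Traces are stored as plain CSV with exactly the columns `time_s`,
#' `angle_rad`, `torque_Nm` (full double precision), and a sidecar JSON file
#' (`<path>.json`) holding the mandatory test metadata: `cs_percent`,
#' `shear_percent`, `freq_hz`, `height_m`, `radius_m`, `points_per_period`,
#' `n_burnin`, `n_record`.  Reading validates the column set, time
#' monotonicity and the metadata keys, and restores the trace together with
#' its [test_condition()].  Round trips are lossless.
#'
#' @param trace A tibble with columns `time`, `angle` and `torque` (or a
#'   `torque_trace` from [simulate_test()], whose `tau` column is stored as
#'   the torque).
#' @param cond The [test_condition()] of the trace (taken from the trace
#'   attribute if omitted).
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a tibble (`time`, `angle`, `torque`) with the condition in
#'   `attr(, "condition")`.
#' @export
write_trace <- function(trace, path, cond = attr(trace, "condition")) {
  if (is.null(cond)) abort("no test condition supplied or attached to the trace")
  stopifnot(inherits(cond, "test_condition"))
  torque <- if ("torque" %in% names(trace)) trace$torque else trace$tau
  df <- data.frame(time_s = sprintf("%.17g", trace$time),
                   angle_rad = sprintf("%.17g", trace$angle),
                   torque_Nm = sprintf("%.17g", torque))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  g <- cond$geometry
  meta <- list(cs_percent = 100 * g$cs, shear_percent = 100 * cond$gamma,
               freq_hz = cond$freq, height_m = g$H, radius_m = g$R,
               points_per_period = cond$points_per_period,
               n_burnin = cond$n_burnin, n_record = cond$n_record)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such trace file: %s", path))
  df <- utils::read.csv(path, blank.lines.skip = TRUE)
  need <- c("time_s", "angle_rad", "torque_Nm")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(sprintf("trace file %s is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    abort(sprintf("trace file %s has non-monotone time_s", path))
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    abort(sprintf("metadata sidecar %s not found", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  need_meta <- c("cs_percent", "shear_percent", "freq_hz", "height_m",
                 "radius_m", "points_per_period", "n_burnin", "n_record")
  missing <- setdiff(need_meta, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("metadata sidecar %s is missing key(s): %s",
                  meta_path, paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(time = df$time_s, angle = df$angle_rad,
                        torque = df$torque_Nm)
  attr(out, "condition") <- test_condition(
    sample_geometry(meta$height_m, meta$radius_m, meta$cs_percent / 100),
    meta$shear_percent / 100, meta$freq_hz, meta$points_per_period,
    meta$n_burnin, meta$n_record)
  out
}

#' Write / read a full dataset as a directory of trace files
#'
#' One `test_<k>.csv` (plus JSON sidecar) per test and a `manifest.json`
#' carrying the protocol table and, for synthetic datasets, the
#' ground-truth manifest.
#'
#' @param dataset A `laos_dataset` (see [generate_dataset()]).
#' @param dir Directory path (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `laos_dataset` tibble usable by [sweep_fit()].
#' @export
write_dataset <- function(dataset, dir) {
  d <- tibble::as_tibble(dataset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  conds <- protocol_conditions(d)
  for (i in seq_len(nrow(d))) {
    write_trace(d$trace[[i]],
                file.path(dir, sprintf("test_%02d.csv", d$test[i])),
                cond = conds[[i]])
  }
  manifest <- list(
    protocol = d[, setdiff(names(d), "trace")],
    ground_truth = attr(dataset, "manifest")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) abort(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  p <- tibble::as_tibble(manifest$protocol)
  traces <- lapply(p$test, function(k) {
    tr <- read_trace(file.path(dir, sprintf("test_%02d.csv", k)))
    tibble::as_tibble(tr)
  })
  out <- dplyr::mutate(p, trace = traces)
  class(out) <- c("laos_dataset", class(out))
  attr(out, "manifest") <- manifest$ground_truth
  out
}

#' Write a structured fit report
#'
#' Serialises a [sweep_fit()] result as a self-describing JSON document:
#' model, norm, sweep grids, argmin node, linear parameters (global, or
#' shared-plus-scalings with per-test absolutes), error, iteration counts,
#' the full error surface and the package version.  Re-running the fit on
#' the same inputs reproduces the report exactly (the pipeline is
#' deterministic).
#'
#' @param fit A `laos_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "laos_fit"))
  rep_ <- list(
    software = paste0("laosfit ", as.character(utils::packageVersion("laosfit"))),
    model = fit$model, norm = fit$norm,
    grid = list(alpha = fit$alpha_grid, b = fit$b_grid),
    argmin = list(alpha = fit$alpha, b = fit$b),
    error_percent = fit$error,
    iterations = fit$iterations,
    n_tests = fit$n_tests,
    linear_parameters = as.list(fit$x),
    surface = fit$surface
  )
  if (fit$norm == "scaling") {
    rep_$linear_parameters <- list(
      x_star = as.list(fit$x_star),
      beta = fit$beta,
      per_test = as.data.frame(t(fit$x_tests))
    )
    rep_$converged <- fit$converged
  }
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
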