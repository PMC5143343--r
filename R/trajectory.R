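# Developmental trajectories: second-order polynomial fits of a network
# metric against age, per group, fit descriptively (no between-group test).

#' Fit quadratic developmental trajectories per group
#'
#' Least-squares fit of `value = b0 + b1 * age + b2 * age^2` separately for
#' each group. Fits are to individual subject points by default; with
#' `on_means = TRUE` each (group, age) cell is first collapsed to its mean,
#' in which case three distinct ages give an exact interpolation of the
#' three cell means.
#'
#' @param ages numeric ages (years, as recorded).
#' @param values numeric metric values.
#' @param groups group labels, same length.
#' @param on_means fit on per-(group, age) cell means instead of subjects.
#' @param metric optional metric name carried into the result.
#' @return Object of class `trajectory_fits`: named list of per-group
#'   `trajectory_fit` objects (fields `coefficients` (b0, b1, b2),
#'   `resid_sd`, `n`, `group`, `metric`).
#' @export
fit_quadratic_per_group <- function(ages, values, groups, on_means = FALSE,
                                    metric = NULL) {
  if (!(length(ages) == length(values) && length(values) == length(groups)))
    stop("ages, values and groups must have equal length")
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- groups == g & is.finite(ages) & is.finite(values)
    a <- ages[sel]; v <- values[sel]
    if (on_means) {
      cells <- split(v, a)
      a <- as.numeric(names(cells))
      v <- vapply(cells, mean, numeric(1))
    }
    if (length(unique(a)) < 3)
      stop(sprintf("group '%s' has fewer than 3 distinct ages", g))
    X <- cbind(1, a, a^2)
    fit <- lm.fit(X, v)
    rdf <- length(v) - 3
    out[[g]] <- structure(
      list(coefficients = setNames(fit$coefficients, c("b0", "b1", "b2")),
           resid_sd = if (rdf > 0) sqrt(sum(fit$residuals^2) / rdf) else 0,
           n = length(v), group = g, metric = metric),
      class = "trajectory_fit")
  }
  structure(out, class = "trajectory_fits")
}

#' Evaluate a fitted trajectory on an age grid
#'
#' @param fit a `trajectory_fit`.
#' @param ages numeric age grid.
#' @return Numeric vector of the same length as `ages`.
#' @export
evaluate_trajectory <- function(fit, ages) {
  stopifnot(inherits(fit, "trajectory_fit"))
  b <- fit$coefficients
  b[1] + b[2] * ages + b[3] * ages^2
}

#' @export
coef.trajectory_fit <- function(object, ...) object$coefficients

#' @export
predict.trajectory_fit <- function(object, newdata = NULL, ...) {
  ages <- if (is.null(newdata)) stop("supply `newdata` with an `age` column")
          else if (is.data.frame(newdata)) newdata$age else newdata
  evaluate_trajectory(object, ages)
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit>%s group %s: %.4g %+.4g*age %+.4g*age^2 (n = %d, resid SD %.3g)\n",
              if (is.null(x$metric)) "" else paste0(" ", x$metric),
              x$group, x$coefficients[1], x$coefficients[2],
              x$coefficients[3], x$n, x$resid_sd))
  invisible(x)
}

#' @export
print.trajectory_fits <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}

#' @export
coef.trajectory_fits <- function(object, ...) {
  do.call(rbind, lapply(object, coef))
}

#' @export
plot.trajectory_fits <- function(x, ages = NULL, ...) {
  if (is.null(ages)) ages <- seq(0.5, 11, by = 0.1)
  curves <- lapply(x, evaluate_trajectory, ages = ages)
  ylim <- range(unlist(curves))
  graphics::plot(range(ages), ylim, type = "n", xlab = "age (years)",
                 ylab = if (!is.null(x[[1]]$metric)) x[[1]]$metric
                        else "metric", ...)
  lt <- 1
  for (g in names(x)) {
    graphics::lines(ages, curves[[g]], lty = lt)
    lt <- lt + 1
  }
  graphics::legend("topright", legend = names(x), lty = seq_along(x),
                   bty = "n")
  invisible(x)
}

#' Trajectory fit table for export
#'
#' @param fits a `trajectory_fits` object (or list of them).
#' @return data frame with columns `metric`, `group`, `b0`, `b1`, `b2`,
#'   `resid_sd`, `n`.
#' @export
trajectory_table <- function(fits) {
  if (inherits(fits, "trajectory_fits")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(fs)
    do.call(rbind, lapply(fs, function(f)
      data.frame(metric = if (is.null(f$metric)) NA_character_ else f$metric,
                 group = f$group, b0 = f$coefficients[1],
                 b1 = f$coefficients[2], b2 = f$coefficients[3],
                 resid_sd = f$resid_sd, n = f$n,
                 row.names = NULL, stringsAsFactors = FALSE)))))
}
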