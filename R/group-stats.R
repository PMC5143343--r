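# Case-control statistics: covariate-adjusted group comparisons via ordinary
# least squares, age residualization, and partial correlations with
# confounders. Mirroring the analysis design, no multiple-comparison
# correction is applied; raw p-values are always reported.

#' Build the covariate design matrix for a group comparison
#'
#' Columns: intercept, group indicator (IUGR = 1), gender indicator,
#' maternal education (ordinal numeric), gestational age at birth, and age —
#' age at MR scan for network-metric responses, age at test for
#' neuropsychological-score responses. Rows with missing covariates are
#' dropped (listwise deletion) with a message.
#'
#' @param records data frame with columns `group`, `gender`, `maternal_edu`,
#'   `ga_weeks` and `age_scan`/`age_test` (e.g. from [cohort_metadata()]).
#' @param response_kind `"metric"` (age at scan) or `"score"` (age at test).
#' @return Numeric matrix with named columns and attributes `kept` (row
#'   indices of `records` retained) and `response_kind`.
#' @export
build_design_matrix <- function(records,
                                response_kind = c("metric", "score")) {
  response_kind <- match.arg(response_kind)
  age_col <- if (response_kind == "metric") "age_scan" else "age_test"
  need <- c("group", "gender", "maternal_edu", "ga_weeks", age_col)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "))
  if (!all(records$group %in% c("control", "IUGR", NA)))
    stop("`group` values must be 'control' or 'IUGR'")
  X <- cbind(intercept = 1,
             group = as.numeric(records$group == "IUGR"),
             gender = as.numeric(records$gender),
             maternal_edu = as.numeric(records$maternal_edu),
             ga = as.numeric(records$ga_weeks),
             age = as.numeric(records[[age_col]]))
  keep <- stats::complete.cases(X)
  if (any(!keep))
    message(sum(!keep), " record(s) dropped for missing covariates")
  X <- X[keep, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  attr(X, "kept") <- which(keep)
  attr(X, "response_kind") <- response_kind
  X
}

#' Covariate-adjusted group comparison by ordinary least squares
#'
#' Fits `values ~ design` by OLS and reports the group-indicator
#' coefficient with its standard error and two-sided t-test p-value. With a
#' design containing only intercept and group this reproduces the classical
#' pooled-variance two-sample t-test exactly.
#'
#' @param values numeric response (metric or score), one per design row.
#' @param design matrix from [build_design_matrix()], or any numeric design
#'   with a column named `group`.
#' @param name optional label for the response.
#' @return An object of class `group_comparison`: list with `name`,
#'   `estimate` (adjusted group effect, IUGR minus control), `se`, `p`,
#'   `df`, `n`, `n_per_group` and `covariates`.
#' @export
glm_group_compare <- function(values, design, name = NULL) {
  if (!is.matrix(design) || !"group" %in% colnames(design))
    stop("`design` must be a matrix with a 'group' column")
  if (length(values) != nrow(design))
    stop("`values` length must match design rows")
  ok <- is.finite(values)
  values <- values[ok]; design <- design[ok, , drop = FALSE]
  n <- nrow(design); p <- ncol(design)
  if (n <= p) stop("need more observations than design columns")
  fit <- lm.fit(design, values)
  if (fit$rank < p) stop("singular normal equations; cannot estimate")
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - p)
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  se_all <- sqrt(sigma2 * diag(XtXinv))
  j <- match("group", colnames(design))
  est <- fit$coefficients[j]
  se <- se_all[j]
  tval <- est / se
  structure(list(name = name,
                 estimate = unname(est), se = unname(se),
                 t = unname(tval),
                 p = unname(2 * pt(abs(tval), n - p, lower.tail = FALSE)),
                 df = n - p, n = n,
                 n_per_group = c(control = sum(design[, j] == 0),
                                 IUGR = sum(design[, j] == 1)),
                 covariates = setdiff(colnames(design),
                                      c("intercept", "group"))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s effect %.4g (SE %.3g), t(%d) = %.3f, p = %.4g\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$estimate, x$se, x$df, x$t, x$p))
  invisible(x)
}

#' Residualize values on age
#'
#' OLS regression of `values` on (intercept, age); returns the residuals,
#' which sum to zero and are orthogonal to age. Used to correct network
#' metrics by age at scan and scores by age at test before correlating them.
#'
#' @param values numeric vector (>= 3 finite values).
#' @param ages numeric vector, non-constant, same length.
#' @return Numeric residual vector.
#' @export
residualize_by_age <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch")
  if (sum(is.finite(values) & is.finite(ages)) < 3)
    stop("need at least 3 complete observations")
  if (var(ages) == 0) stop("ages are constant; age effect is inestimable")
  unname(resid(lm.fit(cbind(1, ages), values)))
}

#' Partial correlation with confounders
#'
#' Pearson correlation between the residuals of `x` and `y` after each is
#' regressed on (intercept + confounders). The p-value comes from
#' `t = rho * sqrt(df / (1 - rho^2))` with `df = n - 2 - k` confounders,
#' two-sided.
#'
#' @param x,y numeric vectors.
#' @param confounders numeric matrix or data frame (0 columns allowed, in
#'   which case this is the plain Pearson correlation).
#' @param names optional character pair labeling x and y.
#' @return An object of class `partial_correlation`: list with `rho`, `p`,
#'   `df`, `n`, `confounders` (column names) and `names`.
#' @export
partial_correlation <- function(x, y, confounders = NULL, names = NULL) {
  if (is.null(confounders)) {
    C <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    C <- as.matrix(confounders)
  }
  if (length(x) != length(y) || nrow(C) != length(x))
    stop("x, y and confounders must have matching lengths")
  ok <- is.finite(x) & is.finite(y) &
    (if (ncol(C)) apply(is.finite(C), 1, all) else TRUE)
  x <- x[ok]; y <- y[ok]; C <- C[ok, , drop = FALSE]
  n <- length(x); k <- ncol(C)
  if (n <= k + 2) stop("need n > number of confounders + 2")
  X <- cbind(1, C)
  rx <- resid(lm.fit(X, x))
  ry <- resid(lm.fit(X, y))
  # tolerance relative to the input scale: a constant (or confounder-
  # determined) variable leaves only rounding noise in its residuals
  near_zero <- function(r, orig)
    sd(r) <= 1e-10 * max(1, abs(mean(orig)), sd(orig))
  if (near_zero(rx, x) || near_zero(ry, y))
    stop("zero-variance residuals; partial correlation undefined")
  rho <- cor(rx, ry)
  df <- n - 2 - k
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt(df / (1 - rho^2))
    2 * pt(abs(tval), df, lower.tail = FALSE)
  }
  structure(list(rho = unname(rho), p = p, df = df, n = n,
                 confounders = colnames(C), names = names),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  lab <- if (is.null(x$names)) "" else paste0(" ", paste(x$names, collapse = " ~ "))
  cat(sprintf("<partial_correlation>%s rho = %.4f, df = %d, p = %.4g\n",
              lab, x$rho, x$df, x$p))
  invisible(x)
}

#' Run the full case-control analysis battery
#'
#' For one cohort (one age): a covariate-adjusted group comparison per
#' network metric (age-at-scan covariate) and per score (age-at-test
#' covariate), and an age-residualized partial correlation for each
#' requested (metric, score) pair with gender, gestational age, maternal
#' education and group as confounders. Raw p-values are always retained;
#' `significant` flags p < `alpha` and `trend` flags p < `trend_alpha`.
#'
#' @param records metadata data frame (see [build_design_matrix()]) with a
#'   `subject_id` column.
#' @param metrics metric table keyed by `subject_id`.
#' @param scores optional score table keyed by `subject_id`.
#' @param pairs optional 2-column data frame / matrix of (metric, score)
#'   pairs to correlate; default all combinations.
#' @param alpha significance level (default 0.05).
#' @param trend_alpha trend-reporting level (default 0.1).
#' @return List of class `battery_result` with data frames `comparisons`
#'   (name, kind, estimate, se, p, df, n, significant, trend) and
#'   `correlations` (metric, score, rho, p, df, n, significant, trend), plus
#'   `n_join_failures`.
#' @export
run_case_control_battery <- function(records, metrics, scores = NULL,
                                     pairs = NULL, alpha = 0.05,
                                     trend_alpha = 0.1) {
  stopifnot("subject_id" %in% names(records),
            "subject_id" %in% names(metrics))
  dat <- merge(records, metrics, by = "subject_id", sort = FALSE)
  n_fail <- nrow(records) - nrow(dat)
  if (!is.null(scores)) {
    stopifnot("subject_id" %in% names(scores))
    dat <- merge(dat, scores, by = "subject_id", sort = FALSE)
  }
  if (n_fail > 0)
    message(n_fail, " subject(s) dropped: no matching metric row")
  metric_cols <- setdiff(names(metrics), "subject_id")
  score_cols <- if (is.null(scores)) character(0)
                else setdiff(names(scores), "subject_id")

  one_cmp <- function(col, kind) {
    X <- build_design_matrix(dat, response_kind = kind)
    v <- dat[[col]][attr(X, "kept")]
    cmp <- glm_group_compare(v, X, name = col)
    data.frame(name = col, kind = kind, estimate = cmp$estimate,
               se = cmp$se, p = cmp$p, df = cmp$df, n = cmp$n,
               significant = cmp$p < alpha, trend = cmp$p < trend_alpha,
               stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, c(
    lapply(metric_cols, one_cmp, kind = "metric"),
    lapply(score_cols, function(cl)
      if (all(is.na(dat[[cl]]))) NULL else one_cmp(cl, "score"))))

  correlations <- NULL
  if (length(score_cols)) {
    if (is.null(pairs))
      pairs <- expand.grid(metric = metric_cols, score = score_cols,
                           stringsAsFactors = FALSE)
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    conf <- cbind(gender = as.numeric(dat$gender),
                  ga = as.numeric(dat$ga_weeks),
                  maternal_edu = as.numeric(dat$maternal_edu),
                  group = as.numeric(dat$group == "IUGR"))
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      mcol <- pairs[i, 1]; scol <- pairs[i, 2]
      if (all(is.na(dat[[scol]]))) return(NULL)
      ok <- is.finite(dat[[mcol]]) & is.finite(dat[[scol]])
      if (sum(ok) < ncol(conf) + 3) return(NULL)
      mres <- residualize_by_age(dat[[mcol]][ok], dat$age_scan[ok])
      sres <- residualize_by_age(dat[[scol]][ok], dat$age_test[ok])
      pc <- partial_correlation(mres, sres, conf[ok, , drop = FALSE],
                                names = c(mcol, scol))
      data.frame(metric = mcol, score = scol, rho = pc$rho, p = pc$p,
                 df = pc$df, n = pc$n, significant = pc$p < alpha,
                 trend = pc$p < trend_alpha, stringsAsFactors = FALSE)
    })
    correlations <- do.call(rbind, rows)
  }
  structure(list(comparisons = comparisons, correlations = correlations,
                 n_join_failures = n_fail, alpha = alpha,
                 trend_alpha = trend_alpha),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat("<battery_result>\n")
  cat(sprintf("  %d comparison(s), %d significant at alpha = %g\n",
              NROW(x$comparisons), sum(x$comparisons$significant), x$alpha))
  if (!is.null(x$correlations))
    cat(sprintf("  %d correlation(s), %d significant\n",
                nrow(x$correlations), sum(x$correlations$significant)))
  invisible(x)
}
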