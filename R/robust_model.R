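# Robust MM-regression of amphibian onset on plant onset (+ MAT), with
# influence diagnostics, multicollinearity checks, leave-one-out
# cross-validation, null-model comparison and lag forecasts.
#
# The estimator is the MM type: a high-breakdown S-estimate of residual
# scale followed by a redescending bisquare M-step tuned to 95% Gaussian
# efficiency (c = 4.685), as provided by MASS::rlm(method = "MM"). The
# S-stage subsampling is run under a fixed, documented seed so fits are
# reproducible; coefficient covariance is the robust sandwich form from
# summary.rlm (stddev^2 * cov.unscaled).

MM_SEED_DEFAULT <- 20211103L

#' Specify a prediction model
#'
#' @param response amphibian species (response variable).
#' @param predictors character vector of one or at most two plant
#'   phenophase onset variables.
#' @param include_mat include the scalar MAT covariate.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response, predictors, include_mat = TRUE) {
  predictors <- as.character(predictors)
  if (length(predictors) < 1 || length(predictors) > 2) {
    stop("models take one or at most two plant predictors", call. = FALSE)
  }
  if (anyDuplicated(predictors)) stop("duplicated predictor", call. = FALSE)
  structure(list(response = response, predictors = predictors,
                 include_mat = isTRUE(include_mat)),
            class = "model_spec")
}

# Map a spec onto the columns actually present in `data`. pair_series()
# output uses generic names (amphibian_doy / plant_doy); model_table()
# output uses taxon names.
resolve_model_frame <- function(spec, data) {
  data <- as.data.frame(data)
  resp <- if (spec$response %in% names(data)) spec$response
          else if ("amphibian_doy" %in% names(data)) "amphibian_doy"
          else stop("response column '", spec$response, "' not found",
                    call. = FALSE)
  preds <- spec$predictors
  if (!all(preds %in% names(data))) {
    if (length(preds) == 1 && "plant_doy" %in% names(data)) {
      preds <- "plant_doy"
    } else {
      stop("predictor column(s) not found: ",
           paste(setdiff(preds, names(data)), collapse = ", "),
           call. = FALSE)
    }
  }
  rhs <- preds
  mat_col <- NULL
  if (spec$include_mat) {
    mat_col <- if ("mat" %in% names(data)) "mat"
               else if ("mat_covariate" %in% names(data)) "mat_covariate"
               else stop("include_mat = TRUE but no mat column", call. = FALSE)
    rhs <- c(rhs, mat_col)
  }
  df <- data[, c(resp, rhs), drop = FALSE]
  df <- df[complete.cases(df), , drop = FALSE]
  list(df = df, response = resp, predictors = preds, mat_col = mat_col,
       formula = reformulate(rhs, response = resp))
}

with_fixed_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

# MM fit with an exact-fit shortcut: when least squares already
# interpolates the data (zero residuals) the S-scale is 0 and IRLS cannot
# iterate, so the least-squares fit -- to which the MM estimator degenerates
# -- is returned directly.
fit_mm <- function(formula, df, seed = MM_SEED_DEFAULT, maxit = 200) {
  ols <- lm(formula, data = df)
  tol <- 1e-8 * (1 + max(abs(stats::fitted(ols))))
  if (max(abs(stats::residuals(ols))) < tol) return(ols)
  rf <- with_fixed_seed(seed,
    MASS::rlm(formula, data = df, method = "MM",
              psi = MASS::psi.bisquare, c = 4.685, maxit = maxit))
  # Integer-rounded onsets can put > 50% of the rows exactly on one line,
  # collapsing the S-scale to machine zero and degenerating the M-step
  # weights; the remaining deviations are rounding noise, not outliers,
  # so least squares is the appropriate fit in that regime.
  if (rf$s < 1e-6 * (1 + stats::sd(df[[all.vars(formula)[1]]]))) {
    return(ols)
  }
  rf
}

robust_adj_r2 <- function(y, fitted, w, p) {
  n <- length(y)
  ybar <- sum(w * y) / sum(w)
  sse <- sum(w * (y - fitted)^2)
  sst <- sum(w * (y - ybar)^2)
  if (sst <= 0) return(NA_real_)
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p)
}

#' Fit a robust MM-regression
#'
#' Fits amphibian onset day-of-year on plant onset (one or two plant
#' predictors) plus optionally the MAT covariate, with the
#' 95%-efficiency bisquare MM estimator. The fit is deterministic given
#' `seed` (which drives only the S-stage subsampling). Leave-one-out
#' RMSE and a robust weighted adjusted R^2 are computed alongside.
#'
#' @param spec a [model_spec()].
#' @param data paired table from [pair_series()] or [model_table()].
#' @param seed subsampling seed for the S-stage.
#' @param maxit IRLS iteration cap.
#' @return object of class `robust_fit`: coefficients, robust `scale`
#'   (days), per-observation `weights` in \[0, 1\], `cov` (coefficient
#'   covariance), coefficient table `coef_table` (estimate, se, t, p),
#'   `adj_r2`, `rmse_loocv` (days), `n`, and the model frame.
#' @export
fit_robust <- function(spec, data, seed = MM_SEED_DEFAULT, maxit = 200) {
  stopifnot(inherits(spec, "model_spec"))
  rs <- resolve_model_frame(spec, data)
  df <- rs$df
  n <- nrow(df)
  rhs <- attr(stats::terms(rs$formula), "term.labels")
  min_n <- length(spec$predictors) + 3 + as.integer(spec$include_mat)
  if (n < min_n) {
    stop("insufficient data: ", n, " rows, need at least ", min_n,
         call. = FALSE)
  }
  novar <- rhs[vapply(rhs, function(v) sd(df[[v]]) == 0, logical(1))]
  if (length(novar) > 0) {
    stop("predictor(s) with zero variance: ", paste(novar, collapse = ", "),
         call. = FALSE)
  }
  X <- model.matrix(rs$formula, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- fit_mm(rs$formula, df, seed = seed, maxit = maxit)
  if (inherits(fit, "rlm")) {
    sm <- summary(fit, method = "XtWX")
    covm <- sm$stddev^2 * sm$cov.unscaled
    scale_est <- fit$s
    wts <- fit$w
    converged <- fit$converged
  } else {
    # least-squares branch (exact interpolation or collapsed S-scale):
    # classical covariance, unit weights; zero matrix when the fit is exact
    scale_est <- suppressWarnings(summary(fit)$sigma)
    if (!is.finite(scale_est) ||
        scale_est < 1e-10 * (1 + mean(abs(df[[rs$response]])))) {
      scale_est <- 0
    }
    covm <- if (scale_est == 0) {
      matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
    } else {
      suppressWarnings(stats::vcov(fit))
    }
    wts <- rep(1, n)
    converged <- TRUE
  }
  beta <- coef(fit)
  se <- sqrt(diag(covm))
  p_mm <- length(beta)
  tval <- beta / se
  coef_table <- tibble::tibble(
    term = names(beta), estimate = unname(beta), se = unname(se),
    t = unname(tval), p_value = unname(2 * pt(-abs(tval), df = n - p_mm)))
  out <- structure(list(
    spec = spec, formula = rs$formula, data = tibble::as_tibble(df),
    response = rs$response, predictors = rs$predictors,
    mat_col = rs$mat_col, coefficients = beta, cov = covm,
    coef_table = coef_table, scale = scale_est, weights = wts,
    fitted = unname(fit$fitted.values), residuals = unname(fit$residuals),
    n = n, df_residual = n - p_mm, seed = seed,
    converged = converged,
    adj_r2 = robust_adj_r2(df[[rs$response]], fit$fitted.values, wts,
                           p_mm),
    plant_range = range(df[[rs$predictors[1]]]),
    mat_default = if (!is.null(rs$mat_col)) mean(df[[rs$mat_col]]) else NULL
  ), class = "robust_fit")
  out$rmse_loocv <- loocv_rmse(spec, data, engine = "mm", seed = seed)
  out
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("Robust MM-regression: %s (n = %d)\n",
              deparse(x$formula), x$n))
  print(as.data.frame(x$coef_table), row.names = FALSE, digits = 4)
  cat(sprintf("robust scale = %.2f days, adj R^2 = %.3f, LOOCV RMSE = %.2f days\n",
              x$scale, x$adj_r2, x$rmse_loocv))
  invisible(x)
}

#' Cook's distance and leverage flags
#'
#' Classical Cook's distance for every observation of a fitted model,
#' computed from the least-squares hat matrix of the same design (unit
#' weights by default: the robust fit's own weights would hide exactly
#' the influential points the diagnostic exists to surface). Rows with
#' D > 4/n are flagged for scrutiny, never dropped.
#'
#' @param fit a `robust_fit`.
#' @param weights "unit" (classical OLS Cook's D, default) or "robust"
#'   (weighted by the MM fit's final weights).
#' @return tibble (`row`, `leverage`, `cooks_d`, `flagged`) with the
#'   4/n threshold as attribute `threshold`.
#' @export
cooks_leverage <- function(fit, weights = c("unit", "robust")) {
  weights <- match.arg(weights)
  stopifnot(inherits(fit, "robust_fit"))
  df <- as.data.frame(fit$data)
  X <- model.matrix(fit$formula, df)
  y <- df[[fit$response]]
  w <- if (weights == "unit") rep(1, nrow(X)) else fit$weights
  sw <- sqrt(w)
  Xw <- X * sw
  XtXinv <- chol2inv(chol(crossprod(Xw)))
  h <- unname(rowSums((Xw %*% XtXinv) * Xw))
  betaw <- XtXinv %*% crossprod(Xw, y * sw)
  e <- unname(y - as.vector(X %*% betaw))
  p <- ncol(X)
  n <- nrow(X)
  s2 <- sum(w * e^2) / (n - p)
  d <- if (s2 < 1e-12) rep(0, n) else w * e^2 * h / (p * s2 * (1 - h)^2)
  thr <- 4 / n
  out <- tibble::tibble(row = seq_len(n), leverage = h, cooks_d = d,
                        flagged = d > thr)
  attr(out, "threshold") <- thr
  out
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' right-hand-side variables (plant predictors plus MAT when included).
#' A single predictor has VIF 1 by definition; perfect collinearity is
#' reported as `Inf`. Values above 10 are flagged.
#'
#' @param data paired/model table.
#' @param spec a [model_spec()]; or pass a `robust_fit` as `data` alone.
#' @return named numeric vector of VIFs with logical attribute `flagged`.
#' @export
vif <- function(data, spec = NULL) {
  if (inherits(data, "robust_fit")) {
    spec <- data$spec
    data <- data$data
  }
  stopifnot(inherits(spec, "model_spec"))
  rs <- resolve_model_frame(spec, data)
  rhs <- attr(stats::terms(rs$formula), "term.labels")
  if (length(rhs) < 2) {
    out <- setNames(rep(1, length(rhs)), rhs)
    attr(out, "flagged") <- setNames(rep(FALSE, length(rhs)), rhs)
    return(out)
  }
  out <- vapply(rhs, function(v) {
    r2 <- suppressWarnings(
      summary(lm(reformulate(setdiff(rhs, v), response = v),
                 data = rs$df))$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  attr(out, "flagged") <- out > 10
  out
}

#' Leave-one-out cross-validated RMSE
#'
#' Refits the model on every n-1 subset and predicts the held-out row;
#' the RMSE over all n out-of-sample predictions measures predictive
#' performance. A fold whose refit fails is skipped with a warning and
#' counted in the `folds_skipped` attribute. `engine = "ols"` uses plain
#' least squares (in which limit the summed squared LOOCV errors equal
#' the hat-matrix PRESS statistic exactly).
#'
#' @param spec a [model_spec()].
#' @param data paired/model table.
#' @param engine "mm" (robust, default) or "ols".
#' @param seed S-stage subsampling seed (per refit).
#' @return RMSE in days, with attribute `folds_skipped`.
#' @export
loocv_rmse <- function(spec, data, engine = c("mm", "ols"),
                       seed = MM_SEED_DEFAULT) {
  engine <- match.arg(engine)
  stopifnot(inherits(spec, "model_spec"))
  rs <- resolve_model_frame(spec, data)
  df <- rs$df
  n <- nrow(df)
  min_n <- length(spec$predictors) + 4 + as.integer(spec$include_mat)
  if (n < min_n) {
    stop("insufficient data for LOOCV: ", n, " rows, need at least ",
         min_n, call. = FALSE)
  }
  errs <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    train <- df[-i, , drop = FALSE]
    pred <- tryCatch({
      f <- if (engine == "mm") fit_mm(rs$formula, train, seed = seed)
           else lm(rs$formula, data = train)
      predict(f, newdata = df[i, , drop = FALSE])
    }, error = function(e) NA_real_)
    if (is.na(pred)) skipped <- skipped + 1L
    errs[i] <- pred - df[[rs$response]][i]
  }
  if (skipped > 0) {
    warning(skipped, " LOOCV fold(s) skipped after refit failure")
  }
  out <- sqrt(mean(errs^2, na.rm = TRUE))
  attr(out, "folds_skipped") <- skipped
  out
}

#' Compare a model to the intercept-only null
#'
#' The null model is an intercept-only robust location fit (no
#' predictors). Both models are scored by LOOCV RMSE and adjusted R^2
#' (the null's adjusted R^2 is 0 by construction).
#'
#' @param spec a [model_spec()].
#' @param data paired/model table.
#' @param seed S-stage subsampling seed.
#' @return list of class `model_comparison`: `table` (one row per model)
#'   and `rmse_improvement` (null - model, days).
#' @export
compare_to_null <- function(spec, data, seed = MM_SEED_DEFAULT) {
  fit <- fit_robust(spec, data, seed = seed)
  rs <- resolve_model_frame(spec, data)
  df <- rs$df
  y <- df[[rs$response]]
  n <- length(y)
  null_formula <- reformulate("1", response = rs$response)
  null_errs <- vapply(seq_len(n), function(i) {
    f <- fit_mm(null_formula, df[-i, , drop = FALSE], seed = seed)
    unname(coef(f)[1]) - y[i]
  }, numeric(1))
  null_rmse <- sqrt(mean(null_errs^2))
  tab <- tibble::tibble(
    model = c(paste(deparse(fit$formula), collapse = ""), "null (intercept only)"),
    rmse_loocv = c(fit$rmse_loocv, null_rmse),
    adj_r2 = c(fit$adj_r2, 0)
  )
  structure(list(table = tab, fit = fit,
                 rmse_improvement = null_rmse - fit$rmse_loocv),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model vs intercept-only null (LOOCV RMSE in days):\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  cat(sprintf("RMSE improvement over null: %.2f days\n",
              x$rmse_improvement))
  invisible(x)
}

#' Predict migration onset and lag from a plant onset
#'
#' Point prediction from the fitted linear predictor at the given plant
#' day of year (and MAT), with a 95% interval. The default interval is
#' the confidence interval of the conditional mean, from the coefficient
#' covariance and the t quantile with n - p degrees of freedom;
#' `interval = "prediction"` adds the robust residual scale for a new
#' single year. The lag is the prediction minus the plant day; integer
#' summaries round half away from zero while the real values are kept.
#'
#' @param fit a `robust_fit` with exactly one plant predictor.
#' @param plant_doy numeric vector of plant onset days (1-366).
#' @param mat MAT covariate: numeric, a region name ("cool", "moderate",
#'   "warm", mapped to its band midpoint), or NULL for the fit's sample
#'   mean. Ignored when the model has no MAT term.
#' @param interval "confidence" (mean CI, default) or "prediction".
#' @param level interval level.
#' @return tibble: `plant_doy`, `mat`, `predicted_amphibian_doy`,
#'   `lag_days`, `ci95_low`, `ci95_high` (lag scale), plus rounded
#'   integer columns `lag_days_int`, `ci95_low_int`, `ci95_high_int`. A
#'   plant day more than 15 days outside the fitted range triggers an
#'   extrapolation warning, recorded in the `extrapolated` column.
#' @export
predict_onset <- function(fit, plant_doy, mat = NULL,
                          interval = c("confidence", "prediction"),
                          level = 0.95) {
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "robust_fit"))
  if (length(fit$predictors) != 1) {
    stop("lag prediction is defined for single-plant models; ",
         "predict with a full newdata row instead", call. = FALSE)
  }
  if (any(plant_doy < 1 | plant_doy > 366)) {
    stop("plant_doy must be in [1, 366]", call. = FALSE)
  }
  has_mat <- !is.null(fit$mat_col)
  if (has_mat) {
    if (is.null(mat)) {
      mat <- fit$mat_default
    } else if (is.character(mat)) {
      mat <- region_mat_midpoint(mat)
    }
    mat <- rep_len(mat, length(plant_doy))
  } else {
    mat <- rep(NA_real_, length(plant_doy))
  }
  nd <- data.frame(plant_doy)
  names(nd) <- fit$predictors
  if (has_mat) nd[[fit$mat_col]] <- mat
  X0 <- model.matrix(stats::delete.response(stats::terms(fit$formula)), nd)
  pred <- as.vector(X0 %*% fit$coefficients)
  se <- sqrt(rowSums((X0 %*% fit$cov) * X0))
  if (interval == "prediction") se <- sqrt(se^2 + fit$scale^2)
  tq <- qt(1 - (1 - level) / 2, df = fit$df_residual)
  lag <- pred - plant_doy
  lo <- lag - tq * se
  hi <- lag + tq * se
  extrap <- plant_doy < fit$plant_range[1] - 15 |
    plant_doy > fit$plant_range[2] + 15
  if (any(extrap)) {
    warning("prediction(s) extrapolate > 15 days outside the fitted ",
            "plant-onset range [", round(fit$plant_range[1]), ", ",
            round(fit$plant_range[2]), "]")
  }
  tibble::tibble(
    plant_doy = plant_doy, mat = mat,
    predicted_amphibian_doy = pred, lag_days = lag,
    ci95_low = lo, ci95_high = hi,
    lag_days_int = as.integer(round_half_away(lag)),
    ci95_low_int = as.integer(round_half_away(lo)),
    ci95_high_int = as.integer(round_half_away(hi)),
    extrapolated = extrap
  )
}

#' Lag lookup table over a range of plant onsets
#'
#' Convenience wrapper around [predict_onset()] for the forecast table a
#' field volunteer would use (plant day 50-90 in steps of 5 by default).
#'
#' @param fit a `robust_fit`.
#' @param plant_doys plant onset days to tabulate.
#' @param mat see [predict_onset()].
#' @return tibble as from [predict_onset()].
#' @export
lag_table <- function(fit, plant_doys = seq(50, 90, by = 5), mat = NULL) {
  suppressWarnings(predict_onset(fit, plant_doys, mat = mat))
}
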