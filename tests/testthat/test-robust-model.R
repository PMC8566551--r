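# Paired-table builder: amphibian onset linear in plant onset with
# configurable noise/outliers, mirroring the pair_series() layout.
linear_table <- function(n = 25, intercept = 20, slope = 0.75, sd = 0.1,
                         mat = NULL) {
  x <- seq(45, 85, length.out = n)
  tibble::tibble(
    region = "moderate", year = seq_len(n) + 1999,
    amphibian_doy = intercept + slope * x + rnorm(n, 0, sd),
    plant_doy = x,
    mat = mat %||% rep(8, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

spec1 <- model_spec("common_frog", "goat_willow", include_mat = FALSE)

test_that("outlier-free fits coincide with least squares", {
  set.seed(101)
  tab <- linear_table(n = 40, sd = 0.02)
  fit <- fit_robust(spec1, tab)
  expect_lt(abs(fit$coefficients[[1]] - 20), 0.05)
  expect_lt(abs(fit$coefficients[[2]] - 0.75), 0.05)
  ols <- coef(lm(amphibian_doy ~ plant_doy, tab))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-3)
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
})

test_that("a gross outlier barely moves the slope and gets weight < 0.1", {
  set.seed(102)
  tab <- linear_table(n = 40, sd = 0.5)
  clean <- fit_robust(spec1, tab)
  dirty_tab <- tab
  dirty_tab$amphibian_doy[10] <- dirty_tab$amphibian_doy[10] + 60
  dirty <- fit_robust(spec1, dirty_tab)
  expect_lt(abs(dirty$coefficients[2] - clean$coefficients[2]), 0.05)
  expect_lt(dirty$weights[10], 0.1)
  # least squares, by contrast, is dragged far off
  ols <- coef(lm(amphibian_doy ~ plant_doy, dirty_tab))
  expect_gt(abs(ols[1] - clean$coefficients[1]), 5)
})

test_that("insufficient data and degenerate designs error informatively", {
  set.seed(103)
  tab <- linear_table(n = 3)
  expect_error(fit_robust(spec1, tab), "insufficient data")
  tab2 <- linear_table(n = 10)
  tab2$plant_doy <- 60
  expect_error(fit_robust(spec1, tab2), "zero variance")
  # duplicated predictor column -> rank-deficient design is named
  tab3 <- linear_table(n = 10)
  tab3$goat_willow <- tab3$plant_doy
  tab3$apricot <- tab3$plant_doy
  sp2 <- model_spec("common_frog", c("goat_willow", "apricot"),
                    include_mat = FALSE)
  names(tab3)[names(tab3) == "amphibian_doy"] <- "common_frog"
  expect_error(fit_robust(sp2, tab3), "collinear")
})

test_that("response shifts are absorbed by the intercept (equivariance)", {
  set.seed(104)
  tab <- linear_table(sd = 1)
  f0 <- fit_robust(spec1, tab)
  tab2 <- tab
  tab2$amphibian_doy <- tab2$amphibian_doy + 40
  f1 <- fit_robust(spec1, tab2)
  expect_equal(unname(f1$coefficients[1] - f0$coefficients[1]), 40,
               tolerance = 1e-6)
  expect_equal(unname(f1$coefficients[2]), unname(f0$coefficients[2]),
               tolerance = 1e-6)
  p0 <- predict_onset(f0, 60)
  p1 <- predict_onset(f1, 60)
  expect_equal(p1$predicted_amphibian_doy - p0$predicted_amphibian_doy, 40,
               tolerance = 1e-6)
})

test_that("slope stays near truth with up to 25% gross contamination", {
  set.seed(105)
  tab <- linear_table(n = 28, sd = 1)
  clean <- fit_robust(spec1, tab)
  se_clean <- clean$coef_table$se[2]
  bad <- sample(28, 6)  # ~21% of rows
  tab$amphibian_doy[bad] <- tab$amphibian_doy[bad] + 80
  fit <- fit_robust(spec1, tab)
  expect_lt(abs(fit$coefficients[2] - clean$coefficients[2]), 3 * se_clean)
})

test_that("Cook's distance matches a direct hat-matrix oracle", {
  set.seed(106)
  tab <- linear_table(n = 20, sd = 1)
  tab$amphibian_doy[7] <- tab$amphibian_doy[7] + 45
  fit <- fit_robust(spec1, tab)
  cd <- cooks_leverage(fit)

  # independent computation from first principles on the same design
  X <- cbind(1, tab$plant_doy)
  y <- tab$amphibian_doy
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  e <- as.vector((diag(20) - H) %*% y)
  s2 <- sum(e^2) / (20 - 2)
  d_oracle <- e^2 * diag(H) / (2 * s2 * (1 - diag(H))^2)
  expect_equal(cd$cooks_d, d_oracle, tolerance = 1e-10)

  # the gross outlier exceeds the 4/n threshold and is flagged, not dropped
  expect_gt(cd$cooks_d[7], 4 / 20)
  expect_true(cd$flagged[7])
  expect_equal(sum(cd$flagged), sum(cd$cooks_d > 4 / 20))
  expect_equal(attr(cd, "threshold"), 0.2)

  # identical responses: zero residual variance, all distances zero
  flat <- linear_table(n = 10, slope = 0, sd = 0)
  flat$amphibian_doy <- 80
  flat$plant_doy <- seq(50, 70, length.out = 10) # keep design non-degenerate
  fitf <- fit_robust(spec1, flat)
  expect_true(all(cooks_leverage(fitf)$cooks_d == 0))
})

test_that("VIF follows the 1/(1 - R^2) closed form", {
  set.seed(107)
  n <- 40
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  x2 <- x2 - sum(x1 * x2) / sum(x1^2) * x1   # exactly orthogonal, mean ~0
  tab <- tibble::tibble(common_frog = rnorm(n, 80, 5),
                        goat_willow = x1 + 60, apricot = x2 + 75)
  sp <- model_spec("common_frog", c("goat_willow", "apricot"),
                   include_mat = FALSE)
  v <- vif(tab, sp)
  expect_equal(as.numeric(v), c(1, 1), tolerance = 1e-6)

  # duplicated predictor: infinite VIF
  tab$apricot <- tab$goat_willow
  expect_true(all(is.infinite(vif(tab, sp))))

  # VIF increases as predictors grow collinear, matching 1/(1 - r^2)
  prev <- 0
  for (sigma in c(2, 1, 0.5, 0.25)) {
    tab$apricot <- tab$goat_willow + rnorm(n, 0, sigma)
    v <- vif(tab, sp)
    r2 <- cor(tab$goat_willow, tab$apricot)^2
    expect_equal(as.numeric(v[1]), 1 / (1 - r2), tolerance = 1e-6)
    expect_gt(v[1], prev)
    prev <- v[1]
  }

  # single predictor: VIF is trivially 1
  expect_equal(as.numeric(vif(linear_table(), spec1)), 1)
})

test_that("LOOCV equals the PRESS identity in the least-squares limit", {
  set.seed(108)
  tab <- linear_table(n = 15, sd = 2)
  got <- loocv_rmse(spec1, tab, engine = "ols")
  f <- lm(amphibian_doy ~ plant_doy, tab)
  h <- stats::hatvalues(f)
  press_rmse <- sqrt(mean((stats::residuals(f) / (1 - h))^2))
  expect_equal(as.numeric(got), press_rmse, tolerance = 1e-10)

  # noiseless exactly-linear data: zero out-of-sample error, both engines
  exact <- linear_table(n = 12, sd = 0)
  expect_equal(as.numeric(loocv_rmse(spec1, exact, engine = "ols")), 0,
               tolerance = 1e-8)
  expect_equal(as.numeric(loocv_rmse(spec1, exact, engine = "mm")), 0,
               tolerance = 1e-6)
})

test_that("a pure-noise predictor does not improve LOOCV RMSE", {
  set.seed(109)
  deltas <- vapply(1:25, function(i) {
    tab <- linear_table(n = 20, sd = 2)
    names(tab)[names(tab) == "amphibian_doy"] <- "common_frog"
    names(tab)[names(tab) == "plant_doy"] <- "goat_willow"
    tab$noise <- rnorm(20)
    r1 <- loocv_rmse(model_spec("common_frog", "goat_willow",
                                include_mat = FALSE), tab, engine = "ols")
    r2 <- loocv_rmse(model_spec("common_frog", c("goat_willow", "noise"),
                                include_mat = FALSE), tab, engine = "ols")
    r2 - r1
  }, numeric(1))
  expect_gte(median(deltas), 0)
})

test_that("null-model comparison behaves at both signal extremes", {
  set.seed(110)
  # strong linear signal: model clearly beats the intercept-only null
  tab <- linear_table(n = 20, sd = 1)
  cmp <- compare_to_null(spec1, tab)
  expect_lt(cmp$table$rmse_loocv[1], cmp$table$rmse_loocv[2])
  expect_equal(cmp$table$adj_r2[2], 0)
  expect_gt(cmp$rmse_improvement, 0)

  # response independent of the predictor: no real improvement
  tab$amphibian_doy <- rnorm(20, 80, 3)
  cmp2 <- compare_to_null(spec1, tab)
  expect_lt(abs(cmp2$rmse_improvement), 1.5)
})

test_that("lag predictions are affine in plant day with slope (b - 1)", {
  set.seed(111)
  tab <- linear_table(n = 23, intercept = 20, slope = 0.75, sd = 0.5)
  fit <- fit_robust(spec1, tab)
  lt <- lag_table(fit, plant_doys = c(60, 70, 80))
  dlag <- diff(lt$lag_days)
  expect_equal(dlag, rep(10 * (fit$coefficients[[2]] - 1), 2),
               tolerance = 1e-10)
  # interval always brackets the point lag, and is ordered
  expect_true(all(lt$ci95_low <= lt$lag_days & lt$lag_days <= lt$ci95_high))
  # with slope 0.75, +20 days of plant delay removes 5 days of lag
  expect_equal(lt$lag_days[1] - lt$lag_days[3], 5, tolerance = 0.2)

  # identity model: lag identically zero
  ident <- linear_table(n = 12, intercept = 0, slope = 1, sd = 0)
  fid <- fit_robust(spec1, ident)
  expect_equal(predict_onset(fid, c(50, 70, 90))$lag_days, rep(0, 3),
               tolerance = 1e-8)
})

test_that("prediction intervals, extrapolation and rounding conventions", {
  set.seed(112)
  tab <- linear_table(n = 23, sd = 1.5)
  fit <- fit_robust(spec1, tab)
  pc <- predict_onset(fit, 60)
  pp <- predict_onset(fit, 60, interval = "prediction")
  expect_gt(pp$ci95_high - pp$ci95_low, pc$ci95_high - pc$ci95_low)

  expect_warning(predict_onset(fit, 20), "extrapolate")
  expect_true(suppressWarnings(predict_onset(fit, 20))$extrapolated)
  expect_false(pc$extrapolated)
  expect_error(predict_onset(fit, 400), "366")

  # half-away-from-zero rounding on the integer summaries
  expect_equal(amphipheno:::round_half_away(c(2.5, -2.5, 0.4)),
               c(3, -3, 0))

  # MAT covariate: region names map to band midpoints
  tabm <- linear_table(n = 23, sd = 1,
                       mat = rep(c(6, 8), length.out = 23))
  sp_mat <- model_spec("common_frog", "goat_willow", include_mat = TRUE)
  fitm <- fit_robust(sp_mat, tabm)
  p_cool <- predict_onset(fitm, 60, mat = "cool")
  p_named <- predict_onset(fitm, 60, mat = 6)
  expect_equal(p_cool$predicted_amphibian_doy, p_named$predicted_amphibian_doy)
})

test_that("fits are deterministic under the documented seed policy", {
  set.seed(113)
  tab <- linear_table(n = 20, sd = 2)
  tab$amphibian_doy[3] <- tab$amphibian_doy[3] + 50
  f1 <- fit_robust(spec1, tab)
  f2 <- fit_robust(spec1, tab)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$rmse_loocv, f2$rmse_loocv)
  # and the fit does not disturb the caller's RNG stream
  set.seed(200); before <- runif(1)
  set.seed(200); invisible(fit_robust(spec1, tab)); after <- runif(1)
  expect_identical(before, after)
})
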