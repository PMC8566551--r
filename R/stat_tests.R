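# Descriptive/inferential layer: normality, region comparison, temporal
# trend and plant-amphibian correlation. All pipeline reports evaluate at
# alpha = 0.05; no multiple-testing correction is applied (documented).

pheno_test <- function(statistic, p_value, n, method, extras = list()) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n = n, method = method, extras = extras),
            class = "pheno_test")
}

#' @export
print.pheno_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %d\n", x$method,
              x$statistic, x$p_value, x$n))
  if (length(x$extras) > 0) {
    ex <- vapply(x$extras, function(v) format(v, digits = 4), character(1))
    cat("  ", paste(names(ex), ex, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Two-tailed test of linear association between two onset series; the p
#' value comes from the t transform with n - 2 degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3) with nonzero
#'   variance.
#' @return `pheno_test` with statistic r and extras `t`, `df`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  pheno_test(ct$estimate, ct$p.value, length(x), "pearson_correlation",
             extras = list(t = unname(ct$statistic),
                           df = unname(ct$parameter)))
}

# Exact null distribution of Kendall's S for tie-free data via the
# inversion-count generating function prod_i (1 + x + ... + x^(i-1)).
kendall_s_exact_p <- function(s_obs, n) {
  counts <- 1
  for (i in 2:n) {
    counts <- round(stats::convolve(counts, rep(1, i), type = "open"))
  }
  inv <- 0:(length(counts) - 1)        # number of discordant pairs
  s_vals <- n * (n - 1) / 2 - 2 * inv  # S for each inversion count
  min(1, sum(counts[abs(s_vals) >= abs(s_obs)]) / sum(counts))
}

# Exact two-sided p with ties: enumerate all orderings (n <= 8).
kendall_s_exact_p_ties <- function(values, s_obs) {
  n <- length(values)
  s_stat <- function(v) {
    s <- 0
    for (i in 1:(n - 1)) s <- s + sum(sign(v[(i + 1):n] - v[i]))
    s
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_s <- vapply(perms(values), s_stat, numeric(1))
  min(1, mean(abs(all_s) >= abs(s_obs)))
}

#' Mann-Kendall trend test
#'
#' Non-parametric test for a monotone temporal trend in an onset series.
#' S is the sum over ordered pairs of the sign of the value difference;
#' the variance uses the standard tie-group correction, z is continuity-
#' corrected, and tau = S / (n(n-1)/2). For short series an exact
#' two-sided permutation p is reported alongside the normal approximation
#' (by enumeration of the inversion-count distribution when the values
#' are tie-free and n <= 10, by full enumeration when tied and n <= 8).
#'
#' @param year integer years (sorting key), or a data frame with columns
#'   `year` and `onset_doy`.
#' @param onset_doy values, same length as `year`.
#' @return `pheno_test` with statistic tau and extras `S`, `var_S`, `z`,
#'   `p_exact` (NA when not computed).
#' @export
mann_kendall <- function(year, onset_doy = NULL) {
  if (is.data.frame(year)) {
    onset_doy <- year$onset_doy
    year <- year$year
  }
  n <- length(onset_doy)
  if (n < 4) stop("Mann-Kendall needs at least 4 observations",
                  call. = FALSE)
  x <- onset_doy[order(year)]
  s <- 0
  for (i in 1:(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * pnorm(-abs(z))
  tau <- s / (n * (n - 1) / 2)
  has_ties <- length(ties) > 0
  p_exact <- if (!has_ties && n <= 10) {
    kendall_s_exact_p(s, n)
  } else if (has_ties && n <= 8) {
    kendall_s_exact_p_ties(x, s)
  } else {
    NA_real_
  }
  pheno_test(tau, p, n, "mann_kendall",
             extras = list(S = s, var_S = var_s, z = z, p_exact = p_exact))
}

#' Paired comparison of onsets between two climatic regions
#'
#' Paired t-test on within-(taxon, year) onset differences between two
#' regions (e.g. does migration start earlier in the moderate than in the
#' cool region). When the differences have zero variance the t statistic
#' is degenerate; the result then carries `exact_difference = TRUE` with
#' p = 1 for a zero shift and p = 0 otherwise.
#'
#' @param series_a,series_b onset tibbles (`taxon`, `year`, `onset_doy`),
#'   matched on (taxon, year); or plain numeric vectors already matched.
#' @return `pheno_test` with statistic t and extras `mean_difference`
#'   (a - b), `df`, `exact_difference`.
#' @export
paired_region_test <- function(series_a, series_b) {
  if (is.data.frame(series_a)) {
    m <- dplyr::inner_join(
      tibble::as_tibble(series_a)[, c("taxon", "year", "onset_doy")],
      tibble::as_tibble(series_b)[, c("taxon", "year", "onset_doy")],
      by = c("taxon", "year"), suffix = c("_a", "_b"))
    a <- m$onset_doy_a; b <- m$onset_doy_b
  } else {
    a <- series_a; b <- series_b
  }
  if (length(a) < 2) stop("need at least 2 matched pairs", call. = FALSE)
  d <- a - b
  if (sd(d) < 1e-12) {
    md <- mean(d)
    return(pheno_test(if (md == 0) 0 else sign(md) * Inf,
                      if (md == 0) 1 else 0, length(d),
                      "paired_region_test",
                      extras = list(mean_difference = md,
                                    df = length(d) - 1,
                                    exact_difference = TRUE)))
  }
  tt <- t.test(a, b, paired = TRUE)
  pheno_test(unname(tt$statistic), tt$p.value, length(d),
             "paired_region_test",
             extras = list(mean_difference = mean(d),
                           df = unname(tt$parameter),
                           exact_difference = FALSE))
}

#' Shapiro-Wilk normality test
#'
#' Reported as a diagnostic on onset series (never used as a gate).
#'
#' @param values numeric vector, 3 <= n <= 5000, nonzero variance.
#' @return `pheno_test` with statistic W.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (sd(values) == 0) stop("zero variance", call. = FALSE)
  st <- shapiro.test(values)
  pheno_test(unname(st$statistic), st$p.value, n, "shapiro_wilk")
}
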