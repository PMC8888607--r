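# Agreement statistics for comparing muscle mass estimates between methods:
# Bland-Altman bias and limits of agreement, Mann-Whitney U rank tests,
# within-range summaries against reference measurement spreads, and linear
# regression comparisons.

#' Pair two methods' values by muscle
#'
#' @param data Long-format data frame with columns `muscle`, `method` and
#'   `value`.
#' @param method_a,method_b The two method labels to pair.
#' @return A tibble with columns `muscle`, `a`, `b` (one row per muscle with
#'   both methods present; muscles missing either value are dropped).
#' @export
pair_methods <- function(data, method_a, method_b) {
  wide <- tibble::as_tibble(data) |>
    dplyr::filter(.data$method %in% c(method_a, method_b)) |>
    tidyr::pivot_wider(
      id_cols = "muscle", names_from = "method", values_from = "value"
    )
  if (!all(c(method_a, method_b) %in% names(wide))) {
    stop("one of the requested methods has no values", call. = FALSE)
  }
  wide |>
    dplyr::transmute(
      muscle = .data$muscle,
      a = .data[[method_a]], b = .data[[method_b]]
    ) |>
    tidyr::drop_na()
}

#' Bland-Altman agreement analysis
#'
#' Agreement between two paired measurement series via the differences
#' d = a - b: bias (mean difference) with its t-based confidence interval,
#' and limits of agreement bias +/- 1.96 SD(d). The interval printed after
#' a bias as "bias +/- h" is the CI half-width h, not the limits of
#' agreement, which are reported separately.
#'
#' @param data Data frame with paired columns.
#' @param a,b Column names of the two series (default `"a"`, `"b"`).
#' @param ci_level Confidence level for the bias CI.
#' @return Object of class `bland_altman` with fields `bias`, `bias_ci`
#'   (low/high), `ci_half_width`, `sd_diff`, `loa_low`, `loa_high`, `n` and
#'   the paired data.
#' @export
bland_altman <- function(data, a = "a", b = "b", ci_level = 0.95) {
  data <- tibble::as_tibble(data)
  d <- data[[a]] - data[[b]]
  n <- length(d)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  bias <- mean(d)
  sd_diff <- sd(d)
  half <- qt(1 - (1 - ci_level) / 2, df = n - 1) * sd_diff / sqrt(n)
  structure(
    list(
      bias = bias,
      bias_ci = c(low = bias - half, high = bias + half),
      ci_half_width = half,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      ci_level = ci_level,
      n = n,
      data = tibble::tibble(
        mean = (data[[a]] + data[[b]]) / 2,
        diff = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.6g +/- %.6g (%.0f%% CI), LoA [%.6g, %.6g]\n",
    x$n, x$bias, x$ci_half_width, 100 * x$ci_level, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    estimate = c(x$bias, x$loa_low, x$loa_high),
    term = c("bias", "loa_low", "loa_high"),
    conf.low = c(x$bias_ci[["low"]], NA, NA),
    conf.high = c(x$bias_ci[["high"]], NA, NA)
  )[, c("term", "estimate", "conf.low", "conf.high")]
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, ci_half_width = x$ci_half_width, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high, n = x$n
  )
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum test with the first-sample W convention: W is the
#' rank sum of `x` (midranks for ties) minus n_x (n_x + 1) / 2, so
#' 0 <= W <= n_x n_y. The p-value is exact — full enumeration of all
#' choose(n_x + n_y, n_x) group assignments — when both samples are small
#' (max size <= 8) and tie-free; otherwise a normal approximation with tie
#' and continuity corrections is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest sample size for which exact enumeration is used.
#' @return Object of class `mwu_test` with `W`, `p_value`, `method` and the
#'   sample sizes.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && max(nx, ny) <= exact_max) {
    p <- mwu_exact_p(c(x, y), nx, W)
    method <- "exact"
  } else {
    p <- mwu_normal_p(c(x, y), nx, ny, W)
    method <- "normal_approx"
  }
  structure(
    list(
      W = W, p_value = p, method = method, n_x = nx, n_y = ny,
      alternative = "two_sided"
    ),
    class = "mwu_test"
  )
}

# exact two-sided p by enumerating every assignment of nx labels
mwu_exact_p <- function(pooled, nx, W) {
  n <- length(pooled)
  r <- rank(pooled)
  combs <- combn(n, nx)
  base <- nx * (nx + 1) / 2
  Ws <- colSums(matrix(r[combs], nrow = nx)) - base
  eps <- 1e-9
  p_le <- mean(Ws <= W + eps)
  p_ge <- mean(Ws >= W - eps)
  min(1, 2 * min(p_le, p_ge))
}

# normal approximation with tie correction and continuity correction
mwu_normal_p <- function(pooled, nx, ny, W) {
  n <- nx + ny
  mu <- nx * ny / 2
  tie_sizes <- table(pooled)
  sigma2 <- nx * ny / 12 *
    (n + 1 - sum(tie_sizes^3 - tie_sizes) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U: W = %g, p-value = %.4g (%s, n = %d/%d)\n",
    x$W, x$p_value, x$method, x$n_x, x$n_y
  ))
  invisible(x)
}

#' @method tidy mwu_test
#' @export
tidy.mwu_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$W, p.value = x$p_value, method = x$method,
    alternative = x$alternative, n.x = x$n_x, n.y = x$n_y
  )
}

#' @method glance mwu_test
#' @export
glance.mwu_test <- function(x, ...) tidy.mwu_test(x, ...)

#' Within-range summary of estimates against reference spreads
#'
#' For each muscle with an estimate and a set of reference measurements,
#' checks whether the estimate falls within the reference mean +/- 1 SD,
#' mean +/- 2 SD, [min, max], and [min - 20% min, max + 20% max], and
#' reports the percentage of muscles inside each interval together with the
#' median/min/max of the normalised estimates (estimate divided by the
#' reference median per muscle). Muscles with fewer than 2 reference values
#' are excluded with a warning.
#'
#' @param estimates Data frame with columns `muscle`, `value`.
#' @param reference Data frame with columns `muscle`, `value` (>= 2 rows per
#'   muscle).
#' @return A one-row tibble of class `range_summary`: `median`, `min`,
#'   `max` (of normalised estimates), `pct_within_1sd`, `pct_within_2sd`,
#'   `pct_within_range`, `pct_within_range_20`, `n_muscles`.
#' @export
within_range_summary <- function(estimates, reference) {
  estimates <- tibble::as_tibble(estimates)
  reference <- tibble::as_tibble(reference)
  ref_stats <- reference |>
    dplyr::group_by(.data$muscle) |>
    dplyr::summarise(
      ref_mean = mean(.data$value), ref_sd = sd(.data$value),
      ref_min = min(.data$value), ref_max = max(.data$value),
      ref_median = median(.data$value), n_ref = dplyr::n(),
      .groups = "drop"
    )
  joined <- dplyr::inner_join(estimates, ref_stats, by = "muscle")
  missing <- setdiff(estimates$muscle, joined$muscle)
  few <- joined$muscle[joined$n_ref < 2]
  if (length(missing) > 0 || length(few) > 0) {
    warning(sprintf(
      "excluded muscle(s) without >= 2 reference values: %s",
      paste(c(missing, few), collapse = ", ")
    ), call. = FALSE)
    joined <- dplyr::filter(joined, .data$n_ref >= 2)
  }
  if (nrow(joined) == 0) stop("no muscles with usable references", call. = FALSE)
  per <- joined |>
    dplyr::mutate(
      normalized = .data$value / .data$ref_median,
      in_1sd = .data$value >= .data$ref_mean - .data$ref_sd &
        .data$value <= .data$ref_mean + .data$ref_sd,
      in_2sd = .data$value >= .data$ref_mean - 2 * .data$ref_sd &
        .data$value <= .data$ref_mean + 2 * .data$ref_sd,
      in_range = .data$value >= .data$ref_min & .data$value <= .data$ref_max,
      in_range_20 = .data$value >= 0.8 * .data$ref_min &
        .data$value <= 1.2 * .data$ref_max
    )
  out <- tibble::tibble(
    median = median(per$normalized),
    min = min(per$normalized),
    max = max(per$normalized),
    pct_within_1sd = 100 * mean(per$in_1sd),
    pct_within_2sd = 100 * mean(per$in_2sd),
    pct_within_range = 100 * mean(per$in_range),
    pct_within_range_20 = 100 * mean(per$in_range_20),
    n_muscles = nrow(per)
  )
  attr(out, "per_muscle") <- per
  class(out) <- c("range_summary", class(out))
  out
}

#' Ordinary least-squares comparison fit
#'
#' Fits `b ~ a` by least squares (via [stats::lm()]) and reports slope,
#' intercept and adjusted R^2 — the regression drawn through
#' method-comparison scatter plots, where slope 1 and intercept 0 indicate
#' perfect agreement.
#'
#' @param data Data frame of paired values.
#' @param a,b Column names for predictor and response.
#' @return Object of class `ols_fit`: `slope`, `intercept`, `r2`,
#'   `adjusted_r2`, `n`, and the underlying `lm` fit.
#' @export
ols_fit <- function(data, a = "a", b = "b") {
  data <- tibble::as_tibble(data)
  n <- nrow(data)
  if (n < 3) stop("regression needs at least 3 pairs", call. = FALSE)
  if (sd(data[[a]]) == 0) stop("predictor is constant", call. = FALSE)
  fit <- lm(stats::reformulate(a, b), data = data)
  # R^2 from sums of squares; a constant response has no explainable
  # variance, so R^2 is 0 by definition there
  tss <- sum((data[[b]] - mean(data[[b]]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2 = r2, adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n,
      fit = fit, a = a, b = b, data = data
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS: y = %.6g x + %.6g; adjusted R^2 = %.4f (n = %d)\n",
    x$slope, x$intercept, x$adjusted_r2, x$n
  ))
  invisible(x)
}

#' @method tidy ols_fit
#' @export
tidy.ols_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r.squared = x$r2, adj.r.squared = x$adjusted_r2, n = x$n
  )
}

#' Full method-comparison report
#'
#' Runs the whole evaluation layer for one method pair: Bland-Altman,
#' Mann-Whitney U on the (optionally normalised) values, OLS comparison fit,
#' and — when reference measurements are supplied — the within-range
#' summary.
#'
#' @param data Long data frame with columns `muscle`, `method`, `value`.
#' @param method_a,method_b Method labels to compare.
#' @param reference Optional reference data frame (`muscle`, `value`) for
#'   [within_range_summary()] of `method_a`'s values.
#' @return A list of class `method_comparison` with elements `pairs`,
#'   `bland_altman`, `mwu`, `ols` and optionally `range_summary`.
#' @export
compare_methods <- function(data, method_a, method_b, reference = NULL) {
  pairs <- pair_methods(data, method_a, method_b)
  out <- list(
    method_a = method_a, method_b = method_b, pairs = pairs,
    bland_altman = bland_altman(pairs),
    mwu = mann_whitney_u(pairs$a, pairs$b),
    ols = ols_fit(pairs)
  )
  if (!is.null(reference)) {
    est <- tibble::tibble(muscle = pairs$muscle, value = pairs$a)
    out$range_summary <- within_range_summary(est, reference)
  }
  structure(out, class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Comparison: %s vs %s (%d muscles)\n", x$method_a, x$method_b, nrow(x$pairs)))
  print(x$bland_altman)
  print(x$mwu)
  print(x$ols)
  invisible(x)
}
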