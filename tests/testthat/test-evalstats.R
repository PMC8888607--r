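test_that("pair_methods aligns values by muscle and drops incomplete pairs", {
  long <- tibble::tibble(
    muscle = c("A", "B", "C", "A", "B"),
    method = c("phys", "phys", "phys", "model", "model"),
    value = c(1, 2, 3, 1.1, 2.2)
  )
  p <- pair_methods(long, "phys", "model")
  expect_equal(p$muscle, c("A", "B"))
  expect_equal(p$a, c(1, 2))
  expect_equal(p$b, c(1.1, 2.2))
  expect_error(pair_methods(long, "phys", "dice"), "no values")
})

test_that("bland_altman matches hand computation and is antisymmetric", {
  # identity: zero bias, zero spread, degenerate CI
  same <- bland_altman(tibble::tibble(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(unname(same$bias_ci), c(0, 0))

  # constant shift
  shift <- bland_altman(tibble::tibble(a = c(3, 5, 9), b = c(2, 4, 8)))
  expect_equal(shift$bias, 1)
  expect_equal(shift$sd_diff, 0)

  # 4-point hand-computed example: d = (-0.1, 0.1, -0.2, 0.2)
  ba <- bland_altman(tibble::tibble(
    a = c(1, 2, 3, 4), b = c(1.1, 1.9, 3.2, 3.8)
  ))
  sd_hand <- sqrt((0.1^2 + 0.1^2 + 0.2^2 + 0.2^2) / 3)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd_hand, tolerance = 1e-12)
  expect_equal(ba$ci_half_width, qt(0.975, 3) * sd_hand / 2, tolerance = 1e-12)
  expect_equal(ba$loa_high, 1.96 * sd_hand, tolerance = 1e-12)
  expect_error(bland_altman(tibble::tibble(a = 1, b = 2)), "at least 2")

  set.seed(4)
  df <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  fwd <- bland_altman(df)
  rev <- bland_altman(tibble::tibble(a = df$b, b = df$a))
  expect_equal(fwd$bias, -rev$bias)
  expect_equal(fwd$loa_low, -rev$loa_high)

  td <- tidy(ba)
  expect_equal(td$term, c("bias", "loa_low", "loa_high"))
  expect_equal(glance(ba)$n, 4L)
})

test_that("Mann-Whitney U follows the rank-sum convention exactly", {
  m <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(m$W, 9)
  expect_equal(m$p_value, 0.1)
  expect_equal(m$method, "exact")

  # identical samples: W = n m / 2
  eq <- mann_whitney_u(c(1, 2, 3, 4) + 0.5, c(1.5, 2.5, 3.5, 4.5))
  expect_equal(eq$W, 8)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact MWU p equals brute-force enumeration and wilcox.test", {
  set.seed(9)
  for (k in 1:12) {
    nx <- sample(2:7, 1)
    ny <- sample(2:7, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, mean = 0.5)
    mine <- mann_whitney_u(x, y)
    brute <- mwu_brute_force(x, y)
    ref <- wilcox.test(x, y)
    expect_equal(mine$W, brute$W)
    expect_equal(mine$p_value, brute$p, tolerance = 1e-12)
    expect_equal(mine$W, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    # two-sided p is invariant under swapping samples; W_x + W_y = n m
    swap <- mann_whitney_u(y, x)
    expect_equal(swap$W + mine$W, nx * ny)
    expect_equal(swap$p_value, mine$p_value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact MWU p for n = 8 vs 8", {
  set.seed(10)
  for (k in 1:5) {
    x <- rnorm(8)
    y <- rnorm(8)
    exact <- mann_whitney_u(x, y)$p_value
    approx_p <- mann_whitney_u(x, y, exact_max = 0)$p_value
    expect_lt(abs(exact - approx_p), 0.02)
  }
  # ties force the corrected normal approximation
  tied <- mann_whitney_u(c(1, 2, 2, 3), c(2, 3, 4, 5))
  expect_equal(tied$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(c(1, 2, 2, 3), c(2, 3, 4, 5),
    correct = TRUE, exact = FALSE
  ))
  expect_equal(tied$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("within-range summary scores the hand-constructed fixture", {
  est <- tibble::tibble(
    muscle = c("in1sd", "inRangeOnly", "outside"),
    value = c(1.0, 1.99, 10)
  )
  ref <- tibble::tibble(
    muscle = c(
      rep("in1sd", 4), rep("inRangeOnly", 6), rep("outside", 4)
    ),
    value = c(
      0.9, 1.0, 1.1, 1.05, # mean 1.0125, sd ~ 0.085 -> inside 1SD
      1, 1, 1, 1, 1, 2, # range [1,2]; mean 7/6, 2SD top ~ 1.98 -> range only
      1, 1.2, 1.4, 1.1 # estimate 10 is outside everything
    )
  )
  s <- within_range_summary(est, ref)
  expect_equal(s$pct_within_1sd, 100 / 3, tolerance = 1e-9)
  expect_equal(s$pct_within_2sd, 100 / 3, tolerance = 1e-9)
  expect_equal(s$pct_within_range, 200 / 3, tolerance = 1e-9)
  expect_equal(s$pct_within_range_20, 200 / 3, tolerance = 1e-9)
  expect_equal(s$n_muscles, 3L)

  # perfect estimates: all four percentages 100
  perfect <- within_range_summary(
    tibble::tibble(muscle = c("a", "b"), value = c(1.0125, 7 / 6)),
    tibble::tibble(
      muscle = c(rep("a", 4), rep("b", 6)),
      value = c(0.9, 1.0, 1.1, 1.05, 1, 1, 1, 1, 1, 2)
    )
  )
  expect_true(all(perfect[, c(
    "pct_within_1sd", "pct_within_2sd",
    "pct_within_range", "pct_within_range_20"
  )] == 100))

  # far-off estimates: all zero
  off <- within_range_summary(
    tibble::tibble(muscle = c("a", "b"), value = c(100, 200)),
    tibble::tibble(
      muscle = c(rep("a", 3), rep("b", 3)),
      value = c(1, 1.1, 0.9, 2, 2.1, 1.9)
    )
  )
  expect_true(all(off[, c(
    "pct_within_1sd", "pct_within_2sd",
    "pct_within_range", "pct_within_range_20"
  )] == 0))

  # muscle order does not matter; missing references warn and are dropped
  shuffled <- within_range_summary(est[c(3, 1, 2), ], ref)
  cols <- c(
    "median", "min", "max", "pct_within_1sd", "pct_within_2sd",
    "pct_within_range", "pct_within_range_20", "n_muscles"
  )
  expect_equal(unlist(shuffled[, cols]), unlist(s[, cols]))
  expect_warning(
    with_extra <- within_range_summary(
      dplyr::bind_rows(est, tibble::tibble(muscle = "ghost", value = 1)), ref
    ),
    "ghost"
  )
  expect_equal(with_extra$n_muscles, 3L)
})

test_that("OLS comparison fit matches the normal equations", {
  exact <- ols_fit(tibble::tibble(a = 1:10, b = 2 * (1:10) + 1))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$adjusted_r2, 1)

  flat <- ols_fit(tibble::tibble(a = 1:5, b = rep(3, 5)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r2, 0)
  expect_lte(flat$adjusted_r2, flat$r2)
  expect_error(ols_fit(tibble::tibble(a = rep(1, 5), b = 1:5)), "constant")
  expect_error(ols_fit(tibble::tibble(a = 1:2, b = 1:2)), "at least 3")

  set.seed(14)
  df <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  f <- ols_fit(df)
  X <- cbind(1, df$a)
  beta <- solve(t(X) %*% X, t(X) %*% df$b)
  expect_lt(abs(f$intercept - beta[1]), 1e-10)
  expect_lt(abs(f$slope - beta[2]), 1e-10)
  r2 <- 1 - sum((df$b - X %*% beta)^2) / sum((df$b - mean(df$b))^2)
  expect_lt(abs(f$adjusted_r2 - (1 - (1 - r2) * 9 / 8)), 1e-10)
  expect_equal(tidy(f)$estimate, c(f$intercept, f$slope))
})

test_that("compare_methods assembles the full evaluation report", {
  set.seed(6)
  muscles <- sprintf("m%02d", 1:12)
  phys <- runif(12, 0.5, 2)
  long <- tibble::tibble(
    muscle = rep(muscles, 2),
    method = rep(c("physical", "model"), each = 12),
    value = c(phys, phys * 0.9 + rnorm(12, sd = 0.05))
  )
  ref <- tibble::tibble(
    muscle = rep(muscles, each = 4),
    value = rep(phys, each = 4) * rnorm(48, 1, 0.1)
  )
  cmp <- compare_methods(long, "physical", "model", reference = ref)
  expect_s3_class(cmp$bland_altman, "bland_altman")
  expect_s3_class(cmp$mwu, "mwu_test")
  expect_s3_class(cmp$ols, "ols_fit")
  expect_s3_class(cmp$range_summary, "range_summary")
  expect_equal(nrow(cmp$pairs), 12)
  # plots build without error
  expect_s3_class(autoplot(cmp$bland_altman), "ggplot")
  expect_s3_class(autoplot(cmp$ols), "ggplot")
})
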