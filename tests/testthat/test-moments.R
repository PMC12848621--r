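test_that("central moments match closed forms on exact supports", {
  m <- central_moments(c(-1, 1))
  expect_equal(m$mean, 0)
  expect_equal(m$std, 1)
  expect_equal(m$skewness, 0)
  expect_equal(m$kurtosis, 1)   # symmetric two-point mass

  # Bernoulli(p = 1/4) on its exact four-point support:
  # skew = (1-2p)/sqrt(pq), kurt = 3 + (1-6pq)/(pq)
  m <- central_moments(c(0, 0, 0, 1))
  p <- 0.25; q <- 0.75
  expect_equal(m$mean, p)
  expect_equal(m$std, sqrt(p * q), tolerance = 1e-12)
  expect_equal(m$skewness, (1 - 2 * p) / sqrt(p * q), tolerance = 1e-12)
  expect_equal(m$kurtosis, 3 + (1 - 6 * p * q) / (p * q), tolerance = 1e-12)
  expect_equal(m$skewness, 1.1547, tolerance = 1e-4)
  expect_equal(m$kurtosis, 2.3333, tolerance = 1e-4)

  expect_error(central_moments(1), "at least 2")
  zeroes <- central_moments(c(2, 2, 2))
  expect_true(is.na(zeroes$skewness) && is.na(zeroes$kurtosis))
  expect_error(central_moments(c(1, NA, 3)), "non-finite")
})

test_that("moment formulas agree with naive summation on random vectors", {
  set.seed(13)
  for (n in c(5, 100, 10000)) {
    x <- rnorm(n) * 10 + rexp(n)
    m <- central_moments(x)
    o <- naive_moments(x)
    expect_equal(m$mean, o["mean"], ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(m$std, o["std"], ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(m$skewness, o["skewness"], ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(m$kurtosis, o["kurtosis"], ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("gaussian samples give non-excess kurtosis 3", {
  set.seed(101)
  m <- central_moments(rnorm(1e6))
  expect_equal(m$kurtosis, 3, tolerance = 0.05)
  expect_equal(m$skewness, 0, tolerance = 0.05)
})

test_that("moments are affine-equivariant and respect the Pearson bound", {
  set.seed(19)
  for (k in 1:20) {
    x <- rexp(500) + rnorm(500)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    m0 <- central_moments(x)
    m1 <- central_moments(a * x + b)
    expect_equal(m1$mean, a * m0$mean + b, tolerance = 1e-10)
    expect_equal(m1$std, a * m0$std, tolerance = 1e-10)
    expect_equal(m1$skewness, m0$skewness, tolerance = 1e-10)
    expect_equal(m1$kurtosis, m0$kurtosis, tolerance = 1e-10)
    expect_gte(m0$kurtosis, m0$skewness^2 + 1)
  }
})

test_that("group aggregation averages moments per age with honest error bars", {
  mk <- function(id, age, vals) central_moments(
    vals, "m44", meta = list(sample_id = id, age_days = age))
  one <- rbind(mk("a", 75, c(1, 2, 3)), mk("b", 100, c(2, 4, 6)))
  tr <- moments_by_group(one, fit_models = c(mean = "linear", std = "linear",
                                             skewness = "linear",
                                             kurtosis = "linear"))
  expect_equal(tr$ages, c(75, 100))
  expect_equal(tr$table$mean, c(2, 4))
  expect_equal(tr$table$mean_sd, c(0, 0))

  # identical replicates: error bars zero, means unchanged
  three <- do.call(rbind, lapply(1:3, function(i) mk(paste0("s", i), 75, c(1, 5))))
  tr3 <- moments_by_group(three, fit_models = c(mean = "linear", std = "linear",
                                                skewness = "linear",
                                                kurtosis = "linear"))
  expect_equal(tr3$table$mean_sd, 0)
  expect_equal(tr3$table$mean, 3)

  # group means match direct recomputation from pooled values
  set.seed(3)
  vals <- replicate(6, rexp(50), simplify = FALSE)
  ages <- rep(c(75, 100), each = 3)
  df <- do.call(rbind, lapply(1:6, function(i)
    mk(paste0("s", i), ages[i], vals[[i]])))
  tr6 <- moments_by_group(df)
  for (gi in 1:2) {
    idx <- which(ages == c(75, 100)[gi])
    expect_equal(tr6$table$skewness[gi],
                 mean(vapply(vals[idx], function(v)
                   central_moments(v)$skewness, 0)))
  }
  expect_error(moments_by_group(df[0, ]), "no summaries")
  df2 <- df; df2$parameter[1] <- "m22"
  expect_error(moments_by_group(df2), "mix parameters")
})

test_that("linear fits are exact on lines and sane on noise", {
  f <- fit_linear(c(75, 100, 125), c(0.5, 0.5, 0.5))
  expect_equal(unname(f$params["slope"]), 0, tolerance = 1e-14)
  expect_equal(unname(f$params["intercept"]), 0.5)

  x <- seq(75, 225, 25)
  f <- fit_linear(x, 0.002 * x + 0.1)
  expect_equal(unname(f$params["slope"]), 0.002, tolerance = 1e-12)
  expect_equal(unname(f$params["intercept"]), 0.1, tolerance = 1e-12)

  # analytic OLS variance oracle: slope within 3 standard errors
  set.seed(37)
  sigma <- 0.05
  y <- 0.002 * x + 0.1 + rnorm(length(x), 0, sigma)
  f <- fit_linear(x, y)
  se <- sigma / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(f$params["slope"] - 0.002), 3 * se)
  expect_error(fit_linear(c(1, 1), c(2, 3)), "distinct")
})

test_that("exponential fits recover noiseless parameters and flag degeneracy", {
  x <- seq(75, 225, 25)
  f <- fit_exponential(x, 2 * exp(0.01 * x))
  expect_true(f$converged)
  expect_equal(unname(f$params["alpha"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$params["beta"]), 0.01, tolerance = 1e-6)
  expect_equal(unname(f$params["offset"]), 0, tolerance = 1e-5)

  # negative-going series need the offset term
  f <- fit_exponential(x, -0.5 * exp(0.008 * x) + 0.3)
  expect_equal(unname(f$params["beta"]), 0.008, tolerance = 1e-5)
  expect_equal(unname(f$params["offset"]), 0.3, tolerance = 1e-4)

  f <- fit_exponential(x, rep(0.7, length(x)))
  expect_false(f$converged)
  expect_equal(unname(f$params["offset"]), 0.7)
  expect_error(fit_exponential(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("trend tables mirror the age-column layout and round-trip", {
  mk <- function(id, age, vals) central_moments(
    vals, "Delta", meta = list(sample_id = id, age_days = age))
  set.seed(8)
  df <- do.call(rbind, lapply(seq(75, 225, 25), function(a)
    mk(paste0("s", a), a, rnorm(30, 0.4, 0.05))))
  tr <- moments_by_group(df)
  tab <- trend_table(list(Delta = tr))
  expect_equal(nrow(tab), 4L)
  expect_equal(sum(grepl("^age_", names(tab))), 7L)
  expect_identical(names(tab)[3:9], paste0("age_", seq(75, 225, 25)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trend_table(tab, f)
  expect_equal(read_trend_table(f), tab, tolerance = 1e-12)
  expect_match(format_trend_table(tab), "Skew")
})
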