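test_that("the plaque density schedule is zero before onset and linear after", {
  expect_equal(default_age_schedule(45), 0)
  expect_equal(default_age_schedule(30), 0)
  expect_equal(default_age_schedule(225), 4 * default_age_schedule(90))
  expect_true(all(diff(default_age_schedule(seq(0, 300, 5))) >= 0))
})

test_that("phantom generation is deterministic in the phantom spec", {
  sp <- phantom_spec(shape = c(48L, 48L), age_days = 150L, seed = 77L)
  g1 <- generate_phantom(sp)
  g2 <- generate_phantom(sp)
  expect_identical(g1$mueller_map, g2$mueller_map)
  expect_identical(g1$label_map, g2$label_map)
  s1 <- forward_measure(g1, noise_snr = 50)
  s2 <- forward_measure(g2, noise_snr = 50)
  expect_identical(s1$images, s2$images)
  # and does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_phantom(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("a zero-density phantom is homogeneous Rayleigh tissue", {
  sp <- phantom_spec(shape = c(64L, 64L), age_days = 40L, seed = 5L,
                     patch_coverage = 0, patch_coverage_growth = 0)
  gt <- generate_phantom(sp)
  expect_equal(sum(gt$label_map == 2L), 0L)
  m44 <- gt$mueller_map[, , 4, 4][gt$tissue]
  expect_lt(abs(central_moments(m44)$skewness), 0.25)  # symmetric jitter only
})

test_that("generated pixels encode the scattering-regime orderings and physicality", {
  for (age in c(75L, 225L)) {
    gt <- generate_phantom(phantom_spec(shape = c(64L, 64L), age_days = age,
                                        seed = age))
    m22 <- gt$mueller_map[, , 2, 2]; m33 <- gt$mueller_map[, , 3, 3]
    m44 <- gt$mueller_map[, , 4, 4]
    core <- gt$label_map == 2L; tis <- gt$label_map == 1L
    expect_true(all(m44[core] >= m22[core]))
    expect_true(all(m22[tis] > m44[tis]))
    # Rayleigh background: m22 ~ m33 > m44 on unperturbed tissue
    expect_gt(median(m22[tis]), median(m44[tis]))
    expect_lt(abs(median(m22[tis]) - median(m33[tis])), 0.1)
    # every pixel physical
    set.seed(1)
    idx <- sample(which(gt$tissue), 200)
    for (p in idx) {
      rc <- arrayInd(p, dim(gt$label_map))
      expect_true(is_physical(gt$mueller_map[rc[1], rc[2], , ],
                              tol = 1e-9)$pass)
    }
  }
})

test_that("noiseless forward measurement round-trips through the pipeline", {
  gt <- generate_phantom(phantom_spec(shape = c(40L, 40L), age_days = 125L,
                                      seed = 2L))
  stack <- forward_measure(gt, noise_snr = Inf)
  # crossed/aligned analyzer on an identity-like bright pixel
  expect_true(all(vapply(stack$images, function(x) all(x >= 0), TRUE)))
  nm <- normalize_by_m11(reconstruct_mueller(stack))
  expect_lt(max(abs(nm$elements - gt$mueller_map), na.rm = TRUE), 1e-10)
  expect_error(forward_measure(gt, noise_snr = -1), "positive")
})

test_that("the age-series cohort mirrors the study design", {
  ser <- make_age_series(seed = 42L, shape = c(32L, 32L))
  expect_equal(nrow(ser$manifest), 21L)
  expect_equal(sort(unique(ser$manifest$age_days)), seq(75L, 225L, 25L))
  expect_equal(unname(table(ser$manifest$age_days)), rep(3L, 7L),
               ignore_attr = TRUE)
  expect_equal(anyDuplicated(ser$manifest$seed), 0L)
  ser2 <- make_age_series(seed = 42L, shape = c(32L, 32L))
  expect_identical(ser$manifest, ser2$manifest)

  wl <- lapply(c(445L, 532L, 632L), function(w)
    make_age_series(seed = 7L, shape = c(32L, 32L), wavelength_nm = w))
  geo <- lapply(wl, function(s) generate_phantom(s$specs[[1]])$label_map)
  expect_identical(geo[[1]], geo[[2]])   # identical geometry across lambda
  expect_identical(geo[[1]], geo[[3]])
  c44 <- vapply(wl, function(s) {
    gt <- generate_phantom(s$specs[[1]])
    median(gt$mueller_map[, , 4, 4][gt$label_map == 1L])
  }, 0)
  expect_true(c44[1] < c44[2] && c44[2] < c44[3])  # deeper Rayleigh at 445 nm
})

test_that("paraffin embedding scales down the polarimetric signal", {
  g0 <- generate_phantom(phantom_spec(shape = c(40L, 40L), age_days = 150L,
                                      seed = 3L))
  g1 <- generate_phantom(phantom_spec(shape = c(40L, 40L), age_days = 150L,
                                      seed = 3L, preparation = "paraffin"))
  expect_lt(median(g1$mueller_map[, , 2, 2][g1$tissue]),
            median(g0$mueller_map[, , 2, 2][g0$tissue]))
})

test_that("mixture moments of m44 match the closed-form two-component oracle", {
  # with patches and jitter suppressed, the m44 tissue distribution is a
  # two-point (background/core) mixture convolved with tiny jitter; its
  # skewness follows the closed-form mixture expression in the mixing
  # fraction within Monte-Carlo error
  sp <- phantom_spec(shape = c(96L, 96L), age_days = 225L, seed = 11L,
                     patch_coverage = 0, patch_coverage_growth = 0,
                     jitter_a = 1e-4, jitter_c = 1e-3, jitter_c_core = 1e-3,
                     rim_width_px = 0.01)
  gt <- generate_phantom(sp)
  m44 <- gt$mueller_map[, , 4, 4][gt$tissue]
  f <- mean(gt$label_map[gt$tissue] == 2L)
  expect_gt(f, 0)          # deterministic draw at this seed
  expect_lt(f, 0.49)
  emp <- central_moments(m44)
  skew_oracle <- (1 - 2 * f) / sqrt(f * (1 - f))
  # MC standard error of the skewness of a Bernoulli mixture
  se <- sqrt(6 / (f * length(m44)))
  expect_lt(abs(emp$skewness - skew_oracle), 3 * max(se, 0.05))
})
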