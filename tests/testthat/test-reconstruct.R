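test_that("intensity stacks validate completeness, shape and sign", {
  imgs <- setNames(lapply(state_pairs(), function(k) matrix(1, 2, 2)),
                   state_pairs())
  expect_s3_class(intensity_stack(imgs), "intensity_stack")
  err <- expect_error(intensity_stack(imgs[setdiff(names(imgs), "LV")]))
  expect_match(conditionMessage(err), "LV")
  bad <- imgs; bad$HH <- matrix(1, 3, 2)
  expect_error(intensity_stack(bad), "shape")
  neg <- imgs; neg$HH[1, 1] <- -1
  expect_error(intensity_stack(neg), "nonnegative")
})

test_that("a uniform stack reconstructs an ideal depolarizer of strength 4c", {
  cval <- 2.5
  imgs <- setNames(lapply(state_pairs(), function(k) matrix(cval, 3, 4)),
                   state_pairs())
  rec <- reconstruct_mueller(intensity_stack(imgs))
  expect_equal(rec$elements[2, 3, 1, 1], 4 * cval)
  for (i in 1:4) for (j in 1:4)
    if (i != 1 || j != 1) expect_equal(max(abs(rec$elements[, , i, j])), 0)
})

test_that("ideal synthesized stacks reconstruct to exactly twice the sample matrix", {
  rec <- reconstruct_mueller(ideal_stack(diag(4)))
  expect_equal(rec$elements[1, 1, , ], 2 * diag(4), tolerance = 1e-14)

  set.seed(23)
  for (k in 1:100) {
    M <- random_physical_mueller()
    rec <- reconstruct_mueller(ideal_stack(M))
    expect_equal(rec$elements[1, 1, , ], 2 * M, tolerance = 1e-12)
  }
})

test_that("reconstruction is linear in the stack", {
  set.seed(5)
  M1 <- random_physical_mueller(); M2 <- random_physical_mueller()
  s1 <- ideal_stack(M1); s2 <- ideal_stack(M2)
  ssum <- intensity_stack(setNames(lapply(state_pairs(), function(k)
    s1$images[[k]] + s2$images[[k]]), state_pairs()))
  expect_equal(reconstruct_mueller(ssum)$elements,
               reconstruct_mueller(s1)$elements +
                 reconstruct_mueller(s2)$elements,
               tolerance = 1e-12)
})

test_that("perturbing one intensity image changes exactly its element planes", {
  # an intensity (g, a) enters plane (i, j) iff the generator belongs to the
  # column-j state pair and the analyzer to the row-i pair
  combos <- list("1" = c("H", "V"), "2" = c("H", "V"),
                 "3" = c("P", "M"), "4" = c("R", "L"))
  sign_of <- function(state, idx)
    if (idx == 1) 1 else if (state %in% c("H", "P", "R")) 1 else -1
  base <- ideal_stack(random_physical_mueller())
  rec0 <- reconstruct_mueller(base)
  for (pair in c("HH", "RL", "PV", "MR")) {
    g <- substr(pair, 1, 1); a <- substr(pair, 2, 2)
    pert <- base
    pert$images[[pair]] <- pert$images[[pair]] + 1
    rec1 <- reconstruct_mueller(pert)
    for (i in 1:4) for (j in 1:4) {
      delta <- rec1$elements[1, 1, i, j] - rec0$elements[1, 1, i, j]
      in_formula <- g %in% combos[[j]] && a %in% combos[[i]]
      if (in_formula) expect_equal(delta, sign_of(g, j) * sign_of(a, i))
      else expect_equal(delta, 0)
    }
  }
})

test_that("m11 normalization cancels scale and masks degenerate pixels", {
  M <- random_physical_mueller()
  img <- reconstruct_mueller(ideal_stack(M, shape = c(4L, 4L)))
  img$elements[2, 2, , ] <- 0          # dead pixel: m11 = 0
  nm <- normalize_by_m11(img)
  expect_true(nm$normalized)
  expect_false(nm$mask[2, 2])
  expect_true(all(is.na(nm$elements[2, 2, , ])))
  expect_equal(nm$elements[1, 1, , ], M / M[1, 1], tolerance = 1e-12)
  expect_equal(nm$elements[1, 1, 1, 1], 1)
  expect_error(normalize_by_m11(nm), "already normalized")
  expect_error(normalize_by_m11(img, floor = 2), "fraction")
})

test_that("round-trip identity holds for the full measure-reconstruct-normalize chain", {
  set.seed(31)
  for (k in 1:20) {
    M <- random_physical_mueller()
    nm <- normalize_by_m11(reconstruct_mueller(ideal_stack(M)))
    expect_lt(max(abs(nm$elements[1, 1, , ] - M / M[1, 1])), 1e-10)
  }
})

test_that("tissue masks recover the phantom footprint and reject empty input", {
  sp <- phantom_spec(shape = c(48L, 48L), age_days = 100L, seed = 9L)
  gt <- generate_phantom(sp)
  stack <- forward_measure(gt, noise_snr = 50)
  raw <- reconstruct_mueller(stack)
  mask <- tissue_mask(raw, method = "fixed", param = 0.6)
  agreement <- mean(mask == (gt$label_map > 0))
  expect_gte(agreement, 0.95)

  # uniform m11 with percentile 0 keeps everything
  uni <- reconstruct_mueller(intensity_stack(setNames(
    lapply(state_pairs(), function(k) matrix(1, 2, 2)), state_pairs())))
  expect_true(all(tissue_mask(uni, "percentile", 0)))

  # zero image: empty mask, downstream statistics refuse to run
  zero <- uni
  zero$elements[, , , ] <- 0
  expect_warning(mk <- tissue_mask(zero, "percentile", 50), "no signal")
  expect_false(any(mk))
  nzero <- normalize_by_m11(zero)
  expect_false(any(nzero$mask))
  expect_error(sample_moments(nzero, parameters = "m22"), "empty region")
})
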