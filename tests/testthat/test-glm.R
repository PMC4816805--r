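test_that("voxelwise t equals an independent per-voxel regression oracle", {
  co <- make_test_cohort(20)
  stk <- make_noise_stack(20, c(4, 3, 2), seed = 13)
  des <- make_design(co)
  sm <- fit_voxelwise_t(stk, des)
  expect_equal(sm$df, 20 - 7)
  for (v in c(1, 5, 11, 24)) {
    fit <- lm(stk$data[, v] ~ bais_vividness + age + gender + total_gm +
                digit_span + music_years, data = as.data.frame(co))
    oracle_t <- summary(fit)$coefficients["bais_vividness", "t value"]
    expect_equal(as.vector(sm$values)[v], oracle_t, tolerance = 1e-10)
  }
})

test_that("opposite contrasts mirror the t map and masks exclude voxels", {
  co <- make_test_cohort(18)
  stk <- make_noise_stack(18, c(4, 4, 3), seed = 6)
  des <- make_design(co)
  tp <- fit_voxelwise_t(stk, des, contrast = 1)
  tn <- fit_voxelwise_t(stk, des, contrast = -1)
  expect_equal(tn$values, -tp$values)
  mask <- volume_map(as.numeric(seq_len(48) <= 10), stk$grid, "mask")
  tm <- fit_voxelwise_t(stk, des, mask = mask)
  expect_true(all(is.na(as.vector(tm$values)[11:48])))
  expect_equal(attr(tm, "n_excluded"), 38L)
})

test_that("zero-residual-variance voxels are excluded rather than infinite", {
  co <- make_test_cohort(15)
  stk <- make_noise_stack(15, c(3, 3, 3), seed = 2)
  stk$data[, 4] <- co$bais_vividness          # y exactly equals the interest column
  des <- make_design(co)
  sm <- fit_voxelwise_t(stk, des)
  expect_true(is.na(as.vector(sm$values)[4]))
  expect_gte(attr(sm, "n_excluded"), 1L)
})

test_that("null t statistics follow the Student reference distribution", {
  set.seed(32)
  co <- make_test_cohort(24, seed = 77)
  co$bais_vividness <- sample(co$bais_vividness)  # sever any link to the maps
  co$bais_total <- (co$bais_vividness + co$bais_control) / 2
  stk <- make_noise_stack(24, c(12, 12, 12), seed = 32)
  sm <- fit_voxelwise_t(stk, make_design(co))
  ks <- ks.test(as.vector(sm$values), pt, df = sm$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("a nuisance column orthogonal to interest and data leaves t unchanged", {
  co <- make_test_cohort(22)
  stk <- make_noise_stack(22, c(2, 2, 2), seed = 10)
  des <- make_design(co)
  t0 <- fit_voxelwise_t(stk, des)
  # build a column orthogonal to every design column and every map voxel
  set.seed(99)
  w <- rnorm(22)
  w <- resid(lm(w ~ unclass(des) + stk$data - 1))
  co2 <- as.data.frame(co); co2$extra <- w
  des2 <- make_design(co2, nuisances = c("age", "gender", "total_gm",
                                         "digit_span", "music_years", "extra"))
  t1 <- fit_voxelwise_t(volume_stack(stk$data, stk$grid), des2)
  # same beta/SE geometry, df differs by one
  rat <- as.vector(t1$values) / as.vector(t0$values)
  expect_equal(rat, rep(sqrt((22 - 8) / (22 - 7)), 8), tolerance = 1e-8)
})

test_that("design construction enforces a single interest score and full rank", {
  co <- make_test_cohort(16)
  expect_error(make_design(co, interest = c("bais_vividness", "bais_control")),
               "exactly one")
  expect_error(make_design(co, nuisances = c("age", "bais_control")), "nuisance")
  co$dup <- co$age
  expect_error(make_design(co, nuisances = c("age", "dup")), "rank deficient")
})

test_that("ROI gray matter residualization behaves at its degenerate corners", {
  co <- make_test_cohort(14)
  stk <- make_noise_stack(14, c(4, 4, 4), seed = 5)
  sel <- seq_len(64) <= 8
  # nuisance-free: residuals are the centered ROI means
  roi <- adjusted_roi_gm(stk, NULL, sel)
  means <- rowMeans(stk$data[, sel])
  expect_equal(roi, means - mean(means), tolerance = 1e-12)
  # constant maps: all residuals zero
  cstk <- volume_stack(matrix(1, 14, 64), stk$grid)
  expect_equal(max(abs(adjusted_roi_gm(cstk, NULL, sel))), 0, tolerance = 1e-12)
  expect_error(adjusted_roi_gm(stk, NULL, rep(FALSE, 64)), "empty")
  # implanted effect survives residualization with the implanted sign
  nuis <- cbind(co$age, co$gender)
  stk$data[, sel] <- stk$data[, sel] + outer(2 * co$bais_vividness + 0.5 * co$age,
                                             rep(1, 8))
  roi2 <- adjusted_roi_gm(stk, nuis, sel)
  expect_gt(pearson_r(roi2, co$bais_vividness)$r, 0.5)
})

test_that("t-to-Z conversion preserves tail probability and symmetry", {
  expect_equal(z_from_t(0, 30), 0)
  expect_equal(z_from_t(1.8, 1e7), 1.8, tolerance = 1e-3)
  z <- z_from_t(3.57, 67)
  expect_equal(pnorm(z, lower.tail = FALSE), pt(3.57, 67, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(z, 2), 3.40)  # the df-67 deviate prints as expected
  expect_equal(z_from_t(-2.2, 40), -z_from_t(2.2, 40))
  zf <- z_from_f(5.51, 4, 220)
  expect_equal(pnorm(zf, lower.tail = FALSE), pf(5.51, 4, 220, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(round(zf, 2), 3.43)
})
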