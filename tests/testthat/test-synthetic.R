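test_that("generators are pure functions of (config, seed)", {
  cfg <- synth_config(n_structural = 12L, n_functional = 10L,
                      structural_grid = voxel_grid(c(9L, 9L, 9L), 1.5),
                      functional_grid = voxel_grid(c(15L, 15L, 15L), 2))
  expect_identical(gen_cohort(cfg, seed = 5), gen_cohort(cfg, seed = 5))
  co <- gen_cohort(cfg, seed = 5)
  g1 <- gen_gm_maps(co, cfg, seed = 6)
  g2 <- gen_gm_maps(co, cfg, seed = 6)
  expect_identical(g1$stack$data, g2$stack$data)
  f1 <- gen_condition_tmaps(co, cfg, seed = 7)
  f2 <- gen_condition_tmaps(co, cfg, seed = 7)
  expect_identical(f1$stack$data, f2$stack$data)
  # generation does not clobber the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_cohort(cfg, seed = 9)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("cohort scores respect scale ranges and large-sample correlation targets", {
  cfg <- synth_config(n_structural = 5000L)
  co <- gen_cohort(cfg, seed = 10)
  expect_true(all(co$bais_vividness >= 1 & co$bais_vividness <= 7))
  expect_true(all(co$vviq_vividness >= 1 & co$vviq_vividness <= 5))
  expect_true(all(co$age >= 20 & co$age <= 81))
  expect_equal(co$bais_total, (co$bais_vividness + co$bais_control) / 2)
  expect_lt(abs(cor(co$bais_vividness, co$bais_control) - 0.68), 0.03)
  expect_lt(abs(cor(co$bais_vividness, co$vviq_vividness) - 0.57), 0.03)
  # zero targets give near-zero correlations
  cfg0 <- synth_config(n_structural = 5000L, rho_vividness_control = 0,
                       rho_vividness_vviq = 0, rho_control_vviq = 0)
  co0 <- gen_cohort(cfg0, seed = 11)
  expect_lt(abs(cor(co0$bais_vividness, co0$bais_control)), 0.04)
  expect_lt(abs(cor(co0$bais_vividness, co0$vviq_vividness)), 0.04)
  expect_error(synth_config(rho_vividness_control = 0.99, rho_vividness_vviq = -0.99),
               "positive definite")
})

test_that("gray-matter maps are nonnegative with a null effect when slope is zero", {
  cfg <- synth_config(n_structural = 40L, gm_target_r = 0, gm_effect_sd = 0,
                      structural_grid = voxel_grid(c(13L, 13L, 13L), 1.5))
  co <- gen_cohort(cfg, seed = 2)
  gm <- gen_gm_maps(co, cfg, seed = 3)
  expect_true(all(gm$stack$data >= 0))
  roi <- adjusted_roi_gm(gm$stack, NULL, gm$truth$effect_mask)
  expect_gt(pearson_r(roi, co$bais_vividness)$p_two_sided, 0.001)
  expect_error(gen_gm_maps(co, synth_config(
    gm_effect_center_mm = c(500, 0, 0),
    structural_grid = voxel_grid(c(13L, 13L, 13L), 1.5)), seed = 3),
    "outside the grid")
})

test_that("zero similarity coupling yields a null similarity-behaviour link", {
  cfg <- synth_config(n_functional = 200L, n_structural = 200L, rsa_coupling = 0,
                      functional_grid = voxel_grid(c(15L, 15L, 15L), 2))
  co <- gen_cohort(cfg, seed = 4)
  fn <- gen_condition_tmaps(co, cfg, seed = 5)
  sph <- make_sphere_mask(c(0, 0, 0), 12, cfg$functional_grid)
  summ <- rsa_summary(fn$stack, sph)
  res <- similarity_behavior_link(summ, co[seq_len(200), ])
  expect_lt(abs(res$r), 0.2)
})

test_that("ground truth travels beside the data, never inside it", {
  cfg <- synth_config(n_structural = 12L,
                      structural_grid = voxel_grid(c(9L, 9L, 9L), 1.5),
                      functional_grid = voxel_grid(c(15L, 15L, 15L), 2))
  co <- gen_cohort(cfg, seed = 1)
  gm <- gen_gm_maps(co, cfg, seed = 2)
  fn <- gen_condition_tmaps(co, cfg, seed = 3)
  expect_named(gm, c("stack", "truth"))
  expect_named(fn, c("stack", "truth"))
  expect_false(any(c("truth", "d", "z_target") %in% names(gm$stack)))
  expect_false(any(c("truth", "z_target") %in% names(fn$stack)))
})

test_that("each analysis stage recovers its implanted effect across 50 seeded replicates", {
  cfg <- synth_config()
  sph <- make_sphere_mask(cfg$sphere_center_mm, cfg$sphere_radius_mm,
                          cfg$functional_grid)
  nuis_cols <- c("age", "gender", "total_gm", "digit_span", "music_years")
  vbm_hit <- anova_hit <- rsa_hit <- logical(50)
  for (s in 1:50) {
    co <- gen_cohort(cfg, seed = s)
    gm <- gen_gm_maps(co, cfg, seed = 1000 + s)
    stk <- gaussian_smooth(gm$stack, cfg$smooth_fwhm)
    mask <- absolute_mask(stk, 0.05)
    des <- make_design(co)
    tab <- cluster_fwe(stk, des, n_perm = 39, seed = 2000 + s, mask = mask)
    hit <- FALSE
    if (nrow(tab)) {
      sig <- tab[tab$p_fwe <= 0.05, , drop = FALSE]
      if (nrow(sig)) {
        d <- sqrt((sig$peak_x - cfg$gm_effect_center_mm[1])^2 +
                  (sig$peak_y - cfg$gm_effect_center_mm[2])^2 +
                  (sig$peak_z - cfg$gm_effect_center_mm[3])^2)
        hit <- any(d <= 1.5 * max(cfg$gm_effect_extent_mm))
      }
    }
    vbm_hit[s] <- hit
    fn <- gen_condition_tmaps(co, cfg, seed = 3000 + s)
    sv <- anova_svc_peak_fwe(fn$stack, sph, n_perm = 39, seed = 4000 + s)
    anova_hit[s] <- sv$p_fwe <= 0.05
    summ <- rsa_summary(fn$stack, sph)
    rsa_hit[s] <- similarity_behavior_link(summ, co)$r < 0
  }
  expect_gte(mean(vbm_hit), 0.9)
  expect_gte(mean(anova_hit), 0.9)
  expect_gte(mean(rsa_hit), 0.9)
})
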