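test_that("cluster labeling finds constructed blobs and matches a graph oracle", {
  g <- voxel_grid(c(10, 10, 10), 2)
  vals <- array(0, g$shape)
  vals[2:4, 2:4, 2:4] <- 10          # one 27-voxel blob
  vals[8:9, 8:9, 8] <- 10            # a second, separated blob (4 voxels)
  sm <- volume_map(vals, g, "t"); sm$df <- 30; class(sm) <- c("stat_map", class(sm))
  tab <- label_clusters(sm, forming_threshold_p = 0.005)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$size, c(27L, 4L))
  expect_equal(tab$peak_stat, c(10, 10))
  # random map: decomposition equals an igraph connected-components oracle
  set.seed(12)
  vals2 <- array(rnorm(1000), g$shape)
  sm2 <- volume_map(vals2, g, "t"); sm2$df <- 30; class(sm2) <- c("stat_map", class(sm2))
  for (conn in c(6, 18, 26)) {
    tab2 <- label_clusters(sm2, forming_threshold_p = 0.1, connectivity = conn)
    cutoff <- qt(0.1, 30, lower.tail = FALSE)
    supra <- which(vals2 > cutoff)
    ijk <- arrayInd(supra, g$shape)
    lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(conn)]
    adj <- which(outer(seq_along(supra), seq_along(supra), Vectorize(function(a, b) {
      d <- abs(ijk[a, ] - ijk[b, ])
      a < b && all(d <= 1) && sum(d) > 0 && sum(d > 0) <= lim &&
        (lim > 1 || sum(d) == 1)
    })), arr.ind = TRUE)
    gr <- igraph::graph_from_edgelist(cbind(adj[, 1], adj[, 2]), directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0, length(supra) - igraph::vcount(gr)))
    comp <- igraph::components(gr)
    expect_equal(sort(tab2$size, decreasing = TRUE),
                 sort(as.integer(comp$csize), decreasing = TRUE))
  }
  # no supra-threshold voxels: empty table, not an error
  low <- volume_map(array(-1, g$shape), g, "t"); low$df <- 30
  class(low) <- c("stat_map", class(low))
  expect_equal(nrow(label_clusters(low)), 0L)
})

test_that("permutation cluster FWE is reproducible, monotone, and floored at 1/(m+1)", {
  co <- make_test_cohort(16)
  stk <- make_noise_stack(16, c(8, 8, 8), seed = 3)
  # implant a strong effect in a corner block
  block <- as.vector(array(seq_len(512), c(8, 8, 8))[1:3, 1:3, 1:3])
  stk$data[, block] <- stk$data[, block] + outer(co$bais_vividness, rep(2, 27))
  des <- make_design(co)
  tab1 <- cluster_fwe(stk, des, n_perm = 99, seed = 7)
  tab2 <- cluster_fwe(stk, des, n_perm = 99, seed = 7)
  expect_identical(as.data.frame(tab1), as.data.frame(tab2))
  expect_identical(attr(tab1, "max_cluster_null"), attr(tab2, "max_cluster_null"))
  expect_gte(nrow(tab1), 1L)
  # strongest implanted cluster reaches the plus-one floor
  expect_equal(tab1$p_fwe[1], 1 / 100)
  # p_fwe monotone nonincreasing in cluster size
  if (nrow(tab1) > 1) expect_true(all(diff(tab1$p_fwe) >= 0))
  expect_true(all(tab1$p_fwe > 0 & tab1$p_fwe <= 1))
})

test_that("a single-voxel sphere reduces SVC to a direct permutation test", {
  co <- make_test_cohort(14)
  stk <- make_noise_stack(14, c(5, 5, 5), seed = 21)
  des <- make_design(co)
  g <- stk$grid
  sph1 <- make_sphere_mask(voxel_centers(g, matrix(c(3, 3, 3), 1)), 0, g)
  expect_equal(sph1$n_voxels, 1L)
  res <- svc_peak_fwe(stk, des, sphere = sph1, n_perm = 199, seed = 5)
  # independent single-voxel oracle: Freedman-Lane by explicit lm residuals
  v <- sph1$linear_indices
  y <- stk$data[, v]
  X <- unclass(des)
  Z <- X[, -2]
  e <- resid(lm(y ~ Z - 1)); fit0 <- fitted(lm(y ~ Z - 1))
  tobs <- summary(lm(y ~ X - 1))$coefficients[2, "t value"]
  perms <- imageryvbm:::with_seed(5, lapply(1:199, function(i) sample.int(14)))
  tperm <- vapply(perms, function(p) {
    ystar <- fit0 + e[p]
    summary(lm(ystar ~ X - 1))$coefficients[2, "t value"]
  }, numeric(1))
  expect_equal(res$peak_stat, tobs, tolerance = 1e-10)
  expect_equal(res$p_fwe, (sum(tperm >= tobs) + 1) / 200)
})

test_that("SVC over the whole mask equals whole-map peak-level FWE", {
  co <- make_test_cohort(15)
  stk <- make_noise_stack(15, c(6, 6, 6), seed = 17)
  des <- make_design(co)
  full <- volume_map(array(1, stk$grid$shape), stk$grid, "mask")
  a <- svc_peak_fwe(stk, des, sphere = full, n_perm = 99, seed = 3)
  big <- make_sphere_mask(c(0, 0, 0), 1000, stk$grid)
  b <- svc_peak_fwe(stk, des, sphere = big, n_perm = 99, seed = 3)
  expect_equal(a$peak_stat, b$peak_stat)
  expect_equal(a$p_fwe, b$p_fwe)
  expect_equal(a$max_stat_null, b$max_stat_null)
})

test_that("SVC p values are the plus-one tail fraction of the null maxima", {
  co <- make_test_cohort(12)
  stk <- make_noise_stack(12, c(5, 5, 5), seed = 8)
  des <- make_design(co)
  sph <- make_sphere_mask(c(0, 0, 0), 4, stk$grid)
  res <- svc_peak_fwe(stk, des, sphere = sph, n_perm = 49, seed = 2)
  expect_equal(res$p_fwe,
               (sum(res$max_stat_null >= res$peak_stat) + 1) /
                 (res$n_permutations + 1))
  expect_true(res$p_fwe > 0 && res$p_fwe <= 1)
})

test_that("too few subjects triggers exhaustive enumeration with a warning", {
  expect_warning(p <- imageryvbm:::.draw_perms(4, 100), "exhaustively")
  expect_equal(length(p), 24L)
  expect_equal(length(unique(lapply(p, paste, collapse = ","))), 24L)
})

test_that("sphere errors when it lies outside the analysis mask", {
  co <- make_test_cohort(12)
  stk <- make_noise_stack(12, c(5, 5, 5), seed = 8)
  des <- make_design(co)
  sph <- make_sphere_mask(c(0, 0, 0), 2, stk$grid)
  empty_mask <- volume_map(array(0, stk$grid$shape), stk$grid, "mask")
  expect_error(svc_peak_fwe(stk, des, sphere = sph, mask = empty_mask,
                            n_perm = 19, seed = 1), "outside")
})
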