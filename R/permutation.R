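#' @title Permutation inference
#' @name permutation_inference
#' @description
#' Multiple-comparison correction by max-statistic permutation: cluster
#' level family-wise error (FWE) over the whole analysis mask, and
#' peak-level FWE restricted to a small a-priori sphere (small volume
#' correction, SVC). The subject-level exchangeability scheme is
#' Freedman--Lane: the data are residualized on the nuisance columns,
#' residual rows are permuted, the nuisance fit is added back, and the
#' full model is refit. p-values use the plus-one convention
#' `(b + 1) / (m + 1)` so they are never exactly zero.
NULL

# Save/restore RNG state around a seeded computation.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# All permutations of 1..n (n small), as a list.
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", factorial(n))
  idx <- 1L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[idx]] <- append(p, n, after = pos)
      idx <- idx + 1L
    }
  }
  out
}

# Draw n_perm row permutations of 1..n; falls back to exhaustive
# enumeration (with a warning) when n! <= n_perm.
.draw_perms <- function(n, n_perm) {
  if (n <= 10 && factorial(n) <= n_perm) {
    warning(sprintf("only %d distinct permutations of %d subjects; enumerating exhaustively",
                    factorial(n), n), call. = FALSE)
    return(.all_perms(n))
  }
  lapply(seq_len(n_perm), function(i) sample.int(n))
}

# Freedman-Lane engine: returns a function(perm) -> t vector over the
# supplied voxel columns, plus the observed t vector (identity fit).
.fl_engine <- function(Y, design) {
  X <- unclass(design)
  cidx <- attr(design, "interest")
  Z <- X[, -cidx, drop = FALSE]
  Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
  Fit0 <- Hz %*% Y
  E <- Y - Fit0
  list(observed = .ols_t(Y, X, cidx)$t,
       perm_t = function(perm) .ols_t(Fit0 + E[perm, , drop = FALSE], X, cidx)$t,
       df = nrow(X) - ncol(X), cidx = cidx)
}

#' Cluster-level FWE correction by permutation
#'
#' Computes the observed supra-threshold clusters of the contrast t map,
#' then builds the permutation null distribution of the *maximum* cluster
#' size under Freedman--Lane row permutation; each observed cluster's
#' `p_fwe` is the plus-one-corrected proportion of permutations whose
#' maximum cluster size is at least as large.
#'
#' @param stack a `volume_stack` of subject maps.
#' @param design a `vbm_design`.
#' @param contrast `+1` or `-1` for the direction of the interest column.
#' @param forming_threshold_p cluster-forming per-voxel p (default 0.005).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed integer seed; results are bit-reproducible given
#'   `(seed, n_perm)`.
#' @param connectivity 6, 18 or 26.
#' @param mask optional analysis mask (`volume_map`, logical, or 0/1).
#' @return a `cluster_table` with an extra `p_fwe` column and attributes
#'   `n_permutations`, `seed`, `max_cluster_null`.
#' @export
cluster_fwe <- function(stack, design, contrast = 1, forming_threshold_p = 0.005,
                        n_perm = 1000, seed = 1L, connectivity = 18, mask = NULL) {
  grid <- stack$grid
  V <- ncol(stack$data)
  sel <- if (is.null(mask)) rep(TRUE, V) else mask_selector(mask, grid)
  lin_of_col <- which(sel)
  Y <- stack$data[, sel, drop = FALSE]
  eng <- .fl_engine(Y, design)
  cutoff <- stats::qt(forming_threshold_p, eng$df, lower.tail = FALSE)
  sgn <- sign(contrast)

  obs_t <- sgn * eng$observed
  supra <- lin_of_col[!is.na(obs_t) & obs_t > cutoff]
  comps <- .label_components(supra, grid$shape, connectivity)
  vals <- rep(NA_real_, V); vals[lin_of_col] <- obs_t
  tab <- .cluster_table_from_comps(comps, vals, grid, cutoff, connectivity,
                                   eng$df, "t")

  max_null <- with_seed(seed, {
    perms <- .draw_perms(nrow(Y), n_perm)
    vapply(perms, function(p) {
      tv <- sgn * eng$perm_t(p)
      sup <- lin_of_col[!is.na(tv) & tv > cutoff]
      if (!length(sup)) return(0L)
      max(lengths(.label_components(sup, grid$shape, connectivity)))
    }, integer(1))
  })
  m <- length(max_null)
  if (nrow(tab)) {
    tab$p_fwe <- vapply(tab$size, function(s) (sum(max_null >= s) + 1) / (m + 1),
                        numeric(1))
  } else {
    tab$p_fwe <- numeric(0)
  }
  attr(tab, "n_permutations") <- m
  attr(tab, "seed") <- seed
  attr(tab, "max_cluster_null") <- max_null
  tab
}

#' Peak-level FWE within a small volume (SVC)
#'
#' Max-statistic permutation restricted to the voxels of an a-priori
#' sphere: the observed peak t within the sphere is compared with the
#' permutation distribution of the sphere-wise maximum.
#'
#' @inheritParams cluster_fwe
#' @param sphere a `sphere_mask` (or any mask accepted by the package); a
#'   mask covering the whole analysis mask reduces SVC to whole-map
#'   peak-level FWE.
#' @return list with `peak_stat`, `peak_mm` (world coordinate),
#'   `peak_z_score`, `p_fwe`, `df`, `n_permutations`, `seed`,
#'   `max_stat_null`.
#' @export
svc_peak_fwe <- function(stack, design, contrast = 1, sphere, n_perm = 1000,
                         seed = 1L, mask = NULL) {
  grid <- stack$grid
  sel <- mask_selector(sphere, grid)
  if (!is.null(mask)) sel <- sel & mask_selector(mask, grid)
  if (!any(sel))
    stop("sphere lies entirely outside the analysis mask", call. = FALSE)
  lin_of_col <- which(sel)
  Y <- stack$data[, sel, drop = FALSE]
  eng <- .fl_engine(Y, design)
  sgn <- sign(contrast)
  obs <- sgn * eng$observed
  pk <- which.max(obs)
  pk_lin <- lin_of_col[pk] - 1L
  idx <- cbind(pk_lin %% grid$shape[1],
               (pk_lin %/% grid$shape[1]) %% grid$shape[2],
               pk_lin %/% (grid$shape[1] * grid$shape[2])) + 1L
  max_null <- with_seed(seed, {
    perms <- .draw_perms(nrow(Y), n_perm)
    vapply(perms, function(p) max(sgn * eng$perm_t(p), na.rm = TRUE), numeric(1))
  })
  m <- length(max_null)
  list(peak_stat = obs[pk],
       peak_mm = drop(voxel_centers(grid, idx)),
       peak_z_score = z_from_t(obs[pk], eng$df),
       p_fwe = (sum(max_null >= obs[pk]) + 1) / (m + 1),
       df = eng$df, n_permutations = m, seed = seed,
       max_stat_null = max_null)
}
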