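#' @title Voxelwise repeated-measures ANOVA across vocalization conditions
#' @name condition_anova
#' @description
#' Second-level one-way repeated-measures ANOVA applied voxelwise to
#' per-subject per-condition t maps for the five intelligible
#' vocalization types (neutral vowels, laughter, screams, pleasure,
#' disgust; a sixth, spectrally rotated, condition serves as an
#' unintelligible control and is not part of the omnibus F). With k = 5
#' conditions and n = 56 subjects the classical within-subject
#' decomposition gives F degrees of freedom (4, 220). No sphericity
#' correction is applied.
NULL

#' Canonical condition labels
#' @export
vocal_conditions <- c("neutral", "laughter", "scream", "pleasure", "disgust")

#' Build a subjects x conditions x voxels stack
#'
#' @param data numeric array `n_subjects x n_conditions x n_voxels`, or a
#'   list (over conditions) of `volume_stack`s on one grid.
#' @param grid a `voxel_grid` (required when `data` is an array).
#' @param conditions condition labels (length = 2nd dimension).
#' @param subject_ids optional subject labels.
#' @return object of class `condition_stack`.
#' @export
condition_stack <- function(data, grid = NULL,
                            conditions = c(vocal_conditions, "rotated"),
                            subject_ids = NULL) {
  if (is.list(data) && !is.array(data)) {
    grid <- data[[1]]$grid
    n <- nrow(data[[1]]$data)
    arr <- array(NA_real_, dim = c(n, length(data), ncol(data[[1]]$data)))
    for (j in seq_along(data)) {
      if (!grids_equal(data[[j]]$grid, grid)) stop("grid mismatch across conditions")
      arr[, j, ] <- data[[j]]$data
    }
    data <- arr
  }
  if (length(dim(data)) != 3L) stop("data must be subjects x conditions x voxels")
  if (dim(data)[2] != length(conditions))
    stop("conditions must label the second dimension")
  if (anyNA(data)) stop("missing condition map: every subject needs every condition")
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(dim(data)[1]))
  structure(list(data = data, grid = grid, conditions = conditions,
                 subject_ids = subject_ids),
            class = "condition_stack")
}

#' @export
print.condition_stack <- function(x, ...) {
  cat(sprintf("condition_stack: %d subjects x %d conditions (%s) x %d voxels\n",
              dim(x$data)[1], dim(x$data)[2],
              paste(x$conditions, collapse = ", "), dim(x$data)[3]))
  invisible(x)
}

# Vectorized classical one-way within-subject ANOVA over voxels.
# A: n x k x V array. Returns list(F = vector over V, df = c(k-1, (k-1)(n-1))).
# Engine over the classical within-subject decomposition. Exploits the
# fact that under within-subject condition-label permutation the total,
# per-subject and squared-value sums are invariant — only the condition
# sums move — so each permutation costs a single rowsum pass.
.rm_anova_engine <- function(A) {
  n <- dim(A)[1]; k <- dim(A)[2]; V <- dim(A)[3]
  M <- matrix(A, n * k, V)                     # row index s + n*(j-1)
  subj <- rep(seq_len(n), k)
  tot_sum <- colSums(M)
  C <- tot_sum^2 / (n * k)
  ss_total <- colSums(M^2) - C
  subj_sum <- rowsum(M, subj)
  ss_subj <- colSums(subj_sum^2) / k - C
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  f_from_labels <- function(lab) {
    cond_sum <- rowsum(M, lab)
    ss_cond <- colSums(cond_sum^2) / n - C
    ss_err <- ss_total - ss_subj - ss_cond
    Fv <- (ss_cond / df1) / (ss_err / df2)
    # no between-condition variation at all (e.g. flat profiles): F is 0
    Fv[ss_cond <= 1e-12 * (abs(C) + ss_total)] <- 0
    Fv
  }
  list(F = f_from_labels(rep(seq_len(k), each = n)), df = c(df1, df2),
       f_from_labels = f_from_labels, n = n, k = k)
}

# Within-subject label permutation for the engine: returns a label vector
# aligned with rows s + n*(j-1) of the flattened data.
.perm_labels <- function(n, k) {
  lab <- matrix(0L, n, k)
  for (s in seq_len(n)) lab[s, ] <- sample.int(k)
  as.vector(lab)
}

.rm_anova_core <- function(A) {
  eng <- .rm_anova_engine(A)
  list(F = eng$F, df = eng$df)
}

#' Voxelwise repeated-measures F map
#'
#' Per voxel, the classical one-way within-subject ANOVA:
#' `F = MS_condition / MS_error` with df `(k - 1, (k - 1)(n - 1))` — the
#' subject main effect is absorbed, so F is invariant to adding any
#' per-subject constant.
#'
#' @param cstack a `condition_stack`.
#' @param conditions which condition labels to include (default: the five
#'   intelligible vocal conditions).
#' @return a `stat_map` of kind `"F"` with `df` a pair.
#' @export
rm_anova_f <- function(cstack, conditions = vocal_conditions) {
  j <- match(conditions, cstack$conditions)
  if (anyNA(j)) stop("unknown condition label(s): ",
                     paste(conditions[is.na(j)], collapse = ", "))
  if (length(j) < 2L) stop("need at least 2 conditions")
  A <- cstack$data[, j, , drop = FALSE]
  if (dim(A)[1] < 2L) stop("need at least 2 subjects")
  res <- .rm_anova_core(A)
  fv <- res$F
  fv[!is.finite(fv)] <- NA_real_
  sm <- volume_map(fv, cstack$grid, kind = "F")
  sm$df <- res$df
  attr(sm, "n_excluded") <- sum(is.na(fv))
  class(sm) <- c("stat_map", class(sm))
  sm
}

#' Cluster-level FWE for the condition F map
#'
#' Delegates to max-statistic permutation with condition-label permutation
#' *within subject* as the exchangeability scheme (under the null of no
#' condition effect, a subject's condition maps are exchangeable).
#'
#' @inheritParams rm_anova_f
#' @param forming_threshold_p per-voxel cluster-forming p.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param connectivity 6, 18 or 26.
#' @param mask optional analysis mask.
#' @return a `cluster_table` with `p_fwe`, as in [cluster_fwe()].
#' @export
anova_cluster_fwe <- function(cstack, conditions = vocal_conditions,
                              forming_threshold_p = 0.005, n_perm = 1000,
                              seed = 1L, connectivity = 18, mask = NULL) {
  j <- match(conditions, cstack$conditions)
  A <- cstack$data[, j, , drop = FALSE]
  grid <- cstack$grid
  V <- dim(A)[3]
  sel <- if (is.null(mask)) rep(TRUE, V) else mask_selector(mask, grid)
  lin_of_col <- which(sel)
  A <- A[, , sel, drop = FALSE]
  eng <- .rm_anova_engine(A)
  cutoff <- stats::qf(forming_threshold_p, eng$df[1], eng$df[2], lower.tail = FALSE)
  fobs <- eng$F
  supra <- lin_of_col[is.finite(fobs) & fobs > cutoff]
  comps <- .label_components(supra, grid$shape, connectivity)
  vals <- rep(NA_real_, V); vals[lin_of_col] <- fobs
  tab <- .cluster_table_from_comps(comps, vals, grid, cutoff, connectivity,
                                   eng$df, "F")
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      fp <- eng$f_from_labels(.perm_labels(eng$n, eng$k))
      sup <- lin_of_col[is.finite(fp) & fp > cutoff]
      if (!length(sup)) return(0L)
      max(lengths(.label_components(sup, grid$shape, connectivity)))
    }, integer(1))
  })
  m <- length(max_null)
  tab$p_fwe <- if (nrow(tab))
    vapply(tab$size, function(s) (sum(max_null >= s) + 1) / (m + 1), numeric(1))
  else numeric(0)
  attr(tab, "n_permutations") <- m
  attr(tab, "seed") <- seed
  attr(tab, "max_cluster_null") <- max_null
  tab
}

#' Peak-level SVC for the condition F map
#'
#' Small-volume correction of the repeated-measures F within an a-priori
#' sphere, by within-subject condition-label permutation of the maximum F.
#'
#' @inheritParams anova_cluster_fwe
#' @param sphere a `sphere_mask` or other mask.
#' @return list with `peak_stat`, `peak_mm`, `peak_z_score`, `p_fwe`,
#'   `df`, `n_permutations`, `seed`, `max_stat_null`.
#' @export
anova_svc_peak_fwe <- function(cstack, sphere, conditions = vocal_conditions,
                               n_perm = 1000, seed = 1L, mask = NULL) {
  j <- match(conditions, cstack$conditions)
  grid <- cstack$grid
  sel <- mask_selector(sphere, grid)
  if (!is.null(mask)) sel <- sel & mask_selector(mask, grid)
  if (!any(sel)) stop("sphere lies entirely outside the analysis mask", call. = FALSE)
  lin_of_col <- which(sel)
  A <- cstack$data[, j, sel, drop = FALSE]
  eng <- .rm_anova_engine(A)
  obs <- list(F = eng$F, df = eng$df)
  pk <- which.max(obs$F)
  pk_lin <- lin_of_col[pk] - 1L
  idx <- cbind(pk_lin %% grid$shape[1],
               (pk_lin %/% grid$shape[1]) %% grid$shape[2],
               pk_lin %/% (grid$shape[1] * grid$shape[2])) + 1L
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      max(eng$f_from_labels(.perm_labels(eng$n, eng$k)), na.rm = TRUE), numeric(1))
  })
  m <- length(max_null)
  list(peak_stat = obs$F[pk],
       peak_mm = drop(voxel_centers(grid, idx)),
       peak_z_score = z_from_f(obs$F[pk], obs$df[1], obs$df[2]),
       p_fwe = (sum(max_null >= obs$F[pk]) + 1) / (m + 1),
       df = obs$df, n_permutations = m, seed = seed,
       max_stat_null = max_null)
}
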