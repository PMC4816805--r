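#' @title Voxelwise structure-behaviour regression
#' @name structure_behavior_glm
#' @description
#' Mass-univariate ordinary-least-squares regression of per-subject
#' modulated gray-matter maps on a behavioural score of interest, with the
#' standard nuisance set (age, gender, total gray-matter volume, digit
#' span, years of musical training). With n = 74 subjects and 7 design
#' columns the contrast t statistic carries 67 error degrees of freedom.
NULL

.nuisance_default <- c("age", "gender", "total_gm", "digit_span", "music_years")
.imagery_columns <- c("bais_vividness", "bais_control", "bais_total", "vviq_vividness")

#' Build a design matrix from a cohort table
#'
#' One column of interest (a single imagery score — the two auditory
#' subscales are never entered together because they are very highly
#' correlated), an intercept, and the nuisance covariates. Covariates are
#' entered unstandardized; the OLS t is invariant to affine column
#' rescaling given the intercept.
#'
#' @param cohort a cohort data frame (see [read_cohort()]).
#' @param interest name of the column of interest.
#' @param nuisances character vector of nuisance column names.
#' @return numeric design matrix with attributes `interest` (column index)
#'   and class `vbm_design`; columns `intercept`, interest, nuisances.
#' @export
make_design <- function(cohort, interest = "bais_vividness",
                        nuisances = .nuisance_default) {
  if (length(interest) != 1L)
    stop("exactly one column of interest per fit", call. = FALSE)
  if (any(nuisances %in% .imagery_columns))
    stop("imagery scores may not be used as nuisance covariates in the voxelwise design",
         call. = FALSE)
  cols <- c(interest, nuisances)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) stop("cohort lacks column(s): ", paste(missing, collapse = ", "))
  X <- cbind(intercept = 1,
             as.matrix(as.data.frame(cohort)[, cols, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  structure(X, interest = 2L, class = c("vbm_design", "matrix", "array"))
}

# Core vectorized OLS over voxels.
# Y: n x V; X: n x p; cidx: contrast column. Returns list(t, beta, df, sigma2).
.ols_t <- function(Y, X, cidx) {
  n <- nrow(X); p <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  Beta <- XtXinv %*% crossprod(X, Y)        # p x V
  Res <- Y - X %*% Beta
  df <- n - p
  sigma2 <- colSums(Res^2) / df
  se <- sqrt(sigma2 * XtXinv[cidx, cidx])
  tval <- Beta[cidx, ] / se
  list(t = tval, beta = Beta, df = df, sigma2 = sigma2)
}

#' Voxelwise t map for a contrast of interest
#'
#' Fits ordinary least squares independently at every in-mask voxel and
#' returns `t = beta / SE(beta)` for the column of interest, with
#' `df = n - p`. Voxels outside the mask, or with zero residual variance,
#' are excluded (set to `NA`) and their count is recorded.
#'
#' @param stack a `volume_stack` of gray-matter maps (rows = subjects,
#'   order matching the design rows).
#' @param design a `vbm_design` from [make_design()].
#' @param contrast `+1` or `-1`: sign applied to the interest column's t.
#' @param mask optional `volume_map` of kind `"mask"`.
#' @return object of class `stat_map` (also a `volume_map`) with fields
#'   `values` (t array, `NA` outside mask), `grid`, `kind = "t"`, `df`,
#'   and attribute `n_excluded`.
#' @export
fit_voxelwise_t <- function(stack, design, contrast = 1, mask = NULL) {
  X <- unclass(design)
  if (nrow(X) != nrow(stack$data))
    stop("design rows must match number of subject maps", call. = FALSE)
  if (nrow(X) < ncol(X) + 2L)
    stop("need at least 2 more subjects than design columns", call. = FALSE)
  cidx <- attr(design, "interest")
  V <- ncol(stack$data)
  inmask <- if (is.null(mask)) rep(TRUE, V) else as.vector(mask$values) > 0
  Y <- stack$data[, inmask, drop = FALSE]
  fit <- .ols_t(Y, X, cidx)
  tv <- sign(contrast) * fit$t
  zerovar <- !is.finite(tv) |
    fit$sigma2 <= 1e-16 * pmax(colMeans(Y^2), 1e-300)
  tv[zerovar] <- NA_real_
  out <- rep(NA_real_, V)
  out[inmask] <- tv
  sm <- volume_map(out, stack$grid, kind = "t")
  sm$df <- fit$df
  attr(sm, "n_excluded") <- sum(!inmask) + sum(zerovar)
  class(sm) <- c("stat_map", class(sm))
  sm
}

#' @export
print.stat_map <- function(x, ...) {
  df <- if (length(x$df) == 2) sprintf("(%d, %d)", x$df[1], x$df[2]) else sprintf("%d", x$df)
  cat(sprintf("stat_map [%s, df = %s] %s; max = %.3f, %d voxels excluded\n",
              x$kind, df, paste(x$grid$shape, collapse = "x"),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              attr(x, "n_excluded") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residualized mean gray matter within a cluster
#'
#' Per subject, the mean gray-matter value over a cluster mask is
#' residualized on an intercept plus the nuisance covariates (the design
#' *without* the column of interest), yielding adjusted values suitable
#' for scatterplots and partial correlations against behavioural scores.
#'
#' @param stack a `volume_stack` of gray-matter maps.
#' @param nuisance_matrix numeric matrix of nuisance covariates (no
#'   intercept, no interest column); `NULL` for simple centering.
#' @param cluster_mask `volume_map` of kind `"mask"`, `sphere_mask`, or
#'   logical/0-1 vector over voxels; must select at least one voxel.
#' @return numeric vector of per-subject residualized ROI means.
#' @export
adjusted_roi_gm <- function(stack, nuisance_matrix = NULL, cluster_mask) {
  sel <- mask_selector(cluster_mask, stack$grid)
  if (!any(sel)) stop("empty cluster mask", call. = FALSE)
  roi_mean <- rowMeans(stack$data[, sel, drop = FALSE])
  X <- if (is.null(nuisance_matrix)) matrix(1, length(roi_mean), 1)
       else cbind(1, as.matrix(nuisance_matrix))
  stats::lm.fit(X, roi_mean)$residuals
}

# Normalize the many mask representations to a logical voxel selector.
mask_selector <- function(mask, grid) {
  if (inherits(mask, "sphere_mask")) {
    sel <- rep(FALSE, n_voxels(grid))
    sel[mask$linear_indices] <- TRUE
    sel
  } else if (inherits(mask, "volume_map")) {
    as.vector(mask$values) > 0
  } else if (is.logical(mask)) {
    mask
  } else {
    as.vector(mask) > 0
  }
}

#' Convert a t statistic to a standard-normal deviate
#'
#' Returns the Z value with the same upper-tail probability as `t` under a
#' Student t distribution with `df` degrees of freedom, computed on the
#' log scale for numerical stability in the far tails.
#'
#' @param t t value(s).
#' @param df error degrees of freedom.
#' @return Z value(s); `z_from_t(0, df) = 0` and `Z -> t` as `df` grows.
#' @export
z_from_t <- function(t, df) {
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  z <- -stats::qnorm(lp, log.p = TRUE)
  sign(t) * z
}

#' Convert an F statistic to a standard-normal deviate
#'
#' @param f F value(s) (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Z with the same upper-tail probability as `f`.
#' @export
z_from_f <- function(f, df1, df2) {
  lp <- stats::pf(f, df1, df2, lower.tail = FALSE, log.p = TRUE)
  -stats::qnorm(lp, log.p = TRUE)
}
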