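#' @title Questionnaire scoring and correlation machinery
#' @name behavioral
#' @description
#' Scoring for the two self-report imagery instruments used throughout the
#' package — a 2 x 14-item auditory imagery scale (vividness and control
#' subscales, 7-point ratings) and a 16-item visual imagery questionnaire
#' (5-point ratings, inverted so that higher = more vivid) — together with
#' the Pearson / Fisher-z / partial-correlation machinery used by every
#' brain--behaviour analysis.
NULL

.check_items <- function(x, n, lo, hi, label) {
  if (length(x) != n)
    stop(sprintf("%s: expected %d item responses, got %d", label, n, length(x)),
         call. = FALSE)
  bad <- which(is.na(x) | x < lo | x > hi | x != round(x))
  if (length(bad))
    stop(sprintf("%s: invalid response at item index %s (must be integer in %d..%d)",
                 label, paste(bad, collapse = ", "), lo, hi), call. = FALSE)
  invisible(TRUE)
}

#' Score the auditory imagery scale
#'
#' Each 14-item subscale is scored as the arithmetic mean of its item
#' ratings (1--7); the total score is the mean of the two subscale scores.
#'
#' @param vividness_items integer vector of 14 vividness ratings in 1..7.
#' @param control_items integer vector of 14 control ratings in 1..7.
#' @return list with components `vividness`, `control`, `total`, each in
#'   \[1, 7\].
#' @examples
#' score_bais(rep(4, 14), rep(6, 14))  # vividness 4, control 6, total 5
#' @export
score_bais <- function(vividness_items, control_items) {
  .check_items(vividness_items, 14L, 1L, 7L, "vividness subscale")
  .check_items(control_items, 14L, 1L, 7L, "control subscale")
  v <- mean(vividness_items)
  k <- mean(control_items)
  list(vividness = v, control = k, total = (v + k) / 2)
}

#' Score the visual imagery questionnaire
#'
#' Raw ratings run from 1 (perfectly clear and vivid) to 5 (no image at
#' all); the score is inverted, `6 - mean(raw)`, so that higher scores
#' correspond to more vivid visual imagery, matching the direction of the
#' auditory scale.
#'
#' @param item_responses integer vector of 16 ratings in 1..5.
#' @return inverted vividness score in \[1, 5\].
#' @export
score_vviq <- function(item_responses) {
  .check_items(item_responses, 16L, 1L, 5L, "visual imagery questionnaire")
  6 - mean(item_responses)
}

correlation_result <- function(r, p, n, df) {
  structure(list(r = r, p_two_sided = p, n = n, df = df),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g (two-sided), n = %d, df = %d\n",
              x$r, x$p_two_sided, x$n, x$df))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t distribution on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return a `correlation_result` with fields `r`, `p_two_sided`, `n`, `df`.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  df <- n - 2L
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  correlation_result(r, p, n, df)
}

#' Fisher z transformation
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to
#' correlation coefficients before averaging. By default `|r|` is clipped
#' at `1 - 1e-7` so that identical maps (r exactly 1) yield a large finite
#' z rather than infinity; set `clip = NULL` to disable clipping, in which
#' case `|r| = 1` is a domain error.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @param clip clipping bound for `|r|`, or `NULL` to disable.
#' @return z value(s); odd symmetric in `r`.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must not exceed 1", call. = FALSE)
  if (is.null(clip)) {
    if (any(abs(r) == 1, na.rm = TRUE))
      stop("|r| = 1 with clipping disabled: Fisher z undefined", call. = FALSE)
  } else {
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on an intercept plus the covariate columns; the degrees of
#' freedom are reduced by the number of covariates.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix (or data frame) of covariates, one row
#'   per observation; `NULL` or zero columns reduces to [pearson_r()].
#' @return a `correlation_result`; `df = n - 2 - ncol(covariates)`.
#' @export
partial_r <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates) || NCOL(covariates) == 0L || length(covariates) == 0L)
    return(pearson_r(x, y))
  Z <- as.matrix(covariates)
  if (nrow(Z) != n) stop("covariate rows must match length of x", call. = FALSE)
  k <- ncol(Z)
  if (n <= k + 2L) stop("too few observations for the covariate set", call. = FALSE)
  X <- cbind(intercept = 1, Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    drop <- setdiff(seq_len(ncol(X)), keep)
    nm <- colnames(X)[drop]
    stop(sprintf("rank-deficient covariates: collinear column(s) %s",
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), 1e-300) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), 1e-300))
    stop("degenerate input: zero residual variance after partialling", call. = FALSE)
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  correlation_result(r, p, n, as.integer(df))
}

#' Shapiro-Wilk normality check
#'
#' Convenience wrapper over [stats::shapiro.test()] for checking that
#' questionnaire scores are compatible with normality before parametric
#' correlation analyses.
#'
#' @param x numeric vector.
#' @return the `htest` object from [stats::shapiro.test()].
#' @export
normality_check <- function(x) stats::shapiro.test(x)

.cohort_columns <- c("subject_id", "age", "gender", "total_gm", "digit_span",
                     "music_years", "bais_vividness", "bais_control",
                     "bais_total", "vviq_vividness")

#' Read or write a cohort table
#'
#' One row per subject with columns for all subject-level fields:
#' `subject_id`, `age`, `gender` (0/1), `total_gm`, `digit_span`,
#' `music_years`, `bais_vividness`, `bais_control`, `bais_total`,
#' `vviq_vividness`.
#'
#' @param path CSV file path.
#' @return `read_cohort` returns a data frame of class `cohort`.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_columns, names(d))
  if (length(missing))
    stop("cohort table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_cohort(d)
  class(d) <- c("cohort", "data.frame")
  d
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(d) {
  rng <- list(bais_vividness = c(1, 7), bais_control = c(1, 7),
              bais_total = c(1, 7), vviq_vividness = c(1, 5))
  for (nm in names(rng)) {
    v <- d[[nm]]
    if (any(v < rng[[nm]][1] | v > rng[[nm]][2], na.rm = TRUE))
      stop(sprintf("column %s outside its scale range [%g, %g]",
                   nm, rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
  }
  tot <- (d$bais_vividness + d$bais_control) / 2
  if (any(abs(tot - d$bais_total) > 1e-6, na.rm = TRUE))
    stop("bais_total must equal the mean of the two subscale scores", call. = FALSE)
  invisible(TRUE)
}
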