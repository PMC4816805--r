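#' @title Representational similarity analysis on ROI spheres
#' @name rsa
#' @description
#' Per subject, condition t maps are reduced to vectors over the voxels
#' of a 12-mm ROI sphere (925 voxels on a 2-mm grid), all unordered pairs
#' of intelligible-condition vectors are Pearson-correlated (10 pairs for
#' 5 conditions), correlations are Fisher-z transformed and averaged into
#' one similarity summary per subject; an analogous summary averages the
#' 5 pairs of each vocal condition against the rotated condition. Lower
#' mean similarity = more distinct (more specific) condition
#' representations. The summaries are then correlated with vividness of
#' auditory imagery — the package's sign convention is that a *negative*
#' correlation means higher representational specificity goes with more
#' vivid imagery.
NULL

#' Extract the ROI vector of a statistic map
#'
#' Values at the sphere's voxels in deterministic (lexicographic index)
#' order; length equals the mask size.
#'
#' @param t_map a `volume_map`/`stat_map` of kind `"t"` (other kinds are
#'   accepted with a warning).
#' @param sphere a `sphere_mask` on the same grid.
#' @return numeric vector of length `sphere$n_voxels`.
#' @export
extract_roi_vector <- function(t_map, sphere) {
  if (!grids_equal(t_map$grid, sphere$grid))
    stop("sphere and map are on different grids", call. = FALSE)
  if (!identical(t_map$kind, "t"))
    warning("extracting from a map of kind '", t_map$kind, "', not 't'")
  v <- as.vector(t_map$values)[sphere$linear_indices]
  if (anyNA(v))
    stop("NaN/NA inside sphere at voxel indices: ",
         paste(utils::head(which(is.na(v)), 10), collapse = ", "), call. = FALSE)
  v
}

.pair_cor_z <- function(vectors, pairs, clip) {
  sds <- vapply(vectors, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance ROI vector for condition(s): ",
         paste(names(vectors)[sds == 0], collapse = ", "), call. = FALSE)
  zs <- apply(pairs, 1, function(pr)
    fisher_z(stats::cor(vectors[[pr[1]]], vectors[[pr[2]]]), clip = clip))
  mean(zs)
}

#' Mean within-vocal pattern similarity
#'
#' Pearson correlations between all `k(k-1)/2` unordered pairs of
#' condition ROI vectors (10 pairs for the 5 vocal conditions), Fisher-z
#' transformed and averaged.
#'
#' @param vectors named list of condition ROI vectors of equal length.
#' @param clip Fisher-z clipping bound (see [fisher_z()]).
#' @return mean Fisher-z similarity (scalar).
#' @export
pairwise_mean_similarity <- function(vectors, clip = 1 - 1e-7) {
  k <- length(vectors)
  if (k < 2L) stop("need at least two condition vectors")
  if (length(unique(lengths(vectors))) != 1L) stop("vectors must have equal length")
  if (is.null(names(vectors))) names(vectors) <- paste0("cond", seq_len(k))
  pairs <- t(utils::combn(names(vectors), 2))
  .pair_cor_z(vectors, pairs, clip)
}

#' Mean vocal-versus-rotated pattern similarity
#'
#' The 5 pairwise correlations of each intelligible condition vector with
#' the rotated-condition vector, Fisher-z transformed and averaged.
#'
#' @param vocal_vectors named list of intelligible-condition ROI vectors.
#' @param rotated_vector rotated-condition ROI vector.
#' @inheritParams pairwise_mean_similarity
#' @return mean Fisher-z similarity (scalar).
#' @export
vocal_vs_rotated_similarity <- function(vocal_vectors, rotated_vector,
                                        clip = 1 - 1e-7) {
  if (is.null(names(vocal_vectors)))
    names(vocal_vectors) <- paste0("cond", seq_along(vocal_vectors))
  all_v <- c(vocal_vectors, list(rotated = rotated_vector))
  pairs <- cbind(names(vocal_vectors), "rotated")
  .pair_cor_z(all_v, pairs, clip)
}

#' Per-subject similarity summaries for a condition stack
#'
#' Runs the ROI extraction and both similarity summaries for every
#' subject of a `condition_stack`.
#'
#' @param cstack a `condition_stack` whose conditions include the five
#'   vocal conditions (and optionally `"rotated"`).
#' @param sphere a `sphere_mask` on the stack's grid.
#' @inheritParams pairwise_mean_similarity
#' @return data frame of class `similarity_summary` with columns
#'   `subject_id`, `mean_z_within_vocal`, `mean_z_vocal_vs_rotated` (NA
#'   when no rotated condition is present) and `n_voxels_roi`.
#' @export
rsa_summary <- function(cstack, sphere, clip = 1 - 1e-7) {
  jv <- match(vocal_conditions, cstack$conditions)
  if (anyNA(jv)) stop("stack lacks vocal condition(s): ",
                      paste(vocal_conditions[is.na(jv)], collapse = ", "))
  jr <- match("rotated", cstack$conditions)
  sel <- sphere$linear_indices
  n <- dim(cstack$data)[1]
  wv <- numeric(n); vr <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    vecs <- lapply(jv, function(j) cstack$data[s, j, sel])
    names(vecs) <- vocal_conditions
    if (anyNA(unlist(vecs))) stop("NaN/NA inside sphere for subject ", s)
    wv[s] <- pairwise_mean_similarity(vecs, clip = clip)
    if (!is.na(jr))
      vr[s] <- vocal_vs_rotated_similarity(vecs, cstack$data[s, jr, sel], clip = clip)
  }
  structure(data.frame(subject_id = cstack$subject_ids,
                       mean_z_within_vocal = wv,
                       mean_z_vocal_vs_rotated = vr,
                       n_voxels_roi = sphere$n_voxels,
                       stringsAsFactors = FALSE),
            class = c("similarity_summary", "data.frame"))
}

#' Correlate pattern similarity with behaviour
#'
#' Pearson (or, given covariates, partial) correlation between a
#' per-subject similarity summary and a behavioural score. A negative r
#' means that subjects with more distinct condition representations
#' report more vivid imagery.
#'
#' @param summaries a `similarity_summary` data frame.
#' @param vividness named numeric vector (names = subject ids) or a
#'   cohort data frame with `subject_id` plus the score column.
#' @param score column name used when `vividness` is a cohort table.
#' @param covariates optional covariate matrix/data frame (e.g. the
#'   nuisance set of the structural analysis), rows in subject order.
#' @param which `"within_vocal"` or `"vocal_vs_rotated"`.
#' @return a `correlation_result`.
#' @export
similarity_behavior_link <- function(summaries, vividness,
                                     score = "bais_vividness",
                                     covariates = NULL,
                                     which = c("within_vocal", "vocal_vs_rotated")) {
  which <- match.arg(which)
  col <- paste0("mean_z_", which)
  if (is.data.frame(vividness)) {
    m <- match(summaries$subject_id, vividness$subject_id)
    if (anyNA(m))
      stop("unmatched subject id(s): ",
           paste(summaries$subject_id[is.na(m)], collapse = ", "), call. = FALSE)
    v <- vividness[[score]][m]
    if (!is.null(covariates)) covariates <- as.matrix(covariates)[m, , drop = FALSE]
  } else {
    if (!is.null(names(vividness))) {
      m <- match(summaries$subject_id, names(vividness))
      if (anyNA(m))
        stop("unmatched subject id(s): ",
             paste(summaries$subject_id[is.na(m)], collapse = ", "), call. = FALSE)
      v <- unname(vividness[m])
    } else {
      if (length(vividness) != nrow(summaries))
        stop("vividness length must match number of subjects", call. = FALSE)
      v <- vividness
    }
  }
  partial_r(summaries[[col]], v, covariates)
}
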