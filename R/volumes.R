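#' @title Volume data model
#' @name volumes
#' @description
#' Lightweight 3-D volume containers shared by every imaging stage: a
#' `voxel_grid` (shape, isotropic-or-not voxel size, world origin), a
#' `volume_map` (scalar values on a grid), a `volume_stack` (one map per
#' subject, stored as a subjects x voxels matrix), and a `sphere_mask`
#' ROI. World coordinates are millimetres in an MNI-like axis-aligned
#' frame; the world coordinate of the *center* of voxel `(i, j, k)`
#' (1-based R indices) is `origin + (index - 1) * voxel_size`, and ROI
#' membership is always evaluated at voxel centers.
NULL

#' Construct a voxel grid
#'
#' @param shape integer vector of 3 positive extents.
#' @param voxel_size_mm voxel edge lengths in mm (scalar recycled to 3).
#' @param origin_mm world coordinate (mm) of the center of the first voxel;
#'   defaults to centering the grid on the world origin.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size_mm,
                       origin_mm = -(shape - 1) / 2 * voxel_size_mm) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  origin_mm <- rep_len(as.numeric(origin_mm), 3L)
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid %s @ %s mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(x$voxel_size_mm, collapse = "x"),
              paste(format(x$origin_mm), collapse = ", ")))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$shape)

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size_mm, b$voxel_size_mm)) &&
    isTRUE(all.equal(a$origin_mm, b$origin_mm))
}

#' World coordinates of voxel centers
#'
#' @param grid a `voxel_grid`.
#' @param index matrix (n x 3) of 1-based voxel indices; `NULL` for all voxels.
#' @return n x 3 matrix of world mm coordinates of voxel centers.
#' @export
voxel_centers <- function(grid, index = NULL) {
  if (is.null(index)) {
    index <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                                   j = seq_len(grid$shape[2]),
                                   k = seq_len(grid$shape[3])))
  }
  index <- matrix(as.numeric(index), ncol = 3)
  sweep(sweep(index - 1, 2, grid$voxel_size_mm, "*"), 2, grid$origin_mm, "+")
}

#' Construct a volume map
#'
#' @param values numeric array matching `grid$shape` (a vector is reshaped).
#' @param grid a `voxel_grid`.
#' @param kind one of `"gray_matter"`, `"t"`, `"F"`, `"mask"`, `"other"`.
#' @return an object of class `volume_map`.
#' @export
volume_map <- function(values, grid, kind = c("other", "gray_matter", "t", "F", "mask")) {
  kind <- match.arg(kind)
  values <- array(as.numeric(values), dim = grid$shape)
  if (kind == "gray_matter" && any(values < 0, na.rm = TRUE))
    stop("gray-matter values must be nonnegative")
  if (kind == "mask" && !all(values %in% c(0, 1) | is.na(values)))
    stop("mask values must be 0/1")
  structure(list(values = values, grid = grid, kind = kind),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat(sprintf("volume_map [%s] %s @ %s mm; range [%.4g, %.4g]\n",
              x$kind, paste(x$grid$shape, collapse = "x"),
              paste(x$grid$voxel_size_mm, collapse = "x"),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Stack per-subject maps into a subjects-by-voxels matrix
#'
#' @param maps list of `volume_map`s on one grid, or a numeric matrix
#'   (subjects x voxels) plus `grid`.
#' @param grid required when `maps` is a matrix.
#' @param kind value kind carried by the stack.
#' @param subject_ids optional labels, one per row.
#' @return object of class `volume_stack` with fields `data` (n x V
#'   matrix, voxels in R array order), `grid`, `kind`, `subject_ids`.
#' @export
volume_stack <- function(maps, grid = NULL, kind = "gray_matter", subject_ids = NULL) {
  if (is.matrix(maps)) {
    if (is.null(grid)) stop("grid required when maps is a matrix")
    data <- maps
  } else {
    grid <- maps[[1]]$grid
    for (m in maps) {
      if (!grids_equal(m$grid, grid)) stop("grid mismatch across subject maps")
    }
    data <- do.call(rbind, lapply(maps, function(m) as.vector(m$values)))
  }
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(nrow(data)))
  structure(list(data = data, grid = grid, kind = kind,
                 subject_ids = subject_ids),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("volume_stack [%s]: %d subjects x %d voxels (%s grid)\n",
              x$kind, nrow(x$data), ncol(x$data),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Spherical region-of-interest mask
#'
#' Materializes a sphere given by a world-coordinate center and radius as
#' the set of voxels whose *centers* lie at Euclidean distance less than
#' or equal to the radius (inclusive boundary). On a 2-mm isotropic grid a
#' 12-mm sphere centered on a voxel center contains exactly 925 voxels.
#'
#' @param center_mm world coordinate (mm) of the sphere center.
#' @param radius_mm sphere radius in mm (>= 0).
#' @param grid a `voxel_grid`.
#' @return object of class `sphere_mask` with fields `center_mm`,
#'   `radius_mm`, `voxel_indices` (n x 3 matrix of 1-based indices in
#'   lexicographic order), `linear_indices`, `n_voxels`, `grid`.
#' @export
make_sphere_mask <- function(center_mm, radius_mm, grid) {
  if (radius_mm < 0) stop("radius must be nonnegative")
  center_mm <- rep_len(as.numeric(center_mm), 3L)
  # candidate index window (bounding box), clipped to the grid
  lo <- pmax(1L, ceiling((center_mm - radius_mm - grid$origin_mm) / grid$voxel_size_mm) + 1L)
  hi <- pmin(grid$shape, floor((center_mm + radius_mm - grid$origin_mm) / grid$voxel_size_mm) + 1L)
  if (any(lo > hi))
    stop("sphere lies entirely outside the grid", call. = FALSE)
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  ctr <- voxel_centers(grid, idx)
  d2 <- rowSums(sweep(ctr, 2, center_mm)^2)
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep))
    stop("sphere lies entirely outside the grid (no voxel center within radius)",
         call. = FALSE)
  idx <- idx[keep, , drop = FALSE]
  ord <- order(idx[, 3], idx[, 2], idx[, 1])  # lexicographic, fastest first = i
  idx <- idx[ord, , drop = FALSE]
  lin <- idx[, 1] + (idx[, 2] - 1L) * grid$shape[1] +
    (idx[, 3] - 1L) * grid$shape[1] * grid$shape[2]
  structure(list(center_mm = center_mm, radius_mm = radius_mm,
                 voxel_indices = idx, linear_indices = as.integer(lin),
                 n_voxels = nrow(idx), grid = grid),
            class = "sphere_mask")
}

#' @export
print.sphere_mask <- function(x, ...) {
  cat(sprintf("sphere_mask: center (%s) mm, radius %g mm, %d voxels\n",
              paste(format(x$center_mm), collapse = ", "),
              x$radius_mm, x$n_voxels))
  invisible(x)
}

# 1-D Gaussian convolution matrix for one axis (zero-padded boundary).
.conv_matrix <- function(n, sigma_vox, boundary = "zero") {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-half, half), sd = sigma_vox)
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in seq(-half, half)) {
    w <- k[o + half + 1]
    rows <- seq_len(n) + o
    ok <- rows >= 1 & rows <= n
    M[cbind(rows[ok], seq_len(n)[ok])] <- M[cbind(rows[ok], seq_len(n)[ok])] + w
  }
  if (boundary == "replicate") {
    # renormalize columns so edge mass is preserved
    cs <- colSums(M)
    M <- sweep(M, 2, cs, "/")
  }
  M
}

.smooth_array <- function(a, grid, fwhm_mm, boundary = "zero") {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- grid$shape
  for (ax in 1:3) {
    sv <- sigma / grid$voxel_size_mm[ax]
    if (sv <= 0) next
    M <- .conv_matrix(d[ax], sv, boundary)
    perm <- c(ax, setdiff(1:3, ax))
    ap <- aperm(a, perm)
    ap <- matrix(ap, nrow = d[ax])
    ap <- M %*% ap
    ap <- array(ap, dim = d[perm])
    a <- aperm(ap, order(perm))
  }
  a
}

#' Gaussian smoothing of a volume
#'
#' Separable convolution with an isotropic Gaussian kernel of the given
#' full-width at half-maximum; `sigma = fwhm / (2 sqrt(2 ln 2))` per axis,
#' converted to voxel units by the axis voxel size. Boundaries are
#' zero-padded by default (mass of interior impulses is conserved).
#'
#' @param map a `volume_map` (or `volume_stack`, smoothed row-wise).
#' @param fwhm_mm kernel FWHM in mm (>= 0; 0 is the identity).
#' @param boundary `"zero"` or `"replicate"`.
#' @return smoothed object of the same class.
#' @export
gaussian_smooth <- function(map, fwhm_mm, boundary = c("zero", "replicate")) {
  boundary <- match.arg(boundary)
  if (fwhm_mm < 0) stop("fwhm must be nonnegative")
  if (fwhm_mm == 0) return(map)
  if (inherits(map, "volume_stack")) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
    d <- map$grid$shape
    X <- map$data  # n x V; smooth every subject with shared conv matrices
    n <- nrow(X)
    a <- array(t(X), dim = c(d, n))
    for (ax in 1:3) {
      sv <- sigma / map$grid$voxel_size_mm[ax]
      M <- .conv_matrix(d[ax], sv, boundary)
      perm <- c(ax, setdiff(1:3, ax), 4L)
      ap <- aperm(a, perm)
      dimp <- dim(ap)
      ap <- M %*% matrix(ap, nrow = d[ax])
      ap <- array(ap, dim = dimp)
      a <- aperm(ap, order(perm))
    }
    map$data <- t(matrix(a, nrow = prod(d)))
    return(map)
  }
  map$values <- .smooth_array(map$values, map$grid, fwhm_mm, boundary)
  map
}

#' Absolute masking across subjects
#'
#' A voxel is retained only if *every* subject's value is at or above the
#' threshold (the usual absolute-threshold convention for modulated
#' gray-matter analyses, here with threshold 0.05 by default to avoid edge
#' effects at tissue borders).
#'
#' @param stack a `volume_stack` (or list of `volume_map`s on one grid).
#' @param threshold absolute intensity threshold.
#' @return a `volume_map` of kind `"mask"` with values in `{0, 1}`.
#' @export
absolute_mask <- function(stack, threshold = 0.05) {
  if (!inherits(stack, "volume_stack")) stack <- volume_stack(stack)
  keep <- apply(stack$data, 2, min) >= threshold
  volume_map(as.numeric(keep), stack$grid, kind = "mask")
}
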