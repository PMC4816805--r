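#' @title NIfTI-1 input/output
#' @name nifti_io
#' @description
#' Round-trip between the package's `volume_map` container and NIfTI-1
#' files via the RNifti library. Only axis-aligned RAS-like affines (a
#' positive diagonal scale plus translation) are supported; the world
#' coordinate of voxel `(1,1,1)`'s center is the affine translation.
NULL

.grid_affine <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$voxel_size_mm[1]
  m[2, 2] <- grid$voxel_size_mm[2]
  m[3, 3] <- grid$voxel_size_mm[3]
  m[1:3, 4] <- grid$origin_mm
  m
}

.grid_from_affine <- function(aff, shape) {
  rot <- aff[1:3, 1:3]
  offdiag <- rot - diag(diag(rot))
  if (max(abs(offdiag)) > 1e-4 || any(diag(rot) <= 0))
    stop("unsupported orientation: affine must be axis-aligned with positive scales",
         call. = FALSE)
  voxel_grid(shape, diag(rot), aff[1:3, 4])
}

#' Write a volume map to a NIfTI-1 file
#'
#' @param map a `volume_map`; masks are written as uint8, everything else
#'   as float32.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  dt <- if (map$kind == "mask") "uint8" else "float"
  img <- RNifti::asNifti(map$values, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(.grid_affine(map$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume map from a NIfTI-1 file
#'
#' @param path input path.
#' @param kind value kind to attach to the result.
#' @return a `volume_map` (3-D input) with shape, voxel size and origin
#'   recovered from the affine.
#' @export
read_volume <- function(path, kind = "other") {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L) stop("expected a 3-D NIfTI volume; see read_volume_stack")
  grid <- .grid_from_affine(RNifti::xform(img), dm)
  volume_map(as.array(img), grid, kind = kind)
}

#' Write/read a 4-D subject stack
#'
#' A `volume_stack` round-trips through a single 4-D NIfTI file whose
#' fourth dimension indexes subjects.
#'
#' @param stack a `volume_stack`.
#' @param path file path.
#' @return `write_volume_stack` returns `path`; `read_volume_stack`
#'   returns a `volume_stack`.
#' @export
write_volume_stack <- function(stack, path) {
  a <- array(t(stack$data), dim = c(stack$grid$shape, nrow(stack$data)))
  img <- RNifti::asNifti(a, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(.grid_affine(stack$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_stack
#' @param kind value kind to attach.
#' @export
read_volume_stack <- function(path, kind = "gray_matter") {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4L) stop("expected a 4-D NIfTI volume")
  grid <- .grid_from_affine(RNifti::xform(img), dm[1:3])
  data <- t(matrix(as.array(img), nrow = prod(dm[1:3])))
  volume_stack(data, grid, kind = kind)
}
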