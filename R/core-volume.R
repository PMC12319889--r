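#' Volumetric image with a world-space affine
#'
#' A `volume_grid` holds a 3D (or 4D) scalar array together with a 4x4 affine
#' mapping 0-based voxel indices to world coordinates in mm (RAS+). The 4th
#' axis, when present, is declared as `"time"` or `"echo"` in `axis4`; it is
#' never inferred from the data.
#'
#' @param data numeric array, 3D or 4D.
#' @param affine invertible 4x4 matrix, voxel-index (0-based) to world mm.
#' @param axis4 semantics of the 4th axis: `"none"`, `"time"` or `"echo"`.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(data, affine = diag(4), axis4 = c("none", "time", "echo")) {
  axis4 <- match.arg(axis4)
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("volume_grid data must be 3D or 4D, got ", nd, "D")
  if (nd == 4L && axis4 == "none") axis4 <- "time"
  if (nd == 3L) axis4 <- "none"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine is not invertible")
  structure(list(data = data, affine = affine, axis4 = axis4),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$data), collapse = " x "),
      if (x$axis4 != "none") paste0(" (axis4: ", x$axis4, ")"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param axis4 declared semantics of a 4th axis, if any.
#' @return a [volume_grid].
#' @export
read_volume <- function(path, axis4 = c("none", "time", "echo")) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  aff <- if (hdr$sform_code > 0L) {
    # the sform rows store the affine exactly; the qform is quaternion-coded
    rbind(hdr$srow_x, hdr$srow_y, hdr$srow_z, c(0, 0, 0, 1))
  } else structure(RNifti::xform(img), class = NULL)
  dimnames(aff) <- NULL
  arr <- unclass(as.array(img))
  attributes(arr) <- list(dim = dim(arr))
  d <- dim(arr)
  if (length(d) == 3L) axis4 <- "none"
  else axis4 <- match.arg(axis4)
  if (length(d) == 4L && axis4 == "none") axis4 <- "time"
  volume_grid(arr, aff, axis4)
}

#' Write a NIfTI-1 volume
#'
#' @param vol a [volume_grid].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Map world-mm points to continuous 0-based voxel coordinates
#'
#' @param points n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @param grid a [volume_grid] (or a 4x4 affine).
#' @return n x 3 matrix of continuous voxel coordinates, 0-based.
#' @export
world_to_voxel <- function(points, grid) {
  aff <- if (inherits(grid, "volume_grid")) grid$affine else as.matrix(grid)
  pts <- rbind(t(matrix(points, ncol = 3L)), 1)
  out <- solve(aff, pts)
  t(out[1:3, , drop = FALSE])
}

#' Map 0-based voxel coordinates to world mm
#'
#' @inheritParams world_to_voxel
#' @param voxels n x 3 matrix of continuous voxel coordinates.
#' @return n x 3 matrix of world coordinates, mm.
#' @export
voxel_to_world <- function(voxels, grid) {
  aff <- if (inherits(grid, "volume_grid")) grid$affine else as.matrix(grid)
  pts <- rbind(t(matrix(voxels, ncol = 3L)), 1)
  out <- aff %*% pts
  t(out[1:3, , drop = FALSE])
}
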