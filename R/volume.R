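#' Scalar volume: a 3-D grid with a voxel-to-world affine
#'
#' Container for scalar parameter maps (FA, ADC, ...), binary masks and
#' integer label maps. World coordinates are RAS millimetres; voxel indices
#' are 0-based; a world point belongs to the voxel whose center is nearest
#' (componentwise round of the inverse-affine image).
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#' @return An object of class `scalar_volume` with fields `data`, `affine`
#'   and `spacing` (per-axis voxel size in mm, the column norms of the
#'   affine's rotation/scale block).
#' @export
scalar_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, affine = affine, spacing = spacing),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Read a NIfTI volume
#'
#' @param path path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("expected a 3-D image, got ",
                                   length(dim(arr)), " dimensions: ", path)
  affine <- unclass(RNifti::xform(img))
  scalar_volume(array(as.numeric(arr), dim = dim(arr)), affine)
}

#' Write a scalar volume to NIfTI
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; default `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write an integer label map
#'
#' Stores a parcellation label grid against a reference geometry, picking the
#' smallest unsigned/signed integer type that holds the label range.
#'
#' @param labels integer 3-D array (or a voxel-space [parcellation()]).
#' @param reference a [scalar_volume()] supplying the affine; label grid must
#'   match its shape.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labels, reference, path) {
  if (inherits(labels, "parcellation")) labels <- labels$labels
  if (!all(dim(labels) == dim(reference$data)))
    stop("label grid shape does not match reference shape")
  if (any(labels < 0)) stop("labels must be non-negative")
  mx <- max(labels)
  datatype <- if (mx <= 255) "uint8" else if (mx <= 32767) "int16" else "int32"
  vol <- scalar_volume(array(as.numeric(labels), dim = dim(labels)),
                       reference$affine)
  write_volume(vol, path, datatype = datatype)
}

# world (n x 3 mm) -> 0-based voxel indices, nearest voxel center
world_to_voxel <- function(points, affine) {
  points <- rbind_points(points)
  inv <- solve(affine)
  v <- cbind(points, 1) %*% t(inv)
  round(v[, 1:3, drop = FALSE])
}

# 0-based voxel indices -> world mm (voxel centers)
voxel_to_world <- function(idx, affine) {
  idx <- rbind_points(idx)
  w <- cbind(idx, 1) %*% t(affine)
  w[, 1:3, drop = FALSE]
}

rbind_points <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

# trilinear interpolation of a volume at world-mm points; outside-grid
# points evaluate to `outside`
sample_volume <- function(vol, points, method = c("trilinear", "nearest"),
                          outside = NA_real_) {
  method <- match.arg(method)
  points <- rbind_points(points)
  inv <- solve(vol$affine)
  v <- cbind(points, 1) %*% t(inv)
  v <- v[, 1:3, drop = FALSE]
  d <- dim(vol$data)
  if (method == "nearest") {
    i <- round(v)
    ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 &
          i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
          i[, 3] >= 0 & i[, 3] <= d[3] - 1
    out <- rep(outside, nrow(v))
    out[ok] <- vol$data[cbind(i[ok, 1] + 1, i[ok, 2] + 1, i[ok, 3] + 1)]
    return(out)
  }
  f <- floor(v)
  w <- v - f
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 2 &
        f[, 2] >= 0 & f[, 2] <= d[2] - 2 &
        f[, 3] >= 0 & f[, 3] <= d[3] - 2
  # clamp points on the upper boundary into the last cell
  for (ax in 1:3) {
    hi <- abs(v[, ax] - (d[ax] - 1)) < 1e-9
    ok[hi & f[, ax] == d[ax] - 1] <- TRUE
    f[hi, ax] <- pmin(f[hi, ax], d[ax] - 2)
  }
  w <- v - f
  out <- rep(outside, nrow(v))
  if (any(ok)) {
    fo <- f[ok, , drop = FALSE]
    wo <- w[ok, , drop = FALSE]
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
            (if (dy) wo[, 2] else 1 - wo[, 2]) *
            (if (dz) wo[, 3] else 1 - wo[, 3])
      acc <- acc + wt * vol$data[cbind(fo[, 1] + dx + 1,
                                       fo[, 2] + dy + 1,
                                       fo[, 3] + dz + 1)]
    }
    out[ok] <- acc
  }
  out
}
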