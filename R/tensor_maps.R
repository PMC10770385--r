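#' Tensor-derived parameter maps from a diffusion-tensor eigenvalue field
#'
#' Computes the four standard tensor scalar maps from per-voxel sorted
#' eigenvalues (lambda1 >= lambda2 >= lambda3, in mm^2/s):
#' \describe{
#'   \item{ADC}{(l1 + l2 + l3) / 3 (mean diffusivity)}
#'   \item{AD}{l1 (axial diffusivity)}
#'   \item{RD}{(l2 + l3) / 2 (radial diffusivity)}
#'   \item{FA}{sqrt(3/2) * sqrt(sum (li - lbar)^2) / sqrt(sum li^2)}
#' }
#' Voxels outside the mask are 0 in all maps; an all-zero tensor inside the
#' mask gets FA = 0 (not NaN). Negative eigenvalues — a common fit artifact —
#' are clamped to 0 before computing the maps, with a message giving the
#' count.
#'
#' @param lambdas 4-D array (x, y, z, 3) of eigenvalues, sorted descending in
#'   the 4th dimension, or a list of three 3-D arrays.
#' @param mask optional binary 3-D array of valid voxels; default all voxels.
#' @param affine 4x4 voxel-to-world affine shared by all output maps.
#' @return Named list of [scalar_volume()]s: `FA`, `ADC`, `AD`, `RD`.
#' @export
compute_parameter_maps <- function(lambdas, mask = NULL, affine = diag(4)) {
  if (is.list(lambdas)) {
    stopifnot(length(lambdas) == 3L)
    d <- dim(lambdas[[1]])
    lam <- array(0, c(d, 3L))
    for (i in 1:3) lam[, , , i] <- lambdas[[i]]
    lambdas <- lam
  }
  d4 <- dim(lambdas)
  if (length(d4) != 4L || d4[4] != 3L)
    stop("`lambdas` must be an (x, y, z, 3) array")
  d <- d4[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  mask <- array(as.logical(mask), d)
  l1 <- lambdas[, , , 1]; l2 <- lambdas[, , , 2]; l3 <- lambdas[, , , 3]
  if (any((l1 < l2 | l2 < l3) & mask))
    stop("eigenvalues must be sorted descending (l1 >= l2 >= l3) in-mask")
  n_neg <- sum((l1 < 0 | l2 < 0 | l3 < 0) & mask)
  if (n_neg > 0) {
    message("clamping negative eigenvalues to 0 in ", n_neg, " voxel(s)")
    l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  }
  lbar <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- sqrt(1.5) * ifelse(den > 0, num / den, 0)
  zero <- function(x) { x[!mask] <- 0; array(x, d) }
  list(FA  = scalar_volume(zero(pmin(pmax(fa, 0), 1)), affine),
       ADC = scalar_volume(zero(lbar), affine),
       AD  = scalar_volume(zero(l1), affine),
       RD  = scalar_volume(zero((l2 + l3) / 2), affine))
}
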