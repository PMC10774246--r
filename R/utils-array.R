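## Array axis convention throughout the package: dim = c(nz, ny, nx),
## i.e. a[z, y, x], 0-based voxel i has its centre at (i + 0.5) * voxel_mm.
## y is the anterior-posterior axis; the gantry rotates about z.

#' Discretized Gaussian kernel
#'
#' One-dimensional Gaussian kernel sampled at integer offsets and truncated
#' at 4 standard deviations, normalized to unit sum.
#'
#' @param sigma standard deviation in voxel units (> 0)
#' @return numeric vector of odd length
#' @keywords internal
gauss_kernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Convert a FWHM in mm to a kernel standard deviation in voxels
#' @keywords internal
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

## Band matrix implementing 1-D convolution along the first array axis.
## pad = "replicate" clamps indices at the border (kernel mass preserved,
## suitable for image smoothing); pad = "zero" drops out-of-range taps
## (symmetric => the matrix is symmetric => the operator is self-adjoint,
## required by the projector).
conv_matrix <- function(n, kernel, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    w <- kernel[o + r + 1L]
    src <- seq_len(n) + o
    if (pad == "replicate") {
      src <- pmin(pmax(src, 1L), n)
      K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + w
    } else {
      keep <- src >= 1L & src <= n
      K[cbind(which(keep), src[keep])] <- K[cbind(which(keep), src[keep])] + w
    }
  }
  K
}

## Apply a matrix along axis `axis` of a 3-D array (BLAS-backed).
apply_along <- function(x, K, axis) {
  d <- dim(x)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  xp <- if (axis == 1L) x else aperm(x, perm)
  dp <- dim(xp)
  y <- K %*% matrix(xp, nrow = dp[1L])
  dim(y) <- dp
  if (axis == 1L) y else aperm(y, order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' @param x 3-D numeric array
#' @param sigma_vox standard deviation in voxel units; scalar (isotropic)
#' @param pad border handling, `"replicate"` or `"zero"`
#' @return smoothed array of the same dimensions
#' @export
gauss_blur3d <- function(x, sigma_vox, pad = "replicate") {
  stopifnot(length(dim(x)) == 3L)
  if (sigma_vox <= 0) return(x)
  k <- gauss_kernel(sigma_vox)
  d <- dim(x)
  for (a in 1:3) x <- apply_along(x, conv_matrix(d[a], k, pad), a)
  x
}

## 2-D version used on projection bins.
gauss_blur2d <- function(x, sigma_vox, pad = "zero") {
  if (sigma_vox <= 0) return(x)
  k <- gauss_kernel(sigma_vox)
  K1 <- conv_matrix(nrow(x), k, pad)
  K2 <- conv_matrix(ncol(x), k, pad)
  K1 %*% x %*% t(K2)
}

## --- binary morphology on 3-D logical arrays (6-connectivity cross) -----

shift3d <- function(x, axis, by) {
  d <- dim(x)
  out <- array(FALSE, d)
  idx_src <- idx_dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    idx_dst[[axis]] <- (by + 1L):n; idx_src[[axis]] <- 1L:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1L:(n + by); idx_src[[axis]] <- (1L - by):n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Binary dilation by the 6-connected cross element
#' @param x 3-D logical array
#' @param iter number of dilation passes
#' @return logical array
#' @export
dilate3d <- function(x, iter = 1L) {
  for (i in seq_len(iter)) {
    y <- x
    for (a in 1:3) y <- y | shift3d(x, a, 1L) | shift3d(x, a, -1L)
    x <- y
  }
  x
}

#' Binary erosion by the 6-connected cross element
#' @param x 3-D logical array
#' @param iter number of erosion passes
#' @return logical array
#' @export
erode3d <- function(x, iter = 1L) {
  for (i in seq_len(iter)) {
    y <- x
    for (a in 1:3) y <- y & shift3d(x, a, 1L) & shift3d(x, a, -1L)
    x <- y
  }
  x
}

#' Largest 6-connected component of a 3-D mask
#'
#' Repeated seeded flood fill (vectorized frontier dilation); components are
#' extracted in decreasing order of discovery until the mask is exhausted.
#'
#' @param mask 3-D logical array
#' @return logical array marking the largest component (all-`FALSE` input
#'   returns all-`FALSE`)
#' @export
largest_component3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  best <- array(FALSE, dim(mask))
  best_n <- 0L
  remaining <- mask
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- dilate3d(seed) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) { best <- seed; best_n <- n }
    remaining <- remaining & !seed
  }
  best
}

## --- NIfTI I/O ------------------------------------------------------------

#' Write a 3-D volume as NIfTI
#'
#' @param values 3-D numeric/integer array
#' @param voxel_mm isotropic voxel size in mm
#' @param path output path (`.nii` or `.nii.gz`)
#' @param datatype passed to [RNifti::writeNifti()]
#' @return `path`, invisibly
#' @export
write_volume_nifti <- function(values, voxel_mm, path, datatype = "auto") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(voxel_mm, 3L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a 3-D volume from NIfTI
#'
#' @param path file path
#' @return list with `values` (3-D array) and `voxel_mm`
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim(img)),
       voxel_mm = RNifti::pixdim(img)[1L])
}
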