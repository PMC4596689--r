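# ---- small volume utilities shared across modules ----

#' Spherical brain mask on a voxel grid
#'
#' Builds a boolean mask covering a centred ball, the stand-in for a brain
#' mask on the synthetic grids used throughout the package.
#'
#' @param grid_shape integer vector of length 3, voxel grid dimensions.
#' @param radius_frac radius as a fraction of the smallest half-dimension.
#' @return logical 3-D array of dimension `grid_shape`.
#' @export
spherical_mask <- function(grid_shape, radius_frac = 0.9) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 2))
  ctr <- (grid_shape + 1) / 2
  r <- radius_frac * (min(grid_shape) - 1) / 2
  d2 <- array(0, grid_shape)
  for (a in 1:3) {
    co <- slice.index(d2, a) - ctr[a]
    d2 <- d2 + co^2
  }
  d2 <= r^2
}

# voxel coordinates (index space) of TRUE entries of a mask, n x 3 matrix
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# shift an array along one axis by k (positive = towards higher index),
# replicating the edge slice
shift_replicate <- function(x, axis, k) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - k
  src <- pmin(pmax(src, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Convolves with a truncated Gaussian kernel along each axis in turn,
#' renormalising at the edges so that a constant volume is preserved.
#'
#' @param vol numeric 3-D array.
#' @param sigma kernel standard deviation in voxels (scalar or length 3).
#' @return smoothed array of the same dimension.
#' @export
smooth_volume <- function(vol, sigma) {
  stopifnot(length(dim(vol)) == 3, all(is.finite(vol)))
  sigma <- rep_len(sigma, 3)
  out <- vol
  for (a in 1:3) {
    if (sigma[a] <= 0) next
    half <- max(1L, ceiling(3 * sigma[a]))
    off <- -half:half
    k <- exp(-off^2 / (2 * sigma[a]^2))
    k <- k / sum(k)
    acc <- array(0, dim(out))
    wts <- array(0, dim(out))
    ones <- array(1, dim(out))
    for (j in seq_along(off)) {
      acc <- acc + k[j] * shift_edge_zero(out, a, off[j])
      wts <- wts + k[j] * shift_edge_zero(ones, a, off[j])
    }
    out <- acc / wts
  }
  out
}

# shift with zero padding (used by smoothing so edge weights renormalise)
shift_edge_zero <- function(x, axis, k) {
  d <- dim(x)
  out <- array(0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  idx_src <- lapply(d, seq_len)
  idx_dst <- lapply(d, seq_len)
  if (k >= 0) {
    idx_dst[[axis]] <- (1 + k):n
    idx_src[[axis]] <- 1:(n - k)
  } else {
    idx_dst[[axis]] <- 1:(n + k)
    idx_src[[axis]] <- (1 - k):n
  }
  src <- do.call(`[`, c(list(x), idx_src, list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idx_dst, list(src)))
  out
}

# plain fourth-standardised-moment kurtosis (Gaussian = 3)
moment_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) stop("kurtosis undefined for a constant vector")
  mean((x - m)^4) / v^2
}

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean(((x - m) / s)^3)
}

# ---- NIfTI I/O ----

#' Read / write scalar volumes and displacement fields as NIfTI
#'
#' Thin wrappers around RNifti. Displacement fields are stored as 4-D
#' volumes with the vector dimension last, in mm; voxel spacing is taken
#' from the header unless overridden.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x array to write (3-D scalar or 4-D with last dim 3).
#' @param spacing voxel dimensions in mm (length 3).
#' @return `read_volume` returns a plain array with a `spacing` attribute.
#' @export
write_volume <- function(x, path, spacing = c(1, 1, 1)) {
  x <- array(as.numeric(x), dim(x))
  img <- RNifti::asNifti(x)
  pd <- rep_len(spacing, 3)
  if (length(dim(x)) == 4) pd <- c(pd, 1)
  img <- RNifti::`pixdim<-`(img, pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' @rdname write_volume
#' @export
write_displacement_nifti <- function(field, path) {
  write_volume(field$u, path, spacing = field$spacing)
}

#' @rdname write_volume
#' @export
read_displacement_nifti <- function(path, mask = NULL, spacing = NULL) {
  arr <- read_volume(path)
  if (length(dim(arr)) != 4 || dim(arr)[4] != 3)
    stop("expected a 4-D NIfTI with the vector dimension (size 3) last")
  if (is.null(spacing)) spacing <- attr(arr, "spacing")
  if (is.null(mask)) mask <- array(TRUE, dim(arr)[1:3])
  displacement_field(array(arr, dim(arr)), spacing = spacing, mask = mask)
}

# write a matrix as TSV with region-id header row/column
write_matrix_tsv <- function(m, path, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(nrow(m))
  df <- data.frame(region = ids, m, check.names = FALSE)
  colnames(df) <- c("region", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
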