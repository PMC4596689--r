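# Deformation-based morphometry: |det(I + dU/dx)| - 1 maps from
# displacement fields, and regional averaging against a parcellation.

#' Displacement field container
#'
#' A dense per-voxel 3-vector field \eqn{U(x) = (u_1, u_2, u_3)} in mm,
#' describing how each template voxel is displaced to match a subject.
#'
#' @param u numeric 4-D array, grid dims first, vector component (size 3) last.
#' @param spacing voxel dimensions \eqn{(\delta_1,\delta_2,\delta_3)} in mm.
#' @param mask logical 3-D array, same grid as `u`.
#' @param subject optional subject identifier carried into provenance.
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing = c(1, 1, 1), mask = NULL,
                               subject = NA_character_) {
  if (length(dim(u)) != 4 || dim(u)[4] != 3)
    stop("`u` must be a 4-D array with the vector dimension (size 3) last")
  spacing <- as.numeric(rep_len(spacing, 3))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all voxel spacings must be positive and finite")
  if (is.null(mask)) mask <- array(TRUE, dim(u)[1:3])
  if (!identical(dim(mask), dim(u)[1:3]))
    stop("mask grid does not match the field grid")
  bad <- sum(!is.finite(u[, , , 1][mask]) | !is.finite(u[, , , 2][mask]) |
               !is.finite(u[, , , 3][mask]))
  if (bad > 0)
    stop(sprintf("displacement field has %d non-finite values inside the mask", bad))
  structure(list(u = u, spacing = spacing, mask = mask, subject = subject),
            class = "displacement_field")
}

#' DBM map container
#'
#' Scalar volume of relative local volume change, \eqn{|J| - 1} with
#' \eqn{J = I + \partial U/\partial x}: 0 means no change, negative values
#' mean local volume smaller than template (the atrophy direction).
#'
#' @param values numeric 3-D array.
#' @param mask logical 3-D array.
#' @param provenance list recording subject, spacing and boundary policy.
#' @return an object of class `dbm_map`.
#' @export
dbm_map <- function(values, mask = NULL, provenance = list()) {
  stopifnot(length(dim(values)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  structure(list(values = values, mask = mask, provenance = provenance),
            class = "dbm_map")
}

# first-order derivative of a 3-D volume along `axis` with step delta:
# central differences in the interior, one-sided (or replicate-padded
# central) differences at the two boundary slices
grad_axis <- function(vol, axis, delta, boundary = c("one_sided", "replicate")) {
  boundary <- match.arg(boundary)
  n <- dim(vol)[axis]
  fwd <- shift_replicate(vol, axis, -1L)   # value at i+1 (edge replicated)
  bwd <- shift_replicate(vol, axis, +1L)   # value at i-1
  g <- (fwd - bwd) / (2 * delta)
  if (boundary == "one_sided" && n >= 2) {
    # overwrite the two boundary slices with one-sided first differences
    idx <- lapply(dim(vol), seq_len)
    for (side in c(1L, n)) {
      i2 <- if (side == 1L) 2L else n - 1L
      idx_b <- idx; idx_b[[axis]] <- side
      idx_n <- idx; idx_n[[axis]] <- i2
      vb <- do.call(`[`, c(list(vol), idx_b, list(drop = FALSE)))
      vn <- do.call(`[`, c(list(vol), idx_n, list(drop = FALSE)))
      one <- if (side == 1L) (vn - vb) / delta else (vb - vn) / delta
      g <- do.call(`[<-`, c(list(g), idx_b, list(one)))
    }
  }
  g
}

#' Jacobian-determinant DBM map from a displacement field
#'
#' Estimates the local Jacobian of the displacement by first-order finite
#' differences, \eqn{\partial u_i/\partial x_j \approx
#' (u_i(\ldots,x_j+\delta_j,\ldots) - u_i(\ldots,x_j-\delta_j,\ldots)) /
#' (2\delta_j)}, and returns \eqn{\det(I + \partial U/\partial x) - 1}
#' per voxel. The identity term reflects that the displacement is relative
#' to position, so a uniform translation yields exactly 0 (no volume
#' change) and negative values indicate local contraction.
#'
#' @param field a [displacement_field()].
#' @param boundary `"one_sided"` (default): first-order one-sided differences
#'   at the grid boundary; `"replicate"`: replicate-padded central differences.
#' @return a [dbm_map()] with the boundary policy recorded in provenance.
#' @export
jacobian_determinant_map <- function(field,
                                     boundary = c("one_sided", "replicate")) {
  boundary <- match.arg(boundary)
  if (!inherits(field, "displacement_field"))
    field <- do.call(displacement_field, as.list(field))
  if (!any(field$mask)) stop("mask is empty")
  d <- field$spacing
  # J[[i]][[j]] = d u_i / d x_j
  J <- vector("list", 3)
  for (i in 1:3) {
    ui <- field$u[, , , i]
    J[[i]] <- lapply(1:3, function(j) grad_axis(ui, j, d[j], boundary))
  }
  # det(I + J) expanded along the first row
  a11 <- 1 + J[[1]][[1]]; a12 <- J[[1]][[2]]; a13 <- J[[1]][[3]]
  a21 <- J[[2]][[1]]; a22 <- 1 + J[[2]][[2]]; a23 <- J[[2]][[3]]
  a31 <- J[[3]][[1]]; a32 <- J[[3]][[2]]; a33 <- 1 + J[[3]][[3]]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  dbm_map(det - 1, mask = field$mask,
          provenance = list(subject = field$subject, spacing = d,
                            boundary = boundary))
}

#' Regional mean DBM values
#'
#' Averages a DBM map over each parcellation label, restricted to the map's
#' mask. Regions with no in-mask voxels are returned as `NA` and flagged in
#' the `missing_regions` attribute rather than silently zeroed.
#'
#' @param map a [dbm_map()] (or plain 3-D array).
#' @param parcellation a [make_parcellation()] result.
#' @return named numeric vector, one mean per region id.
#' @export
regional_means <- function(map, parcellation) {
  vals <- if (inherits(map, "dbm_map")) map$values else map
  msk <- if (inherits(map, "dbm_map")) map$mask else array(TRUE, dim(vals))
  if (!identical(dim(vals), dim(parcellation$labels)))
    stop("parcellation grid does not match map grid")
  ids <- parcellation$table$region
  lab <- parcellation$labels[msk]
  v <- vals[msk]
  keep <- lab > 0
  sums <- tapply(v[keep], factor(lab[keep], levels = ids), mean)
  out <- as.numeric(sums)
  names(out) <- ids
  missing <- ids[is.na(out)]
  attr(out, "missing_regions") <- missing
  out
}
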