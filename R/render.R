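# Gaussian object rendering.
#
# Objects are rendered as separable anisotropic 3-D Gaussians integrated
# over voxels (differences of the normal CDF at voxel edges), so the sum
# over an unbounded grid equals the requested integrated intensity exactly
# and sub-voxel positions are handled without aliasing. Support is
# truncated at RENDER_CUTOFF_SIGMA per axis; the per-axis mass loss at 4
# sigma is 6.3e-5, i.e. < 0.02% in 3-D.

RENDER_CUTOFF_SIGMA <- 4

# voxel-integrated 1-D Gaussian weights over index range lo:hi (1-based
# array indices; voxel i spans [i-1.5, i-0.5] in 0-based coordinates)
gauss_weights_1d <- function(lo, hi, mu0, sigma) {
  i <- lo:hi
  pnorm(i - 0.5, mean = mu0, sd = sigma) -
    pnorm(i - 1.5, mean = mu0, sd = sigma)
}

# sparse rendering: returns index ranges and the value sub-array
render_patch <- function(position, integrated_intensity, sigma, field_shape) {
  stopifnot(length(position) == 3L, length(field_shape) == 3L)
  sg <- c(sigma[["z"]], sigma[["xy"]], sigma[["xy"]])
  if (any(sg <= 0)) stop("sigma must be > 0")
  pos <- as.numeric(position)  # 0-based fractional (z, y, x)
  if (any(pos < 0) || any(pos > field_shape - 1))
    stop("position outside field")
  lo <- pmax(1L, as.integer(floor(pos + 1 - RENDER_CUTOFF_SIGMA * sg)))
  hi <- pmin(as.integer(field_shape),
             as.integer(ceiling(pos + 1 + RENDER_CUTOFF_SIGMA * sg)))
  w <- lapply(1:3, function(a) gauss_weights_1d(lo[a], hi[a], pos[a], sg[a]))
  vals <- integrated_intensity *
    outer(outer(w[[1]], w[[2]]), w[[3]])
  dim(vals) <- c(hi - lo + 1L)
  captured <- if (integrated_intensity > 0) sum(vals) / integrated_intensity else 1
  list(lo = lo, hi = hi, values = vals, captured = captured)
}

add_patch <- function(arr, patch) {
  idx <- lapply(1:3, function(a) patch$lo[a]:patch$hi[a])
  arr[idx[[1]], idx[[2]], idx[[3]]] <-
    arr[idx[[1]], idx[[2]], idx[[3]]] + patch$values
  arr
}

#' Render a diffraction-limited point source
#'
#' Places a separable anisotropic 3-D Gaussian of total (integrated)
#' intensity `integrated_intensity` at a possibly fractional voxel position,
#' integrating the Gaussian over each voxel so that the grid sum equals the
#' integrated intensity up to truncation of the tails (support is cut at
#' 4 sigma per axis). This is the forward model for a phage particle under
#' a compact as-if-deconvolved PSF.
#'
#' @param position numeric (z, y, x), 0-based fractional voxel coordinates.
#' @param integrated_intensity total photons attributed to the object.
#' @param sigma named numeric `c(z=, xy=)` Gaussian sigma in voxel units.
#' @param field_shape integer (z, y, x) output array dimensions.
#' @return A numeric array of `field_shape` holding the object's intensity
#'   contribution; non-negative everywhere. Attribute `captured` gives the
#'   in-grid fraction of the integrated intensity, and `truncation_warning`
#'   is TRUE when more than 1% of the light fell outside the grid.
#' @export
#' @examples
#' a <- render_point_source(c(4, 16, 16), 1000, c(z = 1.5, xy = 1.6),
#'                          c(9, 32, 32))
#' sum(a)  # ~1000 up to tail truncation
render_point_source <- function(position, integrated_intensity, sigma,
                                field_shape) {
  if (integrated_intensity < 0) stop("integrated_intensity must be >= 0")
  field_shape <- as.integer(field_shape)
  arr <- array(0, dim = field_shape)
  if (integrated_intensity > 0) {
    p <- render_patch(position, integrated_intensity, sigma, field_shape)
    arr <- add_patch(arr, p)
    attr(arr, "captured") <- p$captured
    attr(arr, "truncation_warning") <- p$captured < 0.99
  } else {
    attr(arr, "captured") <- 1
    attr(arr, "truncation_warning") <- FALSE
  }
  arr
}

#' Render an extended Gaussian blob
#'
#' Identical contract to [render_point_source()] but intended for extended
#' objects (kinetochores, chromatin masses) whose Gaussian extent
#' `sigma_blob` exceeds the PSF. With `sigma_blob` equal to the PSF sigma it
#' degenerates to the point-source renderer.
#'
#' @param position,integrated_intensity,field_shape as in
#'   [render_point_source()].
#' @param sigma_blob named numeric `c(z=, xy=)` blob sigma in voxel units.
#' @return As [render_point_source()].
#' @export
render_blob <- function(position, integrated_intensity, sigma_blob,
                        field_shape) {
  render_point_source(position, integrated_intensity, sigma_blob, field_shape)
}
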