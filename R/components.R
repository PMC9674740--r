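#' Label connected components of a 3D binary mask
#'
#' Partitions the foreground voxels of a binary 3D array into maximal
#' connected components under 6-, 18- or 26-connectivity (face, face+edge,
#' or face+edge+corner adjacency). Components are returned sorted by size,
#' largest first.
#'
#' @param mask Logical 3D array, or a [SignalMask-class] /
#'   [NucleusMask-class] object.
#' @param connectivity One of 6, 18, 26. Default 26: corner-touching voxel
#'   groups count as one continuous signal.
#' @return A list with `labels` (integer 3D array, 0 = background, labels
#'   ranked by component size descending) and `sizes` (integer vector of
#'   component voxel counts, decreasing).
#' @export
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
#' labelComponents(m, 26)$sizes  # one corner-connected component
#' labelComponents(m, 6)$sizes   # two components
labelComponents <- function(mask, connectivity = 26) {
  if (is(mask, "SignalMask") || is(mask, "NucleusMask"))
    mask <- maskArray(mask)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  lab <- cpp_label3d(as.logical(mask), dim(mask), as.integer(connectivity))
  dim(lab) <- dim(mask)
  if (!any(lab > 0))
    return(list(labels = lab, sizes = integer(0)))
  sizes <- tabulate(lab)
  ord <- order(sizes, decreasing = TRUE)
  rank <- integer(length(sizes))
  rank[ord] <- seq_along(ord)
  relab <- lab
  relab[lab > 0] <- rank[lab[lab > 0]]
  list(labels = relab, sizes = sizes[ord])
}

#' Fill interior holes of a 3D binary mask
#'
#' A hole is a background component (6-connectivity) that does not touch
#' the array border.
#'
#' @param mask Logical 3D array.
#' @return Logical 3D array with holes filled.
#' @export
fillHoles3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  bg <- labelComponents(!mask, connectivity = 6)$labels
  d <- dim(mask)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

#' Anisotropic Gaussian smoothing of a 3D array
#'
#' Separable Gaussian filter with reflective boundary handling.
#'
#' @param img Numeric 3D array.
#' @param sigma Per-axis standard deviation in voxel units, length 3 in
#'   `(y, x, z)` order (scalar recycled). Axes with `sigma <= 0` are left
#'   untouched.
#' @return Numeric 3D array of the same dimensions.
#' @export
gaussianSmooth3d <- function(img, sigma) {
  stopifnot(is.numeric(img), length(dim(img)) == 3)
  sigma <- rep_len(as.numeric(sigma), 3)
  out <- cpp_blur3d(as.numeric(img), dim(img), sigma)
  dim(out) <- dim(img)
  out
}

#' Chebyshev dilation of a 3D binary mask
#'
#' Dilation with a cubic structuring element of half-width `radius`,
#' i.e. every voxel within Chebyshev distance `radius` of the foreground
#' becomes foreground. Used to enforce minimum background gaps.
#'
#' @param mask Logical 3D array.
#' @param radius Non-negative integer.
#' @return Logical 3D array.
#' @export
dilate3d <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, radius >= 0)
  if (radius == 0) return(mask)
  out <- cpp_dilate3d(mask, dim(mask), as.integer(radius))
  dim(out) <- dim(mask)
  out
}

#' Jaccard overlap of two binary masks
#'
#' @param a,b Logical arrays of identical dimensions.
#' @return Intersection over union in `[0, 1]` (1 if both are empty).
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
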