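.otsu_threshold <- function(values) {
  v <- values[is.finite(values)]
  mx <- max(v)
  if (mx <= 0 || max(v) == min(v)) return(NA_real_)
  v <- v / mx
  thr <- EBImage::otsu(EBImage::Image(matrix(v, nrow = length(v))),
                       range = c(0, 1), levels = 256L)
  thr * mx
}

.smooth_sigma <- function(sigma, sp) {
  # sigma is in xy voxels; the z sigma is scaled by the spacing ratio so
  # smoothing is (approximately) isotropic in physical units
  c(sigma, sigma, sigma * sp[["x"]] / sp[["z"]])
}

#' Segment the nucleus from a multi-channel stack
#'
#' The nucleus mask is the largest connected foreground object of the
#' summed-channel image after Gaussian pre-smoothing, Otsu thresholding,
#' and interior hole filling. The threshold is computed on max-normalised
#' intensities, so the mask is invariant to uniform intensity scaling.
#'
#' @param stack A [VoxelStack-class].
#' @param sigma Pre-smoothing sigma in xy voxels (z is scaled by the
#'   spacing ratio); `0` disables smoothing.
#' @param connectivity Voxel connectivity used for the largest-object
#'   selection (6, 18 or 26).
#' @param id Nucleus identifier stored in the result.
#' @return A [NucleusMask-class].
#' @export
segmentNucleus <- function(stack, sigma = 0.7, connectivity = 26,
                           id = "nucleus") {
  stopifnot(is(stack, "VoxelStack"))
  total <- Reduce(`+`, stack@channels)
  if (max(total) <= 0) stop("no nucleus found: blank stack")
  sv <- .smooth_sigma(sigma, stack@spacing)
  sm <- if (sigma > 0) gaussianSmooth3d(total, sv) else total
  thr <- .otsu_threshold(sm)
  if (is.na(thr)) stop("no nucleus found: constant intensity")
  mask <- sm > thr
  mask <- fillHoles3d(mask)
  lab <- labelComponents(mask, connectivity)
  if (!length(lab$sizes)) stop("no nucleus found")
  new("NucleusMask", nucleusId = id, mask = lab$labels == 1L,
      spacing = stack@spacing)
}

.bbox3 <- function(mask, pad = 0L) {
  w <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(1L, apply(w, 2, min) - pad)
  hi <- pmin(d, apply(w, 2, max) + pad)
  list(lo = lo, hi = hi)
}

# Boundary refinement for blob-shaped signals. The half-maximum surface
# of a Gaussian-blurred step edge sits at the true boundary when the edge
# is flat, but for a convex blob of radius R it is displaced inward by
# about sigma^2/R. Both sigma and R are estimated from the data: R from
# the equivalent-sphere radius of the detected component, sigma from the
# radial distance between the 50% and 35% iso-surfaces (0.375 sigma for a
# Gaussian edge). The final threshold factor is 0.5 - sigma/(R sqrt(2 pi)),
# clamped to [0.35, 0.5].
.refine_halfmax <- function(sm, mask, nuc, connectivity) {
  lab <- labelComponents(mask, connectivity)
  out <- array(FALSE, dim(mask))
  d <- dim(mask)
  for (cmp in seq_along(lab$sizes)) {
    sel <- lab$labels == cmp
    vox <- which(sel)
    peak <- unname(stats::quantile(sm[vox], 0.95))
    if (peak <= 0) next
    bb <- .bbox3(sel, pad = 3L)
    ix <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; iz <- bb$lo[3]:bb$hi[3]
    lsm <- sm[ix, iy, iz, drop = FALSE]
    lnuc <- nuc[ix, iy, iz, drop = FALSE]
    lsel <- sel[ix, iy, iz, drop = FALSE]
    vol_at <- function(f) {
      m <- lsm >= f * peak & lnuc
      if (!any(m & lsel)) return(0L)
      ll <- labelComponents(m, connectivity)
      keep <- unique(ll$labels[lsel & m])
      keep <- keep[keep > 0]
      sum(ll$labels %in% keep)
    }
    v50 <- vol_at(0.5); v35 <- vol_at(0.35)
    r50 <- (3 * max(v50, 1) / (4 * pi))^(1 / 3)
    r35 <- (3 * max(v35, 1) / (4 * pi))^(1 / 3)
    sigma_hat <- max((r35 - r50) / 0.375, 0)
    f <- max(0.35, min(0.5, 0.5 - sigma_hat / (r50 * sqrt(2 * pi))))
    m <- lsm >= f * peak & lnuc
    ll <- labelComponents(m, connectivity)
    keep <- unique(ll$labels[lsel & m])
    keep <- keep[keep > 0]
    loc <- array(ll$labels %in% keep, dim(m))
    full <- array(FALSE, d)
    full[ix, iy, iz] <- loc
    out <- out | full
  }
  out
}

#' Segment one chromosome's territory signal
#'
#' Territory signals are detected by Otsu thresholding of the smoothed
#' channel, with the threshold computed from the voxels inside the
#' nucleus mask, then each detected component's boundary is refined at
#' half its peak intensity (the full-width-half-maximum criterion, which
#' places the boundary of a blurred step edge at its true position).
#' The result is restricted to the nucleus; speckle components smaller
#' than `minSize` voxels are removed and interior holes filled. A channel
#' that is blank (constant) inside the nucleus yields an empty mask, not
#' an error — callability is decided downstream.
#'
#' @param stack A [VoxelStack-class].
#' @param channel Channel name or chromosome id.
#' @param nucleus A [NucleusMask-class] in the same frame.
#' @param sigma Pre-smoothing sigma in xy voxels; `0` disables smoothing.
#' @param minSize Minimum retained component size, voxels.
#' @param connectivity Connectivity for speckle removal (6, 18 or 26).
#' @param refine Half-maximum boundary refinement on/off.
#' @return A [SignalMask-class] (possibly empty).
#' @export
segmentTerritory <- function(stack, channel, nucleus, sigma = 0.7,
                             minSize = 5, connectivity = 26,
                             refine = TRUE) {
  stopifnot(is(stack, "VoxelStack"), is(nucleus, "NucleusMask"))
  img <- getChannel(stack, channel)
  if (!identical(dim(img), dim(nucleus@mask)))
    stop("stack and nucleus mask dimensions differ")
  chr <- if (channel %in% names(stack@channelMap))
    stack@channelMap[[channel]] else channel
  out <- array(FALSE, dim(img))
  # work inside the nucleus bounding box only
  bb <- .bbox3(nucleus@mask, pad = 2L)
  ix <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; iz <- bb$lo[3]:bb$hi[3]
  sub <- img[ix, iy, iz, drop = FALSE]
  nuc <- nucleus@mask[ix, iy, iz, drop = FALSE]
  sv <- .smooth_sigma(sigma, stack@spacing)
  sm <- if (sigma > 0) gaussianSmooth3d(sub, sv) else sub
  thr <- .otsu_threshold(sm[nuc])
  mask <- array(FALSE, dim(sub))
  if (!is.na(thr)) {
    mask <- sm > thr & nuc
    if (any(mask) && refine)
      mask <- .refine_halfmax(sm, mask, nuc, connectivity)
    if (any(mask)) {
      lab <- labelComponents(mask, connectivity)
      keep <- which(lab$sizes >= minSize)
      mask <- array(lab$labels %in% keep & lab$labels > 0, dim(sub))
      if (any(mask)) mask <- fillHoles3d(mask) & nuc
    }
  }
  out[ix, iy, iz] <- mask
  new("SignalMask", nucleusId = nucleus@nucleusId,
      chromosome = as.character(chr),
      roundId = stack@roundId, mask = out, spacing = stack@spacing)
}
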