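#' Circular structuring element
#'
#' The discrete closed ball of radius `r`: all integer offsets (dy, dx) with
#' dy^2 + dx^2 <= r^2. It always contains (0, 0) and is symmetric under
#' negation, so dilation and erosion with it are adjoint.
#'
#' @param r non-negative integer radius in pixels. `r = 0` gives the identity
#'   element \{(0, 0)\}.
#' @return an object of class `structuring_element` with fields `radius` and
#'   `offsets` (an n x 2 integer matrix of (dy, dx) pairs).
#' @export
se_disk <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 0 || r != round(r))
    stop("`r` must be a single non-negative integer")
  r <- as.integer(r)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- g$dy^2 + g$dx^2 <= r^2
  structure(list(radius = r,
                 offsets = as.matrix(g[keep, , drop = FALSE])),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("<structuring_element> disk r=%d (%d offsets)\n",
              x$radius, nrow(x$offsets)))
  invisible(x)
}

as_se <- function(se) {
  if (inherits(se, "structuring_element")) return(se)
  se_disk(se)
}

#' Morphological dilation and erosion of a binary mask
#'
#' Dilation sets a pixel to 1 iff any structuring-element offset from it lands
#' on a foreground pixel (Minkowski sum); erosion keeps a pixel iff every
#' offset lands on foreground. Pixels outside the grid count as background,
#' so erosion shrinks objects touching the image border.
#'
#' @param mask a [binary_mask] (or plain 0/1 matrix).
#' @param se a [se_disk()] structuring element, or an integer radius.
#' @return a [binary_mask] with the same labels as the input.
#' @export
mask_dilate <- function(mask, se) {
  mask <- as_binary_mask(mask)
  se <- as_se(se)
  mask_like(cpp_dilate(unclass(mask), se$offsets), mask)
}

#' @rdname mask_dilate
#' @export
mask_erode <- function(mask, se) {
  mask <- as_binary_mask(mask)
  se <- as_se(se)
  mask_like(cpp_erode(unclass(mask), se$offsets), mask)
}

#' Potential boundary region (PBR)
#'
#' The annular band `dilate(P, SE_r) \ erode(P, SE_r)` around the coarse
#' boundary, of half-width about `r_m` pixels: the region where the true
#' object boundary is most likely to lie given a coarse segmentation. The set
#' difference is computed as dilation AND NOT erosion (erosion is always a
#' subset of dilation, so this equals arithmetic subtraction and is robust).
#'
#' An empty coarse mask yields an empty PBR with a warning; pipeline-level
#' bundle construction substitutes an all-ones PBR in that case (see
#' [make_bundles()]) so the fine stage degrades to ordinary segmentation.
#'
#' @param coarse coarse segmentation as a [binary_mask].
#' @param r_m structuring-element radius in pixels (>= 1).
#' @return a [binary_mask] marking the band.
#' @export
potential_boundary_region <- function(coarse, r_m) {
  coarse <- as_binary_mask(coarse)
  if (r_m < 1) stop("`r_m` must be >= 1")
  if (sum(coarse) == 0L) {
    warning("empty coarse mask: PBR is empty; downstream must handle")
    return(mask_like(matrix(0L, nrow(coarse), ncol(coarse)), coarse))
  }
  se <- se_disk(r_m)
  d <- cpp_dilate(unclass(coarse), se$offsets)
  e <- cpp_erode(unclass(coarse), se$offsets)
  mask_like(d * (1L - e), coarse)
}

# Truncated normalized Gaussian kernel: window r x r (r+1 if r is even, so a
# center pixel exists), standard deviation r, renormalized to unit sum.
gaussian_kernel <- function(r) {
  if (r < 1 || r != round(r)) stop("`r` must be a positive integer")
  w <- if (r %% 2 == 0) r + 1L else as.integer(r)
  half <- (w - 1L) %/% 2L
  ax <- (-half):half
  k <- outer(ax, ax, function(y, x) exp(-(y^2 + x^2) / (2 * r^2)))
  k / sum(k)
}

#' Boundary uncertainty map (BUM)
#'
#' Smooths a 0/1 potential boundary region with a truncated normalized
#' Gaussian (window `r_g` x `r_g`, standard deviation `r_g`) so pixels near
#' the centerline of the band take the largest values, decaying with distance
#' from it; values stay in \[0, 1\]. Borders are handled by symmetric
#' reflection and the raw convolution values are kept (no re-normalization).
#'
#' @param pbr a [binary_mask], typically from [potential_boundary_region()].
#' @param r_g Gaussian size parameter in pixels (>= 1). Even values are
#'   widened by one pixel so the kernel has a center.
#' @return a numeric matrix in \[0, 1\].
#' @export
boundary_uncertainty_map <- function(pbr, r_g) {
  pbr <- as_binary_mask(pbr)
  k <- gaussian_kernel(r_g)
  out <- cpp_conv2_reflect(matrix(as.numeric(pbr), nrow(pbr)), k)
  pmin(pmax(out, 0), 1)  # clamp float fuzz at the [0,1] contract
}

#' Background excluded image (BEI)
#'
#' Elementwise product `PBR * I`: image content is kept inside the band and
#' zeroed elsewhere, removing background that is irrelevant to boundary
#' refinement. A single-channel PBR broadcasts across image channels.
#'
#' @param pbr a [binary_mask].
#' @param image matrix or H x W x C array in \[0, 1\].
#' @return an image of the same shape as `image`.
#' @export
background_excluded_image <- function(pbr, image) {
  pbr <- as_binary_mask(pbr)
  img <- as_image(image)
  if (!all(dim(img)[1:2] == dim(pbr)))
    stop("PBR and image spatial shapes differ")
  out <- img * array(as.numeric(pbr), dim(img))
  if (is.matrix(image)) out[, , 1] else out
}

#' Build the uncertainty bundle for one object
#'
#' Composes [potential_boundary_region()], [boundary_uncertainty_map()] and
#' [background_excluded_image()] from one coarse mask and one image. By
#' default the morphology radius and the Gaussian size share one value, the
#' configuration found to work best when the two are tied.
#'
#' @param coarse coarse segmentation [binary_mask].
#' @param image the image the coarse mask belongs to.
#' @param r_m morphology radius (pixels, >= 1).
#' @param r_g Gaussian size (pixels, >= 1); defaults to `r_m`.
#' @return an object of class `uncertainty_bundle` with fields `pbr`, `bum`,
#'   `bei`.
#' @export
build_uncertainty_bundle <- function(coarse, image, r_m, r_g = r_m) {
  pbr <- potential_boundary_region(coarse, r_m)
  bum <- boundary_uncertainty_map(pbr, r_g)
  bei <- background_excluded_image(pbr, image)
  structure(list(pbr = pbr, bum = bum, bei = bei),
            class = "uncertainty_bundle")
}

#' @export
print.uncertainty_bundle <- function(x, ...) {
  cat(sprintf("<uncertainty_bundle> %dx%d  |PBR|=%d  max(BUM)=%.3f\n",
              nrow(x$pbr), ncol(x$pbr), sum(x$pbr), max(x$bum)))
  invisible(x)
}
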