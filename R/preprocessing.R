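#' Normalize image intensities
#'
#' Per-channel standardization (subtract mean, divide by SD) followed by an
#' affine rescale of each channel to \[0, 1\]; a constant channel maps to
#' all 0.5. The standardization makes the result invariant to global shifts
#' and rescalings of the raw intensities, absorbing exposure and camera
#' differences.
#'
#' @param image matrix or H x W x C array of finite intensities.
#' @return image of the same shape with values in \[0, 1\].
#' @export
normalize_image <- function(image) {
  was_matrix <- is.matrix(image)
  img <- as_image(image)
  for (cch in seq_len(dim(img)[3])) {
    ch <- img[, , cch]
    s <- sd(ch)
    if (s < 1e-12) { img[, , cch] <- 0.5; next }
    z <- (ch - mean(ch)) / s
    img[, , cch] <- (z - min(z)) / (max(z) - min(z))
  }
  if (was_matrix) img[, , 1] else img
}

#' Resize an image or mask
#'
#' Bilinear interpolation for images, nearest-neighbour for masks (masks stay
#' strictly binary). Resizing to the input size is the identity.
#'
#' @param x matrix, H x W x C array, or [binary_mask].
#' @param size target `(height, width)`; a scalar is used for both.
#' @return the resized object, same kind as the input.
#' @export
resize <- function(x, size = c(256L, 256L)) {
  if (length(size) == 1L) size <- c(size, size)
  if (is_binary_mask(x)) {
    out <- cpp_resize(matrix(as.numeric(x), nrow(x)), size[1], size[2], TRUE)
    return(mask_like(matrix(as.integer(out), size[1]), x))
  }
  if (is.matrix(x)) {
    if (all(dim(x) == size)) return(x)
    return(cpp_resize(x, size[1], size[2], FALSE))
  }
  img <- as_image(x)
  out <- array(0, c(size, dim(img)[3]))
  for (cch in seq_len(dim(img)[3]))
    out[, , cch] <- cpp_resize(img[, , cch], size[1], size[2], FALSE)
  out
}

#' Extract a square patch around a reference object
#'
#' The patch is centred on the reference-mask centroid with side
#' `round(3 * r_eq)` where `r_eq = sqrt(area / pi)` is the equivalent-circle
#' radius of the reference mask (the disc-patch convention: the object fills
#' roughly two thirds of the patch). Regions falling outside the image are
#' zero-padded so the patch stays square. The image is resampled bilinearly
#' to `output_size`, all masks by nearest neighbour.
#'
#' @param image matrix or H x W x C array.
#' @param masks named list of [binary_mask]s cropped identically.
#' @param reference_mask non-empty [binary_mask] defining centre and side.
#' @param output_size side of the resized square patch (default 256).
#' @return `list(image =, masks =, geometry = list(center, side))`.
#' @export
extract_patch <- function(image, masks, reference_mask, output_size = 256L) {
  ref <- as_binary_mask(reference_mask)
  if (sum(ref) == 0L) stop("reference mask is empty")
  idx <- which(ref == 1L, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  r_eq <- sqrt(sum(ref) / pi)
  side <- max(1L, round(3 * r_eq))
  half <- side %/% 2L
  rows <- (ctr[1] - half):(ctr[1] - half + side - 1L)
  cols <- (ctr[2] - half):(ctr[2] - half + side - 1L)
  crop_chan <- function(m) {
    out <- matrix(0, side, side)
    rin <- rows >= 1 & rows <= nrow(m)
    cin <- cols >= 1 & cols <= ncol(m)
    out[rin, cin] <- m[rows[rin], cols[cin], drop = FALSE]
    out
  }
  was_matrix <- is.matrix(image)
  img <- as_image(image)
  patch <- array(0, c(side, side, dim(img)[3]))
  for (cch in seq_len(dim(img)[3])) patch[, , cch] <- crop_chan(img[, , cch])
  patch <- resize(if (was_matrix) patch[, , 1] else patch, output_size)
  masks_out <- lapply(masks, function(m) {
    cm <- mask_like(matrix(as.integer(crop_chan(matrix(as.numeric(m), nrow(m)))),
                           side), as_binary_mask(m))
    resize(cm, output_size)
  })
  list(image = patch, masks = masks_out,
       geometry = list(center = as.integer(ctr), side = as.integer(side),
                       equivalent_radius = r_eq))
}
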