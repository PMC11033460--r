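#' Phantom specification
#'
#' Describes the two phantom families the pipeline is exercised on:
#' `"fundus"` -- a bright elliptical optic-disc (OD) region containing a
#' smaller, low-contrast optic-cup (OC) ellipse on a textured background,
#' emulating a disc patch from a fundus photograph; `"lungs"` -- two disjoint
#' dark mirrored lobes on a brighter thorax-like background, emulating a
#' frontal chest radiograph. Geometry is jittered per image; noise is
#' additive Gaussian clipped to \[0, 1\].
#'
#' Defaults (64 px canvas, noise SD 0.05, OC/OD contrast 0.08) are chosen so
#' the OC is "hard" -- visually similar to the surrounding OD -- while the
#' lungs are high-contrast, mirroring the relative difficulty of the two
#' real tasks.
#'
#' @param kind `"fundus"` or `"lungs"`.
#' @param size canvas side in pixels (divisible by 2^depth of the backbone).
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param contrast OC minus OD intensity difference (fundus only).
#' @param seed integer seed making the phantom deterministic.
#' @param od_axes,oc_frac,lung_a,lung_b,jitter geometry ranges as fractions
#'   of `size` (axes semi-lengths; `oc_frac` is the OC/OD axis ratio range).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("fundus", "lungs"), size = 64L,
                         noise_sd = 0.05, contrast = 0.08, seed = 1L,
                         od_axes = c(0.20, 0.28), oc_frac = c(0.4, 0.7),
                         lung_a = c(0.26, 0.33), lung_b = c(0.12, 0.17),
                         jitter = 0.04) {
  kind <- match.arg(kind)
  stopifnot(size >= 16, noise_sd >= 0, contrast > 0)
  structure(list(kind = kind, size = as.integer(size), noise_sd = noise_sd,
                 contrast = contrast, seed = as.integer(seed),
                 od_axes = od_axes, oc_frac = oc_frac, lung_a = lung_a,
                 lung_b = lung_b, jitter = jitter),
            class = "phantom_spec")
}

# filled rotated ellipse as a 0/1 integer matrix
ellipse_mask <- function(S, center, a, b, theta) {
  rr <- matrix(seq_len(S), S, S) - center[1]
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) - center[2]
  u <- rr * cos(theta) + cc * sin(theta)
  v <- -rr * sin(theta) + cc * cos(theta)
  ((u / a)^2 + (v / b)^2 <= 1) * 1L
}

smooth_noise_field <- function(S, scale = 0.04) {
  f <- cpp_conv2_reflect(matrix(rnorm(S * S), S, S), gaussian_kernel(8L))
  f / max(sd(f), 1e-12) * scale
}

#' Generate one phantom image with ground-truth masks
#'
#' Deterministic per seed: calling twice with the same spec gives bitwise
#' identical output. Fundus phantoms guarantee OC strictly inside OD; lung
#' phantoms guarantee disjoint non-empty lobes (geometry is re-jittered up
#' to five times, then an error is raised).
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = <size x size matrix in [0,1]>, masks = <named list
#'   of truth-sourced [binary_mask]s>, objects = <character>)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_rng(spec$seed, {
    S <- spec$size
    if (spec$kind == "fundus") out <- phantom_fundus(spec, S)
    else out <- phantom_lungs(spec, S)
    img <- out$image
    if (spec$noise_sd > 0) img <- img + rnorm(S * S, sd = spec$noise_sd)
    out$image <- matrix(pmin(pmax(img, 0), 1), S, S)
    out
  })
}

phantom_fundus <- function(spec, S) {
  ctr <- S / 2 + runif(2, -spec$jitter, spec$jitter) * S
  ax <- sort(runif(2, spec$od_axes[1], spec$od_axes[2]) * S, decreasing = TRUE)
  th <- runif(1, 0, pi)
  od <- ellipse_mask(S, ctr, ax[1], ax[2], th)
  frac <- runif(1, spec$oc_frac[1], spec$oc_frac[2])
  # keep the cup strictly inside the disc: bound the centre offset
  max_off <- (1 - frac) * min(ax) * 0.5
  cctr <- ctr + runif(2, -max_off, max_off)
  oc <- ellipse_mask(S, cctr, frac * ax[1], frac * ax[2], th)
  if (sum(oc) == 0L || any(oc == 1L & od == 0L))
    stop("fundus geometry ranges cannot satisfy OC inside OD")
  img <- 0.30 + smooth_noise_field(S)
  img[od == 1L] <- 0.62
  img[oc == 1L] <- 0.62 + spec$contrast
  list(image = img,
       masks = list(OD = binary_mask(od, "OD", source = "truth"),
                    OC = binary_mask(oc, "OC", source = "truth")),
       objects = c("OD", "OC"))
}

phantom_lungs <- function(spec, S) {
  for (attempt in 1:5) {
    crow <- 0.5 * S + runif(1, -spec$jitter, spec$jitter) * S
    tilt <- runif(1, 2, 8) * pi / 180
    mk <- function(colfrac, sgn) {
      ellipse_mask(S,
                   c(crow + runif(1, -spec$jitter, spec$jitter) * S * 0.5,
                     colfrac * S + runif(1, -spec$jitter, spec$jitter) * S * 0.5),
                   runif(1, spec$lung_a[1], spec$lung_a[2]) * S,
                   runif(1, spec$lung_b[1], spec$lung_b[2]) * S,
                   sgn * tilt)
    }
    left <- mk(0.30, +1)
    right <- mk(0.70, -1)
    if (sum(left) > 0L && sum(right) > 0L && sum(left & right) == 0L) {
      img <- 0.70 + smooth_noise_field(S)
      img[left == 1L | right == 1L] <- 0.30
      return(list(image = img,
                  masks = list(lung_L = binary_mask(left, "lung_L", source = "truth"),
                               lung_R = binary_mask(right, "lung_R", source = "truth")),
                  objects = c("lung_L", "lung_R")))
    }
  }
  stop("lung geometry ranges cannot produce disjoint lobes")
}

#' Perturb a mask to emulate a coarse prediction
#'
#' Applies random dilation or erosion (structuring-element radius up to
#' `magnitude`) independently in random angular sectors around the mask
#' centroid, displacing the boundary by at most `magnitude` pixels. The
#' expected Dice between input and output decreases with `magnitude`, giving
#' a training-free stand-in for coarse network predictions. If the result
#' would be empty the draw is retried at a smaller magnitude (5 attempts,
#' then an error).
#'
#' @param mask a non-empty [binary_mask].
#' @param magnitude maximum boundary displacement in pixels (0 = identity).
#' @param seed RNG seed.
#' @param n_sectors number of angular sectors.
#' @return a [binary_mask] with `source = "prediction"`.
#' @export
perturb_mask <- function(mask, magnitude, seed = 1L, n_sectors = 8L) {
  mask <- as_binary_mask(mask)
  if (sum(mask) == 0L) stop("cannot perturb an empty mask")
  if (magnitude == 0)
    return(binary_mask(unclass(mask), attr(mask, "object_id"), "prediction"))
  with_local_rng(seed, {
    S <- dim(mask)
    idx <- which(mask == 1L, arr.ind = TRUE)
    ctr <- colMeans(idx)
    ang <- atan2(matrix(seq_len(S[1]), S[1], S[2]) - ctr[1],
                 matrix(seq_len(S[2]), S[1], S[2], byrow = TRUE) - ctr[2])
    mag <- magnitude
    for (attempt in 1:5) {
      cuts <- sort(runif(n_sectors, -pi, pi))
      sector <- findInterval(ang, cuts)  # 0..n_sectors, 0 wraps with n_sectors
      sector[sector == 0L] <- n_sectors
      out <- unclass(mask)
      for (s in seq_len(n_sectors)) {
        op <- sample(c(-1L, 0L, 1L), 1)
        if (op == 0L) next
        r <- sample.int(mag, 1)
        alt <- if (op > 0L) cpp_dilate(unclass(mask), se_disk(r)$offsets)
               else cpp_erode(unclass(mask), se_disk(r)$offsets)
        sel <- sector == s
        out[sel] <- alt[sel]
      }
      if (sum(out) > 0L)
        return(binary_mask(out, attr(mask, "object_id"), "prediction"))
      mag <- max(1L, mag - 1L)
    }
    stop("perturbation emptied the mask after 5 attempts")
  })
}

#' Generate a phantom dataset with a three-way split
#'
#' Per-phantom seeds are derived from the master seed and the phantom index,
#' so regenerating with one index changed alters only that phantom. Ids are
#' split deterministically into train/val/test thirds (remainder to train).
#'
#' @param n number of phantoms (>= 3).
#' @param spec a [phantom_spec()]; its `seed` field is ignored in favour of
#'   derived per-phantom seeds.
#' @param seed master seed.
#' @return a `ugls_dataset` list: `images`, `masks` (per image, per object,
#'   truth-sourced), `objects`, `split` (named `"train"/"val"/"test"`),
#'   `kind`, `size`.
#' @export
generate_dataset <- function(n, spec = phantom_spec("lungs"), seed = 1L) {
  stopifnot(n >= 3)
  ids <- sprintf("img%03d", seq_len(n))
  images <- list(); masks <- list(); objects <- NULL
  for (i in seq_len(n)) {
    si <- spec
    si$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
    ph <- generate_phantom(si)
    images[[ids[i]]] <- ph$image
    masks[[ids[i]]] <- ph$masks
    objects <- ph$objects
  }
  m <- n %/% 3L
  split <- rep("train", n)
  split[(m + 1):(2 * m)] <- "val"
  split[(2 * m + 1):(3 * m)] <- "test"
  # indices beyond 3m (remainder) stay "train"
  if (n > 3 * m) split[(3 * m + 1):n] <- "train"
  names(split) <- ids
  structure(list(images = images, masks = masks, objects = objects,
                 split = split, kind = spec$kind, size = spec$size),
            class = "ugls_dataset")
}

#' @export
print.ugls_dataset <- function(x, ...) {
  cat(sprintf("<ugls_dataset> %d %s phantoms %dx%d  objects: %s\n",
              length(x$images), x$kind, x$size, x$size,
              paste(x$objects, collapse = ", ")))
  cat("  split:", paste(sprintf("%s=%d", names(table(x$split)),
                                table(x$split)), collapse = "  "), "\n")
  invisible(x)
}
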