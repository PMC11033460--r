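#' Read and write masks and images as PNG
#'
#' Masks use the 0/255 single-channel PNG dialect; on read, any pixel not
#' exactly 0 or 1 (after the PNG scaling to \[0, 1\]) is an error naming the
#' file, so accidentally anti-aliased or probabilistic masks are rejected.
#'
#' @param mask a [binary_mask].
#' @param path file path.
#' @param object_id,source labels attached to the mask on read.
#' @return `read_mask_png` returns a [binary_mask]; writers return the path,
#'   invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_binary_mask(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, object_id = "object", source = "truth") {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  if (any(abs(v - round(v)) > 1e-6) || any(!round(v) %in% c(0, 1)))
    stop("non-binary mask PNG: ", path)
  binary_mask(round(v), object_id = object_id, source = source)
}

#' @rdname write_mask_png
#' @param image matrix or H x W x C array in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  img <- as_image(image)
  img <- pmin(pmax(img, 0), 1)
  if (dim(img)[3] == 1L) img <- img[, , 1]
  png::writePNG(img, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_image_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L && dim(v)[3] == 4L) v <- v[, , 1:3]  # drop alpha
  if (length(dim(v)) == 3L && dim(v)[3] == 2L) v <- v[, , 1]    # gray+alpha
  v
}

#' Read/write a boundary uncertainty map as plain-text TSV
#'
#' Full-precision decimal text; no float-TIFF writer exists in this R stack.
#'
#' @param bum numeric matrix in \[0, 1\].
#' @param path file path.
#' @export
write_bum_tsv <- function(bum, path) {
  utils::write.table(bum, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_bum_tsv
#' @export
read_bum_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Save a dataset in the canonical directory layout
#'
#' Layout: `images/<id>.png`, `masks/<object>/<id>.png` (0/255), and
#' `split.json` mapping every id to train/val/test.
#'
#' @param dataset a `ugls_dataset`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
save_dataset <- function(dataset, root) {
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  for (obj in dataset$objects)
    dir.create(file.path(root, "masks", obj), recursive = TRUE,
               showWarnings = FALSE)
  for (id in names(dataset$images)) {
    write_image_png(dataset$images[[id]],
                    file.path(root, "images", paste0(id, ".png")))
    for (obj in dataset$objects)
      write_mask_png(dataset$masks[[id]][[obj]],
                     file.path(root, "masks", obj, paste0(id, ".png")))
  }
  jsonlite::write_json(as.list(dataset$split),
                       file.path(root, "split.json"), auto_unbox = TRUE)
  invisible(root)
}

#' Load a dataset from the canonical directory layout
#'
#' Image ids are sorted lexicographically so in-memory order is independent
#' of directory listing order. Every image must have a mask for every object
#' with an identical spatial shape; violations are errors naming the path.
#'
#' @param root dataset directory (see [save_dataset()]).
#' @return a `ugls_dataset`.
#' @export
load_dataset <- function(root) {
  img_dir <- file.path(root, "images")
  if (!dir.exists(img_dir)) stop("no images/ directory under ", root)
  files <- sort(list.files(img_dir, pattern = "\\.png$"))
  if (!length(files)) stop("no PNG images under ", img_dir)
  ids <- sub("\\.png$", "", files)
  objects <- sort(list.dirs(file.path(root, "masks"), recursive = FALSE,
                            full.names = FALSE))
  if (!length(objects)) stop("no mask object directories under ", root)
  split_path <- file.path(root, "split.json")
  if (!file.exists(split_path)) stop("missing split file: ", split_path)
  split <- unlist(jsonlite::read_json(split_path))
  if (!setequal(names(split), ids))
    stop("split.json does not cover the image ids exactly once")
  images <- list(); masks <- list()
  for (id in ids) {
    img <- read_image_png(file.path(img_dir, paste0(id, ".png")))
    images[[id]] <- img
    ml <- list()
    for (obj in objects) {
      mp <- file.path(root, "masks", obj, paste0(id, ".png"))
      if (!file.exists(mp)) stop("missing mask: ", mp)
      m <- read_mask_png(mp, object_id = obj, source = "truth")
      if (!all(dim(m) == dim(img)[1:2]))
        stop("mask shape mismatch: ", mp)
      ml[[obj]] <- m
    }
    masks[[id]] <- ml
  }
  sz <- nrow(if (is.matrix(images[[1]])) images[[1]] else images[[1]][, , 1])
  structure(list(images = images, masks = masks, objects = objects,
                 split = split[ids], kind = "unknown", size = sz),
            class = "ugls_dataset")
}
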