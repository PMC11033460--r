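#' Binary segmentation mask
#'
#' A 2-D 0/1 integer matrix tagged with the object it segments and its
#' provenance. Provenance (`"truth"` for manual annotations, `"prediction"`
#' for network output or anything derived from it) is carried through all
#' operations and audited by the pipeline so that ground-truth masks can
#' never seed bundle construction for validation or test images.
#'
#' @param data matrix (logical or numeric) with values strictly in \{0, 1\}.
#' @param object_id label of the segmented object, e.g. `"OC"` or `"lung_L"`.
#' @param source `"prediction"` or `"truth"`.
#' @return an integer matrix of class `binary_mask` with attributes
#'   `object_id` and `source`.
#' @export
binary_mask <- function(data, object_id = "object",
                        source = c("prediction", "truth")) {
  source <- match.arg(source)
  if (!is.matrix(data)) stop("`data` must be a matrix")
  m <- data
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L))
    stop("mask values must be strictly in {0, 1}")
  structure(m, class = "binary_mask", object_id = object_id, source = source)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %dx%d  object=%s  source=%s  |mask|=%d\n",
              nrow(x), ncol(x), attr(x, "object_id"), attr(x, "source"),
              sum(x)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

as_binary_mask <- function(x, object_id = "object", source = "prediction") {
  if (is_binary_mask(x)) return(x)
  binary_mask(x, object_id = object_id, source = source)
}

# rebuild a mask from raw integer data, inheriting labels from a template
mask_like <- function(data, template) {
  binary_mask(data, object_id = attr(template, "object_id") %||% "object",
              source = attr(template, "source") %||% "prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coerce to an image array
#'
#' Images are H x W x C numeric arrays with intensities in \[0, 1\] and
#' C in \{1, 3\}; a plain matrix is promoted to a single-channel array.
#'
#' @param x matrix or 3-D array of finite numeric intensities.
#' @return an H x W x C array.
#' @export
as_image <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("an image must be a matrix or an H x W x C array")
  if (!dim(x)[3] %in% c(1L, 3L)) stop("channel count must be 1 or 3")
  if (!all(is.finite(x))) stop("image intensities must be finite")
  x
}

image_channels <- function(x) if (is.matrix(x)) 1L else dim(x)[3]
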