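#' Backbone configuration
#'
#' Describes the symmetric encoder-decoder used in both stages: two 3x3
#' convolutions + ReLU per level, 2x2 max-pool down, nearest-neighbour
#' upsample + 3x3 conv up with skip concatenation, and a per-object sigmoid
#' head (objects are independent channels, not softmax classes). Filter
#' counts double per level, so `base_filters * 2^depth` is the bottleneck
#' width: the full-scale setting `base_filters = 32, depth = 5` gives the
#' classic 32 -> 1024 progression; the desk-scale default
#' `base_filters = 8, depth = 3` trains in seconds on a CPU.
#'
#' @param in_channels input channel count (image channels plus any derived
#'   uncertainty channels).
#' @param n_objects number of independent objects K (output channels).
#' @param base_filters filters at the first level.
#' @param depth number of down-samplings; input height and width must be
#'   divisible by `2^depth`.
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(in_channels = 1L, n_objects = 1L,
                            base_filters = 8L, depth = 3L) {
  stopifnot(in_channels >= 1, n_objects >= 1, base_filters >= 1, depth >= 1)
  structure(list(in_channels = as.integer(in_channels),
                 n_objects = as.integer(n_objects),
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth)),
            class = "backbone_config")
}

# channel plan: (Cin, Cout) of every convolution, in parameter order
backbone_shapes <- function(cfg) {
  f <- cfg$base_filters; d <- cfg$depth
  sh <- list()
  cin <- cfg$in_channels
  for (i in seq_len(d) - 1L) {
    co <- f * 2L^i
    sh[[paste0("enc", i, "_A")]] <- c(cin, co, 9L)
    sh[[paste0("enc", i, "_B")]] <- c(co, co, 9L)
    cin <- co
  }
  cb <- f * 2L^d
  sh[["bot_A"]] <- c(cin, cb, 9L)
  sh[["bot_B"]] <- c(cb, cb, 9L)
  for (i in rev(seq_len(d) - 1L)) {
    co <- f * 2L^i
    sh[[paste0("up", i)]] <- c(2L * co, co, 9L)      # after upsample from below
    sh[[paste0("dec", i, "_A")]] <- c(2L * co, co, 9L)  # skip + up concat
    sh[[paste0("dec", i, "_B")]] <- c(co, co, 9L)
  }
  sh[["out"]] <- c(f, cfg$n_objects, 1L)
  sh
}

#' Build (initialize) a backbone model
#'
#' He-normal weight initialization driven by R's RNG: two builds with the
#' same seed are bitwise identical.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer seed for the initialization.
#' @return a `ugls_backbone` list with fields `cfg` and `params`.
#' @export
build_backbone <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "backbone_config"))
  with_local_rng(seed, {
    params <- list()
    for (nm in names(sh <- backbone_shapes(cfg))) {
      s <- sh[[nm]]
      fan_in <- s[1] * s[3]
      params[[paste0(nm, "_W")]] <-
        matrix(rnorm(s[2] * fan_in, sd = sqrt(2 / fan_in)), s[2], fan_in)
      params[[paste0(nm, "_b")]] <- numeric(s[2])
    }
    structure(list(cfg = cfg, params = params), class = "ugls_backbone")
  })
}

#' @export
print.ugls_backbone <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf("<ugls_backbone> in=%d K=%d base=%d depth=%d (%d parameters)\n",
              x$cfg$in_channels, x$cfg$n_objects, x$cfg$base_filters,
              x$cfg$depth, np))
  invisible(x)
}

# run a block with a private RNG stream, restoring the caller's afterwards
with_local_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_input_stack <- function(model, xs) {
  if (!is.list(xs)) xs <- list(xs)
  cfg <- model$cfg
  lapply(xs, function(x) {
    x <- as_input_array(x)
    if (dim(x)[3] != cfg$in_channels)
      stop(sprintf("input has %d channels; model expects %d",
                   dim(x)[3], cfg$in_channels))
    if (any(dim(x)[1:2] %% 2L^cfg$depth != 0L))
      stop(sprintf("spatial dims must be divisible by 2^depth = %d",
                   2L^cfg$depth))
    x
  })
}

as_input_array <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Predict probability maps
#'
#' Runs the backbone on one or more input stacks and returns per-object
#' probability maps in \[0, 1\] (no thresholding). Deterministic in eval:
#' identical inputs give identical outputs.
#'
#' @param model a `ugls_backbone`.
#' @param xs one H x W x C array (or matrix) or a list of them.
#' @return a list of H x W x K probability arrays (a single array if a single
#'   input was given).
#' @export
backbone_predict <- function(model, xs) {
  single <- !is.list(xs)
  inputs <- check_input_stack(model, xs)
  cfg <- model$cfg
  out <- cpp_unet_predict(model$params, cfg$in_channels, cfg$n_objects,
                          cfg$base_filters, cfg$depth, inputs)
  if (single) out[[1]] else out
}

#' Binarize probability maps
#'
#' Pixels with probability `>= threshold` become foreground (ties go to
#' foreground, which makes the 0.5 default deterministic).
#'
#' @param p probability matrix or H x W x K array in \[0, 1\].
#' @param threshold scalar strictly inside (0, 1); default 0.5.
#' @param object_ids labels for the resulting masks.
#' @return a [binary_mask] (matrix input) or list of masks (array input),
#'   tagged with `source = "prediction"`.
#' @export
binarize <- function(p, threshold = 0.5, object_ids = NULL) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)")
  if (is.matrix(p)) {
    return(binary_mask((p >= threshold) * 1L,
                       object_id = object_ids %||% "object",
                       source = "prediction"))
  }
  stopifnot(is.array(p), length(dim(p)) == 3L)
  K <- dim(p)[3]
  ids <- object_ids %||% paste0("object", seq_len(K))
  out <- lapply(seq_len(K), function(k)
    binary_mask((p[, , k] >= threshold) * 1L, object_id = ids[k],
                source = "prediction"))
  names(out) <- ids
  out
}

#' Save / load a model checkpoint
#'
#' The configuration travels inside the checkpoint, so a loaded model is
#' self-describing.
#'
#' @param model a `ugls_backbone`.
#' @param path checkpoint file path.
#' @return `load_model` returns the `ugls_backbone`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ugls_backbone"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "ugls_backbone"))
  m
}
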