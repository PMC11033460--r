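#' Joint image/mask augmentation specification
#'
#' The sampled transform is applied identically to the image and every mask:
#' horizontal/vertical flips (each with probability 1/2), uniform scaling in
#' `[0.9, 1.1]`, per-axis translation in `[-10, +10]` percent, rotation in
#' `[-180, 180]` degrees and shearing in `[-5, 5]` degrees. Images are
#' resampled bilinearly, masks by nearest neighbour (so they stay binary).
#'
#' @param hflip,vflip enable the random flips.
#' @param scale,rotate,shear two-element ranges (scale factor, degrees).
#' @param translate maximum |shift| as a fraction of each axis.
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(hflip = TRUE, vflip = TRUE,
                              scale = c(0.9, 1.1), translate = 0.1,
                              rotate = c(-180, 180), shear = c(-5, 5)) {
  structure(list(hflip = hflip, vflip = vflip, scale = scale,
                 translate = translate, rotate = rotate, shear = shear),
            class = "augmentation_spec")
}

#' @rdname augmentation_spec
#' @export
identity_augmentation <- function() {
  augmentation_spec(hflip = FALSE, vflip = FALSE, scale = c(1, 1),
                    translate = 0, rotate = c(0, 0), shear = c(0, 0))
}

#' Apply one random joint transform
#'
#' @param image matrix or H x W x C array.
#' @param masks a [binary_mask], or list of them, transformed jointly with
#'   the image.
#' @param spec an [augmentation_spec()].
#' @param seed optional seed for an isolated draw (used in tests); by default
#'   the transform is sampled from the current RNG stream.
#' @return `list(image =, masks =)` with unchanged shapes.
#' @export
augment <- function(image, masks, spec = augmentation_spec(), seed = NULL) {
  run <- function() {
    H <- nrow(if (is.matrix(image)) image else image[, , 1])
    W <- ncol(if (is.matrix(image)) image else image[, , 1])
    fh <- if (spec$hflip && runif(1) < 0.5) -1 else 1
    fv <- if (spec$vflip && runif(1) < 0.5) -1 else 1
    sc <- runif(1, spec$scale[1], spec$scale[2])
    th <- runif(1, spec$rotate[1], spec$rotate[2]) * pi / 180
    shr <- tan(runif(1, spec$shear[1], spec$shear[2]) * pi / 180)
    tr <- c(runif(1, -spec$translate, spec$translate) * H,
            runif(1, -spec$translate, spec$translate) * W)
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    shear <- matrix(c(1, 0, shr, 1), 2, 2)
    lin <- diag(c(fv, fh)) %*% rot %*% shear * sc
    ctr <- c((H - 1) / 2, (W - 1) / 2)
    Minv <- solve(lin)
    off <- ctr - Minv %*% (ctr + tr)
    warp1 <- function(m, nearest)
      cpp_warp_affine(m, Minv, as.numeric(off), nearest, 0)
    img_out <- if (is.matrix(image)) warp1(image, FALSE) else {
      out <- image
      for (cch in seq_len(dim(image)[3])) out[, , cch] <- warp1(image[, , cch], FALSE)
      out
    }
    single <- is_binary_mask(masks)
    ml <- if (single) list(masks) else masks
    ml_out <- lapply(ml, function(m)
      mask_like(matrix(as.integer(warp1(matrix(as.numeric(m), nrow(m)), TRUE)),
                       nrow(m)), m))
    names(ml_out) <- names(ml)
    list(image = img_out, masks = if (single) ml_out[[1]] else ml_out)
  }
  if (is.null(seed)) run() else with_local_rng(seed, run())
}

#' Training configuration
#'
#' Defaults mirror the reference training recipe: RMSprop at learning rate
#' 0.001, batch size 8, up to 100 epochs with early stopping after 20 epochs
#' without validation improvement, 0.5 binarization threshold, and the
#' standard augmentation ranges. `r_m`/`r_g` are the morphology radius and
#' Gaussian size used to build bundles (shared value by default).
#'
#' @param learning_rate,batch_size,max_epochs,patience optimizer schedule.
#' @param r_m,r_g bundle radii in pixels.
#' @param input_mode fine-stage input: `"bum"` (uncertainty maps only),
#'   `"ori+bum"` (original image + maps) or `"bei+bum"` (background-excluded
#'   image + maps, the recommended mode).
#' @param threshold binarization threshold for coarse masks.
#' @param base_filters,depth backbone scale (see [backbone_config()]).
#' @param augmentation an [augmentation_spec()] or `NULL` to disable.
#' @param clip_norm global gradient-norm ceiling (batch gradients with a
#'   larger L2 norm are rescaled to it); `Inf` disables. Outlier batches
#'   otherwise throw small nets into sigmoid saturation they cannot escape.
#' @param seed master seed for all randomness in a run.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 8L,
                         max_epochs = 100L, patience = 20L,
                         r_m = 6L, r_g = r_m,
                         input_mode = c("bei+bum", "bum", "ori+bum"),
                         threshold = 0.5, base_filters = 8L, depth = 3L,
                         augmentation = augmentation_spec(), clip_norm = 5,
                         seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (patience > max_epochs) stop("`patience` must be <= `max_epochs`")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 r_m = as.integer(r_m), r_g = as.integer(r_g),
                 input_mode = input_mode, threshold = threshold,
                 base_filters = as.integer(base_filters),
                 depth = as.integer(depth),
                 augmentation = augmentation, clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "train_config")
}

# rescale the whole gradient list to a global L2 ceiling
clip_grads <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (gn > max_norm) grads <- lapply(grads, function(g) g * (max_norm / gn))
  grads
}

# One RMSprop step (rho 0.9, eps 1e-7, the Keras parameterization): slower
# accumulator decays (0.99) proved unstable at desk scale -- a stale large
# second-moment suppresses recovery from transient all-background collapses.
rmsprop_step <- function(params, grads, state, lr, alpha = 0.9, eps = 1e-7) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    v <- state[[nm]]
    if (is.null(v)) v <- g * 0
    v <- alpha * v + (1 - alpha) * g^2
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
    state[[nm]] <- v
  }
  list(params = params, state = state)
}

stack_truth <- function(masks, objects) {
  a <- array(0, c(dim(masks[[1]]), length(objects)))
  for (k in seq_along(objects)) a[, , k] <- as.numeric(masks[[objects[k]]])
  a
}

#' Train one segmentation stage
#'
#' Mini-batch RMSprop on `1 - L` where `L` is the mean per-object Dice
#' ([dice_cost()]) of the probability maps. After every epoch the mean Dice
#' on the validation split is computed (never augmented); training stops when
#' it has not improved by more than 1e-5 for `patience` consecutive epochs,
#' or at `max_epochs`. The returned model carries the parameters of the best
#' validation epoch.
#'
#' @param model a `ugls_backbone` (its initialization seed is the caller's
#'   business; use [build_backbone()]).
#' @param inputs named list of H x W x C input arrays, one per image id.
#' @param truths named list of H x W x K truth arrays (see objects order).
#' @param train_ids,val_ids disjoint id vectors indexing `inputs`.
#' @param cfg a [train_config()].
#' @param score_fn optional override of the validation scorer, a
#'   `function(model, epoch) -> scalar`; used to unit-test the early-stopping
#'   logic with scripted score sequences.
#' @return `list(model =, history =)`; `history` has columns
#'   `epoch, train_dice, val_dice`.
#' @export
train_stage <- function(model, inputs, truths, train_ids, val_ids, cfg,
                        score_fn = NULL) {
  stopifnot(length(train_ids) >= 1)
  if (length(intersect(train_ids, val_ids)) > 0)
    stop("train and validation splits overlap")
  ccfg <- model$cfg
  lr <- cfg$learning_rate
  state <- list()
  best <- -Inf; best_params <- model$params; wait <- 0L
  hist <- data.frame(epoch = integer(), train_dice = double(),
                     val_dice = double())
  val_x <- unname(lapply(inputs[val_ids], as_input_array))
  val_y <- unname(truths[val_ids])
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_ids)
    tr_dice <- c()
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      xs <- list(); ys <- list()
      for (id in ids) {
        x <- inputs[[id]]; y <- truths[[id]]
        if (!is.null(cfg$augmentation)) {
          ml <- lapply(seq_len(dim(y)[3]), function(k)
            binary_mask((y[, , k] >= 0.5) * 1L))
          aug <- augment(x, ml, cfg$augmentation)
          x <- aug$image
          y <- array(0, dim(y))
          for (k in seq_along(aug$masks)) y[, , k] <- as.numeric(aug$masks[[k]])
        }
        xs[[length(xs) + 1L]] <- as_input_array(x)
        ys[[length(ys) + 1L]] <- y
      }
      res <- cpp_unet_batch(model$params, ccfg$in_channels, ccfg$n_objects,
                            ccfg$base_filters, ccfg$depth, xs, ys, TRUE)
      tr_dice <- c(tr_dice, res$dice)
      upd <- rmsprop_step(model$params,
                          clip_grads(res$grads, cfg$clip_norm %||% Inf),
                          state, lr)
      model$params <- upd$params
      state <- upd$state
    }
    val <- if (!is.null(score_fn)) score_fn(model, epoch)
           else if (length(val_ids) == 0) mean(tr_dice)
           else cpp_unet_batch(model$params, ccfg$in_channels, ccfg$n_objects,
                               ccfg$base_filters, ccfg$depth,
                               val_x, val_y, FALSE)$dice
    hist <- rbind(hist, data.frame(epoch = epoch, train_dice = mean(tr_dice),
                                   val_dice = val))
    if (val > best + 1e-5) {
      best <- val; best_params <- model$params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$params <- best_params
  list(model = model, history = hist)
}

#' Build uncertainty bundles for a set of images
#'
#' One PBR/BUM per object plus a single BEI computed from the union of the
#' per-object PBRs. Coarse masks must come from predictions: a ground-truth
#' mask is refused unless `allow_truth = TRUE` (useful only for plumbing
#' experiments with an oracle coarse stage), which keeps manual annotations
#' from leaking into validation/test bundle construction. An empty coarse
#' mask falls back to an all-ones PBR (the whole image is uncertain), so the
#' fine stage degrades to ordinary segmentation rather than seeing zeros.
#'
#' @param images named list of images.
#' @param coarse_masks named list (per image) of per-object [binary_mask]s.
#' @param r_m,r_g bundle radii in pixels.
#' @param allow_truth permit ground-truth-sourced coarse masks.
#' @return named list per image: `list(bums = <list per object>, bei =, pbrs =)`.
#' @export
make_bundles <- function(images, coarse_masks, r_m, r_g = r_m,
                         allow_truth = FALSE) {
  out <- list()
  for (id in names(images)) {
    img <- images[[id]]
    ms <- coarse_masks[[id]]
    if (is_binary_mask(ms)) ms <- list(ms)
    bums <- list(); pbrs <- list()
    for (k in seq_along(ms)) {
      m <- ms[[k]]
      if (!allow_truth && identical(attr(m, "source"), "truth"))
        stop(sprintf(
          "image '%s': ground-truth mask reached bundle construction", id))
      pbr <- if (sum(m) == 0L) {
        warning(sprintf("image '%s': empty coarse mask, using all-ones PBR", id))
        mask_like(matrix(1L, nrow(m), ncol(m)), m)
      } else {
        suppressWarnings(potential_boundary_region(m, r_m))
      }
      pbrs[[k]] <- pbr
      bums[[k]] <- boundary_uncertainty_map(pbr, r_g)
    }
    names(bums) <- names(pbrs) <- names(ms)
    un <- Reduce(function(a, b) pmax(a, b), lapply(pbrs, unclass))
    bei <- background_excluded_image(binary_mask(un), img)
    out[[id]] <- list(bums = bums, bei = bei, pbrs = pbrs)
  }
  out
}

#' Assemble fine-stage input stacks
#'
#' Channel layout per image: image-derived channels first (the original image
#' for `"ori+bum"`, the BEI for `"bei+bum"`, none for `"bum"`), then one BUM
#' channel per object, in object order.
#'
#' @param images named list of images.
#' @param bundles output of [make_bundles()].
#' @param input_mode `"bum"`, `"ori+bum"` or `"bei+bum"`.
#' @return named list of H x W x C arrays.
#' @export
fine_inputs <- function(images, bundles, input_mode) {
  out <- list()
  for (id in names(images)) {
    chans <- list()
    if (input_mode == "ori+bum") {
      img <- as_image(images[[id]])
      for (cch in seq_len(dim(img)[3])) chans[[length(chans) + 1L]] <- img[, , cch]
    } else if (input_mode == "bei+bum") {
      bei <- as_image(bundles[[id]]$bei)
      for (cch in seq_len(dim(bei)[3])) chans[[length(chans) + 1L]] <- bei[, , cch]
    } else if (input_mode != "bum") stop("unknown input mode: ", input_mode)
    for (b in bundles[[id]]$bums) chans[[length(chans) + 1L]] <- b
    a <- array(0, c(dim(chans[[1]]), length(chans)))
    for (j in seq_along(chans)) a[, , j] <- chans[[j]]
    out[[id]] <- a
  }
  out
}

#' Number of fine-stage input channels for a mode
#' @param image_channels channels of the raw image.
#' @param n_objects number of objects K.
#' @param input_mode see [fine_inputs()].
#' @return integer channel count.
#' @export
fine_channel_count <- function(image_channels, n_objects, input_mode) {
  base <- if (input_mode == "bum") 0L else as.integer(image_channels)
  base + as.integer(n_objects)
}

#' Rotate three data subsets through train/val/test roles
#'
#' Partitions the ids into three equal subsets (any remainder is pinned to
#' the training role in every experiment, with a message) and returns the six
#' role assignments obtained by permuting the subsets, in seed-determined
#' order. Every subset serves in every role across the six experiments.
#'
#' @param ids character or integer vector of image ids.
#' @param n_experiments number of rotations (at most 6).
#' @param seed RNG seed for the partition and the permutation order.
#' @return list of `list(train =, val =, test =)` id vectors.
#' @export
rotate_subsets <- function(ids, n_experiments = 6L, seed = 1L) {
  stopifnot(length(ids) >= 3, n_experiments >= 1, n_experiments <= 6)
  with_local_rng(seed, {
    ids <- sample(ids)
    m <- length(ids) %/% 3L
    extra <- if (length(ids) %% 3L) ids[(3L * m + 1L):length(ids)] else character(0)
    if (length(extra)) message(length(extra), " leftover id(s) pinned to train")
    subsets <- list(ids[1:m], ids[(m + 1):(2 * m)], ids[(2 * m + 1):(3 * m)])
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    perms <- perms[sample(6L)][seq_len(n_experiments)]
    lapply(perms, function(p)
      list(train = c(subsets[[p[1]]], extra),
           val = subsets[[p[2]]],
           test = subsets[[p[3]]]))
  })
}

#' Run the full uncertainty-guided two-stage pipeline
#'
#' Trains the coarse stage on raw images, binarizes its predictions for every
#' image (train, validation and test alike, each from its own prediction --
#' ground truth never seeds a bundle), builds the uncertainty bundles, trains
#' the fine stage on the configured input mode with the same recipe, and
#' evaluates both stages on the test split.
#'
#' @param dataset a dataset as produced by [generate_dataset()] or
#'   [load_dataset()]: fields `images`, `masks`, `objects`, `split`.
#' @param cfg a [train_config()].
#' @param split optional named split vector overriding `dataset$split`.
#' @return list with `coarse_model`, `fine_model`, histories, per-image
#'   metric rows and aggregate reports for both stages, and the bundles.
#' @export
run_ugls <- function(dataset, cfg = train_config(), split = NULL) {
  split <- split %||% dataset$split
  ids <- names(dataset$images)
  tr <- ids[split[ids] == "train"]
  va <- ids[split[ids] == "val"]
  te <- ids[split[ids] == "test"]
  if (!length(tr)) stop("empty training split")
  objects <- dataset$objects
  K <- length(objects)
  img_ch <- image_channels(dataset$images[[1]])
  truths <- lapply(dataset$masks, stack_truth, objects = objects)

  with_local_rng(cfg$seed, {
    coarse <- build_backbone(
      backbone_config(img_ch, K, cfg$base_filters, cfg$depth),
      seed = sample.int(2^31 - 1, 1))
    coarse_fit <- train_stage(coarse, dataset$images, truths, tr, va, cfg)
    coarse <- coarse_fit$model

    probs <- backbone_predict(coarse, unname(lapply(dataset$images, as_input_array)))
    names(probs) <- ids
    coarse_masks <- lapply(ids, function(id)
      binarize(probs[[id]], cfg$threshold, object_ids = objects))
    names(coarse_masks) <- ids

    bundles <- withCallingHandlers(
      make_bundles(dataset$images, coarse_masks, cfg$r_m, cfg$r_g),
      warning = function(w) invokeRestart("muffleWarning"))
    fin <- fine_inputs(dataset$images, bundles, cfg$input_mode)
    stopifnot(dim(fin[[1]])[3] ==
                fine_channel_count(img_ch, K, cfg$input_mode))

    fine <- build_backbone(
      backbone_config(dim(fin[[1]])[3], K, cfg$base_filters, cfg$depth),
      seed = sample.int(2^31 - 1, 1))
    fine_fit <- train_stage(fine, fin, truths, tr, va, cfg)
    fine <- fine_fit$model

    eval_stage <- function(model, inputs) {
      rows <- list()
      for (id in te) {
        p <- backbone_predict(model, inputs[[id]])
        pm <- binarize(p, cfg$threshold, object_ids = objects)
        for (k in seq_len(K)) {
          truth <- binary_mask((truths[[id]][, , k] >= 0.5) * 1L,
                               object_id = objects[k], source = "truth")
          rows[[length(rows) + 1L]] <-
            evaluate_masks(pm[[k]], truth, objects[k], id)
        }
      }
      do.call(rbind, rows)
    }
    coarse_rows <- if (length(te)) eval_stage(coarse, dataset$images) else NULL
    fine_rows <- if (length(te)) eval_stage(fine, fin) else NULL

    list(coarse_model = coarse, fine_model = fine,
         coarse_history = coarse_fit$history, fine_history = fine_fit$history,
         coarse_rows = coarse_rows, fine_rows = fine_rows,
         coarse_report = if (!is.null(coarse_rows)) aggregate_metrics(coarse_rows),
         fine_report = if (!is.null(fine_rows)) aggregate_metrics(fine_rows),
         bundles = bundles, split = split)
  })
}
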