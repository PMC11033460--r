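# Shared driver for direction-of-effect runs: trains the coarse stage once
# per rotation and reuses its bundles for several fine-stage input modes.

mean_test_ds <- function(model, inputs, truths, te, objects, threshold) {
  ds_vals <- c()
  for (id in te) {
    p <- backbone_predict(model, uglseg:::as_input_array(inputs[[id]]))
    pm <- binarize(p, threshold, object_ids = objects)
    for (k in seq_along(objects)) {
      y <- matrix(truths[[id]][, , k], dim(truths[[id]])[1])
      ds_vals <- c(ds_vals,
                   dice_cost(matrix(as.numeric(pm[[k]]), nrow(pm[[k]])), y))
    }
  }
  mean(ds_vals)
}

run_rotation <- function(ds, split, cfg, modes = c("bei+bum", "bum")) {
  ids <- names(ds$images)
  tr <- ids[split[ids] == "train"]
  va <- ids[split[ids] == "val"]
  te <- ids[split[ids] == "test"]
  K <- length(ds$objects)
  truths <- lapply(ds$masks, uglseg:::stack_truth, objects = ds$objects)
  uglseg:::with_local_rng(cfg$seed, {
    coarse <- build_backbone(
      backbone_config(1, K, cfg$base_filters, cfg$depth),
      seed = sample.int(2^31 - 1, 1))
    cf <- train_stage(coarse, ds$images, truths, tr, va, cfg)
    probs <- backbone_predict(cf$model,
                              unname(lapply(ds$images, uglseg:::as_input_array)))
    names(probs) <- ids
    cm <- lapply(probs, binarize, threshold = cfg$threshold,
                 object_ids = ds$objects)
    bundles <- suppressWarnings(make_bundles(ds$images, cm, cfg$r_m, cfg$r_g))
    out <- list(coarse = mean_test_ds(cf$model, ds$images, truths, te,
                                      ds$objects, cfg$threshold))
    for (mode in modes) {
      fi <- fine_inputs(ds$images, bundles, mode)
      fine <- build_backbone(
        backbone_config(dim(fi[[1]])[3], K, cfg$base_filters, cfg$depth),
        seed = sample.int(2^31 - 1, 1))
      ff <- train_stage(fine, fi, truths, tr, va, cfg)
      out[[mode]] <- mean_test_ds(ff$model, fi, truths, te, ds$objects,
                                  cfg$threshold)
    }
    out
  })
}
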