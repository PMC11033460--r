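#' Mean per-object Dice of probability maps
#'
#' The training criterion: for K objects,
#' `L = (1/K) * sum_k 2*sum(p_k*y_k) / (sum(p_k^2) + sum(y_k^2))`,
#' with the squared-denominator form for probabilistic predictions (on binary
#' inputs `p^2 = p`, recovering the classic Dice coefficient
#' `2*TP / (2*TP + FP + FN)`). Training maximizes `L`; optimizers in this
#' package minimize `1 - L`. An object empty in both prediction and truth
#' scores 1 so degenerate images do not poison aggregates.
#'
#' @param pred probability maps in \[0, 1\]: a matrix (K = 1), an H x W x K
#'   array, or a list of matrices.
#' @param truth binary masks of the same layout.
#' @return scalar `L` in \[0, 1\].
#' @export
dice_cost <- function(pred, truth) {
  p <- as_map_list(pred)
  y <- as_map_list(truth)
  if (length(p) != length(y)) stop("pred and truth must have the same number of objects")
  ds <- mapply(function(pk, yk) {
    if (!all(dim(pk) == dim(yk))) stop("pred/truth shape mismatch")
    den <- sum(pk^2) + sum(yk^2)
    if (den == 0) 1 else 2 * sum(pk * yk) / den
  }, p, y)
  mean(ds)
}

as_map_list <- function(x) {
  if (is.list(x)) lapply(x, function(m) matrix(as.numeric(m), nrow(m)))
  else if (is.matrix(x)) list(matrix(as.numeric(x), nrow(x)))
  else if (is.array(x) && length(dim(x)) == 3L)
    lapply(seq_len(dim(x)[3]), function(k) x[, , k])
  else stop("expected a matrix, H x W x K array, or list of matrices")
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth [binary_mask]s (or 0/1 matrices) of identical shape.
#' @return a `confusion_counts` list with fields `tp`, `fp`, `tn`, `fn`,
#'   summing to the pixel count.
#' @export
confusion <- function(pred, truth) {
  p <- as_binary_mask(pred); y <- as_binary_mask(truth, source = "truth")
  if (!all(dim(p) == dim(y))) stop("pred and truth shapes differ")
  tp <- sum(p == 1L & y == 1L)
  fp <- sum(p == 1L & y == 0L)
  tn <- sum(p == 0L & y == 0L)
  fn <- sum(p == 0L & y == 1L)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, in \[-1, 1\].
#' Any zero factor in the denominator returns 0 (the conventional value for
#' degenerate all-foreground/all-background comparisons).
#'
#' @param c a `confusion_counts` object or list with tp/fp/tn/fn.
#' @return scalar in \[-1, 1\].
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  tn <- as.numeric(c$tn); fn <- as.numeric(c$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sensitivity (recall)
#'
#' `tp / (tp + fn)`; an empty truth (`tp + fn = 0`) is perfectly recalled and
#' returns 1.
#'
#' @inheritParams mcc
#' @return scalar in \[0, 1\].
#' @export
sensitivity <- function(c) {
  tp <- as.numeric(c$tp); fn <- as.numeric(c$fn)
  if (tp + fn == 0) return(1)
  tp / (tp + fn)
}

#' Boundary pixels of a mask
#'
#' Foreground pixels with at least one background 4-neighbour or lying on the
#' image border; the point set on which the Hausdorff distance is evaluated.
#'
#' @param mask a [binary_mask] or 0/1 matrix.
#' @return an n x 2 matrix of (row, col) coordinates (1-based).
#' @export
boundary_pixels <- function(mask) {
  m <- unclass(as_binary_mask(mask))
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  which(inner == 1L & nb_min == 0L, arr.ind = TRUE)
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric Hausdorff distance `max(d(X, Y), d(Y, X))` with
#' `d(X, Y) = max_x min_y ||x - y||` (Euclidean, in pixels) between the
#' boundary point sets of two masks (see [boundary_pixels()]).
#'
#' @param pred,truth [binary_mask]s of identical shape; both must be
#'   non-empty after boundary extraction.
#' @return non-negative scalar, in pixels at the evaluation resolution.
#' @export
hausdorff <- function(pred, truth) {
  bx <- boundary_pixels(pred)
  by <- boundary_pixels(truth)
  if (nrow(bx) == 0L || nrow(by) == 0L)
    stop("Hausdorff distance is undefined for an empty mask")
  cpp_hausdorff(matrix(as.numeric(bx), ncol = 2),
                matrix(as.numeric(by), ncol = 2))
}

#' Per-image, per-object metric row
#'
#' Computes DS, MCC, SEN and HSD for one predicted mask against its manual
#' annotation. If either mask is empty the Hausdorff distance is undefined
#' and reported as `NA` (and skipped by [aggregate_metrics()]).
#'
#' @param pred,truth binary masks of identical shape.
#' @param object_id,image_id labels recorded in the row.
#' @return a one-row data.frame with columns
#'   `object, image_id, ds, mcc, sen, hsd`.
#' @export
evaluate_masks <- function(pred, truth, object_id = "object", image_id = "img") {
  cc <- confusion(pred, truth)
  hs <- if (sum(pred == 1) == 0 || sum(truth == 1) == 0) NA_real_
        else hausdorff(pred, truth)
  data.frame(object = object_id, image_id = image_id,
             ds = dice_cost(matrix(as.numeric(pred), nrow(pred)),
                            matrix(as.numeric(truth), nrow(truth))),
             mcc = mcc(cc), sen = sensitivity(cc), hsd = hs,
             stringsAsFactors = FALSE)
}

#' Aggregate a metric table into mean +/- SD per object
#'
#' Mirrors the usual reporting layout: one row per object with the sample
#' mean and SD (n - 1 denominator; SD defined as 0 for n = 1) of each metric,
#' plus an `"Overall"` row pooling every input row. `NA` Hausdorff entries
#' are dropped from the HSD aggregate only.
#'
#' @param rows a data.frame of [evaluate_masks()] rows.
#' @return an object of class `metric_report`: a data.frame with columns
#'   `object, n, ds_mean, ds_sd, mcc_mean, mcc_sd, sen_mean, sen_sd,
#'   hsd_mean, hsd_sd`.
#' @export
aggregate_metrics <- function(rows) {
  if (nrow(rows) < 1L) stop("need at least one metric row")
  sd0 <- function(v) if (length(v) <= 1L) 0 else sd(v)
  one <- function(df, label) {
    hs <- df$hsd[!is.na(df$hsd)]
    data.frame(object = label, n = nrow(df),
               ds_mean = mean(df$ds), ds_sd = sd0(df$ds),
               mcc_mean = mean(df$mcc), mcc_sd = sd0(df$mcc),
               sen_mean = mean(df$sen), sen_sd = sd0(df$sen),
               hsd_mean = if (length(hs)) mean(hs) else NA_real_,
               hsd_sd = if (length(hs)) sd0(hs) else NA_real_,
               stringsAsFactors = FALSE)
  }
  sp <- split(rows, rows$object)
  parts <- Map(one, sp, names(sp))
  out <- do.call(rbind, c(unname(parts), list(one(rows, "Overall"))))
  rownames(out) <- NULL
  structure(out, class = c("metric_report", "data.frame"))
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>  (mean +/- SD per object)\n")
  df <- as.data.frame(x)
  fmt <- function(m, s) sprintf("%.4f +/- %.4f", m, s)
  show <- data.frame(object = df$object, n = df$n,
                     DS = fmt(df$ds_mean, df$ds_sd),
                     MCC = fmt(df$mcc_mean, df$mcc_sd),
                     SEN = fmt(df$sen_mean, df$sen_sd),
                     HSD = fmt(df$hsd_mean, df$hsd_sd))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write per-image and aggregate metric tables to CSV
#'
#' @param rows per-image rows from [evaluate_masks()].
#' @param path path of the per-image CSV; the aggregate table is written next
#'   to it with suffix `_aggregate.csv`.
#' @return invisibly, the aggregate [metric_report].
#' @export
write_metric_report <- function(rows, path) {
  write.csv(rows, path, row.names = FALSE)
  agg <- aggregate_metrics(rows)
  write.csv(as.data.frame(agg),
            sub("\\.csv$", "_aggregate.csv", path), row.names = FALSE)
  invisible(agg)
}
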