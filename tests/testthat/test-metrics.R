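# Cost function and evaluation metrics against frozen values and oracles.

test_that("dice_cost: perfect, disjoint, and the 2*3/(4+6) worked example", {
  m <- disk_mask(16, 4)
  expect_equal(dice_cost(matrix(as.numeric(m), 16), matrix(as.numeric(m), 16)), 1)
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1
  b <- matrix(0, 8, 8); b[5:6, 5:6] <- 1
  expect_equal(dice_cost(a, b), 0)
  # |P| = 4, |Y| = 6, |P n Y| = 3 -> DS = 2*3/(4+6) = 0.6
  p <- matrix(0, 8, 8); p[1, 1:4] <- 1
  y <- matrix(0, 8, 8); y[1, 2:7] <- 1
  expect_equal(dice_cost(p, y), 0.6)
  # both empty scores 1; mean over K objects
  expect_equal(dice_cost(list(p, matrix(0, 8, 8)), list(y, matrix(0, 8, 8))),
               mean(c(0.6, 1)))
})

test_that("dice_cost uses the squared denominator for probabilities", {
  set.seed(21)
  p <- matrix(runif(64), 8)
  y <- matrix(as.numeric(runif(64) < 0.5), 8)
  expect_equal(dice_cost(p, y), 2 * sum(p * y) / (sum(p^2) + sum(y^2)))
})

test_that("confusion counts match enumeration and sum to the pixel count", {
  ones <- binary_mask(matrix(1L, 4, 4))
  cc <- confusion(ones, ones)
  expect_equal(unclass(cc), list(tp = 16L, fp = 0L, tn = 0L, fn = 0L))
  zz <- confusion(binary_mask(matrix(0L, 4, 4)), ones)
  expect_equal(zz$fn, 16L)
  set.seed(9)
  for (case in 1:30) {
    p <- random_mask(8, 8); y <- random_mask(8, 8)
    got <- confusion(p, y)
    want <- oracle_confusion(unclass(p), unclass(y))
    expect_equal(got$tp, want$tp); expect_equal(got$fp, want$fp)
    expect_equal(got$tn, want$tn); expect_equal(got$fn, want$fn)
    expect_equal(got$tp + got$fp + got$tn + got$fn, 64L)
  }
})

test_that("mcc: perfect = 1, worked value 10/sqrt(180), degenerate -> 0", {
  expect_equal(mcc(list(tp = 5, fp = 0, tn = 11, fn = 0)), 1)
  expect_equal(mcc(list(tp = 2, fp = 1, tn = 5, fn = 0)), 10 / sqrt(180))
  expect_equal(mcc(list(tp = 0, fp = 0, tn = 16, fn = 0)), 0)
})

test_that("mcc symmetry under pred<->truth swap and bounds", {
  set.seed(31)
  for (case in 1:50) {
    p <- random_mask(8, 8); y <- random_mask(8, 8)
    v1 <- mcc(confusion(p, y))
    v2 <- mcc(confusion(y, p))
    expect_equal(v1, v2)
    expect_true(v1 >= -1 && v1 <= 1)
  }
})

test_that("sensitivity: formula and degenerate conventions", {
  expect_equal(sensitivity(list(tp = 3, fn = 1)), 0.75)
  expect_equal(sensitivity(list(tp = 7, fn = 0)), 1)
  expect_equal(sensitivity(list(tp = 0, fn = 5)), 0)
  expect_equal(sensitivity(list(tp = 0, fn = 0)), 1)
})

test_that("hausdorff: identity, 3-4-5 pair, asymmetric-directed case, errors", {
  m <- disk_mask(20, 6)
  expect_equal(hausdorff(m, m), 0)
  expect_equal(hausdorff(points_mask(12, cbind(1, 1)),
                         points_mask(12, cbind(4, 5))), 5)
  # d(X,Y) = 10, d(Y,X) = 0 -> HSD = 10
  expect_equal(hausdorff(points_mask(12, rbind(c(1, 1), c(11, 1))),
                         points_mask(12, cbind(1, 1))), 10)
  expect_error(hausdorff(binary_mask(matrix(0L, 5, 5)), m), "empty")
})

test_that("hausdorff equals the brute-force oracle; symmetric", {
  set.seed(13)
  for (case in 1:50) {
    p <- random_mask(10, 10, 0.3); y <- random_mask(10, 10, 0.3)
    if (sum(p) == 0 || sum(y) == 0) next
    got <- hausdorff(p, y)
    want <- oracle_hausdorff(boundary_pixels(p), boundary_pixels(y))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, hausdorff(y, p))
  }
})

test_that("metrics are invariant to joint translation", {
  base_p <- matrix(0L, 20, 20); base_p[4:8, 4:9] <- 1L
  base_y <- matrix(0L, 20, 20); base_y[5:9, 5:10] <- 1L
  shift <- function(m, d) {
    out <- matrix(0L, 20, 20)
    idx <- which(m == 1L, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + d[1]; idx[, 2] <- idx[, 2] + d[2]
    for (i in seq_len(nrow(idx))) out[idx[i, 1], idx[i, 2]] <- 1L
    out
  }
  for (d in list(c(3, 2), c(-2, 5))) {
    p1 <- binary_mask(base_p); y1 <- binary_mask(base_y)
    p2 <- binary_mask(shift(base_p, d)); y2 <- binary_mask(shift(base_y, d))
    expect_equal(mcc(confusion(p1, y1)), mcc(confusion(p2, y2)))
    expect_equal(hausdorff(p1, y1), hausdorff(p2, y2))
    expect_equal(dice_cost(matrix(as.numeric(p1), 20), matrix(as.numeric(y1), 20)),
                 dice_cost(matrix(as.numeric(p2), 20), matrix(as.numeric(y2), 20)))
  }
})

test_that("aggregate_metrics: single row, frozen mean/SD, order invariance", {
  r1 <- evaluate_masks(disk_mask(16, 4), disk_mask(16, 4), "obj", "a")
  agg1 <- aggregate_metrics(r1)
  expect_equal(agg1$ds_sd, c(0, 0))  # SD defined as 0 for n = 1
  rows <- data.frame(object = "o", image_id = c("a", "b"),
                     ds = c(0.8, 1.0), mcc = c(0.8, 1.0),
                     sen = c(0.8, 1.0), hsd = c(2, 4))
  agg <- aggregate_metrics(rows)
  expect_equal(agg$ds_mean, c(0.9, 0.9))
  expect_equal(agg$ds_sd, c(sqrt(0.02), sqrt(0.02)), tolerance = 1e-12)
  expect_equal(round(agg$ds_sd[1], 4), 0.1414)
  perm <- aggregate_metrics(rows[2:1, ])
  expect_equal(as.data.frame(agg), as.data.frame(perm))
  # Overall row pools objects
  rows2 <- rbind(rows, transform(rows, object = "p"))
  agg2 <- aggregate_metrics(rows2)
  expect_equal(agg2$object, c("o", "p", "Overall"))
  expect_equal(agg2$n[3], 4L)
})

test_that("evaluate_masks reports NA Hausdorff for empty masks, not an error", {
  row <- evaluate_masks(binary_mask(matrix(0L, 8, 8)), disk_mask(8, 2), "o", "i")
  expect_true(is.na(row$hsd))
  expect_equal(row$sen, 0)
})
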