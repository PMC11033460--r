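# Brute-force reference implementations, deliberately independent of the
# package's algorithms: per-output-pixel enumeration for morphology, dense
# double-loop convolution, O(|X||Y|) Hausdorff. Used to freeze expected
# values and for property-based equivalence tests.

oracle_dilate <- function(m, off) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && m[ii, jj] == 1L) {
        out[i, j] <- 1L
        break
      }
    }
  }
  out
}

oracle_erode <- function(m, off) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(1L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      if (!(ii >= 1 && ii <= H && jj >= 1 && jj <= W && m[ii, jj] == 1L)) {
        out[i, j] <- 0L
        break
      }
    }
  }
  out
}

# symmetric reflection including the edge pixel (1-based)
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_conv2_reflect <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  ch <- (nrow(k) - 1) / 2; cw <- (ncol(k) - 1) / 2
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- 0
    for (a in seq_len(nrow(k))) for (b in seq_len(ncol(k))) {
      ii <- reflect1(i + a - 1 - ch, H)
      jj <- reflect1(j + b - 1 - cw, W)
      s <- s + k[a, b] * x[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

oracle_hausdorff <- function(X, Y) {
  dmat <- sqrt(outer(X[, 1], Y[, 1], "-")^2 + outer(X[, 2], Y[, 2], "-")^2)
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_confusion <- function(p, y) {
  tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
  for (q in seq_along(p)) {
    if (p[q] == 1L && y[q] == 1L) tp <- tp + 1L
    else if (p[q] == 1L) fp <- fp + 1L
    else if (y[q] == 1L) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# fixtures -------------------------------------------------------------------

random_mask <- function(H = 16, W = 16, p = 0.4) {
  binary_mask(matrix(as.integer(runif(H * W) < p), H, W))
}

disk_mask <- function(S, r, center = c((S + 1) / 2, (S + 1) / 2)) {
  rr <- matrix(seq_len(S), S, S) - center[1]
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) - center[2]
  binary_mask((rr^2 + cc^2 <= r^2) * 1L)
}

# point-set mask: 1s at the given (row, col) pairs
points_mask <- function(S, pts) {
  m <- matrix(0L, S, S)
  for (i in seq_len(nrow(pts))) m[pts[i, 1], pts[i, 2]] <- 1L
  binary_mask(m)
}
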