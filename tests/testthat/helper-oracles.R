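# Independent brute-force oracles shared across test files. These are
# deliberately written as plain loops, separate from the package
# implementations they check.

# dense-grid bilinear ROI pooling: per-bin-center sampling, temporal mean,
# spatial max
roi_pool_oracle <- function(volume, box, S = 8) {
  dv <- dim(volume); C <- dv[1]; Tt <- dv[2]; H <- dv[3]; W <- dv[4]
  u1 <- 1 + box[1] * (W - 1); u2 <- 1 + box[3] * (W - 1)
  v1 <- 1 + box[2] * (H - 1); v2 <- 1 + box[4] * (H - 1)
  sample_at <- function(f, y, x) {
    y <- min(max(y, 1), H); x <- min(max(x, 1), W)
    y0 <- floor(y); x0 <- floor(x)
    y1 <- min(y0 + 1, H); x1 <- min(x0 + 1, W)
    fy <- y - y0; fx <- x - x0
    f[y0, x0] * (1 - fy) * (1 - fx) + f[y1, x0] * fy * (1 - fx) +
      f[y0, x1] * (1 - fy) * fx + f[y1, x1] * fy * fx
  }
  out <- numeric(C)
  for (c_ in 1:C) {
    m <- matrix(0, S, S)
    for (ky in 1:S) for (kx in 1:S) {
      y <- v1 + (ky - 0.5) / S * (v2 - v1)
      x <- u1 + (kx - 0.5) / S * (u2 - u1)
      acc <- 0
      for (t in 1:Tt)
        acc <- acc + sample_at(matrix(volume[c_, t, , ], H, W), y, x)
      m[ky, kx] <- acc / Tt
    }
    out[c_] <- max(m)
  }
  out
}

# precision-recall enumeration: at each recall step take the maximum
# precision at recall >= r
ap_oracle <- function(flags, n_truth) {
  if (n_truth == 0) return(NA_real_)
  tp <- cumsum(flags); fp <- cumsum(!flags)
  prec <- tp / (tp + fp); rec <- tp / n_truth
  ap <- 0
  prev_r <- 0
  for (i in seq_along(flags)) {
    if (!flags[i]) next
    r <- rec[i]
    ap <- ap + (r - prev_r) * max(prec[rec >= r - 1e-15])
    prev_r <- r
  }
  ap
}
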