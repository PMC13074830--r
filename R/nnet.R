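# Minimal neural-network primitives with hand-written gradients.
#
# Tensors are plain R arrays; feature volumes are channel-first
# (C x T x H x W). The package trains desk-scale models only, so clarity and
# verifiability (finite-difference and brute-force oracles in the tests)
# take precedence over speed. Forward passes return caches consumed by the
# matching backward passes.

# --- 3D convolution, kernel 3x3x3, stride 1, zero 'same' padding ----------

conv3d_forward <- function(x, w, b) {
  dx <- dim(x)                 # Cin, T, H, W
  dw <- dim(w)                 # Cout, Cin, 3, 3, 3
  stopifnot(dx[1] == dw[2], all(dw[3:5] == 3), length(b) == dw[1])
  Cin <- dx[1]; Tt <- dx[2]; H <- dx[3]; W <- dx[4]; Cout <- dw[1]
  xp <- array(0, c(Cin, Tt + 2, H + 2, W + 2))
  xp[, 2:(Tt + 1), 2:(H + 1), 2:(W + 1)] <- x
  out <- array(0, c(Cout, Tt, H, W))
  nel <- Tt * H * W
  for (co in seq_len(Cout)) {
    acc <- rep(b[co], nel)
    for (ci in seq_len(Cin)) for (a in 1:3) for (bb in 1:3) for (cc in 1:3) {
      wv <- w[co, ci, a, bb, cc]
      if (wv != 0)
        acc <- acc + wv * as.vector(xp[ci, a:(a + Tt - 1), bb:(bb + H - 1),
                                       cc:(cc + W - 1), drop = FALSE])
    }
    out[co, , , ] <- acc
  }
  list(out = out, cache = list(xp = xp, w = w, dims = dx))
}

conv3d_backward <- function(dout, cache) {
  xp <- cache$xp; w <- cache$w; dx_ <- cache$dims
  dw <- dim(w)
  Cin <- dx_[1]; Tt <- dx_[2]; H <- dx_[3]; W <- dx_[4]; Cout <- dw[1]
  dW <- array(0, dim(w))
  db <- numeric(Cout)
  dXp <- array(0, dim(xp))
  for (co in seq_len(Cout)) {
    dy <- as.vector(dout[co, , , , drop = FALSE])
    db[co] <- sum(dy)
    for (ci in seq_len(Cin)) for (a in 1:3) for (bb in 1:3) for (cc in 1:3) {
      xs <- as.vector(xp[ci, a:(a + Tt - 1), bb:(bb + H - 1),
                         cc:(cc + W - 1), drop = FALSE])
      dW[co, ci, a, bb, cc] <- sum(dy * xs)
      wv <- w[co, ci, a, bb, cc]
      if (wv != 0) {
        cur <- as.vector(dXp[ci, a:(a + Tt - 1), bb:(bb + H - 1),
                             cc:(cc + W - 1), drop = FALSE])
        dXp[ci, a:(a + Tt - 1), bb:(bb + H - 1), cc:(cc + W - 1)] <-
          cur + wv * dy
      }
    }
  }
  dx <- dXp[, 2:(Tt + 1), 2:(H + 1), 2:(W + 1), drop = FALSE]
  list(dx = array(dx, dx_), dw = dW, db = db)
}

relu <- function(x) pmax(x, 0)
relu_backward <- function(dout, x) dout * (x > 0)

# --- bilinear ROI sampling -------------------------------------------------

# Neighbor indices and weights for bilinear interpolation at continuous
# 1-based position p within an axis of length n (positions clamped to
# [1, n]).
bilinear_axis <- function(p, n) {
  p <- clamp(p, 1, n)
  lo <- floor(p)
  hi <- pmin(lo + 1, n)
  whi <- p - lo
  list(lo = lo, hi = hi, wlo = 1 - whi, whi = whi)
}

# Sampling grid for a normalized box on an H x W feature map: `output_size`
# bin centers per axis. Normalized coordinate u in [0,1] maps to continuous
# pixel position 1 + u * (n - 1) (corner-aligned).
roi_grid <- function(box, H, W, output_size) {
  u1 <- 1 + box[1] * (W - 1); u2 <- 1 + box[3] * (W - 1)
  v1 <- 1 + box[2] * (H - 1); v2 <- 1 + box[4] * (H - 1)
  k <- seq_len(output_size)
  list(x = u1 + (k - 0.5) / output_size * (u2 - u1),
       y = v1 + (k - 0.5) / output_size * (v2 - v1))
}

#' Pathway frame sampling
#'
#' Splits a clip of T frames into the sparse (slow) and dense (fast) streams
#' of a dual-pathway video model: the slow pathway keeps one frame every
#' `slow_stride` frames, the fast pathway one every `fast_stride`, both
#' starting at the first frame. With T = 32 and the default strides 8 and 2
#' this yields 4 slow and 16 fast frames, the slow indices being a subset of
#' the fast ones.
#'
#' @param frames array T x H x W.
#' @param slow_stride,fast_stride sampling strides (defaults 8 and 2).
#' @return list with `slow` and `fast` frame arrays and the sampled `indices`.
#' @export
sample_pathways <- function(frames, slow_stride = 8, fast_stride = 2) {
  stopifnot(length(dim(frames)) == 3)
  Tt <- dim(frames)[1]
  stop_if(Tt < slow_stride, "clip has %d frames, need at least %d", Tt, slow_stride)
  si <- seq(1, Tt, by = slow_stride)
  fi <- seq(1, Tt, by = fast_stride)
  list(slow = frames[si, , , drop = FALSE],
       fast = frames[fi, , , drop = FALSE],
       indices = list(slow = si, fast = fi))
}

#' ROI feature pooling
#'
#' Extracts a per-box feature vector from a feature volume: per temporal
#' slice, bilinear ROI alignment to an `output_size` x `output_size` grid
#' (one sample at each bin center); then temporal average pooling to a single
#' slice and spatial max pooling to 1 x 1. The result is one value per
#' channel, i.e. a D-dimensional descriptor with D equal to the volume's
#' channel count.
#'
#' @param volume feature volume, array C x T x H x W.
#' @param box normalized box `c(x1, y1, x2, y2)` with positive area.
#' @param output_size spatial grid size (default 8).
#' @return numeric vector of length C.
#' @export
roi_pool <- function(volume, box, output_size = 8) {
  roi_pool_fwd(volume, box, output_size)$out
}

roi_pool_fwd <- function(volume, box, output_size = 8) {
  stopifnot(length(dim(volume)) == 4, length(box) == 4)
  stop_if(any(box < 0) || any(box > 1), "box must lie in [0,1]^2")
  stop_if(box[3] <= box[1] || box[4] <= box[2], "degenerate box (zero area)")
  dv <- dim(volume); C <- dv[1]; Tt <- dv[2]; H <- dv[3]; W <- dv[4]
  g <- roi_grid(box, H, W, output_size)
  ax <- bilinear_axis(g$x, W)
  ay <- bilinear_axis(g$y, H)
  S <- output_size
  # time-averaged bilinear samples, per channel: C x S x S
  M <- array(0, c(C, S, S))
  for (c_ in seq_len(C)) {
    plane <- matrix(0, S, S)      # rows = y bins, cols = x bins
    for (t in seq_len(Tt)) {
      f <- matrix(volume[c_, t, , ], H, W)
      # vectorized bilinear over the S x S grid
      v <- f[cbind(rep(ay$lo, S), rep(ax$lo, each = S))] *
             (rep(ay$wlo, S) * rep(ax$wlo, each = S)) +
           f[cbind(rep(ay$hi, S), rep(ax$lo, each = S))] *
             (rep(ay$whi, S) * rep(ax$wlo, each = S)) +
           f[cbind(rep(ay$lo, S), rep(ax$hi, each = S))] *
             (rep(ay$wlo, S) * rep(ax$whi, each = S)) +
           f[cbind(rep(ay$hi, S), rep(ax$hi, each = S))] *
             (rep(ay$whi, S) * rep(ax$whi, each = S))
      plane <- plane + matrix(v, S, S)
    }
    M[c_, , ] <- plane / Tt
  }
  out <- numeric(C)
  argmax <- matrix(0L, C, 2)
  for (c_ in seq_len(C)) {
    m <- matrix(M[c_, , ], S, S)
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    out[c_] <- m[ij[1], ij[2]]
    argmax[c_, ] <- ij
  }
  list(out = out,
       cache = list(ax = ax, ay = ay, argmax = argmax, dims = dv,
                    output_size = S))
}

roi_pool_backward <- function(dout, cache) {
  dv <- cache$dims; C <- dv[1]; Tt <- dv[2]; H <- dv[3]; W <- dv[4]
  ax <- cache$ax; ay <- cache$ay
  dvol <- array(0, dv)
  for (c_ in seq_len(C)) {
    if (dout[c_] == 0) next
    iy <- cache$argmax[c_, 1]; ix <- cache$argmax[c_, 2]
    g <- dout[c_] / Tt
    for (t in seq_len(Tt)) {
      dvol[c_, t, ay$lo[iy], ax$lo[ix]] <- dvol[c_, t, ay$lo[iy], ax$lo[ix]] +
        g * ay$wlo[iy] * ax$wlo[ix]
      dvol[c_, t, ay$hi[iy], ax$lo[ix]] <- dvol[c_, t, ay$hi[iy], ax$lo[ix]] +
        g * ay$whi[iy] * ax$wlo[ix]
      dvol[c_, t, ay$lo[iy], ax$hi[ix]] <- dvol[c_, t, ay$lo[iy], ax$hi[ix]] +
        g * ay$wlo[iy] * ax$whi[ix]
      dvol[c_, t, ay$hi[iy], ax$hi[ix]] <- dvol[c_, t, ay$hi[iy], ax$hi[ix]] +
        g * ay$whi[iy] * ax$whi[ix]
    }
  }
  dvol
}

# --- losses ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Multi-label behavior classification loss
#'
#' Binary cross-entropy averaged over samples and summed over the six
#' behavior classes:
#' `-(1/N) sum_i sum_c [y log p + (1 - y) log(1 - p)]`.
#' Probabilities are clamped to [1e-7, 1 - 1e-7] before taking logs.
#'
#' @param probs N x C matrix of per-class probabilities.
#' @param labels N x C matrix of 0/1 multi-hot labels.
#' @return scalar loss (non-negative; ~0 at perfect prediction).
#' @export
behavior_loss <- function(probs, labels) {
  stop_if(!is.matrix(probs) || !is.matrix(labels) ||
            !all(dim(probs) == dim(labels)),
          "probs and labels must be matrices of identical shape")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  p <- clamp(probs, 1e-7, 1 - 1e-7)
  -sum(labels * log(p) + (1 - labels) * log(1 - p)) / nrow(p)
}

#' Motion-attribute classification loss
#'
#' Softmax cross-entropy over the static/dynamic logits, averaged over
#' samples, computed in log-sum-exp form.
#'
#' @param logits N x 2 matrix of raw scores.
#' @param labels length-N vector in \{0, 1\} (0 = static, 1 = dynamic).
#' @return scalar loss.
#' @export
motion_loss <- function(logits, labels) {
  stop_if(!is.matrix(logits) || ncol(logits) != 2, "logits must be N x 2")
  stop_if(length(labels) != nrow(logits), "labels length must match logits rows")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  mx <- pmax(logits[, 1], logits[, 2])
  lse <- mx + log(exp(logits[, 1] - mx) + exp(logits[, 2] - mx))
  truth <- logits[cbind(seq_len(nrow(logits)), labels + 1)]
  mean(lse - truth)
}

softmax2 <- function(logits) {
  mx <- pmax(logits[, 1], logits[, 2])
  e <- exp(logits - mx)
  e / rowSums(e)
}

# gradients of the two losses w.r.t. logits (per sample already / N)
behavior_loss_grad_logits <- function(logits, labels) {
  (sigmoid(logits) - labels) / nrow(logits)
}
motion_loss_grad_logits <- function(logits, labels) {
  p <- softmax2(logits)
  y <- cbind(labels == 0, labels == 1) * 1
  (p - y) / nrow(logits)
}

one_hot <- function(ids, n_classes = length(BEHAVIOR_CLASSES)) {
  m <- matrix(0, length(ids), n_classes)
  m[cbind(seq_along(ids), ids)] <- 1
  m
}
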