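# Desk-scale dual-pathway, dual-head detection model and the multi-task
# training loop.
#
# Two model kinds share one training interface:
#   * conflict MLP — a small shared hidden layer with two linear heads, used
#     on the tabular conflicting-task generator;
#   * toy clip model — dual-pathway 3D-conv trunk (sparse/dense frame
#     sampling, two conv blocks per pathway, lateral channel concatenation),
#     ROI feature pooling, a linear 6-class behavior head and a two-layer
#     motion head.
# A model is a list with `params` (named arrays), `registry` (shared vs
# task-specific parameter names, in declaration order) and `fb`, a function
# (params, batch) -> list(l_act, l_mov, g_act, g_mov) computing both losses
# and the full per-task gradients.

flatten_named <- function(glist, names) {
  unlist(lapply(names, function(nm) as.numeric(glist[[nm]])), use.names = FALSE)
}

unflatten_named <- function(flat, template, names) {
  out <- template
  pos <- 0
  for (nm in names) {
    n <- length(template[[nm]])
    v <- flat[pos + seq_len(n)]
    out[[nm]] <- if (is.null(dim(template[[nm]]))) v
                 else array(v, dim(template[[nm]]))
    pos <- pos + n
  }
  out
}

#' Shared-parameter registry of a model
#'
#' Lists which parameters are shared (trunk) and which belong to each
#' task-specific head, in the fixed flattening order (parameter declaration
#' order, frozen at model construction). The two sets are disjoint and cover
#' all trainable parameters.
#'
#' @param model a model built by [build_conflict_mlp()] or [build_toy_model()].
#' @return list with `shared`, `act_head`, `mov_head` (character vectors of
#'   parameter names) and `n_shared`, the total flattened shared length.
#' @export
param_registry <- function(model) {
  r <- model$registry
  r$n_shared <- sum(vapply(r$shared, function(nm) length(model$params[[nm]]),
                           numeric(1)))
  r
}

zero_like <- function(params) lapply(params, function(p) {
  if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p))
})

# --- conflict MLP ----------------------------------------------------------

#' Build a small two-head MLP for the conflict test bed
#'
#' Shared ReLU hidden layer, a linear 6-class behavior head trained with
#' multi-label binary cross-entropy, and a linear static/dynamic head trained
#' with softmax cross-entropy. The trunk is randomly initialized
#' (scaled Gaussian); heads start at zero so first-step shared gradients
#' vanish and later trunk gradients reflect learned task structure rather
#' than random head noise.
#'
#' @param latent_dim input feature dimension.
#' @param hidden hidden width (default 16).
#' @param seed initialization seed.
#' @return model list (`params`, `registry`, `fb`, `predict`).
#' @export
build_conflict_mlp <- function(latent_dim, hidden = 16, seed = 1) {
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(latent_dim * hidden, sd = 1 / sqrt(latent_dim)),
                latent_dim, hidden),
    b1 = numeric(hidden),
    Wa = matrix(0, hidden, 6), ba = numeric(6),
    Wm = matrix(0, hidden, 2), bm = numeric(2)))
  registry <- list(shared = c("W1", "b1"), act_head = c("Wa", "ba"),
                   mov_head = c("Wm", "bm"))
  fb <- function(params, batch) {
    x <- batch$x
    n <- nrow(x)
    z <- sweep(x %*% params$W1, 2, params$b1, "+")
    a <- relu(z)
    la <- sweep(a %*% params$Wa, 2, params$ba, "+")
    lm <- sweep(a %*% params$Wm, 2, params$bm, "+")
    y <- one_hot(batch$behavior_id)
    l_act <- behavior_loss(sigmoid(la), y)
    l_mov <- motion_loss(lm, batch$motion_attr)
    back <- function(dla, dlm) {
      g <- zero_like(params)
      if (!is.null(dla)) {
        g$Wa <- crossprod(a, dla); g$ba <- colSums(dla)
        da <- dla %*% t(params$Wa)
      } else da <- matrix(0, n, ncol(a))
      if (!is.null(dlm)) {
        g$Wm <- crossprod(a, dlm); g$bm <- colSums(dlm)
        da <- da + dlm %*% t(params$Wm)
      }
      dz <- relu_backward(da, z)
      g$W1 <- crossprod(x, dz); g$b1 <- colSums(dz)
      g
    }
    list(l_act = l_act, l_mov = l_mov,
         g_act = back(behavior_loss_grad_logits(la, y), NULL),
         g_mov = back(NULL, motion_loss_grad_logits(lm, batch$motion_attr)),
         probs_act = sigmoid(la), probs_mov = softmax2(lm))
  }
  pred <- function(params, x) {
    a <- relu(sweep(x %*% params$W1, 2, params$b1, "+"))
    list(behavior = sigmoid(sweep(a %*% params$Wa, 2, params$ba, "+")),
         motion = softmax2(sweep(a %*% params$Wm, 2, params$bm, "+")))
  }
  structure(list(params = params, registry = registry, fb = fb,
                 predict = pred, kind = "conflict_mlp"),
            class = "mtl_model")
}

# --- toy clip model ----------------------------------------------------------

#' Configuration for the toy clip model
#'
#' Desk-scale analogue of a dual-pathway video backbone: the fast pathway
#' has `c_fast` channels and the slow pathway `channel_ratio * c_fast`
#' channels (ratio 8, as in full-scale dual-pathway designs where
#' 2048/256 = 8); the pooled descriptor has `D = c_slow + c_fast` entries.
#'
#' @param clip_len clip length T (must be divisible by `slow_stride`).
#' @param height,width frame size.
#' @param slow_stride,fast_stride pathway sampling strides.
#' @param c_fast fast-pathway channel count (default 1).
#' @param channel_ratio slow/fast channel ratio (default 8).
#' @param output_size ROI grid size (default 8).
#' @param seed initialization seed.
#' @return list of validated settings with derived `c_slow` and `D`.
#' @export
toy_model_config <- function(clip_len = 32, height = 16, width = 16,
                             slow_stride = 8, fast_stride = 2, c_fast = 1,
                             channel_ratio = 8, output_size = 8, seed = 1) {
  stop_if(clip_len %% slow_stride != 0,
          "clip_len must be divisible by slow_stride")
  stop_if(slow_stride %% fast_stride != 0,
          "slow_stride must be a multiple of fast_stride")
  stop_if(c_fast < 1 || channel_ratio < 1, "invalid channel configuration")
  c_slow <- c_fast * channel_ratio
  list(clip_len = clip_len, height = height, width = width,
       slow_stride = slow_stride, fast_stride = fast_stride,
       c_fast = c_fast, c_slow = c_slow, channel_ratio = channel_ratio,
       D = c_slow + c_fast, output_size = output_size, seed = seed)
}

# forward through one pathway's two conv blocks; returns activations + caches
pathway_forward <- function(x, params, prefix) {
  c1 <- conv3d_forward(x, params[[paste0(prefix, "W1")]],
                       params[[paste0(prefix, "b1")]])
  a1 <- relu(c1$out)
  c2 <- conv3d_forward(a1, params[[paste0(prefix, "W2")]],
                       params[[paste0(prefix, "b2")]])
  a2 <- relu(c2$out)
  list(a2 = a2, cache = list(c1 = c1$cache, z1 = c1$out,
                             c2 = c2$cache, z2 = c2$out))
}

pathway_backward <- function(da2, cache, g, prefix) {
  dz2 <- relu_backward(da2, cache$z2)
  b2 <- conv3d_backward(dz2, cache$c2)
  g[[paste0(prefix, "W2")]] <- g[[paste0(prefix, "W2")]] + b2$dw
  g[[paste0(prefix, "b2")]] <- g[[paste0(prefix, "b2")]] + b2$db
  dz1 <- relu_backward(b2$dx, cache$z1)
  b1 <- conv3d_backward(dz1, cache$c1)
  g[[paste0(prefix, "W1")]] <- g[[paste0(prefix, "W1")]] + b1$dw
  g[[paste0(prefix, "b1")]] <- g[[paste0(prefix, "b1")]] + b1$db
  g
}

#' Build the desk-scale dual-pathway dual-head model
#'
#' Shared trunk: per pathway, two 3x3x3 conv blocks with ReLU; the fast
#' stream is temporally averaged onto the slow stream's time axis and the
#' two are concatenated along channels into a single feature volume (lateral
#' fusion). Per box, [roi_pool()] yields a D-vector, fed to a linear 6-class
#' behavior head (sigmoid + multi-label BCE) and a two-layer motion head
#' (hidden width D, ReLU, 2-way softmax cross-entropy). The registry marks
#' all conv parameters as shared and head parameters as task-specific.
#' Trunk weights are random (scaled Gaussian), heads start at zero.
#'
#' @param config a [toy_model_config()].
#' @return model list (`params`, `registry`, `fb`, `predict`).
#' @export
build_toy_model <- function(config = toy_model_config()) {
  cs <- config$c_slow; cf <- config$c_fast; D <- config$D
  stop_if(D != cs + cf, "inconsistent channel dimensions")
  kinit <- function(co, ci) array(stats::rnorm(co * ci * 27,
                                               sd = 1 / sqrt(ci * 27)),
                                  c(co, ci, 3, 3, 3))
  params <- with_seed(config$seed, list(
    sW1 = kinit(cs, 1), sb1 = numeric(cs),
    sW2 = kinit(cs, cs), sb2 = numeric(cs),
    fW1 = kinit(cf, 1), fb1 = numeric(cf),
    fW2 = kinit(cf, cf), fb2 = numeric(cf),
    Wa = matrix(0, D, 6), ba = numeric(6),
    Wm1 = matrix(0, D, D), bm1 = numeric(D),
    Wm2 = matrix(0, D, 2), bm2 = numeric(2)))
  registry <- list(shared = c("sW1", "sb1", "sW2", "sb2",
                              "fW1", "fb1", "fW2", "fb2"),
                   act_head = c("Wa", "ba"),
                   mov_head = c("Wm1", "bm1", "Wm2", "bm2"))

  trunk_forward <- function(params, frames) {
    sp <- sample_pathways(frames, config$slow_stride, config$fast_stride)
    ds <- dim(sp$slow); df_ <- dim(sp$fast)
    xs <- array(sp$slow, c(1, ds))
    xf <- array(sp$fast, c(1, df_))
    ps <- pathway_forward(xs, params, "s")
    pf <- pathway_forward(xf, params, "f")
    Ts <- dim(ps$a2)[2]; Tf <- dim(pf$a2)[2]
    group <- Tf / Ts
    stop_if(group != floor(group), "pathway temporal sizes are incompatible")
    H <- dim(ps$a2)[3]; W <- dim(ps$a2)[4]
    fal <- array(0, c(cf, Ts, H, W))
    for (ts in seq_len(Ts)) {
      idx <- (ts - 1) * group + seq_len(group)
      sl <- pf$a2[, idx, , , drop = FALSE]
      fal[, ts, , ] <- apply(sl, c(1, 3, 4), mean)
    }
    Fv <- array(0, c(D, Ts, H, W))
    Fv[seq_len(cs), , , ] <- ps$a2
    Fv[cs + seq_len(cf), , , ] <- fal
    list(Fv = Fv, ps = ps, pf = pf, group = group, Ts = Ts)
  }

  trunk_backward <- function(dFv, tf, g) {
    cs_ <- cs
    dslow <- dFv[seq_len(cs_), , , , drop = FALSE]
    dfal <- dFv[cs_ + seq_len(cf), , , , drop = FALSE]
    df2 <- array(0, dim(tf$pf$a2))
    for (ts in seq_len(tf$Ts)) {
      idx <- (ts - 1) * tf$group + seq_len(tf$group)
      for (t2 in idx) df2[, t2, , ] <- dfal[, ts, , ] / tf$group
    }
    g <- pathway_backward(array(dslow, dim(tf$ps$a2)), tf$ps$cache, g, "s")
    pathway_backward(df2, tf$pf$cache, g, "f")
  }

  fb <- function(params, batch) {
    tf <- trunk_forward(params, batch$frames)
    n <- nrow(batch$boxes)
    rps <- lapply(seq_len(n), function(i)
      roi_pool_fwd(tf$Fv, batch$boxes[i, ], config$output_size))
    fmat <- do.call(rbind, lapply(rps, `[[`, "out"))
    la <- sweep(fmat %*% params$Wa, 2, params$ba, "+")
    zm <- sweep(fmat %*% params$Wm1, 2, params$bm1, "+")
    hm <- relu(zm)
    lm <- sweep(hm %*% params$Wm2, 2, params$bm2, "+")
    y <- one_hot(batch$behavior_id)
    l_act <- behavior_loss(sigmoid(la), y)
    l_mov <- motion_loss(lm, batch$motion_attr)
    back_to_trunk <- function(dfmat, g) {
      dFv <- array(0, dim(tf$Fv))
      for (i in seq_len(n))
        dFv <- dFv + roi_pool_backward(dfmat[i, ], rps[[i]]$cache)
      trunk_backward(dFv, tf, g)
    }
    g_act <- zero_like(params)
    dla <- behavior_loss_grad_logits(la, y)
    g_act$Wa <- crossprod(fmat, dla); g_act$ba <- colSums(dla)
    g_act <- back_to_trunk(dla %*% t(params$Wa), g_act)
    g_mov <- zero_like(params)
    dlm <- motion_loss_grad_logits(lm, batch$motion_attr)
    g_mov$Wm2 <- crossprod(hm, dlm); g_mov$bm2 <- colSums(dlm)
    dhm <- dlm %*% t(params$Wm2)
    dzm <- relu_backward(dhm, zm)
    g_mov$Wm1 <- crossprod(fmat, dzm); g_mov$bm1 <- colSums(dzm)
    g_mov <- back_to_trunk(dzm %*% t(params$Wm1), g_mov)
    list(l_act = l_act, l_mov = l_mov, g_act = g_act, g_mov = g_mov,
         probs_act = sigmoid(la), probs_mov = softmax2(lm), features = fmat)
  }

  pred <- function(params, batch) {
    tf <- trunk_forward(params, batch$frames)
    n <- nrow(batch$boxes)
    fmat <- do.call(rbind, lapply(seq_len(n), function(i)
      roi_pool(tf$Fv, batch$boxes[i, ], config$output_size)))
    hm <- relu(sweep(fmat %*% params$Wm1, 2, params$bm1, "+"))
    list(behavior = sigmoid(sweep(fmat %*% params$Wa, 2, params$ba, "+")),
         motion = softmax2(sweep(hm %*% params$Wm2, 2, params$bm2, "+")))
  }
  structure(list(params = params, registry = registry, fb = fb,
                 predict = pred, kind = "toy_clip", config = config),
            class = "mtl_model")
}

#' @export
print.mtl_model <- function(x, ...) {
  reg <- param_registry(x)
  cat(sprintf("<mtl_model: %s> %d shared parameters, heads: %s | %s\n",
              x$kind, reg$n_shared,
              paste(reg$act_head, collapse = ","),
              paste(reg$mov_head, collapse = ",")))
  invisible(x)
}

#' Cut a generated clip into per-keyframe training batches
#'
#' For each annotated keyframe, extracts a window of `clip_len` frames
#' centered on the keyframe (clamped to the clip), the keyframe's boxes and
#' both label sets.
#'
#' @param toy output of [gen_toy_clips()].
#' @param clip_len window length (default: the full clip).
#' @return list of batches, each with `frames`, `boxes`, `behavior_id`,
#'   `motion_attr`, `video_id`, `timestamp`.
#' @export
make_clip_batches <- function(toy, clip_len = NULL) {
  nT <- dim(toy$frames)[1]
  if (is.null(clip_len)) clip_len <- nT
  stop_if(clip_len > nT, "clip_len exceeds the clip length")
  ann <- toy$annotations
  lapply(unique(ann$timestamp), function(ts) {
    rows <- ann[ann$timestamp == ts, , drop = FALSE]
    kf <- round(ts * toy$spec$fps) + 1
    start <- clamp(kf - clip_len %/% 2, 1, nT - clip_len + 1)
    list(frames = toy$frames[start:(start + clip_len - 1), , , drop = FALSE],
         boxes = as.matrix(rows[, c("x1", "y1", "x2", "y2")]),
         behavior_id = rows$behavior_id,
         motion_attr = rows$motion_attr,
         video_id = rows$video_id[1], timestamp = ts,
         individual_id = rows$individual_id)
  })
}

# one optimisation step; returns decision row + new params/state
mtl_step <- function(model, params, batch, strategy, state, lr, weight_decay,
                     step_index) {
  out <- model$fb(params, batch)
  stop_if(!is.finite(out$l_act) || !is.finite(out$l_mov),
          "non-finite loss at step %d: training diverged (l_act=%g, l_mov=%g)",
          step_index, out$l_act, out$l_mov)
  reg <- model$registry
  ctx <- list(g_act = flatten_named(out$g_act, reg$shared),
              g_mov = flatten_named(out$g_mov, reg$shared),
              l_act = out$l_act, l_mov = out$l_mov, step = step_index)
  dec <- strategy$step(ctx, state)
  shared_g <- unflatten_named(dec$shared, params[reg$shared], reg$shared)
  for (nm in reg$shared)
    params[[nm]] <- params[[nm]] - lr * (shared_g[[nm]] + weight_decay * params[[nm]])
  for (nm in reg$act_head)
    params[[nm]] <- params[[nm]] -
      lr * (dec$act_scale * out$g_act[[nm]] + weight_decay * params[[nm]])
  for (nm in reg$mov_head)
    params[[nm]] <- params[[nm]] -
      lr * (dec$mov_scale * out$g_mov[[nm]] + weight_decay * params[[nm]])
  lam_eff <- if (is.na(dec$lambda)) 1 else dec$lambda
  decision <- data.frame(step = step_index, rho = dec$rho, lambda = dec$lambda,
                         conflicted = dec$conflicted,
                         l_act = out$l_act, l_mov = out$l_mov,
                         l_total = combine_losses(out$l_act, out$l_mov, lam_eff))
  list(params = params, state = dec$state, decision = decision)
}

#' One LGH optimisation step
#'
#' Computes both task losses and gradients on `batch`, derives the gradient
#' cosine `rho` over the shared parameters only, sets the auxiliary weight by
#' the LGH rule and applies one SGD update: shared parameters move along
#' `g_act + lambda * g_mov`, the behavior head receives only the behavior
#' gradient, and the motion head receives `lambda` times the motion gradient.
#'
#' @param model a model (see [build_conflict_mlp()], [build_toy_model()]).
#' @param batch a training batch for the model kind.
#' @param config an [lgh_config()].
#' @param lr,weight_decay SGD settings.
#' @return list with the updated `model`, the one-row `decision` data frame
#'   (step, rho, lambda, conflicted, losses) and the raw per-task `grads`.
#' @export
lgh_step <- function(model, batch, config = lgh_config(), lr = 0.2,
                     weight_decay = 1e-5) {
  strategy <- strategy_lgh(config)
  out <- model$fb(model$params, batch)
  st <- mtl_step(model, model$params, batch, strategy, strategy$init(),
                 lr, weight_decay, 1L)
  model$params <- st$params
  list(model = model, decision = st$decision,
       grads = list(g_act = out$g_act, g_mov = out$g_mov))
}

#' Train a model under a weighting strategy
#'
#' Plain SGD (default learning rate 0.2, weight decay 1e-5) over either a
#' tabular conflict dataset (shuffled mini-batches) or a list of clip batches
#' (one step per clip). Each step logs a weight decision
#' (step, rho, lambda, conflicted, losses); each epoch logs mean losses.
#' Deterministic given `seed`. Non-finite losses abort with a diagnostic.
#'
#' @param model a model from [build_conflict_mlp()] or [build_toy_model()].
#' @param data either the output of [gen_conflict_dataset()] or a list of
#'   clip batches from [make_clip_batches()].
#' @param strategy a weighting strategy (see [make_strategy()]).
#' @param epochs number of passes over the data.
#' @param seed shuffling seed.
#' @param lr,weight_decay SGD settings.
#' @param batch_size mini-batch size for tabular data.
#' @return object of class `mtl_fit`: the trained `model`, per-epoch
#'   `history` (epoch, l_act, l_mov, l_total) and the per-step `decisions`
#'   log.
#' @export
train_toy <- function(model, data, strategy = strategy_lgh(), epochs = 5,
                      seed = 1, lr = 0.2, weight_decay = 1e-5,
                      batch_size = 64) {
  stopifnot(inherits(model, "mtl_model"), inherits(strategy, "mtl_strategy"))
  tabular <- !is.null(data$x)
  n_obs <- if (tabular) nrow(data$x) else length(data)
  stop_if(n_obs < 1, "no training data")
  params <- model$params
  state <- strategy$init()
  decisions <- vector("list", 0)
  history <- data.frame()
  step_index <- 0L
  perms <- with_seed(seed, lapply(seq_len(epochs), function(e) sample.int(n_obs)))
  for (epoch in seq_len(epochs)) {
    perm <- perms[[epoch]]
    batches <- if (tabular) {
      starts <- seq(1, n_obs, by = batch_size)
      lapply(starts, function(s) {
        idx <- perm[s:min(s + batch_size - 1, n_obs)]
        list(x = data$x[idx, , drop = FALSE],
             behavior_id = data$behavior_id[idx],
             motion_attr = data$motion_attr[idx])
      })
    } else data[perm]
    ep <- matrix(NA_real_, length(batches), 3)
    for (k in seq_along(batches)) {
      step_index <- step_index + 1L
      st <- mtl_step(model, params, batches[[k]], strategy, state, lr,
                     weight_decay, step_index)
      params <- st$params; state <- st$state
      decisions[[step_index]] <- st$decision
      ep[k, ] <- c(st$decision$l_act, st$decision$l_mov, st$decision$l_total)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         l_act = mean(ep[, 1]),
                                         l_mov = mean(ep[, 2]),
                                         l_total = mean(ep[, 3])))
  }
  model$params <- params
  structure(list(model = model, strategy = strategy$name,
                 history = history,
                 decisions = do.call(rbind, decisions),
                 settings = list(epochs = epochs, seed = seed, lr = lr,
                                 weight_decay = weight_decay,
                                 batch_size = batch_size)),
            class = "mtl_fit")
}

#' @export
print.mtl_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mtl_fit> strategy=%s, %d epochs, %d steps\n", x$strategy,
              nrow(h), nrow(x$decisions)))
  cat(sprintf("final losses: behavior %.4f, motion %.4f, total %.4f\n",
              h$l_act[nrow(h)], h$l_mov[nrow(h)], h$l_total[nrow(h)]))
  invisible(x)
}

#' @export
summary.mtl_fit <- function(object, ...) {
  d <- object$decisions
  out <- list(strategy = object$strategy,
              epochs = nrow(object$history),
              final = object$history[nrow(object$history), ],
              conflict_fraction = mean(d$conflicted),
              rho_range = range(d$rho),
              mean_lambda = mean(d$lambda))
  class(out) <- "summary.mtl_fit"
  out
}

#' @export
print.summary.mtl_fit <- function(x, ...) {
  cat(sprintf("Strategy %s over %d epochs\n", x$strategy, x$epochs))
  cat(sprintf("final behavior loss %.4f, motion loss %.4f\n",
              x$final$l_act, x$final$l_mov))
  cat(sprintf("conflicted steps: %.1f%%; rho in [%.3f, %.3f]; mean lambda %.4f\n",
              100 * x$conflict_fraction, x$rho_range[1], x$rho_range[2],
              x$mean_lambda))
  invisible(x)
}

#' @export
plot.mtl_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$l_total, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$l_act, h$l_mov, h$l_total)), ...)
  graphics::lines(h$epoch, h$l_act, lty = 2)
  graphics::lines(h$epoch, h$l_mov, lty = 3)
  graphics::legend("topright", legend = c("total", "behavior", "motion"),
                   lty = 1:3, bty = "n")
  invisible(x)
}

#' @export
predict.mtl_fit <- function(object, newdata, ...) {
  m <- object$model
  if (m$kind == "conflict_mlp") {
    x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
    m$predict(m$params, x)
  } else {
    if (!is.null(newdata$frames)) newdata <- list(newdata)
    lapply(newdata, function(b) m$predict(m$params, b))
  }
}

#' Score clip batches into a prediction table
#'
#' Runs the model over clip batches in the classification regime
#' (ground-truth boxes, optionally jittered into proposals) and emits one
#' scored row per box and behavior class, suitable for [evaluate_detections()]
#' or [write_predictions()].
#'
#' @param fit an `mtl_fit` (or a bare `mtl_model`).
#' @param clips list of clip batches from [make_clip_batches()].
#' @param jitter_sd normalized box jitter (0 = classification regime).
#' @param top_only keep only the highest-scoring class per box (default
#'   FALSE: one row per class).
#' @param seed jitter seed.
#' @return prediction data frame (see [read_predictions()] for columns).
#' @export
predict_detections <- function(fit, clips, jitter_sd = 0, top_only = FALSE,
                               seed = 1) {
  model <- if (inherits(fit, "mtl_fit")) fit$model else fit
  rows <- with_seed(seed, lapply(clips, function(b) {
    boxes <- b$boxes
    if (jitter_sd > 0) {
      boxes <- boxes + matrix(stats::rnorm(length(boxes), 0, jitter_sd),
                              nrow(boxes))
      boxes <- clamp(boxes, 0, 1)
      boxes[, 3] <- pmax(boxes[, 3], boxes[, 1] + 1e-3)
      boxes[, 4] <- pmax(boxes[, 4], boxes[, 2] + 1e-3)
    }
    pr <- model$predict(model$params, list(frames = b$frames, boxes = boxes))
    do.call(rbind, lapply(seq_len(nrow(boxes)), function(i) {
      cls <- if (top_only) which.max(pr$behavior[i, ]) else seq_len(6)
      data.frame(video_id = b$video_id, timestamp = b$timestamp,
                 x1 = boxes[i, 1], y1 = boxes[i, 2],
                 x2 = boxes[i, 3], y2 = boxes[i, 4],
                 behavior_id = as.integer(cls),
                 confidence = pr$behavior[i, cls],
                 motion_p0 = pr$motion[i, 1], motion_p1 = pr$motion[i, 2])
    }))
  }))
  do.call(rbind, rows)
}
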