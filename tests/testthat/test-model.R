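# Model harness: pathway sampling, ROI pooling, losses, the dual-head toy
# model, and the multi-task training loop.

test_that("pathway sampling follows the stated strides", {
  frames <- array(runif(32 * 6 * 6), c(32, 6, 6))
  sp <- sample_pathways(frames)
  expect_equal(dim(sp$slow)[1], 4)
  expect_equal(dim(sp$fast)[1], 16)
  expect_true(all(sp$indices$slow %in% sp$indices$fast))
  sp8 <- sample_pathways(array(runif(8 * 4 * 4), c(8, 4, 4)))
  expect_equal(dim(sp8$slow)[1], 1)
  expect_equal(dim(sp8$fast)[1], 4)
  expect_error(sample_pathways(array(0, c(4, 4, 4)), slow_stride = 8),
               "at least")
})

test_that("roi_pool pools constants to constants and keeps channel length", {
  vol <- array(2.5, c(5, 3, 6, 6))
  expect_equal(roi_pool(vol, c(0.1, 0.2, 0.7, 0.9)), rep(2.5, 5))
  big <- array(runif(2304 * 1 * 4 * 4), c(2304, 1, 4, 4))
  expect_equal(length(roi_pool(big, c(0, 0, 1, 1))), 2304)
  expect_error(roi_pool(vol, c(0.4, 0.2, 0.4, 0.9)), "degenerate")
  expect_error(roi_pool(vol, c(-0.1, 0.2, 0.5, 0.9)), "box")
})

test_that("roi_pool matches the brute-force bilinear oracle", {
  set.seed(23)
  for (i in 1:100) {
    vol <- array(rnorm(4 * 2 * 6 * 6), c(4, 2, 6, 6))
    b <- random_box()
    expect_equal(roi_pool(vol, b), roi_pool_oracle(vol, b), tolerance = 1e-6)
  }
})

test_that("roi_pool is channel-equivariant and temporal-order invariant", {
  set.seed(3)
  vol <- array(rnorm(5 * 4 * 6 * 6), c(5, 4, 6, 6))
  b <- c(0.1, 0.1, 0.8, 0.9)
  perm <- sample(5)
  expect_equal(roi_pool(vol[perm, , , ], b), roi_pool(vol, b)[perm])
  expect_equal(roi_pool(vol[, c(3, 1, 4, 2), , ], b), roi_pool(vol, b))
})

test_that("behavior loss is the multi-label BCE with probability clamping", {
  y <- one_hot(c(2, 5))
  expect_lt(behavior_loss(y, y), 1e-5)                     # perfect prediction
  p <- matrix(0.5, 1, 6)
  expect_equal(behavior_loss(p, one_hot(3)), 6 * log(2), tolerance = 1e-12)
  # duplicating the batch leaves the per-sample average unchanged
  set.seed(4)
  p <- matrix(runif(18, 0.05, 0.95), 3, 6)
  yy <- one_hot(c(1, 4, 6))
  expect_equal(behavior_loss(rbind(p, p), rbind(yy, yy)),
               behavior_loss(p, yy), tolerance = 1e-12)
  expect_gt(behavior_loss(p, yy), 0)
  expect_error(behavior_loss(p, yy[1:2, ]), "identical shape")
})

test_that("motion loss is softmax cross-entropy", {
  expect_equal(motion_loss(matrix(0, 3, 2), c(0, 1, 0)), log(2),
               tolerance = 1e-12)
  strong <- matrix(c(20, -20, -20, 20), 2, 2, byrow = TRUE)
  expect_lt(motion_loss(strong, c(0, 1)), 1e-8)
  # independent log-sum-exp oracle
  set.seed(6)
  for (i in 1:50) {
    lg <- matrix(rnorm(8, sd = 4), 4, 2)
    lab <- sample(0:1, 4, replace = TRUE)
    oracle <- mean(vapply(1:4, function(j)
      log(sum(exp(lg[j, ]))) - lg[j, lab[j] + 1], numeric(1)))
    expect_equal(motion_loss(lg, lab), oracle, tolerance = 1e-9)
  }
  expect_error(motion_loss(matrix(0, 2, 3), c(0, 1)), "N x 2")
})

test_that("the toy model honors its output and parameter contracts", {
  cfg <- toy_model_config(clip_len = 16, height = 12, width = 12, seed = 2)
  model <- build_toy_model(cfg)
  D <- cfg$D
  expect_equal(cfg$c_slow / cfg$c_fast, cfg$channel_ratio)
  expect_equal(length(model$params$Wa) + length(model$params$ba), D * 6 + 6)
  expect_equal(length(model$params$Wm1) + length(model$params$bm1) +
                 length(model$params$Wm2) + length(model$params$bm2),
               D * D + D + D * 2 + 2)
  reg <- param_registry(model)
  expect_setequal(c(reg$shared, reg$act_head, reg$mov_head),
                  names(model$params))
  expect_equal(length(intersect(reg$shared, c(reg$act_head, reg$mov_head))), 0)
  toy <- gen_toy_clips(clip_spec(frame_count = 16, height = 12, width = 12,
                                 n_individuals = 2, seed = 5))
  batch <- make_clip_batches(toy)[[1]]
  pr <- model$predict(model$params, batch)
  expect_equal(dim(pr$behavior), c(2, 6))
  expect_true(all(pr$behavior >= 0 & pr$behavior <= 1))
  expect_equal(rowSums(pr$motion), c(1, 1), tolerance = 1e-12)
})

test_that("hand-written gradients match finite differences", {
  # tabular model
  m <- build_conflict_mlp(5, hidden = 6, seed = 2)
  set.seed(9)
  m$params$Wa[] <- rnorm(length(m$params$Wa), sd = 0.3)
  m$params$Wm[] <- rnorm(length(m$params$Wm), sd = 0.3)
  batch <- random_tab_batch(n = 15, d = 5, seed = 3)
  check_grads <- function(model, batch, n_coords = 3, tol = 1e-6) {
    out <- model$fb(model$params, batch)
    for (nm in names(model$params)) {
      idx <- sample(length(model$params[[nm]]),
                    min(n_coords, length(model$params[[nm]])))
      for (i in idx) for (task in c("l_act", "l_mov")) {
        eps <- 1e-6
        p1 <- model$params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] - eps
        fd <- (model$fb(p1, batch)[[task]] - model$fb(p2, batch)[[task]]) /
          (2 * eps)
        g <- if (task == "l_act") out$g_act[[nm]][i] else out$g_mov[[nm]][i]
        expect_equal(g, fd, tolerance = tol)
      }
    }
  }
  check_grads(m, batch)
  # clip model (nonzero heads so all paths carry gradient)
  cfg <- toy_model_config(clip_len = 16, height = 10, width = 10, seed = 4)
  tm <- build_toy_model(cfg)
  set.seed(10)
  for (nm in c("Wa", "Wm1", "Wm2"))
    tm$params[[nm]][] <- rnorm(length(tm$params[[nm]]), sd = 0.2)
  toy <- gen_toy_clips(clip_spec(frame_count = 16, height = 10, width = 10,
                                 n_individuals = 2, seed = 6))
  # looser tolerance: central differences straddle ReLU / max-pool kinks
  check_grads(tm, make_clip_batches(toy)[[1]], n_coords = 2, tol = 5e-4)
})

test_that("an LGH step combines gradients as g_act + lambda * g_mov", {
  m <- build_conflict_mlp(6, hidden = 5, seed = 7)
  set.seed(11)
  m$params$Wa[] <- rnorm(length(m$params$Wa), sd = 0.4)
  m$params$Wm[] <- rnorm(length(m$params$Wm), sd = 0.4)
  batch <- random_tab_batch(n = 20, d = 6, seed = 8)
  lr <- 0.05; wd <- 0
  before <- m$params
  st <- lgh_step(m, batch, lgh_config(0.3, 0.2), lr = lr, weight_decay = wd)
  lam <- st$decision$lambda
  # two-pass oracle: explicit per-task gradients drive the expected update
  for (nm in c("W1", "b1")) {
    expected <- before[[nm]] -
      lr * (st$grads$g_act[[nm]] + lam * st$grads$g_mov[[nm]])
    expect_equal(st$model$params[[nm]], expected, tolerance = 1e-6)
  }
  # behavior head moves only along the behavior gradient,
  # motion head along lambda times the motion gradient
  expect_equal(st$model$params$Wa, before$Wa - lr * st$grads$g_act$Wa,
               tolerance = 1e-12)
  expect_equal(st$model$params$Wm, before$Wm - lr * lam * st$grads$g_mov$Wm,
               tolerance = 1e-12)
})

test_that("identical objectives cannot conflict at shared parameters", {
  # duplicate-task batch: motion labels copy the indicator of one behavior
  # class, heads initialized identically (zero), so the first shared
  # gradients vanish and rho = 0 with lambda = lambda_base
  m <- build_conflict_mlp(6, hidden = 5, seed = 1)
  batch <- random_tab_batch(n = 20, d = 6, seed = 2)
  batch$motion_attr <- as.integer(batch$behavior_id == 3)
  st <- lgh_step(m, batch, lgh_config(0.2, 0.1))
  expect_gte(st$decision$rho, 0)
  expect_equal(st$decision$lambda, 0.1)
  # and it stays non-conflicting once heads have learned a step
  st2 <- lgh_step(st$model, batch, lgh_config(0.2, 0.1))
  expect_gte(st2$decision$rho, 0)
  expect_equal(st2$decision$lambda, 0.1)
})

test_that("analytically opposed task gradients are flagged as conflict", {
  # two-parameter linear fixture: losses l_act = w . a, l_mov = w . (-a),
  # so g_act = a, g_mov = -a exactly and rho = -1
  a <- c(0.6, -0.8)
  fake <- structure(list(
    params = list(w = c(0.1, 0.2), ha = 0, hm = 0),
    registry = list(shared = "w", act_head = "ha", mov_head = "hm"),
    fb = function(params, batch) {
      list(l_act = sum(params$w * a) + 2,
           l_mov = -sum(params$w * a) + 2,
           g_act = list(w = a, ha = 0, hm = 0),
           g_mov = list(w = -a, ha = 0, hm = 0))
    }), class = "mtl_model")
  st <- lgh_step(fake, list(), lgh_config(alpha = 0.5, lambda_base = 0.2))
  expect_equal(st$decision$rho, -1)
  expect_true(st$decision$conflicted)
  expect_equal(st$decision$lambda, 0.2 * (1 - 0.5))
  expect_lt(st$decision$lambda, 0.2)
})

test_that("training is deterministic and logs every step", {
  ds <- gen_conflict_dataset(conflict_spec(n_samples = 50, seed = 3))
  f1 <- train_toy(build_conflict_mlp(12, seed = 1), ds, strategy_lgh(),
                  epochs = 2, seed = 5, batch_size = 10)
  f2 <- train_toy(build_conflict_mlp(12, seed = 1), ds, strategy_lgh(),
                  epochs = 2, seed = 5, batch_size = 10)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$decisions, f2$decisions)
  expect_equal(nrow(f1$decisions), 2 * ceiling(50 / 10))
  # one epoch on 10 samples still logs at least one decision
  small <- gen_conflict_dataset(conflict_spec(n_samples = 10, seed = 4))
  fs <- train_toy(build_conflict_mlp(12, seed = 1), small, strategy_lgh(),
                  epochs = 1, seed = 1)
  expect_gte(nrow(fs$decisions), 1)
  expect_s3_class(fs, "mtl_fit")
  expect_output(print(fs), "strategy=lgh")
  expect_output(print(summary(fs)), "conflicted steps")
})

test_that("aligned tasks keep lambda at its base value throughout", {
  exp_out <- aligned_experiment(seed = 2, n_samples = 400, steps = 10)
  expect_true(exp_out$lambda_always_base)
  expect_equal(mean(exp_out$decisions$lambda), lgh_config()$lambda_base)
  expect_lt(exp_out$conflict_fraction, 0.2)
  expect_true(exp_out$rolling_positive)
})

test_that("ablating the motion head reproduces single-task training", {
  ds <- gen_conflict_dataset(conflict_spec(n_samples = 60, seed = 6))
  fit <- train_toy(build_conflict_mlp(12, seed = 2), ds, strategy_fixed(0),
                   epochs = 2, seed = 3, weight_decay = 0, batch_size = 20)
  # the lambda path never executes: motion head stays at its (zero) init
  expect_true(all(fit$decisions$lambda == 0))
  expect_equal(fit$model$params$Wm, matrix(0, 16, 2))
  # shared update used only the behavior gradient: replay single-task SGD
  replay <- build_conflict_mlp(12, seed = 2)$params
  model <- build_conflict_mlp(12, seed = 2)
  perms <- lghdetect:::with_seed(3, lapply(1:2, function(e) sample.int(60)))
  for (e in 1:2) for (s in seq(1, 60, by = 20)) {
    idx <- perms[[e]][s:(s + 19)]
    b <- list(x = ds$x[idx, ], behavior_id = ds$behavior_id[idx],
              motion_attr = ds$motion_attr[idx])
    out <- model$fb(replay, b)
    for (nm in c("W1", "b1", "Wa", "ba"))
      replay[[nm]] <- replay[[nm]] - 0.2 * out$g_act[[nm]]
  }
  expect_equal(fit$model$params$W1, replay$W1, tolerance = 1e-10)
  expect_equal(fit$model$params$Wa, replay$Wa, tolerance = 1e-10)
})

test_that("training aborts with a diagnostic on divergence", {
  ds <- gen_conflict_dataset(conflict_spec(n_samples = 40, seed = 8))
  expect_error(train_toy(build_conflict_mlp(12, seed = 1), ds,
                         strategy_equal(), epochs = 10, seed = 1, lr = 1e308),
               "diverged")
})

test_that("clip-model training runs end to end with LGH", {
  toy <- gen_toy_clips(clip_spec(frame_count = 16, height = 10, width = 10,
                                 n_individuals = 2, seed = 9))
  clips <- make_clip_batches(toy, clip_len = 16)
  cfg <- toy_model_config(clip_len = 16, height = 10, width = 10, seed = 3)
  fit <- train_toy(build_toy_model(cfg), clips, strategy_lgh(), epochs = 2,
                   seed = 4, lr = 0.1)
  expect_equal(nrow(fit$decisions), 2 * length(clips))
  expect_true(all(is.finite(fit$history$l_total)))
  dets <- predict_detections(fit, clips)
  expect_equal(nrow(dets), sum(vapply(clips, function(b) nrow(b$boxes) * 6,
                                      numeric(1))))
  expect_true(all(dets$confidence >= 0 & dets$confidence <= 1))
})
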