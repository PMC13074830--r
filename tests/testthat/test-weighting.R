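# Weighting strategies: the LGH rule, gradient cosine, and the comparison
# policies (fixed/equal, uncertainty, GradNorm, PCGrad, rescaled PCGrad).

test_that("grad_cosine handles canonical geometries", {
  g <- c(0.3, -1.2, 4)
  expect_equal(grad_cosine(g, g), 1)
  expect_equal(grad_cosine(g, -g), -1)
  expect_equal(grad_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(grad_cosine(numeric(3), g), 0)     # vanishing gradient
  expect_error(grad_cosine(1:3, 1:4), "length mismatch")
  expect_error(grad_cosine(c(1, NA), c(1, 2)), "non-finite")
})

test_that("grad_cosine matches an independent dot/norm oracle", {
  set.seed(5)
  for (i in 1:100) {
    a <- rnorm(100); b <- rnorm(100)
    oracle <- sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)) + 1e-12)
    expect_equal(grad_cosine(a, b), oracle, tolerance = 1e-12)
  }
})

test_that("the LGH rule reproduces its worked values", {
  cfg <- lgh_config(alpha = 0.2, lambda_base = 0.10)
  expect_equal(lgh_weight(0.62, cfg), 0.10)           # no conflict: base weight
  expect_equal(lgh_weight(-0.55, cfg), 0.089)         # 0.10 * (1 - 0.2 * 0.55)
  # alpha = 0 reduces to fixed weighting for any conflict
  cfg0 <- lgh_config(alpha = 0, lambda_base = 0.10)
  for (rho in c(-1, -0.5, -1e-9)) expect_equal(lgh_weight(rho, cfg0), 0.10)
  # full conflict at alpha = 1 suppresses the auxiliary task entirely
  expect_equal(lgh_weight(-1, lgh_config(alpha = 1, lambda_base = 0.10)), 0)
  expect_error(lgh_weight(1.2, cfg), "rho")
  expect_error(lgh_config(alpha = 2), "alpha")
  expect_error(lgh_config(lambda_base = 0), "lambda_base")
})

test_that("lambda is bounded, continuous at zero and monotone in conflict", {
  cfg <- lgh_config(alpha = 0.7, lambda_base = 0.3)
  rhos <- seq(-1, 1, by = 0.01)
  lams <- lgh_weight(rhos, cfg)
  expect_true(all(lams >= cfg$lambda_base * (1 - cfg$alpha) - 1e-15))
  expect_true(all(lams <= cfg$lambda_base + 1e-15))
  # continuity at rho = 0
  expect_equal(lgh_weight(-1e-12, cfg), lgh_weight(0, cfg), tolerance = 1e-9)
  # non-increasing in |rho| on the conflicted branch
  neg <- lams[rhos < 0]
  expect_true(all(diff(neg) >= 0))   # rho increasing toward 0 => lambda rises
})

test_that("combine_losses is the exact weighted sum", {
  expect_equal(combine_losses(1.0, 0.5, 0.1), 1.05)
  expect_equal(combine_losses(0.8, 123, 0), 0.8)
  l <- 0.37
  expect_equal(combine_losses(l, l, 1), 2 * l)
  expect_error(combine_losses(1, 1, -0.1), "non-negative")
})

test_that("pcgrad projection removes exactly the conflicting component", {
  expect_equal(pcgrad_project(c(1, 0), c(-1, 1)), c(0.5, 0.5))
  expect_equal(pcgrad_project(c(1, 0), c(0, 1)), c(1, 0))   # orthogonal
  g <- c(2, -1, 0.5)
  expect_equal(pcgrad_project(g, -g), c(0, 0, 0))           # full conflict
  expect_equal(pcgrad_project(g, numeric(3)), g)            # zero reference
  set.seed(8)
  for (i in 1:100) {
    a <- rnorm(10); b <- rnorm(10)
    p <- pcgrad_project(a, b)
    expect_gte(sum(p * b), -1e-12)
    # oracle: direct formula
    oracle <- if (sum(a * b) < 0) a - sum(a * b) / sum(b * b) * b else a
    expect_equal(p, oracle, tolerance = 1e-12)
  }
})

test_that("rescaled pcgrad restores pre-projection norms", {
  strat <- strategy_ripcgrad()
  set.seed(13)
  for (i in 1:50) {
    ga <- rnorm(10); gm <- rnorm(10)
    out <- strat$step(list(g_act = ga, g_mov = gm, l_act = 1, l_mov = 1),
                      strat$init())
    # brute-force recomputation
    pa <- pcgrad_project(ga, gm); pm <- pcgrad_project(gm, ga)
    resc <- function(g, n0) if (sqrt(sum(g^2)) < 1e-12) g
                            else g * n0 / sqrt(sum(g^2))
    oracle <- resc(pa, sqrt(sum(ga^2))) + resc(pm, sqrt(sum(gm^2)))
    expect_equal(out$shared, oracle, tolerance = 1e-9)
  }
  # no conflict: identical to pcgrad and to the plain sum
  ga <- c(1, 2); gm <- c(2, 1)
  out <- strat$step(list(g_act = ga, g_mov = gm, l_act = 1, l_mov = 1),
                    strat$init())
  expect_equal(out$shared, ga + gm)
  pc <- strategy_pcgrad()$step(list(g_act = ga, g_mov = gm, l_act = 1,
                                    l_mov = 1), list())
  expect_equal(out$shared, pc$shared)
})

test_that("uncertainty weighting follows the log-variance form", {
  strat <- strategy_uncertainty(s_lr = 0.1)
  st <- strat$init()
  expect_equal(st$s_act, 0)
  # at s = 0 the combined gradient is the plain sum
  out <- strat$step(list(g_act = c(1, 0), g_mov = c(0, 1),
                         l_act = 0.7, l_mov = 0.4), st)
  expect_equal(out$shared, c(1, 1))
  # scalar gradient -exp(-s) l + 1/2 vanishes when exp(-s) l = 1/2:
  # at l = 0.5 and s = 0 the update leaves s unchanged
  out2 <- strat$step(list(g_act = 1, g_mov = 1, l_act = 0.5, l_mov = 0.5),
                     strat$init())
  expect_equal(out2$state$s_act, 0, tolerance = 1e-12)
  # a larger loss drives its scalar up over steps on a frozen model
  st <- strat$init()
  for (i in 1:20)
    st <- strat$step(list(g_act = 1, g_mov = 1, l_act = 2.0, l_mov = 0.1),
                     st)$state
  expect_gt(st$s_act, 0)
  expect_lt(st$s_mov, 0)
})

test_that("gradnorm keeps weights positive, normalized and symmetric", {
  strat <- strategy_gradnorm()
  st <- strat$init()
  # identical tasks: weights stay equal
  g <- rnorm(8)
  for (i in 1:10)
    st <- strat$step(list(g_act = g, g_mov = g, l_act = 1, l_mov = 1), st)$state
  expect_equal(st$w[1], st$w[2], tolerance = 1e-12)
  # asymmetric tasks: always positive, sum to 2
  st <- strat$init()
  set.seed(2)
  for (i in 1:30) {
    st <- strat$step(list(g_act = rnorm(8), g_mov = 0.1 * rnorm(8),
                          l_act = 1.5, l_mov = 0.3), st)$state
    expect_true(all(st$w > 0))
    expect_equal(sum(st$w), 2, tolerance = 1e-12)
  }
  expect_error(strat$step(list(g_act = 1, g_mov = 1, l_act = 0, l_mov = 1),
                          strat$init()), "positive initial losses")
})

test_that("gradnorm weight updates match a finite-difference oracle", {
  asym <- 1.5; w_lr <- 0.025
  strat <- strategy_gradnorm(asymmetry = asym, w_lr = w_lr)
  set.seed(31)
  for (i in 1:20) {
    ga <- rnorm(6); gm <- rnorm(6)
    la <- runif(1, 0.5, 2); lm <- runif(1, 0.5, 2)
    l0 <- c(runif(1, 0.5, 2), runif(1, 0.5, 2))
    st <- list(w = c(1, 1), l0 = l0)
    new_w_raw <- function(w) {
      # objective with targets held constant, as in the strategy
      norms <- c(sqrt(sum(ga^2)), sqrt(sum(gm^2)))
      obj <- function(wv) {
        gw <- wv * norms
        ratio <- c(la, lm) / l0
        r <- ratio / mean(ratio)
        target <- mean(w * norms) * r^asym   # target frozen at current w
        sum(abs(gw - target))
      }
      eps <- 1e-6
      grad <- vapply(1:2, function(k) {
        w1 <- w; w1[k] <- w1[k] + eps
        w2 <- w; w2[k] <- w2[k] - eps
        (obj(w1) - obj(w2)) / (2 * eps)
      }, numeric(1))
      w - w_lr * grad
    }
    expected <- pmax(new_w_raw(c(1, 1)), 1e-6)
    expected <- 2 * expected / sum(expected)
    out <- strat$step(list(g_act = ga, g_mov = gm, l_act = la, l_mov = lm), st)
    expect_equal(out$state$w, expected, tolerance = 1e-4)
  }
})

test_that("strategies are selectable by their config names", {
  for (nm in c("lgh", "equal", "fixed", "uncertainty", "gradnorm",
               "pcgrad", "ripcgrad"))
    expect_s3_class(make_strategy(nm), "mtl_strategy")
  expect_error(make_strategy("nashmtl"), "unknown strategy")
})

test_that("LGH keeps the combined gradient inside the task-gradient cone", {
  # contrast with pcgrad: LGH never re-directs either task gradient, it only
  # scales the auxiliary one, so shared = g_act + lambda g_mov exactly
  set.seed(17)
  strat <- strategy_lgh(lgh_config(0.2, 0.1))
  for (i in 1:25) {
    ga <- rnorm(12); gm <- rnorm(12)
    out <- strat$step(list(g_act = ga, g_mov = gm, l_act = 1, l_mov = 1),
                      strat$init())
    expect_equal(out$shared, ga + out$lambda * gm, tolerance = 1e-12)
    expect_true(out$lambda >= 0.1 * (1 - 0.2) - 1e-15 && out$lambda <= 0.1)
    expect_identical(out$conflicted, out$rho < 0)
  }
})
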