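# Multi-task weighting and gradient-combination strategies.
#
# All strategies operate on a pair of per-task gradients over a shared
# parameter registry plus the task-specific head gradients, and return the
# combined update together with a per-step weight decision
# (step, rho, lambda, conflicted). The primary task is behavior
# classification (act); the auxiliary task is motion-attribute prediction
# (mov).

#' Cosine similarity between two task gradients
#'
#' `rho = dot(g1, g2) / (|g1| |g2| + epsilon)`, clamped to [-1, 1]. When
#' either gradient norm is below `epsilon` the similarity is defined as 0:
#' a vanishing task gradient cannot witness a conflict.
#'
#' @param g1,g2 numeric vectors of equal length (flattened shared-parameter
#'   gradients).
#' @param epsilon denominator guard (default 1e-12).
#' @return scalar in [-1, 1].
#' @export
grad_cosine <- function(g1, g2, epsilon = 1e-12) {
  stop_if(length(g1) != length(g2), "gradient length mismatch: %d vs %d",
          length(g1), length(g2))
  stop_if(!all(is.finite(g1)) || !all(is.finite(g2)),
          "gradients contain non-finite entries")
  n1 <- sqrt(sum(g1^2)); n2 <- sqrt(sum(g2^2))
  if (n1 < epsilon || n2 < epsilon) return(0)
  clamp(sum(g1 * g2) / (n1 * n2 + epsilon), -1, 1)
}

#' LGH configuration
#'
#' @param alpha conflict reduction factor in [0, 1]. At 0 the rule reduces to
#'   fixed weighting; at 1 the auxiliary weight is maximally suppressed under
#'   full conflict. Default 0.2 (the value the sensitivity grid selects).
#' @param lambda_base base auxiliary weight, > 0. Default 0.10.
#' @param epsilon cosine denominator guard.
#' @return object of class `lgh_config`.
#' @export
lgh_config <- function(alpha = 0.2, lambda_base = 0.10, epsilon = 1e-12) {
  stop_if(!is.numeric(alpha) || alpha < 0 || alpha > 1, "alpha must lie in [0, 1]")
  stop_if(!is.numeric(lambda_base) || lambda_base <= 0, "lambda_base must be > 0")
  structure(list(alpha = alpha, lambda_base = lambda_base, epsilon = epsilon),
            class = "lgh_config")
}

#' LGH auxiliary-weight rule
#'
#' The conflict-aware piecewise rule: when the gradient cosine `rho` is
#' negative the auxiliary weight is `lambda_base * (1 - alpha * |rho|)`;
#' otherwise it stays at `lambda_base`. The weight is therefore always inside
#' `[lambda_base * (1 - alpha), lambda_base]`, continuous in `rho` at 0, and
#' non-increasing in |rho| on the conflicted branch.
#'
#' @param rho gradient cosine similarity in [-1, 1].
#' @param config an [lgh_config()].
#' @return effective auxiliary weight lambda.
#' @export
lgh_weight <- function(rho, config = lgh_config()) {
  stopifnot(inherits(config, "lgh_config"))
  stop_if(!is.numeric(rho) || any(!is.finite(rho)) || any(abs(rho) > 1),
          "rho must lie in [-1, 1]")
  ifelse(rho < 0, config$lambda_base * (1 - config$alpha * abs(rho)),
         config$lambda_base)
}

#' Weighted total loss
#'
#' `l_total = l_act + lam * l_mov`.
#'
#' @param l_act primary (behavior) loss.
#' @param l_mov auxiliary (motion) loss.
#' @param lam auxiliary weight, >= 0.
#' @return total loss.
#' @export
combine_losses <- function(l_act, l_mov, lam) {
  stop_if(!is.finite(l_act) || !is.finite(l_mov), "losses must be finite")
  stop_if(!is.numeric(lam) || lam < 0, "lam must be non-negative")
  l_act + lam * l_mov
}

#' PCGrad projection
#'
#' When `g_i` conflicts with `g_j` (negative dot product), removes the
#' component of `g_i` along `g_j`:
#' `g_i - (dot(g_i, g_j) / |g_j|^2) g_j`. Non-conflicting gradients pass
#' through unchanged, as does any `g_i` when `g_j` is (numerically) zero.
#'
#' @param g_i gradient to project.
#' @param g_j reference gradient.
#' @param epsilon norm guard.
#' @return projected `g_i`, with non-negative dot product with `g_j`.
#' @export
pcgrad_project <- function(g_i, g_j, epsilon = 1e-12) {
  stop_if(length(g_i) != length(g_j), "gradient length mismatch")
  d <- sum(g_i * g_j)
  nj2 <- sum(g_j^2)
  if (d >= 0 || nj2 < epsilon^2) return(g_i)
  g_i - (d / nj2) * g_j
}

# ---------------------------------------------------------------------------
# Strategy objects. A strategy is a list with fields:
#   name      : identifier
#   init      : function() -> state
#   step      : function(ctx, state) -> list(shared, act_scale, mov_scale,
#                rho, lambda, conflicted, state, extra_updates)
# where ctx carries g_act / g_mov (flat shared gradients), l_act / l_mov and
# the step index. `shared` is the combined flat shared-parameter gradient;
# act_scale / mov_scale multiply the task-specific head gradients.
# ---------------------------------------------------------------------------

new_strategy <- function(name, init, step) {
  structure(list(name = name, init = init, step = step),
            class = "mtl_strategy")
}

#' @export
print.mtl_strategy <- function(x, ...) {
  cat(sprintf("<mtl_strategy: %s>\n", x$name)); invisible(x)
}

#' LGH weighting strategy
#'
#' At each step computes the cosine `rho` between the two tasks'
#' shared-parameter gradients, sets the auxiliary weight by [lgh_weight()],
#' and combines `g_act + lambda * g_mov` on the shared parameters. Task
#' gradients are never re-directed individually: only the scalar mixing
#' weight changes, so the combined update stays in the cone spanned by the
#' two task gradients. Head parameters receive their own task gradient
#' (behavior head unscaled, motion head scaled by lambda).
#'
#' @param config an [lgh_config()].
#' @return strategy object.
#' @export
strategy_lgh <- function(config = lgh_config()) {
  stopifnot(inherits(config, "lgh_config"))
  new_strategy("lgh",
    init = function() list(),
    step = function(ctx, state) {
      rho <- grad_cosine(ctx$g_act, ctx$g_mov, config$epsilon)
      lam <- lgh_weight(rho, config)
      list(shared = ctx$g_act + lam * ctx$g_mov,
           act_scale = 1, mov_scale = lam,
           rho = rho, lambda = lam, conflicted = rho < 0, state = state)
    })
}

#' Fixed and equal weighting strategies
#'
#' Constant auxiliary weight regardless of gradients. `strategy_equal()` is
#' the unweighted sum (lambda = 1); `strategy_fixed(0.5)` is the static
#' half-weight variant.
#'
#' @param lam constant auxiliary weight, >= 0.
#' @return strategy object.
#' @export
strategy_fixed <- function(lam) {
  stop_if(!is.numeric(lam) || lam < 0, "lam must be non-negative")
  new_strategy(if (lam == 1) "equal" else sprintf("fixed(%g)", lam),
    init = function() list(),
    step = function(ctx, state) {
      rho <- grad_cosine(ctx$g_act, ctx$g_mov)
      list(shared = ctx$g_act + lam * ctx$g_mov,
           act_scale = 1, mov_scale = lam,
           rho = rho, lambda = lam, conflicted = rho < 0, state = state)
    })
}

#' @rdname strategy_fixed
#' @export
strategy_equal <- function() strategy_fixed(1)

#' Homoscedastic uncertainty weighting
#'
#' Learns per-task log-variance scalars `s_act`, `s_mov`; the total loss is
#' `exp(-s_act) l_act + s_act / 2 + exp(-s_mov) l_mov + s_mov / 2` (stable
#' log-variance form), so each task gradient is scaled by `exp(-s_task)` and
#' the scalars follow their own gradient
#' `d total / d s = -exp(-s) l + 1/2`, updated with `s_lr`.
#'
#' @param s_lr learning rate for the uncertainty scalars.
#' @return strategy object.
#' @export
strategy_uncertainty <- function(s_lr = 0.05) {
  new_strategy("uncertainty",
    init = function() list(s_act = 0, s_mov = 0),
    step = function(ctx, state) {
      wa <- exp(-state$s_act); wm <- exp(-state$s_mov)
      rho <- grad_cosine(ctx$g_act, ctx$g_mov)
      state$s_act <- state$s_act - s_lr * (-wa * ctx$l_act + 0.5)
      state$s_mov <- state$s_mov - s_lr * (-wm * ctx$l_mov + 0.5)
      list(shared = wa * ctx$g_act + wm * ctx$g_mov,
           act_scale = wa, mov_scale = wm,
           rho = rho, lambda = wm, conflicted = rho < 0, state = state)
    })
}

#' GradNorm adaptive loss balancing
#'
#' Maintains positive task weights (renormalized to sum to the task count)
#' and nudges each task's weighted shared-gradient norm toward the mean norm
#' scaled by the relative inverse training rate raised to the `asymmetry`
#' exponent. Initial losses are recorded at the first step.
#'
#' @param asymmetry restoring-force exponent (default 1.5).
#' @param w_lr learning rate on the task weights.
#' @return strategy object.
#' @export
strategy_gradnorm <- function(asymmetry = 1.5, w_lr = 0.025) {
  new_strategy("gradnorm",
    init = function() list(w = c(1, 1), l0 = NULL),
    step = function(ctx, state) {
      if (is.null(state$l0)) {
        stop_if(ctx$l_act <= 0 || ctx$l_mov <= 0,
                "GradNorm requires positive initial losses")
        state$l0 <- c(ctx$l_act, ctx$l_mov)
      }
      w <- state$w
      norms <- c(sqrt(sum(ctx$g_act^2)), sqrt(sum(ctx$g_mov^2)))
      gw <- w * norms                     # weighted gradient norms G_i
      ratio <- c(ctx$l_act, ctx$l_mov) / state$l0
      r <- ratio / mean(ratio)            # relative inverse training rate
      target <- mean(gw) * r^asymmetry
      # d |G_i - target_i| / d w_i = sign(G_i - target_i) * |g_i|
      w <- w - w_lr * sign(gw - target) * norms
      w <- pmax(w, 1e-6)
      w <- 2 * w / sum(w)                 # renormalize to task count
      state$w <- w
      rho <- grad_cosine(ctx$g_act, ctx$g_mov)
      list(shared = w[1] * ctx$g_act + w[2] * ctx$g_mov,
           act_scale = w[1], mov_scale = w[2],
           rho = rho, lambda = w[2], conflicted = rho < 0, state = state)
    })
}

#' PCGrad gradient surgery
#'
#' Projects each task's shared gradient away from the other task's gradient
#' when they conflict, then sums the projected gradients. Head gradients are
#' untouched.
#'
#' @return strategy object.
#' @export
strategy_pcgrad <- function() {
  new_strategy("pcgrad",
    init = function() list(),
    step = function(ctx, state) {
      rho <- grad_cosine(ctx$g_act, ctx$g_mov)
      ga <- pcgrad_project(ctx$g_act, ctx$g_mov)
      gm <- pcgrad_project(ctx$g_mov, ctx$g_act)
      list(shared = ga + gm, act_scale = 1, mov_scale = 1,
           rho = rho, lambda = NA_real_, conflicted = rho < 0, state = state)
    })
}

#' Rescaled PCGrad (RI-PCGrad)
#'
#' As [strategy_pcgrad()], but each projected gradient is rescaled back to
#' its pre-projection norm before summation, controlling the relative
#' influence of each task after projection. With no conflict this reduces to
#' the plain equal sum. The rescaling rule is one reasonable reading of the
#' method's one-line description; see the methods vignette.
#'
#' @return strategy object.
#' @export
strategy_ripcgrad <- function() {
  rescale <- function(g, n0) {
    n <- sqrt(sum(g^2))
    if (n < 1e-12) g else g * (n0 / n)
  }
  new_strategy("ripcgrad",
    init = function() list(),
    step = function(ctx, state) {
      rho <- grad_cosine(ctx$g_act, ctx$g_mov)
      na <- sqrt(sum(ctx$g_act^2)); nm <- sqrt(sum(ctx$g_mov^2))
      ga <- rescale(pcgrad_project(ctx$g_act, ctx$g_mov), na)
      gm <- rescale(pcgrad_project(ctx$g_mov, ctx$g_act), nm)
      list(shared = ga + gm, act_scale = 1, mov_scale = 1,
           rho = rho, lambda = NA_real_, conflicted = rho < 0, state = state)
    })
}

#' Select a weighting strategy by name
#'
#' Names follow the config-file vocabulary:
#' `lgh`, `equal`, `fixed`, `uncertainty`, `gradnorm`, `pcgrad`, `ripcgrad`.
#'
#' @param name strategy name.
#' @param alpha,lambda_base LGH parameters (used by `lgh`).
#' @param lam constant weight for `fixed`.
#' @param ... further arguments passed to the specific constructor.
#' @return strategy object.
#' @export
make_strategy <- function(name, alpha = 0.2, lambda_base = 0.10, lam = 0.5, ...) {
  switch(name,
         lgh = strategy_lgh(lgh_config(alpha = alpha, lambda_base = lambda_base)),
         equal = strategy_equal(),
         fixed = strategy_fixed(lam),
         uncertainty = strategy_uncertainty(...),
         gradnorm = strategy_gradnorm(...),
         pcgrad = strategy_pcgrad(),
         ripcgrad = strategy_ripcgrad(),
         stop_if(TRUE, "unknown strategy '%s'", name))
}
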