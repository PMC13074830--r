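# Synthetic data generators.
#
# Two families: (a) conflicting two-task tabular datasets with a controllable
# angle between the task-optimal directions in the shared feature space, used
# to exercise the weighting strategies; (b) toy annotated clips whose moving
# Gaussian blobs emulate the annotation schema, class proportions and
# static/dynamic structure of the crane benchmark, used to exercise the
# detection harness end to end. All generators are pure functions of their
# spec (seed included).

#' Default behavior-conditional motion table
#'
#' The benchmark reports only the marginals (70.6\% static / 29.4\% dynamic)
#' and that both static and dynamic instances occur within each class. The
#' default joint makes walk and flight almost always dynamic, feeding and
#' social mixed, vigilance and maintenance mostly static, and then rescales
#' the non-locomotor dynamic propensities by a common factor so the implied
#' marginal hits the reported 29.4\% exactly under
#' \code{\link{CRANE_CLASS_PROBS}}.
#'
#' @param class_probs behavior marginals used for the calibration.
#' @param dynamic_marginal target P(dynamic), default `1 - CRANE_STATIC_PROP`.
#' @return 6x2 matrix, rows = behavior classes, columns = c("static",
#'   "dynamic"), each row summing to 1.
#' @export
default_motion_joint <- function(class_probs = CRANE_CLASS_PROBS,
                                 dynamic_marginal = 1 - CRANE_STATIC_PROP) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-9)
  raw <- c(feeding = 0.40, vigilance = 0.08, social = 0.50,
           maintenance = 0.06, walk = 0.95, flight = 0.97)
  locomotor <- c("walk", "flight")
  locked <- sum(class_probs[locomotor] * raw[locomotor])
  others <- setdiff(BEHAVIOR_CLASSES, locomotor)
  k <- (dynamic_marginal - locked) / sum(class_probs[others] * raw[others])
  stop_if(k <= 0 || any(raw[others] * k >= 1),
          "cannot calibrate motion joint to the requested marginal")
  dyn <- raw
  dyn[others] <- raw[others] * k
  m <- cbind(static = 1 - dyn[BEHAVIOR_CLASSES], dynamic = dyn[BEHAVIOR_CLASSES])
  rownames(m) <- BEHAVIOR_CLASSES
  m
}

#' Specification for a conflicting two-task dataset
#'
#' Describes a latent-feature population in which a primary 6-class behavior
#' signal and an auxiliary binary motion signal live along two directions
#' whose cosine equals `conflict_level`. At `conflict_level = 1` the tasks
#' read the same feature axis (fully cooperative); at negative values the
#' population-optimal linear predictors of the two tasks are misaligned, so
#' shared-representation gradients conflict during joint training.
#'
#' @param n_samples number of rows to draw.
#' @param latent_dim feature dimension (>= 2).
#' @param conflict_level cosine in [-1, 1] between the two task directions.
#' @param class_probs behavior marginals (default crane benchmark values).
#' @param motion_joint 6x2 behavior-conditional motion table (rows sum to 1).
#' @param noise_sd isotropic feature noise standard deviation.
#' @param behavior_scale,motion_scale signal amplitudes along the two task
#'   directions. The default makes the coarse static/dynamic cue four times
#'   stronger than one behavior-code step, mirroring monitoring video where
#'   gross locomotion dominates the subtle appearance differences between
#'   fine-grained behaviors; this is what lets a misaligned auxiliary task
#'   produce measurable gradient conflict on shared parameters.
#' @param seed integer seed.
#' @return object of class `conflict_spec`.
#' @export
conflict_spec <- function(n_samples = 2000, latent_dim = 12,
                          conflict_level = 0,
                          class_probs = CRANE_CLASS_PROBS,
                          motion_joint = default_motion_joint(class_probs),
                          noise_sd = 1.0, behavior_scale = 1.0,
                          motion_scale = 4.0, seed = 1) {
  stop_if(!is_count(n_samples) || n_samples < 1, "n_samples must be positive")
  stop_if(!is_count(latent_dim) || latent_dim < 2, "latent_dim must be >= 2")
  stop_if(!is.numeric(conflict_level) || abs(conflict_level) > 1,
          "conflict_level must lie in [-1, 1]")
  stop_if(length(class_probs) != length(BEHAVIOR_CLASSES) ||
            any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-9,
          "class_probs must be a 6-vector summing to 1")
  stop_if(!is.matrix(motion_joint) || nrow(motion_joint) != 6 ||
            ncol(motion_joint) != 2 || any(motion_joint < 0) ||
            any(abs(rowSums(motion_joint) - 1) > 1e-9),
          "motion_joint must be a 6x2 table with rows summing to 1")
  stop_if(noise_sd <= 0, "noise_sd must be positive")
  spec <- list(n_samples = as.integer(n_samples),
               latent_dim = as.integer(latent_dim),
               conflict_level = conflict_level,
               class_probs = as.numeric(class_probs),
               motion_joint = motion_joint, noise_sd = noise_sd,
               behavior_scale = behavior_scale, motion_scale = motion_scale,
               seed = as.integer(seed))
  # implied static marginal, reported for reference
  spec$static_marginal <- sum(spec$class_probs * motion_joint[, "static"])
  class(spec) <- "conflict_spec"
  spec
}

#' Generate a conflicting two-task dataset
#'
#' Draws behavior labels from `class_probs`, motion labels from the
#' behavior-conditional `motion_joint`, and features
#' `x = noise + t_y * u + s_m * v`, where `u` and `v` are unit directions
#' with `cos(u, v) = conflict_level`, `t_y` is a centered per-class code and
#' `s_m = +/- motion_scale`. Deterministic under the spec seed.
#'
#' @param spec a [conflict_spec()].
#' @return list with `x` (n x d matrix), `behavior_id` (integer 1..6),
#'   `motion_attr` (integer 0/1), and the `spec`.
#' @export
gen_conflict_dataset <- function(spec) {
  stopifnot(inherits(spec, "conflict_spec"))
  d <- spec$latent_dim
  u <- c(1, rep(0, d - 1))
  cl <- spec$conflict_level
  v <- cl * u
  v[2] <- sqrt(max(0, 1 - cl^2))
  codes <- (seq_along(BEHAVIOR_CLASSES) - mean(seq_along(BEHAVIOR_CLASSES))) *
    spec$behavior_scale
  with_seed(spec$seed, {
    y <- sample.int(6, spec$n_samples, replace = TRUE, prob = spec$class_probs)
    m <- stats::rbinom(spec$n_samples, 1, spec$motion_joint[y, "dynamic"])
    x <- matrix(stats::rnorm(spec$n_samples * d, sd = spec$noise_sd),
                spec$n_samples, d)
    x <- x + tcrossprod(codes[y], u) +
      tcrossprod((2 * m - 1) * spec$motion_scale, v)
    list(x = x, behavior_id = as.integer(y), motion_attr = as.integer(m),
         spec = spec)
  })
}

#' Specification for a toy annotated clip
#'
#' Describes a grayscale clip of `frame_count` frames populated by Gaussian
#' blobs, one per individual, moving according to a behavior-keyed kinematics
#' profile: feeding = stationary with a vertical head-dip bob; vigilance =
#' stationary tall blob; social = larger grouped blob with jitter;
#' maintenance = stationary jitter; walk = slow translation; flight = fast
#' large translation.
#'
#' @param frame_count frames per clip T (>= 8, default 32).
#' @param height,width spatial size in pixels.
#' @param n_individuals number of blobs.
#' @param behaviors optional integer vector (length `n_individuals`) of
#'   behavior ids; drawn from `class_probs` when NULL.
#' @param class_probs behavior marginals used when `behaviors` is NULL.
#' @param fps frames per second (used to convert frame indices to seconds).
#' @param keyframe_interval seconds between annotated keyframes (default 1).
#' @param motion_threshold fraction of frame width a centroid must travel
#'   over the clip to be labeled dynamic (default 0.10).
#' @param video_id video identifier written into annotations.
#' @param seed integer seed.
#' @return object of class `clip_spec`.
#' @export
clip_spec <- function(frame_count = 32, height = 16, width = 16,
                      n_individuals = 2, behaviors = NULL,
                      class_probs = CRANE_CLASS_PROBS, fps = 8,
                      keyframe_interval = 1, motion_threshold = 0.10,
                      video_id = "toy_video", seed = 1) {
  stop_if(!is_count(frame_count) || frame_count < 8, "frame_count must be >= 8")
  stop_if(height < 8 || width < 8, "frames must be at least 8x8 pixels")
  stop_if(!is_count(n_individuals) || n_individuals < 1,
          "n_individuals must be positive")
  # each blob needs roughly a 4x4-pixel cell to stay distinguishable
  stop_if(n_individuals > floor(height / 4) * floor(width / 4),
          "too many individuals for the frame area")
  if (!is.null(behaviors)) {
    stop_if(length(behaviors) != n_individuals ||
              !all(behaviors %in% seq_along(BEHAVIOR_CLASSES)),
            "behaviors must be %d ids in 1..6", n_individuals)
  }
  spec <- list(frame_count = as.integer(frame_count), height = as.integer(height),
               width = as.integer(width), n_individuals = as.integer(n_individuals),
               behaviors = behaviors, class_probs = as.numeric(class_probs),
               fps = fps, keyframe_interval = keyframe_interval,
               motion_threshold = motion_threshold, video_id = video_id,
               seed = as.integer(seed))
  class(spec) <- "clip_spec"
  spec
}

# Behavior-keyed kinematics: returns per-frame centroid (normalized units)
# and blob shape for one individual. `start` is the initial centroid.
blob_track <- function(behavior, start, tt) {
  nT <- length(tt)
  cx <- rep(start[1], nT); cy <- rep(start[2], nT)
  sx <- 0.06; sy <- 0.06  # blob sd in normalized units
  name <- BEHAVIOR_CLASSES[behavior]
  if (name == "feeding") {
    cy <- cy + 0.02 * sin(2 * pi * tt / max(tt))  # head-dip bob, no net drift
    sy <- 0.05
  } else if (name == "vigilance") {
    sy <- 0.09; sx <- 0.045                        # tall, still
  } else if (name == "social") {
    sx <- 0.10; sy <- 0.08                         # grouped, larger extent
    cx <- cx + cumsum(stats::rnorm(nT, 0, 0.003))
    cy <- cy + cumsum(stats::rnorm(nT, 0, 0.003))
  } else if (name == "maintenance") {
    cx <- cx + stats::rnorm(nT, 0, 0.005)          # stationary jitter
    cy <- cy + stats::rnorm(nT, 0, 0.005)
  } else if (name == "walk") {
    dir <- stats::runif(1, 0, 2 * pi)
    dist <- 0.18                                   # slow translation
    cx <- cx + cos(dir) * dist * (tt / max(tt))
    cy <- cy + sin(dir) * dist * (tt / max(tt))
  } else if (name == "flight") {
    dir <- stats::runif(1, 0, 2 * pi)
    dist <- 0.55                                   # fast large translation
    cx <- cx + cos(dir) * dist * (tt / max(tt))
    cy <- cy + sin(dir) * dist * (tt / max(tt))
    sx <- 0.08
  }
  list(cx = clamp(cx, 0.12, 0.88), cy = clamp(cy, 0.12, 0.88), sx = sx, sy = sy)
}

#' Generate a toy annotated clip
#'
#' Renders Gaussian blobs onto grayscale frames and emits one annotation
#' record per individual per keyframe. The motion attribute is 1 (dynamic)
#' exactly when the blob centroid's net displacement across the clip exceeds
#' `motion_threshold` of the frame width — a quantitative surrogate for the
#' qualitative displacement/amplitude judgment used by human annotators.
#'
#' @param spec a [clip_spec()].
#' @return list with `frames` (array T x H x W, values in [0,1]),
#'   `annotations` (annotation data frame), and `tracks` (per-individual
#'   centroid traces).
#' @export
gen_toy_clips <- function(spec) {
  stopifnot(inherits(spec, "clip_spec"))
  with_seed(spec$seed, {
    nT <- spec$frame_count; H <- spec$height; W <- spec$width
    n <- spec$n_individuals
    behaviors <- spec$behaviors
    if (is.null(behaviors))
      behaviors <- sample.int(6, n, replace = TRUE, prob = spec$class_probs)
    # spread starting positions on a jittered grid to avoid initial overlap
    gx <- ceiling(sqrt(n)); gy <- ceiling(n / gx)
    pos <- expand.grid(x = seq(0.2, 0.8, length.out = gx),
                       y = seq(0.2, 0.8, length.out = gy))[seq_len(n), ]
    pos$x <- clamp(pos$x + stats::runif(n, -0.03, 0.03), 0.15, 0.85)
    pos$y <- clamp(pos$y + stats::runif(n, -0.03, 0.03), 0.15, 0.85)
    tt <- seq_len(nT)
    tracks <- lapply(seq_len(n), function(i)
      blob_track(behaviors[i], c(pos$x[i], pos$y[i]), tt))
    # render: pixel centers at (j - 0.5)/W, (i - 0.5)/H
    px <- (seq_len(W) - 0.5) / W
    py <- (seq_len(H) - 0.5) / H
    frames <- array(0, c(nT, H, W))
    for (t in tt) {
      f <- matrix(0, H, W)
      for (i in seq_len(n)) {
        tr <- tracks[[i]]
        gx_ <- exp(-0.5 * ((px - tr$cx[t]) / tr$sx)^2)
        gy_ <- exp(-0.5 * ((py - tr$cy[t]) / tr$sy)^2)
        f <- f + outer(gy_, gx_)
      }
      frames[t, , ] <- clamp(f, 0, 1)
    }
    # annotations at keyframes
    kf_frames <- unique(pmin(nT, round(seq(1, nT,
                                           by = spec$keyframe_interval * spec$fps))))
    ann <- do.call(rbind, lapply(kf_frames, function(t) {
      do.call(rbind, lapply(seq_len(n), function(i) {
        tr <- tracks[[i]]
        disp <- sqrt((tr$cx[nT] - tr$cx[1])^2 + (tr$cy[nT] - tr$cy[1])^2)
        data.frame(video_id = spec$video_id,
                   timestamp = (t - 1) / spec$fps,
                   x1 = clamp(tr$cx[t] - 2 * tr$sx, 0, 1 - 1e-4),
                   y1 = clamp(tr$cy[t] - 2 * tr$sy, 0, 1 - 1e-4),
                   x2 = clamp(tr$cx[t] + 2 * tr$sx, 1e-4, 1),
                   y2 = clamp(tr$cy[t] + 2 * tr$sy, 1e-4, 1),
                   behavior_id = behaviors[i],
                   motion_attr = as.integer(disp > spec$motion_threshold),
                   individual_id = i - 1L)
      }))
    }))
    ann$x2 <- pmax(ann$x2, ann$x1 + 1e-4)
    ann$y2 <- pmax(ann$y2, ann$y1 + 1e-4)
    validate_annotations(ann)
    list(frames = frames, annotations = ann, tracks = tracks,
         behaviors = behaviors, spec = spec)
  })
}

#' Generate a synthetic training-loss curve
#'
#' Exponential decay from `initial` to `final` over `epochs` points with
#' optional seeded multiplicative jitter; the first and last values equal the
#' endpoints exactly. Used as a fixture for loss-curve diagnostics.
#'
#' @param initial,final positive loss endpoints, `initial > final`.
#' @param epochs number of points (>= 2).
#' @param jitter_sd relative jitter standard deviation on interior points
#'   (0 = smooth curve).
#' @param seed integer seed (used when `jitter_sd > 0`).
#' @return numeric vector of length `epochs`.
#' @export
gen_loss_curve <- function(initial, final, epochs, jitter_sd = 0, seed = 1) {
  stop_if(!is.numeric(initial) || !is.numeric(final) || initial <= 0 || final <= 0,
          "loss endpoints must be positive")
  stop_if(final >= initial, "initial must exceed final")
  stop_if(!is_count(epochs) || epochs < 2, "epochs must be >= 2")
  rate <- log(initial / final) / (epochs - 1)
  curve <- initial * exp(-rate * (seq_len(epochs) - 1))
  if (jitter_sd > 0 && epochs > 2) {
    mid <- 2:(epochs - 1)
    curve[mid] <- with_seed(seed,
      curve[mid] * exp(stats::rnorm(length(mid), 0, jitter_sd)))
  }
  curve[1] <- initial
  curve[epochs] <- final
  curve
}

#' Write a clip's frames as a PNG stack
#'
#' Lossless grayscale PNGs `frame_0001.png`, ... under `dir`.
#'
#' @param frames array T x H x W with values in [0,1].
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_frame_stack <- function(frames, dir) {
  stopifnot(length(dim(frames)) == 3)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_len(dim(frames)[1]), function(t) {
    p <- file.path(dir, sprintf("frame_%04d.png", t))
    png::writePNG(frames[t, , ], p)
    p
  }, character(1))
  invisible(paths)
}
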