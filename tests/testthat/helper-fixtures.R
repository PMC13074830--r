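# Shared fixtures: small annotation tables and random-box helpers.

make_ann <- function(n = 3, video_id = "vid_a", timestamp = NULL,
                     behavior_id = NULL, motion_attr = NULL,
                     individual_id = NULL, seed = 1) {
  set.seed(seed)
  x1 <- runif(n, 0, 0.5); y1 <- runif(n, 0, 0.5)
  data.frame(video_id = video_id,
             timestamp = if (is.null(timestamp)) seq_len(n) - 1 else timestamp,
             x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 0.1, 0.4), y2 = y1 + runif(n, 0.1, 0.4),
             behavior_id = if (is.null(behavior_id))
               sample(1:6, n, replace = TRUE) else behavior_id,
             motion_attr = if (is.null(motion_attr))
               sample(0:1, n, replace = TRUE) else motion_attr,
             individual_id = if (is.null(individual_id)) seq_len(n) - 1L
                             else individual_id)
}

random_box <- function() {
  x1 <- runif(1, 0, 0.6); y1 <- runif(1, 0, 0.6)
  c(x1, y1, x1 + runif(1, 0.15, 0.39), y1 + runif(1, 0.15, 0.39))
}

# small random conflict batch for model tests
random_tab_batch <- function(n = 12, d = 5, seed = 1) {
  set.seed(seed)
  list(x = matrix(rnorm(n * d), n, d),
       behavior_id = sample(1:6, n, replace = TRUE),
       motion_attr = sample(0:1, n, replace = TRUE))
}
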