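# Evaluation protocol: IoU, greedy matching, AP/mAP, confusion, agreement.

test_that("iou handles canonical box geometries", {
  b <- c(0.2, 0.2, 0.6, 0.8)
  expect_equal(iou(b, b), 1)
  expect_equal(iou(c(0, 0, 0.3, 0.3), c(0.5, 0.5, 0.9, 0.9)), 0)
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 0.5, 1)), 0.5)
  expect_error(iou(c(0.3, 0.2, 0.3, 0.9), b), "degenerate")
})

test_that("greedy matching is one-to-one within groups", {
  truths <- make_ann(3, timestamp = c(0, 0, 1), behavior_id = c(1, 1, 2))
  dets <- oracle_detections(truths)
  m <- match_detections(dets, truths)
  expect_true(all(m$tp))
  # duplicate detections of one truth: one TP, one FP
  dup <- rbind(dets[1, ], dets[1, ])
  dup$confidence <- c(0.9, 0.8)
  m2 <- match_detections(dup, truths[1, ])
  expect_equal(sum(m2$tp), 1)
  expect_equal(m2$tp, c(TRUE, FALSE))
})

test_that("matching agrees with an independent implementation and never
           exceeds the truth count", {
  # oracle: plain-loop greedy matcher over the same grouping rule
  greedy_oracle <- function(dets, truths, thr) {
    tp <- logical(nrow(dets))
    used <- logical(nrow(truths))
    for (j in order(-dets$confidence)) {
      best <- -1; best_k <- 0
      for (k in seq_len(nrow(truths))) {
        if (used[k]) next
        if (truths$behavior_id[k] != dets$behavior_id[j]) next
        if (truths$video_id[k] != dets$video_id[j]) next
        if (abs(truths$timestamp[k] - dets$timestamp[j]) > 1e-9) next
        v <- iou(as.numeric(dets[j, c("x1", "y1", "x2", "y2")]),
                 as.numeric(truths[k, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; best_k <- k }
      }
      if (best_k > 0 && best >= thr) { tp[j] <- TRUE; used[best_k] <- TRUE }
    }
    tp
  }
  set.seed(14)
  for (i in 1:25) {
    truths <- make_ann(sample(2:5, 1), timestamp = 0,
                       behavior_id = sample(1:2, sample(2:5, 1)[1],
                                            replace = TRUE)[1], seed = i)
    n_det <- sample(2:6, 1)
    dets <- data.frame(video_id = "vid_a", timestamp = 0,
                       x1 = runif(n_det, 0, 0.5), y1 = runif(n_det, 0, 0.5),
                       behavior_id = truths$behavior_id[1],
                       confidence = runif(n_det))
    dets$x2 <- dets$x1 + runif(n_det, 0.1, 0.4)
    dets$y2 <- dets$y1 + runif(n_det, 0.1, 0.4)
    m <- match_detections(dets, truths, 0.3)
    expect_equal(m$tp, greedy_oracle(dets, truths, 0.3))
    expect_lte(sum(m$tp), nrow(truths))
  }
})

test_that("average precision reproduces canonical rankings", {
  expect_equal(average_precision(c(TRUE, TRUE, FALSE, FALSE), 2), 1.0)
  expect_equal(average_precision(c(FALSE, FALSE, FALSE), 4), 0)
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               ap_oracle(c(TRUE, FALSE, TRUE), 2))
  expect_true(is.na(average_precision(logical(0), 0)))
})

test_that("average precision matches the brute-force PR oracle", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    flags <- runif(n) < 0.5
    n_truth <- sum(flags) + sample(0:3, 1)
    if (n_truth == 0) n_truth <- 1
    expect_equal(average_precision(flags, n_truth), ap_oracle(flags, n_truth),
                 tolerance = 1e-12)
  }
})

test_that("AP is invariant to monotone confidence transforms", {
  set.seed(20)
  truths <- make_ann(6, timestamp = 0, behavior_id = 2)
  dets <- oracle_detections(truths, jitter = 0.4, seed = 3)
  ev1 <- evaluate_detections(dets, truths)
  dets2 <- dets
  dets2$confidence <- dets$confidence^3 * 0.5       # strictly monotone
  ev2 <- evaluate_detections(dets2, truths)
  expect_equal(ev1$per_class$ap, ev2$per_class$ap)
})

test_that("mean AP reproduces the published per-class summaries", {
  ours <- c(0.8318, 0.5477, 0.9403, 0.7046, 0.2320, 0.8595)
  expect_equal(as.numeric(mean_ap(ours)), 0.6860)
  single <- c(0.8148, 0.4778, 0.9617, 0.6934, 0.2199, 0.7806)
  expect_equal(as.numeric(mean_ap(single)), 0.6580)
  expect_equal(as.numeric(mean_ap(rep(0.42, 6))), 0.42)
  withna <- c(NA, 0.5, 0.7, NA, 0.3, 0.5)
  m <- mean_ap(withna)
  expect_equal(as.numeric(m), 0.5)
  expect_equal(attr(m, "n_classes"), 4)
})

test_that("the oracle classifier attains mAP 1.0 on a toy scene", {
  toy <- gen_toy_clips(clip_spec(frame_count = 16, n_individuals = 4,
                                 seed = 31))
  dets <- oracle_detections(toy$annotations, jitter = 0.2, seed = 1)
  ev <- evaluate_detections(dets, toy$annotations)
  expect_equal(as.numeric(ev$map), 1.0)
  expect_output(print(ev), "mAP 1.0000")
})

test_that("confusion matrices are row-normalized tallies", {
  perfect <- confusion_matrix(1:6, 1:6)
  expect_equal(unname(perfect), diag(6))
  set.seed(22)
  pred <- sample(1:6, 200, replace = TRUE)
  true <- sample(1:6, 200, replace = TRUE)
  cm <- confusion_matrix(pred, true)
  expect_equal(unname(rowSums(cm)), rep(1, 6), tolerance = 1e-12)
  # direct counting oracle
  counts <- confusion_matrix(pred, true, normalize = "none")
  for (a in 1:6) for (b in 1:6)
    expect_equal(counts[a, b], sum(true == a & pred == b))
  expect_error(confusion_matrix(c(1, 7), c(1, 2)), "labels")
})

test_that("Cohen's kappa matches hand-computed agreement", {
  expect_equal(cohens_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1)
  # worked 2x2 table: a = (1,1,2,2,1), b = (1,2,2,2,1)
  # p_o = 4/5; p_e = (3/5)(2/5) + (2/5)(3/5) = 12/25
  # kappa = (0.8 - 0.48) / 0.52 = 8/13
  expect_equal(cohens_kappa(c(1, 1, 2, 2, 1), c(1, 2, 2, 2, 1)), 8 / 13,
               tolerance = 1e-12)
  set.seed(25)
  a <- sample(1:4, 10000, replace = TRUE)
  b <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)), 0.05)   # chance level
  # degenerate marginals
  expect_equal(cohens_kappa(c(1, 1), c(1, 1)), 1)
  expect_true(is.na(cohens_kappa(c(1, 1, 1), c(1, 1, 2))) ||
                cohens_kappa(c(1, 1, 1), c(1, 1, 2)) < 1)
})

test_that("mean pairwise IoU summarizes box agreement", {
  a <- rbind(c(0, 0, 1, 1), c(0.2, 0.2, 0.6, 0.6))
  b <- rbind(c(0, 0, 0.5, 1), c(0.2, 0.2, 0.6, 0.6))
  expect_equal(mean_pairwise_iou(a, b), mean(c(0.5, 1)))
})

test_that("evaluation reports are written as CSV and text", {
  toy <- gen_toy_clips(clip_spec(frame_count = 16, n_individuals = 3,
                                 seed = 33))
  ev <- evaluate_detections(oracle_detections(toy$annotations),
                            toy$annotations)
  csv <- withr::local_tempfile(fileext = ".csv")
  txt <- withr::local_tempfile(fileext = ".txt")
  write_eval_report(ev, csv, txt)
  back <- read.csv(csv)
  expect_equal(back$class[7], "mAP")
  expect_equal(back$ap[7], 1.0)
  expect_match(paste(readLines(txt), collapse = "\n"), "overall")
})
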