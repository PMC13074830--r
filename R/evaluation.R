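# Frame-level detection evaluation: IoU box matching, per-class average
# precision via precision-recall integration, mAP over the six behavior
# classes, normalized confusion matrices and annotation-agreement utilities.

#' Intersection over union of two boxes
#'
#' @param box_a,box_b boxes as `c(x1, y1, x2, y2)` with positive area.
#' @return IoU in [0, 1].
#' @export
iou <- function(box_a, box_b) {
  stop_if(length(box_a) != 4 || length(box_b) != 4, "boxes must have 4 coordinates")
  stop_if(box_a[3] <= box_a[1] || box_a[4] <= box_a[2] ||
            box_b[3] <= box_b[1] || box_b[4] <= box_b[2],
          "degenerate box (zero area)")
  ix <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  iy <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- ix * iy
  area <- function(b) (b[3] - b[1]) * (b[4] - b[2])
  inter / (area(box_a) + area(box_b) - inter)
}

#' Greedy IoU matching of detections to ground truth
#'
#' Within each (video, timestamp, class) group, detections are visited in
#' descending confidence and greedily matched one-to-one to the unmatched
#' ground-truth box of highest IoU; a detection is a true positive iff that
#' IoU reaches `iou_thresh`. Duplicate detections of one truth are false
#' positives, so the TP count never exceeds the number of truths.
#'
#' @param dets prediction data frame (video_id, timestamp, x1..y2,
#'   behavior_id, confidence).
#' @param truths annotation data frame.
#' @param iou_thresh IoU threshold (default 0.5).
#' @return `dets` with logical column `tp` added (original row order kept).
#' @export
match_detections <- function(dets, truths, iou_thresh = 0.5) {
  need <- c("video_id", "timestamp", "x1", "y1", "x2", "y2", "behavior_id",
            "confidence")
  stop_if(!all(need %in% names(dets)), "detections missing required columns")
  dets$tp <- FALSE
  if (nrow(dets) == 0) return(dets)
  key <- function(df) paste(df$video_id, sprintf("%.6f", df$timestamp),
                            df$behavior_id)
  dk <- key(dets); tk <- key(truths)
  for (grp in unique(dk)) {
    di <- which(dk == grp)
    ti <- which(tk == grp)
    if (length(ti) == 0) next
    used <- logical(length(ti))
    for (j in di[order(-dets$confidence[di])]) {
      dbox <- as.numeric(dets[j, c("x1", "y1", "x2", "y2")])
      ious <- vapply(seq_along(ti), function(k) {
        if (used[k]) return(-1)
        iou(dbox, as.numeric(truths[ti[k], c("x1", "y1", "x2", "y2")]))
      }, numeric(1))
      best <- which.max(ious)
      if (length(best) && ious[best] >= iou_thresh) {
        dets$tp[j] <- TRUE
        used[best] <- TRUE
      }
    }
  }
  dets
}

#' Average precision from ranked true/false-positive flags
#'
#' All-point interpolation: the area under the precision envelope of the
#' precision-recall curve traced by visiting detections in descending
#' confidence. With zero ground-truth instances AP is undefined and `NA` is
#' returned (such classes are excluded from the mean).
#'
#' @param flags logical vector, TRUE for true positives, ordered by
#'   descending confidence.
#' @param n_truth number of ground-truth instances of the class.
#' @return AP in [0, 1], or `NA` when `n_truth` is 0.
#' @export
average_precision <- function(flags, n_truth) {
  stop_if(!is_count(n_truth) || n_truth < 0, "n_truth must be a non-negative count")
  if (n_truth == 0) return(NA_real_)
  if (length(flags) == 0 || !any(flags)) return(0)
  tp <- cumsum(flags)
  fp <- cumsum(!flags)
  prec <- tp / (tp + fp)
  rec <- tp / n_truth
  env <- rev(cummax(rev(prec)))            # precision envelope
  drec <- diff(c(0, rec))
  sum(drec * env)
}

#' Mean average precision over the six behavior classes
#'
#' Arithmetic mean of the per-class APs, reported to 4 decimals. Classes with
#' undefined AP (no ground truth) are dropped from the mean and flagged.
#'
#' @param per_class numeric vector of 6 per-class APs (NA allowed).
#' @return mAP, with attribute `n_classes` = number of classes averaged.
#' @export
mean_ap <- function(per_class) {
  stop_if(length(per_class) != length(BEHAVIOR_CLASSES),
          "expected %d per-class APs", length(BEHAVIOR_CLASSES))
  ok <- !is.na(per_class)
  stop_if(!any(ok), "no class has a defined AP")
  out <- round(mean(per_class[ok]), 4)
  attr(out, "n_classes") <- sum(ok)
  out
}

#' Evaluate scored detections against annotations
#'
#' Full frame-level protocol: greedy IoU matching per class, per-class AP by
#' precision-recall integration, and the mAP over the six classes.
#'
#' @param dets prediction data frame.
#' @param truths annotation data frame.
#' @param iou_thresh IoU threshold for matching (default 0.5).
#' @return object of class `eval_result`: list with `per_class`
#'   (data frame: class, ap, support), `map`, `n_detections`.
#' @export
evaluate_detections <- function(dets, truths, iou_thresh = 0.5) {
  validate_annotations(truths)
  m <- match_detections(dets, truths, iou_thresh)
  per <- do.call(rbind, lapply(seq_along(BEHAVIOR_CLASSES), function(k) {
    dk <- m[m$behavior_id == k, , drop = FALSE]
    dk <- dk[order(-dk$confidence), , drop = FALSE]
    support <- sum(truths$behavior_id == k)
    data.frame(class = BEHAVIOR_CLASSES[k],
               ap = average_precision(dk$tp, support),
               support = support)
  }))
  structure(list(per_class = per, map = mean_ap(per$ap),
                 n_detections = nrow(dets), iou_thresh = iou_thresh),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Frame-level evaluation (IoU >= %.2f, %d detections)\n",
              x$iou_thresh, x$n_detections))
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("  %-12s AP %s  (support %d)\n", x$per_class$class[i],
                ifelse(is.na(x$per_class$ap[i]), "  --  ",
                       sprintf("%.4f", x$per_class$ap[i])),
                x$per_class$support[i]))
  cat(sprintf("  %-12s mAP %.4f over %d classes\n", "overall", x$map,
              attr(x$map, "n_classes")))
  invisible(x)
}

#' Write an evaluation result as CSV and a text report
#'
#' The text report mirrors a per-class AP table with the overall mAP row.
#'
#' @param result an `eval_result`.
#' @param csv_path,txt_path output paths (either may be NULL to skip).
#' @return `result`, invisibly.
#' @export
write_eval_report <- function(result, csv_path = NULL, txt_path = NULL) {
  stopifnot(inherits(result, "eval_result"))
  if (!is.null(csv_path)) {
    df <- rbind(result$per_class,
                data.frame(class = "mAP", ap = as.numeric(result$map),
                           support = sum(result$per_class$support)))
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    writeLines(utils::capture.output(print(result)), con)
  }
  invisible(result)
}

#' Row-normalized confusion matrix
#'
#' Counts of predicted vs true behavior labels; each true-class row is
#' divided by its support (rows without support stay zero).
#'
#' @param pred_labels,true_labels integer vectors in 1..6, equal length.
#' @param normalize `"row"` (default) or `"none"`.
#' @return 6 x 6 matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(pred_labels, true_labels, normalize = c("row", "none")) {
  normalize <- match.arg(normalize)
  stop_if(length(pred_labels) != length(true_labels), "label length mismatch")
  k <- length(BEHAVIOR_CLASSES)
  stop_if(!all(pred_labels %in% seq_len(k)) || !all(true_labels %in% seq_len(k)),
          "labels must be integers in 1..%d", k)
  m <- matrix(0, k, k, dimnames = list(true = BEHAVIOR_CLASSES,
                                       pred = BEHAVIOR_CLASSES))
  for (i in seq_along(true_labels))
    m[true_labels[i], pred_labels[i]] <- m[true_labels[i], pred_labels[i]] + 1
  if (normalize == "row") {
    rs <- rowSums(m)
    nz <- rs > 0
    m[nz, ] <- m[nz, , drop = FALSE] / rs[nz]
  }
  m
}

#' Cohen's kappa between two annotators
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the product of
#' the two annotators' marginal label distributions. When `p_e` is 1 (both
#' annotators constant): returns 1 if observed agreement is also perfect,
#' otherwise `NA` (undefined).
#'
#' @param labels_a,labels_b equal-length label vectors over a shared label set.
#' @return kappa in [-1, 1] (or NA in the degenerate case).
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  stop_if(length(labels_a) != length(labels_b), "label length mismatch")
  stop_if(length(labels_a) == 0, "empty label vectors")
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  n <- length(a)
  po <- mean(a == b)
  pe <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Mean pairwise IoU between annotators' boxes
#'
#' Agreement utility for re-labeled instances: given matrices of boxes (one
#' row per instance, columns x1,y1,x2,y2) from two annotators over the same
#' instances, returns the mean IoU.
#'
#' @param boxes_a,boxes_b n x 4 matrices of boxes over the same instances.
#' @return mean pairwise IoU.
#' @export
mean_pairwise_iou <- function(boxes_a, boxes_b) {
  stop_if(!all(dim(boxes_a) == dim(boxes_b)), "box matrices must match")
  mean(vapply(seq_len(nrow(boxes_a)), function(i)
    iou(boxes_a[i, ], boxes_b[i, ]), numeric(1)))
}
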