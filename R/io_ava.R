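# AVA-style annotation / prediction CSV IO and dataset descriptive statistics.
#
# Annotations are data frames with one row per spatio-temporal instance:
# one bounding box for one individual at one keyframe timestamp, carrying a
# behavior class id (1..6) and a binary motion attribute (0 = static,
# 1 = dynamic). Boxes are normalized corner coordinates x1,y1,x2,y2 in [0,1].

ANNOTATION_COLS <- c("video_id", "timestamp", "x1", "y1", "x2", "y2",
                     "behavior_id", "motion_attr", "individual_id")
PREDICTION_COLS <- c("video_id", "timestamp", "x1", "y1", "x2", "y2",
                     "behavior_id", "confidence", "motion_p0", "motion_p1")

#' Validate a data frame of annotation records
#'
#' Checks the invariants every annotation must satisfy: x1 < x2 and y1 < y2,
#' coordinates in [0,1], behavior id in 1..6, binary motion attribute,
#' non-negative timestamp and individual id.
#'
#' @param records data frame with the columns
#'   \code{video_id, timestamp, x1, y1, x2, y2, behavior_id, motion_attr,
#'   individual_id}.
#' @param lines optional integer vector of source line numbers used in error
#'   messages (defaults to row numbers).
#' @return the validated data frame, invisibly unchanged.
#' @export
validate_annotations <- function(records, lines = NULL) {
  stop_if(!is.data.frame(records), "annotations must be a data frame")
  miss <- setdiff(ANNOTATION_COLS, names(records))
  stop_if(length(miss) > 0, "missing annotation columns: %s",
          paste(miss, collapse = ", "))
  if (is.null(lines)) lines <- seq_len(nrow(records))
  fail <- function(ok, what) {
    bad <- which(!ok)
    stop_if(length(bad) > 0, "invalid annotation at line %s: %s",
            paste(lines[utils::head(bad, 5)], collapse = ", "), what)
  }
  num <- function(col) {
    v <- records[[col]]
    fail(is.finite(suppressWarnings(as.numeric(v))), paste(col, "not numeric"))
    as.numeric(v)
  }
  ts <- num("timestamp")
  fail(ts >= 0, "timestamp must be >= 0")
  x1 <- num("x1"); y1 <- num("y1"); x2 <- num("x2"); y2 <- num("y2")
  fail(x1 >= 0 & y1 >= 0 & x2 <= 1 & y2 <= 1, "box outside [0,1]")
  fail(x1 < x2, "x1 must be < x2")
  fail(y1 < y2, "y1 must be < y2")
  b <- num("behavior_id")
  fail(b == floor(b) & b >= 1 & b <= length(BEHAVIOR_CLASSES),
       "behavior_id out of range 1..6")
  m <- num("motion_attr")
  fail(m %in% c(0, 1), "motion_attr must be 0 or 1")
  iid <- num("individual_id")
  fail(iid == floor(iid) & iid >= 0, "individual_id must be a non-negative integer")
  invisible(records)
}

# Shared reader for the two CSV dialects. AVA-style files carry no header;
# a header line is accepted when the second field of the first row is not
# numeric.
read_ava_csv <- function(path, cols) {
  stop_if(!file.exists(path), "file not found: %s", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  stop_if(length(nf) == 0, "empty file: %s", path)
  bad <- which(nf != length(cols))
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           colClasses = "character")
  has_header <- is.na(suppressWarnings(as.numeric(first[[2]])))
  if (has_header) bad <- setdiff(bad, 1L)
  stop_if(length(bad) > 0,
          "malformed row at line %s of %s: expected %d fields",
          paste(utils::head(bad, 5), collapse = ", "), path, length(cols))
  df <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE,
                        colClasses = c("character", rep("numeric", length(cols) - 1)))
  names(df) <- cols
  attr(df, "source_lines") <- seq_len(nrow(df)) + as.integer(has_header)
  df
}

#' Read AVA-style annotations from CSV
#'
#' Column order is fixed: video_id, timestamp, x1, y1, x2, y2, behavior_id,
#' motion_attr, individual_id. Files are headerless by default (the AVA
#' dialect); a header line is detected and skipped when present. Every row is
#' validated; a malformed or invalid row raises an error naming its line.
#'
#' @param path path to a CSV file.
#' @return data frame of annotation records, row order preserved.
#' @seealso [write_annotations()], [validate_annotations()]
#' @export
read_annotations <- function(path) {
  df <- read_ava_csv(path, ANNOTATION_COLS)
  lines <- attr(df, "source_lines")
  attr(df, "source_lines") <- NULL
  for (col in ANNOTATION_COLS[-1]) df[[col]] <- as.numeric(df[[col]])
  df$behavior_id <- as.integer(df$behavior_id)
  df$motion_attr <- as.integer(df$motion_attr)
  df$individual_id <- as.integer(df$individual_id)
  validate_annotations(df, lines)
  df
}

#' Write AVA-style annotations to CSV
#'
#' Writes the headerless AVA dialect with floats at 4 decimals, so that
#' read/write round-trips are the identity on valid files.
#'
#' @param records annotation data frame (validated before writing).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  validate_annotations(records)
  out <- data.frame(
    records$video_id,
    sprintf("%.4f", records$timestamp),
    sprintf("%.4f", records$x1), sprintf("%.4f", records$y1),
    sprintf("%.4f", records$x2), sprintf("%.4f", records$y2),
    records$behavior_id, records$motion_attr, records$individual_id)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prediction CSVs
#'
#' Prediction rows mirror annotations but replace motion_attr/individual_id
#' with a per-row behavior confidence and a static/dynamic probability pair.
#' Columns: video_id, timestamp, x1, y1, x2, y2, behavior_id, confidence,
#' motion_p0, motion_p1.
#'
#' @param path path to a CSV file.
#' @return data frame of scored predictions.
#' @export
read_predictions <- function(path) {
  df <- read_ava_csv(path, PREDICTION_COLS)
  lines <- attr(df, "source_lines")
  for (col in PREDICTION_COLS[-1]) df[[col]] <- as.numeric(df[[col]])
  df$behavior_id <- as.integer(df$behavior_id)
  bad <- which(df$confidence < 0 | df$confidence > 1)
  stop_if(length(bad) > 0, "confidence outside [0,1] at line %s",
          paste(lines[utils::head(bad, 5)], collapse = ", "))
  bad <- which(abs(df$motion_p0 + df$motion_p1 - 1) > 1e-9)
  stop_if(length(bad) > 0, "motion probabilities do not sum to 1 at line %s",
          paste(lines[utils::head(bad, 5)], collapse = ", "))
  attr(df, "source_lines") <- NULL
  df
}

#' Write prediction CSVs
#' @param preds prediction data frame (see [read_predictions()] for columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  stop_if(!all(PREDICTION_COLS %in% names(preds)),
          "predictions must have columns: %s", paste(PREDICTION_COLS, collapse = ", "))
  out <- data.frame(
    preds$video_id,
    sprintf("%.4f", preds$timestamp),
    sprintf("%.4f", preds$x1), sprintf("%.4f", preds$y1),
    sprintf("%.4f", preds$x2), sprintf("%.4f", preds$y2),
    preds$behavior_id,
    sprintf("%.4f", preds$confidence),
    sprintf("%.4f", preds$motion_p0), sprintf("%.4f", preds$motion_p1))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dataset descriptive statistics
#'
#' Per-class instance counts and proportions, static/dynamic proportions, and
#' per-class box geometry summaries: area on a log scale (mean and sd of
#' log10 area in normalized units) and aspect ratio W/H.
#'
#' @param records annotation data frame.
#' @return an object of class `dataset_stats`: list with elements
#'   `n`, `class_counts`, `class_props`, `static_prop`, `dynamic_prop`,
#'   and `box_geometry` (per-class data frame).
#' @export
dataset_stats <- function(records) {
  validate_annotations(records)
  stop_if(nrow(records) == 0, "dataset_stats requires a non-empty record set")
  n <- nrow(records)
  cls <- factor(records$behavior_id, levels = seq_along(BEHAVIOR_CLASSES),
                labels = BEHAVIOR_CLASSES)
  counts <- as.integer(table(cls))
  names(counts) <- BEHAVIOR_CLASSES
  w <- records$x2 - records$x1
  h <- records$y2 - records$y1
  area <- w * h
  aspect <- w / h
  geom <- do.call(rbind, lapply(seq_along(BEHAVIOR_CLASSES), function(k) {
    i <- records$behavior_id == k
    data.frame(class = BEHAVIOR_CLASSES[k], n = sum(i),
               log10_area_mean = if (any(i)) mean(log10(area[i])) else NA_real_,
               log10_area_sd = if (sum(i) > 1) stats::sd(log10(area[i])) else NA_real_,
               aspect_mean = if (any(i)) mean(aspect[i]) else NA_real_,
               aspect_median = if (any(i)) stats::median(aspect[i]) else NA_real_)
  }))
  out <- list(n = n,
              class_counts = counts,
              class_props = counts / n,
              static_prop = mean(records$motion_attr == 0),
              dynamic_prop = mean(records$motion_attr == 1),
              box_geometry = geom)
  class(out) <- "dataset_stats"
  out
}

#' @export
print.dataset_stats <- function(x, ...) {
  cat(sprintf("Dataset: %d spatio-temporal instances\n", x$n))
  cat("Class proportions:\n")
  for (k in seq_along(x$class_props))
    cat(sprintf("  %-12s %6d  (%.1f%%)\n", names(x$class_props)[k],
                x$class_counts[k], 100 * x$class_props[k]))
  cat(sprintf("Static %.1f%% / dynamic %.1f%%\n",
              100 * x$static_prop, 100 * x$dynamic_prop))
  invisible(x)
}

#' Largest-remainder split allocation
#'
#' Allocates `n_items` into splits proportional to `ratio` by the
#' largest-remainder method: each split gets the floor of its exact share and
#' remaining units go to the largest fractional parts, ties broken by split
#' order (train, val, test first). With 19,926 instances at 8:1:1 this yields
#' (15941, 1993, 1992).
#'
#' @param n_items positive integer total.
#' @param ratio vector of positive weights, e.g. `c(8, 1, 1)`.
#' @return integer vector of counts summing to `n_items`.
#' @export
split_allocate <- function(n_items, ratio = c(8, 1, 1)) {
  stop_if(!is_count(n_items) || n_items < 1, "n_items must be a positive integer")
  stop_if(!is.numeric(ratio) || any(ratio <= 0), "ratio components must be positive")
  stop_if(n_items < length(ratio), "n_items smaller than the number of splits")
  share <- n_items * ratio / sum(ratio)
  base <- floor(share)
  rem <- n_items - sum(base)
  frac <- share - base
  if (rem > 0) {
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Video-level train/val/test split
#'
#' Partitions annotation records by video id so that no video contributes to
#' more than one split; the number of videos per split follows
#' [split_allocate()] on the distinct video count. Deterministic under
#' `seed`.
#'
#' @param records annotation data frame.
#' @param ratio split weights (default 8:1:1).
#' @param seed integer seed for the video shuffle.
#' @return named list of data frames `train`, `val`, `test` (or `split1..k`
#'   for other ratio lengths).
#' @export
video_level_split <- function(records, ratio = c(8, 1, 1), seed = 1) {
  validate_annotations(records)
  vids <- unique(records$video_id)
  stop_if(length(vids) < length(ratio),
          "need at least %d distinct videos", length(ratio))
  counts <- split_allocate(length(vids), ratio)
  perm <- with_seed(seed, sample(vids))
  idx <- rep(seq_along(counts), counts)
  assign_split <- stats::setNames(idx, perm)
  nm <- if (length(ratio) == 3) c("train", "val", "test")
        else paste0("split", seq_along(ratio))
  out <- lapply(seq_along(counts), function(k) {
    records[assign_split[records$video_id] == k, , drop = FALSE]
  })
  stats::setNames(out, nm)
}
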