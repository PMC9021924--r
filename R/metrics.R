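# Detection evaluation: intersection-over-union, greedy matching, average
# precision over a ranked prediction list, and the rate metrics used for
# per-environment detector audits.

#' Create a bounding box
#'
#' Axis-aligned, 0-based pixel coordinates with half-open extent
#' `[x, x+w) x [y, y+h)`.
#'
#' @param x,y top-left corner (pixels).
#' @param width,height positive box dimensions.
#' @param score optional confidence in `[0, 1]` (predictions).
#' @return list of class `fg_bbox`.
#' @export
bbox <- function(x, y, width, height, score = NULL) {
  if (width <= 0 || height <= 0) stop("box width and height must be positive")
  if (!is.null(score) && (score < 0 || score > 1))
    stop("score must lie in [0, 1]")
  structure(list(x = x, y = y, width = width, height = height, score = score),
            class = "fg_bbox")
}

.as_box <- function(b) {
  if (inherits(b, "fg_bbox")) return(b)
  if (is.list(b)) return(do.call(bbox, b[!vapply(b, is.null, TRUE)]))
  if (is.numeric(b) && length(b) >= 4L)
    return(bbox(b[1], b[2], b[3], b[4],
                score = if (length(b) >= 5L) b[5] else NULL))
  stop("cannot interpret bounding box")
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes ([bbox()] or numeric `c(x, y, w, h)`).
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- .as_box(a); b <- .as_box(b)
  ix <- max(0, min(a$x + a$width, b$x + b$width) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$height, b$y + b$height) - max(a$y, b$y))
  inter <- ix * iy
  union <- a$width * a$height + b$width * b$height - inter
  inter / union
}

.norm_boxes <- function(boxes) lapply(boxes, .as_box)

#' Match predictions to ground truth (greedy, one-to-one)
#'
#' Predictions are ranked by descending score; each claims the unmatched
#' ground-truth box of highest IoU provided IoU >= `iou_threshold` (true
#' positive), else it is a false positive.  Ground truths left unmatched are
#' misses.  This is the standard PASCAL-VOC protocol.
#'
#' @param gt list of ground-truth boxes.
#' @param pred list of scored predicted boxes.
#' @param iou_threshold IoU threshold in (0, 1).
#' @return list with `tp` (logical per prediction, rank order), `order`
#'   (prediction indices by rank), `matched` (logical per ground truth),
#'   `n_miss`.
#' @export
match_detections <- function(gt, pred, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold >= 1)
    stop("iou_threshold must lie in (0, 1)")
  gt <- .norm_boxes(gt)
  pred <- .norm_boxes(pred)
  scores <- vapply(pred, function(p) p$score %||% NA_real_, numeric(1))
  if (length(pred) && any(is.na(scores)))
    stop("all predictions must carry scores")
  ord <- order(scores, decreasing = TRUE)
  matched <- rep(FALSE, length(gt))
  tp <- rep(FALSE, length(pred))
  for (r in seq_along(ord)) {
    p <- pred[[ord[r]]]
    ious <- vapply(gt, function(g) iou(p, g), numeric(1))
    ious[matched] <- -1
    if (length(ious) && max(ious) >= iou_threshold) {
      j <- which.max(ious)
      matched[j] <- TRUE
      tp[r] <- TRUE
    }
  }
  list(tp = tp, order = ord, matched = matched, n_miss = sum(!matched))
}

#' Average precision at an IoU threshold
#'
#' The ranked-list sum `AP = sum_k P(k) * delta_recall(k)`: precision at
#' each rank times the recall increment contributed by that rank.  By
#' default no precision-envelope interpolation is applied (the literal sum);
#' `interpolated = TRUE` applies the monotone envelope first.
#'
#' @param dets a detection set: list of per-image lists with elements `gt`
#'   and `pred`, or a single list with those elements.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param interpolated apply the precision envelope.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, iou_threshold = 0.5,
                              interpolated = FALSE) {
  if (!is.null(dets$gt) || !is.null(dets$pred)) dets <- list(dets)
  flags <- list()
  scores <- numeric(0)
  n_gt <- 0L
  for (im in dets) {
    m <- match_detections(im$gt %||% list(), im$pred %||% list(),
                          iou_threshold)
    sc <- vapply(.norm_boxes(im$pred %||% list()), `[[`, numeric(1), "score")
    flags <- c(flags, list(m$tp))
    scores <- c(scores, sc[m$order])
    n_gt <- n_gt + length(im$gt %||% list())
  }
  if (n_gt == 0L) stop("average precision is undefined without ground truth")
  tp <- unlist(flags) %||% logical(0)
  if (!length(tp)) return(0)
  ord <- order(scores, decreasing = TRUE)
  average_precision_from_flags(tp[ord], n_gt, interpolated)
}

#' Average precision from a ranked true-positive flag list
#'
#' Evaluates the ranked-list sum directly from per-rank true/false-positive
#' flags and the ground-truth count.
#'
#' @param tp logical vector, TRUE where the rank-k prediction is a true
#'   positive (ranks in descending score order).
#' @param n_gt number of ground-truth boxes (> 0).
#' @param interpolated apply the precision envelope.
#' @return AP in `[0, 1]`.
#' @export
average_precision_from_flags <- function(tp, n_gt, interpolated = FALSE) {
  if (n_gt <= 0) stop("average precision is undefined without ground truth")
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  if (interpolated) precision <- rev(cummax(rev(precision)))
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Round half away from zero
#'
#' Reporting convention for rates: half-up rounding to `digits` decimals
#' (base R's `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Detection rate metrics
#'
#' Correct, error and miss rates as percentages of the total sample count:
#' the error rate is the ratio of falsely detected samples to total samples,
#' the miss rate the ratio of undetected samples to total samples.  Rates
#' are rounded half-up to 2 decimals for reporting; pass `digits = NULL`
#' for full precision.
#'
#' @param total total number of samples (> 0).
#' @param correct,false_det,missed nonnegative counts.
#' @param digits reporting decimals (default 2), or NULL.
#' @return named numeric: `correct_pct`, `error_pct`, `miss_pct`.
#' @export
rate_metrics <- function(total, correct, false_det, missed, digits = 2) {
  if (total <= 0) stop("total must be positive")
  if (any(c(correct, false_det, missed) < 0)) stop("counts must be nonnegative")
  r <- 100 * c(correct_pct = correct, error_pct = false_det,
               miss_pct = missed) / total
  if (!is.null(digits)) r <- round_half_up(r, digits)
  r
}

#' Relative improvement between two percentages
#'
#' `100 * (new - old) / old`, reported to 2 decimals.
#'
#' @param old baseline value (> 0).
#' @param new new value.
#' @param digits reporting decimals (default 2), or NULL.
#' @export
relative_improvement <- function(old, new, digits = 2) {
  if (old <= 0) stop("old value must be positive")
  r <- 100 * (new - old) / old
  if (!is.null(digits)) r <- round_half_up(r, digits)
  r
}

#' Evaluate a detection set
#'
#' @param dets per-image list of `list(gt, pred)`.
#' @param iou_threshold IoU threshold.
#' @return list with `ap`, counts (`n_gt`, `tp`, `fp`, `miss`), and the
#'   `rates` vector from [rate_metrics()] (total = ground-truth count).
#' @export
evaluate_detections <- function(dets, iou_threshold = 0.5) {
  if (!is.null(dets$gt) || !is.null(dets$pred)) dets <- list(dets)
  tp <- fp <- miss <- n_gt <- 0L
  for (im in dets) {
    m <- match_detections(im$gt %||% list(), im$pred %||% list(),
                          iou_threshold)
    tp <- tp + sum(m$tp)
    fp <- fp + sum(!m$tp)
    miss <- miss + m$n_miss
    n_gt <- n_gt + length(im$gt %||% list())
  }
  ap <- average_precision(dets, iou_threshold)
  list(ap = ap, n_gt = n_gt, tp = tp, fp = fp, miss = miss,
       rates = rate_metrics(n_gt, tp, fp, miss))
}

# ---- JSON-lines detection schema -------------------------------------------

#' Read detections from a JSON-lines file
#'
#' One image per line: `{"image": id, "gt": [{"x":..,"y":..,"width":..,
#' "height":..}, ...], "pred": [{.., "score":..}, ...]}`.
#'
#' @param path file path.
#' @return per-image list of `list(image, gt, pred)`.
#' @export
read_detections_jsonl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyDataFrame = FALSE)
    list(image = o$image,
         gt = lapply(o$gt %||% list(), .as_box),
         pred = lapply(o$pred %||% list(), .as_box))
  })
}

#' Write detections to a JSON-lines file
#' @param dets per-image list of `list(image, gt, pred)`.
#' @param path output path.
#' @export
write_detections_jsonl <- function(dets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (im in dets) {
    strip <- function(bs) lapply(bs, function(b)
      Filter(Negate(is.null), unclass(.as_box(b))))
    writeLines(jsonlite::toJSON(
      list(image = im$image %||% NA, gt = strip(im$gt %||% list()),
           pred = strip(im$pred %||% list())),
      auto_unbox = TRUE, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Published per-environment detection counts
#'
#' Reference counts of flower heads detected under nine unstructured field
#' environments (three illumination, three overlap, three occlusion levels):
#' total flowers, correctly identified, falsely identified, and missed.
#' Useful as worked input for [rate_metrics()].
#'
#' @return data frame with columns `environment`, `total`, `correct`,
#'   `false_det`, `missed`.
#' @export
environment_counts <- function() {
  data.frame(
    environment = c("strong_light", "weak_light", "normal_light",
                    "high_overlap", "moderate_overlap", "normal_overlap",
                    "high_occlusion", "moderate_occlusion",
                    "normal_occlusion"),
    total = c(6511L, 10162L, 18686L, 5249L, 11892L, 17443L, 7811L, 12162L,
              19299L),
    correct = c(5021L, 8786L, 17458L, 4167L, 10420L, 16499L, 6284L, 10661L,
                18147L),
    false_det = c(686L, 857L, 988L, 379L, 659L, 419L, 729L, 630L, 648L),
    missed = c(804L, 519L, 240L, 703L, 813L, 525L, 798L, 890L, 504L))
}
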