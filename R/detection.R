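# Detection-evaluation calculus: IoU, greedy confidence-ordered matching,
# precision/recall/F1, all-point-interpolated AP50, and the field-test
# miss/false accounting.

.check_boxes <- function(boxes, conf = FALSE, arg = "boxes") {
  need <- c("class_id", "cx", "cy", "w", "h")
  if (conf) need <- c(need, "conf")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop(sprintf("%s must be a data.frame with columns %s", arg,
                 paste(need, collapse = ", ")))
  if (nrow(boxes)) {
    if (any(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1))
      stop(sprintf("%s: centers must lie in [0, 1]", arg))
    if (any(boxes$w <= 0 | boxes$h <= 0 | boxes$w > 1 | boxes$h > 1))
      stop(sprintf("%s: box sizes must lie in (0, 1]", arg))
    if (conf && any(boxes$conf < 0 | boxes$conf > 1))
      stop(sprintf("%s: confidences must lie in [0, 1]", arg))
  }
  invisible(boxes)
}

#' Construct ground-truth or detection box tables
#'
#' Boxes follow the YOLO convention: normalized center \code{(cx, cy)} and
#' size \code{(w, h)} in [0, 1], origin at the top-left of the image.
#' Detections additionally carry a confidence in [0, 1].
#'
#' @param class_id integer class labels.
#' @param cx,cy,w,h normalized box geometry.
#' @param conf detection confidences (for \code{detectionBoxes}).
#' @return a validated data.frame.
#' @export
yoloBoxes <- function(class_id, cx, cy, w, h) {
  .check_boxes(data.frame(class_id = as.integer(class_id),
                          cx = cx, cy = cy, w = w, h = h))
}

#' @rdname yoloBoxes
#' @export
detectionBoxes <- function(class_id, cx, cy, w, h, conf) {
  .check_boxes(data.frame(class_id = as.integer(class_id),
                          cx = cx, cy = cy, w = w, h = h, conf = conf),
               conf = TRUE)
}

# Corner coordinates (x1, y1, x2, y2) from a box table.
.corners <- function(b) {
  cbind(b$cx - b$w / 2, b$cy - b$h / 2, b$cx + b$w / 2, b$cy + b$h / 2)
}

#' Intersection over Union of two boxes
#'
#' @param a,b single boxes: length-4 numeric \code{c(cx, cy, w, h)} or
#'   one-row box data.frames.
#' @return overlap area divided by union area, in [0, 1]; 0 when disjoint.
#' @export
iou <- function(a, b) {
  cv <- function(z) if (is.data.frame(z)) c(z$cx[1], z$cy[1], z$w[1], z$h[1])
                    else as.numeric(z)
  a <- cv(a); b <- cv(b)
  iw <- min(a[1] + a[3] / 2, b[1] + b[3] / 2) -
        max(a[1] - a[3] / 2, b[1] - b[3] / 2)
  ih <- min(a[2] + a[4] / 2, b[2] + b[4] / 2) -
        max(a[2] - a[4] / 2, b[2] - b[4] / 2)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# Dense IoU matrix between two box tables (rows: first table).
.iou_matrix <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(matrix(0, nrow(a), nrow(b)))
  ca <- .corners(a); cb <- .corners(b)
  iw <- outer(ca[, 3], cb[, 3], pmin) - outer(ca[, 1], cb[, 1], pmax)
  ih <- outer(ca[, 4], cb[, 4], pmin) - outer(ca[, 2], cb[, 2], pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  uni <- outer(a$w * a$h, b$w * b$h, "+") - inter
  inter / uni
}

#' @describeIn matchDetections construct an [EvalCounts-class] directly.
#' @param tp,fp,fn non-negative counts.
#' @export
evalCounts <- function(tp, fp, fn) {
  new("EvalCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn))
}

#' @describeIn matchDetections true-positive count.
#' @param x an \code{EvalCounts}.
#' @export
truePositives <- function(x) x@tp

#' @describeIn matchDetections false-positive count.
#' @export
falsePositives <- function(x) x@fp

#' @describeIn matchDetections false-negative (missed) count.
#' @export
falseNegatives <- function(x) x@fn

setMethod("show", "EvalCounts", function(object) {
  cat(sprintf("EvalCounts: TP = %d, FP = %d, FN = %d\n",
              object@tp, object@fp, object@fn))
})

#' Match detections to ground truth
#'
#' Greedy confidence-ordered one-to-one matching at a fixed IoU threshold:
#' detections are visited in descending confidence (ties keep input order);
#' each claims the not-yet-matched ground-truth box of the same class with
#' the highest IoU, provided that IoU reaches \code{iouThr} (IoU ties go to
#' the lower ground-truth index). Unclaimed detections are false positives;
#' unclaimed ground truths are false negatives.
#'
#' @param dets detection table (see [detectionBoxes()]).
#' @param gts ground-truth table (see [yoloBoxes()]).
#' @param iouThr IoU threshold in (0, 1]; default 0.5.
#' @return list with \code{counts} (an [EvalCounts-class]) and
#'   \code{matches}, a data.frame of matched (det, gt, iou) index pairs.
#' @export
matchDetections <- function(dets, gts, iouThr = 0.5) {
  .check_boxes(dets, conf = TRUE, arg = "dets")
  .check_boxes(gts, arg = "gts")
  if (iouThr <= 0 || iouThr > 1) stop("iouThr must lie in (0, 1]")
  nd <- nrow(dets); ng <- nrow(gts)
  m <- .iou_matrix(dets, gts)
  ord <- order(-dets$conf)           # stable: confidence ties keep input order
  gtFree <- rep(TRUE, ng)
  matches <- list()
  for (di in ord) {
    if (!ng) break
    cand <- which(gtFree & gts$class_id == dets$class_id[di] &
                  m[di, ] >= iouThr)
    if (!length(cand)) next
    gi <- cand[which.max(m[di, cand])]  # which.max: first max = lowest index
    gtFree[gi] <- FALSE
    matches[[length(matches) + 1L]] <- data.frame(det = di, gt = gi,
                                                  iou = m[di, gi])
  }
  matches <- if (length(matches)) do.call(rbind, matches)
             else data.frame(det = integer(), gt = integer(), iou = numeric())
  tp <- nrow(matches)
  list(counts = evalCounts(tp, nd - tp, ng - tp), matches = matches)
}

#' Precision, recall and F1
#'
#' The basic detection identities: precision \code{tp / (tp + fp)} is the
#' fraction of predicted seedlings that are real; recall \code{tp / (tp + fn)}
#' the fraction of real seedlings found; F1 their harmonic mean
#' \code{2PR / (P + R)} (0 when \code{P + R = 0}). Degenerate denominators
#' return 0.
#'
#' @param tp,fp,fn counts, or (for \code{f1Score}) precision and recall.
#' @return a value in [0, 1].
#' @export
precisionScore <- function(tp, fp) if (tp + fp == 0) 0 else tp / (tp + fp)

#' @rdname precisionScore
#' @export
recallScore <- function(tp, fn) if (tp + fn == 0) 0 else tp / (tp + fn)

#' @rdname precisionScore
#' @param p,r precision and recall in [0, 1].
#' @export
f1Score <- function(p, r) {
  if (any(c(p, r) < 0 | c(p, r) > 1)) stop("p and r must lie in [0, 1]")
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Average precision at a fixed IoU threshold
#'
#' All-point interpolated AP: detections are ranked by confidence, flagged
#' TP/FP by greedy matching against same-class ground truth at \code{iouThr},
#' the precision-recall staircase is traced, precision is replaced by its
#' monotone (running-maximum from the right) envelope, and the envelope is
#' integrated over recall. \code{map50} averages AP over the classes present
#' in the ground truth; with a single class it equals \code{ap50}.
#'
#' @inheritParams matchDetections
#' @return list with \code{perClass} (named AP per ground-truth class) and
#'   \code{map} (their mean).
#' @export
averagePrecision <- function(dets, gts, iouThr = 0.5) {
  .check_boxes(dets, conf = TRUE, arg = "dets")
  .check_boxes(gts, arg = "gts")
  if (!nrow(gts)) stop("average precision is undefined without ground truth")
  classes <- sort(unique(gts$class_id))
  ap <- vapply(classes, function(cl) {
    g <- gts[gts$class_id == cl, , drop = FALSE]
    d <- dets[dets$class_id == cl, , drop = FALSE]
    if (!nrow(d)) return(0)
    ord <- order(-d$conf)
    d <- d[ord, , drop = FALSE]
    m <- .iou_matrix(d, g)
    gtFree <- rep(TRUE, nrow(g))
    tpFlag <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      cand <- which(gtFree & m[i, ] >= iouThr)
      if (length(cand)) {
        gi <- cand[which.max(m[i, cand])]
        gtFree[gi] <- FALSE
        tpFlag[i] <- TRUE
      }
    }
    tpc <- cumsum(tpFlag)
    rec <- tpc / nrow(g)
    prec <- tpc / seq_along(tpc)
    # monotone precision envelope, integrated over recall increments
    env <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * env)
  }, numeric(1))
  names(ap) <- classes
  list(perClass = ap, map = mean(ap))
}

# Round half away from zero to `digits` decimals (matches hand-rounded
# percentage tables; R's round() would round half to even).
.round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Field-test detection accounting
#'
#' Converts matcher counts on a field test set into the quantities a field
#' trial reports: the number of targets the model drew boxes for
#' (\code{detected = (nGt - fn) + fp}), the number and rate of missed
#' targets, and the number and rate of false detections. Rates are
#' percentages of the ground-truth total, rounded half-up to 1 decimal
#' place.
#'
#' @param nGt total ground-truth targets in the test set (> 0).
#' @param counts an [EvalCounts-class] with \code{tp + fn == nGt}.
#' @return list with \code{nGt}, \code{detected}, \code{missed},
#'   \code{falseDets}, \code{missedRate}, \code{falseRate} (rates in %).
#' @examples
#' fieldCounts(930, evalCounts(tp = 824, fp = 9, fn = 106))
#' @export
fieldCounts <- function(nGt, counts) {
  if (nGt <= 0) stop("nGt must be positive")
  if (counts@tp + counts@fn != nGt)
    stop("tp + fn must equal nGt")
  list(
    nGt = as.integer(nGt),
    detected = as.integer((nGt - counts@fn) + counts@fp),
    missed = counts@fn,
    falseDets = counts@fp,
    missedRate = .round_half_up(100 * counts@fn / nGt, 1),
    falseRate = .round_half_up(100 * counts@fp / nGt, 1)
  )
}

#' Read a prediction file
#'
#' One detection per line: \code{class conf cx cy w h}, whitespace
#' separated, coordinates YOLO-normalized.
#'
#' @param path prediction text file.
#' @return a detection data.frame (see [detectionBoxes()]).
#' @export
readPredictions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep))
    return(detectionBoxes(integer(), numeric(), numeric(), numeric(),
                          numeric(), numeric()))
  rows <- lapply(keep, function(i) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 6L)
      stop(sprintf("%s:%d: expected 6 fields 'class conf cx cy w h'",
                   path, i))
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)))
      stop(sprintf("%s:%d: non-numeric field", path, i))
    vals
  })
  m <- do.call(rbind, rows)
  detectionBoxes(m[, 1], m[, 3], m[, 4], m[, 5], m[, 6], m[, 2])
}

#' Evaluate detections over a set of images
#'
#' Pools per-image greedy matching into aggregate counts, precision, recall,
#' F1, AP at the threshold (detections ranked by confidence across images,
#' each matched only within its own image), and the field accounting of
#' [fieldCounts()].
#'
#' @param gtList,detList parallel lists of per-image ground-truth and
#'   detection tables.
#' @param iouThr IoU threshold; default 0.5.
#' @return list with \code{counts}, \code{precision}, \code{recall},
#'   \code{f1}, \code{ap50}, \code{field}.
#' @export
evalDetections <- function(gtList, detList, iouThr = 0.5) {
  stopifnot(length(gtList) == length(detList))
  nImg <- length(gtList)
  nGt <- sum(vapply(gtList, nrow, integer(1)))
  if (!nGt) stop("no ground-truth boxes to evaluate against")
  tp <- fp <- 0L
  pooled <- list()
  for (i in seq_len(nImg)) {
    res <- matchDetections(detList[[i]], gtList[[i]], iouThr)
    tp <- tp + res$counts@tp
    fp <- fp + res$counts@fp
    d <- detList[[i]]
    if (nrow(d)) {
      hit <- logical(nrow(d))
      hit[res$matches$det] <- TRUE
      pooled[[length(pooled) + 1L]] <- data.frame(conf = d$conf, tp = hit)
    }
  }
  counts <- evalCounts(tp, fp, nGt - tp)
  p <- precisionScore(tp, fp)
  r <- recallScore(tp, nGt - tp)
  ap <- 0
  if (length(pooled)) {
    all <- do.call(rbind, pooled)
    all <- all[order(-all$conf), , drop = FALSE]
    tpc <- cumsum(all$tp)
    rec <- tpc / nGt
    prec <- tpc / seq_along(tpc)
    env <- rev(cummax(rev(prec)))
    ap <- sum(diff(c(0, rec)) * env)
  }
  list(counts = counts, precision = p, recall = r, f1 = f1Score(p, r),
       ap50 = ap, field = fieldCounts(nGt, counts))
}
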