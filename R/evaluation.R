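#' Match detected centers to ground-truth centers
#'
#' One-to-one nearest-neighbor matching: all detection-truth pairs within
#' `max_dist` are considered in ascending distance order (ties broken by
#' truth index, then detection index, for determinism) and accepted greedily,
#' each detection and each truth matching at most once. Matched pairs are
#' true positives; unmatched detections are false positives; unmatched truths
#' are false negatives.
#'
#' @param detected Matrix or data.frame of detected centers (one row per
#'   detection; coordinate columns only).
#' @param truth Matrix or data.frame of ground-truth centers, same coordinate
#'   convention and column order as `detected`.
#' @param max_dist Maximum matching distance in voxels (> 0).
#' @return List with `tp`, `fp`, `fn` and `matches` (data.frame with columns
#'   `detection`, `truth`, `distance`).
#' @export
match_centers <- function(detected, truth, max_dist) {
  stopifnot(max_dist > 0)
  det <- as.matrix(detected)
  tru <- as.matrix(truth)
  nd <- nrow(det)
  nt <- nrow(tru)
  matches <- data.frame(detection = integer(0), truth = integer(0),
                        distance = numeric(0))
  if (nd > 0 && nt > 0) {
    stopifnot(ncol(det) == ncol(tru))
    dmat <- sqrt(outer(rowSums(det^2), rep(1, nt)) +
                 outer(rep(1, nd), rowSums(tru^2)) -
                 2 * det %*% t(tru))
    cand <- which(dmat <= max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      dists <- dmat[cand]
      ord <- order(dists, cand[, 2], cand[, 1])
      used_d <- logical(nd)
      used_t <- logical(nt)
      for (k in ord) {
        i <- cand[k, 1]
        j <- cand[k, 2]
        if (used_d[i] || used_t[j]) next
        used_d[i] <- TRUE
        used_t[j] <- TRUE
        matches <- rbind(matches,
                         data.frame(detection = i, truth = j,
                                    distance = dmat[i, j]))
      }
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fp = nd - tp, fn = nt - tp, matches = matches)
}

#' Detection-quality metrics
#'
#' Precision, recall, F-measure and Jaccard index from true-positive,
#' false-positive and false-negative counts:
#' \deqn{Pr = TP/(TP+FP), \quad Re = TP/(TP+FN),}
#' \deqn{F = 2 Pr Re/(Pr+Re), \quad J = Pr Re/(Pr + Re - Pr Re).}
#' Metrics whose defining ratio is 0/0 are reported as `NA` (flagged
#' undefined), never silently as 0. Alternatively, supply `precision` and
#' `recall` directly to evaluate only the derived `F` and `J`.
#'
#' @param tp,fp,fn Non-negative counts.
#' @param precision,recall Optional: supply rates instead of counts.
#' @return An object of class `evaluation_report` with fields `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f_measure`, `jaccard`, `undefined`.
#' @examples
#' r <- compute_metrics(precision = 0.93, recall = 0.98)
#' round(c(r$f_measure, r$jaccard), 2)  # 0.95 0.91
#' @export
compute_metrics <- function(tp = NULL, fp = NULL, fn = NULL,
                            precision = NULL, recall = NULL) {
  if (is.null(precision) != is.null(recall))
    stop("supply both precision and recall, or neither", call. = FALSE)
  if (!is.null(precision)) {
    stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
    pr <- precision
    re <- recall
    tp <- fp <- fn <- NA_integer_
  } else {
    stopifnot(tp >= 0, fp >= 0, fn >= 0)
    pr <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    re <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  }
  f <- j <- NA_real_
  if (!is.na(pr) && !is.na(re)) {
    if (pr + re > 0) {
      f <- 2 * pr * re / (pr + re)
      j <- pr * re / (pr + re - pr * re)
    } else {
      f <- 0
      j <- 0
    }
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, precision = pr, recall = re,
         f_measure = f, jaccard = j,
         undefined = c(precision = is.na(pr), recall = is.na(re))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA (undefined)" else sprintf("%.4f", v)
  cat("<evaluation_report>\n")
  if (!is.na(x$tp))
    cat(sprintf("  TP=%d FP=%d FN=%d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision=%s recall=%s F=%s Jaccard=%s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$f_measure),
              fmt(x$jaccard)))
  invisible(x)
}

#' Score detections against ground-truth centers
#'
#' Convenience wrapper: extracts centers from a [detect()] result (or a
#' detections data.frame) and a truth table, matches them with
#' [match_centers()], and computes the metrics. Coordinates are taken from
#' the shared columns among `z`, `y`, `x` so the CSV schemas of the pipeline
#' and the phantom generator align automatically.
#'
#' @param detections A `detection_result`, or a data.frame with center
#'   columns `x`, `y`(, `z`).
#' @param truth Data.frame with center columns (`z`, `y`, `x` order is fine)
#'   and optionally `r0`.
#' @param max_dist Matching cutoff; default the mean true radius (requires a
#'   `r0` column in `truth`).
#' @return An `evaluation_report` with the match list attached as `matches`.
#' @export
evaluate_detections <- function(detections, truth, max_dist = NULL) {
  det <- if (inherits(detections, "detection_result")) detections$detections
         else detections
  axes <- intersect(c("x", "y", "z"), intersect(names(det), names(truth)))
  if (!length(axes))
    stop("no shared coordinate columns between detections and truth",
         call. = FALSE)
  if (is.null(max_dist)) {
    if (is.null(truth$r0))
      stop("max_dist not given and truth has no r0 column", call. = FALSE)
    max_dist <- mean(truth$r0)
  }
  m <- match_centers(det[, axes, drop = FALSE], truth[, axes, drop = FALSE],
                     max_dist)
  rep <- compute_metrics(tp = m$tp, fp = m$fp, fn = m$fn)
  rep$matches <- m$matches
  rep$max_dist <- max_dist
  rep
}
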