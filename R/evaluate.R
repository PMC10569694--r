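# Instance-level scoring of machine counts against ground truth: one-to-one
# matching (centroid distance or volume overlap) and precision/recall/F1.

truth_centroids <- function(truth) {
  if (inherits(truth, "ground_truth")) return(truth$centroids)
  if (inherits(truth, "instance_labels")) return(instance_centroids(truth))
  stopf("`truth` must be a ground_truth or instance_labels object")
}

truth_instances <- function(truth) {
  if (inherits(truth, "ground_truth")) truth$instances else truth
}

#' Match predicted instances to ground-truth instances
#'
#' Centroid criterion: greedy nearest-first one-to-one matching of predicted
#' to truth centroids with physical distance <= `tol` (default: the mean
#' truth nucleus radius -- point-based counting validation). Overlap
#' criterion: greedy one-to-one matching by intersection-over-union >= `tol`
#' (default 0.3).
#'
#' @param pred an [instance_labels()] object.
#' @param truth a `ground_truth` or [instance_labels()] object on the same
#'   grid.
#' @param criterion `"centroid"` or `"overlap"`.
#' @param tol matching tolerance (um for centroid, IoU for overlap).
#' @return object of class `match_result`: `TP`, `FP`, `FN`, `pairs`
#'   (data.frame `pred`, `truth`, `score`), `criterion`, `tol`.
#' @export
match_instances <- function(pred, truth, criterion = c("centroid", "overlap"),
                            tol = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(pred, "instance_labels"))
  ti <- truth_instances(truth)
  if (!identical(dim(pred$labels), dim(ti$labels)) ||
      !isTRUE(all.equal(pred$spacing, ti$spacing)))
    stopf("prediction and truth grids differ in shape or spacing")

  if (criterion == "centroid") {
    if (is.null(tol)) {
      if (inherits(truth, "ground_truth")) tol <- mean(truth$radii_um)
      else stopf("centroid matching against instance_labels needs an explicit `tol`")
    }
    pc <- instance_centroids(pred)
    tc <- truth_centroids(truth)
    np <- nrow(pc); nt <- nrow(tc)
    cand <- NULL
    if (np && nt) {
      d2 <- outer(rowSums(pc^2), rowSums(tc^2), `+`) - 2 * pc %*% t(tc)
      d <- sqrt(pmax(d2, 0))
      hit <- which(d <= tol, arr.ind = TRUE)
      if (nrow(hit))
        cand <- data.frame(pred = hit[, 1], truth = hit[, 2],
                           score = d[hit])
    }
    pairs <- greedy_match(cand, np, nt, decreasing = FALSE)
  } else {
    tol <- tol %||% 0.3
    np <- pred$n; nt <- ti$n
    cand <- NULL
    if (np && nt) {
      sel <- pred$labels > 0L & ti$labels > 0L
      if (any(sel)) {
        tab <- table(pred = pred$labels[sel], truth = ti$labels[sel])
        hit <- which(tab > 0, arr.ind = TRUE)
        p_id <- as.integer(rownames(tab))[hit[, 1]]
        t_id <- as.integer(colnames(tab))[hit[, 2]]
        inter <- tab[hit]
        iou <- inter / (pred$voxel_counts[p_id] + ti$voxel_counts[t_id] - inter)
        ok <- iou >= tol
        if (any(ok))
          cand <- data.frame(pred = p_id[ok], truth = t_id[ok], score = iou[ok])
      }
    }
    pairs <- greedy_match(cand, np, nt, decreasing = TRUE)
  }
  structure(list(TP = nrow(pairs), FP = np_count(pred) - nrow(pairs),
                 FN = nt_count(truth) - nrow(pairs), pairs = pairs,
                 criterion = criterion, tol = tol),
            class = "match_result")
}

np_count <- function(pred) pred$n
nt_count <- function(truth) {
  if (inherits(truth, "ground_truth")) truth$count else truth$n
}

# one-to-one greedy matching over a candidate table, best score first
greedy_match <- function(cand, np, nt, decreasing) {
  empty <- data.frame(pred = integer(0), truth = integer(0), score = numeric(0))
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- cand[order(cand$score, cand$pred, cand$truth,
                     decreasing = c(decreasing, FALSE, FALSE), method = "radix"), ]
  used_p <- logical(np); used_t <- logical(nt)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$pred[i]; t <- cand$truth[i]
    if (!used_p[p] && !used_t[t]) {
      used_p[p] <- TRUE; used_t[t] <- TRUE; keep[i] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (%s matching, tol %.3g)\n",
              x$TP, x$FP, x$FN, x$criterion, x$tol))
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' @param match a `match_result` (or any list with `TP`, `FP`, `FN`).
#' @return named numeric vector `(precision, recall, f1)`; all zero (with a
#'   warning) when no instances exist on either side.
#' @export
f1_score <- function(match) {
  TP <- match$TP; FP <- match$FP; FN <- match$FN
  if (TP + FP + FN == 0L) {
    warnf("no predicted or true instances; precision/recall/F1 reported as 0")
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = F1)
}
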