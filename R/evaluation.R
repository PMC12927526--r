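check_same_shape <- function(gt, pred) {
  dg <- dim(gt$labels); dp <- dim(pred$labels)
  if (!identical(dg, dp))
    stop(sprintf("grid shapes differ: gt (z,y,x) = %s, pred = %s",
                 paste(dg, collapse = "x"), paste(dp, collapse = "x")),
         call. = FALSE)
}

#' Voxel-level semantic accuracy
#'
#' Binarizes both volumes (any positive label is foreground) and counts
#' voxels as TP (foreground in both), FP (predicted foreground only) or FN
#' (ground-truth foreground only). Semantic accuracy is
#' `TP / (TP + FP + FN)` — a Jaccard-style score insensitive to how the
#' foreground is partitioned into instances. When both foregrounds are
#' empty the score is 1 (nothing to find, nothing found).
#'
#' @param gt,pred [instance_volume()]s on identical grids.
#' @return List with `tp_vox`, `fp_vox`, `fn_vox`, `accuracy_sem`.
#' @export
semantic_accuracy <- function(gt, pred) {
  stopifnot(inherits(gt, "instance_volume"), inherits(pred, "instance_volume"))
  check_same_shape(gt, pred)
  g <- gt$labels > 0L; p <- pred$labels > 0L
  tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p)
  acc <- if (tp + fp + fn == 0L) 1 else tp / (tp + fp + fn)
  list(tp_vox = tp, fp_vox = fp, fn_vox = fn, accuracy_sem = acc)
}

#' Dense ground-truth x prediction IoU matrix
#'
#' Computes `|g intersect p| / |g union p|` over voxels for every pair of a
#' ground-truth and a predicted instance, via a single sparse overlap pass
#' (only co-foreground voxels are tabulated; non-overlapping pairs are 0).
#'
#' @inheritParams semantic_accuracy
#' @return An object of class `iou_table`: list with sorted `gt_ids`,
#'   `pred_ids`, the `|G| x |P|` matrix `iou` (rows = gt), and the instance
#'   size vectors `gt_sizes`, `pred_sizes`.
#' @export
iou_table <- function(gt, pred) {
  stopifnot(inherits(gt, "instance_volume"), inherits(pred, "instance_volume"))
  check_same_shape(gt, pred)
  gt_ids <- instance_ids(gt); pred_ids <- instance_ids(pred)
  gs <- instance_sizes(gt); ps <- instance_sizes(pred)
  iou <- matrix(0, nrow = length(gt_ids), ncol = length(pred_ids),
                dimnames = list(gt_ids, pred_ids))
  both <- gt$labels > 0L & pred$labels > 0L
  if (any(both) && length(gt_ids) && length(pred_ids)) {
    inter <- table(factor(gt$labels[both], levels = gt_ids),
                   factor(pred$labels[both], levels = pred_ids))
    inter <- unclass(inter)
    uni <- outer(unname(gs[as.character(gt_ids)]),
                 unname(ps[as.character(pred_ids)]), `+`) - inter
    iou[] <- ifelse(inter > 0, inter / uni, 0)
  }
  structure(list(gt_ids = gt_ids, pred_ids = pred_ids, iou = iou,
                 gt_sizes = gs, pred_sizes = ps),
            class = "iou_table")
}

# Optimal one-to-one assignment maximizing total score on a rectangular
# matrix (rows gt, cols pred). Returns integer vector over rows: matched
# column index or NA. Uses the Hungarian solver on a zero-padded square
# matrix; rows/columns are already in sorted id order, which fixes the
# solver's tie-breaking deterministically.
solve_assignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  sq <- matrix(0, n, n)
  sq[seq_len(nr), seq_len(nc)] <- score
  sol <- as.integer(clue::solve_LSAP(sq, maximum = TRUE))
  ans <- sol[seq_len(nr)]
  ans[ans > nc] <- NA_integer_
  ans
}

#' Match predicted to ground-truth instances at an IoU threshold
#'
#' Hungarian (optimal one-to-one) assignment maximizing total IoU over the
#' full rectangular matrix, followed by thresholding: assigned pairs with
#' IoU >= `tau` are true positives; sub-threshold pairs are discarded, so
#' their members join the unmatched sets. Unmatched predictions are false
#' positives, unmatched ground-truth instances false negatives. IoU exactly
#' equal to `tau` counts as matched.
#'
#' @param table an [iou_table()].
#' @param tau IoU acceptance threshold in (0, 1]; default 0.5.
#' @param premask if TRUE, entries below `tau` are zeroed *before* solving
#'   (an alternative formulation some toolkits use); default FALSE =
#'   assign first, threshold after.
#' @return An object of class `match_result`: list with `tau`, `matches`
#'   (data.frame gt_id, pred_id, iou), `unmatched_gt`, `unmatched_pred`,
#'   and counts `tp`, `fp`, `fn`.
#' @export
match_instances <- function(table, tau = 0.5, premask = FALSE) {
  stopifnot(inherits(table, "iou_table"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("`tau` must be a single number in (0, 1]", call. = FALSE)
  score <- table$iou
  if (premask) score[score < tau] <- 0
  assign <- solve_assignment(score)
  gi <- which(!is.na(assign))
  ious <- if (length(gi)) table$iou[cbind(gi, assign[gi])] else numeric(0)
  keep <- ious >= tau & ious > 0
  gi <- gi[keep]
  pj <- assign[which(!is.na(assign))][keep]
  matches <- data.frame(gt_id = table$gt_ids[gi],
                        pred_id = table$pred_ids[pj],
                        iou = ious[keep])
  if (nrow(matches) > 1L)
    matches <- matches[order(matches$gt_id, matches$pred_id), , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(
    tau = tau,
    matches = matches,
    unmatched_gt = setdiff(table$gt_ids, matches$gt_id),
    unmatched_pred = setdiff(table$pred_ids, matches$pred_id),
    tp = nrow(matches),
    fp = length(setdiff(table$pred_ids, matches$pred_id)),
    fn = length(setdiff(table$gt_ids, matches$gt_id))
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tau = %g\n", x$tau))
  cat(sprintf("  TP = %d   FP = %d   FN = %d   accuracy = %.4f\n",
              x$tp, x$fp, x$fn, instance_accuracy(x)))
  invisible(x)
}

#' Instance-level accuracy of a match result
#'
#' `TP / (TP + FP + FN)` over instances. With no ground truth and no
#' predictions the score is 1; an empty ground truth with predictions (or
#' the reverse) scores 0.
#'
#' @param match a [match_instances()] result.
#' @return Numeric in \[0, 1\].
#' @export
instance_accuracy <- function(match) {
  stopifnot(inherits(match, "match_result"))
  denom <- match$tp + match$fp + match$fn
  if (denom == 0L) 1 else match$tp / denom
}

size_bin_labels <- function(edges) {
  edges <- sort(unique(c(0, edges)))
  upper <- c(edges[-1], Inf)
  lab <- sprintf("[%s,%s)", format(edges, trim = TRUE, scientific = FALSE),
                 ifelse(is.finite(upper), format(upper, trim = TRUE, scientific = FALSE), "Inf"))
  list(edges = edges, labels = unique(lab))
}

bin_of <- function(sizes, edges) findInterval(sizes, edges)

#' Evaluate a predicted instance volume against ground truth
#'
#' Runs the two-tier protocol: voxel-level semantic accuracy (foreground
#' Jaccard after binarization) and instance-level accuracy from Hungarian
#' matching at IoU threshold `tau`. Optionally stratifies the instance
#' counts by voxel-count bins: a matched pair or a false negative is binned
#' by the ground-truth instance's size (ground truth defines the reference
#' population); an unmatched prediction by its own size.
#'
#' @inheritParams semantic_accuracy
#' @param tau IoU threshold, default 0.5 (the "Accuracy@50" setting).
#' @param size_bins numeric vector of lower bin edges in voxels, or NULL
#'   (no stratification). `c(500, 5000, 50000)` gives bins
#'   (0,500), \[500,5000), \[5000,50000), \[50000,Inf).
#' @param premask see [match_instances()].
#' @return An object of class `evaluation_report`: `semantic` (voxel
#'   counts + accuracy), `instance` (tp/fp/fn, accuracy, tau), `match`
#'   (the `match_result`), optional `strata` data.frame, and `settings`.
#' @examples
#' lab <- array(0L, c(6, 6, 6)); lab[2:4, 2:4, 2:4] <- 1L
#' v <- instance_volume(lab)
#' evaluate(v, v)$instance$accuracy_inst  # 1
#' @export
evaluate <- function(gt, pred, tau = 0.5, size_bins = NULL, premask = FALSE) {
  sem <- semantic_accuracy(gt, pred)
  tab <- iou_table(gt, pred)
  m <- match_instances(tab, tau = tau, premask = premask)
  inst <- list(tp_inst = m$tp, fp_inst = m$fp, fn_inst = m$fn,
               accuracy_inst = instance_accuracy(m), tau = tau)
  strata <- NULL
  if (!is.null(size_bins)) {
    bins <- size_bin_labels(size_bins)
    nb <- length(bins$labels)
    tp <- fp <- fn <- integer(nb)
    if (nrow(m$matches) > 0L) {
      b <- bin_of(tab$gt_sizes[as.character(m$matches$gt_id)], bins$edges)
      for (i in b) tp[i] <- tp[i] + 1L
    }
    for (id in m$unmatched_gt) {
      b <- bin_of(tab$gt_sizes[as.character(id)], bins$edges); fn[b] <- fn[b] + 1L
    }
    for (id in m$unmatched_pred) {
      b <- bin_of(tab$pred_sizes[as.character(id)], bins$edges); fp[b] <- fp[b] + 1L
    }
    strata <- data.frame(bin = bins$labels, tp = tp, fp = fp, fn = fn,
                         accuracy_inst = ifelse(tp + fp + fn == 0L, 1,
                                                tp / pmax(tp + fp + fn, 1L)))
  }
  structure(list(semantic = sem, instance = inst, match = m, strata = strata,
                 settings = list(tau = tau, premask = premask,
                                 size_bins = size_bins,
                                 gt = gt$name, pred = pred$name)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> gt = %s, pred = %s\n",
              x$settings$gt, x$settings$pred))
  cat(sprintf("  semantic : TP %d  FP %d  FN %d  accuracy %.4f\n",
              x$semantic$tp_vox, x$semantic$fp_vox, x$semantic$fn_vox,
              x$semantic$accuracy_sem))
  cat(sprintf("  instance : TP %d  FP %d  FN %d  accuracy %.4f  (tau = %g)\n",
              x$instance$tp_inst, x$instance$fp_inst, x$instance$fn_inst,
              x$instance$accuracy_inst, x$instance$tau))
  if (!is.null(x$strata)) {
    cat("  size-stratified instance accuracy:\n")
    print(x$strata, row.names = FALSE)
  }
  invisible(x)
}

#' Instance accuracy across a range of IoU thresholds
#'
#' Re-uses one IoU table across thresholds. Instance accuracy is
#' non-increasing in `tau`: raising the bar can only demote matches.
#'
#' @inheritParams evaluate
#' @param taus strictly increasing thresholds in (0, 1].
#' @return data.frame with columns `tau`, `tp`, `fp`, `fn`,
#'   `accuracy_inst`.
#' @export
sweep_tau <- function(gt, pred, taus = c(0.25, 0.5, 0.75), premask = FALSE) {
  if (is.unsorted(taus, strictly = TRUE))
    stop("`taus` must be strictly increasing", call. = FALSE)
  tab <- iou_table(gt, pred)
  rows <- lapply(taus, function(t) {
    m <- match_instances(tab, tau = t, premask = premask)
    data.frame(tau = t, tp = m$tp, fp = m$fp, fn = m$fn,
               accuracy_inst = instance_accuracy(m))
  })
  do.call(rbind, rows)
}

#' Pool evaluation reports across volumes
#'
#' Multi-volume scores: either pool TP/FP/FN across volumes before the
#' ratio (default) or average the per-volume accuracies.
#'
#' @param reports list of `evaluation_report`s.
#' @param mode "pooled" (sum counts, then ratio) or "mean" (average
#'   per-volume accuracies).
#' @return List with `accuracy_sem`, `accuracy_inst`, the pooled counts and
#'   `mode`.
#' @export
aggregate_evaluations <- function(reports, mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, logical(1), "evaluation_report")))
  sem <- vapply(reports, function(r) unlist(r$semantic[c("tp_vox", "fp_vox", "fn_vox")]),
                numeric(3))
  ins <- vapply(reports, function(r) unlist(r$instance[c("tp_inst", "fp_inst", "fn_inst")]),
                numeric(3))
  pooled_sem <- rowSums(sem); pooled_ins <- rowSums(ins)
  ratio <- function(v) if (sum(v) == 0) 1 else v[[1]] / sum(v)
  if (mode == "pooled") {
    acc_sem <- ratio(pooled_sem); acc_ins <- ratio(pooled_ins)
  } else {
    acc_sem <- mean(vapply(reports, function(r) r$semantic$accuracy_sem, numeric(1)))
    acc_ins <- mean(vapply(reports, function(r) r$instance$accuracy_inst, numeric(1)))
  }
  list(accuracy_sem = acc_sem, accuracy_inst = acc_ins,
       tp_vox = pooled_sem[[1]], fp_vox = pooled_sem[[2]], fn_vox = pooled_sem[[3]],
       tp_inst = pooled_ins[[1]], fp_inst = pooled_ins[[2]], fn_inst = pooled_ins[[3]],
       mode = mode, n_volumes = length(reports))
}

#' Per-instance match table of an evaluation
#'
#' Flat CSV-ready table: one row per ground-truth or predicted instance
#' with its match status (TP rows carry both ids and the IoU; FN rows only
#' the gt id; FP rows only the pred id).
#'
#' @param report an `evaluation_report`.
#' @return data.frame with columns gt_id, pred_id, iou, status.
#' @export
match_table <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  m <- report$match
  tp <- if (nrow(m$matches)) cbind(m$matches, status = "TP") else NULL
  fn <- if (length(m$unmatched_gt))
    data.frame(gt_id = m$unmatched_gt, pred_id = NA_integer_,
               iou = NA_real_, status = "FN") else NULL
  fp <- if (length(m$unmatched_pred))
    data.frame(gt_id = NA_integer_, pred_id = m$unmatched_pred,
               iou = NA_real_, status = "FP") else NULL
  out <- rbind(tp, fn, fp)
  if (is.null(out))
    out <- data.frame(gt_id = integer(0), pred_id = integer(0),
                      iou = numeric(0), status = character(0))
  rownames(out) <- NULL
  out
}
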