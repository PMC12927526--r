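two_cube_merge <- function() {
  # two 4x4x4 gt cubes (64 voxels each); prediction merges them into one
  gt <- array(0L, c(6, 12, 6))
  gt[2:5, 2:5, 2:5] <- 1L
  gt[2:5, 6:9, 2:5] <- 2L
  pred <- array(0L, dim(gt))
  pred[gt > 0L] <- 7L
  list(gt = instance_volume(gt, name = "gt"),
       pred = instance_volume(pred, name = "merged"))
}

test_that("semantic accuracy counts voxels after binarization", {
  v <- random_label_volume(seed = 3L)
  expect_equal(semantic_accuracy(v, v)$accuracy_sem, 1)

  # disjoint nonempty foregrounds
  a <- array(0L, c(4, 4, 4)); a[1, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[4, 4, 4] <- 5L
  expect_equal(semantic_accuracy(instance_volume(a), instance_volume(b))$accuracy_sem, 0)

  # 100 gt voxels, pred covers 80 plus 20 background voxels
  gt <- array(0L, c(10, 10, 10)); gt[1:4, 1:5, 1:5] <- 1L  # 100 voxels
  pred <- array(0L, c(10, 10, 10))
  pred[1:4, 1:4, 1:5] <- 2L                                # 80 TP
  pred[6:9, 1, 1:5] <- 2L                                  # 20 FP
  s <- semantic_accuracy(instance_volume(gt), instance_volume(pred))
  expect_equal(s$tp_vox, 80); expect_equal(s$fp_vox, 20); expect_equal(s$fn_vox, 20)
  expect_equal(s$accuracy_sem, 80 / 120)

  # both empty is perfect; one-sided empty is 0
  e <- instance_volume(array(0L, c(3, 3, 3)))
  expect_equal(semantic_accuracy(e, e)$accuracy_sem, 1)
  expect_equal(semantic_accuracy(v, instance_volume(array(0L, dim(v$labels))))$accuracy_sem, 0)
  expect_error(semantic_accuracy(v, e), "shapes differ")
})

test_that("IoU table equals per-pair set arithmetic", {
  # one 64-voxel gt cube, prediction shifted to overlap half of it
  gt <- array(0L, c(8, 12, 8)); gt[2:5, 2:5, 2:5] <- 1L
  pred <- array(0L, dim(gt)); pred[2:5, 4:7, 2:5] <- 1L
  tab <- iou_table(instance_volume(gt), instance_volume(pred))
  expect_equal(unname(tab$iou[1, 1]), 32 / 96)

  v <- random_label_volume(seed = 10L)
  tab2 <- iou_table(v, v)
  expect_equal(unname(diag(tab2$iou)), rep(1, length(tab2$gt_ids)))

  # no overlap anywhere
  a <- array(0L, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1L
  b <- array(0L, c(4, 4, 4)); b[3:4, 3:4, 3:4] <- 3L
  tab3 <- iou_table(instance_volume(a), instance_volume(b))
  expect_true(all(tab3$iou == 0))

  # exhaustive pairwise check on a random pair of volumes
  g <- random_label_volume(seed = 11L)
  p <- random_label_volume(seed = 12L)
  tab4 <- iou_table(g, p)
  for (i in seq_along(tab4$gt_ids)) for (j in seq_along(tab4$pred_ids)) {
    A <- g$labels == tab4$gt_ids[i]; B <- p$labels == tab4$pred_ids[j]
    expect_equal(unname(tab4$iou[i, j]), sum(A & B) / sum(A | B))
  }
})

test_that("Hungarian matching maximizes total IoU (vs enumeration) and applies tau", {
  set.seed(202)
  for (trial in 1:60) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    iou <- matrix(runif(nr * nc), nr, nc)
    iou[runif(nr * nc) < 0.4] <- 0
    m <- match_instances(make_iou_fixture(iou), tau = 1e-9)
    expect_equal(sum(m$matches$iou), oracle_best_total(iou), tolerance = 1e-12)
    # partition identities
    expect_equal(nrow(m$matches) + length(m$unmatched_gt), nr)
    expect_equal(nrow(m$matches) + length(m$unmatched_pred), nc)
    expect_true(!anyDuplicated(m$matches$gt_id) && !anyDuplicated(m$matches$pred_id))
  }
})

test_that("the two-cube merge yields TP=1, FP=0, FN=1 at tau = 0.5", {
  cc <- two_cube_merge()
  tab <- iou_table(cc$gt, cc$pred)
  expect_equal(sort(unname(tab$iou[, 1])), c(0.5, 0.5))  # 64 / 128 each
  m <- match_instances(tab, tau = 0.5)
  expect_equal(m$tp, 1); expect_equal(m$fp, 0); expect_equal(m$fn, 1)
  expect_equal(instance_accuracy(m), 0.5)  # IoU exactly tau counts as matched
  # at tau = 0.75 the match is discarded entirely
  m75 <- match_instances(tab, tau = 0.75)
  expect_equal(m75$tp, 0); expect_equal(m75$fp, 1); expect_equal(m75$fn, 2)
  expect_equal(instance_accuracy(m75), 0)
})

test_that("identity and relabeled predictions score 1.0 at both tiers", {
  v <- random_label_volume(seed = 33L)
  r <- evaluate(v, v)
  expect_equal(r$semantic$accuracy_sem, 1)
  expect_equal(r$instance$accuracy_inst, 1)

  ids <- instance_ids(v)
  perm <- setNames(rev(100L + seq_along(ids)), ids)
  lab2 <- v$labels
  lab2[v$labels > 0L] <- perm[as.character(v$labels[v$labels > 0L])]
  r2 <- evaluate(v, instance_volume(lab2, name = "relabel"))
  expect_equal(r2$semantic$accuracy_sem, 1)
  expect_equal(r2$instance$accuracy_inst, 1)
})

test_that("metrics are invariant to label permutation on both sides", {
  g <- random_label_volume(seed = 41L)
  p <- random_label_volume(seed = 42L)
  base <- evaluate(g, p)
  permute <- function(v, offset) {
    ids <- instance_ids(v)
    perm <- setNames(offset + sample(seq_along(ids)), ids)
    lab <- v$labels
    lab[v$labels > 0L] <- perm[as.character(v$labels[v$labels > 0L])]
    instance_volume(lab, name = paste0(v$name, "-perm"))
  }
  set.seed(5)
  r <- evaluate(permute(g, 300L), permute(p, 600L))
  expect_equal(r$semantic, base$semantic)
  expect_equal(r$instance, base$instance)
})

test_that("instance accuracy handles degenerate inputs as documented", {
  e <- instance_volume(array(0L, c(4, 4, 4)))
  r <- evaluate(e, e)
  expect_equal(r$instance$accuracy_inst, 1)
  expect_equal(r$semantic$accuracy_sem, 1)
  v <- random_label_volume(seed = 50L)
  expect_equal(evaluate(instance_volume(array(0L, dim(v$labels))), v)$instance$accuracy_inst, 0)
})

test_that("tau sweep is non-increasing and re-derives the merge case", {
  cc <- two_cube_merge()
  sw <- sweep_tau(cc$gt, cc$pred, c(0.25, 0.5, 0.75))
  expect_equal(sw$accuracy_inst[sw$tau == 0.5], 0.5)
  expect_equal(sw$accuracy_inst[sw$tau == 0.75], 0)
  expect_true(all(diff(sw$accuracy_inst) <= 0))

  v <- random_label_volume(seed = 60L)
  sw2 <- sweep_tau(v, v, c(0.25, 0.5, 0.75, 0.99))
  expect_true(all(sw2$accuracy_inst == 1))

  g <- random_label_volume(seed = 61L)
  p <- random_label_volume(seed = 62L)
  sw3 <- sweep_tau(g, p, seq(0.1, 0.9, by = 0.2))
  expect_true(all(diff(sw3$accuracy_inst) <= 0))
  expect_error(sweep_tau(g, p, c(0.5, 0.25)), "increasing")
})

test_that("size stratification bins by gt size for TP/FN and pred size for FP", {
  # small gt (27 vox) dropped; large gt (1000 vox) kept; small spurious pred
  gt <- array(0L, c(20, 20, 20))
  gt[1:3, 1:3, 1:3] <- 1L          # 27 voxels -> bin (0, 50)
  gt[6:15, 6:15, 6:15] <- 2L       # 1000 voxels -> bin [50, Inf)
  pred <- array(0L, dim(gt))
  pred[6:15, 6:15, 6:15] <- 9L     # matches gt 2
  pred[17:19, 17:19, 1:3] <- 4L    # 27-voxel spurious blob
  r <- evaluate(instance_volume(gt), instance_volume(pred), size_bins = 50)
  expect_equal(r$strata$tp, c(0, 1))
  expect_equal(r$strata$fn, c(1, 0))
  expect_equal(r$strata$fp, c(1, 0))
  expect_equal(r$strata$accuracy_inst, c(0, 1))
  # overall counts agree with the strata totals
  expect_equal(sum(r$strata$tp), r$instance$tp_inst)
  expect_equal(sum(r$strata$fp), r$instance$fp_inst)
  expect_equal(sum(r$strata$fn), r$instance$fn_inst)
})

test_that("multi-volume aggregation pools counts or averages accuracies", {
  cc <- two_cube_merge()
  v <- random_label_volume(seed = 70L)
  reps <- list(evaluate(cc$gt, cc$pred), evaluate(v, v))
  pooled <- aggregate_evaluations(reps, "pooled")
  expect_equal(pooled$tp_inst, 1 + length(instance_ids(v)))
  expect_equal(pooled$accuracy_inst,
               pooled$tp_inst / (pooled$tp_inst + pooled$fp_inst + pooled$fn_inst))
  avg <- aggregate_evaluations(reps, "mean")
  expect_equal(avg$accuracy_inst, mean(c(0.5, 1)))
})

test_that("match tables carry one row per instance with its status", {
  cc <- two_cube_merge()
  tab <- match_table(evaluate(cc$gt, cc$pred))
  expect_equal(sort(tab$status), c("FN", "TP"))
  expect_equal(nrow(tab), 2)
})
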