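test_that("reindexing maps labels to consecutive ids in scan order", {
  a <- array(0L, c(2, 2, 2)); a[1, 1, 1] <- 7L; a[2, 2, 2] <- 42L
  res <- reindex_instances(instance_volume(a))
  expect_equal(res$id_map, data.frame(old = c(7L, 42L), new = 1:2))
  expect_equal(instance_ids(res$volume), 1:2)

  # already-consecutive ids in scan order: identity map
  b <- array(0L, c(3, 3, 3)); b[1, 1, 1] <- 1L; b[3, 3, 3] <- 2L
  res2 <- reindex_instances(instance_volume(b))
  expect_equal(res2$id_map$old, res2$id_map$new)
  expect_identical(res2$volume$labels, b)
})

test_that("reindexing preserves the voxel partition", {
  v <- random_label_volume(seed = 15L)
  res <- reindex_instances(v)
  lut <- setNames(res$id_map$new, res$id_map$old)
  expect_identical(res$volume$labels == 0L, v$labels == 0L)
  for (i in seq_len(nrow(res$id_map)))
    expect_identical(res$volume$labels == res$id_map$new[i],
                     v$labels == res$id_map$old[i])
})

test_that("minimum-volume filtering keeps exactly the instances at or above the cut", {
  # sizes 499 / 500 / 501 in separate corners of one volume
  lab <- array(0L, c(30, 30, 30))
  lab[1:10, 1:10, 1:5] <- 1L; lab[cbind(1, 1, 5)] <- 0L        # 499
  lab[1:10, 1:10, 11:15] <- 2L                                  # 500
  lab[1:10, 1:10, 21:25] <- 3L; lab[11, 1, 21] <- 3L            # 501
  v <- instance_volume(lab)
  expect_equal(unname(instance_sizes(v)), c(499L, 500L, 501L))

  res <- filter_min_volume(v, 500L)
  expect_equal(instance_ids(res$volume), c(2L, 3L))
  expect_equal(res$log$instances_before, 3)
  expect_equal(res$log$instances_after, 2)
  expect_equal(res$log$removed$instance_id, 1L)
  expect_equal(res$log$removed$voxel_count, 499L)

  # min_voxels = 1 is the identity
  res1 <- filter_min_volume(v, 1L)
  expect_identical(res1$volume$labels, v$labels)
})

test_that("filtering matches the size histogram tail and is idempotent", {
  v <- random_label_volume(c(24L, 24L, 24L), k = 8L, seed = 31L)
  cut <- 60L
  sizes <- instance_sizes(v)
  res <- filter_min_volume(v, cut)
  expect_equal(length(instance_ids(res$volume)), sum(sizes >= cut))
  res2 <- filter_min_volume(res$volume, cut)
  expect_identical(res2$volume$labels, res$volume$labels)
  expect_equal(nrow(res2$log$removed), 0)
})

test_that("filter and reindex commute up to the final id assignment", {
  v <- random_label_volume(c(24L, 24L, 24L), k = 8L, seed = 32L)
  cut <- 40L
  a <- reindex_instances(filter_min_volume(v, cut)$volume)$volume
  b <- filter_min_volume(reindex_instances(v)$volume, cut)$volume
  expect_identical(a$labels == 0L, b$labels == 0L)
  # identical partitions: co-membership agrees on every foreground pair
  fa <- a$labels[a$labels > 0L]; fb <- b$labels[b$labels > 0L]
  expect_identical(outer(fa, fa, `==`), outer(fb, fb, `==`))
})

test_that("image resampling is the identity at the source spacing", {
  set.seed(4)
  img <- image_volume(array(rnorm(10^3), c(10L, 10L, 10L)), spacing = c(16, 16, 16))
  out <- resample_image(img, c(16, 16, 16))
  expect_equal(out$intensities, img$intensities, tolerance = 1e-12)
})

test_that("constant volumes stay constant under 2x downsampling", {
  img <- image_volume(array(3.25, c(16L, 16L, 16L)), spacing = c(8, 8, 8))
  out <- resample_image(img, 16)
  expect_equal(dim(out$intensities), c(8L, 8L, 8L))
  expect_equal(out$spacing, c(16, 16, 16))
  expect_true(max(abs(out$intensities - 3.25)) < 1e-9)
})

test_that("anti-aliasing attenuates energy above the new Nyquist", {
  # pure sinusoid along x above the post-downsampling Nyquist frequency
  n <- 64L
  x <- seq_len(n)
  sig <- sin(2 * pi * 0.4 * x)  # 0.4 cycles/voxel > 0.25 (Nyquist after 2x)
  arr <- array(rep(sig, each = 4 * 4), c(4L, 4L, n))
  img <- image_volume(aperm(arr, c(1, 2, 3)), spacing = c(8, 8, 8))
  with_aa <- resample_image(img, c(8, 8, 16), antialias = TRUE)
  without <- resample_image(img, c(8, 8, 16), antialias = FALSE)
  energy <- function(v) {
    line <- v$intensities[1, 1, ]
    spec <- Mod(fft(line - mean(line)))^2
    sum(spec)
  }
  # sigma = 0.5 at 0.4 cycles/voxel attenuates amplitude by roughly half,
  # so well under half the aliased energy should survive
  expect_lt(energy(with_aa), 0.5 * energy(without))
})

test_that("label resampling introduces no new labels and follows geometry", {
  # half/half two-label volume, 2x downsample
  lab <- array(0L, c(8, 8, 8)); lab[, 1:4, ] <- 1L; lab[, 5:8, ] <- 2L
  v <- instance_volume(lab, spacing = c(8, 8, 8))
  out <- resample_labels(v, 16)
  expect_equal(dim(out$labels), c(4L, 4L, 4L))
  expect_setequal(instance_ids(out), 1:2)
  expect_true(all(out$labels[, 1:2, ] == 1L))
  expect_true(all(out$labels[, 3:4, ] == 2L))

  # identity spacing
  out_id <- resample_labels(v, c(8, 8, 8))
  expect_identical(out_id$labels, v$labels)

  # random volumes: label set inclusion over seeds
  for (seed in 1:6) {
    r <- random_label_volume(c(20L, 20L, 20L), k = 6L, seed = seed)
    rs <- resample_labels(instance_volume(r$labels, c(8, 8, 8)), 16)
    expect_true(all(instance_ids(rs) %in% instance_ids(r)))
  }
  expect_error(resample_labels(v, c(-1, 8, 8)), "positive")
})

test_that("majority-vote label resampling picks the modal block label", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1:2, 1:2] <- 1L   # fills one 2x2x2 block exactly
  lab[3, 3, 3] <- 2L         # minority voxel in an otherwise background block
  v <- instance_volume(lab, spacing = c(8, 8, 8))
  out <- resample_labels(v, 16, method = "majority")
  expect_equal(dim(out$labels), c(2L, 2L, 2L))
  expect_equal(out$labels[1, 1, 1], 1L)
  expect_equal(out$labels[2, 2, 2], 0L)  # background outvotes the single voxel
})

test_that("topology checks flag only multi-component instances", {
  v <- random_label_volume(c(16L, 16L, 16L), k = 4L, seed = 90L)
  rep <- check_topology(v)
  for (i in seq_len(nrow(rep)))
    expect_equal(rep$n_components[i],
                 oracle_components(v$labels == rep$instance_id[i]))

  lab <- array(0L, c(10, 10, 10))
  lab[1:2, 1:2, 1:2] <- 1L
  lab[8:9, 8:9, 8:9] <- 1L  # same id, two distant blobs
  lab[5, 5, 5] <- 2L
  flagged <- check_topology(instance_volume(lab))
  expect_equal(flagged$flagged, c(TRUE, FALSE))
  expect_equal(flagged$n_components[1], 2)
})

test_that("standardization logs serialize to JSON", {
  v <- random_label_volume(seed = 91L)
  res <- filter_min_volume(v, 30L)
  path <- tempfile(fileext = ".json")
  write_std_log(res$log, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$operation, "filter_min_volume")
  expect_equal(back$instances_before, res$log$instances_before)
})
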