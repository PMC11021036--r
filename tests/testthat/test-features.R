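test_that("seed detection finds blobs, ignores gradients, and skips flat images", {
  expect_equal(nrow(detect_seeds(matrix(5, 64, 64))), 0)

  img <- matrix(0, 64, 64)
  blob <- function(r0, c0, a = 10, s2 = 4)
    a * exp(-((row(img) - r0)^2 + (col(img) - c0)^2) / (2 * s2))
  img2 <- img + blob(20, 30) + blob(20, 40)
  seeds <- detect_seeds(img2, min_score = 0.5)
  expect_equal(nrow(seeds), 2)
  found <- seeds[order(seeds$col), ]
  expect_lte(max(abs(found$row - c(20, 20))), 1)
  expect_lte(max(abs(found$col - c(30, 40))), 1)

  # bright smooth gradient: removed by background estimation
  grad <- matrix(seq(0, 40, length.out = 64), 64, 64, byrow = TRUE)
  seeds3 <- detect_seeds(grad + blob(32, 32), min_score = 0.5)
  expect_equal(nrow(seeds3), 1)
  expect_lte(abs(seeds3$row - 32) + abs(seeds3$col - 32), 2)
  # without background subtraction the gradient hides no local max offset:
  # the raw image's maximum sits on the bright edge, not the blob
  expect_false(which.max(grad + blob(32, 32)) ==
                 which.max(blob(32, 32)))
})

test_that("neighborhood correlation maps equal a brute-force Pearson loop", {
  g <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                n_spines = 3L, noise_sd = 2), seed = 6)
  seed <- round(g$truth$spine_centroids[2, ])
  cmap <- neighborhood_correlation_map(g$stack, seed, radius = 6)
  expect_equal(cmap, oracle_corr_map(g$stack, seed, 6), tolerance = 1e-10)
  expect_equal(cmap[seed[1], seed[2]], 1)
  # shared vs independent transients separate cleanly
  m <- g$truth$spine_masks[[2]]
  expect_gt(mean(cmap[m & cmap != 0]), 0.8)
  other <- round(g$truth$spine_centroids[1, ])
  expect_error(neighborhood_correlation_map(
    tstack(array(1, dim = c(50, 8, 8))), c(4, 4), 2), "constant")
})

test_that("spine segmentation recovers isolated spines and rejects by size", {
  g <- make_dendrite_movie(list(n_frames = 300L, height = 64L, width = 64L,
                                n_spines = 3L, noise_sd = 2), seed = 12)
  seed <- round(g$truth$spine_centroids[1, ])
  roi <- segment_spine(g$stack, seed, dendrite_width = 3)
  expect_s3_class(roi, "SpineROI")
  truth_mask <- g$truth$spine_masks[[1]]
  iou <- sum(roi$mask & truth_mask) / sum(roi$mask | truth_mask)
  expect_gte(iou, 0.5)
  expect_true(roi$mask[seed[1], seed[2]])

  # a shaft seed shares the global bAP transient along the shaft, so its
  # component grows elongated and exceeds the size ceiling
  shaft_seed <- round(dendromap:::polyline_point_at(g$truth$dendrite_path,
                                                    20))
  res <- segment_spine(g$stack, shaft_seed, dendrite_width = 3,
                       size_bounds = c(4, 30))
  expect_s3_class(res, "roi_rejection")
  expect_match(res$reason, "size|area|component")

  # vacuous bounds never reject for size
  ok <- segment_spine(g$stack, seed, dendrite_width = 3,
                      size_bounds = c(0, Inf))
  expect_s3_class(ok, "SpineROI")
})

test_that("dendrite proximity gating applies the 3x-width rule exactly", {
  dd <- build_dendrite(rbind(c(30, 5), c(30, 60)), width = 4, c(64, 64))
  sp <- function(r, c) {
    m <- matrix(FALSE, 64, 64); m[r, c] <- TRUE
    dendromap:::spine_roi(1L, m, seed = c(r, c))
  }
  kept <- filter_by_dendrite_proximity(list(sp(42, 30)), dd, 3)   # d = 12.0
  expect_length(kept, 1)
  expect_equal(kept[[1]]$parent_dendrite, 1L)
  near_miss <- sp(42, 30); near_miss$centroid <- c(42.1, 30)      # d = 12.1
  expect_length(filter_by_dendrite_proximity(list(near_miss), dd, 3), 0)
  # factor 0 keeps only centroids on the polyline
  expect_length(filter_by_dendrite_proximity(list(sp(30, 20)), dd, 0), 1)
  expect_length(filter_by_dendrite_proximity(list(sp(31, 20)), dd, 0), 0)
  # distances match a dense point-to-segment oracle
  path <- rbind(c(10, 10), c(30, 40), c(50, 45))
  set.seed(5)
  for (i in 1:10) {
    pt <- c(runif(1, 1, 64), runif(1, 1, 64))
    expect_equal(
      dendromap:::point_polyline_distance(matrix(pt, 1), path),
      oracle_point_polyline(pt, path), tolerance = 1e-5)
  }
})

test_that("dendrite ROIs rasterize a band with correct arc length", {
  dd <- build_dendrite(rbind(c(20, 10), c(20, 59)), width = 4, c(64, 64))
  expect_equal(dd$arc_length, 49)
  expect_true(all(dd$mask[19:22, 10:59]))
  expect_false(any(dd$mask[c(1:17, 24:64), ]))
  expect_error(build_dendrite(rbind(c(20, 10)), 4, c(64, 64)),
               "2 points")
  path <- rbind(c(5, 5), c(20, 30), c(40, 31))
  dd2 <- build_dendrite(path, 3, c(64, 64))
  expect_equal(dd2$arc_length,
               sum(sqrt(rowSums(diff(path)^2))), tolerance = 1e-9)
  expect_error(build_dendrite(rbind(c(0, 5), c(20, 30)), 3, c(64, 64)),
               "outside")
})

test_that("even subdivision tiles the dendrite without overlap", {
  dd <- build_dendrite(rbind(c(32, 5), c(32, 105)), width = 4, c(64, 128))
  subs <- subdivide_dendrite(dd, 25)
  expect_length(subs, 4)
  subs2 <- subdivide_dendrite(dd, 30)
  expect_length(subs2, 4)
  expect_equal(subs2[[4]]$span, c(90, 100))
  un <- Reduce(`|`, lapply(subs, function(s) s$mask))
  expect_equal(un, dd$mask)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(subs[[i]]$mask & subs[[j]]$mask))
})

test_that("shaft-by-spine centers the span at the nearest arc position", {
  dd <- build_dendrite(rbind(c(32, 10), c(32, 110)), width = 4, c(64, 128))
  m <- matrix(FALSE, 64, 128); m[40, 60] <- TRUE
  sp <- dendromap:::spine_roi(3L, m, seed = c(40, 60),
                              parent_dendrite = 1L)
  sr <- shaft_by_spine(dd, sp, 20)
  expect_equal(sr$span, c(40, 60))
  expect_equal(sr$linked_spine, 3L)
  # brute-force nearest arc position
  arcs <- seq(0, dd$arc_length, by = 0.01)
  pts <- dendromap:::polyline_point_at(dd$path, arcs)
  d2 <- (pts[, 1] - 40)^2 + (pts[, 2] - 60)^2
  expect_equal(mean(sr$span), arcs[which.min(d2)], tolerance = 0.01)
  # span clipped at the dendrite end
  m2 <- matrix(FALSE, 64, 128); m2[33, 108] <- TRUE
  sp2 <- dendromap:::spine_roi(4L, m2, parent_dendrite = 1L)
  sr2 <- shaft_by_spine(dd, sp2, 20)
  expect_equal(sr2$span[2], dd$arc_length)
  expect_gt(sr2$span[1], dd$arc_length - 20)
  sp2$parent_dendrite <- 9L
  expect_error(shaft_by_spine(dd, sp2, 20), "not linked")
})

test_that("trace extraction averages masks on the frame clock", {
  st <- tstack(array(runif(40 * 16 * 16), dim = c(40, 16, 16)))
  m1 <- matrix(FALSE, 16, 16); m1[5, 7] <- TRUE
  fmap <- feature_map(spines = list(dendromap:::spine_roi(1L, m1)),
                      image_dim = c(16, 16))
  ts <- extract_traces(st, fmap)
  expect_equal(ts$traces[1, ], st$data[, 5, 7])
  cst <- tstack(array(3, dim = c(10, 16, 16)))
  expect_true(all(extract_traces(cst, fmap)$traces == 3))
  # noiseless generator movie: spine trace = render of input + scale * bAP
  g <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                n_spines = 2L, noise_sd = 0), seed = 3)
  fm2 <- feature_map(
    spines = list(dendromap:::spine_roi(1L, g$truth$spine_masks[[1]])),
    image_dim = c(64, 64))
  tr <- extract_traces(g$stack, fm2)$traces[1, ]
  expected <- g$truth$per_spine_input_trace[1, ] +
    g$truth$bap_scale_per_spine[1] * g$truth$bap_trace
  # the mask-mean trace is an affine image of input + scale * bAP
  expect_gt(stats::cor(tr, expected), 0.999999)
})

test_that("master maps transfer across stacks and drop off-frame ROIs", {
  g <- make_dendrite_movie(list(n_frames = 200L, height = 64L, width = 64L,
                                n_spines = 3L, noise_sd = 0), seed = 13)
  fmap <- feature_map(
    spines = lapply(1:3, function(i)
      dendromap:::spine_roi(i, g$truth$spine_masks[[i]])),
    image_dim = c(64, 64))
  base <- extract_traces(g$stack, fmap)
  idres <- apply_master_map(fmap, g$stack)
  expect_equal(idres$trace_set$traces, base$traces)

  # translate the movie and the map together: traces are preserved
  shift <- c(4, -6)
  moved <- g$stack
  for (t in seq_len(n_frames(moved)))
    moved$data[t, , ] <- dendromap:::roll_matrix(frame_at(g$stack, t),
                                                 shift[1], shift[2])
  tf <- rigid_transform(0, shift)
  mvres <- apply_master_map(fmap, moved, tf)
  expect_equal(mvres$trace_set$traces, base$traces, tolerance = 1e-9)

  # a translation pushing one ROI off-frame excludes it, others intact
  toy <- toy_map(rbind(c(10, 10), c(30, 30), c(60, 60)), c(64, 64))
  part <- rigid_transform(0, c(10, 10))
  expect_warning(out <- apply_master_map(toy, g$stack, part), "excluded")
  expect_equal(length(out$feature_map$spines), 2)
  expect_equal(nrow(out$trace_set$traces), 2)
})

test_that("segmentation is deterministic and auto-detection hits precision/recall targets", {
  g <- make_dendrite_movie(list(n_spines = 12L, height = 96L, width = 128L,
                                noise_sd = 6), seed = 21)
  dd <- build_dendrite(g$truth$dendrite_path, g$truth$dendrite_width,
                       c(96, 128))
  fm1 <- detect_spines(g$stack, dendrite = dd)
  fm2 <- detect_spines(g$stack, dendrite = dd)
  expect_equal(lapply(fm1$spines, `[[`, "mask"),
               lapply(fm2$spines, `[[`, "mask"))
  iou <- function(a, b) sum(a & b) / sum(a | b)
  used <- rep(FALSE, 12); tp <- 0
  for (s in fm1$spines) {
    ious <- vapply(seq_len(12),
                   function(i) iou(s$mask, g$truth$spine_masks[[i]]),
                   numeric(1))
    j <- which.max(ious)
    if (ious[j] >= 0.3 && !used[j]) { tp <- tp + 1; used[j] <- TRUE }
    # proximity bound holds exactly for accepted spines
    d <- dendromap:::point_polyline_distance(matrix(s$centroid, 1),
                                             dd$path)
    expect_lte(d, 3 * dd$width)
  }
  expect_gte(tp / length(fm1$spines), 0.8)
  expect_gte(tp / 12, 0.5)
})
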