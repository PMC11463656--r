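test_that("component boxes have tight half-open extents", {
  m <- matrix(FALSE, 60, 60)
  m[8:27, 6:15] <- TRUE                       # 10 wide x 20 tall at (5, 7)
  b <- masks_to_boxes(m)
  expect_equal(unlist(b[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 5, ymin = 7, xmax = 15, ymax = 27))

  expect_equal(nrow(masks_to_boxes(matrix(FALSE, 10, 10))), 0)

  two <- disk_mask(100, 100, 20, 20, 8) | disk_mask(100, 100, 70, 70, 8)
  bt <- masks_to_boxes(two)
  expect_equal(nrow(bt), 2)
  for (k in 1:2) {
    d <- disk_mask(100, 100, c(20, 70)[k], c(20, 70)[k], 8)
    ext <- which(d, arr.ind = TRUE)
    row <- bt[order(bt$xmin), ][k, ]
    expect_equal(unlist(row[c("xmin", "ymin", "xmax", "ymax")]),
                 c(xmin = min(ext[, 2]) - 1, ymin = min(ext[, 1]) - 1,
                   xmax = max(ext[, 2]), ymax = max(ext[, 1])))
  }
})

test_that("box merging collapses proximity chains and is idempotent", {
  near <- bb(c(0, 100), c(0, 0), c(1, 101), c(1, 1))   # centres 100 apart
  m1 <- merge_boxes(near, 150)
  expect_equal(nrow(m1), 1)
  expect_equal(unlist(m1[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 0, ymin = 0, xmax = 101, ymax = 1))

  far <- bb(c(0, 200), c(0, 0), c(1, 201), c(1, 1))    # centres 200 apart
  expect_equal(nrow(merge_boxes(far, 150)), 2)

  # chain 0-140-280: transitive closure collapses all three
  chain <- bb(c(0, 140, 280), c(0, 0, 0), c(1, 141, 281), c(1, 1, 1))
  mc <- merge_boxes(chain, 150)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$xmax, 281)

  set.seed(12)
  for (rep in 1:5) {
    boxes <- random_boxes(8, lim = 400)
    once <- merge_boxes(boxes, 150)
    expect_equal(merge_boxes(once, 150), once)         # idempotent
  }
})

test_that("ground-truth boxes come from the mask extent in a window around each point", {
  m <- disk_mask(600, 600, 300, 300, 20)
  g <- gt_boxes_from_points(m, data.frame(x = 300, y = 300))
  expect_equal(unlist(g[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 280, ymin = 280, xmax = 321, ymax = 321))

  blank <- gt_boxes_from_points(matrix(FALSE, 600, 600),
                                data.frame(x = 300, y = 300))
  expect_equal(nrow(blank), 0)
  expect_equal(attr(blank, "empty_points"), 1L)

  # two points on one large component give one box each
  big <- matrix(FALSE, 600, 600); big[281:320, 101:500] <- TRUE
  g2 <- gt_boxes_from_points(big, data.frame(x = c(150, 450), y = c(300, 300)))
  expect_equal(nrow(g2), 2)
  expect_true(all(g2$ymin == 280 & g2$ymax == 320))
  expect_equal(g2$xmin, c(100, 250))          # each extent clipped to its window
})

test_that("greedy matching reproduces the brute-force pair ordering", {
  same <- bb(c(0, 50), c(0, 0), c(10, 60), c(10, 10))
  m <- match_boxes(same, same)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$iou == 1))
  expect_equal(length(m$fp) + length(m$fn), 0)

  # one gt, two overlapping preds: higher IOU wins, other is FP
  gt <- bb(0, 0, 10, 10)
  pred <- bb(c(0, 2), c(0, 0), c(10, 12), c(10, 10))
  m2 <- match_boxes(gt, pred)
  expect_equal(m2$pairs$pred, 1)
  expect_equal(m2$fp, 2L)

  set.seed(13)
  for (rep in 1:50) {
    g <- random_boxes(5); p <- random_boxes(5)
    mine <- match_boxes(g, p, min_iou = 0.001)
    ref <- brute_greedy_match(g, p, min_iou = 0.001)
    expect_equal(nrow(mine$pairs), ref$n_match)
    expect_equal(length(mine$fp), ref$fp)
    expect_equal(length(mine$fn), ref$fn)
    if (ref$n_match > 0)
      expect_equal(sort(mine$pairs$iou), sort(ref$pairs$iou), tolerance = 1e-12)
  }

  # sum rule: TP + FP = #pred, TP + FN = #gt
  g <- random_boxes(7); p <- random_boxes(4)
  mm <- match_boxes(g, p)
  expect_equal(nrow(mm$pairs) + length(mm$fp), 4)
  expect_equal(nrow(mm$pairs) + length(mm$fn), 7)

  # min_iou = 0 admits any strictly positive overlap
  tiny <- match_boxes(bb(0, 0, 100, 100), bb(99, 99, 199, 199), min_iou = 0)
  expect_equal(nrow(tiny$pairs), 1)
  none <- match_boxes(bb(0, 0, 10, 10), bb(50, 50, 60, 60), min_iou = 0)
  expect_equal(nrow(none$pairs), 0)
})

test_that("object precision/recall/F1 derive from the match counts", {
  g <- bb(c(0, 100, 200, 300), c(0, 0, 0, 0), c(10, 110, 210, 310),
          c(10, 10, 10, 10))
  p <- bb(c(0, 100, 200, 500), c(0, 0, 0, 0), c(10, 110, 210, 510),
          c(10, 10, 10, 10))
  s <- object_prf(match_boxes(g, p))
  expect_equal(c(s$precision, s$recall, s$f1), c(0.75, 0.75, 0.75))

  perfect <- object_prf(match_boxes(g, g))
  expect_equal(perfect$f1, 1)

  expect_warning(nop <- object_prf(match_boxes(g, g[0, ])), "precision")
  expect_equal(c(nop$precision, nop$recall), c(0, 0))
})

test_that("NMS keeps the highest-confidence box per overlap group", {
  dup <- bb(c(0, 0), c(0, 0), c(10, 10), c(10, 10), conf = c(0.9, 0.8))
  kept <- nms(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$confidence, 0.9)

  disjoint <- bb(c(0, 50), c(0, 0), c(10, 60), c(10, 10), conf = c(0.3, 0.9))
  expect_equal(nrow(nms(disjoint)), 2)

  set.seed(14)
  for (rep in 1:5) {
    boxes <- random_boxes(10, lim = 60, conf = TRUE)
    expect_equal(nms(boxes, 0.4), brute_nms(boxes, 0.4))
  }
  expect_error(nms(bb(0, 0, 1, 1)), "confidence")
})

test_that("average precision matches the hand-enumerated PR staircase", {
  gt <- bb(c(0, 20, 40), c(0, 20, 40), c(10, 30, 50), c(10, 30, 50))
  pred <- bb(c(0, 21, 60, 40), c(0, 21, 60, 41), c(10, 31, 70, 50),
             c(10, 31, 70, 51), conf = c(0.9, 0.8, 0.7, 0.6))
  # ranked TP, TP, FP, TP -> precision 1, 1, 2/3, 3/4; recall 1/3, 2/3, 2/3, 1
  # envelope 1, 1, 3/4, 3/4 -> AP = 1/3 + 1/3 + 0 + (1/3)(3/4) = 11/12
  res <- average_precision(gt, pred, iou_thresh = 0.5)
  expect_equal(res$ap, 11 / 12, tolerance = 1e-12)
  expect_equal(res$precision, c(1, 1, 2 / 3, 3 / 4))
  expect_equal(res$recall, c(1 / 3, 2 / 3, 2 / 3, 1))

  perfect <- average_precision(gt, cbind(gt[, 1:5], confidence = 0.9))
  expect_equal(perfect$ap, 1)

  expect_equal(average_precision(gt, gt[0, ])$ap, 0)
  expect_error(average_precision(gt[0, ], pred), "no ground-truth")

  # AP over 0.50:0.95 averages per-threshold APs
  expect_equal(average_precision_range(gt, pred),
               mean(vapply(seq(0.5, 0.95, 0.05), function(t)
                 average_precision(gt, pred, t)$ap, numeric(1))))
})

test_that("boxes are assigned to the tile containing their centre and clipped", {
  grid <- build_tile_grid(c(2048, 2048), NULL, tile = 1024, stride = 1024)
  overhang <- bb(900, 100, 1100, 200)         # centre (1000, 150) in tile (0,0)
  a <- assign_boxes_to_tiles(overhang, grid)
  expect_named(a, "x0_y0")
  expect_equal(a[["x0_y0"]]$xmax, 1024)       # clipped to the tile edge

  edge <- bb(1016, 0, 1032, 10)               # centre x = 1024, half-open
  e <- assign_boxes_to_tiles(edge, grid)
  expect_named(e, "x1024_y0")

  expect_equal(length(assign_boxes_to_tiles(bb(0, 0, 1, 1)[0, ], grid)), 0)
  outside <- bb(3000, 3000, 3010, 3010)
  expect_warning(o <- assign_boxes_to_tiles(outside, grid), "dropped")
  expect_equal(length(o), 0)
})

test_that("detection text files round-trip boxes in the [label x y x y] format", {
  boxes <- bb(c(5, 20), c(6, 21), c(15, 30), c(16, 31), conf = c(0.9, 0.4))
  f <- withr::local_tempfile(fileext = ".txt")
  write_detections(boxes, f, with_confidence = TRUE)
  lines <- readLines(f)
  expect_equal(length(lines), 2)
  expect_match(lines[1], "^0 5 6 15 16 0.9$")
  back <- read_detections(f)
  expect_equal(back$xmin, boxes$xmin)
  expect_equal(back$confidence, boxes$confidence)

  write_detections(boxes, f)                  # without confidence
  expect_true(all(is.na(read_detections(f)$confidence)))
  writeLines(character(0), f)
  expect_equal(nrow(read_detections(f)), 0)
})

test_that("classical pipeline boxes match point-bootstrapped gt boxes perfectly on clean scenes", {
  sc <- make_annotated_roi(4, 0, dims = c(1000, 1400), noise = 0, seed = 31,
                           gaussian_sd = 0)
  tiles <- points_to_masks(sc$rgb, sc$points)
  gt_mask <- stitch_masks(dim(sc$rgb)[1:2], tiles)
  gt_boxes <- gt_boxes_from_points(gt_mask$mask, sc$points)
  pred <- sliding_window_segment(sc$rgb, tile = 512)
  pred_boxes <- merge_boxes(masks_to_boxes(pred), 150)
  s <- object_prf(match_boxes(gt_boxes, pred_boxes, min_iou = 0.001))
  expect_equal(s$f1, 1)
})
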