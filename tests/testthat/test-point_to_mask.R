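test_that("tile crops centre the annotation and pad with white at borders", {
  set.seed(3)
  roi <- array(sample(0:254, 600 * 600 * 3, TRUE), c(600, 600, 3))
  storage.mode(roi) <- "integer"

  mid <- crop_tile(roi, c(300, 300))
  expect_equal(unname(mid$origin), c(100, 100))
  expect_equal(unname(mid$pad), c(0, 0, 0, 0))
  expect_equal(mid$rgb[201, 201, ], roi[301, 301, ])

  corner <- crop_tile(roi, c(0, 0))
  expect_equal(unname(corner$pad[c("left", "top")]), c(200, 200))
  expect_true(all(corner$rgb[1:200, , ] == 255))
  expect_true(all(corner$rgb[, 1:200, ] == 255))
  expect_equal(corner$rgb[201, 201, ], roi[1, 1, ])

  for (p in list(c(47, 530), c(599, 1))) {
    cr <- crop_tile(roi, p)
    expect_equal(cr$rgb[201, 201, ], roi[p[2] + 1, p[1] + 1, ])
  }
  expect_error(crop_tile(roi, c(600, 10)), "outside")
})

test_that("centre-biased blob selection applies both rules with inclusive boundaries", {
  centered <- disk_mask(400, 400, 200, 200, 20)
  one <- select_center_blobs(centered)
  expect_identical(one$mask, centered)
  expect_equal(one$retained, 1L)

  # off-centre disk at distance 140 > 120 is removed
  two <- centered | disk_mask(400, 400, 200, 340, 20)
  sel <- select_center_blobs(two, center_bias = 120)
  expect_identical(sel$mask, centered)

  # centroid-distance boundary: exactly center_bias is retained ("within")
  for (d in c(119, 120, 121)) {
    m <- disk_mask(400, 400, 200, 200 + d, 10)
    r <- select_center_blobs(m, center_bias = 120)$retained
    expect_equal(r, if (d <= 120) 1L else 0L, info = paste("distance", d))
  }

  # size rule: strictly below size_frac * largest is removed
  mk_pair <- function(a_small) {
    big <- matrix(FALSE, 400, 400)
    big[181:220, 176:200] <- TRUE            # 40 x 25 = 1000 px at centre
    small <- matrix(FALSE, 400, 400)
    small[181:(180 + a_small %/% 20), 241:260] <- TRUE  # a_small px, 20 wide
    big | small
  }
  both <- select_center_blobs(mk_pair(500), center_bias = 120)
  expect_equal(both$retained, 2L)            # 500 >= 0.5 * 1000 kept
  onek <- select_center_blobs(mk_pair(480), center_bias = 120)
  expect_equal(onek$retained, 1L)            # 480 < 500 removed
  expect_equal(onek$largest_area, 1000L)

  # empty input is a valid empty result
  none <- select_center_blobs(matrix(FALSE, 400, 400))
  expect_equal(none$retained, 0L)
  expect_equal(sum(none$mask), 0)
})

test_that("increasing center_bias never decreases retained foreground", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(FALSE, 400, 400)
    for (k in 1:6) {
      cx <- sample(30:370, 1); cy <- sample(30:370, 1)
      m <- m | disk_mask(400, 400, cx, cy, sample(5:25, 1))
    }
    areas <- vapply(c(40, 80, 120, 200, 300),
                    function(cb) sum(select_center_blobs(m, cb)$mask),
                    numeric(1))
    expect_true(all(diff(areas) >= 0))
  }
})

test_that("point_to_mask recovers isolated tangles and flags blank points", {
  sc <- make_annotated_roi(1, 0, dims = c(800, 800), noise = 0, seed = 21,
                           gaussian_sd = 0)
  tm <- point_to_mask(sc$rgb, sc$points[1, ])
  placed <- stitch_masks(c(800, 800), list(tm))
  iou <- sum(placed$mask & sc$masks[[1]]) / sum(placed$mask | sc$masks[[1]])
  expect_gte(iou, 0.7)

  blank <- point_to_mask(render_scene(list(), c(800, 800), 0, 1)$rgb,
                         c(400, 400))
  expect_equal(blank$retained, 0L)

  # neighbour 250 px away: its blob centroid sits > 120 px from centre
  n1 <- object_spec(c(300, 400), c(40, 25), 0, 0, dab_od = 1)
  n2 <- object_spec(c(550, 400), c(40, 25), 0, 0, dab_od = 1)
  two <- render_scene(list(n1, n2), c(800, 800), noise = 0, seed = 2)
  tm2 <- point_to_mask(two$rgb, c(300, 400))
  placed2 <- stitch_masks(c(800, 800), list(tm2))
  expect_gt(sum(placed2$mask & two$masks[[1]]), 0)
  expect_equal(sum(placed2$mask & two$masks[[2]]), 0)
})

test_that("stitching is a clipped, order-independent union", {
  t1 <- list(mask = disk_mask(400, 400, 200, 200, 30), origin = c(0, 0), id = 1)
  t2 <- list(mask = disk_mask(400, 400, 200, 200, 30), origin = c(30, 0), id = 2)

  single <- stitch_masks(c(500, 500), list(t1))
  expect_equal(sum(single$mask), sum(t1$mask))

  # overlapping tiles: union = sum - intersection
  both <- stitch_masks(c(500, 500), list(t1, t2))
  shifted <- matrix(FALSE, 500, 500)
  shifted[1:400, 31:430] <- t2$mask
  base <- matrix(FALSE, 500, 500); base[1:400, 1:400] <- t1$mask
  k <- sum(base & shifted)
  expect_gt(k, 0)
  expect_equal(sum(both$mask), sum(t1$mask) + sum(t2$mask) - k)

  # order independence
  expect_identical(both$mask, stitch_masks(c(500, 500), list(t2, t1))$mask)

  # clipping at the ROI border drops out-of-frame foreground
  t3 <- list(mask = disk_mask(400, 400, 390, 200, 20), origin = c(450, 0), id = 3)
  clipped <- stitch_masks(c(500, 840), list(t3))
  expect_lt(sum(clipped$mask), sum(t3$mask))

  expect_equal(sum(stitch_masks(c(100, 100), list())$mask), 0)
  t_out <- list(mask = t1$mask, origin = c(600, 600), id = 4)
  expect_error(stitch_masks(c(500, 500), list(t_out)), "outside")
})

test_that("mask size report computes tile fractions and flags outliers", {
  mk <- function(area) {
    m <- matrix(FALSE, 400, 400)
    if (area > 0) m[seq_len(area)] <- TRUE
    list(mask = m, id = area, retained = as.integer(area > 0),
         largest_area = as.integer(area))
  }
  rep <- mask_size_report(list(mk(8800), mk(0), mk(160000)))
  expect_equal(rep$fraction, c(0.055, 0, 1))   # 8800 px = 5.5% of a tile
  expect_equal(attr(rep, "n_empty"), 1L)
  expect_equal(attr(rep, "n_oversize"), 1L)
  expect_true(rep$oversize[3])
})
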