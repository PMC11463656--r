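test_that("sliding-window segmentation covers the slide and respects the predictor contract", {
  blank <- render_scene(list(), dims = c(700, 900), noise = 0, seed = 1)
  seg <- sliding_window_segment(blank$rgb, tile = 512)
  expect_equal(dim(seg), c(700, 900))         # border tiles clipped to dims
  expect_equal(sum(seg), 0)

  sc <- make_annotated_roi(3, 0, dims = c(1100, 1100), noise = 0.005,
                           seed = 17, min_sep = 250, margin = 120)
  seg2 <- sliding_window_segment(sc$rgb, tile = 512)
  for (m in sc$masks) expect_gt(sum(seg2 & m), 0)  # each truth overlapped

  expect_error(sliding_window_segment(sc$rgb, tile = 512, stride = 256),
               "stride")
  bad <- structure(function(tile) matrix(0, 2, 2), class = "nft_predictor")
  expect_error(sliding_window_segment(sc$rgb, bad, tile = 512), "dims")
})

test_that("downscaled blob counting preserves separated blobs and fuses close ones", {
  expect_equal(count_blobs_downscaled(matrix(FALSE, 512, 512)), 0)

  # 10 blobs on a 3x4 grid, >= 128 px apart and 64+ px wide: all survive 1/64
  m <- matrix(FALSE, 1280, 1280)
  k <- 0
  for (r in 0:2) for (cc in 0:3) {
    if (k >= 10) break
    y0 <- 100 + r * 400; x0 <- 100 + cc * 300
    m[y0:(y0 + 70), x0:(x0 + 70)] <- TRUE
    k <- k + 1
  }
  expect_equal(count_blobs_downscaled(m, 64), 10)

  # two blobs 32 px apart fuse after 64x block-max reduction
  m2 <- matrix(FALSE, 512, 512)
  m2[100:160, 100:160] <- TRUE
  m2[100:160, 193:253] <- TRUE
  expect_equal(max(label_components(m2)), 2)
  expect_equal(count_blobs_downscaled(m2, 64), 1)

  # block-reduce oracles
  bm <- matrix(0, 8, 8); bm[1, 1] <- 1; bm[8, 8] <- 1
  expect_equal(block_reduce(bm, 4, "max"), matrix(c(1, 0, 0, 1), 2, 2))
  expect_equal(block_reduce(matrix(1:16, 4, 4), 2, "mean"),
               matrix(c(3.5, 5.5, 11.5, 13.5), 2, 2))
})

test_that("tissue detection recovers the rendered tissue fraction", {
  white <- array(255, c(256, 256, 3))
  expect_equal(tissue_mask(white, 32)$area, 0)

  sc <- make_annotated_roi(2, 0, dims = c(2048, 2048), noise = 0.01, seed = 23,
                           tissue_frac = 0.6, min_sep = 200, margin = 100)
  tm <- tissue_mask(sc$rgb, 64)
  frac <- tm$area / prod(dim(tm$mask))
  expect_gt(frac, 0.5)
  expect_lt(frac, 0.7)

  # background speckle barely moves the area
  noisier <- make_annotated_roi(2, 0, dims = c(2048, 2048), noise = 0.02,
                                seed = 23, tissue_frac = 0.6, min_sep = 200,
                                margin = 100)
  tm2 <- tissue_mask(noisier$rgb, 64)
  expect_lt(abs(tm2$area - tm$area) / tm$area, 0.05)
})

test_that("burden scores are linear in count, inverse in area, and rescale-invariant", {
  expect_equal(nft_detector_score(10, 2e6, 2e6), 10)
  expect_equal(nft_detector_score(0, 1e6, 2e6), 0)
  expect_equal(nft_detector_score(10, 2e6, 1e6),
               nft_detector_score(10, 4e6, 1e6) * 2)  # doubling area halves
  expect_equal(nft_detector_score(10, 2e6, 1e6),
               nft_detector_score(10, 2e6 * 3, 1e6 * 3))  # common rescale
  expect_equal(nft_detector_score(20, 2e6, 1e6),
               2 * nft_detector_score(10, 2e6, 1e6))  # linear in count
  expect_error(nft_detector_score(1, 0, 1), "> 0")

  expect_equal(annotator_score(0, 1e6, 1e6), 0)
  expect_equal(annotator_score(45, 7e5, 7e5), 45)
  expect_error(annotator_score(3, 0, 1), "area")
})

test_that("Spearman correlation with ordinal grades matches rank oracles", {
  grades <- c(0, 0, 1, 1, 2, 2, 3, 3)
  inc <- correlate_with_grades(1:8, grades)
  expect_equal(inc$rho, cor(rank(1:8), rank(grades)), tolerance = 1e-12)
  expect_gt(inc$rho, 0.95)
  expect_equal(correlate_with_grades(8:1, grades)$rho, -inc$rho)

  # toy table vs cor() on ranks (midrank ties)
  set.seed(4)
  sc <- runif(8)
  expect_equal(correlate_with_grades(sc, grades)$rho,
               cor(rank(sc), rank(grades)), tolerance = 1e-12)

  # tie-free case (4 slides, distinct grades) agrees with stats::cor.test
  sc2 <- c(0.3, 0.9, 0.1, 0.5)
  ct <- suppressWarnings(cor.test(sc2, 0:3, method = "spearman",
                                  exact = FALSE))
  expect_equal(correlate_with_grades(sc2, 0:3)$rho, unname(ct$estimate),
               tolerance = 1e-12)

  expect_error(correlate_with_grades(1:2, c(0, 1)), "at least 3")
  expect_error(correlate_with_grades(1:5, rep(1, 5)), "constant")
  expect_error(correlate_with_grades(1:3, c(0, 1, 7)), "0-3")

  # named grade levels code to 0-3
  named <- correlate_with_grades(1:4, c("none", "sparse", "moderate", "frequent"))
  expect_equal(named$rho, 1)
})

test_that("Welch comparisons match t.test and handle degenerate groups", {
  set.seed(5)
  a <- rnorm(5); b <- rnorm(5, 2)
  res <- compare_grade_groups(c(a, b), c(rep(0, 5), rep(1, 5)))
  tt <- t.test(a, b)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-9)

  same <- compare_grade_groups(rep(1, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  diffc <- compare_grade_groups(c(1, 1, 5, 5), c(0, 0, 1, 1))
  expect_equal(diffc$p, 0)
  expect_true(diffc$degenerate)

  expect_warning(sk <- compare_grade_groups(c(1, 2, 3), c(0, 0, 1)),
                 "singleton")
  expect_equal(nrow(sk), 0)
})

test_that("slide scores order synthetic slides by their tangle burden", {
  mk <- function(n, seed) make_annotated_roi(
    n, 0, dims = c(1536, 1536), noise = 0.005, seed = seed,
    tissue_frac = 0.8, min_sep = 200, margin = 100)
  slides <- list(mk(0, 41), mk(4, 42), mk(12, 43))
  scores <- vapply(slides, function(s)
    score_slide(s$rgb, tile = 512, factor = 64, median_area = 300)$score,
    numeric(1))
  expect_equal(scores[1], 0)
  expect_true(all(diff(scores) > 0))
})
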