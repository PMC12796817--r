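test_that("extract_cell_records: area, perimeter and centroid conventions", {
  sq <- rect_mask(20, 20, list(c(3, 7, 3, 7)))
  rec <- extract_cell_records(sq)
  expect_equal(rec$area_px2, 25)
  expect_equal(rec$perimeter_px, 20)   # 4s with s = 5
  expect_equal(c(rec$centroid_x, rec$centroid_y), c(4, 4))  # 0-based centre

  unit <- rect_mask(5, 5, list(c(2, 2, 2, 2)))
  rec1 <- extract_cell_records(unit)
  expect_equal(rec1$area_px2, 1)
  expect_equal(rec1$perimeter_px, 4)

  # border cells still get their outside edges counted
  corner <- rect_mask(5, 5, list(c(1, 1, 1, 1)))
  expect_equal(extract_cell_records(corner)$perimeter_px, 4)

  expect_equal(nrow(extract_cell_records(matrix(0, 8, 8))), 0)

  set.seed(9)
  m <- matrix(sample(0:5, 64 * 64, TRUE), 64, 64)
  recs <- extract_cell_records(m)
  expect_equal(sum(recs$area_px2), sum(m > 0))
})

test_that("spatial metrics follow the Table formulas with exact small cases", {
  recs <- data.frame(label = 1:3, area_px2 = 10, perimeter_px = 12,
                     centroid_x = c(0, 3, 6), centroid_y = c(0, 4, 8))
  sp <- spatial_metrics(recs, image_area_px = 100 * 100)
  expect_equal(sp$mean_distance, 5)          # nearest-neighbour distances all 5
  expect_equal(sp$compactness, 25 / 10)
  expect_equal(sp$density, 3e-4)
  expect_true(is.na(sp$distribution))        # N < 4
  expect_match(sp$flags[["distribution"]], "fewer than 4")

  # 4 cells at square corners: symmetric, so distribution is exactly 0
  corners <- data.frame(label = 1:4, area_px2 = 4, perimeter_px = 8,
                        centroid_x = c(0, 10, 0, 10), centroid_y = c(0, 0, 10, 10))
  expect_equal(spatial_metrics(corners, 1e4)$distribution, 0)

  single <- data.frame(label = 1, area_px2 = 4, perimeter_px = 8,
                       centroid_x = 5, centroid_y = 5)
  sp1 <- spatial_metrics(single, 100)
  expect_true(is.na(sp1$mean_distance) && is.na(sp1$compactness))
  expect_equal(sp1$density, 1 / 100)
})

test_that("mean_distance recovers the spacing of a planted regular grid", {
  centers <- expand.grid(x = seq(10, 90, by = 10), y = seq(10, 90, by = 10))
  recs <- data.frame(label = seq_len(nrow(centers)), area_px2 = 9,
                     perimeter_px = 12, centroid_x = centers$x,
                     centroid_y = centers$y)
  sp <- spatial_metrics(recs, 100 * 100)
  expect_lt(abs(sp$mean_distance - 10), 1e-9)
  # near zero, not exactly zero: corner cells see slightly farther 3rd neighbours
  expect_lt(sp$distribution, 0.05)
})

test_that("shape_complexity is mean(P^2)/mean(A), not the mean of ratios", {
  sqs <- rect_mask(30, 30, list(c(1, 2, 1, 2), c(10, 13, 10, 13)))  # sides 2 and 4
  recs <- extract_cell_records(sqs)
  expect_equal(shape_complexity(recs), ((64 + 256) / 2) / ((4 + 16) / 2))  # = 16
  # identical squares: exactly 16 under the pixel-edge perimeter convention
  same <- rect_mask(30, 30, list(c(1, 5, 1, 5), c(10, 14, 10, 14), c(20, 24, 20, 24)))
  expect_equal(shape_complexity(extract_cell_records(same)), 16)
  # a 1-pixel cell: P = 4, A = 1
  expect_equal(shape_complexity(extract_cell_records(rect_mask(5, 5, list(c(3, 3, 3, 3))))), 16)
  # ratio of means differs from mean of per-cell ratios once shapes differ
  # (squares of any size share P^2/A = 16, so use a square plus a rectangle)
  sq_rect <- rect_mask(30, 30, list(c(1, 2, 1, 2), c(10, 11, 10, 15)))
  mixed <- extract_cell_records(sq_rect)
  expect_equal(shape_complexity(mixed), ((64 + 256) / 2) / ((4 + 12) / 2))  # = 20
  expect_false(isTRUE(all.equal(shape_complexity(mixed),
                                mean(mixed$perimeter_px^2 / mixed$area_px2))))
  expect_true(is.na(shape_complexity(extract_cell_records(matrix(0, 4, 4)))))
})

test_that("edge_contrast matches a brute-force Sobel oracle and its policies", {
  # uniform image: zero gradient everywhere -> undefined
  uni <- matrix(50, 16, 16)
  msk <- rect_mask(16, 16, list(c(4, 6, 4, 6)))
  ec <- edge_contrast(uni, msk)
  expect_true(is.na(ec$edge_contrast))
  expect_match(ec$flags[["edge_contrast"]], "uniform|zero")

  # sharp bright cell on noisy background: ratio > 1, equal to the oracle
  set.seed(31)
  img <- matrix(40 + rnorm(24 * 24, 0, 3), 24, 24)
  msk2 <- rect_mask(24, 24, list(c(8, 14, 8, 14)))
  img[msk2 > 0] <- 200
  ec2 <- edge_contrast(img, msk2)
  expect_gt(ec2$edge_contrast, 1)

  grad <- brute_sobel(img)
  edge_px <- msk2 > 0 & (rbind(msk2[-1, ], -1) != msk2 | rbind(-1, msk2[-24, ]) != msk2 |
                         cbind(msk2[, -1], -1) != msk2 | cbind(-1, msk2[, -24]) != msk2)
  dil <- msk2 > 0
  for (k in 1:2) {
    dil <- dil | rbind(dil[-1, ], FALSE) | rbind(FALSE, dil[-24, ]) |
      cbind(dil[, -1], FALSE) | cbind(FALSE, dil[, -24])
  }
  oracle <- mean(grad[edge_px]) / mean(grad[!dil & msk2 == 0])
  expect_equal(ec2$edge_contrast, oracle, tolerance = 1e-12)

  # homogeneity: scaling intensities leaves the ratio unchanged
  ec3 <- edge_contrast(img * 3.7, msk2)
  expect_equal(ec3$edge_contrast, ec2$edge_contrast, tolerance = 1e-12)
})

test_that("morpho_report bundles six metrics with flags and is deterministic", {
  p <- synth_params(height = 128, width = 128, n_cells = 20, seed = 4)
  t <- generate_tissue(p)
  r1 <- morpho_report(t$image, t$mask, image_id = "fix")
  r2 <- morpho_report(t$image, t$mask, image_id = "fix")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$n_cells, 20)
  expect_equal(r1$density, 20 / (128 * 128))
  expect_false(any(is.na(r1[, c("mean_distance", "compactness", "density",
                                "distribution", "shape_complexity", "edge_contrast")])))

  one <- rect_mask(64, 64, list(c(10, 14, 10, 14)))
  img <- matrix(10, 64, 64); img[one > 0] <- 100; img[1, 1] <- 11
  rep1 <- morpho_report(img, one)
  expect_true(is.na(rep1$mean_distance) && is.na(rep1$compactness))
  expect_false(is.na(rep1$density) || is.na(rep1$shape_complexity))
  expect_match(rep1$flags, "mean_distance")

  path <- withr::local_tempfile(fileext = ".csv")
  write_morphology(list(r1, rep1), path)
  expect_equal(nrow(utils::read.csv(path)), 2)
})

test_that("metrics are translation invariant and scale as expected", {
  p <- synth_params(height = 128, width = 128, n_cells = 12,
                    radius_range = c(3, 5), seed = 8)
  t <- generate_tissue(p)
  # embed image+mask in a larger canvas at two offsets (interior content only)
  embed <- function(img, msk, off, H = 256) {
    I <- matrix(0, H, H); M <- matrix(0, H, H)
    I[off + seq_len(nrow(img)), off + seq_len(ncol(img))] <- img
    M[off + seq_len(nrow(img)), off + seq_len(ncol(img))] <- msk
    list(image = I, mask = M)
  }
  a <- embed(t$image, t$mask, 10)
  b <- embed(t$image, t$mask, 60)
  ra <- morpho_report(a$image, a$mask)
  rb <- morpho_report(b$image, b$mask)
  for (m in c("mean_distance", "compactness", "density", "distribution",
              "shape_complexity")) {
    expect_equal(ra[[m]], rb[[m]], tolerance = 1e-12)
  }

  # doubling the canvas with the same cells quarters density, keeps shape
  small <- morpho_report(t$image, t$mask)
  bigc <- embed(t$image, t$mask, 1, H = 256)
  big <- morpho_report(bigc$image, bigc$mask)
  expect_equal(big$density, small$density / 4)
  expect_equal(big$shape_complexity, small$shape_complexity)
})
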