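# Segmentation primitives against their brute-force oracles and their defining
# edge cases.

test_that("find_round_objects detects disks, applies the size band, ignores blanks", {
  blank <- matrix(100, 64, 64)
  expect_equal(n_labels(find_round_objects(blank, 5, 30, 200)), 0)

  # noise-free generator field: centroids within 1 px of the ground truth
  f <- render_cell_field(field_spec(n_cells = 5, noise_sd = 0, seed = 3))
  nuclei <- find_round_objects(f$image$channels$nucleus, 6, 40)
  expect_equal(n_labels(nuclei), 5)
  feats <- mask_features(nuclei)
  truth <- f$truth$nuclei
  for (i in seq_len(nrow(feats))) {
    d <- sqrt((feats$row[i] - truth$row)^2 + (feats$col[i] - truth$col)^2)
    expect_lt(min(d), 1)
  }

  # two disks of diameter 8 and 40, band [10, 30]: neither retained
  img <- matrix(0, 128, 128)
  img[disk_label(128, 128, 30, 30, 4) > 0] <- 1000
  img[disk_label(128, 128, 80, 80, 20) > 0] <- 1000
  expect_equal(n_labels(find_round_objects(img, 10, 30, 500)), 0)
  # sanity: the same image with a wide band finds both
  expect_equal(n_labels(find_round_objects(img, 2, 60, 500)), 2)

  expect_error(find_round_objects(array(0, c(4, 4, 2)), 1, 5, 0), "2-D")
  expect_error(find_round_objects(matrix(0, 8, 8), 5, 5, 0), "smaller")
})

test_that("roundness filter rejects elongated objects but keeps disks", {
  img <- matrix(0, 64, 64)
  img[disk_label(64, 64, 20, 20, 8) > 0] <- 1000   # disk, roundness ~1
  img[45:47, 10:50] <- 1000                         # 3x41 bar
  found <- find_round_objects(img, 2, 40, 500, roundness_min = 0.6)
  expect_equal(n_labels(found), 1)
  feats <- mask_features(found)
  expect_lt(abs(feats$row - 20), 1)
})

test_that("shrink_labels matches the brute-force erosion oracle", {
  # identity at n = 0
  lab <- label_mask(disk_label(64, 64, 32, 32, 10))
  expect_identical(unclass_mask(shrink_labels(lab, 0)), unclass_mask(lab))
  # disk radius 10 eroded by 2 equals the oracle on a 64x64 grid
  got <- shrink_labels(lab, 2)
  expect_identical(unclass_mask(got), oracle_shrink(unclass_mask(lab), 2))
  # annihilation: disk radius 1 vanishes and is reported
  tiny <- label_mask(disk_label(64, 64, 10, 10, 1))
  expect_message(out <- shrink_labels(tiny, 2), "eroded away")
  expect_equal(n_labels(out), 0)
  expect_equal(attr(out, "dropped_labels"), 1L)
  expect_error(shrink_labels(lab, -1), "non-negative")
})

test_that("grow_labels_without_touching matches the exhaustive nearest-label oracle", {
  lab <- label_mask(disk_label(128, 128, 64, 64, 10))
  expect_identical(unclass_mask(grow_labels_without_touching(lab, 0)),
                   unclass_mask(lab))
  got <- grow_labels_without_touching(lab, 25)
  expect_identical(unclass_mask(got), oracle_grow(unclass_mask(lab), 25))

  # two single-pixel seeds 10 px apart: perpendicular-bisector boundary,
  # tie pixels to the smaller id
  m <- matrix(0L, 64, 64)
  m[32, 27] <- 1L; m[32, 37] <- 2L
  g <- grow_labels_without_touching(label_mask(m), 25)
  expect_identical(unclass_mask(g), oracle_grow(m, 25))
  expect_true(all(g[, 32][g[, 32] > 0] == 1L))  # equidistant column -> id 1
  # each side of the bisector belongs to its seed
  expect_true(all(g[32, 28:31] == 1L))
  expect_true(all(g[32, 33:36] == 2L))
  expect_error(grow_labels_without_touching(label_mask(m), -3), "non-negative")
})

test_that("grown territories stay disjoint and input labels are preserved", {
  for (s in 1:5) {
    lab <- random_label_mask(s, k = 6)
    g <- grow_labels_without_touching(label_mask(lab), 12)
    expect_true(all(g[lab > 0] == lab[lab > 0]))
    # territory monotonicity: grow(n) then grow(m) is contained in grow(n+m)
    g2 <- grow_labels_without_touching(
      grow_labels_without_touching(label_mask(lab), 5), 7)
    inside <- unclass_mask(g2) > 0
    expect_true(all(unclass_mask(g)[inside] > 0))
  }
})

test_that("shrink then grow by the same n never flips a pixel to another label", {
  for (s in 1:5) {
    lab <- random_label_mask(s, k = 4, r_max = 8)
    sh <- shrink_labels(label_mask(lab), 2)
    re <- grow_labels_without_touching(sh, 2)
    chg <- lab > 0 & unclass_mask(re) > 0 & unclass_mask(re) != lab
    expect_equal(sum(chg), 0)
  }
})

test_that("remove_border_objects removes exactly the edge-touching labels", {
  lab <- matrix(0L, 32, 32)
  lab[disk_label(32, 32, 10, 10, 3) > 0] <- 1L   # interior
  lab[disk_label(32, 32, 16, 20, 3) > 0] <- 2L   # interior
  lab[disk_label(32, 32, 25, 8, 3) > 0] <- 3L    # interior
  lab[1:3, 15:18] <- 4L                          # touches top edge
  lab[28:32, 28:30] <- 5L                        # touches bottom edge
  out <- remove_border_objects(label_mask(lab))
  expect_setequal(label_ids(out), 1:3)
  # no edge-touching labels: unchanged
  inner <- label_mask(disk_label(32, 32, 16, 16, 5))
  expect_identical(unclass_mask(remove_border_objects(inner)),
                   unclass_mask(inner))
})

test_that("bottom_hat matches the brute-force closing oracle", {
  expect_true(all(bottom_hat(matrix(7, 40, 40), 5) == 0))
  # dark square (side 11) on bright background, radius 15: bright exactly
  # on the square
  img <- matrix(100, 64, 64)
  img[27:37, 27:37] <- 10
  bh <- bottom_hat(img, 15)
  expect_equal(bh, oracle_bottom_hat(img, 15))
  expect_true(all(bh[27:37, 27:37] == 90))
  expect_true(all(bh[img == 100] == 0))
  # radius smaller than the object half-width: centre under-enhanced
  img2 <- matrix(100, 64, 64)
  img2[20:44, 20:44] <- 10          # side 25, half-width 12
  bh2 <- bottom_hat(img2, 5)
  expect_equal(bh2, oracle_bottom_hat(img2, 5))
  expect_lt(bh2[32, 32], max(bh2[20, 20:44]))
  expect_error(bottom_hat(img, 0.5), ">= 1")
})

test_that("otsu/auto_threshold match the exhaustive histogram oracle", {
  set.seed(4)
  # perfect bimodal image: foreground is exactly the high-valued pixels
  img <- matrix(10, 50, 50)
  img[sample(2500, 250)] <- 200
  bm <- auto_threshold(img)
  expect_identical(unclass_mask(bm), unclass(img == 200))
  expect_equal(attr(bm, "threshold"), oracle_otsu(img))
  # inverted contrast swaps the foreground count
  inv <- max(img) + min(img) - img
  bm2 <- auto_threshold(inv)
  expect_equal(sum(bm2), sum(img == 10))
  expect_equal(otsu_threshold(inv), oracle_otsu(inv))
  # 50/50 two-valued image: threshold strictly between the two values
  img3 <- matrix(c(5, 55), 10, 10)
  thr <- otsu_threshold(img3)
  expect_gt(thr, 5); expect_lt(thr, 55)
  expect_error(otsu_threshold(matrix(3, 5, 5)), "constant")
  # agreement with the oracle on random continuous images
  for (s in 1:5) {
    set.seed(s)
    im <- matrix(c(rnorm(300, 20, 3), rnorm(100, 60, 5)), 20, 20)
    expect_equal(otsu_threshold(im), oracle_otsu(im))
  }
})

test_that("fill_holes matches the border-flood oracle and dilation is exact", {
  m <- matrix(FALSE, 40, 40)
  d <- sqrt((row(m) - 20)^2 + (col(m) - 20)^2)
  ann <- d >= 5 & d <= 8
  fh <- fill_holes(binary_mask(ann))
  expect_identical(unclass(unclass_mask(fh)), oracle_fill_holes(ann))
  expect_equal(sum(fh), sum(d <= 8))
  for (s in 1:5) {
    set.seed(s)
    rnd <- matrix(runif(40 * 40) < 0.35, 40, 40)
    expect_identical(unclass(unclass_mask(fill_holes(binary_mask(rnd)))),
                     oracle_fill_holes(rnd))
  }
  # binary dilation equals the offset-union definition
  sq <- matrix(FALSE, 32, 32); sq[15:18, 15:18] <- TRUE
  dil <- dilate_binary(binary_mask(sq), 3)
  off <- perilyso:::disk_offsets(3)
  bf <- matrix(FALSE, 32, 32)
  for (k in seq_len(nrow(off)))
    bf <- bf | perilyso:::shift_mat(sq, off$dr[k], off$dc[k], FALSE)
  expect_identical(unclass(unclass_mask(dil)), bf)
})

test_that("filter_min_area keeps exactly the large-enough components", {
  m <- matrix(FALSE, 64, 64)
  m[2:3, 2:4] <- TRUE                                  # area 6
  m[disk_label(64, 64, 20, 20, 4) > 0] <- TRUE         # area ~49
  m[disk_label(64, 64, 45, 45, 13) > 0] <- TRUE        # area ~530
  expect_identical(unclass_mask(filter_min_area(binary_mask(m), 0)),
                   unclass(m))
  out <- filter_min_area(binary_mask(m), 40)
  lab <- perilyso:::label_components(unclass(unclass_mask(out)))
  expect_equal(max(lab), 2)
  expect_error(filter_min_area(binary_mask(m), -2), "non-negative")
})

test_that("operators are translation-equivariant on interior objects", {
  lab <- matrix(0L, 64, 64)
  lab[disk_label(64, 64, 25, 25, 6) > 0] <- 1L
  lab[disk_label(64, 64, 40, 45, 4) > 0] <- 2L
  shift3 <- function(m) perilyso:::shift_mat(m, 3, 3, 0L)
  for (op in list(function(m) unclass_mask(shrink_labels(label_mask(m), 2)),
                  function(m) unclass_mask(
                    grow_labels_without_touching(label_mask(m), 6)))) {
    expect_identical(op(shift3(lab)), shift3(op(lab)))
  }
  img <- matrix(100, 64, 64); img[20:26, 20:26] <- 10
  expect_equal(bottom_hat(shift3(img) + 100 * (shift3(matrix(1, 64, 64)) == 0), 8)[10:60, 10:60],
               perilyso:::shift_mat(bottom_hat(img, 8), 3, 3, 0)[10:60, 10:60])
})

test_that("detect_puncta resolves well-separated spots and respects thresholds", {
  # sparse noise-free field: high recall and precision against ground truth
  f <- render_cell_field(field_spec(n_cells = 4,
                                    puncta_per_cell_range = c(6, 8),
                                    noise_sd = 0, seed = 9))
  det <- detect_puncta(f$image$channels$marker, intensity_threshold = 600)
  feats <- mask_features(det)
  truth <- f$truth$puncta
  matched_truth <- vapply(seq_len(nrow(truth)), function(i)
    any(sqrt((feats$row - truth$row[i])^2 +
               (feats$col - truth$col[i])^2) <= 2.5), logical(1))
  matched_det <- vapply(seq_len(nrow(feats)), function(i)
    any(sqrt((feats$row[i] - truth$row)^2 +
               (feats$col[i] - truth$col)^2) <= 2.5), logical(1))
  expect_gte(mean(matched_truth), 0.95)   # recall
  expect_gte(mean(matched_det), 0.95)     # precision
  # threshold above the maximum intensity: nothing detected
  expect_equal(n_labels(detect_puncta(f$image$channels$marker,
                                      intensity_threshold = 1e5)), 0)
})

test_that("two close puncta merge at a low threshold and split at the default", {
  img <- matrix(100, 64, 64)
  img <- perilyso:::add_spot(img, 32, 29, 2000, 1.5)$img
  img <- perilyso:::add_spot(img, 32, 36, 2000, 1.5)$img   # 7 px apart
  low <- detect_puncta(img, intensity_threshold = 150)
  def <- detect_puncta(img, intensity_threshold = 600)
  expect_equal(n_labels(low), 1)
  expect_equal(n_labels(def), 2)
})
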