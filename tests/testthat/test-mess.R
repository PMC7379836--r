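test_that("auto mask recovers a noisy bright ellipse", {
  fx <- fix_cell_video()
  m <- make_mask(fx$video)
  truth <- fx$truth$pixels
  jac <- sum(m$pixels & truth) / sum(m$pixels | truth)
  expect_gt(jac, 0.95)
  expect_lt(abs(sum(m$pixels) - sum(truth)) / sum(truth), 0.03)
  ## single connected component
  expect_equal(max(EBImage::bwlabel(m$pixels)), 1)
})

test_that("uniform video and multiple blobs are handled", {
  flat <- new_video(array(100, c(3, 16, 16)), 10)
  expect_error(make_mask(flat), "no cell detected")

  frames <- array(100, c(3, 40, 40))
  frames[, 5:15, 5:15] <- 500    # 121 px blob
  frames[, 25:35, 25:38] <- 500  # larger blob
  m <- make_mask(new_video(frames, 10))
  expect_false(any(m$pixels[5:15, 5:15]))
  expect_true(all(m$pixels[26:34, 26:37]))
})

test_that("alignment recovers the construction angle and handles disks", {
  al <- align_mask(ellipse_mask(121, 121, 50, 20, angle = 30))
  expect_lt(abs(abs(al$angle) - 30), 1.5)
  ## aligned mask is vertical
  theta <- metroidr:::mask_orientation(al$aligned$pixels)
  expect_lt(abs(abs(theta) - 90), 1)

  al0 <- align_mask(ellipse_mask(81, 81, 30, 30))
  expect_equal(al0$angle, 0)
})

test_that("inner/outer split hits the area-fraction target", {
  m <- fix_ellipse()
  al <- align_mask(m)
  tri <- split_inner_outer(al$aligned, 16, 16)
  frac <- sum(tri$inner_mask) / sum(al$aligned$pixels)
  expect_lt(abs(frac - 0.5), 0.06)
  ## oracle: replay the erosion sequence and check the stop rule
  px <- al$aligned$pixels
  areas <- sum(px)
  repeat {
    px <- EBImage::erode(px, EBImage::makeBrush(3, "box")) > 0
    areas <- c(areas, sum(px))
    if (sum(px) <= 0.5 * sum(al$aligned$pixels)) break
  }
  expect_equal(tri$n_erosions, length(areas) - 1)
  expect_equal(sum(tri$inner_mask), areas[length(areas)])
  ## mid contour from half the erosions
  expect_true(all(tri$mid_mask | !tri$inner_mask | tri$inner_mask))
  expect_true(all(tri$inner_mask[tri$inner_mask] <= tri$mid_mask[tri$inner_mask]))

  tri2 <- split_inner_outer(al$aligned, 4, 2)
  frac2 <- sum(tri2$inner_mask) / sum(al$aligned$pixels)
  expect_lt(abs(frac2 - 4 / 6), 0.06)

  expect_error(split_inner_outer(new_mask(matrix(TRUE, 5, 5)), 16, 16),
               "too small")
})

test_that("outer band division tiles the band with symmetric sectors", {
  m <- ellipse_mask(121, 61, 55, 25)  # vertical ellipse
  al <- align_mask(m)
  tri <- split_inner_outer(al$aligned, 16, 16)
  lab4 <- divide_outer(tri, 4)
  band <- tri$aligned & !tri$inner_mask
  expect_identical(lab4 > 0, band)
  a <- tabulate(lab4[lab4 > 0], 4)
  expect_true(all(a > 0))
  ## the two lateral sectors are mirror-symmetric in area within 10 %
  laterals <- sort(a)[c(3, 4)]  # two largest are the long sides
  expect_lt(abs(laterals[1] - laterals[2]) / mean(laterals), 0.10)

  lab2 <- divide_outer(tri, 2)
  expect_setequal(unique(lab2[lab2 > 0]), 1:2)
})

test_that("inner division yields quasi-equal areas in the prescribed layout", {
  m <- ellipse_mask(121, 61, 55, 25)
  al <- align_mask(m)
  tri <- split_inner_outer(al$aligned, 16, 16)
  lab <- divide_inner(tri$inner_mask, 16)
  areas <- tabulate(lab[lab > 0], 16)
  expect_true(all(areas > 0))
  expect_lt(max(abs(areas - mean(areas))) / mean(areas), 0.25)
  expect_identical(lab > 0, tri$inner_mask)

  ## n_in = 4: top / right half / bottom / left half
  lab4 <- divide_inner(tri$inner_mask, 4)
  cent <- t(vapply(1:4, function(k)
    colMeans(which(lab4 == k, arr.ind = TRUE)), numeric(2)))
  expect_true(cent[1, 1] < cent[2, 1])  # top above right-half
  expect_true(cent[3, 1] > cent[2, 1])  # bottom below
  expect_true(cent[2, 2] > cent[4, 2])  # right half right of left half

  ## equal half-column counts for n_in = 8: 3 right + 3 left
  lab8 <- divide_inner(tri$inner_mask, 8)
  cent8 <- t(vapply(1:8, function(k)
    colMeans(which(lab8 == k, arr.ind = TRUE)), numeric(2)))
  mid_c <- mean(cent8[, 2])
  expect_equal(sum(cent8[2:7, 2] > mid_c), 3)
})

test_that("MESS partitions the mask into the requested non-empty ROIs", {
  for (geom in list(fix_ellipse(), ellipse_mask(121, 61, 55, 25))) {
    rs <- mess(geom, 16, 16)
    expect_equal(sort(unique(rs$labels[rs$labels > 0])), 1:32)
    expect_identical(rs$labels > 0, geom$pixels)  # exact tiling
    areas <- tabulate(rs$labels[rs$labels > 0], 32)
    expect_true(all(areas > 0))
    expect_lt(sd(areas) / mean(areas), 0.35)  # quasi-isometry
  }
  expect_error(mess(fix_ellipse(), n_in = 5), "even")
  expect_error(mess(fix_ellipse(), n_in = 16, n_out = 1), "n_ROIs_out")
})

test_that("MESS is standardized across mask orientation", {
  base <- ellipse_mask(241, 241, 110, 52, angle = 0)
  rs0 <- mess(base, 16, 16)
  for (ang in c(30, 90)) {
    ma <- ellipse_mask(241, 241, 110, 52, angle = ang)
    rsa <- mess(ma, 16, 16)
    rot <- metroidr:::rotate_nn(rsa$labels, -ang)
    d <- dim(rot$img)
    r0 <- floor((d[1] - 241) / 2); c0 <- floor((d[2] - 241) / 2)
    labc <- rot$img[r0 + (1:241), c0 + (1:241)]
    expect_gt(label_jaccard(rs0$labels, labc, 1:32), 0.8)
    ## ROI 1 springs at the same anatomical pole
    c1 <- colMeans(which(rs0$labels == 1, arr.ind = TRUE))
    c2 <- colMeans(which(labc == 1, arr.ind = TRUE))
    expect_lt(sqrt(sum((c1 - c2)^2)), 3)
  }
})
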