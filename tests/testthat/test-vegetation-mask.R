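test_that("thresholding recovers crown footprints on a noise-free scene", {
  sim <- tiny_clean_scene()
  ngbdi <- compute_index(normalize_bands(sim$ortho), "NGBDI")
  fp <- crown_footprints(sim$terrain, sim$truth)
  fixed <- reclassify_index(ngbdi, 0.2)
  expect_identical(fixed$grid$values == 1, fp$values > 0)
  auto <- reclassify_index(ngbdi, "auto")
  expect_identical(auto$grid$values == 1, fp$values > 0)
  expect_true(auto$threshold > 0 && auto$threshold < 0.4)
})

test_that("threshold semantics: cutoffs nest and extremes empty the mask", {
  v <- matrix(seq(-1, 1, length.out = 25), 5, 5)
  ix <- make_index(v, gsd = 1)
  hi <- reclassify_index(ix, 2)
  expect_true(all(hi$grid$values == 0))
  m1 <- reclassify_index(ix, 0.1)$grid$values
  m2 <- reclassify_index(ix, 0.6)$grid$values
  expect_true(all(m1[m2 == 1] == 1))             # higher cut is a subset
  expect_error(reclassify_index(make_index(matrix(1, 4, 4)), "auto"),
               "constant")
})

test_that("mask cleaning removes small patches and (0, 0) is the identity", {
  m <- matrix(0, 20, 20)
  m[3:12, 3:12] <- 1                             # 100 px = 1 m^2 at gsd 0.1
  m[16, 16] <- 1; m[16, 17] <- 1                 # 2 px patch = 0.02 m^2
  m[1, 20] <- 1; m[2, 20] <- 1; m[1, 19] <- 1; m[2, 19] <- 1; m[3, 19] <- 1
  mask <- make_mask(m, gsd = 0.1)
  ident <- clean_mask(mask, 0, 0)
  expect_identical(ident$grid$values, mask$grid$values)
  # the 5-pixel patch is 0.05 m^2 and must drop below a 0.1 m^2 floor
  cleaned <- clean_mask(mask, min_patch_area_m2 = 0.1, closing_radius_px = 0)
  expect_equal(sum(cleaned$grid$values), 100)
  all_gone <- clean_mask(mask, min_patch_area_m2 = 50, closing_radius_px = 0)
  expect_true(all(all_gone$grid$values == 0))
  expect_error(clean_mask(mask, -1, 0), "non-negative")
})

test_that("components are 8-connected and ordered top-most then left-most", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1                     # diagonal pair: one label
  m[5, 1] <- 1                                   # separate patch, lower
  m[1, 5] <- 1                                   # separate patch, topmost
  lab <- label_components(m)
  expect_equal(max(lab), 3L)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[1, 5], 1L)                    # topmost pixel -> id 1
  expect_equal(lab[2, 2], 2L)
  expect_equal(lab[5, 1], 3L)
})

test_that("polygon extraction is exact on pixel shapes", {
  m <- matrix(0, 30, 30); m[10:19, 10:19] <- 1
  crowns <- extract_crown_polygons(make_mask(m, gsd = 0.1), simplify_tol_m = 0)
  expect_equal(nrow(crowns), 1L)
  expect_equal(crowns$area_m2, 1.0)              # 100 px x 0.01 m^2
  expect_equal(crowns$n_pixels, 100L)

  two <- matrix(0, 10, 10); two[2:3, 2:3] <- 1; two[7:8, 7:8] <- 1
  crowns2 <- extract_crown_polygons(make_mask(two, gsd = 0.1), 0)
  expect_equal(nrow(crowns2), 2L)

  empty <- extract_crown_polygons(make_mask(matrix(0, 5, 5), gsd = 0.1), 0)
  expect_equal(nrow(empty), 0L)

  holed <- matrix(0, 20, 20); holed[4:15, 4:15] <- 1; holed[8:10, 8:10] <- 0
  ch <- extract_crown_polygons(make_mask(holed, gsd = 0.1), 0)
  expect_equal(length(ch$geometry[[1]]), 2L)     # exterior + hole
  expect_equal(ch$area_m2, (144 - 9) * 0.01)
})

test_that("simplified areas stay within the perimeter x tolerance bound", {
  sim <- tiny_clean_scene()
  ngbdi <- compute_index(normalize_bands(sim$ortho), "NGBDI")
  mask <- clean_mask(reclassify_index(ngbdi, "auto"), 0.5, 1)
  tol <- 2 * mask$grid$px
  crowns <- extract_crown_polygons(mask, tol)
  exact <- extract_crown_polygons(mask, 0)
  for (i in seq_len(nrow(crowns))) {
    pix_area <- crowns$n_pixels[i] * mask$grid$px * mask$grid$py
    ring <- exact$geometry[[i]][[1]]
    per <- sum(sqrt(rowSums((ring - ring[c(2:nrow(ring), 1), ])^2)))
    expect_lt(abs(crowns$area_m2[i] - pix_area), per * tol + 1e-9)
  }
  # every stem of a detected tree lies in exactly one crown polygon
  stems <- sim$truth$trees
  hits <- vapply(seq_len(nrow(stems)), function(i) {
    sum(vapply(crowns$geometry, function(rings) {
      oracle_in_rings(stems$x[i], stems$y[i], rings)
    }, logical(1)))
  }, integer(1))
  expect_true(all(hits == 1L))
})

test_that("crown classification uses quantile breaks with ties going low", {
  m <- matrix(0, 12, 30)
  m[5:8, 3:6] <- 1; m[5:8, 13:16] <- 1; m[5:8, 23:26] <- 1
  mask <- make_mask(m, gsd = 0.1)
  crowns <- extract_crown_polygons(mask, 0)
  vals <- matrix(0, 12, 30)
  vals[5:8, 3:6] <- 0.2; vals[5:8, 13:16] <- 0.5; vals[5:8, 23:26] <- 0.8
  ix <- make_index(vals, gsd = 0.1)
  cl <- classify_crowns(ix, crowns, 3)
  expect_equal(cl$class_label[order(cl$mean_index)], 1:3)

  same <- make_index(matrix(0.4 * m, 12, 30), gsd = 0.1)
  cl2 <- classify_crowns(same, crowns, 3)
  expect_true(all(cl2$class_label == 1L))        # ties go to the lower class
  expect_error(classify_crowns(ix, crowns, 4), "at least")
})

test_that("three crown colours are recovered up to label permutation", {
  sim <- tiny_clean_scene()
  ngbdi <- compute_index(normalize_bands(sim$ortho), "NGBDI")
  mask <- clean_mask(reclassify_index(ngbdi, "auto"), 0.5, 0)
  crowns <- classify_crowns(ngbdi, extract_crown_polygons(mask, 0), 3)
  stems <- sim$truth$trees
  got <- integer(nrow(stems))
  for (i in seq_len(nrow(stems))) {
    hit <- which(vapply(crowns$geometry, function(rings) {
      oracle_in_rings(stems$x[i], stems$y[i], rings)
    }, logical(1)))
    got[i] <- crowns$class_label[hit[1]]
  }
  best <- 0
  for (p in list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                 c(3, 2, 1))) {
    best <- max(best, sum(p[stems$class_label] == got))
  }
  expect_equal(best, nrow(stems))
})

test_that("crown GeoJSON survives a write/read round trip", {
  m <- matrix(0, 15, 15); m[3:7, 3:9] <- 1; m[10:12, 11:13] <- 1
  crowns <- extract_crown_polygons(make_mask(m, gsd = 0.2), 0)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_crowns_geojson(crowns, p)
  back <- read_crowns_geojson(p)
  expect_equal(nrow(back), 2L)
  expect_equal(back$area_m2, crowns$area_m2)
  expect_equal(back$geometry[[1]][[1]], crowns$geometry[[1]][[1]],
               ignore_attr = TRUE)
})
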