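test_that("ground sampling stays on mask-0 pixels and is seed-stable", {
  m <- matrix(0, 10, 10); m[3:6, 3:6] <- 1
  mask <- make_mask(m, gsd = 1)
  dsm <- grid_create(matrix(runif(100, 500, 510), 10, 10), 0, 10, 1)
  gp <- sample_ground_points(mask, dsm, 30, seed = 5)
  expect_equal(nrow(gp), 30L)
  expect_true(all(mask$grid$values[cbind(gp$row, gp$col)] == 0))
  expect_true(all(gp$z == dsm$values[cbind(gp$row, gp$col)]))
  gp2 <- sample_ground_points(mask, dsm, 30, seed = 5)
  expect_identical(gp, gp2)
  # all-ground mask with n = all pixels samples each pixel exactly once
  allg <- make_mask(matrix(0, 6, 6), gsd = 1)
  dsm6 <- grid_create(matrix(1:36, 6, 6), 0, 6, 1)
  gpa <- sample_ground_points(allg, dsm6, 36, seed = 1)
  expect_equal(sort(gpa$row * 10 + gpa$col), sort(rep(1:6, 6) * 10 + rep(1:6, each = 6)))
  expect_error(sample_ground_points(mask, dsm, 90, seed = 1), "ground pixels")
})

test_that("plane-sampled points reproduce the plane exactly", {
  template <- grid_create(matrix(0, 40, 40), 0, 40, 1)
  set.seed(19)
  # corners plus random interior points put the whole grid inside the hull
  x <- c(0.01, 39.99, 0.01, 39.99, runif(40, 1, 39))
  y <- c(0.01, 0.01, 39.99, 39.99, runif(40, 1, 39))
  pts <- tibble::tibble(x = x, y = y, z = 2 * x + 3 * y + 10)
  dem <- interpolate_dem(pts, template)
  truth <- outer(39.5:0.5 * 3, 0.5:39.5 * 2, `+`) + 10
  expect_lt(max(abs(dem$values - truth)), 1e-9)

  flat <- tibble::tibble(x = c(5, 20, 30, 12), y = c(5, 28, 7, 15),
                         z = rep(77, 4))
  demf <- interpolate_dem(flat, template)
  expect_true(all(abs(demf$values - 77) < 1e-9))  # hull + nearest fill

  coll <- tibble::tibble(x = 1:5, y = 2 * (1:5), z = 1:5)
  expect_error(interpolate_dem(coll, template), "collinear")
})

test_that("the DEM agrees with an independent Delaunay barycentric oracle", {
  skip_if_not_installed("deldir")
  ext <- c(0, 0, 40, 40)
  terrain <- generate_terrain(ext, 0.1, 3, 30, 500, seed = 12)
  mask <- make_mask(matrix(0, 400, 400), gsd = 0.1, ymax = 40)
  gp <- sample_ground_points(mask, terrain, 200, seed = 7)
  dem <- interpolate_dem(gp, terrain)
  dd <- deldir::deldir(gp$x, gp$y)
  tl <- deldir::triang.list(dd)
  set.seed(99)
  checked <- 0
  while (checked < 50) {
    r <- sample(400, 1); cc <- sample(400, 1)
    qx <- (cc - 0.5) * 0.1; qy <- 40 - (r - 0.5) * 0.1
    val <- NA
    for (tri in tl) {
      x1 <- tri$x[1]; y1 <- tri$y[1]; x2 <- tri$x[2]; y2 <- tri$y[2]
      x3 <- tri$x[3]; y3 <- tri$y[3]
      det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
      l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
      l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
      l3 <- 1 - l1 - l2
      if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9) {
        zt <- gp$z[match(paste(tri$x, tri$y),
                         paste(gp$x, gp$y))]
        val <- l1 * zt[1] + l2 * zt[2] + l3 * zt[3]
        break
      }
    }
    if (is.na(val)) next                        # outside the hull: skip
    expect_equal(dem$values[r, cc], val, tolerance = 1e-6)
    checked <- checked + 1
  }
})

test_that("accuracy does not degrade as ground points are added", {
  ext <- c(0, 0, 40, 40)
  terrain <- generate_terrain(ext, pixel_size = 0.2, relief_amplitude = 3,
                              correlation_length = 30, base_elevation = 500,
                              seed = 2)
  mask <- make_mask(matrix(0, 200, 200), gsd = 0.2, ymax = 40)
  med_err <- function(n, s) {
    gp <- sample_ground_points(mask, terrain, n, seed = s)
    stats::median(abs(interpolate_dem(gp, terrain)$values - terrain$values))
  }
  worse <- 0
  for (s in 1:5) {
    if (med_err(400, s) > med_err(100, s)) worse <- worse + 1
  }
  expect_lte(worse, 1)           # monotone accuracy over the seed ensemble
})

test_that("the CHM is the clamped difference of aligned surfaces", {
  dsm <- grid_create(matrix(c(512.3, 499.5, 500, 501), 2, 2), 0, 2, 1)
  dem <- grid_create(matrix(500, 2, 2), 0, 2, 1)
  chm <- compute_chm(dsm, dem)
  expect_equal(chm$values[1, 1], 12.3)
  expect_equal(chm$values[2, 1], 0)              # clamped
  expect_equal(attr(chm, "n_clamped"), 1L)
  raw <- compute_chm(dsm, dem, clamp_negative = FALSE)
  expect_equal(raw$values[2, 1], -0.5)
  expect_true(all(compute_chm(dsm, dsm)$values == 0))
  off <- grid_create(matrix(500, 2, 2), 1, 2, 1)
  expect_error(compute_chm(dsm, off), "common grid")
  withna <- dsm; withna$values[1, 2] <- NA
  expect_true(is.na(compute_chm(withna, dem)$values[1, 2]))
})
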