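test_that("buffer maximum picks the right pixel and flags empty buffers", {
  v <- matrix(0, 20, 20)
  v[10, 10] <- 23.4
  chm <- grid_create(v, 0, 4, 0.2)               # pixel (10,10) centre (1.9, 2.1)
  pts <- tibble::tibble(id = 1:2, x = c(2.0, 3.9), y = c(2.0, 0.1),
                        height_m = c(20, 20))
  pairs <- buffer_max_height(chm, pts, radius_m = 1)
  expect_equal(pairs$chm_height[pairs$point_id == 1], 23.4)
  # point 2 sits in-grid, so it has buffer pixels (all zero CHM)
  expect_equal(pairs$chm_height[pairs$point_id == 2], 0)

  far <- tibble::tibble(id = 9, x = 50, y = 50, height_m = 10)
  res <- buffer_max_height(chm, far, radius_m = 1)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_excluded"), 1L)
  expect_equal(attr(res, "excluded_ids"), 9)
})

test_that("buffer maxima match a brute-force distance scan", {
  set.seed(23)
  v <- matrix(runif(70 * 60, 0, 25), 70, 60)
  v[sample(4200, 60)] <- NA
  chm <- grid_create(v, 0, 35, 0.5)
  pts <- tibble::tibble(id = 1:30, x = runif(30, -1, 31),
                        y = runif(30, -1, 36), height_m = runif(30, 5, 25))
  pairs <- buffer_max_height(chm, pts, radius_m = 1)
  for (i in 1:30) {
    o <- oracle_buffer_max(chm, pts$x[i], pts$y[i], 1)
    row <- pairs[pairs$point_id == i, ]
    if (o$n == 0L) {
      expect_equal(nrow(row), 0L)
    } else {
      expect_identical(row$chm_height, o$max)
      expect_identical(row$n_buffer_pixels, o$n)
    }
  }
  expect_equal(nrow(pairs) + attr(pairs, "n_excluded"), 30L)
})

test_that("the Pearson test reproduces hand-computed and reference values", {
  mk_pairs <- function(x, y) tibble::tibble(point_id = seq_along(x),
                                            field_height = y, chm_height = x,
                                            n_buffer_pixels = 1L)
  x <- 1:10
  perfect <- pearson_test(mk_pairs(x, 2 * x + 1))
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$p_value, 0)
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 1)
  expect_equal(perfect$rmse, 0)

  # hand computation: centred cross products 4 x 0.75, variances 5 and 5
  hand <- pearson_test(mk_pairs(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  expect_equal(hand$pearson_r, 0.6)

  expect_error(pearson_test(mk_pairs(rep(2, 5), 1:5)), "constant")
  expect_error(pearson_test(mk_pairs(1:2, 2:3)), "at least 3")
})

test_that("p-values agree with the reference implementation across (r, n)", {
  set.seed(55)
  for (n in c(5, 10, 30, 116)) {
    for (rep in 1:4) {
      x <- rnorm(n)
      y <- 0.6 * x + rnorm(n, sd = runif(1, 0.3, 2))
      pairs <- tibble::tibble(point_id = 1:n, field_height = y, chm_height = x,
                              n_buffer_pixels = 1L)
      mine <- pearson_test(pairs)
      ref <- stats::cor.test(x, y)
      expect_equal(mine$pearson_r, unname(ref$estimate), tolerance = 1e-12)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("r is invariant under positive affine rescaling", {
  set.seed(66)
  x <- rnorm(40); y <- x + rnorm(40)
  mk <- function(x, y) tibble::tibble(point_id = 1:40, field_height = y,
                                      chm_height = x, n_buffer_pixels = 1L)
  r0 <- pearson_test(mk(x, y))$pearson_r
  expect_equal(pearson_test(mk(3 * x + 7, y))$pearson_r, r0)
  expect_equal(pearson_test(mk(x, 0.2 * y - 5))$pearson_r, r0)
})

test_that("the report is self-consistent and conserves points", {
  set.seed(9)
  v <- matrix(runif(400, 0, 20), 20, 20)
  chm <- grid_create(v, 0, 20, 1)
  pts <- tibble::tibble(id = 1:12, x = c(runif(10, 1, 19), 60, 70),
                        y = c(runif(10, 1, 19), 60, 70),
                        height_m = runif(12, 5, 25))
  pairs <- buffer_max_height(chm, pts, 1)
  res <- pearson_test(pairs)
  rep_ <- validation_report(res)
  expect_equal(rep_$summary$n, nrow(rep_$pairs))
  expect_equal(rep_$summary$n + rep_$summary$n_excluded, 12L)
  r_again <- stats::cor(rep_$pairs$chm_height, rep_$pairs$field_height)
  expect_equal(rep_$summary$pearson_r, r_again)
  p <- withr::local_tempfile(fileext = ".json")
  validation_report(res, p)
  disk <- jsonlite::read_json(p)
  expect_equal(disk$summary$pearson_r, res$pearson_r, tolerance = 1e-12)

  expect_equal(glance(res)$pearson_r, res$pearson_r)
  td <- tidy(res)
  expect_equal(td$estimate[td$term == "chm_height"], res$slope)
  expect_s3_class(autoplot(res), "ggplot")
})
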