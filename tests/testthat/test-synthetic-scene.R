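test_that("terrain respects amplitude, determinism and degenerate cases", {
  ext <- c(0, 0, 30, 30)
  flat <- generate_terrain(ext, 0.5, relief_amplitude = 0,
                           base_elevation = 123, seed = 1)
  expect_true(all(flat$values == 123))
  a <- generate_terrain(ext, 0.5, 3, 10, 500, seed = 9)
  b <- generate_terrain(ext, 0.5, 3, 10, 500, seed = 9)
  expect_identical(a$values, b$values)
  expect_false(identical(
    a$values, generate_terrain(ext, 0.5, 3, 10, 500, seed = 10)$values))
  # brute force over many seeds: range never exceeds twice the amplitude
  ranges <- vapply(1:50, function(s) {
    diff(range(generate_terrain(c(0, 0, 20, 20), 0.5, 3, 8, 500, s)$values))
  }, numeric(1))
  expect_true(all(ranges <= 6 + 1e-9))
  expect_error(generate_terrain(ext, -1, 3), "positive")
  expect_error(generate_terrain(ext, 0.5, -2), ">= 0")
})

test_that("tree placement honours spacing, ranges and feasibility", {
  one <- place_trees(c(0, 0, 10, 10), 1, seed = 4)
  expect_equal(nrow(one$trees), 1L)
  expect_true(one$trees$x >= 0 && one$trees$x <= 10)
  expect_true(one$trees$y >= 0 && one$trees$y <= 10)

  tr <- place_trees(c(0, 0, 100, 100), 50, height_range = c(10, 30),
                    min_spacing = 6, seed = 21)$trees
  d <- as.matrix(stats::dist(cbind(tr$x, tr$y)))
  diag(d) <- Inf
  expect_true(min(d) >= 6)                       # brute-force pairwise check
  expect_true(all(tr$height_m >= 10 & tr$height_m <= 30))
  expect_equal(tr$dbh_cm, 2 * tr$height_m)       # default linear allometry
  expect_equal(tr$class_label, rep_len(1:3, 50))
  expect_error(place_trees(c(0, 0, 10, 10), 30, min_spacing = 8, seed = 1,
                           max_tries = 50), "could not place")
})

test_that("the DSM is the max of terrain and paraboloid crowns", {
  ext <- c(0, 0, 20, 20)
  terrain <- generate_terrain(ext, 0.1, relief_amplitude = 0,
                              base_elevation = 100, seed = 1)
  empty <- structure(list(trees = place_trees(ext, 1, seed = 1)$trees[0, ],
                          extent = ext, seed = 1), class = "scene_truth")
  expect_identical(render_dsm(terrain, empty)$values, terrain$values)

  truth <- place_trees(ext, 1, height_range = c(20, 20), crown_ratio = 0.15,
                       seed = 5)
  dsm <- render_dsm(terrain, truth)
  rc <- truth$trees$crown_radius_m
  eps_apex <- 20 * (0.1 / (sqrt(2) * rc))^2      # worst pixel-centre offset
  expect_gte(max(dsm$values), 100 + 20 - eps_apex)
  expect_lte(max(dsm$values), 100 + 20)
  expect_true(all(dsm$values >= terrain$values))

  bumpy <- generate_terrain(ext, 0.1, 2, 10, 500, seed = 3)
  dsm2 <- render_dsm(bumpy, truth)
  expect_true(all(dsm2$values >= bumpy$values))
})

test_that("rendered crowns are exact without noise and greener than ground", {
  sim <- tiny_clean_scene()
  fp <- crown_footprints(sim$terrain, sim$truth)
  cp <- default_colour_params()
  # a pixel owned by tree 1 carries exactly the class-1 colour
  own <- which(fp$values == 1, arr.ind = TRUE)[1, , drop = FALSE]
  cls <- sim$truth$trees$class_label[1]
  expect_equal(sim$ortho$red$values[own], cp$crown[cls, 1])
  expect_equal(sim$ortho$green$values[own], cp$crown[cls, 2])
  expect_equal(sim$ortho$blue$values[own], cp$crown[cls, 3])
  # greenness separation that the masking stage relies on
  ngbdi <- compute_index(normalize_bands(sim$ortho), "NGBDI")$grid$values
  expect_gt(mean(ngbdi[fp$values > 0]), mean(ngbdi[fp$values == 0]))

  again <- render_orthomosaic(sim$terrain, sim$truth, noise_sd = 0,
                              shadow_fraction = 0, seed = sim$params$seed + 3)
  expect_identical(again$red$values, sim$ortho$red$values)

  bad <- default_colour_params()
  bad$crown[2, ] <- c(80, 90, 120)               # blue-heavy crown
  expect_error(render_orthomosaic(sim$terrain, sim$truth, colour_params = bad,
                                  seed = 1), "green fraction")
})

test_that("field surveys respect the DBH rule and sample without replacement", {
  truth <- place_trees(c(0, 0, 60, 60), 30, height_range = c(10, 20),
                       min_spacing = 3, seed = 8)
  exact <- simulate_field_survey(truth, gnss_sd = 0, height_error_sd = 0,
                                 n_points = 30, seed = 2)
  exact <- exact[order(exact$id), ]
  expect_equal(exact$x, truth$trees$x)
  expect_equal(exact$height_m, truth$trees$height_m)

  # a 9 cm DBH tree is never sampled, whatever the seed
  small <- truth
  small$trees$dbh_cm[7] <- 9
  for (s in 1:15) {
    sv <- simulate_field_survey(small, n_points = 29, seed = s)
    expect_false(7 %in% sv$id)
  }
  expect_error(simulate_field_survey(small, n_points = 30, seed = 1),
               "DBH")
  sv <- simulate_field_survey(truth, n_points = 25, seed = 3)
  expect_equal(length(unique(sv$id)), 25L)
})

test_that("a scene is a pure function of its configuration and seed", {
  s1 <- simulate_scene(extent = c(0, 0, 15, 15), gsd = 0.25, n_trees = 3,
                       height_range = c(8, 12), min_spacing = 3,
                       n_field_points = 3, seed = 31)
  s2 <- simulate_scene(extent = c(0, 0, 15, 15), gsd = 0.25, n_trees = 3,
                       height_range = c(8, 12), min_spacing = 3,
                       n_field_points = 3, seed = 31)
  expect_identical(s1$dsm$values, s2$dsm$values)
  expect_identical(s1$ortho$green$values, s2$ortho$green$values)
  expect_identical(s1$survey, s2$survey)
  expect_true(grids_aligned(s1$terrain, s1$dsm, s1$ortho$red))
  diffv <- s1$dsm$values - s1$terrain$values
  expect_true(all(diffv >= 0))
  fp <- crown_footprints(s1$terrain, s1$truth)
  expect_true(all(diffv[fp$values == 0] == 0))
})
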