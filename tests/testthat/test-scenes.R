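test_that("single-berry scene renders the full contour with exact truth", {
  sp <- scene_spec(n_grapes = 1, dropout_rate = 0, spurious_rate = 0,
                   seed = 4)
  sc <- generate_cluster_scene(sp)
  e <- sc$truth$ellipses[[1]]
  px <- rasterize_ellipse_arc(e, 0, 2 * pi, sp$image_size)
  ref <- matrix(0L, sp$image_size[1], sp$image_size[2])
  ref[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 1L
  expect_identical(sc$edge_map, ref)
  expect_equal(sc$truth$areas[1], pi * e$a * e$b)
  expect_equal(sc$truth$visible_fraction[1], 1)
})

test_that("scenes are reproducible and respect their budgets", {
  sp <- scene_spec(n_grapes = 6, seed = 17)
  a <- generate_cluster_scene(sp)
  b <- generate_cluster_scene(sp)
  expect_identical(a$edge_map, b$edge_map)
  expect_identical(a$truth$areas, b$truth$areas)
  expect_true(all(a$truth$visible_fraction >= 1 - sp$max_occlusion))
  expect_true(all(a$truth$visible_fraction <= 1))
  # someone is occluded in a 6-berry overlapping cluster
  expect_lt(min(a$truth$visible_fraction), 1)
  # visible pixels subset of the union of full contours
  H <- sp$image_size[1]; W <- sp$image_size[2]
  full <- matrix(0L, H, W)
  for (e in a$truth$ellipses) {
    px <- rasterize_ellipse_arc(e, 0, 2 * pi, c(H, W))
    full[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 1L
  }
  expect_true(all(full[a$truth$clean_edge_map == 1L] == 1L))
  # boxes contain their ellipses
  for (g in seq_along(a$truth$ellipses)) {
    e <- a$truth$ellipses[[g]]
    bx <- a$truth$boxes[g, ]
    hw <- sqrt((e$a * cos(e$theta))^2 + (e$b * sin(e$theta))^2)
    hh <- sqrt((e$a * sin(e$theta))^2 + (e$b * cos(e$theta))^2)
    expect_true(e$cx - hw >= bx$x_min && e$cx + hw <= bx$x_max)
    expect_true(e$cy - hh >= bx$y_min && e$cy + hh <= bx$y_max)
  }
  expect_error(generate_cluster_scene(
    scene_spec(axis_range = c(200, 300), image_size = c(100, 100))),
    "infeasible")
})

test_that("occlusion matches the analytic circle-lens value", {
  # two unit-speed circles r=50, centers 50 apart, the second on top:
  # hidden arc of the first is |t| < pi/3 -> visible fraction 2/3
  e1 <- ellipse(100, 100, 50, 50)
  e2 <- ellipse(150, 100, 50, 50)
  oc <- occlude_contours(list(e1, e2))
  expect_equal(oc[[1]]$visible_fraction, 2 / 3, tolerance = 1e-2)
  expect_equal(oc[[2]]$visible_fraction, 1)
  # disjoint ellipses: fully visible
  far <- occlude_contours(list(ellipse(0, 0, 10, 5), ellipse(100, 0, 10, 5)))
  expect_equal(far[[1]]$visible_fraction, 1)
  expect_equal(nrow(far[[1]]$intervals), 1)
  # swallowed ellipse: empty visible set
  oc2 <- occlude_contours(list(ellipse(0, 0, 5, 5), ellipse(0, 0, 20, 20)))
  expect_equal(oc2[[1]]$visible_fraction, 0)
  expect_equal(nrow(oc2[[1]]$intervals), 0)
})

test_that("noise operator matches its binomial contract", {
  set.seed(1)
  base <- matrix(0L, 60, 60)
  base[sample(3600, 500)] <- 1L
  expect_identical(add_noise(base, 0, 0), base)
  expect_true(all(add_noise(base, 1, 0, seed = 2) == 0L))
  # surviving count within 3 sigma of Binomial(N, 1 - rate), across seeds
  N <- sum(base); rate <- 0.3
  surv <- vapply(1:100, function(s)
    sum(add_noise(base, rate, 0, seed = s)), 0)
  mu <- N * (1 - rate); sdv <- sqrt(N * rate * (1 - rate))
  expect_lt(abs(mean(surv) - mu), 3 * sdv / sqrt(100))
  expect_true(all(abs(surv - mu) < 5 * sdv))
  # spurious pixels are added deterministically per seed
  n1 <- add_noise(base, 0, 0.2, seed = 9)
  expect_identical(n1, add_noise(base, 0, 0.2, seed = 9))
  expect_gte(sum(n1), sum(base))
})

test_that("augmentation produces the full 96-fold transform grid", {
  img <- matrix(runif(32 * 32), 32, 32)
  aug <- augment_images(list(img))
  expect_length(aug, 96)
  tags <- unique(data.frame(
    flip = vapply(aug, `[[`, TRUE, "flip"),
    rot = vapply(aug, `[[`, 0, "rotation_deg"),
    sc = vapply(aug, `[[`, 0, "scale")))
  expect_equal(nrow(tags), 96)  # 2 x 16 x 3 distinct transforms
  # identity member reproduces the source
  id <- Filter(function(a) !a$flip && a$rotation_deg == 0 && a$scale == 1,
               aug)
  expect_length(id, 1)
  expect_equal(id[[1]]$image, img)
  # scale changes the raster size accordingly
  half <- Filter(function(a) a$scale == 0.5, aug)[[1]]
  expect_identical(dim(half$image), c(16L, 16L))
  expect_length(augment_images(list()), 0)
  expect_length(augment_images(list(img), include_flip = FALSE,
                               rotation_step_deg = 90, scales = 1), 4)
})

test_that("area series encodes trend, sinusoid, and recoverable signal", {
  lin <- generate_area_series(1000, 0, 0.1, days = 5, samples_per_day = 4)
  expect_equal(lin$area, 1000 * (1 + 0.1 * lin$t_days))
  sine <- generate_area_series(1000, 50, 0, days = 2, samples_per_day = 24)
  expect_equal(sine$area, 1000 + 50 * sin(2 * pi * sine$t_days))
  # one-day periodicity
  expect_equal(sine$area[1], sine$area[25])
  # trend recovery under 1% noise across seeds
  slopes <- vapply(1:50, function(s) {
    ser <- generate_area_series(1000, 0, 0.05, days = 6,
                                samples_per_day = 24, noise_sd = 0.01,
                                seed = s)
    unname(coef(lm(area ~ t_days, ser))[2]) / 1000
  }, 0)
  expect_lt(abs(mean(slopes) - 0.05) / 0.05, 0.05)
})
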