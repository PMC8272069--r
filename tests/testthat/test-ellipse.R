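test_that("constructor normalizes axes and orientation", {
  e <- ellipse(0, 0, 3, 5, 0)  # swapped axes
  expect_equal(e$a, 5)
  expect_equal(e$b, 3)
  expect_equal(e$theta, pi / 2)
  expect_equal(ellipse(1, 2, 4, 4, 1.3)$theta, 0)  # circle tie-break
  expect_equal(ellipse(0, 0, 5, 3, pi + 0.2)$theta, 0.2)  # mod pi
  expect_error(ellipse(0, 0, -1, 1), "positive")
})

test_that("area and long axis are closed-form", {
  e <- ellipse(0, 0, 5, 3, 0)
  expect_equal(ellipse_area(e), 15 * pi)
  expect_equal(ellipse_area(ellipse(0, 0, 1, 1)), pi)
  expect_equal(long_axis(e), 10)
  expect_gte(long_axis(e), 2 * e$b)
  # quadratic scaling of area
  k <- 2.7
  expect_equal(ellipse_area(ellipse(0, 0, 5 * k, 3 * k)),
               k^2 * ellipse_area(e))
})

test_that("perimeter matches the elliptic integral to 1e-6 relative", {
  expect_equal(ellipse_perimeter(ellipse(0, 0, 7, 7)), 2 * pi * 7)
  # frozen value: 4 a E(m) via an independent implementation
  expect_equal(ellipse_perimeter(ellipse(2, -3, 5, 3, 1.1)),
               25.52699886339813, tolerance = 1e-9)
  expect_equal(ellipse_perimeter(ellipse(0, 0, 10, 1)),
               dense_perimeter_oracle(10, 1), tolerance = 1e-6)
  # continuity at the circle limit and monotonicity in a
  expect_equal(ellipse_perimeter(ellipse(0, 0, 1 + 1e-9, 1)),
               2 * pi, tolerance = 1e-6)
  per <- vapply(seq(3, 8, by = 0.5),
                function(a) ellipse_perimeter(ellipse(0, 0, a, 3)), 0)
  expect_true(all(diff(per) > 0))
})

test_that("conic conversions invert each other", {
  set.seed(42)
  for (i in 1:25) {
    e <- random_ellipse()
    e2 <- conic_to_geometric(geometric_to_conic(e))
    expect_equal(e2$cx, e$cx, tolerance = 1e-9)
    expect_equal(e2$cy, e$cy, tolerance = 1e-9)
    expect_equal(e2$a, e$a, tolerance = 1e-9)
    expect_equal(e2$b, e$b, tolerance = 1e-9)
    if (e$a / e$b > 1 + 1e-6)
      expect_lt(min(abs(e2$theta - e$theta), pi - abs(e2$theta - e$theta)),
                1e-9)
  }
  expect_equal(conic_to_geometric(c(1 / 25, 0, 1 / 9, 0, 0, -1))$a, 5)
  expect_equal(conic_to_geometric(c(1, 0, 1, 0, 0, -4))$b, 2)
  expect_error(conic_to_geometric(c(1, 0, -1, 0, 0, -1)), "not an ellipse")
})

test_that("direct least-squares fit interpolates 5 points exactly", {
  pts <- cbind(x = c(5, -5, 0, 0, 4), y = c(0, 0, 3, -3, 1.8))
  # oracle: the unique conic through these 5 points is the ellipse
  # x^2/25 + y^2/9 = 1 (the 5th point satisfies 16/25 + 3.24/9 = 1)
  co <- conic_through_5(pts)
  eo <- conic_to_geometric(co)
  e <- fit_ellipse_lsq(pts)
  expect_equal(e$cx, 0, tolerance = 1e-8)
  expect_equal(e$cy, 0, tolerance = 1e-8)
  expect_equal(e$a, 5, tolerance = 1e-8)
  expect_equal(e$b, 3, tolerance = 1e-8)
  expect_equal(e$theta, 0, tolerance = 1e-8)
  expect_equal(eo$a, e$a, tolerance = 1e-8)
  # circle through symmetric points
  ec <- fit_ellipse_lsq(cbind(c(2, 0, -2, 0, sqrt(2)),
                              c(0, 2, 0, -2, sqrt(2))))
  expect_equal(ec$a, 2, tolerance = 1e-8)
  expect_equal(ec$b, 2, tolerance = 1e-8)
  expect_equal(c(ec$cx, ec$cy), c(0, 0), tolerance = 1e-8)
})

test_that("degenerate inputs signal fit failure, never a wrong conic", {
  line <- cbind(1:5, 1:5)
  expect_error(fit_ellipse_lsq(line), class = "vitifit_fit_error")
  expect_error(fit_ellipse_lsq(cbind(rep(1, 6), rep(2, 6))),
               class = "vitifit_fit_error")
  expect_error(fit_ellipse_lsq(cbind(1:4, c(1, 2, 1, 2))),
               class = "vitifit_fit_error")  # < 5 points
})

test_that("fit recovers random ellipses from noiseless samples", {
  set.seed(7)
  for (i in 1:20) {
    e <- random_ellipse(amin = 5, amax = 60)
    t <- seq(0, 2 * pi, length.out = 51)[-51]
    ct <- cos(e$theta); st <- sin(e$theta)
    pts <- cbind(e$cx + ct * e$a * cos(t) - st * e$b * sin(t),
                 e$cy + st * e$a * cos(t) + ct * e$b * sin(t))
    f <- fit_ellipse_lsq(pts)
    expect_equal(f$cx, e$cx, tolerance = 1e-6)
    expect_equal(f$cy, e$cy, tolerance = 1e-6)
    expect_equal(f$a, e$a, tolerance = 1e-6)
    expect_equal(f$b, e$b, tolerance = 1e-6)
    if (e$a / e$b > 1 + 1e-6)
      expect_lt(min(abs(f$theta - e$theta), pi - abs(f$theta - e$theta)),
                1e-6)
  }
})

test_that("foot-point distance agrees with oracles", {
  e <- ellipse(0, 0, 5, 3, 0)
  expect_equal(point_ellipse_distance(cbind(10, 0), e), 5)
  expect_equal(point_ellipse_distance(cbind(0, 0), e), 3)
  expect_equal(point_ellipse_distance(cbind(0, 7), e), 4)
  # frozen dense-sampling oracle values (2e6 parametric samples)
  expect_equal(point_ellipse_distance(cbind(4, 2), e),
               0.158125572974644, tolerance = 1e-6)
  expect_equal(point_ellipse_distance(cbind(7, 1), e),
               2.128750980371581, tolerance = 1e-6)
  # fresh oracle comparison on rotated/translated ellipses,
  # inside and outside points
  set.seed(11)
  for (i in 1:6) {
    er <- random_ellipse(amin = 3, amax = 20)
    p <- c(er$cx + runif(1, -25, 25), er$cy + runif(1, -25, 25))
    expect_equal(point_ellipse_distance(rbind(p), er),
                 dense_distance_oracle(p, er, n = 2e5), tolerance = 1e-4)
  }
})

test_that("distance is zero on the boundary and positive elsewhere", {
  set.seed(3)
  for (i in 1:10) {
    e <- random_ellipse()
    t <- runif(40, 0, 2 * pi)
    ct <- cos(e$theta); st <- sin(e$theta)
    pts <- cbind(e$cx + ct * e$a * cos(t) - st * e$b * sin(t),
                 e$cy + st * e$a * cos(t) + ct * e$b * sin(t))
    expect_true(all(point_ellipse_distance(pts, e) < 1e-9))
  }
  expect_gt(point_ellipse_distance(cbind(0.1, 0.1), ellipse(0, 0, 5, 3)), 0)
})

test_that("rasterized contours are dense, thin, and near the curve", {
  e <- ellipse(100, 100, 50, 50, 0)
  px <- rasterize_ellipse_arc(e, 0, 2 * pi, c(200, 200))
  expect_gte(nrow(px), 2 * pi * 50)
  expect_lte(nrow(px), 1.5 * 2 * pi * 50)
  expect_true(all(point_ellipse_distance(px, e) <= 1))
  expect_equal(nrow(unique(px)), nrow(px))
  # 8-connectivity along the chain
  d <- cbind(diff(px[, 1]), diff(px[, 2]))
  expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))
  # degenerate arc
  expect_lte(nrow(rasterize_ellipse_arc(e, 1, 1, c(200, 200))), 1)
  # fully outside the image
  far <- ellipse(1000, 1000, 20, 10, 0.5)
  expect_equal(nrow(rasterize_ellipse_arc(far, 0, 2 * pi, c(100, 100))), 0)
  # arcs clip to bounds
  partial <- rasterize_ellipse_arc(ellipse(0, 0, 30, 20, 0.3), 0, 2 * pi,
                                   c(50, 50))
  expect_true(all(partial[, 1] >= 0 & partial[, 1] <= 49 &
                  partial[, 2] >= 0 & partial[, 2] <= 49))
})
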