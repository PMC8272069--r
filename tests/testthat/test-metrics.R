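toy_map <- function(H, W, lin) {
  m <- matrix(0, H, W)
  m[lin] <- 1
  m
}

test_that("edge matching agrees with the brute-force oracle", {
  set.seed(8)
  for (rep in 1:12) {
    H <- 20; W <- 20
    X <- toy_map(H, W, sample(H * W, sample(5:40, 1)))
    Y <- toy_map(H, W, sample(H * W, sample(5:40, 1)))
    tol <- sample(c(0, 1, 2, 3), 1)
    m <- match_edge_pixels(X, Y, tol)
    o <- brute_match_oracle(X, Y, tol)
    expect_identical(m$TP, o$TP)
    expect_identical(m$count_X, o$count_X)
    expect_identical(m$count_Y, o$count_Y)
    expect_identical(m$FN, o$count_Y - o$TP)
    expect_lte(m$TP, min(m$count_X, m$count_Y))
  }
})

test_that("matching handles identity, shift, and disjoint cases", {
  Y <- toy_map(20, 20, c(45, 67, 150, 290, 301))
  expect_identical(match_edge_pixels(Y, Y, 0)$TP, 5L)
  expect_identical(match_edge_pixels(Y, Y, 0)$FN, 0L)
  # 1-px shift matched at tol 1
  X <- matrix(0, 20, 20)
  X[2:19, ] <- Y[1:18, ]
  m <- match_edge_pixels(X, Y, 1)
  expect_gte(m$TP, m$count_Y - 2)
  disj <- matrix(0, 20, 20); disj[400] <- 1
  m2 <- match_edge_pixels(disj, Y, 1)
  expect_identical(m2$TP, 0L)
  expect_identical(m2$FN, 5L)
  expect_error(match_edge_pixels(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("D, R, A follow their formulas on known counts", {
  m <- structure(list(TP = 3L, FN = 3L, count_X = 4L, count_Y = 6L),
                 class = "edge_match")
  expect_equal(dice_coefficient(m), 0.6)
  expect_equal(pixel_recall(m), 0.5)
  expect_equal(redundancy_rate(m), 25)
  m2 <- structure(list(TP = 69L, FN = 31L, count_X = 100L, count_Y = 100L),
                  class = "edge_match")
  expect_equal(pixel_recall(m2), 0.69)
  expect_equal(redundancy_rate(m2), 31)
  perfect <- structure(list(TP = 10L, FN = 0L, count_X = 10L,
                            count_Y = 10L), class = "edge_match")
  expect_equal(dice_coefficient(perfect), 1)
  expect_equal(redundancy_rate(perfect), 0)
  zero <- structure(list(TP = 0L, FN = 10L, count_X = 8L, count_Y = 10L),
                    class = "edge_match")
  expect_equal(pixel_recall(zero), 0)
  expect_equal(redundancy_rate(zero), 100)
})

test_that("D and R are translation invariant", {
  set.seed(12)
  X <- toy_map(30, 30, sample(200:600, 25))
  Y <- toy_map(30, 30, sample(200:600, 25))
  shift <- function(M) {
    S <- matrix(0, 30, 30)
    S[6:30, 6:30] <- M[1:25, 1:25]
    S
  }
  m1 <- match_edge_pixels(X, Y, 2)
  m2 <- match_edge_pixels(shift(X), shift(Y), 2)
  # pixels shifted out of frame: restrict to interior content
  expect_equal(dice_coefficient(m2),
               dice_coefficient(match_edge_pixels(X[1:25, 1:25],
                                                  Y[1:25, 1:25], 2)))
})

test_that("fitting recall and AARD are the stated ratios", {
  expect_equal(fitting_recall(60, 60), 100)
  expect_equal(fitting_recall(0, 60), 0)
  expect_equal(fitting_recall(58, 60), 96.66667, tolerance = 1e-6)
  expect_error(fitting_recall(1, 0), "positive")
  expect_equal(aard(c(100, 100), c(100, 100)), 0)
  expect_equal(aard(90, 100), 10)
  expect_error(aard(numeric(0), numeric(0)), "empty")
  # scale invariance
  set.seed(4)
  ms <- runif(10, 80, 120); ts <- runif(10, 80, 120)
  expect_equal(aard(ms, ts), aard(7.3 * ms, 7.3 * ts))
})

test_that("nms thinning collapses ridges and is idempotent", {
  # 7x7 horizontal ridge: rows 3..5 at 0.5, 1.0, 0.5 -> crest is row 4
  P <- matrix(0, 7, 7)
  P[3, ] <- 0.5; P[4, ] <- 1; P[5, ] <- 0.5
  thin <- nms_thin(P)
  expect_true(all(thin[4, 2:6] == 1))
  expect_true(all(thin[c(3, 5), 2:6] == 0))
  # already-thin line unchanged
  L <- matrix(0, 7, 7); L[4, 2:6] <- 0.8
  expect_equal(nms_thin(L), L)
  expect_equal(nms_thin(matrix(0, 5, 5)), matrix(0, 5, 5))
  # idempotence on random smooth maps
  set.seed(9)
  for (i in 1:5) {
    M <- gaussian_blur_for_test(matrix(runif(400), 20, 20))
    t1 <- nms_thin(M)
    expect_identical(nms_thin(t1), t1)
  }
})

test_that("ods/ois behave as F-measure envelopes", {
  set.seed(14)
  truths <- lapply(1:3, function(i) toy_map(25, 25, sample(625, 30)))
  # predictions equal to truths: both scores are 1 at every threshold
  r <- ods_ois(truths, truths)
  expect_equal(r$ods, 1)
  expect_equal(r$ois, 1)
  # all-zero predictions: 0
  zero <- lapply(1:3, function(i) matrix(0, 25, 25))
  r0 <- ods_ois(zero, truths)
  expect_equal(r0$ods, 0)
  expect_equal(r0$ois, 0)
  # graded predictions: OIS >= ODS, both in [0, 1]
  preds <- lapply(truths, function(G) {
    P <- G * matrix(runif(625, 0.3, 1), 25, 25)
    P + (1 - G) * matrix(runif(625, 0, 0.4), 25, 25)
  })
  rg <- ods_ois(preds, truths)
  expect_gte(rg$ois, rg$ods)
  expect_true(rg$ods >= 0 && rg$ois <= 1)
  expect_error(ods_ois(preds, truths[1:2]), "counts differ")
})

test_that("two-image toy set reproduces hand-computed F values", {
  # image 1: P has 3 pixels at 0.9 on truth, 1 pixel at 0.4 off truth
  G1 <- toy_map(10, 10, c(12, 34, 56))
  P1 <- matrix(0, 10, 10); P1[c(12, 34, 56)] <- 0.9; P1[90] <- 0.4
  # image 2: P misses one of two truth pixels
  G2 <- toy_map(10, 10, c(22, 77))
  P2 <- matrix(0, 10, 10); P2[22] <- 0.9
  r <- ods_ois(list(P1, P2), list(G1, G2), thresholds = c(0.3, 0.6),
               tol = 0)
  # t=0.6: img1 P=R=1 -> F=1; img2 P=1, R=0.5 -> F=2/3
  # t=0.3: img1 P=3/4, R=1 -> F=6/7; img2 F=2/3
  expect_equal(r$f_matrix[1, ], c(6 / 7, 1))
  expect_equal(r$f_matrix[2, ], c(2 / 3, 2 / 3))
  expect_equal(r$ods, mean(c(1, 2 / 3)))
  expect_equal(r$ois, mean(c(1, 2 / 3)))
  expect_equal(r$ods_threshold, 0.6)
})
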