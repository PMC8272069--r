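# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (brute force, dense sampling, enumeration).

# unique conic through exactly 5 points, by null space of the 5x6 design
# matrix; returns c(A,B,C,D,E,F)
conic_through_5 <- function(pts) {
  stopifnot(nrow(pts) == 5)
  x <- pts[, 1]; y <- pts[, 2]
  M <- cbind(x^2, x * y, y^2, x, y, 1)
  v <- svd(M, nv = 6)$v[, 6]
  v / sqrt(sum(v^2))
}

# distance from a point to an ellipse by dense parametric sampling
dense_distance_oracle <- function(p, e, n = 1e6) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  ct <- cos(e$theta); st <- sin(e$theta)
  ex <- e$cx + ct * e$a * cos(t) - st * e$b * sin(t)
  ey <- e$cy + st * e$a * cos(t) + ct * e$b * sin(t)
  sqrt(min((ex - p[1])^2 + (ey - p[2])^2))
}

# perimeter by dense polygonal arc-length sum (independent of integrate())
dense_perimeter_oracle <- function(a, b, n = 2e6) {
  t <- seq(0, 2 * pi, length.out = n + 1)
  x <- a * cos(t); y <- b * sin(t)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# greedy one-to-one matching by global nearest pair, brute force over the
# full distance table; same tie-break order as the implementation
brute_match_oracle <- function(X, Y, tol) {
  H <- nrow(X)
  xi <- which(X != 0); yi <- which(Y != 0)
  if (length(xi) == 0 || length(yi) == 0)
    return(list(TP = 0L, count_X = length(xi), count_Y = length(yi)))
  xr <- (xi - 1) %% H; xc <- (xi - 1) %/% H
  yr <- (yi - 1) %% H; yc <- (yi - 1) %/% H
  D <- outer(xr, yr, function(a, b) (a - b)^2) +
       outer(xc, yc, function(a, b) (a - b)^2)
  D <- sqrt(D)
  pairs <- which(D <= tol, arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(list(TP = 0L, count_X = length(xi), count_Y = length(yi)))
  d <- D[pairs]
  ord <- order(d, pairs[, 1], pairs[, 2])
  xm <- logical(length(xi)); ym <- logical(length(yi))
  TP <- 0L
  for (k in ord) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!xm[i] && !ym[j]) {
      xm[i] <- TRUE; ym[j] <- TRUE; TP <- TP + 1L
    }
  }
  list(TP = TP, count_X = length(xi), count_Y = length(yi))
}

# best fitness over all 5-point subsets of a tiny contour (enumeration)
exhaustive_fitness_oracle <- function(contour, d) {
  n <- nrow(contour)
  idx <- utils::combn(n, 5)
  best <- 0
  for (k in seq_len(ncol(idx))) {
    e <- tryCatch(fit_ellipse_lsq(contour[idx[, k], , drop = FALSE]),
                  error = function(err) NULL)
    if (is.null(e)) next
    f <- ellipse_fitness(e, contour, d)
    if (f > best) best <- f
  }
  best
}

gaussian_blur_for_test <- function(m, sigma = 1) {
  vitifit:::gaussian_blur(m, sigma)
}

# random ellipse helper (draws from the current RNG stream)
random_ellipse <- function(amin = 10, amax = 80, aspect_max = 5,
                          cx = runif(1, -50, 50), cy = runif(1, -50, 50)) {
  a <- runif(1, amin, amax)
  b <- runif(1, a / aspect_max, a)
  ellipse(cx, cy, a, b, runif(1, 0, pi))
}

empty_boxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), score = numeric(0))
}
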