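#' Geometric ellipse
#'
#' Construct an ellipse in image coordinates. `x` is the column index and
#' `y` the row index, both 0-based; `theta` is the orientation of the major
#' axis in radians, measured counter-clockwise from the +x axis in the
#' mathematical sense, and is normalized to `[0, pi)`. If `a < b` the axes
#' are swapped (and `theta` rotated by `pi/2`) so that `a >= b` always
#' holds; for circles (`a == b`) `theta` is fixed at 0.
#'
#' @param cx,cy center, pixels.
#' @param a,b semi-axes, pixels; both must be positive.
#' @param theta major-axis orientation, radians.
#' @return An object of class `"ellipse"`: a named list with fields
#'   `cx`, `cy`, `a`, `b`, `theta`.
#' @examples
#' e <- ellipse(10, 20, 5, 3, pi / 4)
#' long_axis(e)
#' ellipse_area(e)
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(a), is.finite(b),
            is.finite(theta))
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  if (a < b) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  theta <- theta %% pi
  if (isTRUE(all.equal(a, b, tolerance = 1e-12))) theta <- 0
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse")
}

#' @export
print.ellipse <- function(x, ...) {
  cat(sprintf("ellipse: center (%.3f, %.3f), a = %.3f, b = %.3f, theta = %.4f rad\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' @export
format.ellipse <- function(x, ...) {
  sprintf("ellipse(%g, %g, %g, %g, %g)", x$cx, x$cy, x$a, x$b, x$theta)
}

is_ellipse <- function(x) inherits(x, "ellipse")

#' Projected area of an ellipse
#'
#' @param e an [ellipse()].
#' @return `pi * a * b`, square pixels.
#' @export
ellipse_area <- function(e) {
  stopifnot(is_ellipse(e))
  pi * e$a * e$b
}

#' Long axis of an ellipse
#'
#' The long (major) axis, `2 a`, the berry length phenotype.
#'
#' @param e an [ellipse()].
#' @return length in pixels.
#' @export
long_axis <- function(e) {
  stopifnot(is_ellipse(e))
  2 * e$a
}

#' Ellipse perimeter
#'
#' Evaluates the complete elliptic integral of the second kind by adaptive
#' quadrature (no series approximation), so downstream ratios that divide
#' by the perimeter carry no approximation bias.
#'
#' @param e an [ellipse()].
#' @return perimeter in pixels, relative accuracy better than 1e-10.
#' @export
ellipse_perimeter <- function(e) {
  stopifnot(is_ellipse(e))
  a <- e$a; b <- e$b
  if (a == b) return(2 * pi * a)
  m <- 1 - (b / a)^2  # squared eccentricity
  f <- function(t) sqrt(1 - m * sin(t)^2)
  4 * a * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12,
                           abs.tol = 0)$value
}

#' Convert geometric ellipse parameters to conic coefficients
#'
#' Returns the coefficients `(A, B, C, D, E, F)` of
#' `A x^2 + B x y + C y^2 + D x + E y + F = 0`, normalized so that
#' `F0 = -1` in the centered frame (the coefficient vector is only defined
#' up to scale).
#'
#' @param e an [ellipse()].
#' @return named numeric vector `c(A, B, C, D, E, F)`.
#' @export
geometric_to_conic <- function(e) {
  stopifnot(is_ellipse(e))
  ct <- cos(e$theta); st <- sin(e$theta)
  a2 <- e$a^2; b2 <- e$b^2
  A <- ct^2 / a2 + st^2 / b2
  B <- 2 * ct * st * (1 / a2 - 1 / b2)
  C <- st^2 / a2 + ct^2 / b2
  D <- -2 * A * e$cx - B * e$cy
  E <- -B * e$cx - 2 * C * e$cy
  F <- A * e$cx^2 + B * e$cx * e$cy + C * e$cy^2 - 1
  c(A = A, B = B, C = C, D = D, E = E, F = F)
}

#' Convert conic coefficients to a geometric ellipse
#'
#' @param conic numeric vector `(A, B, C, D, E, F)` of
#'   `A x^2 + B x y + C y^2 + D x + E y + F = 0`. Must satisfy the ellipse
#'   discriminant `B^2 - 4AC < 0`; otherwise (parabola, hyperbola,
#'   degenerate conic) an error is thrown.
#' @return an [ellipse()].
#' @export
conic_to_geometric <- function(conic) {
  stopifnot(is.numeric(conic), length(conic) == 6, all(is.finite(conic)))
  A <- conic[[1]]; B <- conic[[2]]; C <- conic[[3]]
  D <- conic[[4]]; E <- conic[[5]]; F <- conic[[6]]
  disc <- B^2 - 4 * A * C
  if (!(disc < 0)) stop("conic is not an ellipse (B^2 - 4AC >= 0)")
  # center from grad = 0: [2A B; B 2C] (cx, cy)' = (-D, -E)'
  M <- matrix(c(2 * A, B, B, 2 * C), 2, 2)
  ctr <- solve(M, c(-D, -E))
  cx <- ctr[1]; cy <- ctr[2]
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  # quadratic form Q = [A B/2; B/2 C]; axis^2 = -F0 / eigenvalue
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eg$values
  if (any(!is.finite(ax2)) || any(ax2 <= 0))
    stop("degenerate conic: no real ellipse locus")
  # eigen() sorts values decreasing; smaller eigenvalue -> major axis
  a <- sqrt(ax2[2]); b <- sqrt(ax2[1])
  v <- eg$vectors[, 2]
  theta <- atan2(v[2], v[1])
  ellipse(cx, cy, a, b, theta)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to scattered points with the ellipse-specific direct
#' least-squares formulation (constraint `4AC - B^2 = 1`) in the
#' numerically stable partitioned form of Halir and Flusser: the conic is
#' split into quadratic and linear blocks and the constrained eigenproblem
#' is solved on the reduced 3x3 matrix. The constraint guarantees the
#' returned conic is an ellipse; a hyperbola or parabola is never silently
#' returned. With exactly 5 points in general position the unique
#' interpolating conic is recovered (residual zero) provided it is an
#' ellipse.
#'
#' Points are mean-centered before fitting and the conic is translated
#' back, which keeps the scatter matrix well conditioned for contours far
#' from the origin.
#'
#' @param pts two-column matrix (or data.frame) of point coordinates,
#'   columns `x` (column index) and `y` (row index); at least 5 points.
#' @return an [ellipse()] on success; throws an error of class
#'   `"vitifit_fit_error"` for degenerate input (fewer than 5 distinct
#'   points, collinear points, or no ellipse solution).
#' @seealso [conic_to_geometric()], [ransac_fit_ellipse()]
#' @export
fit_ellipse_lsq <- function(pts) {
  pts <- as_point_matrix(pts)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 5) fit_error("need at least 5 distinct points")
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  x <- pts[, 1] - mx; y <- pts[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T)) fit_error("degenerate point configuration")
  M <- S1 + S2 %*% T
  # premultiply by C1^{-1} for constraint matrix C1 = [0 0 2; 0 -1 0; 2 0 0]
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(eg)) fit_error("eigen decomposition failed")
  evec <- Re(eg$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2  # 4AC - B^2 > 0
  ok <- which(cond > 1e-12 & abs(Im(eg$values)) < 1e-8)
  if (length(ok) == 0) fit_error("no ellipse solution for these points")
  a1 <- evec[, ok[1]]
  a2 <- as.vector(T %*% a1)
  co <- c(a1, a2)
  # undo the centering shift: substitute x -> x - mx, y -> y - my
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  Dn <- D - 2 * A * mx - B * my
  En <- E - B * mx - 2 * C * my
  Fn <- F + A * mx^2 + B * mx * my + C * my^2 - D * mx - E * my
  e <- tryCatch(conic_to_geometric(c(A, B, C, Dn, En, Fn)),
                error = function(err) NULL)
  if (is.null(e)) fit_error("fit produced a degenerate conic")
  e
}

fit_error <- function(msg) {
  stop(structure(class = c("vitifit_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# coerce list/data.frame/matrix point input to an n x 2 numeric matrix
as_point_matrix <- function(pts) {
  if (is.data.frame(pts)) pts <- as.matrix(pts[, c("x", "y")])
  if (!is.matrix(pts) || ncol(pts) != 2)
    stop("points must be an n x 2 matrix or data.frame with columns x, y")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts))) stop("points must be finite")
  colnames(pts) <- c("x", "y")
  pts
}

#' Orthogonal distance from points to an ellipse
#'
#' Euclidean distance from each point to the nearest point on the ellipse
#' boundary (foot-point distance, not an algebraic residual). Solved with
#' the robust bracketed bisection of the foot-point equation in the
#' ellipse-aligned first quadrant, vectorized over points; works for
#' points inside and outside the ellipse.
#'
#' @param pts two-column matrix (or data.frame) of points, columns `x`, `y`.
#' @param e an [ellipse()].
#' @return numeric vector of non-negative distances, one per point,
#'   accurate to well below 1e-9.
#' @export
point_ellipse_distance <- function(pts, e) {
  stopifnot(is_ellipse(e))
  pts <- as_point_matrix(pts)
  fp <- ellipse_foot_point(pts, e)
  unname(sqrt((fp[, 1] - pts[, 1])^2 + (fp[, 2] - pts[, 2])^2))
}

# Nearest boundary point for each input point; returns n x 2 matrix in
# image coordinates. Used by point_ellipse_distance and arc rasterization.
ellipse_foot_point <- function(pts, e) {
  ct <- cos(e$theta); st <- sin(e$theta)
  dx <- pts[, 1] - e$cx; dy <- pts[, 2] - e$cy
  u0 <- ct * dx + st * dy
  v0 <- -st * dx + ct * dy
  su <- ifelse(u0 >= 0, 1, -1)
  sv <- ifelse(v0 >= 0, 1, -1)
  u <- abs(u0); v <- abs(v0)
  a <- e$a; b <- e$b
  n <- length(u)
  fx <- numeric(n); fy <- numeric(n)
  if (a == b) {
    r <- sqrt(u^2 + v^2)
    on_ctr <- r < 1e-300
    scale <- ifelse(on_ctr, 0, a / pmax(r, 1e-300))
    fx <- ifelse(on_ctr, a, u * scale)
    fy <- ifelse(on_ctr, 0, v * scale)
  } else {
    tiny <- 1e-12 * b
    gen <- v > tiny
    if (any(gen)) {
      ug <- u[gen]; vg <- v[gen]
      lo <- -b^2 + b * vg
      hi <- -b^2 + sqrt(a^2 * ug^2 + b^2 * vg^2)
      for (i in seq_len(100)) {
        mid <- 0.5 * (lo + hi)
        f <- (a * ug / (mid + a^2))^2 + (b * vg / (mid + b^2))^2 - 1
        pos <- f > 0
        lo <- ifelse(pos, mid, lo)
        hi <- ifelse(pos, hi, mid)
        if (max(hi - lo) < 1e-14 * (a^2 + max(hi))) break
      }
      t <- 0.5 * (lo + hi)
      fx[gen] <- a^2 * ug / (t + a^2)
      fy[gen] <- b^2 * vg / (t + b^2)
    }
    if (any(!gen)) {
      # v == 0: nearest point is off-axis while u is inside the evolute cusp
      ud <- u[!gen]
      cusp <- (a^2 - b^2) / a
      inner <- ud < cusp
      x0 <- ifelse(inner, a^2 * ud / (a^2 - b^2), a)
      y0 <- ifelse(inner, b * sqrt(pmax(0, 1 - (x0 / a)^2)), 0)
      fx[!gen] <- x0
      fy[!gen] <- y0
    }
  }
  fx <- su * fx; fy <- sv * fy
  cbind(x = e$cx + ct * fx - st * fy,
        y = e$cy + st * fx + ct * fy)
}

# parametric point on the ellipse at eccentric angle t (vectorized)
ellipse_param_point <- function(e, t) {
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$a * cos(t); py <- e$b * sin(t)
  cbind(x = e$cx + ct * px - st * py,
        y = e$cy + st * px + ct * py)
}

#' Rasterize an ellipse arc to a 1-pixel chain
#'
#' Produces an 8-connected, single-pixel-wide chain of integer pixel
#' coordinates tracing the arc of eccentric angles `[t0, t1]`, clipped to
#' the image. Diagonal steps of the rounded trace are completed with the
#' 4-neighbor closest to the curve, so the chain is dense (its length is
#' the L1 length of the arc) and every emitted pixel lies within 1 px
#' orthogonal distance of the ellipse.
#'
#' @param e an [ellipse()].
#' @param t0,t1 eccentric-angle range, radians, `t0 <= t1`; the full range
#'   `[0, 2*pi)` yields a closed contour.
#' @param image_shape integer `c(H, W)`: number of rows and columns. Pixels
#'   outside `[0, W-1] x [0, H-1]` are dropped; an ellipse entirely outside
#'   the image yields a 0-row result.
#' @return integer matrix with columns `x`, `y`, ordered along the arc,
#'   duplicate-free.
#' @export
rasterize_ellipse_arc <- function(e, t0 = 0, t1 = 2 * pi, image_shape) {
  stopifnot(is_ellipse(e), t0 <= t1, length(image_shape) == 2)
  H <- image_shape[1]; W <- image_shape[2]
  if (t1 - t0 < 1e-12) {
    p <- round(ellipse_param_point(e, t0))
    return(clip_pixels(p, H, W))
  }
  closed <- (t1 - t0) >= 2 * pi - 1e-9
  # sample densely enough that consecutive rounded pixels are 8-neighbors
  arc_ub <- (t1 - t0) * max(e$a, e$b)
  ns <- max(8L, ceiling(arc_ub * 8))
  tt <- seq(t0, t1, length.out = ns + 1L)
  if (closed) tt <- tt[-length(tt)]
  pp <- ellipse_param_point(e, tt)
  pix <- round(pp)
  keep <- c(TRUE, diff(pix[, 1]) != 0 | diff(pix[, 2]) != 0)
  pix <- pix[keep, , drop = FALSE]
  if (closed && nrow(pix) > 1 &&
      all(pix[1, ] == pix[nrow(pix), ]))
    pix <- pix[-nrow(pix), , drop = FALSE]
  pix <- fill_diagonal_steps(pix, e, closed)
  clip_pixels(pix, H, W)
}

# insert a 4-neighbor pixel into each diagonal step, choosing the
# candidate nearer the true curve
fill_diagonal_steps <- function(pix, e, closed) {
  n <- nrow(pix)
  if (n < 2) return(pix)
  nxt <- if (closed) c(2:n, 1L) else c(2:n, n)
  dx <- pix[nxt, 1] - pix[, 1]
  dy <- pix[nxt, 2] - pix[, 2]
  diag_step <- abs(dx) == 1 & abs(dy) == 1
  if (!any(diag_step)) return(pix)
  i <- which(diag_step)
  cand1 <- cbind(pix[i, 1] + dx[i], pix[i, 2])
  cand2 <- cbind(pix[i, 1], pix[i, 2] + dy[i])
  d1 <- point_ellipse_distance(cand1, e)
  d2 <- point_ellipse_distance(cand2, e)
  ins <- ifelse(d1 <= d2, seq_along(i), -seq_along(i))
  fill <- cand1
  fill[ins < 0, ] <- cand2[ins < 0, , drop = FALSE]
  out <- matrix(0, n + length(i), 2)
  pos <- seq_len(n) + findInterval(seq_len(n) - 1L, i)
  out[pos, ] <- pix
  out[setdiff(seq_len(nrow(out)), pos), ] <- fill
  out
}

clip_pixels <- function(pix, H, W) {
  pix <- pix[pix[, 1] >= 0 & pix[, 1] <= W - 1 &
             pix[, 2] >= 0 & pix[, 2] <= H - 1, , drop = FALSE]
  pix <- unique(pix)
  storage.mode(pix) <- "integer"
  colnames(pix) <- c("x", "y")
  pix
}
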