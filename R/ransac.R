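#' RANSAC configuration for iterative ellipse fitting
#'
#' @param p probability that at least one of the K draws is all-inlier,
#'   in (0, 1). Default 0.99.
#' @param err assumed fraction of outlier ("outer") points among the
#'   contour pixels, in `[0, 1)`. Default 0.5.
#' @param s sample size per draw, integer >= 5. Five points determine a
#'   conic, so 5 is the minimal (and default) sample.
#' @param d inlier distance threshold in pixels (> 0): a contour pixel is
#'   an inner point of a model when its orthogonal distance to the fitted
#'   ellipse is at most `d`. Default 2.0 px (about twice the rasterization
#'   error of a 1-px contour).
#' @param min_fitness acceptance floor on the fitness score used by the
#'   pipeline to discard spurious fits. Default 0.5.
#' @param max_iterations hard cap on K; the iteration-count formula
#'   diverges as `err` approaches 1. Default 2000.
#' @param refine number of final consensus refits: after the K draws the
#'   best model is re-estimated by least squares over its consensus set,
#'   iterated `refine` times with an annealed band (the first half of the
#'   passes collect inliers within `d`, the remaining passes within
#'   `d/2`, which sheds border-band noise pixels before the last fit).
#'   0 disables. Default 4.
#' @param seed integer RNG seed owned by the fitting call (the global RNG
#'   state is left untouched). Default 1.
#' @return a list of class `"ransac_config"`.
#' @export
ransac_config <- function(p = 0.99, err = 0.5, s = 5L, d = 2.0,
                          min_fitness = 0.5, max_iterations = 2000L,
                          refine = 4L, seed = 1L) {
  stopifnot(p > 0, p < 1, err >= 0, err < 1, s >= 5, d > 0,
            min_fitness >= 0, max_iterations >= 1, refine >= 0)
  structure(list(p = p, err = err, s = as.integer(s), d = d,
                 min_fitness = min_fitness,
                 max_iterations = as.integer(max_iterations),
                 refine = as.integer(refine),
                 seed = as.integer(seed)),
            class = "ransac_config")
}

#' Number of RANSAC iterations
#'
#' `K = ceil( log(1 - p) / log(1 - (1 - err)^s) )`, floored at 1: the
#' number of random draws needed so that with probability `p` at least one
#' draw contains only inlier points, when a fraction `err` of the data are
#' outliers and each draw samples `s` points.
#'
#' @param p success probability in (0, 1).
#' @param err outlier fraction in `[0, 1)`.
#' @param s sample size per draw (>= 5).
#' @return integer K >= 1.
#' @examples
#' compute_iteration_count(0.99, 0.5, 5) # 146
#' compute_iteration_count(0.95, 0.3, 5) # 17
#' @export
compute_iteration_count <- function(p, err, s) {
  stopifnot(s >= 1)
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)")
  if (!(err >= 0 && err < 1)) stop("err must lie in [0, 1)")
  w <- (1 - err)^s  # probability a single draw is all-inlier
  if (w >= 1) return(1L)
  K <- ceiling(log(1 - p) / log(1 - w))
  max(1L, as.integer(K))
}

#' Fitness of an ellipse model against contour pixels
#'
#' The consensus score of the iterative fit: the number of contour pixels
#' whose orthogonal distance to the ellipse is at most `d`, divided by the
#' ellipse perimeter. A perfectly covered contour scores close to the
#' rasterization density (roughly 1 to 1.5); sparse or wrong models score
#' near 0.
#'
#' @param e an [ellipse()].
#' @param contour two-column matrix of contour pixels (columns `x`, `y`).
#' @param d inlier distance threshold, px.
#' @return non-negative scalar fitness; 0 for an empty contour.
#' @export
ellipse_fitness <- function(e, contour, d) {
  stopifnot(is_ellipse(e), d > 0)
  if (is.null(contour) || nrow(contour) == 0) return(0)
  count_inliers(e, contour, d) / ellipse_perimeter(e)
}

# number of contour pixels within orthogonal distance d of the ellipse.
# A conservative algebraic prefilter discards pixels that provably lie
# farther than d (true distance >= 0.5 * b * |q - 1| for a pixel at
# normalized elliptical radius q), so the exact foot-point solve only
# runs on a thin band around the candidate model.
count_inliers <- function(e, contour, d) {
  ct <- cos(e$theta); st <- sin(e$theta)
  dx <- contour[, 1] - e$cx; dy <- contour[, 2] - e$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  q <- sqrt((u / e$a)^2 + (v / e$b)^2)
  near <- abs(q - 1) <= 2 * d / e$b
  if (!any(near)) return(0L)
  sum(point_ellipse_distance(contour[near, , drop = FALSE], e) <= d)
}

#' Iterative least-squares ellipse fitting (RANSAC)
#'
#' Runs exactly K random draws (K from [compute_iteration_count()], capped
#' at `cfg$max_iterations`). Each draw samples `s` distinct contour pixels
#' without replacement, fits a direct least-squares ellipse, and scores it
#' with [ellipse_fitness()]; the model with the highest fitness is kept
#' (ties keep the earlier draw). Draws whose five points admit no ellipse
#' count as consumed iterations with fitness 0. The returned inliers are
#' the contour pixels within `d` of the best model.
#'
#' The procedure is deterministic given `cfg$seed`; it uses a private RNG
#' stream and does not disturb the caller's random state.
#'
#' @param contour two-column matrix of contour pixels (columns `x`, `y`);
#'   at least `cfg$s` pixels.
#' @param cfg a [ransac_config()].
#' @return a list of class `"fit_result"` with fields `ellipse`, `fitness`
#'   (the maximal score), `inliers` (matrix of inner points), and
#'   `iterations` (K actually run). Throws `"vitifit_fit_error"` when no
#'   draw produced a valid ellipse.
#' @examples
#' e <- ellipse(100, 100, 60, 40, 0.3)
#' px <- rasterize_ellipse_arc(e, 0, 2 * pi, c(200, 200))
#' fit <- ransac_fit_ellipse(px, ransac_config(seed = 7))
#' fit$ellipse
#' @export
ransac_fit_ellipse <- function(contour, cfg = ransac_config()) {
  stopifnot(inherits(cfg, "ransac_config"))
  contour <- as_point_matrix(contour)
  n <- nrow(contour)
  if (n < cfg$s)
    stop(sprintf("contour has %d pixels but the sample size is %d", n, cfg$s))
  K <- min(compute_iteration_count(cfg$p, cfg$err, cfg$s),
           cfg$max_iterations)
  best <- NULL
  best_f <- -Inf
  with_private_rng(cfg$seed, {
    for (k in seq_len(K)) {
      idx <- sample.int(n, cfg$s)
      e <- tryCatch(fit_ellipse_lsq(contour[idx, , drop = FALSE]),
                    vitifit_fit_error = function(err) NULL)
      if (is.null(e)) next
      if (is.null(best)) {
        best <- e  # any valid ellipse beats "no model"
        best_f <- ellipse_fitness(e, contour, cfg$d)
        next
      }
      # exact pruning: fitness can never exceed n / perimeter
      if (n / ellipse_perimeter(e) <= best_f) next
      f <- ellipse_fitness(e, contour, cfg$d)
      if (f > best_f) {
        best <- e
        best_f <- f
      }
    }
  })
  if (is.null(best)) fit_error("no RANSAC draw produced a valid ellipse")
  # consensus refinement: re-estimate by least squares over the inlier
  # set (the raw fitness criterion slightly favors shrunken models --
  # a smaller perimeter with the same inlier band -- so the refit is the
  # unbiased final estimate and is accepted unconditionally). The band
  # anneals from d to d/2 so stray noise pixels inside the scoring band
  # do not bias the last fits.
  if (cfg$refine > 0) {
    bands <- c(rep(cfg$d, ceiling(cfg$refine / 2)),
               rep(cfg$d / 2, cfg$refine - ceiling(cfg$refine / 2)))
    for (bd in bands) {
      inl <- contour[point_ellipse_distance(contour, best) <= bd, ,
                     drop = FALSE]
      if (nrow(inl) < cfg$s) break
      cand <- tryCatch(fit_ellipse_lsq(inl),
                       vitifit_fit_error = function(err) NULL)
      if (is.null(cand)) break
      best <- cand
    }
  }
  best_f <- ellipse_fitness(best, contour, cfg$d)
  inl <- contour[point_ellipse_distance(contour, best) <= cfg$d, ,
                 drop = FALSE]
  structure(list(ellipse = best, fitness = best_f, inliers = inl,
                 iterations = K),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: fitness %.3f, %d inliers, %d iterations\n",
              x$fitness, nrow(x$inliers), x$iterations))
  print(x$ellipse)
  invisible(x)
}

# evaluate `expr` under a seeded private RNG stream, restoring the
# caller's .Random.seed afterwards
with_private_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
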