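#' Specification of a synthetic grape-cluster scene
#'
#' The generator emulates the contour-detection regime of a monitored
#' grape cluster: a handful of berry-sized ellipses that mutually overlap,
#' rendered as 1-px contours in which the arcs hidden by nearer berries
#' are missing, part of the visible contour has dropped out, and spurious
#' edge pixels contaminate the map.
#'
#' @param n_grapes number of berries (>= 1). Default 5.
#' @param axis_range `c(min, max)` for the semi-axes, px. Default
#'   `c(25, 60)` (berry-scale at 384 x 544 monitoring resolution).
#' @param aspect_max maximum axis ratio `a / b`. Default 1.5 (grape
#'   berries are mildly elongated).
#' @param image_size `c(H, W)` pixels. Default `c(384, 544)`.
#' @param overlap_factor target center spacing between neighboring berries
#'   as a fraction of their combined mean radius; values below 2 produce
#'   overlap. Default 1.5.
#' @param dropout_rate fraction of visible contour pixels deleted
#'   i.i.d. Default 0.1.
#' @param spurious_rate spurious edge pixels added, as a fraction of the
#'   surviving contour pixel count. Default 0.1.
#' @param max_occlusion maximum tolerated hidden fraction of any berry's
#'   contour; placements exceeding it are re-drawn. Default 0.4.
#' @param seed RNG seed; scenes are bit-reproducible per seed.
#' @return a list of class `"scene_spec"`.
#' @export
scene_spec <- function(n_grapes = 5L, axis_range = c(25, 60),
                       aspect_max = 1.5, image_size = c(384L, 544L),
                       overlap_factor = 1.5, dropout_rate = 0.1,
                       spurious_rate = 0.1, max_occlusion = 0.4,
                       seed = 1L) {
  stopifnot(n_grapes >= 1, length(axis_range) == 2,
            axis_range[1] > 0, axis_range[2] >= axis_range[1],
            aspect_max >= 1, length(image_size) == 2,
            dropout_rate >= 0, dropout_rate < 1, spurious_rate >= 0,
            max_occlusion >= 0, max_occlusion <= 1)
  structure(list(n_grapes = as.integer(n_grapes), axis_range = axis_range,
                 aspect_max = aspect_max,
                 image_size = as.integer(image_size),
                 overlap_factor = overlap_factor,
                 dropout_rate = dropout_rate,
                 spurious_rate = spurious_rate,
                 max_occlusion = max_occlusion, seed = as.integer(seed)),
            class = "scene_spec")
}

# is each point strictly inside ellipse e?
inside_ellipse <- function(pts, e, shrink = 1e-9) {
  ct <- cos(e$theta); st <- sin(e$theta)
  dx <- pts[, 1] - e$cx; dy <- pts[, 2] - e$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  (u / e$a)^2 + (v / e$b)^2 < 1 - shrink
}

#' Visible contour arcs under mutual occlusion
#'
#' A contour point of berry `g` is hidden iff it lies strictly inside a
#' berry with a higher z-index (nearer to the camera). The contour of each
#' ellipse is sampled densely in eccentric angle; runs of visible samples
#' become angular intervals, and the visible fraction is the arc-length
#' (not angle) fraction of the contour that remains visible.
#'
#' @param ellipses list of [ellipse()] objects, ordered by increasing
#'   z-index (the last element is nearest and occludes all others).
#' @param n_samples angular samples per contour. Default 1440.
#' @return list with one entry per ellipse: `intervals` (matrix with
#'   columns `t0`, `t1`, eccentric angles of visible arcs) and
#'   `visible_fraction` in `[0, 1]`.
#' @export
occlude_contours <- function(ellipses, n_samples = 1440L) {
  stopifnot(length(ellipses) >= 1, all(vapply(ellipses, is_ellipse, TRUE)))
  nE <- length(ellipses)
  tt <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  lapply(seq_len(nE), function(g) {
    e <- ellipses[[g]]
    pts <- ellipse_param_point(e, tt)
    hidden <- rep(FALSE, n_samples)
    if (g < nE) {
      for (h in seq(g + 1L, nE)) {
        hidden <- hidden | inside_ellipse(pts, ellipses[[h]])
      }
    }
    visible <- !hidden
    # arc-length weight of each sample
    ds <- sqrt(e$a^2 * sin(tt)^2 + e$b^2 * cos(tt)^2)
    vf <- if (any(visible)) sum(ds[visible]) / sum(ds) else 0
    intervals <- visible_runs_to_intervals(visible, tt)
    list(intervals = intervals, visible_fraction = vf)
  })
}

# convert a cyclic logical mask over angles to [t0, t1] intervals
visible_runs_to_intervals <- function(visible, tt) {
  n <- length(visible)
  if (!any(visible))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("t0", "t1"))))
  step <- tt[2] - tt[1]
  if (all(visible))
    return(matrix(c(0, 2 * pi), 1, 2, dimnames = list(NULL, c("t0", "t1"))))
  # rotate so the mask starts on a hidden sample, then take runs
  first_hidden <- which(!visible)[1]
  idx <- c(first_hidden:n, seq_len(first_hidden - 1L))
  vis <- visible[idx]
  r <- rle(vis)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- NULL
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    t0 <- tt[idx[starts[k]]]
    t1 <- tt[idx[ends[k]]] + step
    if (t1 <= t0) t1 <- t1 + 2 * pi  # interval wraps past 2*pi
    out <- rbind(out, c(t0, t1))
  }
  colnames(out) <- c("t0", "t1")
  out
}

#' Delete and add edge pixels (contour dropout and spurious noise)
#'
#' Each contour pixel is deleted independently with probability
#' `dropout_rate`; then `round(spurious_rate * n_surviving)` spurious
#' pixels are added at uniformly random positions. Deterministic given
#' `seed`; rates of 0 return the input unchanged.
#'
#' @param edge_map binary edge matrix.
#' @param dropout_rate deletion probability in `[0, 1]`.
#' @param spurious_rate spurious pixels as a fraction of the surviving
#'   contour pixels (>= 0).
#' @param seed RNG seed.
#' @return binary matrix of the same shape.
#' @export
add_noise <- function(edge_map, dropout_rate = 0, spurious_rate = 0,
                      seed = 1L) {
  stopifnot(is.matrix(edge_map), dropout_rate >= 0, dropout_rate <= 1,
            spurious_rate >= 0)
  if (dropout_rate == 0 && spurious_rate == 0) return(edge_map)
  out <- edge_map
  with_private_rng(seed, {
    on <- which(out != 0)
    if (dropout_rate > 0 && length(on) > 0) {
      drop <- on[stats::runif(length(on)) < dropout_rate]
      out[drop] <- 0L
    }
    n_spur <- round(spurious_rate * sum(out != 0))
    if (n_spur > 0) {
      pos <- sample.int(length(out), n_spur)
      out[pos] <- 1L
    }
  })
  out
}

#' Generate a synthetic grape-cluster scene
#'
#' Draws `n_grapes` random ellipses (semi-axes and aspect from the spec
#' ranges, orientation uniform), places them with the target overlap
#' spacing while keeping every berry fully inside the image and every
#' contour at most `max_occlusion` hidden, computes the occlusion-aware
#' visible arcs, rasterizes them at 1 px, and applies contour dropout and
#' spurious noise. The returned ground truth carries the exact ellipses,
#' visible arcs and fractions, per-berry bounding boxes, and exact areas
#' `pi * a * b`.
#'
#' @param spec a [scene_spec()].
#' @return list with `edge_map` (binary H x W matrix) and `truth`, a list
#'   with `ellipses` (z-ordered, last = nearest), `visible_arcs`,
#'   `visible_fraction`, `boxes` (data.frame, 0-based half-open),
#'   `areas`, and `clean_edge_map` (pre-noise contours).
#' @export
generate_cluster_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (2 * spec$axis_range[2] >= min(H, W))
    stop("infeasible spec: axes larger than the image")
  ellipses <- NULL
  arcs <- NULL
  with_private_rng(spec$seed, {
    for (attempt in 1:120) {
      # ease the target spacing when tight placements keep busting the
      # occlusion budget, so generation terminates for any feasible spec
      relax <- 1 + 0.015 * (attempt - 1)
      es <- place_cluster(spec, H, W, relax)
      if (is.null(es)) next
      oc <- occlude_contours(es)
      vf <- vapply(oc, function(o) o$visible_fraction, 0)
      if (all(1 - vf <= spec$max_occlusion)) {
        ellipses <- es
        arcs <- oc
        break
      }
    }
  })
  if (is.null(ellipses))
    stop("could not place the cluster within the occlusion budget; ",
         "relax overlap_factor or max_occlusion")
  clean <- matrix(0L, H, W)
  for (g in seq_along(ellipses)) {
    iv <- arcs[[g]]$intervals
    for (k in seq_len(nrow(iv))) {
      px <- rasterize_ellipse_arc(ellipses[[g]], iv[k, 1], iv[k, 2],
                                  c(H, W))
      if (nrow(px) > 0) clean[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- 1L
    }
  }
  noisy <- add_noise(clean, spec$dropout_rate, spec$spurious_rate,
                     seed = spec$seed + 104729L)
  boxes <- do.call(rbind, lapply(ellipses, ellipse_box, H = H, W = W))
  truth <- list(
    ellipses = ellipses,
    visible_arcs = lapply(arcs, function(o) o$intervals),
    visible_fraction = vapply(arcs, function(o) o$visible_fraction, 0),
    boxes = boxes,
    areas = vapply(ellipses, ellipse_area, 0),
    clean_edge_map = clean)
  list(edge_map = noisy, truth = truth)
}

# axis-aligned bounding box of an ellipse, 2 px margin, half-open, clipped
ellipse_box <- function(e, H, W) {
  hw <- sqrt((e$a * cos(e$theta))^2 + (e$b * sin(e$theta))^2)
  hh <- sqrt((e$a * sin(e$theta))^2 + (e$b * cos(e$theta))^2)
  candidate_box(max(0, floor(e$cx - hw) - 2),
                max(0, floor(e$cy - hh) - 2),
                min(W, ceiling(e$cx + hw) + 3),
                min(H, ceiling(e$cy + hh) + 3))
}

# draw one cluster placement; NULL when a berry cannot be placed
place_cluster <- function(spec, H, W, relax = 1) {
  es <- list()
  for (g in seq_len(spec$n_grapes)) {
    a <- stats::runif(1, spec$axis_range[1], spec$axis_range[2])
    b <- stats::runif(1, max(spec$axis_range[1], a / spec$aspect_max), a)
    th <- stats::runif(1, 0, pi)
    m <- a + 3  # keep the whole berry inside the image
    placed <- FALSE
    for (try in 1:40) {
      if (g == 1) {
        cx <- stats::runif(1, W / 2 - W / 8, W / 2 + W / 8)
        cy <- stats::runif(1, H / 2 - H / 8, H / 2 + H / 8)
      } else {
        anchor <- es[[sample.int(length(es), 1)]]
        r_new <- (a + b) / 2
        r_anc <- (anchor$a + anchor$b) / 2
        dist <- relax * spec$overlap_factor * (r_new + r_anc) / 2
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- anchor$cx + dist * cos(ang)
        cy <- anchor$cy + dist * sin(ang)
      }
      if (cx - m >= 0 && cx + m < W && cy - m >= 0 && cy + m < H) {
        es[[g]] <- ellipse(cx, cy, a, b, th)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  es
}

#' Geometric augmentation of an image set
#'
#' Expands each image by sequentially applying horizontal flip (2
#' variants), rotation in `rotation_step_deg` increments covering 360
#' degrees (16 variants at the default 22.5), and rescaling by each factor
#' in `scales` (3 variants by default: reduced to 0.5x, original, and
#' expanded to 1.5x) -- 96 outputs per input, so 200 inputs yield 19,200
#' augmented images.
#'
#' @param images list of grayscale matrices in `[0, 1]`.
#' @param include_flip include the horizontally flipped variants.
#'   Default TRUE.
#' @param rotation_step_deg rotation increment, degrees; must divide 360.
#'   Default 22.5.
#' @param scales rescale factors. Default `c(0.5, 1, 1.5)`.
#' @return list of entries `list(image, flip, rotation_deg, scale)`,
#'   ordered input-major then flip, rotation, scale; `list()` for empty
#'   input.
#' @export
augment_images <- function(images, include_flip = TRUE,
                           rotation_step_deg = 22.5,
                           scales = c(0.5, 1, 1.5)) {
  stopifnot(is.list(images), rotation_step_deg > 0,
            length(scales) >= 1, all(scales > 0))
  n_rot <- 360 / rotation_step_deg
  if (abs(n_rot - round(n_rot)) > 1e-9)
    stop("rotation_step_deg must divide 360")
  n_rot <- as.integer(round(n_rot))
  angles <- (seq_len(n_rot) - 1L) * rotation_step_deg
  flips <- if (include_flip) c(FALSE, TRUE) else FALSE
  rot_cache <- new.env(parent = emptyenv())
  out <- vector("list", length(images) * length(flips) * n_rot *
                  length(scales))
  k <- 0L
  for (img in images) {
    stopifnot(is.matrix(img))
    for (fl in flips) {
      base <- if (fl) img[, rev(seq_len(ncol(img))), drop = FALSE] else img
      for (ang in angles) {
        rot <- rotate_image(base, ang, rot_cache)
        for (sc in scales) {
          scaled <- if (sc == 1) rot else
            bilinear_resize(rot, max(1L, round(nrow(rot) * sc)),
                            max(1L, round(ncol(rot) * sc)))
          k <- k + 1L
          out[[k]] <- list(image = scaled, flip = fl, rotation_deg = ang,
                           scale = sc)
        }
      }
    }
  }
  out
}

# rotate a matrix about its center by `deg` counter-clockwise, bilinear,
# zero fill; sampling maps are cached per (angle, shape)
rotate_image <- function(img, deg, cache = NULL) {
  if (deg %% 360 == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  key <- sprintf("%g_%d_%d", deg, H, W)
  map <- if (!is.null(cache) && !is.null(cache[[key]])) cache[[key]] else {
    th <- deg * pi / 180
    ct <- cos(th); st <- sin(th)
    cy <- (H - 1) / 2; cx <- (W - 1) / 2
    gx <- matrix(seq_len(W) - 1 - cx, H, W, byrow = TRUE)
    gy <- matrix(seq_len(H) - 1 - cy, H, W)
    # inverse rotation: source position of each output pixel
    sx <- ct * gx + st * gy + cx
    sy <- -st * gx + ct * gy + cy
    x0 <- floor(sx); y0 <- floor(sy)
    valid <- sx >= 0 & sx <= W - 1 & sy >= 0 & sy <= H - 1
    x0 <- pmin(pmax(x0, 0), W - 2); y0 <- pmin(pmax(y0, 0), H - 2)
    m <- list(wx = sx - x0, wy = sy - y0, valid = valid,
              i00 = (y0 + 1) + x0 * H)
    if (!is.null(cache)) cache[[key]] <- m
    m
  }
  v <- img
  dim(v) <- NULL
  i00 <- map$i00
  out <- (1 - map$wy) * (1 - map$wx) * v[i00] +
         (1 - map$wy) * map$wx * v[i00 + H] +
         map$wy * (1 - map$wx) * v[i00 + 1] +
         map$wy * map$wx * v[i00 + 1 + H]
  out[!map$valid] <- 0
  matrix(out, H, W)
}

#' Render a cluster as a grayscale photograph surrogate
#'
#' Fills the berries with distinct gray levels over a darker background in
#' z-order (nearer berries paint over farther ones) and applies a Gaussian
#' blur, producing the kind of smooth-shaded image the classical fallback
#' edge detector is meant to handle. Visible berry boundaries coincide
#' with the scene's clean contour map.
#'
#' @param ellipses list of [ellipse()] objects, z-ordered (last nearest).
#' @param image_size `c(H, W)`.
#' @param background background gray level. Default 0.1.
#' @param gray_levels per-berry gray levels; defaults to evenly spaced
#'   values in `[0.4, 0.95]`.
#' @param blur_sigma Gaussian blur sd, px. Default 1.
#' @return H x W matrix in `[0, 1]`.
#' @export
render_scene_image <- function(ellipses, image_size, background = 0.1,
                               gray_levels = NULL, blur_sigma = 1) {
  H <- image_size[1]; W <- image_size[2]
  n <- length(ellipses)
  if (is.null(gray_levels))
    gray_levels <- if (n == 1) 0.8 else seq(0.4, 0.95, length.out = n)
  stopifnot(length(gray_levels) == n)
  img <- matrix(background, H, W)
  xs <- matrix(0:(W - 1), H, W, byrow = TRUE)
  ys <- matrix(0:(H - 1), H, W)
  for (g in seq_len(n)) {
    e <- ellipses[[g]]
    mask <- inside_ellipse(cbind(as.vector(xs), as.vector(ys)), e,
                           shrink = 0)
    img[matrix(mask, H, W)] <- gray_levels[g]
  }
  gaussian_blur(img, blur_sigma)
}

#' Synthetic projected-area monitoring series
#'
#' Emulates the diurnal dynamics of berry projected area: a sinusoid with
#' a 1-day period (shrinking by day, expanding by night) superimposed on a
#' linear growth trend, plus Gaussian measurement noise.
#' `area(t) = base * (1 + trend * t) + amplitude * sin(2 * pi * t) +
#' noise`, with `t` in days.
#'
#' @param base_area baseline projected area, px^2.
#' @param daily_amplitude sinusoid amplitude, px^2.
#' @param trend_per_day relative growth per day (e.g. 0.02 for +2%/day).
#' @param days number of days covered.
#' @param samples_per_day measurements per day.
#' @param noise_sd measurement noise standard deviation as a fraction of
#'   `base_area`.
#' @param seed RNG seed.
#' @return data.frame with `t_days` and `area`.
#' @export
generate_area_series <- function(base_area, daily_amplitude = 0,
                                 trend_per_day = 0, days = 6,
                                 samples_per_day = 24, noise_sd = 0,
                                 seed = 1L) {
  stopifnot(base_area > 0, days > 0, samples_per_day >= 1, noise_sd >= 0)
  t <- seq(0, days, by = 1 / samples_per_day)
  t <- t[t < days]
  area <- base_area * (1 + trend_per_day * t) +
    daily_amplitude * sin(2 * pi * t)
  if (noise_sd > 0) {
    with_private_rng(seed, {
      area <- area + stats::rnorm(length(t), 0, noise_sd * base_area)
    })
  }
  data.frame(t_days = t, area = area)
}
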