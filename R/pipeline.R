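#' Binarize an edge-probability map
#'
#' @param P numeric probability matrix in `[0, 1]`.
#' @param threshold scalar in `[0, 1]`; a pixel becomes 1 iff
#'   `p >= threshold`.
#' @return integer 0/1 matrix of the same shape.
#' @export
binarize_edge_map <- function(P, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  stopifnot(is.matrix(P))
  out <- matrix(0L, nrow(P), ncol(P))
  out[P >= threshold] <- 1L
  out
}

#' Candidate box constructor / validator
#'
#' Boxes are 0-based, half-open rectangles `[x_min, x_max) x [y_min,
#' y_max)` as produced by object detectors.
#'
#' @param x_min,y_min,x_max,y_max pixel bounds; `x_min < x_max`,
#'   `y_min < y_max`.
#' @param score optional detector confidence in `[0, 1]`.
#' @return one-row data.frame with the box columns.
#' @export
candidate_box <- function(x_min, y_min, x_max, y_max, score = NA_real_) {
  stopifnot(x_min < x_max, y_min < y_max)
  data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             score = score)
}

# clip a boxes data.frame to image bounds H x W (half-open)
clip_boxes <- function(boxes, H, W) {
  boxes$x_min <- pmax(boxes$x_min, 0)
  boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, W)
  boxes$y_max <- pmin(boxes$y_max, H)
  boxes[boxes$x_min < boxes$x_max & boxes$y_min < boxes$y_max, ,
        drop = FALSE]
}

#' Extract contour segments inside a candidate box by region growing
#'
#' Grows maximal 8-connected components over the binary edge pixels that
#' fall inside the box; every edge pixel in the box belongs to exactly one
#' segment. Segments shorter than `min_segment_len` pixels are discarded
#' as noise.
#'
#' @param bin binary edge matrix (0/1).
#' @param box one-row data.frame with `x_min`, `y_min`, `x_max`, `y_max`
#'   (0-based half-open; clipped to the image).
#' @param min_segment_len minimum component size kept. Default 10.
#' @return list of segments, each an integer matrix with columns `x`, `y`
#'   (global image coordinates) in growth order; empty list when the box
#'   contains no edge pixels.
#' @export
region_grow_contours <- function(bin, box, min_segment_len = 10) {
  stopifnot(is.matrix(bin))
  H <- nrow(bin); W <- ncol(bin)
  box <- clip_boxes(as.data.frame(box), H, W)
  if (nrow(box) == 0) return(list())
  # 1-based row/col window of the box
  r0 <- box$y_min + 1L; r1 <- box$y_max
  c0 <- box$x_min + 1L; c1 <- box$x_max
  sub <- bin[r0:r1, c0:c1, drop = FALSE] != 0
  if (!any(sub)) return(list())
  h <- nrow(sub); w <- ncol(sub)
  lab <- matrix(0L, h, w)
  nbr_di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nbr_dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  segs <- list()
  on <- which(sub)
  for (start in on) {
    if (lab[start] != 0L) next
    # BFS flood fill of one 8-connected component
    queue <- integer(length(on)); queue[1] <- start
    head <- 1L; tail <- 1L
    lab[start] <- 1L
    comp <- integer(0)
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      comp <- c(comp, cur)
      ci <- (cur - 1L) %% h + 1L
      cj <- (cur - 1L) %/% h + 1L
      for (k in 1:8) {
        ni <- ci + nbr_di[k]; nj <- cj + nbr_dj[k]
        if (ni >= 1L && ni <= h && nj >= 1L && nj <= w &&
            sub[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- 1L
          tail <- tail + 1L
          queue[tail] <- ni + (nj - 1L) * h
        }
      }
    }
    if (length(comp) >= min_segment_len) {
      ci <- (comp - 1L) %% h + 1L
      cj <- (comp - 1L) %/% h + 1L
      segs[[length(segs) + 1L]] <-
        cbind(x = cj - 1L + box$x_min, y = ci - 1L + box$y_min)
    }
  }
  segs
}

#' Fit one grape per candidate box and emit phenotype records
#'
#' The step-two orchestration: binarize the edge map (if it is not binary
#' already), extract each box's contour pixels by region growing, pool the
#' segments (or keep only the longest), run the iterative least-squares
#' (RANSAC) ellipse fit, and keep the fit iff its fitness reaches
#' `cfg$min_fitness` and the fitted center lies inside the box expanded by
#' `expand` on each side. At most one record is produced per box; boxes
#' with fewer than `cfg$s` contour pixels are skipped with a warning.
#' Heavily occluded berries therefore simply yield no record.
#'
#' Each box uses the deterministic seed `cfg$seed + box index`, so the
#' whole pipeline is reproducible.
#'
#' @param edge_map probability or binary edge matrix.
#' @param boxes data.frame of candidate boxes (`x_min`, `y_min`, `x_max`,
#'   `y_max`, optional `score`), 0-based half-open.
#' @param cfg a [ransac_config()].
#' @param threshold binarization threshold for probability input.
#' @param min_segment_len see [region_grow_contours()].
#' @param segments `"pool"` (default: fit all segments of the box
#'   together) or `"longest"` (fit only the largest segment).
#' @param expand fractional box expansion used for the center-containment
#'   check. Default 0.05.
#' @return data.frame of phenotype records: `grape_id`, box bounds, `cx`,
#'   `cy`, `a`, `b`, `theta`, `long_axis_px`, `area_px2`, `fitness`.
#'   Zero rows when nothing is accepted.
#' @export
fit_grapes_in_boxes <- function(edge_map, boxes, cfg = ransac_config(),
                                threshold = 0.5, min_segment_len = 10,
                                segments = c("pool", "longest"),
                                expand = 0.05) {
  segments <- match.arg(segments)
  stopifnot(is.matrix(edge_map))
  H <- nrow(edge_map); W <- ncol(edge_map)
  bin <- if (all(edge_map %in% c(0, 1))) edge_map else
    binarize_edge_map(edge_map, threshold)
  boxes <- as.data.frame(boxes)
  if (is.null(boxes$score)) boxes$score <- NA_real_
  records <- empty_phenotypes()
  if (nrow(boxes) == 0) return(records)
  boxes <- clip_boxes(boxes, H, W)
  for (i in seq_len(nrow(boxes))) {
    bx <- boxes[i, , drop = FALSE]
    segs <- region_grow_contours(bin, bx, min_segment_len)
    if (length(segs) == 0) next
    px <- if (segments == "longest") {
      segs[[which.max(vapply(segs, nrow, 0L))]]
    } else {
      do.call(rbind, segs)
    }
    if (nrow(px) < cfg$s) {
      warning(sprintf("box %d: %d contour pixels < sample size %d; skipped",
                      i, nrow(px), cfg$s))
      next
    }
    box_cfg <- cfg
    box_cfg$seed <- cfg$seed + i
    fit <- tryCatch(ransac_fit_ellipse(px, box_cfg),
                    vitifit_fit_error = function(e) NULL)
    if (is.null(fit) || fit$fitness < cfg$min_fitness) next
    e <- fit$ellipse
    wx <- (bx$x_max - bx$x_min) * expand
    wy <- (bx$y_max - bx$y_min) * expand
    inside <- e$cx >= bx$x_min - wx && e$cx < bx$x_max + wx &&
              e$cy >= bx$y_min - wy && e$cy < bx$y_max + wy
    if (!inside) next
    records <- rbind(records, data.frame(
      grape_id = i,
      x_min = bx$x_min, y_min = bx$y_min,
      x_max = bx$x_max, y_max = bx$y_max,
      cx = e$cx, cy = e$cy, a = e$a, b = e$b, theta = e$theta,
      long_axis_px = long_axis(e), area_px2 = ellipse_area(e),
      fitness = fit$fitness))
  }
  rownames(records) <- NULL
  records
}

empty_phenotypes <- function() {
  data.frame(grape_id = integer(0), x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0), cx = numeric(0),
             cy = numeric(0), a = numeric(0), b = numeric(0),
             theta = numeric(0), long_axis_px = numeric(0),
             area_px2 = numeric(0), fitness = numeric(0))
}

#' Instance-wise aggregation of area measurements over time
#'
#' Averages the projected area over the grape instances measured at each
#' timestamp (the instance-wise average that smooths per-berry measurement
#' noise in monitoring series). Timestamps with no measurements are simply
#' absent from the output.
#'
#' @param records data.frame with columns `timestamp` and `area_px2`
#'   (one row per measured instance).
#' @return data.frame with `timestamp`, `mean_area`, `n_instances`,
#'   ordered by timestamp.
#' @export
aggregate_time_series <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("timestamp", "area_px2") %in% names(records)))
  if (nrow(records) == 0)
    return(data.frame(timestamp = numeric(0), mean_area = numeric(0),
                      n_instances = integer(0)))
  sp <- split(records$area_px2, records$timestamp)
  out <- data.frame(
    timestamp = as.numeric(names(sp)),
    mean_area = vapply(sp, mean, 0),
    n_instances = vapply(sp, length, 0L))
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
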