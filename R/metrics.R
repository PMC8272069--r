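#' Tolerance-based matching of predicted and ground-truth edge pixels
#'
#' Greedy nearest-neighbor one-to-one matching: all (predicted, truth)
#' pixel pairs within Euclidean distance `tol` are considered in order of
#' increasing distance and accepted when both pixels are still unmatched.
#' `tol = 0` degenerates to exact pixel overlap. The counts are the basis
#' of the Dice coefficient, recall, redundancy rate, and the F-measures
#' behind ODS/OIS.
#'
#' @param X binary matrix of predicted edge pixels.
#' @param Y binary matrix of ground-truth edge pixels, same shape.
#' @param tol matching tolerance in pixels (>= 0). Default 2.
#' @return list of class `"edge_match"` with `TP` (matched predicted
#'   pixels), `FN` (`count_Y - TP`), `count_X`, `count_Y`.
#' @export
match_edge_pixels <- function(X, Y, tol = 2) {
  if (!identical(dim(X), dim(Y))) stop("X and Y must have identical shape")
  stopifnot(tol >= 0)
  H <- nrow(X); W <- ncol(X)
  xi <- which(X != 0); yi <- which(Y != 0)
  count_X <- length(xi); count_Y <- length(yi)
  TP <- 0L
  if (count_X > 0 && count_Y > 0) {
    # lookup grid of ground-truth pixel ids
    gt_id <- integer(H * W)
    gt_id[yi] <- seq_along(yi)
    xr <- (xi - 1L) %% H; xc <- (xi - 1L) %/% H
    r <- ceiling(tol)
    offs <- expand.grid(di = -r:r, dj = -r:r)
    offs <- offs[offs$di^2 + offs$dj^2 <= tol^2, , drop = FALSE]
    px <- integer(0); py <- integer(0); pd <- numeric(0)
    for (k in seq_len(nrow(offs))) {
      rr <- xr + offs$di[k]; cc <- xc + offs$dj[k]
      ok <- rr >= 0 & rr < H & cc >= 0 & cc < W
      if (!any(ok)) next
      lin <- rr[ok] + cc[ok] * H + 1L
      hit <- gt_id[lin] > 0L
      if (!any(hit)) next
      px <- c(px, which(ok)[hit])
      py <- c(py, gt_id[lin[hit]])
      pd <- c(pd, rep(sqrt(offs$di[k]^2 + offs$dj[k]^2), sum(hit)))
    }
    if (length(px) > 0) {
      ord <- order(pd, px, py)
      xm <- logical(count_X); ym <- logical(count_Y)
      for (k in ord) {
        if (!xm[px[k]] && !ym[py[k]]) {
          xm[px[k]] <- TRUE; ym[py[k]] <- TRUE
          TP <- TP + 1L
        }
      }
    }
  }
  structure(list(TP = TP, FN = count_Y - TP,
                 count_X = count_X, count_Y = count_Y),
            class = "edge_match")
}

#' Dice coefficient of an edge match
#'
#' `D = 2 TP / (count_X + count_Y)`: the set-overlap similarity between
#' the predicted and ground-truth contour maps under tolerance matching.
#' Two empty maps are defined as identical (`D = 1`).
#'
#' @param match an [match_edge_pixels()] result.
#' @return D in `[0, 1]`.
#' @export
dice_coefficient <- function(match) {
  stopifnot(inherits(match, "edge_match"))
  denom <- match$count_X + match$count_Y
  if (denom == 0) return(1)
  2 * match$TP / denom
}

#' Pixel recall of an edge match
#'
#' `R = TP / (TP + FN)`: the fraction of ground-truth edge pixels that
#' were matched by a prediction. 0 when the ground truth is empty.
#'
#' @inheritParams dice_coefficient
#' @return R in `[0, 1]`.
#' @export
pixel_recall <- function(match) {
  stopifnot(inherits(match, "edge_match"))
  if (match$TP + match$FN == 0) return(0)
  match$TP / (match$TP + match$FN)
}

#' Contour redundancy rate
#'
#' `A = (1 - TP / Count(X)) * 100`: the percentage of predicted edge
#' pixels with no ground-truth correspondence (spurious contour mass);
#' lower is better. 0 when no pixels were predicted.
#'
#' @inheritParams dice_coefficient
#' @return A in `[0, 100]`, percent.
#' @export
redundancy_rate <- function(match) {
  stopifnot(inherits(match, "edge_match"))
  if (match$count_X == 0) return(0)
  (1 - match$TP / match$count_X) * 100
}

#' Fitting recall
#'
#' The percentage of grapes actually present whose contour was
#' successfully fitted: `R = N_D / N_A * 100`.
#'
#' @param n_fitted number of correctly fitted contours (`N_D`).
#' @param n_actual actual number of grape contours (`N_A`, > 0).
#' @return percentage.
#' @export
fitting_recall <- function(n_fitted, n_actual) {
  if (n_actual == 0) stop("actual contour count must be positive")
  n_fitted / n_actual * 100
}

#' Average absolute relative deviation (AARD)
#'
#' `mean(|measured - truth| / truth) * 100`, the percentage error measure
#' used for phenotype tables (long axis, projected area).
#'
#' @param measured numeric vector of measurements.
#' @param truth numeric vector of positive reference values, same length.
#' @return AARD in percent.
#' @examples
#' aard(c(90, 110), c(100, 100)) # 10
#' @export
aard <- function(measured, truth) {
  if (length(measured) == 0) stop("empty measurement list")
  stopifnot(length(measured) == length(truth), all(truth > 0))
  mean(abs(measured - truth) / truth) * 100
}

#' Non-maximum suppression thinning of an edge-probability map
#'
#' Suppresses pixels that are not local maxima across the edge: for each
#' non-zero pixel the local gradient direction (Sobel) is quantized to one
#' of four axes and the pixel is kept only if its value is >= both
#' neighbors along that axis. Pixels with no defined gradient are kept.
#' The pass is repeated until a fixed point, so the operation is
#' idempotent by construction; in practice one or two passes suffice and
#' ridges collapse to 1-px crests.
#'
#' @param P numeric edge-probability matrix in `[0, 1]`.
#' @param max_passes safety cap on the fixed-point iteration. Default 8.
#' @return thinned matrix, same shape.
#' @export
nms_thin <- function(P, max_passes = 8) {
  stopifnot(is.matrix(P))
  cur <- P
  for (pass in seq_len(max_passes)) {
    nxt <- nms_pass(cur)
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

nms_pass <- function(P) {
  H <- nrow(P); W <- ncol(P)
  gr <- sobel_gradients(P)
  ang <- atan2(gr$gy, gr$gx) %% pi
  # quantize direction to 0, 45, 90, 135 degrees
  bin <- (floor((ang + pi / 8) / (pi / 4)) %% 4) + 1
  Pp <- matrix(0, H + 2, W + 2)
  Pp[2:(H + 1), 2:(W + 1)] <- P
  nb <- function(di, dj) Pp[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
  # neighbor pairs along each quantized gradient direction
  n1 <- list(nb(0, 1), nb(1, 1), nb(1, 0), nb(1, -1))
  n2 <- list(nb(0, -1), nb(-1, -1), nb(-1, 0), nb(-1, 1))
  keep <- matrix(TRUE, H, W)
  flat <- gr$gx == 0 & gr$gy == 0
  for (b in 1:4) {
    sel <- bin == b & !flat
    keep[sel] <- P[sel] >= n1[[b]][sel] & P[sel] >= n2[[b]][sel]
  }
  out <- P
  out[!keep] <- 0
  out
}

#' ODS and OIS F-measures over an image set
#'
#' Sweeps a threshold grid over the probability maps; at each threshold
#' every image is binarized, matched against its ground truth with
#' [match_edge_pixels()], and scored with the F-measure
#' `F = 2PR / (P + R)` (precision `TP / count_X`, recall `TP / count_Y`).
#' ODS (optimal dataset scale) is the best mean-over-images F achieved by
#' a single common threshold; OIS (optimal image scale) is the mean of
#' each image's own best F. By construction `OIS >= ODS`.
#'
#' @param predictions list of probability matrices.
#' @param truths list of binary matrices, same lengths and shapes.
#' @param thresholds numeric vector in (0, 1); default 33 evenly spaced
#'   values.
#' @param tol matching tolerance, px. Default 2.
#' @return list with `ods`, `ois`, `ods_threshold`, and the
#'   `f_matrix` (images x thresholds) of per-image F-measures.
#' @export
ods_ois <- function(predictions, truths, thresholds = (1:33) / 34,
                    tol = 2) {
  stopifnot(is.list(predictions), is.list(truths))
  if (length(predictions) != length(truths))
    stop("prediction and truth counts differ")
  if (length(predictions) == 0) stop("empty image set")
  stopifnot(all(thresholds > 0 & thresholds < 1))
  nT <- length(thresholds)
  f_matrix <- matrix(0, length(predictions), nT)
  for (i in seq_along(predictions)) {
    P <- predictions[[i]]; G <- truths[[i]]
    for (j in seq_len(nT)) {
      m <- match_edge_pixels(binarize_edge_map(P, thresholds[j]), G, tol)
      prec <- if (m$count_X == 0) 0 else m$TP / m$count_X
      rec <- if (m$count_Y == 0) 0 else m$TP / m$count_Y
      f_matrix[i, j] <- if (prec + rec == 0) 0 else
        2 * prec * rec / (prec + rec)
    }
  }
  mean_f <- colMeans(f_matrix)
  list(ods = max(mean_f),
       ods_threshold = thresholds[which.max(mean_f)],
       ois = mean(apply(f_matrix, 1, max)),
       f_matrix = f_matrix)
}
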