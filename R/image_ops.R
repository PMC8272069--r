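# Low-level image operations on plain numeric matrices / arrays.
# Convention throughout the package: a grayscale image or probability map
# is an H x W matrix, row = y + 1, column = x + 1 (0-based pixel coords);
# an RGB image is an H x W x 3 array with values in [0, 1].

#' Bilinear image resize
#'
#' @param img H x W matrix or H x W x C array, numeric.
#' @param out_h,out_w output size in pixels (>= 1).
#' @return resized matrix/array of the same kind.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  if (length(dim(img)) == 3) {
    out <- array(0, c(out_h, out_w, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- bilinear_resize(img[, , c], out_h, out_w)
    return(out)
  }
  H <- nrow(img); W <- ncol(img)
  if (H == out_h && W == out_w) return(img)
  # half-pixel-center mapping (matches standard image resamplers)
  sy <- (seq_len(out_h) - 0.5) * H / out_h - 0.5
  sx <- (seq_len(out_w) - 0.5) * W / out_w - 0.5
  sy <- pmin(pmax(sy, 0), H - 1)
  sx <- pmin(pmax(sx, 0), W - 1)
  y0 <- pmin(floor(sy), H - 1); y1 <- pmin(y0 + 1, H - 1)
  x0 <- pmin(floor(sx), W - 1); x1 <- pmin(x0 + 1, W - 1)
  wy <- sy - y0; wx <- sx - x0
  i00 <- img[y0 + 1, x0 + 1, drop = FALSE]
  i01 <- img[y0 + 1, x1 + 1, drop = FALSE]
  i10 <- img[y1 + 1, x0 + 1, drop = FALSE]
  i11 <- img[y1 + 1, x1 + 1, drop = FALSE]
  wyM <- matrix(wy, out_h, out_w)
  wxM <- matrix(wx, out_h, out_w, byrow = TRUE)
  i00 * (1 - wyM) * (1 - wxM) + i01 * (1 - wyM) * wxM +
    i10 * wyM * (1 - wxM) + i11 * wyM * wxM
}

# replicate-pad a matrix by (top, bottom, left, right)
pad_replicate <- function(m, tb, lr) {
  ri <- c(rep(1L, tb[1]), seq_len(nrow(m)), rep(nrow(m), tb[2]))
  ci <- c(rep(1L, lr[1]), seq_len(ncol(m)), rep(ncol(m), lr[2]))
  m[ri, ci, drop = FALSE]
}

# 2-D convolution of an H x W x Cin array with a kh x kw x Cin x Cout
# kernel, stride 1, replicate ("same") padding. Implemented as one matrix
# product per kernel tap.
conv2d <- function(x, w, bias = NULL) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  kh <- dim(w)[1]; kw <- dim(w)[2]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(dim(x)[3] == cin)
  H <- dim(x)[1]; W <- dim(x)[2]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + kh - 1L, W + kw - 1L, cin))
  for (c in seq_len(cin))
    xp[, , c] <- pad_replicate(x[, , c], c(ph, kh - 1L - ph),
                               c(pw, kw - 1L - pw))
  out <- matrix(0, H * W, cout)
  for (di in seq_len(kh)) {
    for (dj in seq_len(kw)) {
      patch <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , drop = FALSE]
      dim(patch) <- c(H * W, cin)
      wk <- matrix(w[di, dj, , ], cin, cout)
      out <- out + patch %*% wk
    }
  }
  if (!is.null(bias)) out <- sweep(out, 2, bias, "+")
  array(out, c(H, W, cout))
}

# 2x2 max pooling, stride 2 (H, W assumed even)
maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  oi <- seq(1L, H, by = 2L); oj <- seq(1L, W, by = 2L)
  pmax(x[oi, oj, , drop = FALSE], x[oi + 1L, oj, , drop = FALSE],
       x[oi, oj + 1L, , drop = FALSE], x[oi + 1L, oj + 1L, , drop = FALSE])
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# separable Gaussian blur, replicate borders
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  mp <- pad_replicate(m, c(r, r), c(r, r))
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W + 2 * r)
  for (i in seq_along(k))
    tmp <- tmp + k[i] * mp[i:(i + H - 1L), , drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(k))
    out <- out + k[j] * tmp[, j:(j + W - 1L), drop = FALSE]
  out
}

# Sobel gradients; returns list(gx, gy) with image-coordinate axes
# (gx: d/dcol, gy: d/drow)
sobel_gradients <- function(m) {
  mp <- pad_replicate(m, c(1, 1), c(1, 1))
  H <- nrow(m); W <- ncol(m)
  sh <- function(di, dj) mp[(1 + di):(H + di), (1 + dj):(W + dj), drop = FALSE]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  list(gx = gx / 8, gy = gy / 8)
}

# coerce RGB / grayscale input to an H x W grayscale matrix in [0, 1]
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc >= 3)
      return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    return(img[, , 1])
  }
  stop("expected an H x W matrix or H x W x C array")
}
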