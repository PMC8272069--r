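#' Network layout for the improved HED edge detector
#'
#' Describes a holistically-nested edge detection backbone: 13
#' convolutional layers in five stages (2, 2, 3, 3, 3 layers), each stage
#' followed by 2x2 max pooling, in the VGG16 layout. Stages listed in
#' `dense_side_stages` route *every* conv layer of the stage through a
#' 1x1 side convolution of depth `side_channels` (default 25); the
#' resulting per-layer side maps are superimposed and reduced by a 1x1->1
#' convolution to give the stage's edge-prediction map. The remaining
#' stages keep the classic single side output from their last conv layer.
#' All stage maps are restored to input resolution by bilinear upsampling
#' and merged into the final edge map.
#'
#' `base_channels` scales the backbone width; the canonical VGG16 width is
#' 64, but the default is 8 so that untrained CPU-only forward passes stay
#' cheap (the layout is unchanged).
#'
#' @param base_channels width of stage 1; stages use
#'   `base_channels * c(1, 2, 4, 8, 8)` channels.
#' @param dense_side_stages integer subset of 1:5 receiving dense
#'   (per-layer) side outputs. Default `c(3, 4, 5)`; `integer(0)` recovers
#'   the classic single-side-output HED layout.
#' @param side_channels depth of the dense 1x1 side convolutions.
#'   Default 25.
#' @param side_combine how per-layer side maps of a dense stage are
#'   superimposed before the 1x1->1 reduction: `"concat"` (channel
#'   concatenation, default) or `"sum"` (elementwise accumulation as in
#'   RCF).
#' @param pyramid_scales default scales for [pyramid_predict()].
#' @param seed seed for the deterministic random weight initialization.
#' @return a list of class `"network_spec"`.
#' @export
network_spec <- function(base_channels = 8L,
                         dense_side_stages = c(3L, 4L, 5L),
                         side_channels = 25L,
                         side_combine = c("concat", "sum"),
                         pyramid_scales = c(0.5, 1, 1.5),
                         seed = 42L) {
  side_combine <- match.arg(side_combine)
  stopifnot(base_channels >= 1, side_channels >= 1,
            all(dense_side_stages %in% 1:5))
  structure(list(base_channels = as.integer(base_channels),
                 dense_side_stages = as.integer(dense_side_stages),
                 side_channels = as.integer(side_channels),
                 side_combine = side_combine,
                 pyramid_scales = pyramid_scales,
                 seed = as.integer(seed)),
            class = "network_spec")
}

# per-stage conv layer counts and channel widths
hed_layout <- function(spec) {
  list(convs = c(2L, 2L, 3L, 3L, 3L),
       channels = spec$base_channels * c(1L, 2L, 4L, 8L, 8L))
}

#' Build an improved-HED edge predictor
#'
#' Instantiates the network described by a [network_spec()] with
#' deterministic He-normal random weights (no pretrained backbone is
#' shipped; training beyond the fusion layer is out of scope). The
#' returned predictor is a plain-R forward pass: convolution, ReLU, max
#' pooling, 1x1 side heads, bilinear upsampling, sigmoid, and a convex
#' fusion of the five stage maps (arithmetic mean by default; the fusion
#' weights are the only parameters [train_fusion_weights()] updates).
#'
#' @param spec a [network_spec()].
#' @return object of class `"hed_predictor"`; call [predict.hed_predictor()]
#'   on an image to obtain the five stage maps and the fused map.
#' @export
build_improved_hed <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  lay <- hed_layout(spec)
  he <- function(kh, kw, cin, cout)
    array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  weights <- NULL
  with_private_rng(spec$seed, {
    w <- list()
    cin <- 3L
    for (s in 1:5) {
      stage <- list(convs = list(), side = list())
      for (l in seq_len(lay$convs[s])) {
        stage$convs[[l]] <- he(3, 3, cin, lay$channels[s])
        cin <- lay$channels[s]
      }
      if (s %in% spec$dense_side_stages) {
        for (l in seq_len(lay$convs[s]))
          stage$side[[l]] <- he(1, 1, lay$channels[s], spec$side_channels)
        nin <- if (spec$side_combine == "concat")
          spec$side_channels * lay$convs[s] else spec$side_channels
        stage$reduce <- he(1, 1, nin, 1L)
      } else {
        stage$reduce <- he(1, 1, lay$channels[s], 1L)
      }
      w[[s]] <- stage
    }
    weights <- w
  })
  structure(list(spec = spec, weights = weights,
                 fusion_weights = rep(1 / 5, 5)),
            class = "hed_predictor")
}

#' Forward pass of the improved-HED predictor
#'
#' Input sizes need not be multiples of 32: the image is replicate-padded
#' internally to the next multiple of 32 and the outputs are cropped back.
#'
#' @param object an [build_improved_hed()] predictor.
#' @param image H x W grayscale matrix or H x W x 3 RGB array, values in
#'   `[0, 1]`.
#' @param ... unused.
#' @return list with `side` (list of five H x W stage probability maps)
#'   and `fused` (H x W fused probability map); all values in `[0, 1]`.
#' @export
predict.hed_predictor <- function(object, image, ...) {
  if (is.matrix(image)) {
    image <- array(rep(image, 3), c(dim(image), 3L))
  }
  stopifnot(length(dim(image)) == 3)
  H <- dim(image)[1]; W <- dim(image)[2]
  Hp <- 32L * as.integer(ceiling(H / 32)); Wp <- 32L * as.integer(ceiling(W / 32))
  if (Hp != H || Wp != W) {
    padded <- array(0, c(Hp, Wp, dim(image)[3]))
    for (c in seq_len(dim(image)[3]))
      padded[, , c] <- pad_replicate(image[, , c], c(0L, Hp - H), c(0L, Wp - W))
    image <- padded
  }
  x <- image
  side_logits <- vector("list", 5)
  spec <- object$spec
  for (s in 1:5) {
    stage <- object$weights[[s]]
    layer_maps <- list()
    for (l in seq_along(stage$convs)) {
      x <- relu(conv2d(x, stage$convs[[l]]))
      if (s %in% spec$dense_side_stages)
        layer_maps[[l]] <- conv2d(x, stage$side[[l]])
    }
    if (s %in% spec$dense_side_stages) {
      stacked <- if (spec$side_combine == "concat") {
        do.call(function(...) {
          arrs <- list(...)
          out <- array(0, c(dim(arrs[[1]])[1:2],
                            sum(vapply(arrs, function(a) dim(a)[3], 0L))))
          at <- 0L
          for (a in arrs) {
            out[, , at + seq_len(dim(a)[3])] <- a
            at <- at + dim(a)[3]
          }
          out
        }, layer_maps)
      } else {
        Reduce(`+`, layer_maps)
      }
      logit <- conv2d(stacked, stage$reduce)
    } else {
      logit <- conv2d(x, stage$reduce)
    }
    side_logits[[s]] <- logit[, , 1]
    if (s < 5) x <- maxpool2(x)
  }
  side <- lapply(side_logits, function(m)
    sigmoid(bilinear_resize(m, Hp, Wp))[seq_len(H), seq_len(W), drop = FALSE])
  w <- object$fusion_weights / sum(object$fusion_weights)
  fused <- Reduce(`+`, Map(`*`, side, as.list(w)))
  list(side = side, fused = fused)
}

#' Multi-scale (image pyramid) edge prediction
#'
#' Resizes the image to each scale with bilinear interpolation, predicts
#' an edge-probability map per scale, restores every map to the original
#' resolution (bilinear), and fuses them by the pixelwise arithmetic mean.
#'
#' @param image H x W matrix or H x W x 3 array in `[0, 1]`.
#' @param scales numeric vector of positive scale factors; must be
#'   non-empty. Default `c(0.5, 1, 1.5)`.
#' @param predictor either a function `image -> probability matrix` or an
#'   `"hed_predictor"` (its fused map is used).
#' @return H x W fused probability map in `[0, 1]`.
#' @export
pyramid_predict <- function(image, scales = c(0.5, 1, 1.5), predictor) {
  if (length(scales) == 0) stop("scales must be non-empty")
  if (any(scales <= 0)) stop("scales must be positive")
  pf <- if (inherits(predictor, "hed_predictor")) {
    function(img) predict(predictor, img)$fused
  } else {
    stopifnot(is.function(predictor))
    predictor
  }
  H <- if (is.matrix(image)) nrow(image) else dim(image)[1]
  W <- if (is.matrix(image)) ncol(image) else dim(image)[2]
  maps <- lapply(scales, function(sc) {
    h <- max(1L, round(H * sc)); w <- max(1L, round(W * sc))
    m <- pf(bilinear_resize(image, h, w))
    bilinear_resize(m, H, W)
  })
  Reduce(`+`, maps) / length(maps)
}

#' Classical fallback edge detector
#'
#' Gradient-magnitude edge detection (Gaussian smoothing followed by Sobel
#' gradients), normalized to `[0, 1]`. It lets the two-step measurement
#' pipeline run end-to-end when no trained network weights are available;
#' on rendered synthetic scenes it recovers the berry contours to within
#' about a pixel.
#'
#' @param image H x W grayscale matrix or H x W x 3 RGB array in `[0, 1]`.
#' @param sigma Gaussian pre-smoothing standard deviation, px. Default 1.
#' @return H x W edge-probability matrix in `[0, 1]` (all zero for a
#'   constant image).
#' @export
fallback_edge_detector <- function(image, sigma = 1) {
  if (!is.numeric(image) || is.null(dim(image)) ||
      !(length(dim(image)) %in% c(2, 3)))
    stop("expected an H x W matrix or H x W x C array")
  g <- gaussian_blur(to_gray(image), sigma)
  gr <- sobel_gradients(g)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  mx <- max(mag)
  if (mx == 0) return(mag)
  mag / mx
}

#' Train the fusion weights for a few gradient steps
#'
#' The backbone is frozen (full training would need a deep-learning
#' framework and the 19,200-image set); the five fusion weights -- the
#' learned 1x1 fusion of the stage maps -- are optimized on one
#' (image, ground truth) pair by numerically differentiated gradient
#' descent on [combined_loss()]. Weights are parameterized through a
#' softmax so the fused map stays a convex combination.
#'
#' @param predictor an `"hed_predictor"`.
#' @param image input image (see [predict.hed_predictor()]).
#' @param G binary ground-truth edge map, same H x W.
#' @param steps number of gradient steps. Default 3.
#' @param lr learning rate. Default 1.
#' @param cfg a [loss_config()].
#' @return list with the updated `predictor` and the vector `losses` of
#'   length `steps + 1` (loss before training, then after each step).
#' @export
train_fusion_weights <- function(predictor, image, G, steps = 3, lr = 1,
                                 cfg = loss_config()) {
  stopifnot(inherits(predictor, "hed_predictor"))
  side <- predict(predictor, image)$side
  loss_of <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    fused <- Reduce(`+`, Map(`*`, side, as.list(w)))
    combined_loss(fused, G, cfg)
  }
  z <- log(pmax(predictor$fusion_weights, 1e-8))
  losses <- loss_of(z)
  h <- 1e-5
  for (step in seq_len(steps)) {
    grad <- vapply(seq_along(z), function(i) {
      zp <- z; zm <- z
      zp[i] <- zp[i] + h; zm[i] <- zm[i] - h
      (loss_of(zp) - loss_of(zm)) / (2 * h)
    }, 0)
    z <- z - lr * grad
    losses <- c(losses, loss_of(z))
  }
  w <- exp(z - max(z)); w <- w / sum(w)
  predictor$fusion_weights <- w
  list(predictor = predictor, losses = losses)
}
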