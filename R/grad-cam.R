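#' Grad-CAM heatmap for a convolutional classifier
#'
#' Gradient-weighted class activation mapping: channel weights are the
#' spatially averaged gradients of the target class score at the chosen
#' stage output; the weighted, rectified activation map is upsampled to the
#' input size and min-max scaled to \[0,1\].
#'
#' @param model A `miml_encoder` with classifier head.
#' @param image H x W numeric matrix in \[0,1\].
#' @param layer `"last"` (final residual stage) or `"penultimate"` (stage
#'   before it), or an explicit layer name.
#' @param class Target class index (0-based); default the predicted class.
#' @return H x W heatmap matrix in \[0,1\].
#' @export
grad_cam <- function(model, image, layer = c("last", "penultimate"),
                     class = NULL) {
  stopifnot(inherits(model, "miml_encoder"),
            model$config$head == "classifier")
  net <- model$net
  names_all <- vapply(net$layers, function(l) l$name, "")
  conv_stages <- grep("^stage[0-9]+_block", names_all, value = TRUE)
  if (length(layer) == 1 && !(layer[1] %in% c("last", "penultimate"))) {
    if (!(layer %in% names_all))
      stop("layer '", layer, "' not found; available: ",
           paste(names_all, collapse = ", "))
    target_name <- layer
  } else {
    layer <- match.arg(layer)
    stages <- as.integer(sub("^stage([0-9]+).*", "\\1", conv_stages))
    want <- if (layer == "last") max(stages) else max(stages) - 1L
    cand <- conv_stages[stages == want]
    if (!length(cand)) stop("no convolutional stage for '", layer, "'")
    target_name <- cand[length(cand)]
  }
  tgt <- match(target_name, names_all)
  x <- images_to_fmap(list(image))
  fw <- nn_forward(net, x, training = FALSE, record = TRUE)
  logits <- fw$out
  if (is.null(class)) class <- which.max(logits[, 1]) - 1L
  gout <- matrix(0, nrow(logits), 1)
  gout[class + 1L, 1] <- 1
  bw <- nn_backward(fw$net, fw$caches, gout, to = tgt + 1L)
  act <- fw$outs[[tgt]]
  grad <- bw$gin
  w <- rowMeans(get_mat(grad))
  cam <- as.numeric(crossprod(w, get_mat(act)))
  cam <- pmax(cam, 0)
  cam_m <- matrix(cam, act$h, act$w)
  up <- bilinear_resize(cam_m, nrow(image), ncol(image))
  rng <- range(up)
  if (diff(rng) > 0) (up - rng[1]) / diff(rng) else up * 0
}

bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == 1 && w == 1) return(matrix(m[1, 1], H, W))
  yi <- if (h == 1) rep(1, H) else seq(1, h, length.out = H)
  xi <- if (w == 1) rep(1, W) else seq(1, w, length.out = W)
  y0 <- pmin(floor(yi), h - 1); fy <- yi - y0
  x0 <- pmin(floor(xi), w - 1); fx <- xi - x0
  if (h == 1) { y0 <- rep(1, H); fy <- rep(0, H) }
  if (w == 1) { x0 <- rep(1, W); fx <- rep(0, W) }
  a <- m[y0, x0, drop = FALSE]; b <- m[pmin(y0 + 1, h), x0, drop = FALSE]
  c_ <- m[y0, pmin(x0 + 1, w), drop = FALSE]; d <- m[pmin(y0 + 1, h), pmin(x0 + 1, w), drop = FALSE]
  fy_m <- matrix(fy, H, W); fx_m <- matrix(fx, H, W, byrow = TRUE)
  a * (1 - fy_m) * (1 - fx_m) + b * fy_m * (1 - fx_m) +
    c_ * (1 - fy_m) * fx_m + d * fy_m * fx_m
}
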