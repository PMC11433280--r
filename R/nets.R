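#' Backbone build specification
#'
#' Configuration of the aligned-Xception-style encoder used by both
#' segmentation subnetworks: all down-sampling is carried by stride-2
#' depthwise separable convolutions (there is no max pooling anywhere in the
#' graph), and the atrous pyramid / decoder follow the usual
#' encoder--decoder semantic-segmentation layout. `width_multiplier` scales
#' every stage's channel count (floored at 8) so that desk-scale CPU models
#' can be built; `middle_repeats` sets the number of middle-flow blocks.
#'
#' @param width_multiplier real in (0, 1]; channel scaling factor.
#' @param output_stride 16 (default) or 8; ratio of input resolution to the
#'   deepest feature map.
#' @param dilation_rates three dilation rates for the atrous pyramid
#'   (doubled internally when `output_stride = 8`).
#' @param input_channels number of input image channels.
#' @param middle_repeats number of middle-flow blocks (16 in the full-size
#'   reference topology; use 1--2 for desk-scale CPU models).
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(width_multiplier = 1, output_stride = 16L,
                          dilation_rates = c(6L, 12L, 18L),
                          input_channels = 3L, middle_repeats = 16L) {
  if (!output_stride %in% c(8L, 16L)) stop("output_stride must be 8 or 16")
  if (width_multiplier <= 0 || width_multiplier > 1)
    stop("width_multiplier must be in (0, 1]")
  if (length(dilation_rates) != 3) stop("dilation_rates must have length 3")
  structure(list(width_multiplier = width_multiplier,
                 output_stride = as.integer(output_stride),
                 dilation_rates = as.integer(dilation_rates),
                 input_channels = as.integer(input_channels),
                 middle_repeats = as.integer(middle_repeats)),
            class = "backbone_spec")
}

# Channel scaling with the >= 8 floor.
scale_ch <- function(ch, wm) max(8L, as.integer(round(ch * wm)))

#' Build the encoder backbone
#'
#' An aligned-Xception-style feature extractor: stem, three entry blocks
#' (strides 2/2/2), configurable middle flow, exit block and three exit
#' separable convolutions. Down-sampling is done exclusively by stride-2
#' depthwise separable convolutions. The forward pass returns both the
#' deepest feature map (at `output_stride`) and a low-level feature map at
#' stride 4 for the decoder.
#'
#' @param spec a [backbone_spec()].
#' @return a backbone module; `$fwd(x, training)` maps an `[H, W, C, N]`
#'   array to `list(deep = , low = )`.
#' @export
build_backbone <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  wm <- spec$width_multiplier
  sc <- function(ch) scale_ch(ch, wm)
  os8 <- spec$output_stride == 8L
  s3 <- if (os8) 1L else 2L
  dil3 <- if (os8) 2L else 1L
  dil_exit <- if (os8) 4L else 2L

  m <- new_module("backbone")
  m$spec <- spec
  m$channels <- list(low = sc(128), deep = sc(2048))
  m$children$stem <- nc_sequential(
    conv2d(spec$input_channels, sc(32), kernel = 3L, stride = 2L, padding = 1L,
           bias = FALSE),
    batchnorm2d(sc(32)), relu(),
    conv2d(sc(32), sc(64), kernel = 3L, stride = 1L, padding = 1L, bias = FALSE),
    batchnorm2d(sc(64)), relu())
  m$children$block1 <- xception_block(sc(64), rep(sc(128), 3), stride = 2L,
                                      start_relu = FALSE)
  m$children$block2 <- xception_block(sc(128), rep(sc(256), 3), stride = 2L)
  m$children$block3 <- xception_block(sc(256), rep(sc(728), 3), stride = s3,
                                      dilation = dil3)
  mids <- lapply(seq_len(spec$middle_repeats), function(i)
    xception_block(sc(728), rep(sc(728), 3), dilation = dil3))
  m$children$middle <- nc_sequential(mids)
  m$children$exitblock <- xception_block(sc(728), c(sc(728), sc(1024), sc(1024)),
                                         dilation = dil_exit)
  m$children$exitconvs <- nc_sequential(
    sep_conv(sc(1024), sc(1536), dilation = dil_exit),
    sep_conv(sc(1536), sc(1536), dilation = dil_exit),
    sep_conv(sc(1536), sc(2048), dilation = dil_exit),
    relu())
  m$fwd <- function(x, training = FALSE) {
    h <- m$children$stem$fwd(x, training)
    low <- m$children$block1$fwd(h, training)
    h <- m$children$block2$fwd(low, training)
    h <- m$children$block3$fwd(h, training)
    h <- m$children$middle$fwd(h, training)
    h <- m$children$exitblock$fwd(h, training)
    deep <- m$children$exitconvs$fwd(h, training)
    list(deep = deep, low = low)
  }
  m$bwd <- function(d_deep, d_low = NULL) {
    g <- m$children$exitconvs$bwd(d_deep)
    g <- m$children$exitblock$bwd(g)
    g <- m$children$middle$bwd(g)
    g <- m$children$block3$bwd(g)
    g <- m$children$block2$bwd(g)
    if (!is.null(d_low)) g <- g + d_low
    g <- m$children$block1$bwd(g)
    m$children$stem$bwd(g)
  }
  m
}

# Atrous spatial pyramid: 1x1 branch, three dilated 3x3 branches, an
# image-pooling branch, concatenated and projected back by a 1x1 convolution.
aspp_module <- function(in_ch, out_ch, rates) {
  m <- new_module("aspp", cfg = list(in_ch = in_ch, out_ch = out_ch))
  m$children$b0 <- conv_bn_relu(in_ch, out_ch, kernel = 1L)
  m$children$b1 <- conv_bn_relu(in_ch, out_ch, kernel = 3L, padding = rates[1],
                                dilation = rates[1])
  m$children$b2 <- conv_bn_relu(in_ch, out_ch, kernel = 3L, padding = rates[2],
                                dilation = rates[2])
  m$children$b3 <- conv_bn_relu(in_ch, out_ch, kernel = 3L, padding = rates[3],
                                dilation = rates[3])
  m$children$gap <- global_avgpool()
  m$children$pool_conv <- conv_bn_relu(in_ch, out_ch, kernel = 1L)
  m$children$project <- conv_bn_relu(5L * out_ch, out_ch, kernel = 1L)
  m$out_ch <- out_ch
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
    m$hw <- c(H, W)
    ys <- list(m$children$b0$fwd(x, training), m$children$b1$fwd(x, training),
               m$children$b2$fwd(x, training), m$children$b3$fwd(x, training))
    g <- m$children$gap$fwd(x, training)
    dim(g) <- c(1L, 1L, d[3], N)
    gp <- m$children$pool_conv$fwd(g, training)
    ys[[5]] <- resize_bilinear_fwd_cpp(gp, H, W)
    cat <- array(0, c(H, W, 5L * out_ch, N))
    for (i in 1:5) cat[, , ((i - 1) * out_ch + 1):(i * out_ch), ] <- ys[[i]]
    m$children$project$fwd(cat, training)
  }
  m$bwd <- function(dy) {
    dcat <- m$children$project$bwd(dy)
    oc <- m$out_ch
    sl <- function(i) dcat[, , ((i - 1) * oc + 1):(i * oc), , drop = FALSE]
    dx <- m$children$b0$bwd(sl(1)) + m$children$b1$bwd(sl(2)) +
      m$children$b2$bwd(sl(3)) + m$children$b3$bwd(sl(4))
    dgp <- resize_bilinear_bwd_cpp(sl(5), 1L, 1L)
    dg <- m$children$pool_conv$bwd(dgp)
    dim(dg) <- c(dim(dg)[3], dim(dg)[4])
    dx + m$children$gap$bwd(dg)
  }
  m
}

# Decoder: upsample the pyramid output to the low-level grid, fuse with a
# 1x1-reduced low-level feature, and refine with one 3x3 separable conv.
decoder_module <- function(deep_ch, low_in_ch, low_ch, out_ch) {
  m <- new_module("decoder")
  m$children$low <- conv_bn_relu(low_in_ch, low_ch, kernel = 1L)
  m$children$up <- bilinear_resize()
  m$children$fuse <- nc_sequential(
    sep_conv(deep_ch + low_ch, out_ch, relu_in = FALSE), relu())
  m$deep_ch <- deep_ch
  m$fwd <- function(deep, low, training = FALSE) {
    lowp <- m$children$low$fwd(low, training)
    up <- m$children$up$fwd(deep, training, out_hw = dim(lowp)[1:2])
    d <- dim(lowp)
    cat <- array(0, c(d[1], d[2], m$deep_ch + d[3], d[4]))
    cat[, , 1:m$deep_ch, ] <- up
    cat[, , (m$deep_ch + 1):(m$deep_ch + d[3]), ] <- lowp
    m$children$fuse$fwd(cat, training)
  }
  m$bwd <- function(dy) {
    dcat <- m$children$fuse$bwd(dy)
    nch <- dim(dcat)[3]
    d_deep <- m$children$up$bwd(dcat[, , 1:m$deep_ch, , drop = FALSE])
    d_low <- m$children$low$bwd(dcat[, , (m$deep_ch + 1):nch, , drop = FALSE])
    list(deep = d_deep, low = d_low)
  }
  m
}

#' Coarse-mask fusion layer for the fine segmentation network
#'
#' Builds the fusion block that distils the coarse probability map into the
#' fine segmentation network: the full-resolution coarse mask is
#' area-downsampled onto the deepest feature grid, concatenated to the
#' encoder features as one extra channel, and fused back to the original
#' channel count by a 1x1 convolution, batch normalisation and ReLU. The
#' fusion weights are randomly initialised.
#'
#' @param channels number of channels of the deepest encoder feature map.
#' @return a module; `$fwd(feat, mask, training)` returns the fused feature
#'   map with the same shape as `feat`, `$bwd(dy)` returns
#'   `list(feat = , mask = )` gradients.
#' @export
fine_layer <- function(channels) {
  m <- new_module("fine_layer", cfg = list(in_ch = channels + 1L, out_ch = channels))
  m$children$fuse <- nc_sequential(
    conv2d(channels + 1L, channels, kernel = 1L, bias = FALSE),
    batchnorm2d(channels), relu())
  m$channels <- channels
  m$fwd <- function(feat, mask, training = FALSE) {
    fd <- dim(feat); md <- dim(mask)
    if (md[1] %% fd[1] != 0 || md[2] %% fd[2] != 0)
      stop("coarse mask resolution is not an integer multiple of the feature grid")
    m$factor <- c(md[1] %/% fd[1], md[2] %/% fd[2])
    mk <- avgpool2d_fwd_cpp(mask, m$factor[1], m$factor[2])
    if (!all(dim(mk)[1:2] == fd[1:2]))
      stop("spatial shape mismatch after mask resize")
    cat <- array(0, c(fd[1], fd[2], m$channels + 1L, fd[4]))
    cat[, , 1:m$channels, ] <- feat
    cat[, , m$channels + 1L, ] <- mk
    m$children$fuse$fwd(cat, training)
  }
  m$bwd <- function(dy) {
    dcat <- m$children$fuse$bwd(dy)
    dmask <- avgpool2d_bwd_cpp(dcat[, , m$channels + 1L, , drop = FALSE],
                               m$factor[1], m$factor[2])
    list(feat = dcat[, , 1:m$channels, , drop = FALSE], mask = dmask)
  }
  m
}

#' Build the coarse segmentation network
#'
#' Encoder (aligned-Xception backbone), atrous pyramid, decoder, and a 1x1
#' convolution with a single output channel followed by a sigmoid as the
#' prediction head (the head replaces the usual final 3x3 convolution and is
#' randomly initialised); the probability map is bilinearly upsampled to the
#' input resolution.
#'
#' @param spec a [backbone_spec()].
#' @return a segmentation network; `$fwd(x, training)` maps `[H, W, C, N]`
#'   images to an `[H, W, 1, N]` probability map.
#' @export
build_coarse_segnet <- function(spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  wm <- spec$width_multiplier
  sc <- function(ch) scale_ch(ch, wm)
  rates <- if (spec$output_stride == 8L) 2L * spec$dilation_rates else spec$dilation_rates
  m <- new_module("segnet")
  m$spec <- spec
  m$role <- "coarse"
  m$children$backbone <- build_backbone(spec)
  m$children$aspp <- aspp_module(sc(2048), sc(256), rates)
  m$children$decoder <- decoder_module(sc(256), sc(128), sc(48), sc(256))
  m$children$head <- conv2d(sc(256), 1L, kernel = 1L, bias = TRUE)
  m$children$act <- sigmoid_act()
  m$children$up <- bilinear_resize()
  m$fwd <- function(x, training = FALSE) {
    m$in_hw <- dim(x)[1:2]
    bb <- m$children$backbone$fwd(x, training)
    a <- m$children$aspp$fwd(bb$deep, training)
    f <- m$children$decoder$fwd(a, bb$low, training)
    p <- m$children$act$fwd(m$children$head$fwd(f, training), training)
    m$children$up$fwd(p, training, out_hw = m$in_hw)
  }
  m$bwd <- function(dP) {
    dp <- m$children$up$bwd(dP)
    df <- m$children$head$bwd(m$children$act$bwd(dp))
    dd <- m$children$decoder$bwd(df)
    da <- m$children$aspp$bwd(dd$deep)
    m$children$backbone$bwd(da, dd$low)
  }
  m
}

#' Build the fine segmentation network
#'
#' Shares the coarse network's structure; every encoder/decoder parameter is
#' initialised as a copy of the coarse model's (and subsequently trained
#' independently). A fusion layer ([fine_layer()]) is inserted between the
#' deepest encoder output and the pyramid/decoder, so the forward pass takes
#' the image together with the coarse probability map.
#'
#' @param spec the [backbone_spec()] the coarse model was built from.
#' @param coarse the coarse segmentation network whose parameters are copied;
#'   `NULL` requests an explicit fresh initialisation.
#' @return a segmentation network; `$fwd(x, mask, training)` returns an
#'   `[H, W, 1, N]` probability map.
#' @export
build_fine_segnet <- function(spec, coarse = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (!is.null(coarse)) {
    if (!identical(coarse$spec, spec))
      stop("spec disagrees with the coarse model it should share parameters with")
  }
  wm <- spec$width_multiplier
  sc <- function(ch) scale_ch(ch, wm)
  rates <- if (spec$output_stride == 8L) 2L * spec$dilation_rates else spec$dilation_rates
  m <- new_module("segnet")
  m$spec <- spec
  m$role <- "fine"
  m$children$backbone <- build_backbone(spec)
  m$children$fine <- fine_layer(sc(2048))
  m$children$aspp <- aspp_module(sc(2048), sc(256), rates)
  m$children$decoder <- decoder_module(sc(256), sc(128), sc(48), sc(256))
  m$children$head <- conv2d(sc(256), 1L, kernel = 1L, bias = TRUE)
  m$children$act <- sigmoid_act()
  m$children$up <- bilinear_resize()
  if (!is.null(coarse)) {
    shared <- param_values(coarse)
    set_param_values(m, shared, strict = FALSE)
    set_module_state(m, module_state(coarse))
  }
  m$fwd <- function(x, mask, training = FALSE) {
    m$in_hw <- dim(x)[1:2]
    bb <- m$children$backbone$fwd(x, training)
    fused <- m$children$fine$fwd(bb$deep, mask, training)
    a <- m$children$aspp$fwd(fused, training)
    f <- m$children$decoder$fwd(a, bb$low, training)
    p <- m$children$act$fwd(m$children$head$fwd(f, training), training)
    m$children$up$fwd(p, training, out_hw = m$in_hw)
  }
  m$bwd <- function(dP) {
    dp <- m$children$up$bwd(dP)
    df <- m$children$head$bwd(m$children$act$bwd(dp))
    dd <- m$children$decoder$bwd(df)
    da <- m$children$aspp$bwd(dd$deep)
    dfl <- m$children$fine$bwd(da)
    m$children$backbone$bwd(dfl$feat, dd$low)
  }
  m
}

#' Classification network build specification
#'
#' @param input_channels 4 when the coarse probability map is concatenated as
#'   a fourth input channel (mask-guided classification), 3 otherwise.
#' @param dilated_exit replace the exit-flow down-sampling with dilation-2,
#'   padding-2 separable convolutions (the modification that preserves
#'   feature-map resolution for small nodules).
#' @param width_multiplier,middle_repeats as in [backbone_spec()] (the
#'   classifier's middle flow has 8 repeats at full size).
#' @param dropout dropout probability on the pooled features before the
#'   logit head (0.5 in the reference classifier topology).
#' @return an object of class `classnet_spec`.
#' @export
classnet_spec <- function(input_channels = 4L, dilated_exit = TRUE,
                          width_multiplier = 1, middle_repeats = 8L,
                          dropout = 0.5) {
  if (!input_channels %in% c(3L, 4L)) stop("input_channels must be 3 or 4")
  structure(list(input_channels = as.integer(input_channels),
                 dilated_exit = isTRUE(dilated_exit),
                 width_multiplier = width_multiplier,
                 middle_repeats = as.integer(middle_repeats),
                 dropout = dropout,
                 num_classes = 1L),
            class = "classnet_spec")
}

#' Extend a 3-channel first-layer kernel bank to 4 input channels
#'
#' The fourth-channel kernels are the elementwise mean of the three RGB
#' channels; the RGB kernels themselves are unchanged. This is how weights
#' pre-trained on RGB images are carried over to the mask-guided classifier
#' whose fourth input channel is the coarse probability map.
#'
#' @param w an `[kh, kw, 3, Cout]` kernel array.
#' @return an `[kh, kw, 4, Cout]` kernel array.
#' @export
init_fourth_channel <- function(w) {
  d <- dim(w)
  if (length(d) != 4 || d[3] != 3) stop("expected a [kh, kw, 3, Cout] kernel bank")
  w4 <- array(0, c(d[1], d[2], 4L, d[4]))
  w4[, , 1:3, ] <- w
  w4[, , 4, ] <- (w[, , 1, ] + w[, , 2, ] + w[, , 3, ]) / 3
  w4
}

#' Build the benign/malignant classification network
#'
#' Xception-style classifier with two modifications: the exit-flow
#' down-sampling stage is removed so the deepest feature map keeps its
#' resolution, and the last two separable convolutions are dilated (rate 2,
#' padding 2) to recover the receptive field. Global average pooling feeds a
#' single-logit head with a sigmoid, giving one malignancy probability per
#' image.
#'
#' @param spec a [classnet_spec()].
#' @param rgb_first_conv optional `[3, 3, 3, C]` first-convolution weights
#'   (e.g. from an RGB-pretrained reference); for a 4-channel build they are
#'   extended with [init_fourth_channel()], preserving the RGB kernels.
#' @return a classifier module; `$fwd(x, training)` maps `[H, W, C, N]` to a
#'   length-`N` vector of probabilities in `[0, 1]`.
#' @export
build_classnet <- function(spec, rgb_first_conv = NULL) {
  stopifnot(inherits(spec, "classnet_spec"))
  wm <- spec$width_multiplier
  sc <- function(ch) scale_ch(ch, wm)
  dil <- if (spec$dilated_exit) 2L else 1L
  exit_stride <- if (spec$dilated_exit) 1L else 2L
  m <- new_module("classnet")
  m$spec <- spec
  m$children$stem <- nc_sequential(
    conv2d(spec$input_channels, sc(32), kernel = 3L, stride = 2L, padding = 1L,
           bias = FALSE),
    batchnorm2d(sc(32)), relu(),
    conv2d(sc(32), sc(64), kernel = 3L, padding = 1L, bias = FALSE),
    batchnorm2d(sc(64)), relu())
  m$children$block1 <- xception_block(sc(64), rep(sc(128), 3), stride = 2L,
                                      start_relu = FALSE)
  m$children$block2 <- xception_block(sc(128), rep(sc(256), 3), stride = 2L)
  m$children$block3 <- xception_block(sc(256), rep(sc(728), 3), stride = 2L)
  mids <- lapply(seq_len(spec$middle_repeats), function(i)
    xception_block(sc(728), rep(sc(728), 3)))
  m$children$middle <- nc_sequential(mids)
  m$children$exitblock <- xception_block(sc(728), c(sc(728), sc(1024), sc(1024)),
                                         stride = exit_stride)
  m$children$exit1 <- sep_conv(sc(1024), sc(1536), dilation = dil)
  m$children$exit2 <- sep_conv(sc(1536), sc(2048), dilation = dil)
  m$children$exit_relu <- relu()
  m$children$gap <- global_avgpool()
  m$children$drop <- dropout(spec$dropout)
  m$children$fc <- dense(sc(2048), 1L)
  m$children$act <- sigmoid_act()
  if (!is.null(rgb_first_conv)) {
    w <- rgb_first_conv
    if (spec$input_channels == 4L) w <- init_fourth_channel(w)
    if (!identical(dim(w), dim(m$children$stem$children$l01$params$w$value)))
      stop("first-conv weights do not match the built stem")
    m$children$stem$children$l01$params$w$value <- w
  }
  m$fwd <- function(x, training = FALSE, keep_features = FALSE) {
    h <- m$children$stem$fwd(x, training)
    h <- m$children$block1$fwd(h, training)
    h <- m$children$block2$fwd(h, training)
    h <- m$children$block3$fwd(h, training)
    h <- m$children$middle$fwd(h, training)
    h <- m$children$exitblock$fwd(h, training)
    h <- m$children$exit1$fwd(h, training)
    h <- m$children$exit2$fwd(h, training)
    h <- m$children$exit_relu$fwd(h, training)
    if (keep_features) m$features <- h
    g <- m$children$drop$fwd(m$children$gap$fwd(h, training), training)
    as.numeric(m$children$act$fwd(m$children$fc$fwd(g, training), training))
  }
  m$bwd <- function(dprob) {
    dy <- matrix(dprob, 1L)
    dg <- m$children$fc$bwd(m$children$act$bwd(dy))
    dh <- m$children$gap$bwd(m$children$drop$bwd(dg))
    dh <- m$children$exit_relu$bwd(dh)
    dh <- m$children$exit2$bwd(dh)
    dh <- m$children$exit1$bwd(dh)
    dh <- m$children$exitblock$bwd(dh)
    dh <- m$children$middle$bwd(dh)
    dh <- m$children$block3$bwd(dh)
    dh <- m$children$block2$bwd(dh)
    dh <- m$children$block1$bwd(dh)
    m$children$stem$bwd(dh)
  }
  m
}
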