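# Layer modules of the CNN engine. Every module is an environment with
# $fwd(x, training) and $bwd(dy); $bwd accumulates parameter gradients and
# returns the gradient with respect to the module input. Activations are
# [H, W, C, N] arrays; caches needed for the backward pass are kept on the
# module and dropped as soon as they are consumed.

accum_grad <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(p)
}

# Per-channel sums of an [H*W, C, N]-shaped vectorised tensor (no copies).
channel_sum <- function(a, HW, C, N) {
  .rowSums(.colSums(a, HW, C * N), C, N)
}

conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, padding = 0L,
                   dilation = 1L, groups = 1L, bias = TRUE, kind = "conv") {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  m <- new_module(kind, cfg = list(kernel = kernel, stride = stride,
                                   padding = padding, dilation = dilation,
                                   groups = groups, in_ch = in_ch, out_ch = out_ch))
  fan_in <- kernel * kernel * (in_ch / groups)
  m$params$w <- nc_param(array(trunc_normal(fan_in * out_ch, sqrt(2 / fan_in)),
                               dim = c(kernel, kernel, in_ch / groups, out_ch)))
  if (bias) m$params$b <- nc_param(numeric(out_ch))
  depthwise <- groups == in_ch && out_ch == in_ch && !bias
  onebyone <- kernel == 1L && stride == 1L && padding == 0L && groups == 1L
  m$fwd <- function(x, training = FALSE) {
    if (depthwise) {
      m$x <- x
      dwconv2d_fwd_cpp(x, m$params$w$value, stride, padding, dilation)
    } else if (onebyone) {
      if (training) m$x <- x
      conv1x1_fwd_cpp(x, m$params$w$value,
                      if (bias) m$params$b$value else numeric(0))
    } else if (groups == 1L && training) {
      m$in_hw <- dim(x)[1:2]
      r <- conv2d_fwd_cache_cpp(x, m$params$w$value,
                                if (bias) m$params$b$value else numeric(0),
                                stride, padding, dilation)
      m$cols <- r$cols
      r$y
    } else {
      m$x <- x
      conv2d_fwd_cpp(x, m$params$w$value,
                     if (bias) m$params$b$value else numeric(0),
                     stride, padding, dilation, groups)
    }
  }
  m$bwd <- function(dy) {
    if (depthwise) {
      r <- dwconv2d_bwd_cpp(m$x, m$params$w$value, dy, stride, padding, dilation)
      m$x <- NULL
    } else if (onebyone) {
      r <- conv1x1_bwd_cpp(m$x, m$params$w$value, dy, bias)
      m$x <- NULL
      if (bias) accum_grad(m$params$b, r$db)
    } else if (!is.null(m$cols)) {
      r <- conv2d_bwd_cache_cpp(m$cols, m$params$w$value, dy,
                                m$in_hw[1], m$in_hw[2],
                                stride, padding, dilation, bias)
      m$cols <- NULL
      if (bias) accum_grad(m$params$b, r$db)
    } else {
      r <- conv2d_bwd_cpp(m$x, m$params$w$value, dy,
                          stride, padding, dilation, groups, bias, TRUE)
      m$x <- NULL
      if (bias) accum_grad(m$params$b, r$db)
    }
    accum_grad(m$params$w, r$dw)
    r$dx
  }
  m
}

batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  m <- new_module("batchnorm", cfg = list(in_ch = ch, out_ch = ch))
  m$params$gamma <- nc_param(rep(1, ch))
  m$params$beta <- nc_param(rep(0, ch))
  m$state$running_mean <- rep(0, ch)
  m$state$running_var <- rep(1, ch)
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    if (training) {
      Mn <- HW * N
      mu <- channel_sum(x, HW, C, N) / Mn
      xc <- x - rep(mu, each = HW)
      v <- channel_sum(xc * xc, HW, C, N) / Mn
      invstd <- 1 / sqrt(v + eps)
      m$state$running_mean <- (1 - momentum) * m$state$running_mean + momentum * mu
      m$state$running_var <- (1 - momentum) * m$state$running_var +
        momentum * v * Mn / max(Mn - 1, 1)
      m$cache <- list(xc = xc, invstd = invstd, HW = HW, C = C, N = N, Mn = Mn,
                      training = TRUE)
      x <- xc * rep(invstd * m$params$gamma$value, each = HW) +
        rep(m$params$beta$value, each = HW)
      dim(x) <- d
      x
    } else {
      invstd <- 1 / sqrt(m$state$running_var + eps)
      m$cache <- list(invstd = invstd, HW = HW, C = C, N = N, training = FALSE)
      y <- (x - rep(m$state$running_mean, each = HW)) *
        rep(invstd * m$params$gamma$value, each = HW) +
        rep(m$params$beta$value, each = HW)
      dim(y) <- d
      y
    }
  }
  m$bwd <- function(dy) {
    cc <- m$cache; HW <- cc$HW; C <- cc$C; N <- cc$N
    d <- dim(dy)
    if (!cc$training) {
      dx <- dy * rep(cc$invstd * m$params$gamma$value, each = HW)
      dim(dx) <- d
      m$cache <- NULL
      return(dx)
    }
    xhat <- cc$xc * rep(cc$invstd, each = HW)
    dbeta <- channel_sum(dy, HW, C, N)
    dgamma <- channel_sum(dy * xhat, HW, C, N)
    accum_grad(m$params$gamma, dgamma)
    accum_grad(m$params$beta, dbeta)
    Mn <- cc$Mn
    dx <- (rep(m$params$gamma$value * cc$invstd / Mn, each = HW)) *
      (Mn * dy - rep(dbeta, each = HW) - xhat * rep(dgamma, each = HW))
    dim(dx) <- d
    m$cache <- NULL
    dx
  }
  m
}

relu <- function() {
  m <- new_module("relu")
  m$fwd <- function(x, training = FALSE) {
    m$mask <- x > 0
    x * m$mask
  }
  m$bwd <- function(dy) {
    dx <- dy * m$mask
    m$mask <- NULL
    dx
  }
  m
}

sigmoid_act <- function() {
  m <- new_module("sigmoid")
  m$fwd <- function(x, training = FALSE) {
    y <- 1 / (1 + exp(-x))
    m$y <- y
    y
  }
  m$bwd <- function(dy) {
    dx <- dy * m$y * (1 - m$y)
    m$y <- NULL
    dx
  }
  m
}

# Bilinear resize to a fixed target or by a scale factor.
bilinear_resize <- function(scale = NULL) {
  m <- new_module("bilinear_resize", cfg = list(stride = if (is.null(scale)) NA else 1 / scale))
  m$scale <- scale
  m$fwd <- function(x, training = FALSE, out_hw = NULL) {
    d <- dim(x)
    m$in_hw <- d[1:2]
    if (is.null(out_hw)) out_hw <- as.integer(round(d[1:2] * m$scale))
    resize_bilinear_fwd_cpp(x, out_hw[1], out_hw[2])
  }
  m$bwd <- function(dy) resize_bilinear_bwd_cpp(dy, m$in_hw[1], m$in_hw[2])
  m
}

# Non-overlapping average pooling by an integer factor (area downsampling;
# used only to bring a full-resolution probability map onto a feature grid).
area_downsample <- function(factor) {
  m <- new_module("area_downsample", cfg = list(kernel = factor, stride = factor))
  m$fwd <- function(x, training = FALSE) avgpool2d_fwd_cpp(x, factor, factor)
  m$bwd <- function(dy) avgpool2d_bwd_cpp(dy, factor, factor)
  m
}

global_avgpool <- function() {
  m <- new_module("global_avgpool")
  m$fwd <- function(x, training = FALSE) {
    d <- dim(x)
    m$in_dim <- d
    matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  }
  m$bwd <- function(dy) {
    d <- m$in_dim; HW <- d[1] * d[2]
    dx <- rep(as.numeric(dy) / HW, each = HW)
    dim(dx) <- d
    dx
  }
  m
}

# Inverted dropout on the pooled feature vector (identity in eval mode).
dropout <- function(p = 0.5) {
  m <- new_module("dropout", cfg = list(kernel = NA, stride = NA))
  m$p <- p
  m$fwd <- function(x, training = FALSE) {
    if (!training || p <= 0) return(x)
    keep <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
    m$mask <- keep
    x * keep
  }
  m$bwd <- function(dy) {
    if (is.null(m$mask)) return(dy)
    dx <- dy * m$mask
    m$mask <- NULL
    dx
  }
  m
}

dense <- function(in_dim, out_dim) {
  m <- new_module("dense", cfg = list(in_ch = in_dim, out_ch = out_dim))
  m$params$w <- nc_param(matrix(trunc_normal(out_dim * in_dim, sqrt(2 / in_dim)),
                                out_dim, in_dim))
  m$params$b <- nc_param(numeric(out_dim))
  m$fwd <- function(x, training = FALSE) {
    m$x <- x
    m$params$w$value %*% x + m$params$b$value
  }
  m$bwd <- function(dy) {
    accum_grad(m$params$w, dy %*% t(m$x))
    accum_grad(m$params$b, rowSums(dy))
    m$x <- NULL
    t(m$params$w$value) %*% dy
  }
  m
}

# ---- containers -------------------------------------------------------------

nc_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1 && is.list(mods[[1]]) && !inherits(mods[[1]], "nc_module"))
    mods <- mods[[1]]
  m <- new_module("sequential")
  names(mods) <- sprintf("l%02d", seq_along(mods))
  m$children <- mods
  m$fwd <- function(x, training = FALSE) {
    for (ch in m$children) x <- ch$fwd(x, training)
    x
  }
  m$bwd <- function(dy) {
    for (ch in rev(m$children)) dy <- ch$bwd(dy)
    dy
  }
  m
}

# y = main(x) + skip(x); skip NULL means identity.
nc_residual <- function(main, skip = NULL) {
  m <- new_module("residual")
  m$children$main <- main
  if (!is.null(skip)) m$children$skip <- skip
  m$fwd <- function(x, training = FALSE) {
    y <- m$children$main$fwd(x, training)
    s <- if (is.null(m$children$skip)) x else m$children$skip$fwd(x, training)
    y + s
  }
  m$bwd <- function(dy) {
    dx <- m$children$main$bwd(dy)
    ds <- if (is.null(m$children$skip)) dy else m$children$skip$bwd(dy)
    dx + ds
  }
  m
}

# Depthwise-separable convolution: [ReLU ->] depthwise 3x3 -> BN -> pointwise
# 1x1 -> BN. Pre-activation ordering as in aligned-Xception blocks.
sep_conv <- function(in_ch, out_ch, stride = 1L, dilation = 1L, relu_in = TRUE) {
  mods <- list()
  if (relu_in) mods <- c(mods, list(relu()))
  mods <- c(mods, list(
    conv2d(in_ch, in_ch, kernel = 3L, stride = stride, padding = dilation,
           dilation = dilation, groups = in_ch, bias = FALSE, kind = "depthwise_conv"),
    batchnorm2d(in_ch),
    conv2d(in_ch, out_ch, kernel = 1L, bias = FALSE, kind = "pointwise_conv"),
    batchnorm2d(out_ch)))
  nc_sequential(mods)
}

# Xception-style block: three separable convolutions, the last carrying the
# stride, with a 1x1 projection skip when shape changes.
xception_block <- function(in_ch, chs, stride = 1L, dilation = 1L, start_relu = TRUE) {
  main <- nc_sequential(
    sep_conv(in_ch, chs[1], dilation = dilation, relu_in = start_relu),
    sep_conv(chs[1], chs[2], dilation = dilation),
    sep_conv(chs[2], chs[3], stride = stride, dilation = dilation))
  skip <- NULL
  if (stride != 1L || in_ch != chs[3])
    skip <- nc_sequential(
      conv2d(in_ch, chs[3], kernel = 1L, stride = stride, bias = FALSE),
      batchnorm2d(chs[3]))
  nc_residual(main, skip)
}

conv_bn_relu <- function(in_ch, out_ch, kernel = 1L, stride = 1L, padding = 0L,
                         dilation = 1L) {
  nc_sequential(
    conv2d(in_ch, out_ch, kernel = kernel, stride = stride, padding = padding,
           dilation = dilation, bias = FALSE),
    batchnorm2d(out_ch),
    relu())
}
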