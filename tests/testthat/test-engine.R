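# Numerical checks of the CNN engine: convolution and batch-norm gradients
# against central finite differences, and resize/pooling adjoint identities.

ns <- asNamespace("nodulecascade")

test_that("convolution gradients match finite differences", {
  set.seed(1)
  cfgs <- list(list(k = 3L, s = 1L, p = 1L, d = 1L, g = 1L),
               list(k = 3L, s = 2L, p = 1L, d = 1L, g = 1L),
               list(k = 3L, s = 1L, p = 2L, d = 2L, g = 4L),
               list(k = 1L, s = 1L, p = 0L, d = 1L, g = 1L))
  for (cf in cfgs) {
    m <- ns$conv2d(4L, 4L, cf$k, cf$s, cf$p, cf$d, cf$g, bias = TRUE)
    x <- array(rnorm(7 * 6 * 4 * 2), c(7, 6, 4, 2))
    y <- m$fwd(x, training = TRUE)
    dy <- array(rnorm(length(y)), dim(y))
    dx <- m$bwd(dy)
    loss <- function(xx) sum(ns$conv2d_fwd_cpp(xx, m$params$w$value,
                                               m$params$b$value,
                                               cf$s, cf$p, cf$d, cf$g) * dy)
    eps <- 1e-5
    for (i in sample(length(x), 10)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      expect_equal(dx[i], (loss(xp) - loss(xm)) / (2 * eps), tolerance = 1e-5)
    }
    lw <- function(ww) sum(ns$conv2d_fwd_cpp(x, ww, m$params$b$value,
                                             cf$s, cf$p, cf$d, cf$g) * dy)
    for (i in sample(length(m$params$w$value), 6)) {
      wp <- m$params$w$value; wp[i] <- wp[i] + eps
      wm <- m$params$w$value; wm[i] <- wm[i] - eps
      expect_equal(m$params$w$grad[i], (lw(wp) - lw(wm)) / (2 * eps),
                   tolerance = 1e-5)
    }
  }
})

test_that("depthwise convolution agrees with the grouped general kernel", {
  set.seed(2)
  C <- 5L
  x <- array(rnorm(8 * 8 * C * 3), c(8, 8, C, 3))
  w <- array(rnorm(9 * C), c(3, 3, 1, C))
  y_dw <- ns$dwconv2d_fwd_cpp(x, w, 1L, 1L, 1L)
  y_gen <- ns$conv2d_fwd_cpp(x, w, numeric(0), 1L, 1L, 1L, C)
  expect_equal(y_dw, y_gen, tolerance = 1e-12)
  dy <- array(rnorm(length(y_dw)), dim(y_dw))
  b_dw <- ns$dwconv2d_bwd_cpp(x, w, dy, 1L, 1L, 1L)
  b_gen <- ns$conv2d_bwd_cpp(x, w, dy, 1L, 1L, 1L, C, FALSE, TRUE)
  expect_equal(b_dw$dx, b_gen$dx, tolerance = 1e-12)
  expect_equal(b_dw$dw, b_gen$dw, tolerance = 1e-12)
})

test_that("batch-norm training-mode gradient matches finite differences", {
  set.seed(3)
  C <- 3L
  bn <- ns$batchnorm2d(C)
  bn$params$gamma$value <- runif(C, 0.5, 1.5)
  bn$params$beta$value <- rnorm(C)
  x <- array(rnorm(5 * 4 * C * 3), c(5, 4, C, 3))
  y <- bn$fwd(x, training = TRUE)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- bn$bwd(dy)
  fwd_loss <- function(xx) {
    b2 <- ns$batchnorm2d(C)
    b2$params$gamma$value <- bn$params$gamma$value
    b2$params$beta$value <- bn$params$beta$value
    sum(b2$fwd(xx, training = TRUE) * dy)
  }
  eps <- 1e-5
  for (i in sample(length(x), 12)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(dx[i], (fwd_loss(xp) - fwd_loss(xm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("bilinear resize backward is the adjoint of forward", {
  set.seed(4)
  x <- array(rnorm(6 * 5 * 2 * 2), c(6, 5, 2, 2))
  y <- ns$resize_bilinear_fwd_cpp(x, 13L, 11L)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- ns$resize_bilinear_bwd_cpp(dy, 6L, 5L)
  # <Ax, dy> == <x, A^T dy>
  expect_equal(sum(y * dy), sum(x * dx), tolerance = 1e-10)
})

test_that("area downsampling averages blocks and distributes gradients", {
  x <- array(1:16, c(4, 4, 1, 1)) * 1.0
  y <- ns$avgpool2d_fwd_cpp(x, 2L, 2L)
  expect_equal(dim(y), c(2L, 2L, 1L, 1L))
  expect_equal(y[1, 1, 1, 1], mean(x[1:2, 1:2, 1, 1]))
  dy <- array(4, c(2, 2, 1, 1))
  dx <- ns$avgpool2d_bwd_cpp(dy, 2L, 2L)
  expect_true(all(dx == 1))
})

test_that("whole-network gradients are correct end to end", {
  set.seed(5)
  spec <- tiny_backbone()
  net <- build_coarse_segnet(spec)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  g <- array(0, c(32, 32, 1, 2)); g[12:20, 12:20, 1, ] <- 1
  lp <- hybrid_loss_params(gamma = 0.02, K = 5, margin = 0.3)
  loss_now <- function() {
    P <- net$fwd(x, training = TRUE)
    ns$hybrid_loss_grad(P, g, lp)$loss
  }
  ns$zero_grads(net)
  P <- net$fwd(x, training = TRUE)
  net$bwd(ns$hybrid_loss_grad(P, g, lp)$dP)
  ps <- ns$module_params(net)
  set.seed(42)
  eps <- 1e-4
  checked <- 0
  for (nm in sample(names(ps), 5)) {
    p <- ps[[nm]]
    i <- sample(length(p$value), 1)
    v0 <- p$value[i]
    p$value[i] <- v0 + eps; l1 <- loss_now()
    p$value[i] <- v0 - eps; l2 <- loss_now()
    p$value[i] <- v0
    num <- (l1 - l2) / (2 * eps)
    ana <- p$grad[i]
    if (abs(num) > 1e-7) {
      expect_equal(ana, num, tolerance = 0.05)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 2)
})

test_that("Adam updates move parameters and zero_grads clears gradients", {
  set.seed(6)
  m <- ns$conv2d(2L, 2L, 3L, padding = 1L)
  x <- array(rnorm(4 * 4 * 2 * 1), c(4, 4, 2, 1))
  y <- m$fwd(x, training = TRUE)
  m$bwd(array(1, dim(y)))
  w0 <- m$params$w$value
  opt <- ns$adam_state()
  ns$adam_step(m, opt, 1e-2)
  expect_false(identical(w0, m$params$w$value))
  ns$zero_grads(m)
  expect_null(m$params$w$grad)
})
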