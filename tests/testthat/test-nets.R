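# Architecture contracts of the three subnetworks.

ns <- asNamespace("nodulecascade")

test_that("backbone spec validates its domain", {
  expect_error(backbone_spec(output_stride = 4), "output_stride")
  expect_error(backbone_spec(width_multiplier = 0), "width_multiplier")
  expect_error(classnet_spec(input_channels = 2), "input_channels")
})

test_that("backbone exposes stride-16 deep and stride-4 low-level features", {
  set.seed(1)
  bb <- build_backbone(tiny_backbone())
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- bb$fwd(x, training = FALSE)
  expect_equal(dim(out$deep)[1:2], c(4L, 4L))     # 64 / 16
  expect_equal(dim(out$low)[1:2], c(16L, 16L))    # 64 / 4
  # output_stride 8 halves the deep stride
  bb8 <- build_backbone(backbone_spec(width_multiplier = 0.125,
                                      middle_repeats = 1L, output_stride = 8L))
  out8 <- bb8$fwd(x, training = FALSE)
  expect_equal(dim(out8$deep)[1:2], c(8L, 8L))
})

test_that("the backbone graph contains no max pooling", {
  set.seed(1)
  layers <- network_layers(build_backbone(tiny_backbone()))
  expect_false(any(grepl("max", layers$type, ignore.case = TRUE)))
  expect_false(any(grepl("pool", layers$type)))  # not even average pooling
  # every spatial down-sampling inside the backbone is a stride-2 convolution
  strided <- layers[!is.na(layers$stride) & layers$stride == 2, ]
  expect_true(all(strided$type %in% c("conv", "depthwise_conv")))
  expect_true(any(strided$type == "depthwise_conv"))
})

test_that("the coarse network outputs a full-resolution probability map", {
  set.seed(2)
  net <- build_coarse_segnet(tiny_backbone())
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  P <- net$fwd(x, training = FALSE)
  expect_equal(dim(P), c(64L, 64L, 1L, 2L))
  expect_true(all(P >= 0 & P <= 1))
  # prediction head: 1x1 convolution with a single output channel
  head <- net$children$head
  expect_equal(head$cfg$kernel, 1L)
  expect_equal(head$cfg$out_ch, 1L)
  # deterministic in inference mode
  expect_identical(P, net$fwd(x, training = FALSE))
  # shape law for another input size divisible by 32
  x96 <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  expect_equal(dim(net$fwd(x96, training = FALSE)), c(96L, 96L, 1L, 1L))
})

test_that("the fusion layer concatenates one mask channel and keeps shape", {
  set.seed(3)
  C <- 16L
  fl <- fine_layer(C)
  feat <- array(rnorm(4 * 4 * C * 2), c(4, 4, C, 2))
  mask <- array(runif(64 * 64 * 1 * 2), c(64, 64, 1, 2))
  fused <- fl$fwd(feat, mask, training = FALSE)
  expect_equal(dim(fused), dim(feat))
  # the fusion convolution receives C + 1 input channels
  expect_equal(fl$children$fuse$children$l01$cfg$in_ch, C + 1L)
  expect_error(fl$fwd(feat, array(0, c(63, 64, 1, 2))), "multiple|mismatch")
})

test_that("the fine network copies every coarse parameter at construction", {
  set.seed(4)
  spec <- tiny_backbone()
  coarse <- build_coarse_segnet(spec)
  fine <- build_fine_segnet(spec, coarse)
  cp <- ns$param_values(coarse)
  fp <- ns$param_values(fine)
  for (nm in names(cp)) expect_identical(fp[[nm]], cp[[nm]])
  # parameter count = coarse count + fusion-layer parameters only
  expect_equal(count_params(fine),
               count_params(coarse) + count_params(fine$children$fine))
  # forward contract
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  mk <- coarse$fwd(x, training = FALSE)
  P <- fine$fwd(x, mk, training = FALSE)
  expect_equal(dim(P), c(64L, 64L, 1L, 2L))
  expect_true(all(P >= 0 & P <= 1))
  # after an optimisation step the shared parameters may diverge
  ns$zero_grads(fine)
  Pf <- fine$fwd(x, mk, training = TRUE)
  fine$bwd(array(1 / length(Pf), dim(Pf)))
  ns$adam_step(fine, ns$adam_state(), 1e-2)
  expect_false(identical(ns$param_values(fine)[["head.w"]], cp[["head.w"]]))
  # a mismatched spec is refused
  other <- backbone_spec(width_multiplier = 0.25, middle_repeats = 1L)
  expect_error(build_fine_segnet(other, coarse), "spec")
})

test_that("the classifier meets its exit-flow and output contracts", {
  set.seed(5)
  net <- build_classnet(tiny_classnet())
  x <- array(runif(64 * 64 * 4 * 3), c(64, 64, 4, 3))
  p <- net$fwd(x, training = FALSE)
  expect_length(p, 3)
  expect_true(all(p >= 0 & p <= 1))
  # last two separable convolutions are dilated with rate 2, padding 2
  for (blk in c("exit1", "exit2")) {
    dw <- network_layers(net$children[[blk]])
    dw <- dw[dw$type == "depthwise_conv", ]
    expect_equal(dw$dilation, 2)
    expect_equal(dw$padding, 2)
  }
  # removing the exit down-sampling doubles the deepest feature resolution
  net$fwd(x, training = FALSE, keep_features = TRUE)
  expect_equal(dim(net$features)[1:2], c(4L, 4L))   # stride 16
  ref <- build_classnet(tiny_classnet(dilated_exit = FALSE))
  ref$fwd(x[, , 1:4, , drop = FALSE], training = FALSE, keep_features = TRUE)
  expect_equal(dim(ref$features)[1:2], c(2L, 2L))   # stride 32 reference
  refdw <- network_layers(ref$children$exit1)
  refdw <- refdw[refdw$type == "depthwise_conv", ]
  expect_equal(refdw$dilation, 1)
})

test_that("fourth-channel initialisation averages the RGB kernels", {
  k <- array(rnorm(3 * 3 * 3 * 8), c(3, 3, 3, 8))
  k4 <- init_fourth_channel(k)
  expect_equal(dim(k4), c(3L, 3L, 4L, 8L))
  expect_identical(k4[, , 1:3, ], k)
  expect_equal(k4[, , 4, ], (k[, , 1, ] + k[, , 2, ] + k[, , 3, ]) / 3,
               tolerance = 1e-12)
  # identical RGB kernels reproduce themselves in channel 4
  same <- array(0, c(3, 3, 3, 8))
  for (ch in 1:3) same[, , ch, ] <- k[, , 1, ]
  expect_equal(init_fourth_channel(same)[, , 4, ], k[, , 1, ], tolerance = 1e-12)
  # constant (1, 2, 3) kernels average to 2
  c123 <- array(rep(1:3, each = 9), c(3, 3, 3, 1))
  expect_true(all(init_fourth_channel(c123)[, , 4, ] == 2))
  expect_error(init_fourth_channel(array(0, c(3, 3, 4, 8))), "3")
})

test_that("RGB-pretrained first-layer weights load into the 4-channel net", {
  set.seed(6)
  w3 <- array(rnorm(3 * 3 * 3 * 8), c(3, 3, 3, 8))
  net <- build_classnet(tiny_classnet(), rgb_first_conv = w3)
  w <- net$children$stem$children$l01$params$w$value
  expect_identical(w[, , 1:3, ], w3)
  expect_equal(w[, , 4, ], (w3[, , 1, ] + w3[, , 2, ] + w3[, , 3, ]) / 3,
               tolerance = 1e-12)
})

test_that("a width-0.125 model runs forward and backward quickly", {
  set.seed(7)
  net <- build_coarse_segnet(tiny_backbone())
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  g <- array(0, c(64, 64, 1, 4)); g[24:40, 24:40, 1, ] <- 1
  net$fwd(x, training = TRUE)  # warm-up allocation
  t0 <- proc.time()[3]
  P <- net$fwd(x, training = TRUE)
  lg <- ns$hybrid_loss_grad(P, g, hybrid_loss_params())
  net$bwd(lg$dP)
  expect_lt(proc.time()[3] - t0, 1)
})

test_that("checkpoints round-trip and refuse mismatched build specs", {
  set.seed(8)
  spec <- tiny_backbone()
  net <- build_coarse_segnet(spec)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  P <- net$fwd(x, training = FALSE)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, list(backbone = spec, role = "coarse"), path)
  ck <- load_checkpoint(path, expect_spec = list(backbone = spec, role = "coarse"))
  net2 <- ns$restore_network(build_coarse_segnet(spec), ck)
  expect_identical(net2$fwd(x, training = FALSE), P)
  wrong <- list(backbone = backbone_spec(width_multiplier = 0.25), role = "coarse")
  expect_error(load_checkpoint(path, expect_spec = wrong), "disagrees")
})
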