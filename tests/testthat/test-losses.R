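# Dice loss, hard-pixel selection, rank loss, hybrid loss, cross-entropy.

test_that("dice loss matches pixel-counting limits and oracle", {
  G <- matrix(0, 10, 10)
  G[1:10, 1:10][1:100 <= 100] <- 0
  G[3:8, 3:8] <- 1  # 36 foreground pixels
  # perfect prediction -> ~0
  expect_lt(dice_loss(G, G, 1e-6), 1e-7)
  # all-zero prediction -> 1 (to within epsilon)
  expect_equal(dice_loss(G * 0, G, 1e-6), 1, tolerance = 1e-6)
  # half-overlap oracle: |P|=|G|=50, intersection 25 -> 1 - 50/100 = 0.5
  P <- matrix(0, 10, 10); G2 <- matrix(0, 10, 10)
  G2[1:10, 1:5] <- 1            # 50 px (columns 1:5)
  P[1:5, 1:10] <- 1             # 50 px (rows 1:5), overlap 5x5 = 25 px
  expect_equal(dice_loss(P, G2, 1e-12), 0.5, tolerance = 1e-9)
  # batch average equals mean of single-image losses
  Pb <- array(c(P, G2), c(10, 10, 2))
  Gb <- array(c(G2, G2), c(10, 10, 2))
  expect_equal(dice_loss(Pb, Gb),
               mean(c(dice_loss(P, G2), dice_loss(G2, G2))),
               tolerance = 1e-12)
})

test_that("dice loss validates its inputs", {
  G <- matrix(c(0, 1), 2, 2)
  expect_error(dice_loss(matrix(0.5, 3, 3), G), "shape")
  expect_error(dice_loss(matrix(1.5, 2, 2), G), "outside")
  expect_error(dice_loss(G, G, epsilon = 0), "epsilon")
})

test_that("hard-pixel selection ranks by error with truncation", {
  # background errors are the probabilities themselves
  P <- matrix(c(0.9, 0.6, 0.1, 0.05, 0.2, 0.5, 0.95, 0.3), 2, 4)
  G <- matrix(c(0, 0, 0, 0, 1, 1, 1, 1), 2, 4)
  hs <- select_hard_pixels(P, G, K = 2)
  expect_equal(hs$background_probs, c(0.9, 0.6))
  expect_equal(hs$foreground_probs, c(0.2, 0.3))
  # foreground errors are 1 - P: the K smallest probabilities
  hs3 <- select_hard_pixels(P, G, K = 3)
  expect_equal(hs3$foreground_probs, c(0.2, 0.3, 0.5))
  # K larger than the region returns the whole region
  hsall <- select_hard_pixels(P, G, K = 10)
  expect_equal(length(hsall$background_probs), 4)
  expect_equal(length(hsall$foreground_probs), 4)
  # degenerate: all-background image yields one empty list
  hs0 <- select_hard_pixels(matrix(0.2, 2, 2), matrix(0, 2, 2), K = 2)
  expect_equal(length(hs0$foreground_probs), 0)
})

test_that("rank loss reproduces hand-computed pairings", {
  # bg hard probs [0.9, 0.6], fg hard probs [0.2, 0.5], margin 0.3:
  # (1/4)(1.0 + 0.7 + 0.7 + 0.4) = 0.7
  P <- matrix(c(0.9, 0.6, 0.1, 0.2, 0.5, 0.95), 1, 6)
  G <- matrix(c(0, 0, 0, 1, 1, 1), 1, 6)
  expect_equal(rank_loss(P, G, K = 2, margin = 0.3), 0.7, tolerance = 1e-12)
  # fully satisfied margin -> 0
  Pg <- matrix(c(0, 0, 1, 1), 1, 4)
  Gg <- matrix(c(0, 0, 1, 1), 1, 4)
  expect_identical(rank_loss(Pg, Gg, K = 2, margin = 0.3), 0)
  # no foreground pixels -> 0 by convention
  expect_identical(rank_loss(matrix(0.4, 3, 3), matrix(0, 3, 3), K = 5), 0)
})

test_that("rank loss agrees with a brute-force oracle on random inputs", {
  set.seed(42)
  for (i in 1:200) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    K <- sample(1:5, 1)
    margin <- runif(1, 0, 0.6)
    pm <- random_prob_mask(h, w)
    expect_equal(rank_loss(pm$P, pm$G, K, margin),
                 rank_loss_brute(pm$P, pm$G, K, margin),
                 tolerance = 1e-9)
  }
})

test_that("rank loss is monotone in the selected hard pixels and bounded", {
  set.seed(7)
  for (i in 1:25) {
    pm <- random_prob_mask(8, 8)
    K <- 4; margin <- 0.3
    base <- rank_loss(pm$P, pm$G, K, margin)
    expect_gte(base, 0)
    expect_lte(base, 1 + margin)
    hs <- select_hard_pixels(pm$P, pm$G, K)
    # raising a selected background probability never decreases the loss
    P2 <- pm$P
    idx <- hs$background_idx[1]
    P2[idx] <- min(1, P2[idx] + 0.05)
    expect_gte(rank_loss(P2, pm$G, K, margin) + 1e-12, base)
    # raising a selected foreground probability never increases it
    P3 <- pm$P
    idx <- hs$foreground_idx[1]
    P3[idx] <- min(1, P3[idx] + 0.05)
    expect_lte(rank_loss(P3, pm$G, K, margin) - 1e-9, base)
  }
})

test_that("margin satisfaction implies exactly zero rank loss", {
  set.seed(11)
  for (i in 1:20) {
    G <- matrix(rbinom(64, 1, 0.4), 8, 8)
    if (all(G == 0) || all(G == 1)) G[1:2] <- c(0, 1)
    P <- matrix(0, 8, 8)
    P[G == 0] <- runif(sum(G == 0), 0, 0.3)
    P[G == 1] <- runif(sum(G == 1), 0.7, 1)
    expect_identical(rank_loss(P, G, K = 5, margin = 0.3), 0)
  }
})

test_that("hybrid loss is affine in gamma with slope rank_loss", {
  set.seed(3)
  pm <- random_prob_mask(12, 12)
  d <- dice_loss(pm$P, pm$G)
  r <- rank_loss(pm$P, pm$G, 20, 0.3)
  expect_equal(hybrid_loss(pm$P, pm$G, hybrid_loss_params(gamma = 0)), d,
               tolerance = 1e-12)
  for (g in c(0.01, 0.02, 0.1))
    expect_equal(hybrid_loss(pm$P, pm$G, hybrid_loss_params(gamma = g)),
                 d + g * r, tolerance = 1e-12)
  # composed example: dice 0.5, rank 0.7, gamma 0.02 -> 0.514
  P <- matrix(0, 10, 10); G2 <- matrix(0, 10, 10)
  G2[1:5, 1:10] <- 1; P[3:7, 1:10] <- 1
  lp <- hybrid_loss_params(gamma = 0.02, K = 50, margin = 0.3, epsilon = 1e-12)
  manual <- dice_loss(P, G2, 1e-12) + 0.02 * rank_loss(P, G2, 50, 0.3)
  expect_equal(hybrid_loss(P, G2, lp), manual, tolerance = 1e-12)
})

test_that("hybrid loss parameter validation matches the documented domain", {
  expect_error(hybrid_loss_params(gamma = -0.1), "gamma")
  expect_error(hybrid_loss_params(K = 0), "K")
  expect_error(hybrid_loss_params(margin = 1), "margin")
  expect_error(hybrid_loss_params(epsilon = 0), "epsilon")
  p <- hybrid_loss_params()
  expect_equal(p$gamma, 0.02)
  expect_equal(p$K, 20L)
  expect_equal(p$margin, 0.3)
})

test_that("binary cross-entropy matches hand arithmetic", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(0.9999, 1), 1.1e-4)
  expect_equal(bce_loss(c(0.8, 0.3), c(1, 0)), (-log(0.8) - log(0.7)) / 2,
               tolerance = 1e-12)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(0, 0.5), c(0, 1)), "in \\(0, 1\\)")
})

test_that("analytic hybrid-loss gradient matches finite differences", {
  set.seed(5)
  pm <- random_prob_mask(6, 6)
  P <- pm$P * 0.8 + 0.1   # keep away from the [0,1] boundary
  lp <- hybrid_loss_params(gamma = 0.05, K = 3, margin = 0.3)
  gr <- nodulecascade:::hybrid_loss_grad(array(P, c(6, 6, 1, 1)),
                                         array(pm$G, c(6, 6, 1, 1)), lp)
  expect_equal(gr$loss, hybrid_loss(P, pm$G, lp), tolerance = 1e-12)
  eps <- 1e-6
  for (idx in sample(36, 8)) {
    Pp <- P; Pp[idx] <- Pp[idx] + eps
    Pm <- P; Pm[idx] <- Pm[idx] - eps
    num <- (hybrid_loss(Pp, pm$G, lp) - hybrid_loss(Pm, pm$G, lp)) / (2 * eps)
    expect_equal(gr$dP[idx], num, tolerance = 1e-4)
  }
})
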