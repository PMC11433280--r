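# Segmentation hybrid loss (Dice + online hard-pixel rank loss) and the
# classification cross-entropy, together with their analytic gradients used
# by the training loops.

# Canonicalise a probability map / mask to a list of per-image matrices:
# accepts [H, W], [H, W, N] or [H, W, 1, N].
as_image_list <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) return(list(as.matrix(x)))
  if (length(d) == 4) {
    if (d[3] != 1) stop("expected a single-channel map")
    dim(x) <- c(d[1], d[2], d[4])
    d <- dim(x)
  }
  lapply(seq_len(d[3]), function(n) x[, , n])
}

check_prob_mask <- function(P, G) {
  if (!identical(dim(as.array(P)), dim(as.array(G))))
    stop("probability map and mask shapes differ")
  if (any(P < 0 | P > 1)) stop("probability map has values outside [0, 1]")
  if (!all(G %in% c(0, 1))) stop("mask is not binary")
  invisible(TRUE)
}

#' Hybrid loss parameters
#'
#' Bundles the tunables of the segmentation hybrid loss: the rank-loss mix
#' weight `gamma`, the number `K` of hard pixels selected per region, the
#' rank-loss `margin`, and the Dice smoothing term `epsilon`. Defaults are
#' the reference operating point (gamma 0.02, K 20, margin 0.3).
#'
#' @param gamma rank-loss weight, >= 0.
#' @param K hard pixels per region, >= 1.
#' @param margin hinge margin in `[0, 1)`.
#' @param epsilon Dice smoothing, > 0.
#' @return an object of class `hybrid_loss_params`.
#' @export
hybrid_loss_params <- function(gamma = 0.02, K = 20L, margin = 0.3,
                               epsilon = 1e-6) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (K < 1) stop("K must be >= 1")
  if (margin < 0 || margin >= 1) stop("margin must be in [0, 1)")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(gamma = gamma, K = as.integer(K), margin = margin,
                 epsilon = epsilon),
            class = "hybrid_loss_params")
}

#' Dice loss
#'
#' `1 - 2 * sum(P * G) / (sum(P + G) + epsilon)`, computed per image and
#' averaged over the batch. Focuses optimisation on the (typically small)
#' foreground region.
#'
#' @param P probability map: `[H, W]`, `[H, W, N]` or `[H, W, 1, N]`, values
#'   in `[0, 1]`.
#' @param G binary ground-truth mask of the same shape.
#' @param epsilon smoothing term, > 0.
#' @return the loss, a scalar in `[0, 1)` for `epsilon > 0`.
#' @export
dice_loss <- function(P, G, epsilon = 1e-6) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  check_prob_mask(P, G)
  ps <- as_image_list(P)
  gs <- as_image_list(G)
  mean(mapply(function(p, g) 1 - 2 * sum(p * g) / (sum(p) + sum(g) + epsilon),
              ps, gs))
}

#' Select the hard pixels for the rank loss
#'
#' Pixels are ranked separately within background (`G = 0`) and foreground
#' (`G = 1`) by prediction error `|P - G|`: for the background that is the K
#' largest probabilities, for the foreground the K smallest. A region with
#' fewer than K pixels contributes all of them; ties are broken by pixel
#' scan order, so the selection is deterministic.
#'
#' @param P probability map (single image, matrix).
#' @param G binary mask, same shape.
#' @param K number of hard pixels per region.
#' @return a list with `background_probs` and `foreground_probs`, each sorted
#'   by descending error, and the corresponding linear `background_idx` /
#'   `foreground_idx`.
#' @export
select_hard_pixels <- function(P, G, K) {
  if (K < 1) stop("K must be >= 1")
  check_prob_mask(P, G)
  p <- as.numeric(P)
  g <- as.numeric(G)
  bg <- which(g == 0)
  fg <- which(g == 1)
  bg_sel <- bg[order(p[bg], decreasing = TRUE)][seq_len(min(K, length(bg)))]
  fg_sel <- fg[order(p[fg], decreasing = FALSE)][seq_len(min(K, length(fg)))]
  list(background_probs = p[bg_sel], foreground_probs = p[fg_sel],
       background_idx = bg_sel, foreground_idx = fg_sel)
}

# Rank loss for one image given its hard sets; returns loss and, optionally,
# the per-pixel gradient contributions.
rank_loss_single <- function(p, hard, margin, want_grad = FALSE, dP = NULL) {
  K0 <- length(hard$background_probs)
  K1 <- length(hard$foreground_probs)
  if (K0 == 0 || K1 == 0)
    return(list(loss = 0, dP = dP))
  viol <- outer(hard$background_probs, hard$foreground_probs,
                function(h0, h1) h0 - h1 + margin)
  act <- viol > 0
  loss <- sum(viol[act]) / (K0 * K1)
  if (want_grad) {
    w <- 1 / (K0 * K1)
    dbg <- rowSums(act) * w
    dfg <- -colSums(act) * w
    dP[hard$background_idx] <- dP[hard$background_idx] + dbg
    dP[hard$foreground_idx] <- dP[hard$foreground_idx] + dfg
  }
  list(loss = loss, dP = dP)
}

#' Online hard-pixel rank loss
#'
#' A pairwise hinge over the K highest-error background pixels and the K
#' highest-error foreground pixels (selected per image after the forward
#' pass): `mean over pairs of max(0, H0_i - H1_j + margin)`, normalised by
#' the actual numbers of selected pixels. It pushes every hard foreground
#' probability above every hard background probability by at least `margin`,
#' concentrating supervision on boundary pixels. Zero when an image has no
#' foreground or no background pixels. Batches are averaged per image.
#'
#' @inheritParams dice_loss
#' @param K hard pixels per region.
#' @param margin hinge margin in `[0, 1)`.
#' @return the loss, a scalar in `[0, 1 + margin]`.
#' @export
rank_loss <- function(P, G, K = 20L, margin = 0.3) {
  if (K < 1) stop("K must be >= 1")
  if (margin < 0 || margin >= 1) stop("margin must be in [0, 1)")
  check_prob_mask(P, G)
  ps <- as_image_list(P)
  gs <- as_image_list(G)
  mean(mapply(function(p, g) {
    hard <- select_hard_pixels(p, g, K)
    rank_loss_single(p, hard, margin)$loss
  }, ps, gs))
}

#' Hybrid segmentation loss
#'
#' `dice_loss + gamma * rank_loss`; with `gamma = 0` it reduces exactly to
#' the Dice loss.
#'
#' @inheritParams dice_loss
#' @param params a [hybrid_loss_params()].
#' @return the scalar loss.
#' @export
hybrid_loss <- function(P, G, params = hybrid_loss_params()) {
  stopifnot(inherits(params, "hybrid_loss_params"))
  dice_loss(P, G, params$epsilon) +
    params$gamma * rank_loss(P, G, params$K, params$margin)
}

# Hybrid loss together with its gradient with respect to P (batch mean).
# Hard-pixel selection carries no gradient; gradients flow only through the
# selected probability values.
hybrid_loss_grad <- function(P, G, params) {
  ps <- as_image_list(P)
  gs <- as_image_list(G)
  n <- length(ps)
  eps <- params$epsilon
  dice <- 0
  rank <- 0
  dlist <- vector("list", n)
  for (i in seq_len(n)) {
    p <- ps[[i]]; g <- gs[[i]]
    S <- sum(p * g)
    D <- sum(p) + sum(g) + eps
    dice <- dice + (1 - 2 * S / D)
    dP <- (-2 * g / D + 2 * S / D^2)
    if (params$gamma > 0) {
      hard <- select_hard_pixels(p, g, params$K)
      rp <- rank_loss_single(p, hard, params$margin, want_grad = TRUE,
                             dP = matrix(0, nrow(p), ncol(p)))
      rank <- rank + rp$loss
      dP <- dP + params$gamma * rp$dP
    }
    dlist[[i]] <- dP / n
  }
  dPfull <- array(unlist(dlist), c(nrow(ps[[1]]), ncol(ps[[1]]), 1L, n))
  list(loss = dice / n + params$gamma * rank / n,
       dice = dice / n, rank = rank / n, dP = dPfull)
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y * log(s) + (1 - y) * log(1 - s))` over the batch; the
#' classification network's training loss.
#'
#' @param scores predicted probabilities in `(0, 1)`.
#' @param labels 0/1 labels of the same length.
#' @return the scalar loss.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) == 0) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (any(scores <= 0 | scores >= 1)) stop("scores must be in (0, 1)")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
}

# BCE gradient with respect to the scores (batch mean), clamped away from
# the asymptotes for numerical safety behind a sigmoid.
bce_loss_grad <- function(scores, labels) {
  s <- pmin(pmax(scores, 1e-7), 1 - 1e-7)
  loss <- -mean(labels * log(s) + (1 - labels) * log(1 - s))
  list(loss = loss, dscores = (s - labels) / (s * (1 - s)) / length(s))
}
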