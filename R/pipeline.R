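# Staged cascade orchestration: train the coarse segmentation network,
# precompute its probability maps, then train the fine segmentation network
# and the classifier with mask guidance; evaluation and class-activation
# maps. The coarse network is trained once and frozen; its masks are
# precomputed, so guidance is prediction distillation, not gradient sharing.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size_seg,batch_size_class mini-batch sizes for the
#'   segmentation and classification networks.
#' @param max_epochs maximum number of epochs.
#' @param loss a [hybrid_loss_params()] for the segmentation loss.
#' @param seed RNG seed controlling initialisation and batch shuffling.
#' @param device only `"cpu"` is supported by the built-in engine.
#' @param augment_online on-the-fly training augmentation: `"none"`,
#'   `"flips"` (random horizontal/vertical flips) or `"full"` (per image, a
#'   uniformly drawn transform among identity, centre-crop at a random
#'   fraction in 0.5--1.0 resized back, equal-ratio 110% zoom, horizontal
#'   flip, vertical flip — the same transform families as the offline
#'   augmentation, applied identically to image, mask and guidance channel).
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size_seg = 16L, batch_size_class = 32L,
                         max_epochs = 100L, loss = hybrid_loss_params(),
                         seed = 1L, device = "cpu",
                         augment_online = c("none", "flips", "full")) {
  if (lr <= 0) stop("lr must be > 0")
  if (batch_size_seg < 1 || batch_size_class < 1) stop("batch sizes must be >= 1")
  device <- match.arg(device, "cpu")
  augment_online <- match.arg(augment_online)
  structure(list(lr = lr, batch_size_seg = as.integer(batch_size_seg),
                 batch_size_class = as.integer(batch_size_class),
                 max_epochs = as.integer(max_epochs), loss = loss,
                 seed = as.integer(seed), device = device,
                 augment_online = augment_online),
            class = "train_config")
}

# On-the-fly augmentation of a batch: the same geometric transform is drawn
# per image and applied to every tensor in `tensors` ([H, W, C, N] each).
# Tensors listed in `nearest` (logical vector) are resampled by nearest
# neighbour (binary masks); the rest bilinearly.
augment_batch <- function(tensors, nearest, mode) {
  if (mode == "none") return(tensors)
  d <- dim(tensors[[1]])
  H <- d[1]; W <- d[2]; n <- d[4]
  fams <- if (mode == "flips") c("none", "hflip", "vflip")
    else c("none", "crop", "zoom", "hflip", "vflip")
  fam <- sample(fams, n, replace = TRUE)
  frac <- runif(n, 0.5, 1.0)
  resize_plane <- function(p, oh, ow, nn) {
    if (nn) resize_nearest(p, oh, ow) else resize_bilinear_img(p, oh, ow)
  }
  for (i in seq_len(n)) {
    f <- fam[i]
    if (f == "none") next
    for (k in seq_along(tensors)) {
      C <- dim(tensors[[k]])[3]
      for (c in seq_len(C)) {
        p <- tensors[[k]][, , c, i]
        p <- switch(f,
          hflip = p[, W:1],
          vflip = p[H:1, ],
          crop = {
            h <- max(2L, round(H * frac[i])); w <- max(2L, round(W * frac[i]))
            r0 <- (H - h) %/% 2; c0 <- (W - w) %/% 2
            resize_plane(p[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)], H, W, nearest[k])
          },
          zoom = {
            zh <- round(H * 1.10); zw <- round(W * 1.10)
            z <- resize_plane(p, zh, zw, nearest[k])
            r0 <- (zh - H) %/% 2; c0 <- (zw - W) %/% 2
            z[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W)]
          })
        tensors[[k]][, , c, i] <- p
      }
    }
  }
  tensors
}

#' Desk-scale build and training profile
#'
#' The configuration used throughout the package's own experiments on
#' synthetic 64x64 patches: width multiplier 0.125, two middle-flow blocks,
#' learning rate 1e-3 and short schedules, sized so the whole cascade trains
#' on a single CPU in minutes. The full-size profile (width 1, 16/8 middle
#' blocks, lr 1e-4, 100 epochs) is what [backbone_spec()], [classnet_spec()]
#' and [train_config()] give by default.
#'
#' @param seed RNG seed used for all stages.
#' @param seg_epochs,class_epochs epochs for the segmentation and
#'   classification stages.
#' @return a list with `backbone`, `classnet`, `classnet_unguided`,
#'   `seg_config`, `class_config`.
#' @export
desk_profile <- function(seed = 1L, seg_epochs = 8L, class_epochs = 10L) {
  list(backbone = backbone_spec(width_multiplier = 0.125, middle_repeats = 1L),
       classnet = classnet_spec(input_channels = 4L, width_multiplier = 0.125,
                                middle_repeats = 1L),
       classnet_unguided = classnet_spec(input_channels = 3L,
                                         width_multiplier = 0.125,
                                         middle_repeats = 1L),
       seg_config = train_config(lr = 2e-3, max_epochs = seg_epochs, seed = seed,
                                 augment_online = "flips"),
       class_config = train_config(lr = 4e-3, batch_size_class = 4L,
                                   max_epochs = class_epochs, seed = seed,
                                   augment_online = "flips"))
}

split_rows <- function(manifest, split) {
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0) stop("empty ", split, " split")
  rows
}

load_guidance <- function(rows, hw) {
  g <- array(0, c(hw[1], hw[2], 1L, nrow(rows)))
  for (i in seq_len(nrow(rows))) {
    mk <- png::readPNG(rows$coarse_mask_path[i])
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    g[, , 1, i] <- mk
  }
  g
}

# Shared mini-batch loop for both segmentation networks. `guid` arrays are
# NULL for the coarse network. Model selection: best validation Jaccard.
train_segnet_loop <- function(net, xtr, gtr, mtr, xva, gva, mva, config) {
  n <- dim(xtr)[4]
  bs <- config$batch_size_seg
  opt <- adam_state()
  params <- module_params(net)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_dice_loss = numeric(), val_ja = numeric())
  best <- list(ja = -Inf, params = NULL, state = NULL)
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot <- 0
    nb <- 0
    for (b in split(ord, ceiling(seq_along(ord) / bs))) {
      zero_grads(params)
      xb <- xtr[, , , b, drop = FALSE]
      gb <- gtr[, , , b, drop = FALSE]
      mb <- if (is.null(mtr)) NULL else mtr[, , , b, drop = FALSE]
      if (config$augment_online != "none") {
        fl <- augment_batch(c(list(xb, gb), if (!is.null(mb)) list(mb)),
                            nearest = c(FALSE, TRUE, FALSE),
                            mode = config$augment_online)
        xb <- fl[[1]]; gb <- fl[[2]]
        if (!is.null(mb)) mb <- fl[[3]]
      }
      P <- if (is.null(mb)) net$fwd(xb, training = TRUE)
        else net$fwd(xb, mb, training = TRUE)
      lg <- hybrid_loss_grad(P, gb, config$loss)
      net$bwd(lg$dP)
      adam_step(params, opt, config$lr)
      tot <- tot + lg$loss
      nb <- nb + 1
    }
    Pv <- predict_probmap(net, xva, guidance = mva)
    vd <- dice_loss(Pv, gva, config$loss$epsilon)
    vja <- segmentation_metrics(binarize(Pv), gva)
    vja <- if (is.null(vja$mean)) vja$ja else vja$mean$ja
    log <- rbind(log, data.frame(epoch = ep, train_loss = tot / nb,
                                 val_dice_loss = vd, val_ja = vja))
    if (vja > best$ja)
      best <- list(ja = vja, params = param_values(net), state = module_state(net))
  }
  set_param_values(net, best$params)
  set_module_state(net, best$state)
  list(net = net, log = log, best_val_ja = best$ja)
}

#' Run a segmentation network in inference mode
#'
#' @param net a segmentation network.
#' @param x `[H, W, C, N]` image array.
#' @param guidance `[H, W, 1, N]` coarse probability maps (fine network
#'   only; `NULL` for the coarse network).
#' @param batch inference batch size.
#' @return an `[H, W, 1, N]` probability map array.
#' @export
predict_probmap <- function(net, x, guidance = NULL, batch = 32L) {
  n <- dim(x)[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], 1L, n))
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    out[, , 1, b] <- if (is.null(guidance))
      net$fwd(x[, , , b, drop = FALSE], training = FALSE)
    else net$fwd(x[, , , b, drop = FALSE], guidance[, , , b, drop = FALSE],
                 training = FALSE)
  }
  out
}

#' Train the coarse segmentation network
#'
#' Optimises the hybrid Dice + rank loss with Adam on the train split and
#' keeps the checkpoint with the best validation Jaccard index.
#'
#' @param manifest dataset manifest with `train` and `val` splits and mask
#'   paths.
#' @param config a [train_config()].
#' @param spec a [backbone_spec()].
#' @param out_path optional checkpoint file to write.
#' @return a list with `net`, `log` (per-epoch losses), `best_val_ja`.
#' @export
train_coarse <- function(manifest, config = train_config(),
                         spec = backbone_spec(), out_path = NULL) {
  tr <- load_batch_tensors(split_rows(manifest, "train"))
  va <- load_batch_tensors(split_rows(manifest, "val"))
  set.seed(config$seed)
  net <- build_coarse_segnet(spec)
  res <- train_segnet_loop(net, tr$x, tr$g, NULL, va$x, va$g, NULL, config)
  if (!is.null(out_path))
    save_checkpoint(res$net, list(backbone = spec, role = "coarse"), out_path,
                    meta = list(log = res$log))
  res
}

#' Precompute coarse probability maps for a manifest
#'
#' Runs the frozen coarse network over every manifest row and writes each
#' probability map as an 8-bit grayscale PNG next to a new
#' `coarse_mask_path` manifest column.
#'
#' @param net trained coarse network (or checkpoint path).
#' @param manifest dataset manifest.
#' @param out_dir directory for the mask PNGs.
#' @return the manifest with a `coarse_mask_path` column.
#' @export
precompute_masks <- function(net, manifest, out_dir) {
  if (is.character(net)) {
    ck <- load_checkpoint(net)
    net <- restore_network(build_coarse_segnet(ck$spec$backbone), ck)
  }
  missing <- !file.exists(manifest$image_path)
  if (any(missing))
    stop("missing images:\n", paste(manifest$image_path[missing], collapse = "\n"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  xs <- load_batch_tensors(manifest)
  P <- predict_probmap(net, xs$x)
  paths <- file.path(out_dir, paste0(manifest$source_id, "_",
                                     seq_len(nrow(manifest)), "_coarse.png"))
  for (i in seq_len(nrow(manifest)))
    png::writePNG(P[, , 1, i], paths[i])
  manifest$coarse_mask_path <- paths
  manifest
}

#' Train the fine segmentation network
#'
#' The fine network is initialised from the coarse network's parameters,
#' receives the precomputed coarse probability map through its fusion layer,
#' and is optimised with the hybrid loss; the best-validation-Jaccard
#' checkpoint is kept. With `use_guidance = FALSE` the guidance channel is
#' all zeros (no prior location information), the unguided ablation arm.
#'
#' @param manifest manifest with `coarse_mask_path` (see
#'   [precompute_masks()]).
#' @param coarse the trained coarse network.
#' @param config a [train_config()].
#' @param spec the [backbone_spec()] shared with the coarse network.
#' @param use_guidance feed the coarse maps (TRUE) or zeros (FALSE).
#' @param out_path optional checkpoint file.
#' @return a list with `net`, `log`, `best_val_ja`.
#' @export
train_fine <- function(manifest, coarse, config = train_config(),
                       spec = backbone_spec(), use_guidance = TRUE,
                       out_path = NULL) {
  if (use_guidance && is.null(manifest$coarse_mask_path))
    stop("manifest has no coarse_mask_path; run precompute_masks first")
  trr <- split_rows(manifest, "train")
  var <- split_rows(manifest, "val")
  tr <- load_batch_tensors(trr)
  va <- load_batch_tensors(var)
  hw <- dim(tr$x)[1:2]
  mtr <- if (use_guidance) load_guidance(trr, hw) else array(0, c(hw, 1L, dim(tr$x)[4]))
  mva <- if (use_guidance) load_guidance(var, hw) else array(0, c(hw, 1L, dim(va$x)[4]))
  set.seed(config$seed)
  net <- build_fine_segnet(spec, coarse)
  res <- train_segnet_loop(net, tr$x, tr$g, mtr, va$x, va$g, mva, config)
  if (!is.null(out_path))
    save_checkpoint(res$net, list(backbone = spec, role = "fine"), out_path,
                    meta = list(log = res$log))
  res
}

# Assemble classifier input: image plus (optionally) the guidance channel.
class_input <- function(rows, use_mask, binarize_guidance = FALSE) {
  td <- load_batch_tensors(rows)
  if (!use_mask) return(list(x = td$x, labels = td$labels))
  hw <- dim(td$x)[1:2]
  g <- load_guidance(rows, hw)
  if (binarize_guidance) g <- binarize(g)
  x <- array(0, c(hw[1], hw[2], 4L, dim(td$x)[4]))
  x[, , 1:3, ] <- td$x
  x[, , 4, ] <- g[, , 1, ]
  list(x = x, labels = td$labels)
}

#' Train the classification network
#'
#' Binary cross-entropy optimisation of the Xception-style classifier. With
#' `use_mask = TRUE` the coarse probability map is concatenated as a fourth
#' input channel whose first-layer kernels are initialised as the mean of
#' the three RGB kernels; with `use_mask = FALSE` a plain 3-channel
#' classifier is trained (the unguided ablation arm). The
#' best-validation-accuracy checkpoint is kept.
#'
#' @param manifest manifest with labels (and `coarse_mask_path` when
#'   `use_mask`).
#' @param config a [train_config()].
#' @param spec a [classnet_spec()]; its `input_channels` must agree with
#'   `use_mask`.
#' @param use_mask concatenate the coarse probability map as channel 4.
#' @param binarize_guidance threshold the guidance channel at 0.5 before
#'   concatenation (by default the raw probability map is passed through,
#'   preserving the coarse network's uncertainty).
#' @param out_path optional checkpoint file.
#' @return a list with `net`, `log`, `best_val_acc`.
#' @export
train_class <- function(manifest, config = train_config(),
                        spec = classnet_spec(), use_mask = TRUE,
                        binarize_guidance = FALSE, out_path = NULL) {
  if (spec$input_channels != (if (use_mask) 4L else 3L))
    stop("spec$input_channels disagrees with use_mask")
  if (use_mask && is.null(manifest$coarse_mask_path))
    stop("manifest has no coarse_mask_path; run precompute_masks first")
  trr <- split_rows(manifest, "train")
  var <- split_rows(manifest, "val")
  tr <- class_input(trr, use_mask, binarize_guidance)
  va <- class_input(var, use_mask, binarize_guidance)
  if (length(unique(tr$labels)) < 2) stop("single-class training split")
  set.seed(config$seed)
  net <- build_classnet(spec)
  if (use_mask) {
    w <- net$children$stem$children$l01$params$w$value
    net$children$stem$children$l01$params$w$value <-
      init_fourth_channel(w[, , 1:3, , drop = FALSE])
  }
  n <- dim(tr$x)[4]
  bs <- config$batch_size_class
  opt <- adam_state()
  params <- module_params(net)
  log <- data.frame(epoch = integer(), train_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, params = NULL, state = NULL)
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (b in split(ord, ceiling(seq_along(ord) / bs))) {
      zero_grads(params)
      xb <- tr$x[, , , b, drop = FALSE]
      if (config$augment_online != "none")
        xb <- augment_batch(list(xb), nearest = FALSE,
                            mode = config$augment_online)[[1]]
      s <- net$fwd(xb, training = TRUE)
      lg <- bce_loss_grad(s, tr$labels[b])
      net$bwd(lg$dscores)
      adam_step(params, opt, config$lr)
      tot <- tot + lg$loss
      nb <- nb + 1
    }
    sv <- predict_class(net, va$x)
    vacc <- mean((sv >= 0.5) == (va$labels == 1))
    log <- rbind(log, data.frame(epoch = ep, train_loss = tot / nb, val_acc = vacc))
    if (vacc > best$acc)
      best <- list(acc = vacc, params = param_values(net), state = module_state(net))
  }
  set_param_values(net, best$params)
  set_module_state(net, best$state)
  if (!is.null(out_path))
    save_checkpoint(net, list(classnet = spec), out_path, meta = list(log = log))
  list(net = net, log = log, best_val_acc = best$acc)
}

#' Run the classifier in inference mode
#'
#' @param net a classification network.
#' @param x `[H, W, C, N]` input array (4th channel = coarse map when the
#'   network is mask-guided).
#' @param batch inference batch size.
#' @return a length-`N` vector of malignancy probabilities.
#' @export
predict_class <- function(net, x, batch = 32L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch)))
    out[b] <- net$fwd(x[, , , b, drop = FALSE], training = FALSE)
  out
}

#' Run the full cascade on a batch of images
#'
#' Coarse probability map, guidance-fused fine probability map, and
#' mask-guided malignancy probability, in one deterministic inference call.
#'
#' @param images `[H, W, 3, N]` image array.
#' @param nets `list(coarse = , fine = , class = )` trained networks.
#' @param binarize_guidance threshold the classifier's guidance channel at
#'   0.5 (must match how the classifier was trained).
#' @return `list(coarse, fine, prob)`: two `[H, W, 1, N]` maps and a
#'   length-`N` probability vector, order-preserving.
#' @export
cascade_predict <- function(images, nets, binarize_guidance = FALSE) {
  stopifnot(all(c("coarse", "fine", "class") %in% names(nets)))
  coarse <- predict_probmap(nets$coarse, images)
  fine <- predict_probmap(nets$fine, images, guidance = coarse)
  d <- dim(images)
  x4 <- array(0, c(d[1], d[2], 4L, d[4]))
  x4[, , 1:3, ] <- images
  x4[, , 4, ] <- if (binarize_guidance) binarize(coarse[, , 1, ]) else coarse[, , 1, ]
  prob <- predict_class(nets$class, x4)
  list(coarse = coarse, fine = fine, prob = prob)
}

#' Evaluate the cascade on the test split
#'
#' Fine probability maps are binarized at 0.5 and scored with
#' [segmentation_metrics()] per image (then averaged); class scores are
#' thresholded at 0.5 for [classification_metrics()] and ranked for
#' [roc_auc()].
#'
#' @param manifest manifest with a `test` split.
#' @param nets `list(coarse, fine, class)` trained networks.
#' @param binarize_guidance threshold the classifier's guidance channel at
#'   0.5 (must match how the classifier was trained).
#' @param out_json optional path for the JSON report.
#' @return an evaluation report: `seg` (per-image data.frame + mean), `cls`
#'   (`acc`, `sen`, `spe`, `auc`), `n_items`, `config_fingerprint`.
#' @export
evaluate_cascade <- function(manifest, nets, binarize_guidance = FALSE,
                             out_json = NULL) {
  rows <- split_rows(manifest, "test")
  td <- load_batch_tensors(rows)
  pr <- cascade_predict(td$x, nets, binarize_guidance)
  seg <- segmentation_metrics(binarize(pr$fine), td$g)
  cls <- classification_metrics(count_confusion(pr$prob, td$labels))
  cls$auc <- roc_auc(pr$prob, td$labels)
  report <- list(seg = seg, cls = cls, n_items = nrow(rows),
                 config_fingerprint = sprintf("segnet:%s/classnet:%s",
                                              nets$coarse$spec$width_multiplier,
                                              nets$class$spec$width_multiplier))
  if (!is.null(out_json))
    write_metrics_json(list(seg = seg$mean, cls = cls, n_items = report$n_items),
                       out_json)
  report
}

#' Class activation map of the classifier
#'
#' Gradient-weighted activation map over the last convolutional features:
#' with a global-average-pool + single-logit head the gradient of the logit
#' with respect to each feature channel is constant over space, so the map
#' is the ReLU of the head-weighted feature sum. The map is min--max
#' normalised to `[0, 1]` per image (flat maps become all zeros, never NaN)
#' and bilinearly upsampled to the input size.
#'
#' @param net a trained classification network.
#' @param x `[H, W, C, N]` classifier input.
#' @param overlay_path optional PNG path (first image only): the heatmap is
#'   written as an RGB overlay on the input's first channel.
#' @return an `[H, W, N]` array of heatmaps in `[0, 1]`.
#' @export
compute_cam <- function(net, x, overlay_path = NULL) {
  d <- dim(x)
  net$fwd(x, training = FALSE, keep_features = TRUE)
  feat <- net$features
  net$features <- NULL
  w <- as.numeric(net$children$fc$params$w$value)
  fd <- dim(feat)
  cam <- array(0, c(fd[1], fd[2], 1L, fd[4]))
  for (n in seq_len(fd[4]))
    for (c in seq_len(fd[3]))
      cam[, , 1, n] <- cam[, , 1, n] + w[c] * feat[, , c, n]
  cam <- pmax(cam, 0)
  dim(cam) <- c(fd[1], fd[2], 1L, fd[4])
  up <- resize_bilinear_fwd_cpp(cam, d[1], d[2])
  out <- array(0, c(d[1], d[2], fd[4]))
  for (n in seq_len(fd[4])) {
    h <- up[, , 1, n]
    rng <- range(h)
    out[, , n] <- if (rng[2] > rng[1]) (h - rng[1]) / (rng[2] - rng[1]) else h * 0
  }
  if (!is.null(overlay_path)) {
    base <- x[, , 1, 1]
    rgb <- array(0, c(d[1], d[2], 3L))
    rgb[, , 1] <- pmin(1, base + 0.5 * out[, , 1])
    rgb[, , 2] <- base * (1 - 0.5 * out[, , 1])
    rgb[, , 3] <- base * (1 - 0.5 * out[, , 1])
    png::writePNG(rgb, overlay_path)
  }
  out
}

#' Run the complete desk-scale cascade experiment
#'
#' Generates a synthetic dataset, splits it, trains the coarse network,
#' precomputes its probability maps, trains the fine network and the
#' mask-guided classifier, and evaluates on the held-out test split.
#' Optionally also trains the two unguided ablation arms (fine network with
#' a zero guidance channel; 3-channel classifier) for the paired
#' guided-versus-unguided comparison.
#'
#' @param seed seed for generation, initialisation and shuffling.
#' @param dir working directory (a tempdir subdirectory by default).
#' @param n_per_class synthetic samples per class.
#' @param ratios train : val : test ratio (default 4:1:1, i.e. 200/50/50
#'   sources at the default `n_per_class`).
#' @param profile a [desk_profile()].
#' @param ablation also run the unguided classification arm (3-channel
#'   classifier, no coarse-mask input); the segmentation ablation contrast
#'   (coarse-only versus guidance-fused fine output) is always reported as
#'   `seg_coarse` versus `seg`.
#' @param unguided_fine additionally train a fine network with an all-zero
#'   guidance channel and report it as `seg_unguided`.
#' @param binarize_guidance threshold the classifier's guidance channel at
#'   0.5 (the desk-scale default: at 64x64 the raw probability map blurs the
#'   thin-spike boundary signal that separates the classes).
#' @param keep_nets return the trained networks.
#' @return a list with `seg` and `cls` test metrics, the training logs, and
#'   (with `ablation`) `cls_unguided`.
#' @export
run_cascade_experiment <- function(seed = 1L,
                                   dir = file.path(tempdir(), paste0("cascade_", seed)),
                                   n_per_class = 150L,
                                   ratios = c(4, 1, 1),
                                   profile = desk_profile(seed = seed),
                                   ablation = TRUE,
                                   unguided_fine = FALSE,
                                   binarize_guidance = TRUE,
                                   keep_nets = FALSE) {
  cfg <- synth_config(n_per_class = n_per_class, seed = seed)
  manifest <- generate_dataset(cfg, dir)
  manifest <- split_manifest(manifest, ratios = ratios, seed = seed)
  co <- train_coarse(manifest, profile$seg_config, profile$backbone)
  manifest <- precompute_masks(co$net, manifest, file.path(dir, "coarse"))
  fi <- train_fine(manifest, co$net, profile$seg_config, profile$backbone)
  cl <- train_class(manifest, profile$class_config, profile$classnet,
                    binarize_guidance = binarize_guidance)
  nets <- list(coarse = co$net, fine = fi$net, class = cl$net)
  ev <- evaluate_cascade(manifest, nets, binarize_guidance)
  out <- list(seg = ev$seg$mean, cls = ev$cls, n_test = ev$n_items,
              coarse_log = co$log, fine_log = fi$log, class_log = cl$log)
  # coarse-only segmentation quality on the test split, for reference
  te <- load_batch_tensors(split_rows(manifest, "test"))
  Pc <- predict_probmap(co$net, te$x)
  out$seg_coarse <- segmentation_metrics(binarize(Pc), te$g)$mean
  if (unguided_fine) {
    fu <- train_fine(manifest, co$net, profile$seg_config, profile$backbone,
                     use_guidance = FALSE)
    Pu <- predict_probmap(fu$net, te$x,
                          guidance = array(0, c(dim(te$x)[1:2], 1L, dim(te$x)[4])))
    out$seg_unguided <- segmentation_metrics(binarize(Pu), te$g)$mean
  }
  if (ablation) {
    cu <- train_class(manifest, profile$class_config, profile$classnet_unguided,
                      use_mask = FALSE)
    su <- predict_class(cu$net, te$x)
    cmu <- classification_metrics(count_confusion(su, te$labels))
    cmu$auc <- roc_auc(su, te$labels)
    out$cls_unguided <- cmu
  }
  if (keep_nets) out$nets <- nets
  out
}
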