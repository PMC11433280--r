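# Independent oracles and small fixture builders shared across tests.

# Brute-force rank loss: full sort of each region, explicit double loop over
# all pairs. Kept deliberately independent of the package implementation.
rank_loss_brute <- function(P, G, K, margin) {
  p <- as.numeric(P)
  g <- as.numeric(G)
  bg <- sort(p[g == 0], decreasing = TRUE)
  bg <- bg[seq_len(min(K, length(bg)))]
  fg <- sort(p[g == 1], decreasing = FALSE)
  fg <- fg[seq_len(min(K, length(fg)))]
  if (length(bg) == 0 || length(fg) == 0) return(0)
  s <- 0
  for (a in bg) for (b in fg) s <- s + max(0, a - b + margin)
  s / (length(bg) * length(fg))
}

# Per-pixel confusion counts of two binary masks.
confusion_oracle <- function(S, GT) {
  list(tp = sum(S == 1 & GT == 1), fp = sum(S == 1 & GT == 0),
       tn = sum(S == 0 & GT == 0), fn = sum(S == 0 & GT == 1))
}

# Random probability map / mask pair on an h x w grid with at least one
# pixel of each region (unless force_* says otherwise).
random_prob_mask <- function(h, w, p_fg = 0.3) {
  P <- matrix(runif(h * w), h, w)
  G <- matrix(rbinom(h * w, 1, p_fg), h, w)
  if (all(G == 1)) G[1] <- 0
  if (all(G == 0)) G[1] <- 1
  list(P = P, G = G)
}

# A small disk mask for geometric fixtures.
disk_mask <- function(size, cx, cy, r) {
  g <- expand.grid(i = seq_len(size), j = seq_len(size))
  m <- matrix(as.numeric((g$i - cx)^2 + (g$j - cy)^2 <= r^2), size, size)
  m
}

# Tiny desk specs used across architecture/pipeline tests.
tiny_backbone <- function(input_channels = 3L)
  backbone_spec(width_multiplier = 0.125, middle_repeats = 1L,
                input_channels = input_channels)

tiny_classnet <- function(input_channels = 4L, dilated_exit = TRUE)
  classnet_spec(input_channels = input_channels, dilated_exit = dilated_exit,
                width_multiplier = 0.125, middle_repeats = 1L)

# A small synthetic dataset on disk for pipeline tests (32x32 patches keep
# the training loops fast).
tiny_dataset <- function(seed = 7L, n_per_class = 12L, image_size = 32L) {
  dir <- file.path(tempdir(), sprintf("tinyds_%d_%d", seed, n_per_class))
  cfg <- synth_config(n_per_class = n_per_class, image_size = image_size,
                      benign_radius_px = c(5, 9), malignant_radius_px = c(5, 9),
                      seed = seed)
  manifest <- generate_dataset(cfg, dir)
  split_manifest(manifest, ratios = c(4, 1, 1), seed = seed)
}

tiny_train_config <- function(seed = 7L, epochs = 2L)
  train_config(lr = 2e-3, max_epochs = epochs, seed = seed,
               augment_online = "flips")
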