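# Synthetic CT-like patch generator: bright blobs on a noisy background,
# smooth ellipses for the benign class and spiculated (star-shaped) regions
# for the malignant class, with paired exact masks. Intensity ranges of the
# two classes are identical, so class is carried by boundary shape alone.

#' Synthetic dataset configuration
#'
#' @param n_per_class samples per class.
#' @param image_size patch side length in pixels.
#' @param background_noise_sd standard deviation of the Gaussian background
#'   noise (image intensities live in `[0, 1]`).
#' @param background_level mean background intensity.
#' @param blob_intensity_range range of the nodule intensity, shared by both
#'   classes so brightness alone cannot solve the classification task.
#' @param benign_radius_px,malignant_radius_px base-radius ranges in pixels.
#' @param spiculation_amplitude radial perturbation fraction of the
#'   malignant boundary, in `[0, 1)`.
#' @param spiculation_lobes number of spikes of the malignant boundary.
#' @param blur_sd Gaussian blur of the nodule boundary in pixels (boundary
#'   fuzziness).
#' @param seed RNG seed for [generate_dataset()].
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 150L, image_size = 64L,
                         background_noise_sd = 0.20,
                         background_level = 0.20,
                         blob_intensity_range = c(0.35, 0.75),
                         benign_radius_px = c(8, 16),
                         malignant_radius_px = c(8, 16),
                         spiculation_amplitude = 0.7,
                         spiculation_lobes = 5L,
                         blur_sd = 1.0, seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (max(benign_radius_px, malignant_radius_px) >= image_size / 2)
    stop("radii must be smaller than image_size / 2")
  if (spiculation_amplitude < 0 || spiculation_amplitude >= 1)
    stop("spiculation_amplitude must be in [0, 1)")
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 background_noise_sd = background_noise_sd,
                 background_level = background_level,
                 blob_intensity_range = blob_intensity_range,
                 benign_radius_px = benign_radius_px,
                 malignant_radius_px = malignant_radius_px,
                 spiculation_amplitude = spiculation_amplitude,
                 spiculation_lobes = as.integer(spiculation_lobes),
                 blur_sd = blur_sd, seed = as.integer(seed)),
            class = "synth_config")
}

gaussian_blur <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- ceiling(3 * sd)
  ax <- -r:r
  k1 <- exp(-ax^2 / (2 * sd^2))
  k <- outer(k1, k1)
  k <- k / sum(k)
  x <- m
  dim(x) <- c(dim(m), 1L, 1L)
  w <- k
  dim(w) <- c(2L * r + 1L, 2L * r + 1L, 1L, 1L)
  y <- conv2d_fwd_cpp(x, w, numeric(0), 1L, r, 1L, 1L)
  dim(y) <- dim(m)
  y
}

#' Draw one synthetic patch
#'
#' Benign samples are ellipses with small eccentricity; malignant samples
#' are star-shaped regions `r(theta) = r0 * (1 + a * max(0, sin(m * theta +
#' phi)))` with `a = spiculation_amplitude` and `m = spiculation_lobes`. The
#' mask is the exact generating region; the image is the mask times a drawn
#' intensity, Gaussian-blurred, plus Gaussian background noise, replicated
#' to three channels and clipped to `[0, 1]`. Uses the session RNG: seed
#' beforehand for reproducibility.
#'
#' @param config a [synth_config()].
#' @param class_label `"benign"` or `"malignant"`.
#' @return `list(image = [H, W, 3], mask = [H, W], label = class_label)`.
#' @export
make_sample <- function(config, class_label = c("benign", "malignant")) {
  stopifnot(inherits(config, "synth_config"))
  class_label <- match.arg(class_label)
  S <- config$image_size
  ctr <- (S + 1) / 2 + runif(2, -S / 10, S / 10)
  rng_r <- if (class_label == "benign") config$benign_radius_px else config$malignant_radius_px
  r0 <- runif(1, rng_r[1], rng_r[2])
  phi <- runif(1, 0, 2 * pi)
  rows <- matrix(seq_len(S) - ctr[1], S, S)
  cols <- matrix(seq_len(S) - ctr[2], S, S, byrow = TRUE)
  rr <- sqrt(rows^2 + cols^2)
  th <- atan2(cols, rows)
  if (class_label == "benign") {
    ecc <- runif(1, 0, 0.15)
    rb <- r0 * (1 + ecc * cos(2 * (th - phi)))
  } else {
    a <- config$spiculation_amplitude
    m <- config$spiculation_lobes
    rb <- r0 * (1 + a * pmax(0, sin(m * th + phi)))
  }
  mask <- (rr <= rb) * 1
  intensity <- runif(1, config$blob_intensity_range[1], config$blob_intensity_range[2])
  img <- gaussian_blur(mask * intensity, config$blur_sd) +
    matrix(rnorm(S * S, config$background_level, config$background_noise_sd), S, S)
  img <- pmin(pmax(img, 0), 1)
  image <- array(img, c(S, S, 3L))
  list(image = image, mask = mask, label = class_label)
}

#' Digital compactness of a binary mask
#'
#' `4 * pi * area / perimeter^2`, with the perimeter measured as the number
#' of 4-neighbour foreground/background pixel edges (image border counts).
#' A digital shape statistic: smooth round regions score high, spiculated
#' regions low.
#'
#' @param mask binary matrix.
#' @return the compactness value.
#' @export
mask_compactness <- function(mask) {
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(0, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- mask
  per <- sum(abs(diff(padded))) + sum(abs(t(diff(t(padded)))))
  4 * pi * area / per^2
}

#' Generate a synthetic dataset on disk
#'
#' Writes `2 * n_per_class` class-balanced samples as PNG pairs (3-channel
#' image, single-channel mask) plus a manifest CSV under `dir`, reproducibly
#' under `config$seed`.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (columns `image_path`, `mask_path`,
#'   `label`, `source_id`, `split` = NA), invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(msk_dir, showWarnings = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  labels <- rep(c("benign", "malignant"), each = config$n_per_class)
  rows <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    s <- make_sample(config, labels[i])
    sid <- sprintf("%s_%04d", substr(labels[i], 1, 3), i)
    ip <- file.path(img_dir, paste0(sid, ".png"))
    mp <- file.path(msk_dir, paste0(sid, "_mask.png"))
    png::writePNG(s$image, ip)
    png::writePNG(s$mask, mp)
    rows[[i]] <- data.frame(image_path = ip, mask_path = mp, label = labels[i],
                            source_id = sid, split = NA_character_,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
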