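# Dataset curation rules (malignancy filtering and labelling, reader
# consensus), patch cropping, augmentation, resampling, and manifest
# splitting. Images enter as 8-bit 3-channel PNG in [0, 1]; masks as 8-bit
# single-channel PNG with {0, 255} mapped to {0, 1}.

#' Per-nodule annotation record
#'
#' @param nodule_id identifier string.
#' @param reader_scores integer malignancy scores, 1--5, one per reader.
#' @param diameter_mm nodule diameter in millimetres, > 0.
#' @param reader_mask_count number of readers who delineated the nodule.
#' @param id_legible whether the nodule's identity record is legible.
#' @return an object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(nodule_id, reader_scores, diameter_mm,
                              reader_mask_count = length(reader_scores),
                              id_legible = TRUE) {
  if (length(reader_scores) == 0) stop("empty reader_scores")
  if (!all(reader_scores %in% 1:5)) stop("reader scores must be integers 1..5")
  if (diameter_mm <= 0) stop("diameter_mm must be > 0")
  structure(list(nodule_id = as.character(nodule_id),
                 reader_scores = as.integer(reader_scores),
                 diameter_mm = diameter_mm,
                 reader_mask_count = as.integer(reader_mask_count),
                 id_legible = isTRUE(id_legible)),
            class = "nodule_annotation")
}

#' Label a nodule as benign, malignant or excluded
#'
#' The per-reader malignancy scores (1--5) are aggregated by their median
#' (halves rounded up). A nodule is excluded when the aggregate rounds to 3
#' (indeterminate malignancy), when its diameter is below `min_diameter` or
#' above `max_diameter` millimetres, when its identity record is illegible,
#' or when fewer than `consensus_frac` of the readers delineated it.
#' Otherwise an aggregate of 1--2 is benign and 4--5 malignant.
#'
#' @param ann a [nodule_annotation()].
#' @param consensus_frac fraction of readers that must have delineated the
#'   nodule for it to be adopted (default 2/3).
#' @param min_diameter,max_diameter inclusion bounds in millimetres.
#' @return `"benign"`, `"malignant"` or `"excluded"`.
#' @export
label_nodule <- function(ann, consensus_frac = 2 / 3,
                         min_diameter = 3, max_diameter = 25) {
  stopifnot(inherits(ann, "nodule_annotation"))
  agg <- floor(median(ann$reader_scores) + 0.5)
  n_readers <- length(ann$reader_scores)
  if (agg == 3) return("excluded")
  if (ann$diameter_mm < min_diameter || ann$diameter_mm > max_diameter)
    return("excluded")
  if (!ann$id_legible) return("excluded")
  if (ann$reader_mask_count < ceiling(consensus_frac * n_readers))
    return("excluded")
  if (agg <= 2) "benign" else "malignant"
}

#' Read an annotation table
#'
#' CSV with header `nodule_id,reader_scores,diameter_mm,reader_mask_count,
#' id_legible`, reader scores semicolon-separated.
#'
#' @param path CSV file.
#' @return a list of [nodule_annotation()] records.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    nodule_annotation(df$nodule_id[i],
                      as.integer(strsplit(df$reader_scores[i], ";")[[1]]),
                      df$diameter_mm[i],
                      df$reader_mask_count[i],
                      as.logical(df$id_legible[i])))
}

#' Majority-vote consensus mask
#'
#' Pixel-level ground truth from several reader delineations: a pixel is
#' foreground when at least `threshold` (default 50%) of the contributing
#' readers marked it.
#'
#' @param reader_masks list of binary masks of identical shape.
#' @param threshold vote fraction required for foreground.
#' @return a binary mask.
#' @export
consensus_mask <- function(reader_masks, threshold = 0.5) {
  if (length(reader_masks) == 0) stop("need at least one mask")
  d <- dim(as.array(reader_masks[[1]]))
  for (mk in reader_masks) {
    if (!identical(dim(as.array(mk)), d)) stop("mask shapes differ")
    if (!all(mk %in% c(0, 1))) stop("masks must be binary")
  }
  votes <- Reduce(`+`, reader_masks)
  out <- (votes / length(reader_masks) >= threshold) * 1
  dim(out) <- d
  out
}

#' Crop a square patch around a centre
#'
#' Cuts a `size x size` window centred on `center` (defaults to the mask
#' centroid), zero-padding where the window exceeds the image bounds; the
#' mask is cropped identically.
#'
#' @param image `[H, W]` or `[H, W, C]` array.
#' @param mask `[H, W]` binary mask.
#' @param center `(row, col)` centre; `NULL` uses the mask centroid.
#' @param size patch side length (default 64).
#' @return `list(patch = , mask_patch = )`.
#' @export
crop_patch <- function(image, mask, center = NULL, size = 64L) {
  img <- as.array(image)
  if (length(dim(img)) == 2) dim(img) <- c(dim(img), 1L)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  if (is.null(center)) {
    idx <- which(mask == 1, arr.ind = TRUE)
    if (nrow(idx) == 0) stop("mask is empty and no center was given")
    center <- colMeans(idx)
  }
  if (center[1] < 1 || center[1] > H || center[2] < 1 || center[2] > W)
    stop("center lies outside the image")
  r0 <- round(center[1]) - size %/% 2
  c0 <- round(center[2]) - size %/% 2
  rows <- r0:(r0 + size - 1)
  cols <- c0:(c0 + size - 1)
  rok <- rows >= 1 & rows <= H
  cok <- cols >= 1 & cols <= W
  patch <- array(0, c(size, size, C))
  mpatch <- matrix(0, size, size)
  patch[which(rok), which(cok), ] <- img[rows[rok], cols[cok], , drop = FALSE]
  mpatch[which(rok), which(cok)] <- mask[rows[rok], cols[cok]]
  if (length(dim(image)) == 2) patch <- patch[, , 1]
  list(patch = patch, mask_patch = mpatch)
}

# Nearest-neighbour resize of a matrix (used for masks so they stay binary).
resize_nearest <- function(m, out_h, out_w = out_h) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(floor((seq_len(out_h) - 0.5) * H / out_h) + 1, 1), H)
  ci <- pmin(pmax(floor((seq_len(out_w) - 0.5) * W / out_w) + 1, 1), W)
  m[ri, ci, drop = FALSE]
}

# Bilinear resize of an [H, W] or [H, W, C] image array.
resize_bilinear_img <- function(img, out_h, out_w = out_h) {
  d2 <- length(dim(img)) == 2 || is.null(dim(img))
  x <- as.array(img)
  if (d2) dim(x) <- c(dim(x), 1L)
  dim(x) <- c(dim(x), 1L)
  y <- resize_bilinear_fwd_cpp(x, as.integer(out_h), as.integer(out_w))
  dim(y) <- dim(y)[1:3]
  if (d2) y <- y[, , 1]
  y
}

#' Augmentation specification
#'
#' @param crop_fraction_range range of the random centre-crop fraction.
#' @param zoom_factor equal-ratio zoom factor.
#' @param copies number of augmented copies per source image (default 9, a
#'   9-fold increase over the original).
#' @param seed RNG seed for reproducible augmentation.
#' @return an object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(crop_fraction_range = c(0.5, 1.0),
                              zoom_factor = 1.10, copies = 9L, seed = 1L) {
  if (copies < 0) stop("copies must be >= 0")
  if (any(crop_fraction_range <= 0) || any(crop_fraction_range > 1))
    stop("crop fractions must lie in (0, 1]")
  structure(list(crop_fraction_range = crop_fraction_range,
                 zoom_factor = zoom_factor, copies = as.integer(copies),
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

augment_one <- function(patch, mask_patch, family, spec, frac) {
  H <- nrow(mask_patch); W <- ncol(mask_patch)
  crop_center <- function(img, mk, h, w) {
    r0 <- (nrow(mk) - h) %/% 2; c0 <- (ncol(mk) - w) %/% 2
    rows <- (r0 + 1):(r0 + h); cols <- (c0 + 1):(c0 + w)
    if (length(dim(img)) == 3) list(i = img[rows, cols, , drop = FALSE], m = mk[rows, cols])
    else list(i = img[rows, cols], m = mk[rows, cols])
  }
  switch(family,
    crop = {
      h <- max(2L, round(H * frac)); w <- max(2L, round(W * frac))
      cc <- crop_center(patch, mask_patch, h, w)
      list(patch = resize_bilinear_img(cc$i, H, W),
           mask_patch = resize_nearest(cc$m, H, W))
    },
    zoom = {
      zh <- round(H * spec$zoom_factor); zw <- round(W * spec$zoom_factor)
      zi <- resize_bilinear_img(patch, zh, zw)
      zm <- resize_nearest(mask_patch, zh, zw)
      cc <- crop_center(zi, zm, H, W)
      list(patch = if (length(dim(patch)) == 3) array(cc$i, dim(patch)) else cc$i,
           mask_patch = cc$m)
    },
    hflip = {
      list(patch = if (length(dim(patch)) == 3) patch[, W:1, , drop = FALSE]
           else patch[, W:1],
           mask_patch = mask_patch[, W:1])
    },
    vflip = {
      list(patch = if (length(dim(patch)) == 3) patch[H:1, , , drop = FALSE]
           else patch[H:1, ],
           mask_patch = mask_patch[H:1, ])
    })
}

#' Augment a patch/mask pair
#'
#' Draws `spec$copies` augmented pairs, each by one uniformly chosen
#' transform family: random centre-crop (fraction in `crop_fraction_range`,
#' resized back), equal-ratio zoom (centre-cropped back to size), horizontal
#' flip, or vertical flip. The identical geometric transform is applied to
#' image and mask (bilinear vs nearest-neighbour interpolation), and the
#' draw is reproducible under `spec$seed`.
#'
#' @param patch `[H, W, C]` or `[H, W]` image patch.
#' @param mask_patch `[H, W]` binary mask.
#' @param spec an [augmentation_spec()].
#' @return a list of `spec$copies` `list(patch, mask_patch)` pairs.
#' @export
augment <- function(patch, mask_patch, spec = augmentation_spec()) {
  stopifnot(inherits(spec, "augmentation_spec"))
  families <- c("crop", "zoom", "hflip", "vflip")
  out <- vector("list", spec$copies)
  if (spec$copies == 0) return(out)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  for (i in seq_len(spec$copies)) {
    fam <- sample(families, 1)
    frac <- runif(1, spec$crop_fraction_range[1], spec$crop_fraction_range[2])
    out[[i]] <- augment_one(patch, mask_patch, fam, spec, frac)
  }
  out
}

#' Resample a patch/mask pair to the network input size
#'
#' Bilinear interpolation for the image, nearest-neighbour for the mask (so
#' the mask stays binary).
#'
#' @param patch square image patch.
#' @param mask_patch square binary mask.
#' @param size target side length (default 224).
#' @return `list(patch, mask_patch)` at `size x size`.
#' @export
resample <- function(patch, mask_patch, size = 224L) {
  if (nrow(mask_patch) != ncol(mask_patch)) stop("expected a square input")
  list(patch = resize_bilinear_img(patch, size, size),
       mask_patch = resize_nearest(mask_patch, size, size))
}

#' Assign train/validation/test splits to a manifest
#'
#' Source images (grouped by `source_id`, so augmented copies can never leak
#' across splits) are shuffled under `seed`, stratified by class label, and
#' assigned to splits in proportion `ratios`; per-stratum split sizes are
#' within one item of the exact fractions.
#'
#' @param manifest data.frame with columns `image_path`, `mask_path`,
#'   `label`, `source_id` (and optionally an existing `split`, overwritten).
#' @param ratios three positive numbers, train : validation : test.
#' @param seed RNG seed.
#' @return the manifest with a `split` column (`train`/`val`/`test`).
#' @export
split_manifest <- function(manifest, ratios = c(6, 2, 2), seed = 1L) {
  if (any(ratios <= 0)) stop("ratios must be positive")
  src <- unique(manifest[, c("source_id", "label")])
  if (nrow(src) < 3) stop("fewer source items than splits")
  frac <- ratios / sum(ratios)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  assign_split <- rep(NA_character_, nrow(src))
  for (lb in unique(src$label)) {
    ids <- which(src$label == lb)
    ids <- ids[sample.int(length(ids))]
    n <- length(ids)
    cuts <- diff(c(0, round(cumsum(frac) * n)))
    labs <- rep(c("train", "val", "test"), times = cuts)
    assign_split[ids] <- labs
  }
  manifest$split <- assign_split[match(manifest$source_id, src$source_id)]
  manifest
}

#' @rdname read_manifest
#' @param manifest the manifest data.frame to write.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' The manifest is a CSV binding image path, mask path, class label, source
#' image id and split assignment.
#'
#' @param path CSV file.
#' @return a data.frame with columns `image_path`, `mask_path`, `label`,
#'   `source_id`, `split` (plus any extra columns present).
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load one image/mask pair under the PNG contract
#'
#' Images are 8-bit 3-channel PNG read into `[H, W, 3]` arrays in `[0, 1]`;
#' masks are 8-bit single-channel PNG whose {0, 255} levels map to {0, 1}.
#'
#' @param image_path,mask_path PNG files.
#' @return `list(image = [H, W, 3], mask = [H, W])`.
#' @export
load_sample <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2) stop("image must be 3-channel PNG: ", image_path)
  img <- img[, , 1:3, drop = FALSE]
  mk <- png::readPNG(mask_path)
  if (length(dim(mk)) == 3) mk <- mk[, , 1]
  list(image = img, mask = (mk >= 0.5) * 1)
}

# Load a set of manifest rows into batch tensors.
load_batch_tensors <- function(rows) {
  n <- nrow(rows)
  first <- load_sample(rows$image_path[1], rows$mask_path[1])
  H <- dim(first$image)[1]; W <- dim(first$image)[2]
  x <- array(0, c(H, W, 3L, n))
  g <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    s <- if (i == 1) first else load_sample(rows$image_path[i], rows$mask_path[i])
    x[, , , i] <- s$image
    g[, , 1, i] <- s$mask
  }
  labels <- if ("label" %in% names(rows)) as.integer(rows$label == "malignant") else NULL
  list(x = x, g = g, labels = labels)
}
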