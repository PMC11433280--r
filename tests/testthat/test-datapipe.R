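# Annotation filtering/labelling, consensus, cropping, augmentation,
# resampling and manifest splitting.

test_that("nodule labelling follows the filtering rules", {
  expect_equal(label_nodule(nodule_annotation("a", c(1, 2, 2, 1), 8, 4)), "benign")
  expect_equal(label_nodule(nodule_annotation("b", c(3, 3, 3, 3), 8, 4)), "excluded")
  expect_equal(label_nodule(nodule_annotation("c", c(5, 4, 4), 2.5, 3)), "excluded")
  expect_equal(label_nodule(nodule_annotation("d", c(5, 4, 4, 5), 8, 4)), "malignant")
  # oversized nodules are excluded
  expect_equal(label_nodule(nodule_annotation("e", c(4, 4), 26, 2)), "excluded")
  # illegible identity records are excluded
  expect_equal(label_nodule(nodule_annotation("f", c(1, 1), 8, 2,
                                              id_legible = FALSE)), "excluded")
  # consensus: fewer than 2/3 of readers delineated it
  expect_equal(label_nodule(nodule_annotation("g", c(1, 1, 2, 1),
                                              8, reader_mask_count = 2)),
               "excluded")
  expect_equal(label_nodule(nodule_annotation("h", c(1, 1, 2, 1),
                                              8, reader_mask_count = 3)),
               "benign")
  expect_error(nodule_annotation("i", integer(0), 8), "empty")
  expect_error(nodule_annotation("j", c(0, 3), 8), "1..5")
})

test_that("every annotation maps to exactly one label", {
  set.seed(31)
  labels <- c("benign", "malignant", "excluded")
  for (i in 1:100) {
    ann <- nodule_annotation(paste0("n", i),
                             sample(1:5, sample(1:4, 1), replace = TRUE),
                             runif(1, 0.5, 30),
                             reader_mask_count = sample(0:4, 1),
                             id_legible = runif(1) < 0.9)
    out <- label_nodule(ann)
    expect_true(out %in% labels)
    expect_length(out, 1)
  }
})

test_that("consensus mask applies the majority vote", {
  m <- disk_mask(8, 4, 4, 2)
  expect_equal(consensus_mask(list(m, m, m, m)), m)
  # a pixel marked by 2 of 4 readers is adopted (50% rule); 1 of 4 is not
  a <- matrix(0, 2, 2); b <- matrix(0, 2, 2)
  a[1, 1] <- 1; b[1, 1] <- 1
  c2 <- matrix(0, 2, 2); c2[2, 2] <- 1
  votes <- consensus_mask(list(a, b, matrix(0, 2, 2), c2))
  expect_equal(votes[1, 1], 1)   # 2/4
  expect_equal(votes[2, 2], 0)   # 1/4
  expect_error(consensus_mask(list(a, matrix(0, 3, 3))), "shape")
  # threshold is configurable
  expect_equal(consensus_mask(list(a, b, matrix(0, 2, 2), c2),
                              threshold = 0.75)[1, 1], 0)
})

test_that("patch cropping centres the nodule and zero-pads at borders", {
  img <- matrix(runif(512 * 512), 512, 512)
  mask <- disk_mask(512, 256, 256, 20)
  cp <- crop_patch(img, mask, size = 64)
  expect_equal(dim(cp$mask_patch), c(64, 64))
  expect_equal(cp$patch, img[224:287, 224:287], tolerance = 1e-12)
  # mask centroid lands at the patch centre (+- 0.5 px)
  idx <- which(cp$mask_patch == 1, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(idx) - 32.5)), 1)
  # a centroid near the corner forces zero padding
  cp2 <- crop_patch(img, mask, center = c(10, 10), size = 64)
  expect_true(all(cp2$patch[1:20, 1:20] == 0))
  expect_equal(dim(cp2$patch), c(64, 64))
  expect_error(crop_patch(img, mask, center = c(600, 10)), "outside")
})

test_that("augmentation produces the requested copies reproducibly", {
  set.seed(41)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  mask <- disk_mask(64, 32, 32, 10)
  spec <- augmentation_spec(copies = 9, seed = 5)
  out <- augment(img, mask, spec)
  expect_length(out, 9)             # 9 copies + the original = 10 per source
  out2 <- augment(img, mask, spec)
  for (i in 1:9) expect_identical(out[[i]], out2[[i]])
  for (o in out) {
    expect_equal(dim(o$patch), dim(img))
    expect_true(all(o$mask_patch %in% c(0, 1)))
  }
})

test_that("flips are involutions and preserve mask area", {
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mask <- disk_mask(32, 14, 20, 6)
  h1 <- nodulecascade:::augment_one(img, mask, "hflip", NULL, NULL)
  h2 <- nodulecascade:::augment_one(h1$patch, h1$mask_patch, "hflip", NULL, NULL)
  expect_identical(h2$patch, img)
  expect_identical(h2$mask_patch, mask)
  expect_equal(sum(h1$mask_patch), sum(mask))
  v1 <- nodulecascade:::augment_one(img, mask, "vflip", NULL, NULL)
  expect_equal(sum(v1$mask_patch), sum(mask))
})

test_that("identical geometry is applied to image and mask", {
  # transform a coordinate grid stored both as image and as mask
  grid <- matrix(0, 64, 64)
  grid[20:30, 40:50] <- 1
  img <- array(rep(grid, 3), c(64, 64, 3))
  spec <- augmentation_spec(copies = 6, seed = 9)
  for (o in augment(img, grid, spec)) {
    # nearest-neighbour mask equals thresholded bilinear image transform
    expect_lt(mean(abs((o$patch[, , 1] >= 0.5) - o$mask_patch)), 0.02)
  }
})

test_that("resampling keeps masks binary and constants constant", {
  img <- array(0.37, c(64, 64, 3))
  mask <- disk_mask(64, 32, 32, 9)
  rs <- resample(img, mask, size = 224)
  expect_equal(dim(rs$patch), c(224, 224, 3))
  expect_equal(dim(rs$mask_patch), c(224, 224))
  expect_true(all(rs$mask_patch %in% c(0, 1)))
  expect_equal(max(abs(rs$patch - 0.37)), 0, tolerance = 1e-12)
  expect_error(resample(img, mask[, 1:32], 224), "square")
})

test_that("manifest splitting is stratified, leak-free and deterministic", {
  src <- data.frame(
    image_path = sprintf("img%03d.png", 1:100),
    mask_path = sprintf("msk%03d.png", 1:100),
    label = rep(c("benign", "malignant"), each = 50),
    source_id = sprintf("s%03d", 1:100),
    stringsAsFactors = FALSE)
  # augmented copies share their source id
  copies <- src[rep(1:100, each = 3), ]
  copies$image_path <- paste0(copies$image_path, "_aug", 1:3)
  manifest <- rbind(src, copies)
  out <- split_manifest(manifest, ratios = c(6, 2, 2), seed = 11)
  bysrc <- unique(out[, c("source_id", "split")])
  expect_equal(nrow(bysrc), 100)          # each source in exactly one split
  expect_equal(as.vector(table(bysrc$split)[c("train", "val", "test")]),
               c(60, 20, 20))
  # stratified: each class contributes half of every split
  u <- unique(out[, c("source_id", "label", "split")])
  tab <- table(u$label, u$split)
  expect_true(all(abs(tab[, "train"] - 30) <= 1))
  expect_true(all(abs(tab[, "val"] - 10) <= 1))
  expect_true(all(abs(tab[, "test"] - 10) <= 1))
  out2 <- split_manifest(manifest, ratios = c(6, 2, 2), seed = 11)
  expect_identical(out$split, out2$split)
  expect_error(split_manifest(src[1:2, ], seed = 1), "fewer")
})

test_that("annotation tables and manifests round-trip through CSV", {
  anns <- data.frame(nodule_id = c("n1", "n2"),
                     reader_scores = c("1;2;2;1", "4;5;4"),
                     diameter_mm = c(8.5, 12),
                     reader_mask_count = c(4, 3),
                     id_legible = c(TRUE, TRUE))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(anns, path, row.names = FALSE)
  back <- read_annotations(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$reader_scores, c(1L, 2L, 2L, 1L))
  expect_equal(label_nodule(back[[2]]), "malignant")
  m <- data.frame(image_path = "a.png", mask_path = "b.png",
                  label = "benign", source_id = "s1", split = "train")
  mp <- tempfile(fileext = ".csv")
  write_manifest(m, mp)
  expect_equal(read_manifest(mp), m)
})

test_that("PNG image/mask pairs honour the loader contract", {
  img <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mask <- disk_mask(16, 8, 8, 4)
  ip <- tempfile(fileext = ".png"); mp <- tempfile(fileext = ".png")
  png::writePNG(img, ip)
  png::writePNG(mask, mp)
  s <- load_sample(ip, mp)
  expect_equal(dim(s$image), c(16L, 16L, 3L))
  expect_true(all(s$mask %in% c(0, 1)))
  expect_equal(s$mask, mask)
  expect_equal(s$image, img, tolerance = 1 / 255)
})
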