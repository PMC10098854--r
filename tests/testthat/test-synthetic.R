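test_that("zero-irregularity scenes carry the analytic ellipse as mask", {
  size <- 48
  p <- clean_scene_params(size = size, irregularity = 0, seed = 3)
  pair <- render_scene(p)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  # axes convention: a = horizontal (column) semi-axis, b = vertical (row)
  a <- p$lesion_axes[1]; b <- p$lesion_axes[2]
  inside <- ((cols - p$lesion_center[2]) / a)^2 +
    ((rows - p$lesion_center[1]) / b)^2 <= 1
  # the renderer tests rho <= r(theta); at the boundary the two forms agree
  # except where floating-point ties differ, so demand near-perfect overlap
  expect_gt(mean((inside * 1) == pair$mask), 0.999)
  expect_true(all(pair$mask %in% c(0, 1)))
})

test_that("rendering is deterministic and seed-sensitive", {
  p <- sample_scene_params(11, 32, "easy")
  s1 <- render_scene(p)
  s2 <- render_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  q <- sample_scene_params(12, 32, "easy")
  expect_false(identical(render_scene(q)$image, s1$image))
})

test_that("contrast 0 hides the lesion in the image but not the mask", {
  p0 <- clean_scene_params(size = 48, seed = 5, contrast = 0)
  p0 <- scene_params(image_size = 48, lesion_center = p0$lesion_center,
                     lesion_axes = p0$lesion_axes, boundary_irregularity = 0,
                     contrast = 0, n_hairs = 0, n_bubbles = 0,
                     noise_sd = 0.02, seed = 5)
  pair <- render_scene(p0)
  expect_gt(sum(pair$mask), 0)
  inside <- lum(pair$image)[pair$mask == 1]
  outside <- lum(pair$image)[pair$mask == 0]
  # lesion pixels statistically indistinguishable from skin: the mean gap is
  # far below the noise floor
  expect_lt(abs(mean(inside) - mean(outside)), 3 * 0.02 / sqrt(length(inside)) + 0.003)
})

test_that("artifacts land on the image only, never the mask", {
  p <- scene_params(image_size = 64, boundary_irregularity = 0,
                    n_hairs = 4, n_bubbles = 3, noise_sd = 0, seed = 21)
  with_art <- render_scene(p, keep_artifacts = TRUE)
  p0 <- scene_params(image_size = 64, boundary_irregularity = 0,
                     n_hairs = 0, n_bubbles = 0, noise_sd = 0, seed = 21)
  without <- render_scene(p0)
  expect_identical(with_art$mask, without$mask)
  expect_gt(sum(attr(with_art, "hair_mask")), 0)
  expect_gt(sum(attr(with_art, "bubble_mask")), 0)
  # hairs really darken the image where stamped
  hm <- attr(with_art, "hair_mask") & !attr(with_art, "bubble_mask")
  expect_lt(mean(lum(with_art$image)[hm]), mean(lum(without$image)[hm]))
})

test_that("degenerate lesion axes and out-of-bounds ellipses are rejected", {
  expect_error(scene_params(image_size = 64, lesion_axes = c(1, 10)),
               "degenerate")
  expect_error(scene_params(image_size = 64, lesion_center = c(5, 32),
                            lesion_axes = c(20, 10)),
               "fit inside")
})

test_that("sampled params respect the difficulty contrast regimes", {
  easy <- sapply(1:100, function(i)
    sample_scene_params(i, 64, "easy")$contrast)
  expect_true(all(easy >= 0.5))
  hard <- sapply(1:100, function(i)
    sample_scene_params(i + 1000, 64, "hard")$contrast)
  expect_true(all(hard >= 0.1 & hard <= 0.3))
  # same seed, same params
  expect_identical(sample_scene_params(42, 64, "hard"),
                   sample_scene_params(42, 64, "hard"))
})

test_that("generate_dataset writes reproducible pairs with sane foreground", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(8, image_size = 32, seed = 6, out_dir = d1)
  m2 <- generate_dataset(8, image_size = 32, seed = 6, out_dir = d2)
  expect_equal(nrow(m1$entries), 8)
  p1 <- load_manifest_pairs(m1, target_size = c(32, 32))
  p2 <- load_manifest_pairs(m2, target_size = c(32, 32))
  for (i in seq_along(p1)) {
    expect_identical(p1[[i]]$image, p2[[i]]$image)
    frac <- mean(p1[[i]]$mask)
    expect_gt(frac, 0.02); expect_lt(frac, 0.6)
  }
  # empty dataset: no error, empty manifest
  d3 <- withr::local_tempdir()
  expect_equal(nrow(generate_dataset(0, 32, seed = 1, out_dir = d3)$entries), 0)
  # different seeds differ
  d4 <- withr::local_tempdir()
  m4 <- generate_dataset(8, image_size = 32, seed = 7, out_dir = d4)
  p4 <- load_manifest_pairs(m4, target_size = c(32, 32))
  expect_false(all(sapply(seq_along(p1), function(i)
    identical(p1[[i]]$image, p4[[i]]$image))))
})

test_that("Otsu thresholding solves clean easy scenes but fails hard ones", {
  otsu_dice <- function(pair) {
    g <- lum(pair$image)
    thr <- EBImage::otsu(EBImage::Image(t(g)))
    evaluate_masks((g < thr) * 1, pair$mask)$dice
  }
  easy <- sapply(1:6, function(i) {
    p <- sample_scene_params(i, 96, "easy")
    q <- scene_params(image_size = 96, lesion_center = p$lesion_center,
                      lesion_axes = p$lesion_axes,
                      boundary_irregularity = p$boundary_irregularity,
                      lesion_color = p$lesion_color, skin_color = p$skin_color,
                      contrast = p$contrast, n_hairs = 0, n_bubbles = 0,
                      noise_sd = p$noise_sd, seed = p$seed)
    otsu_dice(render_scene(q))
  })
  hard <- sapply(1:6, function(i)
    otsu_dice(render_scene(sample_scene_params(i + 500, 96, "hard"))))
  expect_true(all(easy >= 0.85))
  expect_lt(mean(hard), mean(easy) - 0.2)
})
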