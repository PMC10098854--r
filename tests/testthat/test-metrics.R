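test_that("binarize collapses luminance with ties to foreground", {
  expect_true(all(binarize(array(0.9, c(4, 4, 3))) == 1))
  expect_true(all(binarize(array(0.1, c(4, 4, 3))) == 0))
  expect_equal(binarize(matrix(0.5, 2, 2))[1, 1], 1)  # tie rule
  onech <- array(c(0.2, 0.8, 0.5, 0.4), c(2, 2, 1))
  expect_equal(binarize(onech), matrix(c(0, 1, 1, 0), 2, 2))
})

test_that("confusion matches the exhaustive per-pixel tally", {
  p <- matrix(c(rep(1, 30), rep(0, 70)), 10, 10)
  expect_equal(unclass(confusion(p, p))[c("tp", "fp", "tn", "fn")],
               list(tp = 30L, fp = 0L, tn = 70L, fn = 0L))
  cmp <- confusion(1 - p, p)
  expect_equal(cmp$tp, 0L); expect_equal(cmp$tn, 0L)

  set.seed(70)
  for (rep in 1:10) {
    a <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    b <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    got <- confusion(a, b)
    tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
    for (i in 1:16) for (j in 1:16) {
      if (a[i, j] == 1 && b[i, j] == 1) tp <- tp + 1L
      else if (a[i, j] == 1 && b[i, j] == 0) fp <- fp + 1L
      else if (a[i, j] == 0 && b[i, j] == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
    expect_equal(unclass(got)[c("tp", "fp", "tn", "fn")],
                 list(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(got$tp + got$fp + got$tn + got$fn, 256L)
  }
  expect_error(confusion(a, b[1:8, ]), "identical shape")
})

test_that("metrics reproduce hand arithmetic, including the printed specificity", {
  m <- compute_metrics(list(tp = 2, fp = 1, tn = 6, fn = 1))
  expect_equal(m$dice, 4 / 6)
  expect_equal(m$jaccard, 2 / 4)
  expect_equal(m$accuracy, 8 / 10)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity_paper, 2 / 3)       # TP / (TP + FP), as printed
  expect_equal(m$specificity_standard, 6 / 7)    # TN / (TN + FP)
  expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-15)

  perfect <- compute_metrics(list(tp = 30, fp = 0, tn = 70, fn = 0))
  for (f in c("accuracy", "dice", "jaccard", "sensitivity",
              "specificity_paper", "specificity_standard"))
    expect_equal(perfect[[f]], 1)
})

test_that("0/0 denominators follow the agreement convention and are flagged", {
  # no true or predicted foreground: all overlap metrics 1, flagged
  empty <- compute_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_equal(empty$dice, 1)
  expect_equal(empty$sensitivity, 1)
  expect_true("sensitivity" %in% empty$flagged)
  # true foreground missed entirely: sensitivity defined and 0
  missed <- compute_metrics(list(tp = 0, fp = 0, tn = 8, fn = 2))
  expect_equal(missed$sensitivity, 0)
  expect_equal(missed$specificity_paper, 0)  # 0/0 with disagreement (fn > 0)
  expect_true("specificity_paper" %in% missed$flagged)
})

test_that("an all-background prediction has zero sensitivity on lesion scenes", {
  pair <- render_scene(clean_scene_params(size = 32, seed = 15))
  m <- evaluate_masks(matrix(0, 32, 32), pair$mask)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$dice, 0)
})

test_that("evaluate_dataset tabulates per-sample rows and unweighted means", {
  G <- build_generator(micro_generator_spec(16L), seed = 80)
  pair <- render_scene(sample_scene_params(5, 16, "easy"))
  res <- evaluate_dataset(G, list(pair, pair))
  expect_equal(nrow(res$samples), 2)
  # identical inputs give identical rows (deterministic predictions)
  expect_equal(res$samples$dice[1], res$samples$dice[2])
  expect_equal(res$means[["dice"]], mean(res$samples$dice), tolerance = 1e-9)
  csv <- withr::local_tempfile(fileext = ".csv")
  res2 <- evaluate_dataset(G, list(pair, pair), csv_path = csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$id[3], "mean")
})

test_that("contour overlay recolors exactly the 4-adjacency boundary", {
  img <- array(0.5, c(5, 5, 3))
  # empty mask: untouched
  expect_identical(contour_overlay(img, matrix(0, 5, 5)), img)
  # centred 3x3 square: all 8 square pixels are boundary (none interior)
  msk <- matrix(0, 5, 5); msk[2:4, 2:4] <- 1
  out <- contour_overlay(img, msk, color = c(1, 0, 0))
  red <- out[, , 1] == 1 & out[, , 2] == 0
  expect_equal(sum(red), 8)
  expect_false(red[3, 3])
  # full-frame mask: only the image border is boundary
  full <- contour_overlay(img, matrix(1, 5, 5))
  redf <- full[, , 1] == 1 & full[, , 2] == 0
  expect_equal(sum(redf), 16)
  expect_false(redf[3, 3])
})

test_that("metric identities hold over random confusion tables", {
  set.seed(71)
  for (i in 1:50) {
    cnt <- list(tp = sample(0:40, 1), fp = sample(0:40, 1),
                tn = sample(0:40, 1), fn = sample(0:40, 1))
    if (sum(unlist(cnt)) == 0) next
    m <- compute_metrics(cnt)
    vals <- c(m$accuracy, m$dice, m$jaccard, m$sensitivity,
              m$specificity_paper, m$specificity_standard)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_gte(m$dice, m$jaccard)
    expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
    # accuracy is symmetric under swapping prediction and truth
    sw <- compute_metrics(list(tp = cnt$tp, fp = cnt$fn, tn = cnt$tn,
                               fn = cnt$fp))
    expect_equal(sw$accuracy, m$accuracy)
  }
})
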