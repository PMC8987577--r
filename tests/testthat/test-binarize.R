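test_that("unsharp mask has the defining algebraic properties", {
  const <- matrix(42, 20, 20)
  expect_equal(unsharp_mask(const, 2, 5), const)

  img <- matrix(runif(400, 0, 255), 20, 20)
  expect_identical(unsharp_mask(img, 0, 5), img)
  expect_error(unsharp_mask(img, 2, 0), "radius")

  out <- unsharp_mask(img, 2, 3)
  expect_true(all(out >= min(img) & out <= max(img)))
})

test_that("unsharp mask of a step edge matches a direct-convolution oracle", {
  # vertical step edge, constant along rows
  img <- matrix(50, 30, 60)
  img[, 31:60] <- 150
  amount <- 2
  radius <- 3
  half <- ceiling(3 * radius)
  g <- dnorm(seq(-half, half), sd = radius)
  k <- outer(g, g)
  k <- k / sum(k)
  out <- unsharp_mask(img, amount, radius)
  # oracle: direct convolution with replicated edges at sampled pixels
  for (px in list(c(15, 28), c(15, 31), c(15, 33), c(15, 45), c(2, 30))) {
    i <- px[1]
    j <- px[2]
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      a <- min(max(i + di, 1), nrow(img))
      b <- min(max(j + dj, 1), ncol(img))
      acc <- acc + k[di + half + 1, dj + half + 1] * img[a, b]
    }
    expected <- min(max(img[i, j] + amount * (img[i, j] - acc), min(img)), max(img))
    expect_equal(out[i, j], expected, tolerance = 1e-10)
  }
  # overshoot/undershoot on the respective sides of the edge
  expect_lt(out[15, 29], 50 + 1e-9)
  expect_gt(out[15, 32], 150 - 1e-9)
})

test_that("Otsu threshold maximizes between-class variance exhaustively", {
  # perfectly bimodal 4x4
  img <- matrix(c(rep(10, 8), rep(200, 8)), 4, 4)
  mask <- threshold_global(img, "otsu")
  expect_identical(as_mask(mask), img > 100)

  # values 0..15: compare with exhaustive maximizer
  img16 <- matrix(0:15, 4, 4)
  expect_equal(threshold_value(img16, "otsu"), oracle_otsu(img16))

  set.seed(5)
  for (i in 1:25) {
    img <- matrix(sample(0:40, 64, replace = TRUE), 8, 8)
    expect_equal(threshold_value(img, "otsu"), oracle_otsu(img))
  }
})

test_that("constant images yield an all-background mask with a warning", {
  img <- matrix(7, 6, 6)
  for (m in c("otsu", "triangle", "li", "yen")) {
    expect_warning(mask <- threshold_global(img, m), "constant")
    expect_false(any(mask))
    expect_true(attr(mask, "constant_input"))
  }
})

test_that("threshold algorithms match reference values on a fixture image", {
  # expected values computed once with scikit-image 0.26 threshold_* on this
  # exact image (256-bin histogram conventions agree)
  p <- generate_plane(fixture_spec(seed = 11, infiltration_fraction = 0.05,
                                   noise_sd = 3, blur_sigma = 0.4))
  img <- unsharp_mask(p$channels$cortex_glia, 2, 20)
  expect_equal(threshold_value(img, "otsu"), 44.0234375, tolerance = 1e-10)
  expect_equal(threshold_value(img, "triangle"), 1.1484375, tolerance = 1e-10)
  expect_equal(threshold_value(img, "yen"), 0.3828125, tolerance = 1e-10)
  expect_equal(threshold_value(img, "li"), 36.37639522523488, tolerance = 1e-4)
})

test_that("Li threshold sits at the minimum cross-entropy cut", {
  set.seed(13)
  img <- matrix(c(rnorm(150, 30, 8), rnorm(106, 140, 15)), 16, 16)
  thr <- threshold_value(img, "li")
  obj <- oracle_li_objective(img)
  best_cut <- obj$cuts[which.min(obj$ce)]
  # the iteration converges into the same histogram valley as the
  # exhaustive minimizer
  vals <- sort(unique(as.numeric(img)))
  gap <- max(diff(vals))
  expect_lt(abs(thr - best_cut), gap + 1)
})

test_that("blown-out detection compares band white counts around despeckling", {
  # 30x40 mask, middle third = rows 11..20: one large component spanning the
  # band plus twelve 2-px specks inside it (24 of 249 band white px, 9.6%)
  m <- matrix(FALSE, 30, 40)
  m[11:23, 1:25] <- TRUE # large component, partially in the band
  for (cc in seq(28, 37, by = 3)) {
    for (rr in seq(11, 17, by = 3)) {
      m[rr + 0:1, cc] <- TRUE
    }
  }
  band <- 11:20
  before <- sum(m[band, ])
  after <- sum(despeckle(m, 75)[band, ])
  res <- is_blown_out(m, min_size = 75, reduction_threshold = 0.07)
  expect_equal(res$despeckle_reduction, 1 - after / before)
  expect_true(res$blown_out) # specks are a large fraction of the band here

  # one large component only: nothing removed
  big <- matrix(FALSE, 30, 30)
  big[5:25, 5:25] <- TRUE
  res2 <- is_blown_out(big, 75)
  expect_false(res2$blown_out)
  expect_equal(res2$despeckle_reduction, 0)

  # empty band: guard against division by zero
  empty <- matrix(FALSE, 30, 30)
  empty[1:2, 1:20] <- TRUE # outside the middle third
  res3 <- is_blown_out(empty, 75)
  expect_false(res3$blown_out)
  expect_equal(res3$despeckle_reduction, 0)
})

test_that("blown-out reduction never decreases with min_size", {
  set.seed(23)
  for (i in 1:10) {
    m <- random_mask(24, 24, 0.35)
    reds <- vapply(c(2, 5, 10, 20, 50),
                   function(s) is_blown_out(m, s)$despeckle_reduction,
                   numeric(1))
    expect_true(all(diff(reds) >= -1e-12))
  }
})

test_that("blacked-out detection uses a strict 2% white-fraction rule", {
  m <- matrix(FALSE, 100, 100)
  m[1:10, 1:15] <- TRUE # 150 px = 1.5%
  r <- is_blacked_out(m)
  expect_true(r$blacked_out)
  expect_equal(r$white_fraction, 0.015)

  m[1:10, 1:20] <- TRUE # 200 px = exactly 2%: strict inequality
  r2 <- is_blacked_out(m)
  expect_false(r2$blacked_out)
  expect_equal(r2$white_fraction, 0.02)

  expect_false(is_blacked_out(matrix(TRUE, 10, 10))$blacked_out)
})

test_that("decision tree selects the branch each preset forces", {
  clean <- fixture_threshold_image("clean")
  blown <- fixture_threshold_image("blown_out")
  blacked <- fixture_threshold_image("blacked_out")

  sel <- select_threshold(clean, "nuclei")
  expect_equal(sel$decision$chosen_algorithm, "otsu")
  expect_false(sel$decision$blown_out)
  expect_false(sel$decision$blacked_out)

  expect_equal(select_threshold(blown, "nuclei")$decision$chosen_algorithm,
               "triangle")
  expect_equal(select_threshold(blown, "cortex_glia")$decision$chosen_algorithm,
               "triangle")
  expect_equal(select_threshold(blown, "astrocyte")$decision$chosen_algorithm,
               "triangle")

  expect_equal(select_threshold(blacked, "nuclei")$decision$chosen_algorithm,
               "li")
  expect_equal(select_threshold(blacked, "astrocyte")$decision$chosen_algorithm,
               "yen")
  # the cortex-glia tree has no blacked-out branch
  expect_equal(select_threshold(blacked, "cortex_glia")$decision$chosen_algorithm,
               "otsu")
})

test_that("decision tree always stays within each channel's permitted set", {
  permitted <- list(nuclei = c("otsu", "triangle", "li"),
                    cortex_glia = c("otsu", "triangle"),
                    astrocyte = c("otsu", "triangle", "yen"))
  set.seed(31)
  for (i in 1:6) {
    img <- matrix(sample(0:255, 900, replace = TRUE), 30, 30)
    img[10:20, 10:20] <- 250
    for (ch in names(permitted)) {
      sel <- select_threshold(img, ch)
      expect_true(sel$decision$chosen_algorithm %in% permitted[[ch]])
      expect_equal(nrow(sel$decision), 1)
    }
  }
})

test_that("algorithm ranking utility sums 3/2/1 points over images", {
  rankings <- tibble::tibble(
    image = rep(c("a", "b"), each = 4),
    algorithm = rep(c("otsu", "triangle", "li", "yen"), 2),
    rank = c(1, 2, 3, 4, 2, 1, 4, 3)
  )
  sc <- rank_threshold_algorithms(rankings)
  expect_equal(sc$score[sc$algorithm == "otsu"], 3 + 2)
  expect_equal(sc$score[sc$algorithm == "triangle"], 2 + 3)
  expect_equal(sc$score[sc$algorithm == "li"], 1 + 0)
  expect_equal(sc$score[sc$algorithm == "yen"], 0 + 1)
})
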