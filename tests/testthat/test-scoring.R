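test_that("object features follow their closed-form definitions", {
  sq <- matrix(FALSE, 12, 12)
  sq[4:8, 4:8] <- TRUE
  f <- label_objects(sq)
  expect_equal(nrow(f), 1)
  expect_equal(f$area, 25L)
  expect_equal(f$perimeter, 20)
  expect_equal(f$extent, 1)
  expect_equal(f$roundness, 4 * pi * 25 / 400)
  expect_equal(unlist(f[, c("row0", "col0", "row1", "col1")], use.names = FALSE),
               c(4L, 4L, 9L, 9L))

  line <- matrix(FALSE, 5, 12)
  line[3, 2:10] <- TRUE
  f2 <- label_objects(line)
  expect_equal(f2$area, 9L)
  expect_equal(f2$extent, 1)
  expect_equal(f2$perimeter, 20)
  expect_equal(f2$roundness, 4 * pi * 9 / 400)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- TRUE
  diag2[3, 3] <- TRUE
  expect_equal(nrow(label_objects(diag2, connectivity = 8)), 1)
  expect_equal(nrow(label_objects(diag2, connectivity = 4)), 2)
})

test_that("cell-body exclusion removes round compact mid-sized objects only", {
  m <- matrix(FALSE, 60, 60)
  # disk of radius 6 (compact, round, area 113)
  for (i in -6:6) for (j in -6:6) if (i^2 + j^2 <= 36) m[20 + i, 20 + j] <- TRUE
  # 2-px-wide 60-px process (low roundness)
  m[30:59, 45] <- TRUE
  m[30:59, 46] <- TRUE
  ex <- exclude_cell_bodies(m)
  expect_equal(ex$n_excluded, 1L)
  expect_false(any(ex$mask[14:26, 14:26])) # disk removed
  expect_true(all(ex$mask[30:59, 45:46])) # process kept
  expect_true(all(ex$mask <= m))

  empty <- matrix(FALSE, 10, 10)
  ex2 <- exclude_cell_bodies(empty)
  expect_identical(ex2$mask, empty)
  expect_equal(ex2$n_excluded, 0L)
})

test_that("AMI is perimeter as a percent of cortex area", {
  cortex <- matrix(TRUE, 100, 100) # area 10000
  cg <- matrix(FALSE, 100, 100)
  cg[10:34, 10:34] <- TRUE # 25x25 block, perimeter 100
  expect_equal(compute_ami(cg, cortex)$ami, 1.0)
  expect_equal(compute_ami(matrix(FALSE, 100, 100), cortex)$ami, 0)
  expect_warning(res <- compute_ami(cg, matrix(FALSE, 100, 100)), "cortex")
  expect_true(is.na(res$ami))
})

test_that("fragmentation law: m equal tiles have sqrt(m) times the AMI", {
  cortex <- matrix(TRUE, 80, 80)
  # one 20x20 square vs four disjoint 10x10 squares of equal total area
  one <- matrix(FALSE, 80, 80)
  one[10:29, 10:29] <- TRUE
  four <- matrix(FALSE, 80, 80)
  for (o in list(c(10, 10), c(10, 40), c(40, 10), c(40, 40))) {
    four[o[1]:(o[1] + 9), o[2]:(o[2] + 9)] <- TRUE
  }
  expect_equal(sum(one), sum(four))
  ami1 <- compute_ami(one, cortex)$ami
  ami4 <- compute_ami(four, cortex)$ami
  expect_equal(ami4 / ami1, sqrt(4))
})

test_that("AIS is filtered astrocyte overlap as a percent of cortex area", {
  cortex <- matrix(FALSE, 120, 120)
  cortex[11:110, 11:110] <- TRUE # 10000 px
  astro <- matrix(FALSE, 120, 120)
  astro[20:69, 30:34] <- TRUE # 250-px thin rectangle inside the cortex
  res <- compute_ais(astro, cortex)
  expect_equal(res$ais, 2.5)
  expect_equal(res$infiltration_px, 250L)

  outside <- matrix(FALSE, 120, 120)
  outside[1:5, 1:100] <- TRUE # entirely outside the cortex
  expect_equal(compute_ais(outside, cortex)$ais, 0)

  expect_warning(res0 <- compute_ais(astro, matrix(FALSE, 120, 120)), "cortex")
  expect_true(is.na(res0$ais))

  # exclusion can only lower the score
  with_body <- astro
  for (i in -6:6) for (j in -6:6) if (i^2 + j^2 <= 36) with_body[90 + i, 90 + j] <- TRUE
  strict <- compute_ais(with_body, cortex)
  loose <- compute_ais(with_body, cortex,
                       cell_body_filter(min_area = 1e6, max_area = 1e6 + 1))
  expect_lte(strict$ais, loose$ais)
})

test_that("AIS equals the planted infiltration exactly on noiseless fixtures", {
  p <- generate_plane(fixture_spec(seed = 3, infiltration_fraction = 0.04,
                                   noise_sd = 0, blur_sigma = 0))
  masks <- binarize_plane(p)
  area <- sum(p$truth$cortex_mask)
  res <- compute_ais(masks$astrocyte, p$truth$cortex_mask)
  expect_equal(res$ais, 100 * p$truth$true_infiltration_px / area)
  expect_equal(res$infiltration_px, p$truth$true_infiltration_px)
})

test_that("plane scores are invariant to joint translation and rotation", {
  p <- generate_plane(fixture_spec(seed = 9, infiltration_fraction = 0.03,
                                   noise_sd = 0, blur_sigma = 0))
  masks <- binarize_plane(p)
  cortex <- p$truth$cortex_mask
  base <- score_plane(masks$astrocyte, masks$cortex_glia, cortex, z_norm = 0)

  rot <- function(m) t(m[nrow(m):1, , drop = FALSE]) # 90 degrees
  rotated <- score_plane(rot(masks$astrocyte), rot(masks$cortex_glia),
                         rot(cortex), z_norm = 0)
  expect_equal(rotated$ami, base$ami)
  expect_equal(rotated$ais, base$ais)

  shift <- function(m, dr, dc) { # translate within an enlarged frame
    out <- matrix(FALSE, nrow(m) + 10, ncol(m) + 10)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  moved <- score_plane(shift(masks$astrocyte, 4, 7),
                       shift(masks$cortex_glia, 4, 7),
                       shift(cortex, 4, 7), z_norm = 0)
  expect_equal(moved$ami, base$ami)
  expect_equal(moved$ais, base$ais)
})

test_that("zero-cortex planes get missing scores, not zeros", {
  empty <- matrix(FALSE, 20, 20)
  expect_warning(row <- score_plane(empty, empty, empty, z_norm = 50), "missing")
  expect_true(is.na(row$ami))
  expect_true(is.na(row$ais))
  expect_equal(row$cortex_area, 0L)
})

test_that("mesh-like cortex glia score higher AMI than globular at equal area", {
  cortex <- matrix(TRUE, 100, 100)
  # mesh: 8 thin 2x50 strips; globular: disks of matched total area
  mesh <- matrix(FALSE, 100, 100)
  for (k in 0:7) mesh[10 + k * 11 + 0:1, 26:75] <- TRUE
  glob <- matrix(FALSE, 100, 100)
  for (ctr in list(c(25, 25), c(25, 75), c(75, 25), c(75, 75))) {
    for (i in -8:8) for (j in -8:8) {
      if (i^2 + j^2 <= 64) glob[ctr[1] + i, ctr[2] + j] <- TRUE
    }
  }
  expect_gt(compute_ami(mesh, cortex)$ami, compute_ami(glob, cortex)$ami)
})
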