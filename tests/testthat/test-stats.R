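test_that("global scores average planes per animal, skipping missing", {
  tbl <- tibble::tibble(
    animal_id = c("a", "a", "b", "b"),
    group = "control",
    z_index = c(0L, 1L, 0L, 1L),
    z_norm = c(0, 100, 0, 100),
    ami = c(4, 6, NA, 8),
    ais = c(1, 3, 2, NA)
  )
  g <- animal_global_scores(tbl)
  expect_equal(nrow(g), 2)
  expect_equal(g$ami[g$animal_id == "a"], 5)
  expect_equal(g$ami[g$animal_id == "b"], 8)
  expect_equal(g$ais[g$animal_id == "b"], 2)

  tbl$ami[3:4] <- NA
  tbl$ais[3:4] <- NA
  expect_warning(g2 <- animal_global_scores(tbl), "excluding")
  expect_equal(g2$animal_id, "a")
})

test_that("sliding windows average per animal then summarize per group", {
  tbl <- generate_score_table(n_per_group = 3, n_planes = 21, within_sd = 0,
                              noise_sd = 0, seed = 2)
  # constant AMI across z for each animal: every window mean equals it
  prof <- sliding_window(tbl, width = 10, step = 25)
  grp <- prof[!is.na(prof$group) & prof$group == "control", ]
  expect_true(all(abs(diff(grp$ami_mean)) < 1e-9))

  # brute-force recomputation oracle, width 10 / step 5
  prof2 <- sliding_window(tbl, width = 10, step = 5)
  for (ctr in c(0, 35, 70, 100)) {
    lo <- max(0, ctr - 5)
    hi <- min(100, ctr + 5)
    sel <- tbl[tbl$z_norm >= lo & (tbl$z_norm < hi | hi == 100), ]
    manual <- tapply(sel$ami, paste(sel$group, sel$animal_id), mean)
    by_grp <- tapply(manual, sub(" .*", "", names(manual)), mean)
    got <- prof2[prof2$window_center == ctr & !is.na(prof2$group), ]
    expect_equal(got$ami_mean[match(names(by_grp), got$group)],
                 as.vector(by_grp))
  }
})

test_that("a perfect antitone link gives rho -1 in every populated window", {
  tbl <- generate_score_table(n_per_group = 4, n_planes = 11, seed = 3,
                              noise_sd = 0, slope = -1, intercept = 100)
  expect_true(all(abs(tbl$ais - (100 - tbl$ami)) < 1e-9))
  prof <- sliding_window(tbl, width = 10, step = 10)
  rho <- unique(prof$rho[!is.na(prof$rho)])
  expect_true(all(abs(rho + 1) < 1e-12))
})

test_that("a full-width window reproduces the global scores", {
  tbl <- generate_score_table(n_per_group = 3, n_planes = 7, seed = 4)
  prof <- sliding_window(tbl, width = 200, step = 100)
  g <- animal_global_scores(tbl)
  for (grp in unique(g$group)) {
    expect_equal(prof$ami_mean[prof$group == grp][1],
                 mean(g$ami[g$group == grp]))
  }
})

test_that("Spearman correlation matches rank-Pearson and handles ties", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 2, 5, 1, 9) # one tie pair
  expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)))
  expect_equal(spearman_cor(x, y)$rho,
               unname(cor.test(x, y, method = "spearman", exact = FALSE)$estimate))

  # invariance under strictly monotone transforms
  set.seed(8)
  a <- rnorm(12)
  b <- rnorm(12)
  r0 <- spearman_cor(a, b)$rho
  expect_equal(spearman_cor(exp(a), b)$rho, r0)
  expect_equal(spearman_cor(a, b^3 + 5 * b)$rho, r0)

  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("exact permutation p-values agree with cor.test for small n", {
  set.seed(9)
  for (i in 1:5) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    mine <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "exact permutation")
  }
})

test_that("Kruskal-Wallis H and Dunn z match their closed forms", {
  d <- tibble::tibble(value = c(1, 2, 3, 10, 20, 30),
                      group = rep(c("a", "b"), each = 3))
  res <- kruskal_dunn(d, value, group)
  # ranks 1..6: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 3.857142...
  expect_equal(res$h, 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  expect_equal(res$df, 1)
  # Dunn z on pooled ranks, no ties
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(abs(res$dunn$z), abs((2 - 5) / se))
  expect_equal(res$dunn$p_raw, 2 * pnorm(-abs(res$dunn$z)))

  ident <- tibble::tibble(value = rep(5, 9), group = rep(c("a", "b", "c"), 3))
  res2 <- kruskal_dunn(ident, value, group)
  expect_equal(res2$h, 0)
  expect_equal(res2$p_value, 1)
})

test_that("Kruskal-Wallis includes tie correction and monotone invariance", {
  d <- tibble::tibble(value = c(1, 1, 2, 3, 3, 4, 5, 6, 6),
                      group = rep(c("a", "b", "c"), each = 3))
  res <- kruskal_dunn(d, value, group)
  ref <- kruskal.test(d$value, factor(d$group))
  expect_equal(res$h, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # H is invariant under strictly monotone transforms
  d2 <- d
  d2$value <- exp(d2$value / 2)
  expect_equal(kruskal_dunn(d2, value, group)$h, res$h)

  # Dunn variance term: N(N+1)/12 - sum(t^3 - t)/(12 (N - 1))
  ties <- table(d$value)
  var_base <- 9 * 10 / 12 - sum(ties^3 - ties) / (12 * 8)
  r <- rank(d$value)
  z_ab <- (mean(r[1:3]) - mean(r[4:6])) / sqrt(var_base * (2 / 3))
  expect_equal(res$dunn$z[res$dunn$group1 == "a" & res$dunn$group2 == "b"], z_ab)
  expect_equal(res$dunn$p_holm, p.adjust(res$dunn$p_raw, "holm"))
})

test_that("validation regression recovers exact linear relations", {
  manual <- c(0.5, 1, 1.5, 2, 2.5)
  fit2 <- suppressWarnings(validation_regression(manual, 2 * manual))
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 0)
  expect_equal(fit2$r_squared, 1)
  expect_false(any(fit2$outlier)) # |manual - auto| stays within 6
  manual <- c(1, 3, 5, 7, 9)

  # 5-point set against the normal-equations oracle
  set.seed(10)
  auto <- 1.4 * manual + rnorm(5, 0, 0.8)
  fit <- validation_regression(manual, auto)
  sxx <- sum((manual - mean(manual))^2)
  b1 <- sum((manual - mean(manual)) * (auto - mean(auto))) / sxx
  b0 <- mean(auto) - b1 * mean(manual)
  expect_equal(fit$slope, b1)
  expect_equal(fit$intercept, b0)
  resid <- auto - b0 - b1 * manual
  se <- sqrt(sum(resid^2) / 3 / sxx)
  expect_equal(unname(fit$slope_ci),
               unname(b1 + c(-1, 1) * qt(0.975, 3) * se))
  expect_equal(fit$r_squared, cor(manual, auto)^2)
})

test_that("discrepancy outliers are flagged and optionally refitted", {
  manual <- c(1, 2, 3, 4, 5, 6)
  auto <- manual + c(0, 0.5, -0.5, 0, 0, 9) # last pair is off by 9 > 6
  fit <- validation_regression(manual, auto)
  expect_equal(which(fit$outlier), 6L)
  expect_false(is.null(fit$refit))
  expect_lt(abs(fit$refit$slope - 1), abs(fit$slope - 1))
  expect_equal(fit$refit$n, 5)
})

test_that("ICC(3,k) matches the two-way ANOVA decomposition", {
  m <- matrix(c(9, 6, 8, 7,
                10, 6, 9, 8,
                8, 5, 7, 6), 4, 3)
  res <- icc3k(m)
  # oracle: mean squares computed directly from row/column/grand means
  n <- 4; k <- 3
  grand <- mean(m)
  ms_target <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  ms_rater <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  ms_err <- sse / ((n - 1) * (k - 1))
  expect_equal(res$icc, (ms_target - ms_err) / ms_target)
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 6)

  same <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_equal(icc3k(same)$icc, 1)
})

test_that("ICC(3,k) is near zero for independent raters", {
  # each rater is an independent shuffle of the same 30 target scores
  set.seed(12)
  vals <- replicate(500, {
    m <- sapply(1:3, function(r) sample(1:30))
    icc3k(m)$icc
  })
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("tidy and glance methods return the expected summaries", {
  d <- generate_score_table(n_per_group = 5, seed = 14)
  g <- animal_global_scores(d)
  kw <- kruskal_dunn(g, ami, group)
  expect_named(glance(kw), c("statistic", "df", "p.value", "n"))
  expect_equal(nrow(tidy(kw)), 3) # three pairwise comparisons

  fit <- suppressWarnings(validation_regression(g$ami, g$ami * 1.1))
  expect_equal(tidy(fit)$estimate[2], fit$slope)
  expect_equal(glance(fit)$r.squared, 1)
})
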