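#' Per-animal global scores
#'
#' Averages all scored planes of each animal into one global AMI and AIS per
#' animal (unweighted mean; missing plane scores are excluded). Animals with
#' no valid score in either column are dropped with a warning.
#'
#' @param table A score table: one row per plane with at least `animal_id`,
#'   `group`, `ami`, `ais`.
#' @return A tibble with one row per animal: `animal_id`, `group`, `ami`,
#'   `ais`, `n_planes`.
#' @export
animal_global_scores <- function(table) {
  stopifnot(all(c("animal_id", "group", "ami", "ais") %in% names(table)))
  out <- table |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::summarise(
      n_planes = dplyr::n(),
      ami = mean_or_na(.data$ami),
      ais = mean_or_na(.data$ais),
      .groups = "drop"
    ) |>
    dplyr::select("animal_id", "group", "ami", "ais", "n_planes")
  dropped <- is.na(out$ami) & is.na(out$ais)
  if (any(dropped)) {
    warning("excluding ", sum(dropped),
            " animal(s) with no scored planes: ",
            paste(out$animal_id[dropped], collapse = ", "))
    out <- out[!dropped, ]
  }
  out
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) NA_real_ else mean(x)
}

#' Dorsal-ventral sliding-window profiles
#'
#' Slides a window of `width` percent depth along the 0-100 ventral-dorsal
#' axis in steps of `step` percent. Within each window `[c - width/2,
#' c + width/2]` (clipped to `[0, 100]`; closed on the left, open on the
#' right, closed-closed when the upper edge reaches 100), plane scores of
#' each animal are averaged, then summarized per group as mean and SEM over
#' animals. A Spearman correlation between windowed AMI and AIS is computed
#' across all animals pooled over groups; windows with fewer than
#' `min_animals` complete pairs get a missing correlation.
#'
#' @param table A score table with `animal_id`, `group`, `z_norm`, `ami`,
#'   `ais`.
#' @param width Window width in percent depth (default 10).
#' @param step Window step in percent depth (default 1).
#' @param min_animals Minimum animals with both scores for the windowed
#'   correlation (default 3).
#' @return A `window_profile` tibble: one row per window center with
#'   `window_center`, `n_animals`, `rho`, `p_value`, and nested per-group
#'   summaries in columns `group`, `ami_mean`, `ami_sem`, `ais_mean`,
#'   `ais_sem` (long by group).
#' @export
sliding_window <- function(table, width = 10, step = 1, min_animals = 3) {
  stopifnot(all(c("animal_id", "group", "z_norm", "ami", "ais") %in% names(table)),
            width > 0, step > 0)
  centers <- seq(0, 100, by = step)
  per_window <- purrr::map_dfr(centers, function(ctr) {
    lo <- max(0, ctr - width / 2)
    hi <- min(100, ctr + width / 2)
    inside <- table$z_norm >= lo &
      (table$z_norm < hi | (hi >= 100 & table$z_norm <= 100))
    win <- table[inside, ]
    if (nrow(win) == 0L) {
      return(tibble::tibble(window_center = ctr, group = NA_character_,
                            ami_mean = NA_real_, ami_sem = NA_real_,
                            ais_mean = NA_real_, ais_sem = NA_real_,
                            n_animals = 0L, rho = NA_real_, p_value = NA_real_))
    }
    per_animal <- win |>
      dplyr::group_by(.data$animal_id, .data$group) |>
      dplyr::summarise(ami = mean_or_na(.data$ami),
                       ais = mean_or_na(.data$ais), .groups = "drop")
    by_group <- per_animal |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(ami_mean = mean_or_na(.data$ami),
                       ami_sem = sem(.data$ami),
                       ais_mean = mean_or_na(.data$ais),
                       ais_sem = sem(.data$ais), .groups = "drop")
    pair_ok <- !is.na(per_animal$ami) & !is.na(per_animal$ais)
    n_pairs <- sum(pair_ok)
    if (n_pairs >= min_animals) {
      sp <- spearman_cor(per_animal$ami[pair_ok], per_animal$ais[pair_ok])
      rho <- sp$rho
      p <- sp$p_value
    } else {
      rho <- NA_real_
      p <- NA_real_
    }
    by_group$window_center <- ctr
    by_group$n_animals <- n_pairs
    by_group$rho <- rho
    by_group$p_value <- p
    by_group
  })
  out <- dplyr::select(per_window, "window_center", "group", "ami_mean",
                       "ami_sem", "ais_mean", "ais_sem", "n_animals", "rho",
                       "p_value")
  class(out) <- c("window_profile", class(out))
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Spearman rank correlation
#'
#' Spearman's rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). The p-value uses the exact permutation distribution for n of 8 or
#' fewer pairs and the large-sample t approximation otherwise. Pairs with a
#' missing value are dropped.
#'
#' @param x,y Numeric vectors of equal length (at least 3 complete pairs).
#' @return One-row tibble: `rho`, `p_value`, `n`, `method`. `rho` is missing
#'   (with a warning) when either vector is constant.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant vector: Spearman rho undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = NA_character_))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p_value, n = n, method = method)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value (via
#' [stats::kruskal.test()]), followed by Dunn's pairwise z statistics on the
#' pooled mid-ranks with tie correction. Pairwise p-values are reported raw
#' and Holm-adjusted.
#'
#' @param data A data frame.
#' @param value,group Column names (unquoted or strings) of the numeric
#'   response and the group label.
#' @return An object of class `kruskal_dunn`: a list with `h`, `df`,
#'   `p_value`, `n`, `groups` (per-group n and mean rank), and `dunn`
#'   (tibble of pairwise `z`, `p_raw`, `p_holm`).
#' @export
kruskal_dunn <- function(data, value = "value", group = "group") {
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  x <- data[[value]]
  g <- as.character(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- g[ok]
  n <- length(x)
  if (length(unique(g)) < 2L) stop("need at least 2 groups")
  if (n < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L) {
    kw_h <- 0
    kw_p <- 1
    kw_df <- length(unique(g)) - 1L
  } else {
    kw <- stats::kruskal.test(x, factor(g))
    kw_h <- unname(kw$statistic)
    kw_p <- kw$p.value
    kw_df <- unname(kw$parameter)
  }
  r <- rank(x)
  grp <- sort(unique(g))
  ni <- vapply(grp, function(gg) sum(g == gg), numeric(1))
  ri <- vapply(grp, function(gg) mean(r[g == gg]), numeric(1))
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(grp), 2L)
  dunn <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]
    j <- pairs[2L, k]
    se <- sqrt(var_base * (1 / ni[i] + 1 / ni[j]))
    z <- unname((ri[i] - ri[j]) / se)
    tibble::tibble(group1 = grp[i], group2 = grp[j], z = z,
                   p_raw = 2 * pnorm(-abs(z)))
  })
  dunn$p_holm <- stats::p.adjust(dunn$p_raw, method = "holm")
  structure(list(h = kw_h, df = kw_df, p_value = kw_p, n = n,
                 groups = tibble::tibble(group = grp, n = as.integer(ni),
                                         mean_rank = ri),
                 dunn = dunn),
            class = "kruskal_dunn")
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %d)\n",
              x$h, x$df, x$p_value, x$n))
  cat("Dunn pairwise comparisons:\n")
  print(as.data.frame(x$dunn), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.kruskal_dunn <- function(x, ...) x$dunn

#' @export
glance.kruskal_dunn <- function(x, ...) {
  tibble::tibble(statistic = x$h, df = x$df, p.value = x$p_value, n = x$n)
}

#' Manual-versus-automated validation regression
#'
#' Ordinary least squares of the automated score on the manual score, with a
#' t-based 95% confidence interval on the slope. Pairs whose absolute
#' manual-automated discrepancy exceeds `discrepancy_threshold` (default 6
#' score units) are flagged as outliers, and the fit is optionally repeated
#' without them.
#'
#' @param manual,auto Numeric score vectors of equal length (n >= 3).
#' @param discrepancy_threshold Absolute difference flagging an outlier.
#' @param refit Also fit with flagged pairs excluded.
#' @return An object of class `validation_regression`: list with `slope`,
#'   `intercept`, `slope_ci` (length-2), `r_squared`, `p_value`, `n`,
#'   `outlier` (logical vector), and optionally `refit` (same fields,
#'   outliers excluded).
#' @export
validation_regression <- function(manual, auto, discrepancy_threshold = 6,
                                  refit = TRUE) {
  ok <- complete.cases(manual, auto)
  manual <- manual[ok]
  auto <- auto[ok]
  n <- length(manual)
  if (n < 3L) stop("need at least 3 pairs")
  if (sd(manual) == 0) stop("manual scores are constant: slope undefined")
  outlier <- abs(manual - auto) > discrepancy_threshold
  fit <- ols_summary(manual, auto)
  res <- structure(c(fit, list(n = n, outlier = outlier,
                               discrepancy_threshold = discrepancy_threshold)),
                   class = "validation_regression")
  if (refit && any(outlier) && sum(!outlier) >= 3L &&
      sd(manual[!outlier]) > 0) {
    res$refit <- c(ols_summary(manual[!outlier], auto[!outlier]),
                   list(n = sum(!outlier)))
  }
  res
}

ols_summary <- function(manual, auto) {
  fit <- lm(auto ~ manual)
  sm <- summary(fit)
  ci <- confint(fit, "manual", level = 0.95)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       slope_ci = c(ci[1L], ci[2L]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients["manual", "Pr(>|t|)"])
}

#' @export
print.validation_regression <- function(x, ...) {
  cat(sprintf("auto ~ manual: slope = %.3f [%.3f, %.3f], intercept = %.3f, r^2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept,
              x$r_squared, x$p_value, x$n))
  if (any(x$outlier)) {
    cat(sprintf("%d pair(s) with |manual - auto| > %g flagged\n",
                sum(x$outlier), x$discrepancy_threshold))
  }
  invisible(x)
}

#' @export
tidy.validation_regression <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 conf.low = c(NA_real_, x$slope_ci[1]),
                 conf.high = c(NA_real_, x$slope_ci[2]))
}

#' @export
glance.validation_regression <- function(x, ...) {
  tibble::tibble(slope = x$slope, r.squared = x$r_squared,
                 p.value = x$p_value, n = x$n, n_outliers = sum(x$outlier))
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects, consistency, average-of-k-raters intraclass
#' correlation: `ICC(3,k) = (MS_targets - MS_error) / MS_targets`, with mean
#' squares from the two-way ANOVA decomposition (targets + raters, no
#' interaction). Used to assess agreement between raters scoring the same
#' images.
#'
#' @param ratings A numeric matrix, targets in rows and raters in columns
#'   (at least 2 of each, no missing cells).
#' @return An object of class `icc3k`: list with `icc`, `f`, `df1`, `df2`,
#'   `p_value`, `n_targets`, `n_raters`.
#' @export
icc3k <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("ratings matrix must be complete")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 targets and 2 raters")
  long <- data.frame(score = as.vector(ratings),
                     target = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- aov(score ~ target + rater, data = long)
  ms <- summary(fit)[[1L]][["Mean Sq"]]
  ms_target <- ms[1L]
  ms_error <- ms[3L]
  if (ms_target == 0) stop("zero between-target variance: ICC undefined")
  icc <- (ms_target - ms_error) / ms_target
  f <- if (ms_error == 0) Inf else ms_target / ms_error
  df1 <- n - 1L
  df2 <- (n - 1L) * (k - 1L)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(icc = icc, f = f, df1 = df1, df2 = df2, p_value = p,
                 n_targets = n, n_raters = k),
            class = "icc3k")
}

#' @export
print.icc3k <- function(x, ...) {
  cat(sprintf("ICC(3,k) = %.4f (F(%d,%d) = %.3g, p = %.3g; %d targets, %d raters)\n",
              x$icc, x$df1, x$df2, x$f, x$p_value, x$n_targets, x$n_raters))
  invisible(x)
}

#' @export
glance.icc3k <- function(x, ...) {
  tibble::tibble(icc = x$icc, statistic = x$f, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value, n_targets = x$n_targets,
                 n_raters = x$n_raters)
}
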