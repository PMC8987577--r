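#' Unsharp-mask denoising
#'
#' Sharpens an image by adding back a scaled difference between the image and
#' a Gaussian-blurred copy of itself:
#' `out = image + amount * (image - blur(image, radius))`,
#' where the blur is a Gaussian with standard deviation `radius` (pixels) and
#' replicated edges. The result is clipped to the intensity range of the
#' input. Defaults match the pipeline settings for the astrocyte and
#' cortex-glia channels (amount 2, radius 20); the neuronal-nuclei channel
#' uses amount 3, radius 20.
#'
#' @param image Numeric matrix of grayscale intensities.
#' @param amount Non-negative scaling factor for the high-frequency residual.
#' @param radius Positive Gaussian standard deviation, in pixels.
#' @return Numeric matrix of the same shape.
#' @export
unsharp_mask <- function(image, amount = 2, radius = 20) {
  if (!is.matrix(image) || length(image) == 0L) stop("image must be a non-empty matrix")
  if (radius <= 0) stop("radius must be positive")
  if (amount < 0) stop("amount must be non-negative")
  if (amount == 0) return(image)
  blur <- gaussian_blur(image, sigma = radius)
  out <- image + amount * (image - blur)
  lo <- min(image)
  hi <- max(image)
  out[out < lo] <- lo
  out[out > hi] <- hi
  out
}

# Gaussian smoothing with replicate boundary (a constant image stays
# constant). The kernel is the normalized outer product of sampled
# densities, truncated at 3 sigma.
gaussian_blur <- function(image, sigma) {
  half <- as.integer(ceiling(3 * sigma))
  # filter2 needs the kernel to fit; cap at the image extent
  half <- min(half, (min(dim(image)) - 1L) %/% 2L)
  if (half < 1L) return(image)
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- outer(g, g)
  k <- k / sum(k)
  EBImage::imageData(EBImage::filter2(image, k, boundary = "replicate"))
}

#' Global threshold value of a grayscale image
#'
#' Computes the scalar threshold for one of the four global algorithms used by
#' the pipeline's decision trees. Pixels strictly above the returned value are
#' foreground.
#'
#' * `otsu`: maximizes between-class variance over all cuts at the observed
#'   distinct intensity values (exhaustive when the image has at most
#'   `n_bins` distinct values, binned otherwise).
#' * `triangle`: maximal histogram-to-chord distance from the histogram peak
#'   to the far tail.
#' * `li`: minimum cross-entropy, by Li & Tam's fixed-point iteration.
#' * `yen`: maximum correlation criterion.
#'
#' @param image Numeric matrix.
#' @param method One of `"otsu"`, `"triangle"`, `"li"`, `"yen"`.
#' @param n_bins Histogram resolution for the histogram-based methods
#'   (default 256).
#' @return Scalar threshold, or `NA` for a constant image.
#' @export
threshold_value <- function(image, method = c("otsu", "triangle", "li", "yen"),
                            n_bins = 256L) {
  method <- match.arg(method)
  x <- as.numeric(image)
  x <- x[!is.na(x)]
  if (length(unique(x)) < 2L) return(NA_real_)
  switch(method,
    otsu = otsu_threshold(x, n_bins),
    triangle = triangle_threshold(x, n_bins),
    li = li_threshold(x),
    yen = yen_threshold(x, n_bins)
  )
}

# Between-class variance maximization over cuts at distinct observed values
# (quantized to n_bins levels only when there are more distinct values).
otsu_threshold <- function(x, n_bins = 256L) {
  vals <- sort(unique(x))
  if (length(vals) > n_bins) {
    h <- bin_histogram(x, n_bins)
    vals <- h$mids
    cnt <- h$counts
    keep <- cnt > 0
    vals <- vals[keep]
    cnt <- cnt[keep]
  } else {
    cnt <- tabulate(match(x, vals), nbins = length(vals))
  }
  n <- sum(cnt)
  w0 <- cumsum(cnt)
  s0 <- cumsum(cnt * vals)
  total <- s0[length(s0)]
  m <- length(vals) - 1L
  w0 <- w0[seq_len(m)]
  s0 <- s0[seq_len(m)]
  w1 <- n - w0
  mu0 <- s0 / w0
  mu1 <- (total - s0) / w1
  sb <- w0 * w1 * (mu0 - mu1)^2
  vals[which.max(sb)]
}

bin_histogram <- function(x, n_bins) {
  lo <- min(x)
  hi <- max(x)
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((x - lo) / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- lo + (seq_len(n_bins) - 0.5) * width
  list(counts = counts, mids = mids)
}

# Integer-valued images get unit-width bins at the integers so the peak is
# not split; everything else gets n_bins equal bins over the data range.
method_histogram <- function(x, n_bins) {
  vals <- sort(unique(x))
  if (all(vals == round(vals)) && diff(range(vals)) <= n_bins * 4) {
    mids <- seq(min(vals), max(vals))
    counts <- tabulate(match(x, mids), nbins = length(mids))
    list(counts = counts, mids = as.numeric(mids))
  } else {
    bin_histogram(x, n_bins)
  }
}

triangle_threshold <- function(x, n_bins = 256L) {
  h <- method_histogram(x, n_bins)
  counts <- as.numeric(h$counts)
  mids <- h$mids
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1L]
  hi <- nz[length(nz)]
  flipped <- (peak - lo) >= (hi - peak) # longer tail on the left: mirror it
  if (flipped) {
    counts <- rev(counts)
    n <- length(counts)
    peak <- n - peak + 1L
    hi <- n - lo + 1L
  }
  if (hi <= peak) return(mids[if (flipped) length(mids) - peak + 1L else peak])
  idx <- peak:hi
  nx <- (idx - peak) / (hi - peak)
  ny <- counts[idx] / counts[peak]
  dist <- 1 - nx - ny # distance below the peak-to-tail chord (up to scale)
  best <- idx[which.max(dist)]
  if (flipped) best <- length(counts) - best + 1L
  mids[best]
}

# Li & Tam minimum cross-entropy fixed point on strictly positive intensities.
li_threshold <- function(x, tol = NULL, max_iter = 256L) {
  shift <- min(x)
  rng <- diff(range(x))
  eps <- rng / 1e6
  y <- x - shift + eps
  if (is.null(tol)) tol <- rng / 1e5
  t_cur <- mean(y)
  for (i in seq_len(max_iter)) {
    lo <- y[y <= t_cur]
    hi <- y[y > t_cur]
    if (length(lo) == 0L || length(hi) == 0L) break
    mb <- mean(lo)
    mf <- mean(hi)
    t_new <- if (mb == mf) mb else (mb - mf) / (log(mb) - log(mf))
    if (abs(t_new - t_cur) < tol) {
      t_cur <- t_new
      break
    }
    t_cur <- t_new
  }
  t_cur + shift - eps
}

yen_threshold <- function(x, n_bins = 256L) {
  h <- method_histogram(x, n_bins)
  p <- h$counts / sum(h$counts)
  p1 <- cumsum(p)
  p1sq <- cumsum(p^2)
  p2sq <- sum(p^2) - p1sq
  m <- length(p) - 1L
  i <- seq_len(m)
  denom <- p1sq[i] * p2sq[i]
  band <- p1[i] * (1 - p1[i])
  crit <- ifelse(denom > 0 & band > 0, -log(denom) + 2 * log(band), -Inf)
  h$mids[which.max(crit)]
}

#' Binarize an image with a global threshold
#'
#' Pixels strictly above the computed threshold become foreground. A constant
#' image has no definable threshold: it yields an all-background mask with a
#' warning, and the returned mask carries attribute `constant_input = TRUE`.
#'
#' @inheritParams threshold_value
#' @return A logical mask with attributes `threshold` (the scalar used) and
#'   `constant_input`.
#' @export
threshold_global <- function(image, method = c("otsu", "triangle", "li", "yen"),
                             n_bins = 256L) {
  method <- match.arg(method)
  thr <- threshold_value(image, method, n_bins)
  if (is.na(thr)) {
    warning("constant image: no threshold definable, returning all-background mask")
    mask <- matrix(FALSE, nrow(image), ncol(image))
    return(structure(mask, threshold = NA_real_, constant_input = TRUE))
  }
  structure(image > thr, threshold = thr, constant_input = FALSE)
}

#' Row range of the middle third of an image
#'
#' The blown-out detector compares white-pixel counts in the band of the
#' image corresponding to the neuropil, which in longitudinal sections is the
#' middle third of rows.
#'
#' @param mask A matrix (only its dimensions are used).
#' @return Integer vector of row indices.
#' @export
middle_third_rows <- function(mask) {
  nr <- nrow(mask)
  seq.int(floor(nr / 3) + 1L, floor(2 * nr / 3))
}

#' Blown-out diagnostic for a binary image
#'
#' A binarization is "blown out" when noise passes as signal. The detector
#' despeckles the mask (removing components under `min_size` pixels) and
#' compares the white-pixel count within a test band before and after: a
#' fractional reduction of `reduction_threshold` (default 7%) or more flags
#' the image as blown out. The default band is the middle third of rows,
#' where the neuropil lies.
#'
#' @inheritParams despeckle
#' @param band Integer vector of row indices to test; defaults to the middle
#'   third of rows.
#' @param reduction_threshold Fractional white-pixel loss at or above which
#'   the image is blown out (default 0.07).
#' @return A list with `blown_out` (logical) and `despeckle_reduction`
#'   (fraction in `[0, 1]`; 0 when the band has no white pixels).
#' @export
is_blown_out <- function(mask, min_size = 75, reduction_threshold = 0.07,
                         band = NULL, connectivity = 8) {
  mask <- as_mask(mask)
  if (is.null(band)) band <- middle_third_rows(mask)
  if (length(band) == 0L) stop("band selects no rows")
  before <- sum(mask[band, , drop = FALSE])
  if (before == 0L) {
    return(list(blown_out = FALSE, despeckle_reduction = 0))
  }
  after <- sum(despeckle(mask, min_size, connectivity)[band, , drop = FALSE])
  reduction <- 1 - after / before
  list(blown_out = reduction >= reduction_threshold,
       despeckle_reduction = reduction)
}

#' Blacked-out diagnostic for a binary image
#'
#' A binarization is "blacked out" when true signal was removed, detected as
#' a white-pixel fraction strictly below `white_fraction_threshold`
#' (default 2%).
#'
#' @inheritParams despeckle
#' @param white_fraction_threshold Fraction below which the mask counts as
#'   blacked out (default 0.02; the comparison is strict, exactly 2% white is
#'   not blacked out).
#' @return A list with `blacked_out` (logical) and `white_fraction`.
#' @export
is_blacked_out <- function(mask, white_fraction_threshold = 0.02) {
  mask <- as_mask(mask)
  frac <- sum(mask) / length(mask)
  list(blacked_out = frac < white_fraction_threshold, white_fraction = frac)
}

#' Binarization diagnostics parameters
#'
#' Bundles the decision-tree constants with their pipeline defaults:
#' despeckle size 75 px, blown-out reduction 7%, blacked-out white fraction
#' 2%, 8-connectivity, and the middle third of rows as the test band.
#'
#' @param min_size Despeckle component size (px).
#' @param reduction_threshold Blown-out despeckle-reduction cutoff.
#' @param white_fraction_threshold Blacked-out white-fraction cutoff.
#' @param connectivity Component connectivity (4 or 8).
#' @param band Optional explicit row indices for the blown-out test band.
#' @param n_bins Histogram resolution for threshold algorithms.
#' @return A list of class `binarize_params`.
#' @export
binarize_params <- function(min_size = 75, reduction_threshold = 0.07,
                            white_fraction_threshold = 0.02, connectivity = 8,
                            band = NULL, n_bins = 256L) {
  stopifnot(min_size >= 1, reduction_threshold >= 0, reduction_threshold <= 1,
            white_fraction_threshold >= 0, white_fraction_threshold <= 1)
  structure(list(min_size = min_size,
                 reduction_threshold = reduction_threshold,
                 white_fraction_threshold = white_fraction_threshold,
                 connectivity = match_connectivity(connectivity),
                 band = band, n_bins = as.integer(n_bins)),
            class = "binarize_params")
}

#' Quality-aware threshold selection for one channel
#'
#' Implements the per-channel decision trees. All channels are first
#' thresholded with Otsu's method and the result tested for the blown-out
#' failure mode; a blown-out Otsu mask is replaced by a Triangle
#' binarization. Otherwise the nuclei channel falls back to Li and the
#' astrocyte channel to Yen when the Otsu mask is blacked out; the
#' cortex-glia channel keeps Otsu. The decision, both diagnostics, and the
#' threshold used are recorded.
#'
#' @param image Numeric matrix (already denoised).
#' @param channel One of `"nuclei"`, `"cortex_glia"`, `"astrocyte"`.
#' @param params A [binarize_params()] list.
#' @return A list with `mask` (logical matrix) and `decision` (one-row
#'   tibble: channel, chosen_algorithm, blown_out, blacked_out,
#'   despeckle_reduction, white_fraction, threshold).
#' @export
select_threshold <- function(image,
                             channel = c("nuclei", "cortex_glia", "astrocyte"),
                             params = binarize_params()) {
  channel <- match.arg(channel)
  otsu_mask <- threshold_global(image, "otsu", params$n_bins)
  bo <- is_blown_out(otsu_mask, params$min_size, params$reduction_threshold,
                     params$band, params$connectivity)
  bl <- is_blacked_out(otsu_mask, params$white_fraction_threshold)
  if (bo$blown_out) {
    algo <- "triangle"
  } else if (bl$blacked_out && channel == "nuclei") {
    algo <- "li"
  } else if (bl$blacked_out && channel == "astrocyte") {
    algo <- "yen"
  } else {
    algo <- "otsu"
  }
  mask <- if (algo == "otsu") otsu_mask else {
    threshold_global(image, algo, params$n_bins)
  }
  decision <- tibble::tibble(
    channel = channel,
    chosen_algorithm = algo,
    blown_out = bo$blown_out,
    blacked_out = bl$blacked_out,
    despeckle_reduction = bo$despeckle_reduction,
    white_fraction = bl$white_fraction,
    threshold = attr(mask, "threshold")
  )
  list(mask = as_mask(mask), decision = decision)
}

#' Score thresholding algorithms from per-image rankings
#'
#' Utility reproducing the algorithm-selection scoring scheme used to pick
#' the decision-tree vocabulary: for each image the best algorithm earns 3
#' points, second best 2, third 1, all others 0 (ties allowed); points are
#' summed over images.
#'
#' @param rankings A data frame with columns `image`, `algorithm`, and `rank`
#'   (1 = best; ranks above 3 score 0).
#' @return A tibble with `algorithm` and `score`, sorted by decreasing score.
#' @export
rank_threshold_algorithms <- function(rankings) {
  stopifnot(all(c("image", "algorithm", "rank") %in% names(rankings)))
  rankings |>
    dplyr::mutate(points = pmax(4 - .data$rank, 0)) |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(score = sum(.data$points), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
}
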