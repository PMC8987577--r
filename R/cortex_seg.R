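#' Cortex segmentation parameters
#'
#' The four tunable parameters of the cortex-segmentation stage, with the
#' defaults selected by grid search in the original pipeline: fill
#' neighborhood radius `n = 15` px, white-neighbor fraction `thresh = 0.10`,
#' maximum filled hole area `hole_size = 5000` px, and `erosions = 10`
#' finetune iterations.
#'
#' @param n Euclidean-disk radius (px) for the dilation fill; `n >= 1`.
#' @param thresh Fraction of white in-image neighbors above which a black
#'   pixel flips; in `(0, 1)`.
#' @param hole_size Background holes strictly smaller than this area (px)
#'   are filled.
#' @param erosions Number of 8-neighborhood erosion passes.
#' @param connectivity Connectivity used for hole labeling.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(n = 15, thresh = 0.10, hole_size = 5000,
                                erosions = 10, connectivity = 8) {
  n <- as.integer(n)
  stopifnot(n >= 1, thresh > 0, thresh < 1, hole_size >= 0, erosions >= 0)
  structure(list(n = n, thresh = thresh, hole_size = as.integer(hole_size),
                 erosions = as.integer(erosions),
                 connectivity = match_connectivity(connectivity)),
            class = "segmentation_params")
}

#' Merge two binary masks
#'
#' Pixelwise union of the cortex-glia and neuronal-nuclei masks, the first
#' step of cortex segmentation.
#'
#' @param cg,nuclei Binary masks of identical shape.
#' @return A binary mask.
#' @export
merge_masks <- function(cg, nuclei) {
  cg <- as_mask(cg)
  nuclei <- as_mask(nuclei)
  if (!identical(dim(cg), dim(nuclei))) stop("masks must share a shape")
  cg | nuclei
}

# Euclidean-disk kernel of radius n with the center pixel excluded.
disk_kernel <- function(n) {
  d <- 2L * n + 1L
  off <- seq(-n, n)
  k <- outer(off^2, off^2, `+`) <= n^2
  k[n + 1L, n + 1L] <- FALSE
  matrix(as.numeric(k), d, d)
}

# Convolve with zero padding wide enough that the kernel never wraps, and
# round back to exact integer counts.
count_in_disk <- function(mat, kernel) {
  n <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(mat)
  nc <- ncol(mat)
  p <- matrix(0, nr + 2L * n, nc + 2L * n)
  p[(n + 1L):(n + nr), (n + 1L):(n + nc)] <- mat
  conv <- EBImage::imageData(EBImage::filter2(p, kernel, boundary = 0))
  round(conv[(n + 1L):(n + nr), (n + 1L):(n + nc)])
}

#' Neighborhood dilation fill
#'
#' The pipeline's "1st fill": in a single simultaneous pass, a background
#' pixel is turned to foreground when the fraction of white pixels among its
#' in-image neighbors within a Euclidean disk of radius `n` (the pixel itself
#' excluded) is strictly greater than `thresh`. Foreground pixels never
#' change, so the output always contains the input.
#'
#' @inheritParams label_components
#' @param n Disk radius in pixels (default 15).
#' @param thresh White-neighbor fraction cutoff (default 0.10).
#' @return A binary mask.
#' @export
dilation_fill <- function(mask, n = 15, thresh = 0.10) {
  mask <- as_mask(mask)
  n <- as.integer(n)
  stopifnot(n >= 1, thresh > 0, thresh < 1)
  if (all(mask) || !any(mask)) return(mask)
  k <- disk_kernel(n)
  white <- count_in_disk(mask + 0, k)
  total <- count_in_disk(matrix(1, nrow(mask), ncol(mask)), k)
  mask | (white / total > thresh)
}

#' Fill enclosed background holes
#'
#' The pipeline's "2nd fill": background connected components with area
#' strictly below `hole_size` pixels that do not touch the image border are
#' converted to foreground. Border-touching background is never filled.
#'
#' @inheritParams label_components
#' @param hole_size Maximum hole area (exclusive), default 5000 px.
#' @return A binary mask.
#' @export
fill_holes <- function(mask, hole_size = 5000, connectivity = 8) {
  mask <- as_mask(mask)
  stopifnot(hole_size >= 0)
  if (hole_size == 0 || all(mask)) return(mask)
  lab <- label_components(!mask, connectivity)
  nr <- nrow(lab)
  nc <- ncol(lab)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  sizes <- tabulate(lab[lab > 0L])
  fill_ids <- setdiff(which(sizes < hole_size), border)
  if (length(fill_ids) == 0L) return(mask)
  mask | matrix(lab %in% fill_ids, nr, nc)
}

#' Iterated 8-neighborhood erosion
#'
#' The segmentation finetune step: in each of `iterations` simultaneous
#' passes, any foreground pixel with at least one background pixel among its
#' 8 immediate neighbors (the image border counts as background) is turned to
#' background.
#'
#' @inheritParams label_components
#' @param iterations Number of erosion passes (`0` returns the mask
#'   unchanged).
#' @return A binary mask.
#' @export
erode_mask <- function(mask, iterations = 10) {
  mask <- as_mask(mask)
  stopifnot(iterations >= 0)
  nr <- nrow(mask)
  nc <- ncol(mask)
  for (i in seq_len(iterations)) {
    if (!any(mask)) break
    p <- matrix(FALSE, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- mask
    keep <- p[1:nr, 1:nc] & p[1:nr, 2:(nc + 1L)] & p[1:nr, 3:(nc + 2L)] &
      p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 2:(nc + 1L)] & p[2:(nr + 1L), 3:(nc + 2L)] &
      p[3:(nr + 2L), 1:nc] & p[3:(nr + 2L), 2:(nc + 1L)] & p[3:(nr + 2L), 3:(nc + 2L)]
    mask <- keep
  }
  mask
}

#' Segment the cortex region from cortex-glia and nuclei masks
#'
#' Runs the four-step cortex segmentation: merge the two channel masks,
#' dilation fill ([dilation_fill()]), hole fill ([fill_holes()]), and the
#' erosion finetune ([erode_mask()]).
#'
#' @param cg,nuclei Binary masks of identical shape.
#' @param params A [segmentation_params()] list.
#' @return An object of class `cortex_segmentation`: a list with `mask`,
#'   `params`, and `area` (foreground pixel count).
#' @export
segment_cortex <- function(cg, nuclei, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  merged <- merge_masks(cg, nuclei)
  filled <- dilation_fill(merged, params$n, params$thresh)
  filled <- fill_holes(filled, params$hole_size, params$connectivity)
  mask <- erode_mask(filled, params$erosions)
  structure(list(mask = mask, params = params, area = sum(mask)),
            class = "cortex_segmentation")
}

#' @export
print.cortex_segmentation <- function(x, ...) {
  cat(sprintf("<cortex_segmentation> %d x %d, area %d px (n=%d, thresh=%.2f, hole_size=%d, erosions=%d)\n",
              nrow(x$mask), ncol(x$mask), x$area, x$params$n, x$params$thresh,
              x$params$hole_size, x$params$erosions))
  invisible(x)
}

cortex_mask <- function(cortex) {
  if (inherits(cortex, "cortex_segmentation")) cortex$mask else as_mask(cortex)
}

#' Overlap metrics between automated and manual cortex masks
#'
#' `OL/M` is the overlap area as a percent of the manual region (a
#' true-positive-rate proxy); `OL/A` is the overlap as a percent of the
#' automated region (its complement is a false-positive proxy).
#'
#' @param auto Automated mask or `cortex_segmentation`.
#' @param manual Manual (reference) mask.
#' @return One-row tibble: `ol_m`, `ol_a` (percent), `overlap_px`,
#'   `manual_px`, `auto_px`.
#' @export
overlap_metrics <- function(auto, manual) {
  a <- cortex_mask(auto)
  m <- cortex_mask(manual)
  if (!identical(dim(a), dim(m))) stop("masks must share a shape")
  a_px <- sum(a)
  m_px <- sum(m)
  if (m_px == 0L) stop("manual mask is empty: OL/M undefined")
  if (a_px == 0L) stop("automated mask is empty: OL/A undefined")
  ol <- sum(a & m)
  tibble::tibble(ol_m = 100 * ol / m_px, ol_a = 100 * ol / a_px,
                 overlap_px = ol, manual_px = m_px, auto_px = a_px)
}

#' Grid search over cortex-segmentation parameters
#'
#' Evaluates [segment_cortex()] for every combination of the supplied
#' parameter values against manually segmented reference masks, averaging
#' OL/M and OL/A over images. Rows are ranked by descending mean OL/M with
#' mean OL/A as tie-break, and the Pareto front of the two means is flagged.
#'
#' @param images A list of lists, each with elements `cg`, `nuclei`, and
#'   `manual` (binary masks of one plane).
#' @param n,thresh,hole_size,erosions Numeric vectors of candidate values.
#' @param connectivity Connectivity passed through to segmentation.
#' @return A tibble with one row per parameter combination: the four
#'   parameters, `mean_ol_m`, `mean_ol_a`, `rank`, and `pareto`.
#' @export
parameter_grid_search <- function(images, n = c(5, 10, 15, 20),
                                  thresh = c(0.05, 0.10, 0.15, 0.20),
                                  hole_size = c(1000, 2500, 5000, 10000),
                                  erosions = c(5, 10, 15), connectivity = 8) {
  if (length(images) == 0L) stop("need at least one image")
  grid <- tidyr::crossing(n = n, thresh = thresh, hole_size = hole_size,
                          erosions = erosions)
  res <- purrr::pmap_dfr(grid, function(n, thresh, hole_size, erosions) {
    p <- segmentation_params(n, thresh, hole_size, erosions, connectivity)
    m <- purrr::map_dfr(images, function(img) {
      seg <- segment_cortex(img$cg, img$nuclei, p)
      if (seg$area == 0L) {
        tibble::tibble(ol_m = 0, ol_a = 0)
      } else {
        overlap_metrics(seg, img$manual)[, c("ol_m", "ol_a")]
      }
    })
    tibble::tibble(n = n, thresh = thresh, hole_size = hole_size,
                   erosions = erosions, mean_ol_m = mean(m$ol_m),
                   mean_ol_a = mean(m$ol_a))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$mean_ol_m),
                        dplyr::desc(.data$mean_ol_a))
  res$rank <- seq_len(nrow(res))
  res$pareto <- pareto_front(res$mean_ol_m, res$mean_ol_a)
  res
}

# TRUE for rows not dominated (>= on both objectives, > on at least one).
pareto_front <- function(a, b) {
  vapply(seq_along(a), function(i) {
    dom <- a >= a[i] & b >= b[i] & (a > a[i] | b > b[i])
    !any(dom)
  }, logical(1))
}
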