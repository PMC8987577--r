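#' Coerce an object to a binary mask
#'
#' Binary masks are plain logical matrices and are the common currency of all
#' morphology steps in the pipeline. Numeric matrices are converted with
#' `x > 0`; `NA` pixels become background.
#'
#' @param x A logical or numeric matrix.
#' @return A logical matrix of the same dimensions.
#' @export
as_mask <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop("a mask must be a 2D matrix")
  m <- if (is.logical(x)) x else x > 0
  m[is.na(m)] <- FALSE
  attributes(m) <- list(dim = dim(m))
  m
}

#' Label connected components of a binary mask
#'
#' Foreground pixels are grouped into connected components. Labels are
#' assigned deterministically in row-major order of each component's first
#' pixel, so label 1 is always the component whose top-left-most pixel comes
#' first when scanning rows left to right.
#'
#' @param mask A binary mask (logical matrix, or numeric coerced via
#'   [as_mask()]).
#' @param connectivity Pixel connectivity, `8` (default; diagonal neighbors
#'   connect) or `4`.
#' @return An integer matrix of the same shape: `0` for background, `1..K`
#'   for the K components.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  connectivity <- match_connectivity(connectivity)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(EBImage::bwlabel(mask + 0))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 8L) lab <- merge_diagonal_labels(lab)
  relabel_row_major(lab)
}

match_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  connectivity
}

# bwlabel() is 4-connected; union labels that touch across either diagonal.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab)
  nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a <- lab[-nr, -nc]; b <- lab[-1L, -1L]
    s <- a > 0L & b > 0L & a != b
    p1 <- cbind(a[s], b[s])
    a <- lab[-1L, -nc]; b <- lab[-nr, -1L]
    s <- a > 0L & b > 0L & a != b
    pairs <- rbind(p1, cbind(a[s], b[s]))
  }
  if (is.null(pairs) || nrow(pairs) == 0L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find_root(pairs[k, 1L])
    rb <- find_root(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find_root, integer(1))
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  out
}

# Renumber labels 1..K by the row-major position of each component's first
# pixel (deterministic regardless of the labelling backend's scan order).
relabel_row_major <- function(lab) {
  fg <- lab > 0L
  if (!any(fg)) return(lab)
  nc <- ncol(lab)
  rm_index <- (row(lab) - 1L) * nc + col(lab)
  firsts <- tapply(rm_index[fg], lab[fg], min)
  old <- as.integer(names(firsts))
  new <- integer(max(old))
  new[old[order(firsts)]] <- seq_along(old)
  out <- lab
  out[fg] <- new[lab[fg]]
  out
}

#' Remove small foreground objects (despeckle)
#'
#' Every foreground connected component with area strictly below `min_size`
#' pixels is set to background; larger components are untouched. This is the
#' speck-removal step the thresholding decision tree uses to detect blown-out
#' binarizations.
#'
#' @inheritParams label_components
#' @param min_size Minimum component area, in pixels, to survive (default 75).
#' @return A binary mask.
#' @export
despeckle <- function(mask, min_size = 75, connectivity = 8) {
  mask <- as_mask(mask)
  if (min_size < 1) stop("min_size must be >= 1")
  if (!any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
  out
}

#' Total perimeter of a binary mask
#'
#' The perimeter estimator counts exposed unit pixel edges: for every
#' foreground pixel, each of its four edges that borders background or the
#' image boundary contributes 1. A single pixel has perimeter 4; a filled
#' k-by-k square has perimeter 4k.
#'
#' @inheritParams label_components
#' @return Total exposed-edge count (integer scalar); 0 for an empty mask.
#' @export
total_perimeter <- function(mask) {
  mask <- as_mask(mask)
  a <- sum(mask)
  if (a == 0L) return(0L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  nv <- if (nr > 1L) sum(mask[-nr, , drop = FALSE] & mask[-1L, , drop = FALSE]) else 0L
  nh <- if (nc > 1L) sum(mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE]) else 0L
  4L * a - 2L * (nv + nh)
}

# Per-pixel count of foreground 4-neighbors (border counts as background).
count_neighbors4 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core_r <- 2:(nr + 1L)
  core_c <- 2:(nc + 1L)
  p[core_r - 1L, core_c] + p[core_r + 1L, core_c] +
    p[core_r, core_c - 1L] + p[core_r, core_c + 1L]
}
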