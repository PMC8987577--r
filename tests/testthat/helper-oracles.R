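# Independent brute-force oracles for the morphology and threshold
# operators. Deliberately naive (per-pixel loops, breadth-first flood fill)
# so they share no code path with the implementations they check.

random_mask <- function(nr = 24, nc = 24, p = 0.3) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# flood-fill labeling oracle
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue) > 0) {
      q <- queue[[1]]
      queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        a <- q[1] + offs[k, 1]
        b <- q[2] + offs[k, 2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc &&
            mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nxt
          queue[[length(queue) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}

oracle_despeckle <- function(mask, min_size, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  out <- mask
  for (l in which(sizes < min_size)) out[lab == l] <- FALSE
  out
}

oracle_dilation_fill <- function(mask, n, thresh) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (mask[i, j]) next
    white <- 0L
    total <- 0L
    for (di in -n:n) for (dj in -n:n) {
      if (di == 0 && dj == 0) next
      if (di^2 + dj^2 > n^2) next
      a <- i + di
      b <- j + dj
      if (a < 1 || a > nr || b < 1 || b > nc) next
      total <- total + 1L
      if (mask[a, b]) white <- white + 1L
    }
    if (total > 0 && white / total > thresh) out[i, j] <- TRUE
  }
  out
}

oracle_erode_once <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (di in -1:1) for (dj in -1:1) {
      a <- i + di
      b <- j + dj
      if (a < 1 || a > nr || b < 1 || b > nc || !mask[a, b]) {
        out[i, j] <- FALSE
      }
    }
  }
  out
}

oracle_fill_holes <- function(mask, hole_size, connectivity = 8) {
  lab <- oracle_label(!mask, connectivity)
  if (max(lab) == 0) return(mask)
  out <- mask
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  for (l in seq_along(sizes)) {
    if (sizes[l] < hole_size && !(l %in% border)) out[lab == l] <- TRUE
  }
  out
}

# per-edge enumeration perimeter oracle
oracle_perimeter <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  p <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      a <- i + d[1]
      b <- j + d[2]
      if (a < 1 || a > nr || b < 1 || b > nc || !mask[a, b]) p <- p + 1L
    }
  }
  p
}

# exhaustive between-class variance maximization from raw pixel values
oracle_otsu <- function(x) {
  vals <- sort(unique(as.numeric(x)))
  best <- -Inf
  best_t <- NA_real_
  for (t in vals[-length(vals)]) {
    lo <- x[x <= t]
    hi <- x[x > t]
    sb <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (sb > best) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# minimum cross-entropy objective, evaluated exhaustively at all cuts
oracle_li_objective <- function(x) {
  shift <- min(x)
  y <- as.numeric(x) - shift + diff(range(x)) / 1e6
  vals <- sort(unique(y))
  ce <- vapply(vals[-length(vals)], function(t) {
    lo <- y[y <= t]
    hi <- y[y > t]
    -sum(lo) * log(mean(lo)) - sum(hi) * log(mean(hi))
  }, numeric(1))
  list(cuts = vals[-length(vals)] + shift - diff(range(x)) / 1e6, ce = ce)
}

# default per-channel denoising parameters of the pipeline
denoise_plane <- function(channels) {
  list(astrocyte = unsharp_mask(channels$astrocyte, 2, 20),
       cortex_glia = unsharp_mask(channels$cortex_glia, 2, 20),
       nuclei = unsharp_mask(channels$nuclei, 3, 20))
}

# binarize all three channels of a generated plane with the decision tree
binarize_plane <- function(plane) {
  dn <- denoise_plane(plane$channels)
  list(astrocyte = select_threshold(dn$astrocyte, "astrocyte")$mask,
       cortex_glia = select_threshold(dn$cortex_glia, "cortex_glia")$mask,
       nuclei = select_threshold(dn$nuclei, "nuclei")$mask)
}
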