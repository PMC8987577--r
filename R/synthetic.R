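#' Synthetic fixture specification
#'
#' Describes one synthetic 3-channel plane family emulating a longitudinal
#' section of the larval ventral nerve cord: a central horizontal neuropil
#' band (the middle third of rows) flanked by cortex, neuronal nuclei as
#' bright disks in the cortex, cortex glia as a thin mesh (control) grading
#' into sparse round blobs (globular), and astrocytes as interface cell
#' bodies plus thin processes, a controllable fraction of which extend into
#' the cortex.
#'
#' @param shape `c(rows, cols)`, default 256 x 256; rows must be at least 96
#'   to host the neuropil band.
#' @param n_planes Number of z-planes when generating a stack.
#' @param globularity In `[0, 1]`: 0 = fully mesh-like cortex glia,
#'   1 = fully globular.
#' @param infiltration_fraction In `[0, 1]`: target astrocyte-cortex overlap
#'   as a fraction of cortex area.
#' @param n_nuclei Number of neuronal nuclei disks.
#' @param n_cell_bodies Number of astrocyte cell bodies on the
#'   cortex-neuropil interface.
#' @param noise_sd Additive Gaussian noise, intensity units (default 3).
#' @param blur_sigma Gaussian blur of the rendered image, px (default 0.4).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(shape = c(256, 256), n_planes = 1, globularity = 0,
                         infiltration_fraction = 0.02, n_nuclei = 60,
                         n_cell_bodies = 8, noise_sd = 3, blur_sigma = 0.4,
                         seed = 1) {
  stopifnot(length(shape) == 2L, shape[1] >= 96, shape[2] >= 64,
            n_planes >= 1, globularity >= 0, globularity <= 1,
            infiltration_fraction >= 0, infiltration_fraction <= 1,
            n_nuclei >= 1, n_cell_bodies >= 0, noise_sd >= 0, blur_sigma >= 0)
  structure(list(shape = as.integer(shape), n_planes = as.integer(n_planes),
                 globularity = globularity,
                 infiltration_fraction = infiltration_fraction,
                 n_nuclei = as.integer(n_nuclei),
                 n_cell_bodies = as.integer(n_cell_bodies),
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Independent seed per (plane, stream); kept below 2^31.
plane_seed <- function(seed, z_index, stream) {
  as.integer((abs(as.numeric(seed)) * 7919 + z_index * 104729 +
                stream * 7907) %% 2147483647)
}

fixture_geometry_const <- function(shape) {
  nr <- shape[1]
  nc <- shape[2]
  margin <- 14L
  np_r0 <- floor(nr / 3) + 1L # neuropil band = middle third of rows
  np_r1 <- floor(2 * nr / 3)
  list(nr = nr, nc = nc, margin = margin, np_r0 = np_r0, np_r1 = np_r1,
       rind_width = 6L)
}

# Tissue occupies the frame inset by a background margin; the cortex is the
# tissue minus the neuropil interior. The cortex extends two rows into the
# middle-third band on each side: the glial sheath straddles the geometric
# interface, which keeps the band of the cortex-glia channel from being
# empty in a clean binarization. Keeping the cortex clear of the image
# border lets the dilation fill grow outward the same distance everywhere,
# which the erosion finetune then removes.
fixture_cortex_mask <- function(shape) {
  g <- fixture_geometry_const(shape)
  m <- matrix(FALSE, g$nr, g$nc)
  rows <- (g$margin + 1L):(g$nr - g$margin)
  cols <- (g$margin + 1L):(g$nc - g$margin)
  m[rows, cols] <- TRUE
  m[(g$np_r0 + 2L):(g$np_r1 - 2L), ] <- FALSE
  m
}

draw_disks <- function(mask, centers, radii, clip = NULL) {
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]
    c0 <- centers[i, 2]
    rad <- radii[i]
    rr <- max(1L, r0 - rad):min(nrow(mask), r0 + rad)
    cc <- max(1L, c0 - rad):min(ncol(mask), c0 + rad)
    patch <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= rad^2
    mask[rr, cc] <- mask[rr, cc] | patch
  }
  if (!is.null(clip)) mask <- mask & clip
  mask
}

# Seeded blue-noise-ish sampling: candidates in random order, kept when at
# least min_dist from all previously kept points.
sample_spaced_points <- function(region, n, min_dist) {
  idx <- which(region)
  idx <- idx[sample.int(length(idx))]
  rows <- ((idx - 1L) %% nrow(region)) + 1L
  cols <- ((idx - 1L) %/% nrow(region)) + 1L
  keep_r <- numeric(0)
  keep_c <- numeric(0)
  for (i in seq_along(idx)) {
    if (length(keep_r) == n) break
    if (length(keep_r) == 0L ||
        min((keep_r - rows[i])^2 + (keep_c - cols[i])^2) >= min_dist^2) {
      keep_r <- c(keep_r, rows[i])
      keep_c <- c(keep_c, cols[i])
    }
  }
  cbind(keep_r, keep_c)
}

# Voronoi-ridge mesh over the nuclei: a cortex pixel belongs to the mesh
# when its two nearest nuclei are nearly equidistant. Each ridge pixel is
# tagged by its nucleus pair so edges can be removed as globularity rises.
voronoi_mesh <- function(cortex, centers, ridge_width = 2) {
  idx <- which(cortex)
  nr <- nrow(cortex)
  px_r <- ((idx - 1L) %% nr) + 1L
  px_c <- ((idx - 1L) %/% nr) + 1L
  k <- nrow(centers)
  d2 <- matrix(0, length(idx), k)
  for (j in seq_len(k)) {
    d2[, j] <- (px_r - centers[j, 1])^2 + (px_c - centers[j, 2])^2
  }
  ord1 <- max.col(-d2)
  d1 <- sqrt(d2[cbind(seq_along(idx), ord1)])
  d2m <- d2
  d2m[cbind(seq_along(idx), ord1)] <- Inf
  ord2 <- max.col(-d2m)
  dsecond <- sqrt(d2m[cbind(seq_along(idx), ord2)])
  on_ridge <- (dsecond - d1) <= ridge_width
  pair_id <- paste(pmin(ord1, ord2), pmax(ord1, ord2))[on_ridge]
  list(idx = idx[on_ridge], pair_id = pair_id)
}

# Thin process paths descending from the cortex-neuropil interface into the
# cortex, drawn in non-overlapping column corridors; returns an ordered list
# of candidate infiltration pixels (linear indices), outermost last.
infiltration_candidates <- function(shape, body_cols_top, body_cols_bottom) {
  g <- fixture_geometry_const(shape)
  nr <- g$nr
  usable <- function(body_cols) {
    cols <- seq(g$margin + 4L, g$nc - g$margin - 4L, by = 5L)
    if (length(body_cols)) {
      ok <- vapply(cols, function(cc) all(abs(cc - body_cols) > 10), logical(1))
      cols <- cols[ok]
    }
    cols[sample.int(length(cols))]
  }
  paths <- list()
  extensions <- list()
  sides <- list(
    list(cols = usable(body_cols_top), start = g$np_r0 + 1L, dir = -1L,
         stop_row = g$margin + 1L),
    list(cols = usable(body_cols_bottom), start = g$np_r1 - 1L, dir = 1L,
         stop_row = nr - g$margin)
  )
  # interleave the two sides so truncation affects them evenly
  nmax <- max(lengths(lapply(sides, `[[`, "cols")))
  for (i in seq_len(nmax)) {
    for (s in sides) {
      if (i > length(s$cols)) next
      c0 <- s$cols[i]
      depth <- sample(40:72, 1L)
      rows <- seq(s$start, by = s$dir, length.out = depth)
      rows <- rows[rows >= g$margin + 1L & rows <= nr - g$margin &
                     (rows <= g$np_r0 + 1L | rows >= g$np_r1 - 1L)]
      jit <- cumsum(sample(c(-1L, 0L, 0L, 1L), length(rows), replace = TRUE))
      jit <- pmax(pmin(jit, 1L), -1L)
      cc <- c0 + jit
      # width 2: pixel plus its right neighbor
      pix <- rbind(cbind(rows, cc), cbind(rows, cc + 1L))
      ord <- order(rep(seq_along(rows), 2L))
      pix <- pix[ord, , drop = FALSE]
      paths[[length(paths) + 1L]] <- (pix[, 2L] - 1L) * nr + pix[, 1L]
      # reserve the corridor's remaining depth (straight continuation, no
      # further randomness) for high infiltration fractions; these pixels
      # sort after every sampled-depth pixel, so fixtures that never need
      # them are unaffected
      if (length(rows) == 0L) next
      r_end <- rows[length(rows)]
      c_end <- cc[length(cc)]
      bound <- s$stop_row
      ext_rows <- if (s$dir * (bound - r_end) > 0L) {
        seq(r_end + s$dir, bound, by = s$dir)
      } else integer(0)
      if (length(ext_rows)) {
        epix <- rbind(cbind(ext_rows, c_end), cbind(ext_rows, c_end + 1L))
        eord <- order(rep(seq_along(ext_rows), 2L))
        epix <- epix[eord, , drop = FALSE]
        extensions[[length(extensions) + 1L]] <- (epix[, 2L] - 1L) * nr +
          epix[, 1L]
      }
    }
  }
  c(unlist(paths), unlist(extensions))
}

#' Generate one synthetic 3-channel plane with ground truth
#'
#' Renders the three grayscale channels (astrocyte, cortex glia, nuclei) of
#' one plane of the fixture described by `spec`, together with the exact
#' ground truth: the cortex mask, the achieved astrocyte-cortex overlap in
#' pixels (steered to `infiltration_fraction * cortex area` by adding
#' process pixels one at a time), the cortex-glia perimeter, and all object
#' centers. Foreground renders at intensity 180 +/- 20, background at
#' 20 +/- 10, followed by Gaussian blur (`blur_sigma`) and additive Gaussian
#' noise (`noise_sd`), clipped to `[0, 255]`. All randomness derives from
#' `spec$seed`, split per plane and stream, so identical calls are
#' bit-identical.
#'
#' @param spec A [fixture_spec()].
#' @param z_index Plane index (0-based), used to split the random stream.
#' @param globularity,infiltration_fraction Optional per-plane overrides of
#'   the spec values (used for depth profiles).
#' @return A list with `channels` (named list of numeric matrices:
#'   `astrocyte`, `cortex_glia`, `nuclei`) and `truth` (list: `cortex_mask`,
#'   `true_infiltration_px`, `true_cg_perimeter`, `nuclei_centers`,
#'   `cell_body_centers`, `masks` with the noiseless binary channel masks).
#' @export
generate_plane <- function(spec, z_index = 0L, globularity = NULL,
                           infiltration_fraction = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- globularity %||% spec$globularity
  f <- infiltration_fraction %||% spec$infiltration_fraction
  stopifnot(g >= 0, g <= 1, f >= 0, f <= 1)
  geo <- fixture_geometry_const(spec$shape)
  cortex <- fixture_cortex_mask(spec$shape)
  cortex_area <- sum(cortex)

  # --- geometry stream ---
  set.seed(plane_seed(spec$seed, z_index, 1L))
  inner <- erode_mask(cortex, 8L)
  nuc_centers <- sample_spaced_points(inner, spec$n_nuclei, min_dist = 12)
  nuc_radii <- sample(4:7, nrow(nuc_centers), replace = TRUE)
  nuclei_mask <- draw_disks(matrix(FALSE, geo$nr, geo$nc), nuc_centers,
                            nuc_radii, clip = cortex)
  # midline cells: a sparse row of nuclei along the VNC midline, inside the
  # neuropil; they erode away during segmentation but give the nuclei
  # channel its physiological signal in the middle-third band
  mid_row <- round((geo$np_r0 + geo$np_r1) / 2)
  mid_cols <- seq(geo$margin + 16L, geo$nc - geo$margin - 16L, by = 38L)
  mid_centers <- cbind(mid_row + sample(-3:3, length(mid_cols), TRUE), mid_cols)
  mid_radii <- sample(6:7, length(mid_cols), replace = TRUE)
  nuclei_mask <- draw_disks(nuclei_mask, mid_centers, mid_radii)

  # cortex glia: persistent surface sheath (rind) + mesh/blob interpolation
  rind <- cortex & !erode_mask(cortex, geo$rind_width)
  mesh <- voronoi_mesh(cortex, nuc_centers, ridge_width = 2)
  edges <- unique(mesh$pair_id)
  edges <- edges[sample.int(length(edges))]
  keep_edges <- edges[seq_len(ceiling((1 - g) * length(edges)))]
  if (g >= 1) keep_edges <- character(0)
  mesh_mask <- matrix(FALSE, geo$nr, geo$nc)
  mesh_mask[mesh$idx[mesh$pair_id %in% keep_edges]] <- TRUE
  n_blob_max <- 12L
  blob_centers <- sample_spaced_points(inner, n_blob_max, min_dist = 30)
  blob_radii <- sample(8:14, nrow(blob_centers), replace = TRUE)
  n_blobs <- round(g * n_blob_max)
  blob_mask <- matrix(FALSE, geo$nr, geo$nc)
  if (n_blobs > 0) {
    blob_mask <- draw_disks(blob_mask,
                            blob_centers[seq_len(min(n_blobs, nrow(blob_centers))), , drop = FALSE],
                            blob_radii, clip = cortex)
  }
  cg_mask <- rind | mesh_mask | blob_mask

  # astrocytes: cell bodies tangent to the interface, inside the cortex
  n_top <- ceiling(spec$n_cell_bodies / 2)
  n_bot <- spec$n_cell_bodies - n_top
  body_radii <- sample(5:7, spec$n_cell_bodies, replace = TRUE)
  pick_cols <- function(n) {
    cand <- seq(geo$margin + 10L, geo$nc - geo$margin - 10L)
    out <- numeric(0)
    cand <- cand[sample.int(length(cand))]
    for (cc in cand) {
      if (length(out) == n) break
      if (length(out) == 0L || min(abs(out - cc)) >= 22) out <- c(out, cc)
    }
    out
  }
  cols_top <- pick_cols(n_top)
  cols_bot <- pick_cols(n_bot)
  body_centers <- rbind(
    if (n_top > 0) cbind((geo$np_r0 + 1L) - body_radii[seq_len(n_top)], cols_top),
    if (n_bot > 0) cbind((geo$np_r1 - 1L) + body_radii[n_top + seq_len(n_bot)], cols_bot)
  )
  astro_mask <- matrix(FALSE, geo$nr, geo$nc)
  if (spec$n_cell_bodies > 0) {
    astro_mask <- draw_disks(astro_mask, body_centers, body_radii)
  }
  # fine processes inside the neuropil (clipped out of AIS by construction);
  # each spans well over the 75-px despeckle size so clean binarizations are
  # not misread as blown out
  np_rows <- (geo$np_r0 + 2L):(geo$np_r1 - 2L)
  n_proc <- 14L
  len_max <- length(np_rows) - 1L
  len_lo <- min(55L, max(5L, round(0.7 * len_max)))
  len_hi <- min(75L, len_max)
  for (i in seq_len(n_proc)) {
    pick1 <- function(v) v[sample.int(length(v), 1L)] # length-1 safe
    c0 <- pick1(seq(geo$margin + 2L, geo$nc - geo$margin - 2L))
    len <- pick1(len_lo:len_hi)
    dir <- pick1(c(-1L, 1L))
    r0 <- if (dir == 1L) pick1(np_rows[np_rows + len <= max(np_rows)])
          else pick1(np_rows[np_rows - len >= min(np_rows)])
    rows <- r0 + seq_len(len) * dir
    jit <- pmax(pmin(cumsum(sample(c(-1L, 0L, 1L), length(rows), TRUE)), 2L), -2L)
    cc <- pmin(pmax(c0 + jit, 1L), geo$nc - 1L)
    astro_mask[cbind(rows, cc)] <- TRUE
    astro_mask[cbind(rows, cc + 1L)] <- TRUE
  }

  # steered infiltration: add candidate process pixels one at a time until
  # exactly the target overlap is reached
  target_px <- round(f * cortex_area)
  cand <- infiltration_candidates(spec$shape,
                                  body_cols_top = cols_top,
                                  body_cols_bottom = cols_bot)
  cand <- cand[!duplicated(cand)]
  cand <- cand[cortex[cand] & !astro_mask[cand]]
  if (length(cand) < target_px) {
    stop(sprintf("infeasible infiltration target: need %d px, only %d candidate px available",
                 target_px, length(cand)))
  }
  if (target_px > 0) astro_mask[cand[seq_len(target_px)]] <- TRUE

  truth <- list(
    cortex_mask = cortex,
    true_infiltration_px = as.integer(target_px),
    true_cg_perimeter = total_perimeter(cg_mask),
    nuclei_centers = unname(nuc_centers),
    cell_body_centers = unname(body_centers),
    masks = list(astrocyte = astro_mask, cortex_glia = cg_mask,
                 nuclei = nuclei_mask)
  )
  channels <- list(
    astrocyte = render_channel(astro_mask, spec, z_index, stream = 2L),
    cortex_glia = render_channel(cg_mask, spec, z_index, stream = 3L),
    nuclei = render_channel(nuclei_mask, spec, z_index, stream = 4L)
  )
  list(channels = channels, truth = truth)
}

# Staining intensity varies between planes, not within: foreground and
# background levels are drawn once per plane (180 +/- 20 and 20 +/- 10),
# and within-plane texture comes only from blur_sigma and noise_sd. A
# noiseless plane is therefore exactly two-valued and binarizes perfectly.
render_channel <- function(mask, spec, z_index, stream) {
  set.seed(plane_seed(spec$seed, z_index, stream))
  nr <- nrow(mask)
  nc <- ncol(mask)
  bg0 <- runif(1, 10, 30)
  fg0 <- runif(1, 160, 200)
  img <- matrix(bg0, nr, nc)
  img[mask] <- fg0
  if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
  if (spec$noise_sd > 0) img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd),
                                             nr, nc)
  img[img < 0] <- 0
  img[img > 255] <- 255
  round(img)
}

#' Generate a synthetic Z-stack with per-plane ground truth
#'
#' Calls [generate_plane()] for each z-plane, optionally varying globularity
#' and infiltration along depth (for sliding-window tests), and assembles a
#' `stack_record`. When `path` is given, the stack is also written as an
#' interleaved multi-page TIFF via [write_stack()].
#'
#' @param spec A [fixture_spec()].
#' @param globularity_profile,infiltration_profile Optional numeric vectors
#'   of length `spec$n_planes` overriding the spec values per plane.
#' @param animal_id,group Metadata for the resulting `stack_record`.
#' @param z_orientation Passed through to the record.
#' @param path Optional TIFF output path.
#' @return A list with `stack` (a `stack_record`) and `truths` (list of
#'   per-plane truth records).
#' @export
generate_stack <- function(spec, globularity_profile = NULL,
                           infiltration_profile = NULL,
                           animal_id = "fixture", group = "control",
                           z_orientation = "ventral_first", path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  k <- spec$n_planes
  if (!is.null(globularity_profile)) stopifnot(length(globularity_profile) == k)
  if (!is.null(infiltration_profile)) stopifnot(length(infiltration_profile) == k)
  planes <- vector("list", k)
  truths <- vector("list", k)
  for (z in seq_len(k)) {
    p <- generate_plane(spec, z_index = z - 1L,
                        globularity = globularity_profile[z],
                        infiltration_fraction = infiltration_profile[z])
    planes[[z]] <- p$channels
    truths[[z]] <- p$truth
  }
  stack <- new_stack_record(animal_id, group, z_orientation, planes)
  if (!is.null(path)) write_stack(stack, path)
  list(stack = stack, truths = truths)
}

#' Constructed images exercising the threshold decision tree
#'
#' Three small grayscale presets whose Otsu binarizations force each branch
#' of the decision tree by construction:
#' `"clean"` (bimodal, large smooth objects: Otsu retained),
#' `"blown_out"` (dense sub-75-px specks in the middle third: despeckling
#' removes at least 7% of band white pixels, forcing Triangle), and
#' `"blacked_out"` (one faint 10x10 object in a 100x100 frame: under 2%
#' white, forcing Li for nuclei / Yen for astrocytes).
#'
#' @param preset One of `"clean"`, `"blown_out"`, `"blacked_out"`.
#' @param seed Seed for the speck placement of the blown-out preset.
#' @return A numeric 100x100 matrix.
#' @export
fixture_threshold_image <- function(preset = c("clean", "blown_out", "blacked_out"),
                                    seed = 1) {
  preset <- match.arg(preset)
  img <- matrix(20, 100, 100)
  if (preset == "clean") {
    img[10:40, 10:90] <- 200
    img[60:90, 10:90] <- 200
  } else if (preset == "blown_out") {
    img[10:30, 10:90] <- 200 # large true object outside the band
    set.seed(as.integer(seed))
    # speckle the middle third with isolated bright 2x2 dots
    rs <- sample(seq(36, 64, by = 4))
    cs <- sample(seq(6, 94, by = 4), length(rs) * 8, replace = TRUE)
    for (i in seq_along(rs)) {
      for (cc in unique(cs[(i - 1) * 8 + 1:8])) {
        img[rs[i] + 0:1, cc + 0:1] <- 200
      }
    }
  } else {
    img[45:54, 45:54] <- 200 # 100 px white out of 10000 = 1% < 2%
  }
  img
}

#' Generate a synthetic score table with a planted AMI-AIS link
#'
#' Builds a long-format plane-score table for testing the statistics layer:
#' per-animal AMI levels are drawn around group means, per-plane AMI varies
#' around the animal level, and AIS follows the planted linear link
#' `ais = intercept + slope * ami + noise`. `slope = 0` yields null tables
#' for false-positive checks.
#'
#' @param n_per_group Animals per group.
#' @param groups Group labels.
#' @param group_ami Mean AMI per group (same length as `groups`).
#' @param ami_sd Between-animal AMI standard deviation.
#' @param within_sd Between-plane (within-animal) AMI standard deviation.
#' @param intercept,slope Planted link coefficients.
#' @param noise_sd AIS noise standard deviation.
#' @param n_planes Planes per animal; `z_norm` is spread evenly over 0-100.
#' @param seed Integer seed.
#' @return A score-table tibble (`animal_id`, `group`, `z_index`, `z_norm`,
#'   `ami`, `ais`).
#' @export
generate_score_table <- function(n_per_group = 10,
                                 groups = c("control", "driver1", "driver2"),
                                 group_ami = c(16, 12, 8), ami_sd = 2,
                                 within_sd = 0.5, intercept = 12,
                                 slope = -0.5, noise_sd = 0.5, n_planes = 11,
                                 seed = 1) {
  stopifnot(length(group_ami) == length(groups), is.finite(slope),
            noise_sd >= 0)
  set.seed(as.integer(seed))
  z_norm <- if (n_planes == 1) 0 else 100 * (seq_len(n_planes) - 1) / (n_planes - 1)
  rows <- purrr::map_dfr(seq_along(groups), function(gi) {
    purrr::map_dfr(seq_len(n_per_group), function(ai) {
      base_ami <- group_ami[gi] + rnorm(1, 0, ami_sd)
      ami <- base_ami + rnorm(n_planes, 0, within_sd)
      ais <- intercept + slope * ami + rnorm(n_planes, 0, noise_sd)
      tibble::tibble(
        animal_id = sprintf("%s_%02d", groups[gi], ai),
        group = groups[gi],
        z_index = seq_len(n_planes) - 1L,
        z_norm = z_norm,
        ami = ami,
        ais = ais
      )
    })
  })
  rows
}
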