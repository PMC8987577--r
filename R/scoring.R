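#' Label objects and compute their shape features
#'
#' Labels 8-connected foreground objects (deterministic row-major order, see
#' [label_components()]) and computes, per object: area (px), perimeter
#' (exposed-edge estimator, as in [total_perimeter()]), bounding box
#' (half-open `row0/col0/row1/col1`), extent (area divided by bounding-box
#' area), and roundness (`4 * pi * area / perimeter^2`, using the same
#' perimeter estimator). A large digital disk has roundness near
#' `pi^2 / 16` (~0.62) under this estimator; thin processes score far lower.
#'
#' @inheritParams label_components
#' @return A tibble with one row per object: `label`, `area`, `perimeter`,
#'   `extent`, `roundness`, `row0`, `col0`, `row1`, `col1`.
#' @export
label_objects <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  empty <- tibble::tibble(label = integer(), area = integer(),
                          perimeter = numeric(), extent = numeric(),
                          roundness = numeric(), row0 = integer(),
                          col0 = integer(), row1 = integer(), col1 = integer())
  if (!any(mask)) return(empty)
  lab <- label_components(mask, connectivity)
  fg <- lab > 0L
  labs <- lab[fg]
  # exposed edges per pixel; objects from different components are never
  # 4-adjacent, so summing per label gives each object's own perimeter
  exposed <- (4L - count_neighbors4(mask))[fg]
  rows <- row(lab)[fg]
  cols <- col(lab)[fg]
  k <- max(labs)
  area <- tabulate(labs, k)
  perim <- as.numeric(rowsum(exposed, labs)[, 1L])
  r0 <- as.integer(tapply(rows, labs, min))
  r1 <- as.integer(tapply(rows, labs, max)) + 1L
  c0 <- as.integer(tapply(cols, labs, min))
  c1 <- as.integer(tapply(cols, labs, max)) + 1L
  tibble::tibble(
    label = seq_len(k),
    area = area,
    perimeter = perim,
    extent = area / ((r1 - r0) * (c1 - c0)),
    roundness = 4 * pi * area / perim^2,
    row0 = r0, col0 = c0, row1 = r1, col1 = c1
  )
}

#' Astrocyte cell-body exclusion filter
#'
#' Thresholds on the three shape features that distinguish astrocyte cell
#' bodies (compact, round, mid-sized) from infiltrating processes (thin,
#' elongated): area range, minimum bounding-box extent, and minimum
#' roundness. The defaults are calibrated on the synthetic fixtures at their
#' default scale; all four cutoffs are configurable.
#'
#' @param min_area,max_area Area range (px) of a candidate cell body.
#' @param min_extent Minimum foreground/bounding-box ratio.
#' @param min_roundness Minimum `4 * pi * area / perimeter^2`.
#' @return A list of class `cell_body_filter`.
#' @export
cell_body_filter <- function(min_area = 50, max_area = 800,
                             min_extent = 0.6, min_roundness = 0.5) {
  stopifnot(min_area <= max_area, min_extent > 0, min_extent <= 1,
            min_roundness >= 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_extent = min_extent, min_roundness = min_roundness),
            class = "cell_body_filter")
}

#' Remove astrocyte cell bodies from a binary mask
#'
#' Deletes every object that satisfies all clauses of the filter
#' (`min_area <= area <= max_area`, `extent >= min_extent`, and
#' `roundness >= min_roundness`); all other objects are kept verbatim, so
#' aberrant infiltrating processes survive.
#'
#' @inheritParams label_components
#' @param filter A [cell_body_filter()].
#' @return A list with `mask` (filtered), `n_excluded`, and `excluded`
#'   (feature rows of the removed objects).
#' @export
exclude_cell_bodies <- function(mask, filter = cell_body_filter(),
                                connectivity = 8) {
  mask <- as_mask(mask)
  stopifnot(inherits(filter, "cell_body_filter"))
  feats <- label_objects(mask, connectivity)
  if (nrow(feats) == 0L) {
    return(list(mask = mask, n_excluded = 0L, excluded = feats))
  }
  is_body <- feats$area >= filter$min_area & feats$area <= filter$max_area &
    feats$extent >= filter$min_extent & feats$roundness >= filter$min_roundness
  if (!any(is_body)) {
    return(list(mask = mask, n_excluded = 0L, excluded = feats[0, ]))
  }
  lab <- label_components(mask, connectivity)
  drop <- feats$label[is_body]
  out <- mask & !matrix(lab %in% drop, nrow(mask), ncol(mask))
  list(mask = out, n_excluded = sum(is_body), excluded = feats[is_body, ])
}

#' Automated morphology index (AMI)
#'
#' AMI is the total perimeter of the cortex-glia binary mask divided by the
#' cortex area, expressed as a percent of that area. Mesh-like cortex glia
#' (long thin membranes) have high AMI; globular cortex glia have low AMI.
#' By default the full-plane cortex-glia mask is measured while normalizing
#' by the cortex area; `clip_to_cortex = TRUE` restricts the perimeter
#' measurement to the cortex region first.
#'
#' @param cg_mask Binary cortex-glia mask.
#' @param cortex A `cortex_segmentation` (or binary cortex mask).
#' @param clip_to_cortex Measure the perimeter on the cortex-clipped mask.
#' @return One-row tibble: `ami` (percent; `NA` when the cortex is empty),
#'   `cg_perimeter`, `cortex_area`.
#' @export
compute_ami <- function(cg_mask, cortex, clip_to_cortex = FALSE) {
  cg <- as_mask(cg_mask)
  cmask <- cortex_mask(cortex)
  area <- sum(cmask)
  if (area == 0L) {
    warning("zero cortex area: AMI undefined for this plane")
    return(tibble::tibble(ami = NA_real_, cg_perimeter = NA_real_,
                          cortex_area = 0L))
  }
  if (clip_to_cortex) {
    if (!identical(dim(cg), dim(cmask))) stop("masks must share a shape")
    cg <- cg & cmask
  }
  p <- total_perimeter(cg)
  tibble::tibble(ami = 100 * p / area, cg_perimeter = p, cortex_area = area)
}

#' Automated infiltration score (AIS)
#'
#' AIS is the astrocyte signal overlapping the cortex, after cell-body
#' exclusion, as a percent of the cortex area. The astrocyte mask is first
#' clipped to the cortex region; objects of the clipped mask are then
#' assessed against the cell-body filter and surviving pixels counted.
#'
#' @param astro_mask Binary astrocyte mask.
#' @param cortex A `cortex_segmentation` (or binary cortex mask).
#' @param filter A [cell_body_filter()].
#' @param connectivity Object connectivity.
#' @return One-row tibble: `ais` (percent; `NA` when the cortex is empty),
#'   `infiltration_px`, `n_excluded_bodies`, `cortex_area`.
#' @export
compute_ais <- function(astro_mask, cortex, filter = cell_body_filter(),
                        connectivity = 8) {
  astro <- as_mask(astro_mask)
  cmask <- cortex_mask(cortex)
  if (!identical(dim(astro), dim(cmask))) stop("masks must share a shape")
  area <- sum(cmask)
  if (area == 0L) {
    warning("zero cortex area: AIS undefined for this plane")
    return(tibble::tibble(ais = NA_real_, infiltration_px = NA_integer_,
                          n_excluded_bodies = NA_integer_, cortex_area = 0L))
  }
  clipped <- astro & cmask
  ex <- exclude_cell_bodies(clipped, filter, connectivity)
  infil <- sum(ex$mask)
  tibble::tibble(ais = 100 * infil / area, infiltration_px = infil,
                 n_excluded_bodies = ex$n_excluded, cortex_area = area)
}

#' Score one plane
#'
#' Assembles the per-plane score record from [compute_ami()] and
#' [compute_ais()] plus identity and diagnostics. A plane whose cortex is
#' empty gets missing scores (not zeros).
#'
#' @param astro_mask,cg_mask Binary channel masks.
#' @param cortex A `cortex_segmentation` (or binary cortex mask).
#' @param z_norm Normalized depth in `[0, 100]` (0 = ventral surface).
#' @param animal_id,group Stack identity carried into the score table.
#' @param z_index Acquisition plane index.
#' @param filter A [cell_body_filter()].
#' @param clip_to_cortex Passed to [compute_ami()].
#' @return One-row tibble: `animal_id`, `group`, `z_index`, `z_norm`, `ami`,
#'   `ais`, `cortex_area`, `cg_perimeter`, `infiltration_px`,
#'   `n_excluded_bodies`.
#' @export
score_plane <- function(astro_mask, cg_mask, cortex, z_norm,
                        animal_id = NA_character_, group = NA_character_,
                        z_index = NA_integer_, filter = cell_body_filter(),
                        clip_to_cortex = FALSE) {
  area <- sum(cortex_mask(cortex))
  if (area == 0L) {
    warning("zero cortex area: plane scores recorded as missing")
    return(tibble::tibble(
      animal_id = animal_id, group = group, z_index = z_index, z_norm = z_norm,
      ami = NA_real_, ais = NA_real_, cortex_area = 0L,
      cg_perimeter = NA_real_, infiltration_px = NA_integer_,
      n_excluded_bodies = NA_integer_))
  }
  morph <- compute_ami(cg_mask, cortex, clip_to_cortex)
  infil <- compute_ais(astro_mask, cortex, filter)
  tibble::tibble(
    animal_id = animal_id, group = group, z_index = z_index, z_norm = z_norm,
    ami = morph$ami, ais = infil$ais, cortex_area = area,
    cg_perimeter = morph$cg_perimeter, infiltration_px = infil$infiltration_px,
    n_excluded_bodies = infil$n_excluded_bodies)
}
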