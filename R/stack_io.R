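CHANNEL_NAMES <- c("astrocyte", "cortex_glia", "nuclei")

#' Default channel-to-biology mapping
#'
#' Maps TIFF color channels to cell types with the standard staining scheme:
#' red = astrocyte, green = cortex glia, blue = neuronal nuclei. Supply a
#' permutation of `c("astrocyte", "cortex_glia", "nuclei")` to
#' [read_stack()] for other schemes; position `i` names the biology of
#' channel `i`.
#'
#' @return Character vector of length 3.
#' @export
default_channel_map <- function() CHANNEL_NAMES

#' Read a 3-channel confocal Z-stack from a multi-page TIFF
#'
#' Accepts both common dialects: pages that each hold a `rows x cols x 3`
#' channel array (one page per z-plane), and interleaved single-channel
#' pages in channel order (3 pages per z-plane). Intensities are returned as
#' stored (8/16-bit integers stay integers).
#'
#' @param path Path to the TIFF file.
#' @param animal_id Identifier carried through the pipeline.
#' @param group Genotype/condition label.
#' @param z_orientation `"ventral_first"` or `"dorsal_first"`: which surface
#'   the first acquired plane is nearest to. Required metadata; the file
#'   itself cannot tell.
#' @param channel_map Permutation of the three channel names; see
#'   [default_channel_map()].
#' @param keep_range Optional `c(first, last)` plane indices (1-based,
#'   inclusive) to retain, for trimming out-of-focus planes at the stack
#'   ends.
#' @return A `stack_record`: list with `animal_id`, `group`,
#'   `z_orientation`, `planes` (list of named lists of channel matrices),
#'   and `z_index` (original acquisition indices).
#' @export
read_stack <- function(path, animal_id, group,
                       z_orientation = c("ventral_first", "dorsal_first"),
                       channel_map = default_channel_map(),
                       keep_range = NULL) {
  z_orientation <- match.arg(z_orientation)
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                   info = TRUE),
                    error = function(e) stop("unreadable TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  # as.is returns raw integers for grayscale pages only; rescale
  # multi-channel pages from [0, 1] using the stored bit depth
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L && max(p) <= 1) {
      bits <- attr(p, "bits.per.sample") %||% 8L
      p <- round(p * (2^bits - 1))
    }
    p
  })
  planes <- split_pages_to_planes(pages, channel_map)
  record <- new_stack_record(animal_id, group, z_orientation, planes)
  if (!is.null(keep_range)) record <- keep_planes(record, keep_range)
  record
}

split_pages_to_planes <- function(pages, channel_map) {
  stopifnot(length(channel_map) == 3L, setequal(channel_map, CHANNEL_NAMES))
  dims <- lapply(pages, dim)
  nd <- vapply(dims, length, integer(1))
  strip <- function(m) {
    attributes(m) <- list(dim = dim(m))
    m
  }
  if (all(nd == 3L)) {
    nch <- vapply(dims, function(d) d[3L], numeric(1))
    bad <- which(nch != 3L)
    if (length(bad)) stop("page ", bad[1L], " has ", nch[bad[1L]],
                          " channels; expected 3")
    planes <- lapply(pages, function(p) {
      setNames(list(strip(p[, , 1L]), strip(p[, , 2L]), strip(p[, , 3L])),
               channel_map)
    })
  } else if (all(nd == 2L)) {
    if (length(pages) %% 3L != 0L) {
      stop("interleaved single-channel TIFF must have a multiple of 3 pages; got ",
           length(pages), " (channel count is not 3)")
    }
    idx <- split(seq_along(pages), ceiling(seq_along(pages) / 3))
    planes <- lapply(idx, function(i) setNames(lapply(pages[i], strip),
                                               channel_map))
  } else {
    stop("mixed page layouts: page ", which(nd != nd[1L])[1L],
         " does not match page 1")
  }
  # reorder each plane's channels to the canonical astro/cg/nuclei order
  lapply(planes, function(pl) pl[CHANNEL_NAMES])
}

new_stack_record <- function(animal_id, group, z_orientation, planes) {
  if (length(planes) < 1L) stop("stack has no planes")
  shp <- dim(planes[[1L]][[1L]])
  for (k in seq_along(planes)) {
    for (ch in CHANNEL_NAMES) {
      d <- dim(planes[[k]][[ch]])
      if (!identical(d, shp)) {
        stop(sprintf("inconsistent plane shapes: plane %d channel %s is %dx%d, expected %dx%d",
                     k, ch, d[1], d[2], shp[1], shp[2]))
      }
      if (any(planes[[k]][[ch]] < 0, na.rm = TRUE)) {
        stop("negative intensities in plane ", k, " channel ", ch)
      }
    }
  }
  structure(list(animal_id = as.character(animal_id),
                 group = as.character(group),
                 z_orientation = z_orientation,
                 planes = unname(planes),
                 z_index = seq_along(planes) - 1L,
                 z_norm = NULL),
            class = "stack_record")
}

#' @export
print.stack_record <- function(x, ...) {
  shp <- dim(x$planes[[1]][[1]])
  cat(sprintf("<stack_record> %s (%s): %d planes of %dx%d, %s\n",
              x$animal_id, x$group, length(x$planes), shp[1], shp[2],
              x$z_orientation))
  invisible(x)
}

#' Restrict a stack to a range of planes
#'
#' Trims a stack to planes `keep_range[1]..keep_range[2]` (1-based,
#' inclusive), the mechanism for dropping out-of-focus planes at the start or
#' end of a stack. Original acquisition indices are preserved in `z_index`.
#'
#' @param stack A `stack_record`.
#' @param keep_range Integer vector `c(first, last)`.
#' @return A `stack_record`.
#' @export
keep_planes <- function(stack, keep_range) {
  stopifnot(inherits(stack, "stack_record"), length(keep_range) == 2L)
  k <- length(stack$planes)
  first <- max(1L, as.integer(keep_range[1L]))
  last <- min(k, as.integer(keep_range[2L]))
  if (first > last) stop("keep_range selects no planes")
  stack$planes <- stack$planes[first:last]
  stack$z_index <- stack$z_index[first:last]
  stack$z_norm <- NULL
  stack
}

#' Normalize stack depth to a 0-100 ventral-dorsal axis
#'
#' Assigns each retained plane a normalized depth `z_norm`, with the ventral
#' surface at 0 and the dorsal surface at 100: plane `k` of `K` (0-based)
#' gets `100 * k / (K - 1)` for a ventral-first stack, with indices reversed
#' for dorsal-first. A single-plane stack gets `z_norm = 0`.
#'
#' @param stack A `stack_record`.
#' @return The stack with `z_norm` populated.
#' @export
normalize_z <- function(stack) {
  stopifnot(inherits(stack, "stack_record"))
  k <- length(stack$planes)
  z <- if (k == 1L) 0 else 100 * (seq_len(k) - 1L) / (k - 1L)
  if (stack$z_orientation == "dorsal_first") z <- rev(z)
  stack$z_norm <- z
  stack
}

#' Write a stack to a multi-page TIFF
#'
#' Writes interleaved single-channel 8-bit pages (astrocyte, cortex-glia,
#' nuclei per plane), the dialect [read_stack()] reads back exactly.
#' Intensities must lie in `[0, 255]` and are rounded to integers.
#'
#' @param stack A `stack_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "stack_record"))
  pages <- list()
  for (pl in stack$planes) {
    for (ch in CHANNEL_NAMES) {
      img <- round(pl[[ch]])
      if (any(img < 0 | img > 255)) stop("intensities must be within [0, 255]")
      pages[[length(pages) + 1L]] <- img / 255
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
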