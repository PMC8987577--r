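#' Build a run configuration
#'
#' Assembles the full parameter set of an end-to-end run with the pipeline
#' defaults: unsharp amount 2 / radius 20 for the astrocyte and cortex-glia
#' channels and 3 / 20 for nuclei, the decision-tree constants of
#' [binarize_params()], the grid-search-selected [segmentation_params()],
#' and the [cell_body_filter()] defaults.
#'
#' @param stacks A list; each element describes one stack, either
#'   `list(path =, animal_id =, group =, z_orientation =, keep_range =)` or
#'   `list(stack = <stack_record>, keep_range =)` for in-memory stacks.
#' @param denoise Named list of per-channel `c(amount, radius)` pairs.
#' @param binarize A [binarize_params()] list.
#' @param segmentation A [segmentation_params()] list.
#' @param cell_bodies A [cell_body_filter()] list.
#' @param window List with `width`, `step`, `min_animals` for
#'   [sliding_window()].
#' @param clip_to_cortex Passed to [compute_ami()].
#' @param output_dir Directory for CSV/JSON outputs (`NULL` = in-memory
#'   only).
#' @param seed Run seed (the pipeline itself is deterministic; the seed is
#'   recorded and used by any downstream resampling).
#' @return A list of class `run_config`.
#' @export
run_config <- function(stacks,
                       denoise = list(astrocyte = c(2, 20),
                                      cortex_glia = c(2, 20),
                                      nuclei = c(3, 20)),
                       binarize = binarize_params(),
                       segmentation = segmentation_params(),
                       cell_bodies = cell_body_filter(),
                       window = list(width = 10, step = 1, min_animals = 3),
                       clip_to_cortex = FALSE,
                       output_dir = NULL,
                       seed = 1L) {
  stopifnot(length(stacks) >= 1L,
            all(CHANNEL_NAMES %in% names(denoise)))
  structure(list(stacks = stacks, denoise = denoise, binarize = binarize,
                 segmentation = segmentation, cell_bodies = cell_bodies,
                 window = window, clip_to_cortex = clip_to_cortex,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors the arguments of [run_config()]: a `stacks` sequence
#' (each with `path`, `animal_id`, `group`, `z_orientation`, optional
#' `keep_range`), plus optional `denoise`, `binarize`, `segmentation`,
#' `cell_bodies`, `window`, `clip_to_cortex`, `output_dir`, `seed` blocks
#' overriding the defaults. Relative stack paths are resolved against the
#' YAML file's directory.
#'
#' @param path Path to the YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$stacks)) stop("config must list at least one stack")
  base <- dirname(normalizePath(path))
  stacks <- lapply(y$stacks, function(s) {
    if (!is.null(s$path) && !grepl("^(/|[A-Za-z]:)", s$path)) {
      s$path <- file.path(base, s$path)
    }
    s
  })
  args <- list(stacks = stacks)
  if (!is.null(y$denoise)) {
    d <- lapply(y$denoise, as.numeric)
    dflt <- list(astrocyte = c(2, 20), cortex_glia = c(2, 20), nuclei = c(3, 20))
    args$denoise <- modifyList(dflt, d)
  }
  if (!is.null(y$binarize)) args$binarize <- do.call(binarize_params, y$binarize)
  if (!is.null(y$segmentation)) {
    args$segmentation <- do.call(segmentation_params, y$segmentation)
  }
  if (!is.null(y$cell_bodies)) args$cell_bodies <- do.call(cell_body_filter, y$cell_bodies)
  if (!is.null(y$window)) args$window <- y$window
  if (!is.null(y$clip_to_cortex)) args$clip_to_cortex <- isTRUE(y$clip_to_cortex)
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  if (!is.null(y$seed)) args$seed <- y$seed
  do.call(run_config, args)
}

resolve_stack <- function(entry) {
  stack <- if (!is.null(entry$stack)) {
    s <- entry$stack
    if (!is.null(entry$keep_range)) s <- keep_planes(s, entry$keep_range)
    s
  } else {
    read_stack(entry$path, entry$animal_id, entry$group,
               entry$z_orientation %||% "ventral_first",
               keep_range = entry$keep_range)
  }
  normalize_z(stack)
}

#' Score every plane of one stack
#'
#' Runs denoising, decision-tree thresholding of all three channels, cortex
#' segmentation, and plane scoring for each plane of a z-normalized stack.
#'
#' @param stack A `stack_record` with `z_norm` populated (see
#'   [normalize_z()]).
#' @param config A `run_config`.
#' @return A list with `scores` (plane-score tibble) and `decisions`
#'   (per-plane, per-channel threshold decision log).
#' @export
process_stack <- function(stack, config) {
  stopifnot(inherits(stack, "stack_record"), inherits(config, "run_config"))
  if (is.null(stack$z_norm)) stack <- normalize_z(stack)
  scores <- list()
  decisions <- list()
  for (k in seq_along(stack$planes)) {
    plane <- stack$planes[[k]]
    masks <- list()
    for (ch in CHANNEL_NAMES) {
      dn <- config$denoise[[ch]]
      img <- unsharp_mask(plane[[ch]], amount = dn[1], radius = dn[2])
      sel <- select_threshold(img, channel = ch, params = config$binarize)
      masks[[ch]] <- sel$mask
      dec <- sel$decision
      dec$animal_id <- stack$animal_id
      dec$z_index <- stack$z_index[k]
      decisions[[length(decisions) + 1L]] <- dec
    }
    cortex <- segment_cortex(masks$cortex_glia, masks$nuclei,
                             config$segmentation)
    scores[[k]] <- suppressWarnings(score_plane(
      masks$astrocyte, masks$cortex_glia, cortex,
      z_norm = stack$z_norm[k], animal_id = stack$animal_id,
      group = stack$group, z_index = stack$z_index[k],
      filter = config$cell_bodies, clip_to_cortex = config$clip_to_cortex))
  }
  list(scores = dplyr::bind_rows(scores),
       decisions = dplyr::bind_rows(decisions) |>
         dplyr::select("animal_id", "z_index", dplyr::everything()))
}

#' Run the full pipeline over a set of stacks
#'
#' For every stack: read, trim, z-normalize, denoise, threshold via the
#' decision tree, segment the cortex, and score each plane; then aggregate
#' per-animal global scores, dorsal-ventral sliding-window profiles, the
#' global AMI-AIS Spearman correlation, and Kruskal-Wallis/Dunn group
#' comparisons of the global scores. Failures are isolated per stack: the
#' run continues and failed stacks are reported in `failures`.
#'
#' When `config$output_dir` is set, writes `scores.csv`, `decisions.csv`,
#' `global_scores.csv`, `window_profile.csv` (each headed by a comment line
#' carrying the config hash) and `stats.json`. Identical configs produce
#' byte-identical outputs.
#'
#' @param config A `run_config` (or path to a YAML file for
#'   [read_run_config()]).
#' @return A list of class `pipeline_result`: `scores`, `decisions`,
#'   `global_scores`, `window_profile`, `stats` (list with `spearman`,
#'   `kruskal_ami`, `kruskal_ais`), `failures`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  # the hash identifies the analysis parameters, not where results are written
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  hash <- rlang::hash(cfg)
  all_scores <- list()
  all_decisions <- list()
  failures <- list()
  for (i in seq_along(config$stacks)) {
    entry <- config$stacks[[i]]
    res <- tryCatch({
      stack <- resolve_stack(entry)
      process_stack(stack, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      id <- entry$animal_id %||% entry$stack$animal_id %||% sprintf("stack %d", i)
      failures[[length(failures) + 1L]] <- tibble::tibble(
        animal_id = as.character(id), error = conditionMessage(res))
    } else {
      all_scores[[length(all_scores) + 1L]] <- res$scores
      all_decisions[[length(all_decisions) + 1L]] <- res$decisions
    }
  }
  if (length(all_scores) == 0L) stop("all stacks failed")
  scores <- dplyr::bind_rows(all_scores)
  decisions <- dplyr::bind_rows(all_decisions)
  global <- suppressWarnings(animal_global_scores(scores))
  windows <- sliding_window(scores, width = config$window$width,
                            step = config$window$step,
                            min_animals = config$window$min_animals %||% 3)
  stats <- list()
  complete <- global[!is.na(global$ami) & !is.na(global$ais), ]
  if (nrow(complete) >= 3L) {
    stats$spearman <- suppressWarnings(spearman_cor(complete$ami, complete$ais))
  }
  if (length(unique(global$group)) >= 2L && nrow(global) >= 3L) {
    stats$kruskal_ami <- kruskal_dunn(global, "ami", "group")
    stats$kruskal_ais <- kruskal_dunn(global, "ais", "group")
  }
  out <- structure(list(scores = scores, decisions = decisions,
                        global_scores = global, window_profile = windows,
                        stats = stats,
                        failures = dplyr::bind_rows(failures),
                        config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(config$output_dir)) write_run_outputs(out, config$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d planes, %d animals, %d failed stack(s) [config %s]\n",
              nrow(x$scores), nrow(x$global_scores), nrow(x$failures),
              substr(x$config_hash, 1, 8)))
  if (!is.null(x$stats$spearman)) {
    cat(sprintf("  global AMI~AIS Spearman rho = %.3f (p = %.3g)\n",
                x$stats$spearman$rho, x$stats$spearman$p_value))
  }
  invisible(x)
}

write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf("# gliatile config_hash=%s", result$config_hash)
  write_with_header <- function(df, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    write.csv(as.data.frame(df), con, row.names = FALSE)
  }
  write_with_header(result$scores, "scores.csv")
  write_with_header(result$decisions, "decisions.csv")
  write_with_header(result$global_scores, "global_scores.csv")
  write_with_header(result$window_profile, "window_profile.csv")
  stats <- list(config_hash = result$config_hash)
  if (!is.null(result$stats$spearman)) {
    stats$spearman <- as.list(result$stats$spearman)
  }
  for (nm in c("kruskal_ami", "kruskal_ais")) {
    if (!is.null(result$stats[[nm]])) {
      k <- result$stats[[nm]]
      stats[[nm]] <- list(h = k$h, df = k$df, p_value = k$p_value,
                          dunn = k$dunn)
    }
  }
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Validate a run against manual segmentations and scores
#'
#' Reproduces the validation analyses: overlap metrics of automated versus
#' manual cortex masks, the manual-versus-automated score regression with
#' discrepancy flagging, multi-rater ICC(3,k) on manual scores, and per-group
#' manual-versus-automated Kruskal-Wallis comparisons.
#'
#' @param result A `pipeline_result`.
#' @param config The `run_config` used to produce it (needed to re-segment
#'   planes when manual masks are supplied).
#' @param manual_masks Optional list of `list(animal_id, z_index, mask)`
#'   entries with manually traced cortex masks.
#' @param manual_scores Optional data frame with `animal_id` and any of
#'   `mis` (manual infiltration score, joined against global AIS), `mgs`
#'   (manual globularity score), and `rater` (for the ICC).
#' @return A list of class `validation_report` with `overlap` (tibble),
#'   `regression` (a `validation_regression` or `NULL`), `icc` (an `icc3k`
#'   or `NULL`), `group_comparison` (tibble of per-group Kruskal-Wallis
#'   p-values, manual vs automated), and `join_failures`.
#' @export
validate_run <- function(result, config, manual_masks = NULL,
                         manual_scores = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  join_failures <- character(0)
  overlap <- NULL
  if (!is.null(manual_masks)) {
    segs <- resegment_planes(config,
                             vapply(manual_masks, `[[`, "", "animal_id"),
                             vapply(manual_masks, function(m) as.integer(m$z_index), 1L))
    rows <- list()
    for (i in seq_along(manual_masks)) {
      mm <- manual_masks[[i]]
      seg <- segs[[i]]
      if (is.null(seg)) {
        join_failures <- c(join_failures,
                           sprintf("no plane %s/z=%d in run", mm$animal_id, mm$z_index))
        next
      }
      om <- tryCatch(overlap_metrics(seg, mm$mask), error = function(e) NULL)
      if (is.null(om)) {
        join_failures <- c(join_failures,
                           sprintf("empty mask for %s/z=%d", mm$animal_id, mm$z_index))
        next
      }
      om$animal_id <- mm$animal_id
      om$z_index <- mm$z_index
      rows[[length(rows) + 1L]] <- om
    }
    overlap <- dplyr::bind_rows(rows)
  }
  regression <- NULL
  icc <- NULL
  group_comparison <- NULL
  if (!is.null(manual_scores)) {
    joined <- dplyr::inner_join(result$global_scores, manual_scores,
                                by = "animal_id")
    missed <- setdiff(manual_scores$animal_id, result$global_scores$animal_id)
    if (length(missed)) {
      join_failures <- c(join_failures,
                         paste("manual scores without automated match:",
                               paste(missed, collapse = ", ")))
    }
    if ("mis" %in% names(joined) && nrow(joined) >= 3L) {
      one <- if ("rater" %in% names(joined)) {
        joined |>
          dplyr::group_by(.data$animal_id, .data$group, .data$ais) |>
          dplyr::summarise(mis = mean(.data$mis), .groups = "drop")
      } else joined
      regression <- validation_regression(one$mis, one$ais)
      long <- dplyr::bind_rows(
        tibble::tibble(group = one$group, score = one$mis, method = "manual"),
        tibble::tibble(group = one$group, score = one$ais, method = "automated"))
      group_comparison <- long |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(function(d, key) {
          if (length(unique(d$score)) < 2L) {
            return(tibble::tibble(p_value = 1))
          }
          kw <- stats::kruskal.test(d$score, factor(d$method))
          tibble::tibble(p_value = kw$p.value)
        }) |>
        dplyr::ungroup()
    }
    if (all(c("rater", "mgs") %in% names(manual_scores))) {
      wide <- manual_scores |>
        dplyr::select("animal_id", "rater", "mgs") |>
        tidyr::pivot_wider(names_from = "rater", values_from = "mgs")
      m <- as.matrix(wide[, -1])
      if (ncol(m) >= 2L && !anyNA(m)) icc <- icc3k(m)
    }
  }
  structure(list(overlap = overlap, regression = regression, icc = icc,
                 group_comparison = group_comparison,
                 join_failures = join_failures),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$overlap) && nrow(x$overlap)) {
    cat(sprintf("  segmentation overlap (%d plane(s)): mean OL/M %.2f, mean OL/A %.2f\n",
                nrow(x$overlap), mean(x$overlap$ol_m), mean(x$overlap$ol_a)))
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  manual-vs-auto regression: slope %.3f [%.3f, %.3f], r^2 %.3f\n",
                x$regression$slope, x$regression$slope_ci[1],
                x$regression$slope_ci[2], x$regression$r_squared))
  }
  if (!is.null(x$icc)) {
    cat(sprintf("  rater agreement ICC(3,k): %.3f\n", x$icc$icc))
  }
  if (!is.null(x$group_comparison)) {
    cat(sprintf("  group-wise manual-vs-auto comparisons: min p = %.3g\n",
                min(x$group_comparison$p_value)))
  }
  if (length(x$join_failures)) {
    cat("  join failures:\n")
    for (j in x$join_failures) cat("   -", j, "\n")
  }
  if (is.null(x$overlap) && is.null(x$regression) && is.null(x$icc) &&
        is.null(x$group_comparison) && !length(x$join_failures)) {
    cat("  (nothing to validate: no joinable manual inputs)\n")
  }
  invisible(x)
}

# Re-run segmentation for the requested (animal, plane) pairs only.
resegment_planes <- function(config, animal_ids, z_indices) {
  out <- vector("list", length(animal_ids))
  for (entry in config$stacks) {
    id <- entry$animal_id %||% entry$stack$animal_id
    hits <- which(animal_ids == id)
    if (length(hits) == 0L) next
    stack <- tryCatch(resolve_stack(entry), error = function(e) NULL)
    if (is.null(stack)) next
    for (h in hits) {
      k <- match(z_indices[h], stack$z_index)
      if (is.na(k)) next
      plane <- stack$planes[[k]]
      masks <- lapply(CHANNEL_NAMES, function(ch) {
        dn <- config$denoise[[ch]]
        select_threshold(unsharp_mask(plane[[ch]], dn[1], dn[2]), ch,
                         config$binarize)$mask
      })
      names(masks) <- CHANNEL_NAMES
      out[[h]] <- segment_cortex(masks$cortex_glia, masks$nuclei,
                                 config$segmentation)
    }
  }
  out
}
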