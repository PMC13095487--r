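# End-to-end driver: configuration, the per-image analysis chain, file
# round-trips, QC overlays and batch processing.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain with its default.
#' Serializable to/from plain YAML-like key=value text via
#' [write_pipeline_config()] / [read_pipeline_config()]; unknown keys are
#' rejected on read.
#'
#' @param pixel_size acquisition pixel size (um/px); `NA` = take from image.
#' @param target_pixel_size working resolution (default 0.26 um/px).
#' @param clarity background-subtraction strength in `[0, 1]`.
#' @param normalize run background normalization (default TRUE).
#' @param channel_order which input channel is analog 1 / analog 2.
#' @param threshold segmentation threshold (`"otsu"` or numeric).
#' @param smooth_sigma backend pre-smoothing sigma (px).
#' @param tile,overlap_fraction,blend_sigma tiling parameters.
#' @param tta enable test-time augmentation.
#' @param junction_cluster_px single-linkage junction clustering threshold.
#' @param radius_factor junction erasure radius (x fiber width).
#' @param min_branch_px minimum branch size (px).
#' @param trace_px endpoint direction trace length (px).
#' @param max_dist_factor endpoint matching radius (x fiber width).
#' @param match_weights matching cost weights (distance, angle, color).
#' @param min_total_px minimum fiber length (px).
#' @param min_segment_px minimum segment run (px).
#' @param border_margin border exclusion margin (px).
#' @param estimator length estimator (`"corner"` or `"naive"`).
#' @param error_filter apply the false-positive filter (default TRUE).
#' @param error_threshold filter rejection threshold (default 0.5).
#' @param tortuosity_max,curvature_max,intensity_floor scorer thresholds.
#' @param seed integer seed for any stochastic step.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = NA_real_,
                            target_pixel_size = 0.26,
                            clarity = 1,
                            normalize = TRUE,
                            channel_order = c(1, 2),
                            threshold = "otsu",
                            smooth_sigma = 1,
                            tile = 1024L,
                            overlap_fraction = 0.10,
                            blend_sigma = 0.125,
                            tta = FALSE,
                            junction_cluster_px = 10,
                            radius_factor = 1.5,
                            min_branch_px = 5,
                            trace_px = 15,
                            max_dist_factor = 3,
                            match_weights = c(0.15, 0.65, 0.2),
                            min_total_px = 15,
                            min_segment_px = 5,
                            border_margin = 1,
                            estimator = "corner",
                            error_filter = TRUE,
                            error_threshold = 0.5,
                            tortuosity_max = 1.5,
                            curvature_max = 0.3,
                            intensity_floor = 20,
                            seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain text
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_pipeline_config` returns a [pipeline_config()];
#'   unknown keys in the file are an error.
#' @export
write_pipeline_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", paste(format(config[[k]], digits = 12),
                           collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  defaults <- pipeline_config()
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    if (!key %in% names(defaults)) stop("unknown configuration key: ", key)
    raw <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(raw, ",", fixed = TRUE)[[1]])
    proto <- defaults[[key]]
    val <- if (is.character(proto) && suppressWarnings(
      all(is.na(as.numeric(parts))))) {
      parts
    } else if (is.logical(proto)) {
      as.logical(parts)
    } else {
      suppressWarnings({
        num <- as.numeric(parts)
        if (all(!is.na(num))) num else parts
      })
    }
    cfg[[key]] <- val
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Analyze a fluorescence image in memory
#'
#' Runs the full chain on a [fluor_image]: pixel-size standardization (when
#' the image's pixel size differs from the working resolution), background
#' normalization, segmentation (tiled for images larger than one tile),
#' junction disentanglement, measurement, feature extraction and
#' false-positive filtering.
#'
#' @param img a [fluor_image].
#' @param config a [pipeline_config()].
#' @return list with `records` (one data.frame row per fiber), `fibers`
#'   (cleaned fiber objects, same order), `mask`, `prob`,
#'   `reconstruction`, `image` (the preprocessed image).
#' @export
analyze_fluor_image <- function(img, config = pipeline_config()) {
  if (!is.na(config$pixel_size) && is.na(img$pixel_size))
    img$pixel_size <- config$pixel_size
  pp <- prep_params(target_pixel_size = config$target_pixel_size,
                    clarity = config$clarity)
  if (!is.na(img$pixel_size) &&
      abs(img$pixel_size - config$target_pixel_size) > 1e-6)
    img <- rescale_to_pixel_size(img, pp)
  if (config$normalize) img <- normalize_image(img, pp)
  backend <- threshold_backend(threshold = config$threshold,
                               smooth_sigma = config$smooth_sigma,
                               patch_size = config$tile)
  spec <- tile_spec(config$tile, config$overlap_fraction, config$blend_sigma)
  prob <- segment_image(img, backend, spec, tta = config$tta)
  mask <- prob_to_mask(prob)
  rec <- reconstruct_fibers(mask,
                            junction_cluster_px = config$junction_cluster_px,
                            radius_factor = config$radius_factor,
                            min_branch_px = config$min_branch_px,
                            trace_px = config$trace_px,
                            max_dist_factor = config$max_dist_factor,
                            weights = config$match_weights,
                            min_total_px = config$min_total_px,
                            min_segment_px = config$min_segment_px,
                            border_margin = config$border_margin)
  px_size <- if (!is.na(img$pixel_size)) img$pixel_size else
    config$target_pixel_size
  scorer <- default_error_scorer(config$tortuosity_max, config$curvature_max,
                                 config$intensity_floor)
  records <- fiber_records(rec$fibers, img, px_size, config$estimator,
                           scorer)
  if (config$error_filter && nrow(records) > 0)
    records <- apply_error_filter(records, config$error_threshold)
  list(records = records, fibers = rec$fibers, mask = mask, prob = prob,
       reconstruction = rec, image = img)
}

# One record row per fiber; the stable CSV schema (version 1).
FIBER_RECORD_COLUMNS <- c("fiber_id", "type", "n_segments", "analog1_um",
                          "analog2_um", "total_um", "ratio", "tortuosity",
                          "mean_curvature", "mean_intensity1",
                          "mean_intensity2", "error_prob", "valid")

fiber_records <- function(fibers, img, pixel_size, estimator, scorer) {
  if (length(fibers) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)),
                                     length(FIBER_RECORD_COLUMNS)),
                                 FIBER_RECORD_COLUMNS))
    df$type <- character(0); df$valid <- logical(0)
    return(df)
  }
  rows <- lapply(seq_along(fibers), function(i) {
    f <- fibers[[i]]
    m <- measure_fiber(f, pixel_size, estimator)
    ft <- fiber_features(f, img)
    data.frame(fiber_id = i, type = m$type,
               n_segments = nrow(m$segments),
               analog1_um = m$analog1_um, analog2_um = m$analog2_um,
               total_um = m$total_um, ratio = m$ratio,
               tortuosity = ft$tortuosity,
               mean_curvature = ft$mean_curvature,
               mean_intensity1 = ft$mean_intensity1,
               mean_intensity2 = ft$mean_intensity2,
               error_prob = scorer(ft),
               valid = m$valid && m$type != "invalid")
  })
  do.call(rbind, rows)
}

#' Analyze an image file and write results
#'
#' Reads the image (dual-channel file, or two single-channel files), runs
#' [analyze_fluor_image()], writes the per-fiber CSV and a QC overlay PNG
#' (fiber strokes colored by analog class; fibers marked invalid are drawn
#' dimmed).
#'
#' @param path image path (or channel-1 path when `path2` is given).
#' @param config a [pipeline_config()].
#' @param path2 optional channel-2 path.
#' @param out_dir output directory (default: the image's directory).
#' @return invisibly, the analysis list with `csv` and `overlay` paths
#'   added.
#' @export
analyze_image <- function(path, config = pipeline_config(), path2 = NULL,
                          out_dir = dirname(path)) {
  img <- read_fluor_image(path, path2, pixel_size = config$pixel_size,
                          channel_order = config$channel_order)
  res <- analyze_fluor_image(img, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- sub("\\.[^.]+$", "", basename(path))
  csv <- file.path(out_dir, paste0(base, "_fibers.csv"))
  write.csv(res$records, csv, row.names = FALSE)
  overlay <- file.path(out_dir, paste0(base, "_overlay.png"))
  write_overlay(res, overlay)
  res$csv <- csv
  res$overlay <- overlay
  invisible(res)
}

# RGB overlay: red = analog 1, green = analog 2 strokes on the (dimmed)
# image; invalid fibers at reduced opacity.
write_overlay <- function(res, path) {
  d <- dim(res$image)
  rgb <- array(0, c(d, 3))
  for (k in 1:2) {
    ch <- img_channel(res$image, k)
    mx <- max(ch)
    rgb[, , k] <- if (mx > 0) 0.4 * ch / mx else ch
  }
  if (length(res$fibers) > 0) {
    for (i in seq_along(res$fibers)) {
      f <- res$fibers[[i]]
      ok <- if (nrow(res$records) >= i) res$records$valid[i] else TRUE
      gain <- if (ok) 1 else 0.45
      m <- stamp_discs(matrix(FALSE, d[1], d[2]), f$path, 1.5)
      px <- which(m, arr.ind = TRUE)
      lab <- res$mask[px]
      r1 <- px[lab != ANALOG2, , drop = FALSE]
      r2 <- px[lab == ANALOG2, , drop = FALSE]
      if (nrow(r1)) rgb[cbind(r1, 1)] <- gain
      if (nrow(r2)) rgb[cbind(r2, 2)] <- gain
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Batch-analyze a set of images grouped by condition
#'
#' Processes every file, concatenating the per-fiber records with
#' `condition` and `source` columns. Failures on individual files are
#' recorded and the batch continues. Conditions come from a manifest
#' (data.frame `file`, `condition`) or from a regular expression with one
#' capture group applied to the file name.
#'
#' @param paths character vector of image paths.
#' @param config a [pipeline_config()].
#' @param manifest optional data.frame `file`, `condition`.
#' @param condition_pattern fallback regex (first capture group) applied to
#'   the base file name; default: everything before the last underscore.
#' @param out_dir optional output directory for per-image results.
#' @return list `records` (combined data.frame), `failures` (data.frame
#'   `file`, `error`), `summary` (per-condition [compare_to_reference()]
#'   when >= 2 conditions succeed).
#' @export
batch_analyze <- function(paths, config = pipeline_config(),
                          manifest = NULL,
                          condition_pattern = "^(.*)_[^_]*$",
                          out_dir = NULL) {
  if (length(paths) == 0) {
    warning("no input files")
    return(list(records = data.frame(), failures = data.frame(),
                summary = NULL))
  }
  all_rec <- list()
  failures <- data.frame(file = character(0), error = character(0))
  for (p in paths) {
    res <- tryCatch({
      if (!is.null(out_dir)) analyze_image(p, config, out_dir = out_dir)
      else {
        img <- read_fluor_image(p, pixel_size = config$pixel_size,
                                channel_order = config$channel_order)
        analyze_fluor_image(img, config)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(file = p, error = conditionMessage(res)))
      next
    }
    rec <- res$records
    base <- basename(p)
    cond <- if (!is.null(manifest)) {
      i <- match(base, basename(manifest$file))
      if (is.na(i)) NA_character_ else manifest$condition[i]
    } else {
      m <- regmatches(base, regexec(condition_pattern, sub("\\.[^.]+$", "",
                                                           base)))[[1]]
      if (length(m) >= 2) m[2] else sub("\\.[^.]+$", "", base)
    }
    if (nrow(rec) > 0) {
      rec$condition <- cond
      rec$source <- base
    } else {
      rec$condition <- character(0)
      rec$source <- character(0)
    }
    all_rec[[length(all_rec) + 1]] <- rec
  }
  records <- if (length(all_rec)) do.call(rbind, all_rec) else data.frame()
  summary <- NULL
  if (nrow(records) > 0) {
    valid <- records[records$valid & records$n_segments == 2 &
                       is.finite(records$ratio), ]
    conds <- split(valid$ratio, valid$condition)
    conds <- conds[lengths(conds) > 0]
    if (length(conds) >= 2)
      summary <- compare_to_reference(conds, B = 500, seed = config$seed)
  }
  list(records = records, failures = failures, summary = summary)
}
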