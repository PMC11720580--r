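# Configuration, table I/O and the command-line interface.

#' Default run configuration
#'
#' Every parameter has a documented default; [read_config()] rejects keys
#' that do not appear here.
#'
#' @return nested named list with blocks `preprocess`, `segment`,
#'   `quantify`, `morphology`, `flim`, `ocr`, `synth` and globals `seed`,
#'   `output_dir`, `strict`.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      sigma_small = 1,            # despeckle kernel scale, px
      sigma_large = 52,           # background kernel scale, px (~4x cell diameter)
      method = "gaussian",        # despeckle filter: gaussian | median
      background_mode = "mask_excluded",  # or sampled_rois
      correction = "divide",      # divide | subtract
      cell_scale = 13             # expected cell diameter, px
    ),
    segment = list(
      w = 25L, s = 0.1, connectivity = 8L,
      min_area = 30, max_area = 5000,
      w_grid = c(15L, 25L, 35L), s_grid = c(0.05, 0.1, 0.2)
    ),
    quantify = list(
      aggregation = "per_cell",   # per_cell | per_image pooling for ratios
      wound_window = 25L
    ),
    morphology = list(
      w = 9L, s = 0.15,           # smaller window for tubular structures
      min_area = 4, max_area = Inf,
      prune = 4,                  # spur-pruning length, px
      junction_merge_dist = 2     # junction-node merge radius, px
    ),
    flim = list(min_counts = 20, fit_start = "peak", min_rois = 18L),
    ocr = list(strict = FALSE, min_n = 6L),
    synth = list(),               # scene_params()/mito_scene_params() overrides
    seed = 1L,
    output_dir = ".",
    strict = FALSE
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(base))
      stop_fq("unknown configuration key '%s'", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(override[[key]]))
        stop_fq("configuration key '%s' must be a block", full)
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a YAML configuration file
#'
#' Values override [default_config()]; unknown keys are rejected. The
#' `synth` block is passed through unchecked (its keys are the
#' [scene_params()] arguments).
#'
#' @param path YAML file path.
#' @return full configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  base <- default_config()
  synth <- raw$synth
  raw$synth <- NULL
  cfg <- merge_config(base, raw)
  if (!is.null(synth)) cfg$synth <- synth
  cfg
}

#' Write a configuration file
#'
#' @param config configuration list.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  fnv1a32(yaml::as.yaml(config))
}

#' Write a results table as CSV with a provenance header
#'
#' RFC-4180 CSV ('.' decimal separator) preceded by a comment line carrying
#' the package version and a configuration fingerprint. Read back with
#' `read.csv(..., comment.char = "#")`.
#'
#' @param df data.frame.
#' @param path output path.
#' @param config configuration list used for the run (hashed into the
#'   header).
#' @export
write_table <- function(df, path, config = default_config()) {
  ver <- as.character(utils::packageVersion("fluoquant"))
  header <- sprintf("# fluoquant %s config=%s", ver, config_hash(config))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Command-line interface. Subcommands: synth, segment, tune, quantify,
# stats, morph, flim, ocr, pipeline. Returns an exit status (0 success,
# 2 input error, 3 stage failure) instead of quitting, so it is testable;
# the installed script in exec/ wraps it with quit().

cli_log <- function(fmt, ...) message(sprintf(fmt, ...))

#' Command-line entry point
#'
#' @param args character vector of command-line arguments (first element:
#'   the subcommand).
#' @return integer exit status: 0 success, 2 input error, 3 stage failure.
#' @export
fluoquant_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: fluoquant <synth|segment|tune|quantify|stats|morph|flim|ocr|pipeline> [options]\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  handler <- switch(cmd,
    synth = cli_synth, segment = cli_segment, tune = cli_tune,
    quantify = cli_quantify, stats = cli_stats, morph = cli_morph,
    flim = cli_flim, ocr = cli_ocr, pipeline = cli_pipeline,
    NULL)
  if (is.null(handler)) {
    cli_log("unknown subcommand '%s'", cmd)
    return(invisible(2L))
  }
  status <- tryCatch({
    handler(rest)
    0L
  },
  fluoquant_error = function(e) { cli_log("error: %s", conditionMessage(e)); 3L },
  error = function(e) { cli_log("input error: %s", conditionMessage(e)); 2L })
  invisible(status)
}

cli_config <- function(opts) {
  cfg <- if (!is.null(opts$config)) read_config(opts$config)
         else default_config()
  cli_log("config hash: %s", config_hash(cfg))
  cfg
}

make_parser <- function(...) {
  optparse::OptionParser(option_list = list(...),
                         add_help_option = TRUE)
}

opt <- optparse::make_option

cli_synth <- function(args) {
  p <- make_parser(
    opt("--out", type = "character", default = "."),
    opt("--seed", type = "integer", default = 1L),
    opt("--kind", type = "character", default = "cells",
        help = "cells | mito"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  sp_args <- cfg$synth
  sp_args$seed <- o$seed
  scene <- if (o$kind == "mito")
    make_mito_scene(do.call(mito_scene_params, sp_args))
  else
    make_cell_scene(do.call(scene_params, sp_args))
  paths <- write_scene(scene, o$out, prefix = paste0(o$kind, "_", o$seed))
  cli_log("wrote %d files to %s", length(paths), o$out)
}

cli_segment <- function(args) {
  p <- make_parser(
    opt("--image", type = "character"), opt("--seeds", type = "character"),
    opt("--w", type = "integer", default = 25L),
    opt("--s", type = "double", default = 0.1),
    opt("--connectivity", type = "integer", default = 8L),
    opt("--min-area", type = "double", default = 30, dest = "min_area"),
    opt("--max-area", type = "double", default = 5000, dest = "max_area"),
    opt("--out", type = "character", default = "labels.tif"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  cfg$segment$w <- o$w; cfg$segment$s <- o$s
  cfg$segment$connectivity <- o$connectivity
  cfg$segment$min_area <- o$min_area; cfg$segment$max_area <- o$max_area
  res <- run_pipeline(o$image, o$seeds, cfg, tune = FALSE)
  write_image(res$selection$labels, o$out)
  if (nrow(res$selection$missed) > 0)
    cli_log("MISSED_SEEDS n=%d", nrow(res$selection$missed))
  if (res$selection$merges > 0)
    cli_log("SEED_MERGES n=%d", res$selection$merges)
  cli_log("wrote %s (%d objects)", o$out, max(res$selection$labels))
}

cli_tune <- function(args) {
  p <- make_parser(
    opt("--image", type = "character"), opt("--seeds", type = "character"),
    opt("--out", type = "character", default = "tune.csv"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  img <- read_image(o$image)
  seeds <- utils::read.csv(o$seeds, comment.char = "#")
  pp <- cfg$preprocess
  corr <- correct_background(
    despeckle(img, pp$sigma_small),
    estimate_background(img, pp$sigma_large, cell_scale = pp$cell_scale))
  rep <- tune_parameters(corr, seeds, w_grid = cfg$segment$w_grid,
                         s_grid = cfg$segment$s_grid,
                         min_area = cfg$segment$min_area,
                         max_area = cfg$segment$max_area)
  write_table(rep$grid, o$out, cfg)
  cli_log("best: w=%d s=%.3f rate=%.3f", rep$best_w, rep$best_s,
          rep$best_rate)
}

cli_quantify <- function(args) {
  p <- make_parser(
    opt("--image", type = "character"), opt("--seeds", type = "character"),
    opt("--image-id", type = "character", default = "img", dest = "image_id"),
    opt("--out", type = "character", default = "measurements.csv"),
    opt("--no-tune", action = "store_true", default = FALSE, dest = "no_tune"),
    opt("--save-intermediates", type = "character", default = NULL,
        dest = "save_intermediates"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  res <- run_pipeline(o$image, o$seeds, cfg, tune = !o$no_tune,
                      save_intermediates = o$save_intermediates)
  df <- cbind(image_id = o$image_id,
              res$measurements[, c("label", "area_px", "mean_intensity")])
  write_table(df, o$out, cfg)
  cli_log("wrote %s (%d cells; w=%d s=%.3f)", o$out, nrow(df),
          res$params_used$w, res$params_used$s)
}

cli_stats <- function(args) {
  p <- make_parser(
    opt("--values", type = "character",
        help = "CSV with columns group,value"),
    opt("--out", type = "character", default = "stats.csv"),
    opt("--alpha", type = "double", default = 0.05),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  df <- utils::read.csv(o$values, comment.char = "#")
  res <- anova_tukey(split(df$value, df$group), alpha = o$alpha)
  out <- res$tukey
  out$F <- res$F; out$p_anova <- res$p
  write_table(out, o$out, cfg)
  cli_log("F = %.4g, p = %.4g", res$F, res$p)
}

cli_morph <- function(args) {
  p <- make_parser(
    opt("--image", type = "character"),
    opt("--image-id", type = "character", default = "img", dest = "image_id"),
    opt("--out", type = "character", default = "morphology.csv"),
    opt("--network-out", type = "character", default = "network.csv",
        dest = "network_out"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  img <- read_image(o$image)
  mp <- cfg$morphology
  mask <- bradley_threshold(img, segment_params(w = mp$w, s = mp$s,
                                                min_area = mp$min_area,
                                                max_area = min(mp$max_area, length(img))))
  labels <- filter_by_area(label_components(mask, 8L), mp$min_area,
                           mp$max_area)
  morph <- object_metrics(labels)
  nw <- network_metrics(skeletonize(labels > 0, prune = mp$prune),
                        junction_merge_dist = mp$junction_merge_dist)
  write_table(cbind(image_id = o$image_id, morph), o$out, cfg)
  write_table(cbind(image_id = o$image_id, nw$per_network), o$network_out, cfg)
  cli_log("objects: %d; branches: %d; junctions: %d",
          nrow(morph), nw$branches, nw$junctions)
}

cli_flim <- function(args) {
  p <- make_parser(
    opt("--decays", type = "character",
        help = "long-format CSV: roi_id,time_ns,counts"),
    opt("--out", type = "character", default = "lifetimes.csv"),
    opt("--min-counts", type = "double", default = 20, dest = "min_counts"),
    opt("--fit-start", type = "character", default = "peak",
        dest = "fit_start"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  df <- utils::read.csv(o$decays, comment.char = "#")
  fit_start <- if (o$fit_start == "peak") "peak" else as.integer(o$fit_start)
  rois <- split(df, df$roi_id)
  res <- lapply(names(rois), function(id) {
    f <- fit_monoexp(list(time_ns = rois[[id]]$time_ns,
                          counts = rois[[id]]$counts),
                     fit_start = fit_start, min_counts = o$min_counts)
    data.frame(roi_id = id, tau_ns = f$tau_ns, chi2red = f$chi2_reduced,
               converged = f$converged)
  })
  out <- do.call(rbind, res)
  write_table(out, o$out, cfg)
  if (any(!out$converged)) cli_log("NON_CONVERGED n=%d", sum(!out$converged))
  cli_log("wrote %s (%d ROIs, mean tau = %.4f ns)", o$out, nrow(out),
          mean(out$tau_ns))
}

cli_ocr <- function(args) {
  p <- make_parser(
    opt("--traces", type = "character",
        help = "CSV: well,group,time_min,ocr_pmol_min,phase"),
    opt("--out", type = "character", default = "stress_metrics.csv"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  df <- utils::read.csv(o$traces, comment.char = "#")
  wells <- split(df, df$well)
  res <- lapply(wells, function(wdf) {
    wdf <- wdf[order(wdf$time_min), ]
    b <- cumsum(rle(wdf$phase)$lengths)[1:3]
    m <- stress_metrics(ocr_trace(wdf$time_min, wdf$ocr_pmol_min, b,
                                  well = wdf$well[1], group = wdf$group[1]))
    data.frame(well = m$well, group = m$group, non_mito = m$non_mito,
               basal = m$basal, atp_linked = m$atp_linked,
               maximal = m$maximal, spare = m$spare)
  })
  out <- do.call(rbind, res)
  write_table(out, o$out, cfg)
  cli_log("wrote %s (%d wells)", o$out, nrow(out))
}

cli_pipeline <- function(args) {
  p <- make_parser(
    opt("--image", type = "character"), opt("--seeds", type = "character"),
    opt("--out-dir", type = "character", default = "fluoquant_out",
        dest = "out_dir"),
    opt("--save-intermediates", action = "store_true", default = FALSE,
        dest = "save_intermediates"),
    opt("--config", type = "character", default = NULL))
  o <- optparse::parse_args(p, args)
  cfg <- cli_config(o)
  dir.create(o$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_pipeline(o$image, o$seeds, cfg, tune = TRUE,
                      save_intermediates = if (o$save_intermediates) o$out_dir)
  write_table(res$measurements, file.path(o$out_dir, "measurements.csv"), cfg)
  if (!is.null(res$tune_report))
    write_table(res$tune_report$grid, file.path(o$out_dir, "tune.csv"), cfg)
  cli_log("pipeline done: %d cells measured (w=%d, s=%.3f)",
          nrow(res$measurements), res$params_used$w, res$params_used$s)
}
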