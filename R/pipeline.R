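#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults pin the reference
#' processing constants: vessel threshold at tissue mean + 1.96 SD, 3-voxel
#' 3D median filter on, minimum segment radius of one isotropic voxel, bin
#' widths 5 µm (length), 1 µm (diameter) and 0.1 (tortuosity).
#'
#' @param input path to a TIFF stack, or NULL when a phantom/volume is passed
#'   to [run_pipeline()] directly.
#' @param spacing voxel spacing (dy, dx, dz) in µm.
#' @param target isotropic resampling target in µm (NULL = smallest spacing).
#' @param smooth histogram smoothing width (grey levels).
#' @param z vessel-threshold multiplier.
#' @param median_filter apply the 3x3x3 majority filter.
#' @param min_radius artifact-removal radius limit in µm (NULL = one voxel).
#' @param bin_length,bin_diameter,bin_tortuosity frequency-class widths.
#' @param seed RNG seed for any stochastic stage.
#' @param output_dir where to write artifacts (NULL = nothing written).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(input = NULL, spacing = c(1, 1, 1), target = NULL,
                            smooth = 11L, z = 1.96, median_filter = TRUE,
                            min_radius = NULL, bin_length = 5,
                            bin_diameter = 1, bin_tortuosity = 0.1,
                            seed = 1L, output_dir = NULL) {
  cfg <- list(input = input, spacing = spacing, target = target,
              smooth = smooth, z = z, median_filter = median_filter,
              min_radius = min_radius, bin_length = bin_length,
              bin_diameter = bin_diameter, bin_tortuosity = bin_tortuosity,
              seed = seed, output_dir = output_dir)
  num <- c(cfg$spacing, cfg$smooth, cfg$z, cfg$bin_length, cfg$bin_diameter,
           cfg$bin_tortuosity)
  stopifnot(all(num > 0))
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full quantification pipeline on one sample
#'
#' Volume (TIFF or in-memory) -> 8-bit conversion -> isotropic resampling ->
#' two-threshold segmentation -> 3D median filter -> skeletonization +
#' distance map -> fusion -> graph extraction -> artifact removal -> global
#' metrics, per-segment records, and frequency-distribution fits. Given the
#' same configuration and seed the run is deterministic. Every threshold and
#' fitted parameter is returned (and logged to `log` lines) so a run is
#' auditable.
#'
#' @param cfg a `PipelineConfig`.
#' @param volume optional in-memory `VolumeImage` (overrides `cfg$input`).
#' @return List: `model` (`HistogramModel`), `masks`, `skeleton`, `graph`,
#'   `metrics` (`GlobalMetrics`), `segments` (record table), `fits`
#'   (length/diameter/tortuosity `FitResult`s or NULL when too few segments),
#'   `log` (character).
#' @export
run_pipeline <- function(cfg, volume = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  logl <- character(0)
  say <- function(...) logl <<- c(logl, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  v <- stage("load", {
    if (!is.null(volume)) volume
    else if (!is.null(cfg$input)) load_stack(cfg$input, cfg$spacing)
    else stop("no input volume")
  })
  say("input '%s': %s voxels, spacing (%g, %g, %g) um", v$name,
      paste(dim(v$voxels), collapse = "x"),
      v$spacing[1], v$spacing[2], v$spacing[3])
  v <- stage("to_8bit", to_8bit(v))
  target <- if (is.null(cfg$target)) min(v$spacing) else cfg$target
  if (!is_isotropic(v) || abs(v$spacing[1] - target) > 1e-9)
    v <- stage("resample", resample_isotropic(v, target))
  say("isotropic grid: %s at %g um", paste(dim(v$voxels), collapse = "x"),
      v$spacing[1])
  seg <- stage("segmentation",
               segment_volume(v, smooth = cfg$smooth, z = cfg$z,
                              median_filter = cfg$median_filter))
  say("thresholds: background %d, tissue N(%.2f, %.2f), vessel %d (z = %g)",
      seg$model$t_background, seg$model$tissue_mean, seg$model$tissue_sd,
      seg$model$t_vessel, cfg$z)
  sk <- stage("skeletonize", skeletonize(seg$masks$vessel_mask, v$spacing))
  rf <- stage("distance_map", distance_map(seg$masks$vessel_mask, v$spacing))
  sk <- stage("fuse", fuse_skeleton(sk, rf))
  gr <- stage("extract_graph", extract_graph(sk))
  gr <- stage("filter_artifacts", filter_artifacts(gr, cfg$min_radius))
  say("graph: %d segments, %d nodes (%.2f%% removed as artifacts)",
      nrow(gr$segments), nrow(gr$nodes), gr$removed_fraction)
  met <- stage("metrics", global_metrics(seg$masks, gr, sk))
  recs <- segment_records(gr)
  fits <- NULL
  if (nrow(recs) >= 8L) {
    fits <- stage("fits", {
      fl <- tryCatch(fit_exponential_decay(
        relative_frequency(recs$length_um, cfg$bin_length, 0)),
        error = function(e) NULL)
      fdm <- tryCatch(fit_gaussian(
        relative_frequency(recs$diameter_um, cfg$bin_diameter, 0)),
        error = function(e) NULL)
      tv <- recs$tortuosity[!is.na(recs$tortuosity) & recs$tortuosity >= 1]
      ft <- tryCatch(fit_exponential_decay(
        relative_frequency(tv, cfg$bin_tortuosity, 1)),
        error = function(e) NULL)
      list(length = fl, diameter = fdm, tortuosity = ft)
    })
    for (nm in names(fits)) if (!is.null(fits[[nm]]))
      say("fit %s: %s", nm,
          paste(sprintf("%s = %.4g", names(fits[[nm]]$params),
                        fits[[nm]]$params), collapse = ", "))
  }
  out <- list(model = seg$model, masks = seg$masks, skeleton = sk,
              graph = gr, metrics = met, segments = recs, fits = fits,
              log = logl)
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(out, cfg$output_dir)
  out
}

# write the self-describing artifacts of a run (units in headers/names)
write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_stack(res$masks$vessel_mask, file.path(dir, "vessel_mask.tif"))
  save_stack(res$masks$tissue_mask, file.path(dir, "tissue_mask.tif"))
  save_stack(skeleton_mask(res$skeleton), file.path(dir, "skeleton.tif"))
  write.csv(res$segments, file.path(dir, "segments.csv"), row.names = FALSE)
  write.csv(res$graph$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  hm <- res$model
  jsonlite::write_json(list(
    t_background = hm$t_background, t_vessel = hm$t_vessel,
    tissue_mean = hm$tissue_mean, tissue_sd = hm$tissue_sd, z = hm$z),
    file.path(dir, "histogram_model.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(grey = 0:255, count = hm$counts),
            file.path(dir, "histogram.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(res$metrics)[
    c("vascular_density", "fractal_dimension", "fractal_r2",
      "segments_per_mm3", "nodes_per_mm3", "node_percentage",
      "total_length_per_mm3", "tissue_volume_mm3")],
    file.path(dir, "global_metrics.json"), auto_unbox = TRUE, digits = NA)
  writeLines(res$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Compare global parameters across groups of samples
#'
#' Kruskal-Wallis with Dunn's post-hoc on each global parameter across >= 2
#' groups of samples, plus (optionally) pooled-vs-separate F-tests on the
#' frequency curves of the architectural parameters.
#'
#' @param groups named list (>= 2) of data frames, one row per sample,
#'   columns = global parameters (>= 2 samples per group).
#' @param curve_fds optional named list: for each architectural parameter, a
#'   list of per-group `FrequencyDistribution`s plus the model family, e.g.
#'   `list(length = list(fds = ..., model = "exp_decay"))`.
#' @return List with a `global` data frame (parameter, H, p, significant)
#'   with Dunn tables attached, and `curves` comparisons.
#' @export
compare_samples <- function(groups, curve_fds = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, nrow, 0L) < 2L))
    stop("each group needs at least 2 samples")
  params <- Reduce(intersect, lapply(groups, colnames))
  if (length(params) == 0L) stop("no common parameters across groups")
  rows <- list()
  dunns <- list()
  for (p in params) {
    gl <- lapply(groups, function(df) df[[p]])
    res <- kruskal_wallis_dunn(gl)
    rows[[p]] <- data.frame(parameter = p, H = res$H, p = res$p,
                            significant = res$p < 0.05)
    dunns[[p]] <- res$dunn
  }
  global <- do.call(rbind, rows)
  rownames(global) <- NULL
  curves <- NULL
  if (!is.null(curve_fds)) {
    curves <- lapply(curve_fds, function(spec)
      compare_curves_groups(spec$fds, spec$model))
  }
  list(global = global, dunn = dunns, curves = curves)
}
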