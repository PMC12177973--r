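#' Pipeline configuration
#'
#' Controls the end-to-end run: which stages execute (marker detection
#' and restoration can be switched off for platforms without fiducial
#' markers), the trained models for the learned stages, and the stage
#' configs. Restoration requires the marker stage unless an external
#' marker mask is supplied at run time.
#'
#' @param detect_markers,restore Stage toggles.
#' @param marker_model A fitted `marker_net` (required when
#'   `detect_markers = TRUE`).
#' @param tissue_model A fitted `tissue_net` or a
#'   `list(standard =, compact =)` pair.
#' @param tissue A [tissue_config()].
#' @param segregation A [segregation_config()].
#' @param marker_threshold Binarization threshold for the marker mask.
#' @param inpaint_backend Restoration backend id.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic at inference).
#' @param out_dir Optional output directory; when set, every
#'   intermediate artifact plus a YAML manifest is written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detect_markers = TRUE, restore = TRUE,
                            marker_model = NULL, tissue_model = NULL,
                            tissue = tissue_config(),
                            segregation = segregation_config(),
                            marker_threshold = 0.5,
                            inpaint_backend = "diffusion",
                            seed = 1L, out_dir = NULL) {
  if (restore && !detect_markers)
    message("restoration without marker detection requires an external ",
            "marker mask passed to run_pipeline()")
  structure(list(detect_markers = detect_markers, restore = restore,
                 marker_model = marker_model, tissue_model = tissue_model,
                 tissue = tissue, segregation = segregation,
                 marker_threshold = marker_threshold,
                 inpaint_backend = inpaint_backend,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the four-stage image cleaning pipeline
#'
#' Executes, in order: fiducial marker detection, restoration of the
#' marker regions, tissue detection, and segregation of disconnected
#' tissue pieces. Disabled stages pass their input through unchanged.
#' Every produced artifact is returned (and written to `cfg$out_dir`
#' with a manifest when configured).
#'
#' @param img An [rgb_image()] or a path readable by [read_image()].
#' @param cfg A [pipeline_config()].
#' @param marker_mask Optional external [binary_mask()] used for
#'   restoration when marker detection is disabled.
#' @return A `pipeline_result` with (depending on enabled stages)
#'   `marker_prob`, `marker_mask`, `restored`, `tissue` (a
#'   `tissue_result`), `labels` ([labeled_mask()]) and per-stage
#'   `timings` in seconds.
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), marker_mask = NULL) {
  if (is.character(img)) img <- read_image(img)
  stopifnot(inherits(img, "rgb_image"))
  if (cfg$detect_markers && is.null(cfg$marker_model))
    stop("marker detection enabled but no marker_model supplied",
         call. = FALSE)
  if (cfg$restore && !cfg$detect_markers && is.null(marker_mask))
    stop("restoration requires the marker stage or an external marker mask",
         call. = FALSE)
  if (is.null(cfg$tissue_model))
    stop("a tissue_model is required", call. = FALSE)

  result <- list(timings = c())
  current <- img
  tic <- function() proc.time()[["elapsed"]]

  if (cfg$detect_markers) {
    t0 <- tic()
    det <- predict_slide(img, cfg$marker_model,
                         threshold = cfg$marker_threshold)
    result$marker_prob <- det$prob
    result$marker_mask <- det$mask
    result$timings["markers"] <- tic() - t0
  } else if (!is.null(marker_mask)) {
    result$marker_mask <- marker_mask
  }

  if (cfg$restore) {
    t0 <- tic()
    current <- inpaint(current, result$marker_mask,
                       backend = cfg$inpaint_backend)
    result$restored <- current
    result$timings["restore"] <- tic() - t0
  }

  t0 <- tic()
  result$tissue <- detect_tissue(current, cfg$tissue_model, cfg$tissue)
  result$timings["tissue"] <- tic() - t0

  t0 <- tic()
  result$labels <- segregate(result$tissue$prob, cfg$segregation)
  result$timings["segregate"] <- tic() - t0

  class(result) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result, img, cfg)
  result
}

write_pipeline_outputs <- function(result, img, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- function(f) file.path(cfg$out_dir, f)
  artifacts <- character(0)
  put <- function(obj, name, writer) {
    writer(obj, o(name))
    artifacts <<- c(artifacts, name)
  }
  if (!is.null(result$marker_prob))
    put(result$marker_prob, "marker_prob.tif", write_mask)
  if (!is.null(result$marker_mask))
    put(result$marker_mask, "marker_mask.png", write_mask)
  if (!is.null(result$restored))
    put(result$restored, "restored.png", write_image)
  put(result$tissue$prob, "tissue_prob.tif", write_mask)
  put(result$tissue$blend, "tissue_blend.png",
      function(x, p) png::writePNG(unclass(x) / 255, p))
  put(result$labels, "tissue_labels.png", write_mask)
  stage_cfg <- cfg[setdiff(names(cfg), c("marker_model", "tissue_model",
                                         "out_dir"))]
  manifest <- list(
    stages = list(markers = cfg$detect_markers, restore = cfg$restore,
                  tissue = TRUE, segregate = TRUE),
    seed = cfg$seed,
    config_hash = fnv1a_hash(stage_cfg),
    output_hash = fnv1a_hash(lapply(result[c("marker_mask", "restored",
                                             "labels")], unclass)),
    artifacts = artifacts,
    n_components = n_components(result$labels),
    timings = as.list(result$timings),
    version = as.character(utils::packageVersion("stclean")))
  yaml::write_yaml(manifest, o("manifest.yaml"))
  invisible(manifest)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$marker_mask))
    cat(sprintf("  marker mask: %d px flagged\n", sum(x$marker_mask)))
  if (!is.null(x$restored)) cat("  restored image present\n")
  cat(sprintf("  tissue: mean prob %.3f\n", mean(x$tissue$prob)))
  cat(sprintf("  components: %d\n", n_components(x$labels)))
  invisible(x)
}

#' Score a pipeline run against gold-standard annotations
#'
#' @param result A `pipeline_result`.
#' @param gold List with any of `marker_mask` and `tissue_mask`
#'   ([binary_mask()] objects aligned to the input image).
#' @return A `metric_report`; marker IoU is included when both the
#'   prediction and the gold marker mask exist, tissue metrics when the
#'   gold tissue mask exists.
#' @export
evaluate_run <- function(result, gold) {
  rep <- list()
  if (!is.null(result$marker_mask) && !is.null(gold$marker_mask)) {
    rep$marker_iou <- mask_iou(result$marker_mask, gold$marker_mask)
  }
  if (!is.null(gold$tissue_mask)) {
    pred_bin <- binary_mask((as_plain(result$tissue$prob) >= 0.5) * 1L)
    rep$tissue_iou <- mask_iou(pred_bin, gold$tissue_mask)
    rep$tissue_hausdorff <-
      suppressWarnings(hausdorff_distance(pred_bin, gold$tissue_mask))
    rep$tissue_perim_ratio <-
      suppressWarnings(perimeter_ratio(pred_bin, gold$tissue_mask))
    seg_bin <- binary_mask((as_plain(result$labels) > 0L) * 1L)
    rep$comp_diff <- comp_diff(seg_bin, gold$tissue_mask)
  }
  structure(rep, class = "metric_report")
}
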