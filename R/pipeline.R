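# End-to-end processing chain: preprocess -> segment -> centerline ->
# stereo matching, mirroring the acquisition-to-disparity flow of an NIR
# vein imaging rig. Consumes an already rectified stereo pair.

#' Pipeline configuration
#'
#' Nested module configurations plus run-level settings. Round-trips
#' losslessly through YAML; [run_pipeline()] writes the resolved
#' configuration next to its outputs.
#'
#' @param preprocess A [preprocess_config()].
#' @param hessian A [hessian_config()].
#' @param refine A [refine_config()].
#' @param stereo A [stereo_params()].
#' @param checkpoint Optional path to a network checkpoint; when `NULL`
#'   segmentation falls back to thresholding the Hessian vesselness
#'   response.
#' @param stereo_input Which image feeds the matcher: "preprocessed"
#'   (default) or "raw". The segmentation mask gates which disparities are
#'   reported as vessel depth in either case.
#' @param seed Run seed.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            hessian = hessian_config(),
                            refine = refine_config(),
                            stereo = stereo_params(),
                            checkpoint = NULL,
                            stereo_input = c("preprocessed", "raw"),
                            seed = 1, out_dir = NULL) {
  stereo_input <- match.arg(stereo_input)
  structure(list(preprocess = preprocess, hessian = hessian,
                 refine = refine, stereo = stereo, checkpoint = checkpoint,
                 stereo_input = stereo_input, seed = as.integer(seed),
                 out_dir = out_dir), class = "pipeline_config")
}

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  strip(unclass(cfg))
}

#' Restore a pipeline configuration from a plain list (e.g. parsed YAML)
#' @param lst Nested list as produced by writing the config to YAML.
#' @export
pipeline_config_from_list <- function(lst) {
  pipeline_config(
    preprocess = do.call(preprocess_config, lst$preprocess),
    hessian = do.call(hessian_config, lst$hessian),
    refine = do.call(refine_config, lst$refine),
    stereo = do.call(stereo_params, lst$stereo),
    checkpoint = lst$checkpoint,
    stereo_input = lst$stereo_input,
    seed = lst$seed, out_dir = lst$out_dir)
}

#' Run the full vein-imaging pipeline on a rectified stereo pair
#'
#' Preprocesses both images, segments the left image (network checkpoint
#' if configured, otherwise thresholded Hessian vesselness), extracts and
#' refines the vein centerline, matches the pair and reports the disparity
#' map with the vein mask applied as a depth gate.
#'
#' @param left,right Rectified grayscale matrices in \[0,1\].
#' @param cfg A [pipeline_config()].
#' @return List with `preprocessed` (left), `mask`, `prob`, `centerline`,
#'   `disparity` (full refined map), `vein_disparity` (masked to vein
#'   pixels).
#' @export
run_pipeline <- function(left, right, cfg = pipeline_config()) {
  assert_gray(left, "left"); assert_gray(right, "right")
  if (cfg$stereo$d_max >= ncol(left))
    stop("stereo d_max must be smaller than the image width", call. = FALSE)
  set.seed(cfg$seed)
  pl <- preprocess_pipeline(left, cfg$preprocess)
  pr <- preprocess_pipeline(right, cfg$preprocess)
  resp <- vesselness(pl, cfg$hessian)
  if (!is.null(cfg$checkpoint)) {
    if (!file.exists(cfg$checkpoint))
      stop("network checkpoint not found: ", cfg$checkpoint,
           "; train one or unset `checkpoint` to use the Hessian fallback",
           call. = FALSE)
    net <- load_checkpoint(cfg$checkpoint)
    seg <- segment(net, pl)
    prob <- seg$prob; mask <- seg$mask
  } else {
    prob <- resp
    mask <- matrix(as.integer(resp > cfg$hessian$response_threshold),
                   nrow(resp), ncol(resp))
  }
  skel <- extract_centerline(resp, cfg$hessian)
  skel <- refine_centerline(skel, cfg$refine)
  sl <- if (cfg$stereo_input == "preprocessed") pl else left
  sr <- if (cfg$stereo_input == "preprocessed") pr else right
  sm <- match_stereo(sl, sr, cfg$stereo)
  vein_disp <- sm$disparity
  vein_disp[mask == 0] <- NA_real_
  out <- list(preprocessed = pl, prob = prob, mask = mask,
              centerline = skel, disparity = sm$disparity,
              vein_disparity = vein_disp)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(f) file.path(cfg$out_dir, f)
    write_image(pl, w("preprocessed.png"))
    write_mask(mask, w("mask.png"))
    write_mask(skel, w("centerline.png"))
    write_pfm(ifelse(is.finite(sm$disparity), sm$disparity, Inf),
              w("disparity.pfm"))
    write_disparity_png16(sm$disparity, w("disparity.png"))
    pts <- centerline_points(skel)
    write.csv(data.frame(row = pts[, 1], col = pts[, 2]),
              w("centerline.csv"), row.names = FALSE)
    yaml::write_yaml(config_to_list(cfg), w("config.yaml"))
  }
  out
}
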