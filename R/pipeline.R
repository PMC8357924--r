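# End-to-end orchestration: preprocess -> localize -> crop VOIs -> segment
# condyle (A) and socket bone (B) -> classical enhancement + fusion (C) ->
# slice-stack smoothing and reconstruction (D) -> inflation / clipping /
# Boolean difference (E) -> symmetry report.  Every stage's outputs can be
# saved, each stage is timed, and all randomness flows from one seed.

.pipeline_schema <- list(
  input = c("volume", "object", "format"),
  localization = c("resolution", "open_radius", "min_fraction", "margin"),
  segmentation = c("patch_shape", "voi_shape", "threshold"),
  enhancement = c("median_radius", "close_radius", "smooth_radius",
                  "canny_low", "canny_high", "edge_mode", "fuse_tau",
                  "fuse_tau_core", "fuse_dilate", "min_solidity", "min_minority_fraction",
                  "stack_radius", "use_classical_tb", "use_smooth_stack",
                  "mesh_smooth"),
  inflation = c("step", "max_iters", "laplacian_weight",
                "collision_tolerance", "sdf_resolution", "resolution",
                "clip_plane"),
  symmetry = c("refine", "sampling", "n_points", "n_subsamples",
               "subsample_frac", "s_lr_flag"),
  models = c("localization", "mc", "tb"),
  output = c("dir", "save_volumes", "save_meshes"),
  seed = NULL)

#' Pipeline configuration
#'
#' Nested list of stage parameters; unknown keys are a config error (they
#' are listed in the message).  See the pipeline vignette for the meaning
#' and default of every parameter.
#'
#' @param ... named stage lists (`input`, `localization`, `segmentation`,
#'   `enhancement`, `inflation`, `symmetry`, `models`, `output`) and `seed`.
#' @return `nv_pipelineconfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), names(.pipeline_schema))
  if (length(unknown) > 0)
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  for (sec in names(cfg)) {
    if (is.null(.pipeline_schema[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), .pipeline_schema[[sec]])
    if (length(bad) > 0)
      stop(sprintf("unknown config keys in '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  defaults <- list(
    localization = list(resolution = c(48, 48, 48), open_radius = 1,
                        min_fraction = 0.1, margin = 0.1),
    segmentation = list(patch_shape = c(32, 32, 32), voi_shape = NULL,
                        threshold = 0.5),
    enhancement = list(median_radius = 1, close_radius = 1, smooth_radius = 1,
                       canny_low = 0.6, canny_high = 0.85,
                       edge_mode = "canny2d-linked", fuse_tau = 0.5,
                       fuse_tau_core = 0.9, fuse_dilate = 3,
                       min_solidity = 0.2, min_minority_fraction = 0.02,
                       stack_radius = 1, use_classical_tb = TRUE,
                       use_smooth_stack = TRUE, mesh_smooth = 1),
    inflation = list(step = 0.1, max_iters = 500, laplacian_weight = 0.2,
                     collision_tolerance = 0.05, sdf_resolution = 128,
                     resolution = 160, clip_plane = NULL),
    symmetry = list(refine = "centroid", sampling = "vertices",
                    n_points = 1e4, n_subsamples = 20, subsample_frac = 0.5,
                    s_lr_flag = 1.15),
    models = list(localization = NULL, mc = NULL, tb = NULL),
    output = list(dir = NULL, save_volumes = FALSE, save_meshes = TRUE),
    input = list(volume = NULL, object = NULL, format = "auto"),
    seed = 1)
  out <- defaults
  for (sec in names(cfg)) {
    if (sec == "seed") { out$seed <- cfg$seed; next }
    for (k in names(cfg[[sec]])) out[[sec]][[k]] <- cfg[[sec]][[k]]
  }
  structure(out, class = "nv_pipelineconfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file.
#' @return `nv_pipelineconfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.stage_error <- function(stage, msg) {
  stop(structure(class = c("nv_stage_error", "error", "condition"),
                 list(message = sprintf("[stage %s] %s", stage, msg),
                      call = NULL, stage = stage)))
}

.resolve_model <- function(m) {
  if (is.null(m)) return(NULL)
  if (inherits(m, "nv_model")) return(m)
  if (is.character(m) && file.exists(m)) return(load_model(m))
  stop("model must be an nv_model or a checkpoint path", call. = FALSE)
}

#' Run the end-to-end negative-volume pipeline
#'
#' @param cfg an [pipeline_config].  Input is either
#'   `cfg$input$volume` (path) or `cfg$input$object` (an [nv_volume] or a
#'   head phantom from [make_head_phantom], whose ground-truth clip planes
#'   and midline are then used as defaults).
#' @return list with `report` ([symmetry_report]), per-side `sides`
#'   (masks, meshes, negative volumes), `boxes`, and a `timing` tibble.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "nv_pipelineconfig"))
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage, t_prev) {
    t_now <- proc.time()[["elapsed"]]
    timing[[length(timing) + 1]] <<- tibble::tibble(stage = stage,
                                                    seconds = t_now - t_prev)
    t_now
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  # --- input ---
  phantom <- NULL
  if (!is.null(cfg$input$object)) {
    obj <- cfg$input$object
    if (inherits(obj, "nv_head_phantom")) { phantom <- obj; vol <- obj$volume }
    else if (inherits(obj, "nv_volume")) vol <- obj
    else .stage_error("input", "unsupported input object")
  } else if (!is.null(cfg$input$volume)) {
    if (!file.exists(cfg$input$volume))
      .stage_error("input", sprintf("missing input: %s", cfg$input$volume))
    vol <- read_volume(cfg$input$volume, cfg$input$format)
  } else .stage_error("input", "no input volume given")
  mloc <- .resolve_model(cfg$models$localization)
  mmc <- .resolve_model(cfg$models$mc)
  mtb <- .resolve_model(cfg$models$tb)
  if (is.null(mloc) || is.null(mmc))
    .stage_error("input", "localization and condyle models are required")
  t1 <- tick("input", t0)

  # --- preprocess ---
  vn <- minmax_normalize(vol)
  lowres <- resample(vn, cfg$localization$resolution)
  t1 <- tick("preprocess", t1)

  # --- localization ---
  prob <- coarse_segment(minmax_normalize(lowres), mloc)
  locmask <- postprocess_localization(prob, cfg$localization$open_radius,
                                      cfg$localization$min_fraction)
  boxes <- tryCatch(
    extract_voi_boxes(locmask, margin = cfg$localization$margin,
                      full_shape = dim(vn$data)),
    error = function(e) .stage_error("localization", conditionMessage(e)))
  t1 <- tick("localization", t1)

  # --- per-side segmentation + reconstruction + inflation ---
  sides <- list()
  for (side in c("left", "right")) {
    b <- boxes[[side]]
    patch <- as.integer(cfg$segmentation$patch_shape)
    voi_shape <- as.integer(cfg$segmentation$voi_shape %||% patch)
    # working VOI centred on the side's mass centroid (robust to thin
    # structures dropped by the coarse mask)
    vb <- if (!is.null(b$centroid))
      centered_box(b$centroid, voi_shape, dim(vn$data), side) else b
    voi <- crop_voi(vn, vb, patch_shape = voi_shape)
    voi <- minmax_normalize(voi)
    # network predictions run on a centred training-patch-sized sub-crop
    # (the layout the models were trained on); the geometry stages use the
    # full working VOI so the socket is never truncated
    off <- pmax((voi_shape - patch) %/% 2L, 0L)
    bsub <- bounding_box(off + 1L, off + patch + 1L, side)
    subvoi <- minmax_normalize(crop_voi(voi, bsub))
    net_mask <- function(model) {
      p <- predict_volume(model, subvoi)
      full <- array(0, voi_shape)
      full[off[1] + seq_len(patch[1]), off[2] + seq_len(patch[2]),
           off[3] + seq_len(patch[3])] <- p
      full
    }
    # (A) condyle
    pmc <- net_mask(mmc)
    mc_mask <- nv_mask(pmc > cfg$segmentation$threshold, voi$spacing, voi$origin)
    mc_mask <- drop_small_components(mc_mask, 0.5)
    if (!any(mc_mask$data)) .stage_error("segmentation",
                                         sprintf("empty condyle mask (%s)", side))
    # (B+C) socket bone: network heatmap fused with the classical route
    tb_heat <- if (!is.null(mtb))
      nv_volume(net_mask(mtb), voi$spacing, voi$origin) else NULL
    if (isTRUE(cfg$enhancement$use_classical_tb)) {
      e <- cfg$enhancement
      tb_classical <- classical_tb_mask(voi, median_radius = e$median_radius,
        close_radius = e$close_radius, smooth_radius = e$smooth_radius,
        canny_low = e$canny_low, canny_high = e$canny_high,
        edge_mode = e$edge_mode,
        min_solidity = e$min_solidity,
        min_minority_fraction = e$min_minority_fraction)
      # the condyle is bone too; remove it from the socket candidate
      tb_classical$data <- tb_classical$data & !dilate_mask(mc_mask, 1)$data
      tb_mask <- if (!is.null(tb_heat))
        fuse_with_heatmap(tb_classical, tb_heat, tau = e$fuse_tau,
                          tau_core = e$fuse_tau_core,
                          dilate_radius = e$fuse_dilate)
      else tb_classical
    } else {
      if (is.null(tb_heat)) .stage_error("segmentation",
                                         "no socket-bone model or classical route")
      tb_mask <- nv_mask(tb_heat$data > cfg$segmentation$threshold,
                         voi$spacing, voi$origin)
    }
    if (!any(tb_mask$data)) .stage_error("enhancement",
                                         sprintf("empty socket mask (%s)", side))
    # (D) reconstruction
    if (isTRUE(cfg$enhancement$use_smooth_stack)) {
      mc_s <- smooth_stack(mc_mask, radius = cfg$enhancement$stack_radius)
      tb_s <- smooth_stack(tb_mask, radius = cfg$enhancement$stack_radius)
    } else { mc_s <- mc_mask; tb_s <- tb_mask }
    msr <- cfg$enhancement$mesh_smooth
    mc_mesh <- tryCatch(mask_to_mesh(mc_s, smooth_radius = msr),
                        error = function(e) .stage_error("reconstruction",
                                                         conditionMessage(e)))
    tb_mesh <- tryCatch(mask_to_mesh(tb_s, smooth_radius = msr),
                        error = function(e) .stage_error("reconstruction",
                                                         conditionMessage(e)))
    # (E) inflation / clipping / difference
    clip <- cfg$inflation$clip_plane
    if (is.null(clip) && !is.null(phantom)) clip <- phantom[[side]]$clip_plane
    if (is.null(clip)) clip <- default_clip_plane(mc_mesh)
    ip <- inflation_params(step = cfg$inflation$step,
                           max_iters = cfg$inflation$max_iters,
                           laplacian_weight = cfg$inflation$laplacian_weight,
                           collision_tolerance = cfg$inflation$collision_tolerance,
                           sdf_resolution = cfg$inflation$sdf_resolution)
    nv <- tryCatch(negative_volume(mc_mesh, tb_mesh, clip, ip,
                                   resolution = cfg$inflation$resolution),
                   error = function(e) .stage_error("inflation",
                                                    conditionMessage(e)))
    sides[[side]] <- list(box = b, mc_mask = mc_mask, tb_mask = tb_mask,
                          mc_mesh = mc_mesh, tb_mesh = tb_mesh,
                          negative = nv, clip_plane = clip)
    t1 <- tick(paste0("segment+reconstruct+inflate_", side), t1)
  }

  # --- symmetry ---
  midx <- if (!is.null(phantom)) phantom$mid_plane
          else list(point = c((dim(vn$data)[1] - 1) * vn$spacing[1] / 2, 0, 0),
                    normal = c(1, 0, 0))
  s <- cfg$symmetry
  report <- symmetry_report(sides$left$negative$mesh,
                            sides$right$negative$mesh,
                            mid_plane = midx, refine = s$refine,
                            sampling = s$sampling, n_points = s$n_points,
                            n_subsamples = s$n_subsamples,
                            subsample_frac = s$subsample_frac,
                            s_lr_flag = s$s_lr_flag, seed = cfg$seed)
  t1 <- tick("symmetry", t1)
  timing <- do.call(rbind, timing)

  # --- artifacts ---
  if (!is.null(cfg$output$dir)) {
    dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
    od <- cfg$output$dir
    for (side in c("left", "right")) {
      sd <- sides[[side]]
      if (isTRUE(cfg$output$save_meshes)) {
        write_mesh_stl(sd$mc_mesh, file.path(od, sprintf("%s_mc.stl", side)))
        write_mesh_stl(sd$tb_mesh, file.path(od, sprintf("%s_tb.stl", side)))
        if (nrow(sd$negative$mesh$faces) > 0)
          write_mesh_stl(sd$negative$mesh,
                         file.path(od, sprintf("%s_negative.stl", side)))
      }
      if (isTRUE(cfg$output$save_volumes)) {
        write_volume(sd$mc_mask, file.path(od, sprintf("%s_mc_mask.nii.gz", side)))
        write_volume(sd$tb_mask, file.path(od, sprintf("%s_tb_mask.nii.gz", side)))
      }
      utils::write.csv(sd$negative$trace,
                       file.path(od, sprintf("%s_inflation_trace.csv", side)),
                       row.names = FALSE)
    }
    write_symmetry_report(report, file.path(od, "symmetry_report.json"))
    utils::write.csv(timing, file.path(od, "stage_timing.csv"),
                     row.names = FALSE)
  }
  list(report = report, sides = sides, boxes = boxes, timing = timing)
}

#' Default neck clip plane from mesh geometry
#'
#' Heuristic used when no anatomical plane is supplied: the mesh's first
#' principal axis is taken as the neck axis (oriented towards the larger
#' end, the condylar head); stations along the axis between 15% and 60% of
#' the extent are scanned for the minimal cross-section width, and the plane
#' is placed there.
#'
#' @param m condyle [nv_mesh].
#' @return list with `point` and `normal`.
#' @export
default_clip_plane <- function(m) {
  v <- m$vertices
  ctr <- colMeans(v)
  pc <- prcomp(v, center = TRUE)
  ax <- pc$rotation[, 1]
  t <- as.vector(sweep(v, 2, ctr) %*% ax)
  # orient the axis so +ax points to the wider (head) end
  hi_w <- stats::median(sqrt(rowSums((sweep(v, 2, ctr) -
                                        outer(t, ax))[t > stats::quantile(t, 0.7), ,
                                                      drop = FALSE]^2)))
  lo_w <- stats::median(sqrt(rowSums((sweep(v, 2, ctr) -
                                        outer(t, ax))[t < stats::quantile(t, 0.3), ,
                                                      drop = FALSE]^2)))
  if (lo_w > hi_w) { ax <- -ax; t <- -t }
  stations <- stats::quantile(t, seq(0.15, 0.6, by = 0.05))
  widths <- vapply(stations, function(s) {
    sel <- abs(t - s) < (max(t) - min(t)) * 0.05
    if (sum(sel) < 3) return(Inf)
    radial <- sweep(v[sel, , drop = FALSE], 2, ctr) - outer(t[sel], ax)
    max(sqrt(rowSums(radial^2)))
  }, numeric(1))
  s0 <- stations[which.min(widths)]
  list(point = ctr + s0 * ax, normal = ax)
}
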