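#' Job configuration
#'
#' Collects and validates the per-job parameters shared by all pipeline
#' stages.
#'
#' @param nozzle_diameter_mm nozzle inner diameter (mm).
#' @param pressure_mpa print pressure (MPa).
#' @param layer_thickness_mm programmed layer thickness (mm).
#' @param speed_mm_s nominal print speed (mm/s).
#' @param tolerance_mm classification tolerance band half-width.
#' @param dz_mm axial OCT resolution (mm per axial pixel).
#' @param nx,ny grid pixel counts.
#' @param wide_field use the wide-field extents.
#' @param x_extent_mm,y_extent_mm explicit extents (override wide_field).
#' @param layers_per_round printed layers covered by one imaging round.
#' @param min_repair_length_mm repair-selection threshold.
#' @param dialect a [gcode_dialect()].
#' @param calibration optional [calibration_table()].
#' @param window_px optional SSIM window override.
#' @param opening_size stringing-opening element side.
#' @param dilation_radius_px optional stringing dilation radius override.
#' @return validated list of class \code{job_config}.
#' @export
job_config <- function(nozzle_diameter_mm = 0.41, pressure_mpa = 0.18,
                       layer_thickness_mm = 0.25, speed_mm_s = 10,
                       tolerance_mm = 0.05, dz_mm = 0.01,
                       nx = 1024L, ny = 1024L, wide_field = FALSE,
                       x_extent_mm = NULL, y_extent_mm = NULL,
                       layers_per_round = 1L, min_repair_length_mm = 1.5,
                       dialect = gcode_dialect(), calibration = NULL,
                       window_px = NULL, opening_size = 3,
                       dilation_radius_px = NULL) {
  stopifnot(nozzle_diameter_mm > 0, layer_thickness_mm > 0,
            tolerance_mm >= 0, dz_mm > 0, layers_per_round >= 1,
            min_repair_length_mm >= 0, speed_mm_s > 0)
  grid <- grid_spec(x_extent_mm, y_extent_mm, nx = nx, ny = ny,
                    wide_field = wide_field)
  structure(list(nozzle_diameter_mm = nozzle_diameter_mm,
                 pressure_mpa = pressure_mpa,
                 layer_thickness_mm = layer_thickness_mm,
                 speed_mm_s = speed_mm_s,
                 tolerance_mm = tolerance_mm, dz_mm = dz_mm,
                 grid = grid, layers_per_round = as.integer(layers_per_round),
                 min_repair_length_mm = min_repair_length_mm,
                 dialect = dialect, calibration = calibration,
                 window_px = window_px, opening_size = opening_size,
                 dilation_radius_px = dilation_radius_px),
            class = "job_config")
}

#' Read a job configuration from a YAML file
#'
#' Recognized keys mirror the [job_config()] arguments; a
#' \code{calibration} key may hold a CSV path (columns speed_mm_s,
#' pressure_mpa, width_mm, height_mm) or an inline list of entries.
#'
#' @param path YAML file path.
#' @return a [job_config()].
#' @export
read_job_config <- function(path) {
  y <- yaml::read_yaml(path)
  cal <- NULL
  if (!is.null(y$calibration)) {
    tab <- if (is.character(y$calibration)) {
      utils::read.csv(file.path(dirname(path), y$calibration))
    } else do.call(rbind.data.frame, y$calibration)
    cal <- calibration_table(tab$speed_mm_s, tab$pressure_mpa,
                             tab$width_mm, tab$height_mm)
  }
  dialect <- do.call(gcode_dialect, y$dialect %||% list())
  args <- y[names(y) %in% names(formals(job_config))]
  args$dialect <- dialect
  args$calibration <- cal
  do.call(job_config, args)
}

# combine the target maps of the layers covered by one imaging round:
# per-pixel target thickness is the sum of the covered layers' heights
.combine_round_target <- function(maps, segments, config) {
  if (length(maps) == 1) return(maps[[1]])
  base <- rasterize_layer(segments, config$grid, table = config$calibration,
                          nozzle_diameter_mm = config$nozzle_diameter_mm,
                          layer_thickness_mm = config$layer_thickness_mm)
  th <- Reduce(`+`, lapply(maps, function(m) m$thickness))
  base$thickness <- th * base$path_mask +
    base$thickness * (!base$path_mask)
  base$thickness[!base$path_mask] <- 0
  base$z_mm <- maps[[length(maps)]]$z_mm
  base
}

#' Run the full print-imaging analysis pipeline
#'
#' For every imaging round: rasterize the covered layers of the toolpath
#' into a target model map, reconstruct the printed thickness (from an
#' OCT volume plus the base acquisition, or directly from a supplied
#' height map), classify defects, score fidelity, and plan repairs.
#'
#' @param config a [job_config()].
#' @param gcode GCode text (string, lines, or file path).
#' @param rounds list with one element per imaging round; each element is
#'   a list with either \code{heightmap} (ny x nx mm matrix) or
#'   \code{volume} (an [oct_volume()] or [render_volume()] result),
#'   \code{base} (base-acquisition \code{surface_map}, [oct_volume()], or
#'   matrix of base indices) and \code{z_set_height_px}.
#' @param repair plan repairs for qualifying runs (default TRUE).
#' @return object of class \code{run_report}: per-round results
#'   (\code{target}, \code{recon}, \code{defects}, \code{fidelity},
#'   \code{runs}, \code{plan}, \code{repair_gcode}), the fidelity series,
#'   and all measured runs.
#' @export
run_pipeline <- function(config, gcode, rounds, repair = TRUE) {
  stopifnot(inherits(config, "job_config"))
  segments <- parse_gcode(gcode, dialect = config$dialect,
                          pressure_mpa = config$pressure_mpa)
  segments <- group_layers(segments, config$layer_thickness_mm)
  n_layers <- if (nrow(segments)) max(segments$layer) else 0L
  layer_maps <- lapply(seq_len(n_layers), function(k)
    rasterize_layer(segments[segments$layer == k, ], config$grid,
                    table = config$calibration,
                    nozzle_diameter_mm = config$nozzle_diameter_mm,
                    layer_thickness_mm = config$layer_thickness_mm))

  out_rounds <- vector("list", length(rounds))
  for (r in seq_along(rounds)) {
    round_in <- rounds[[r]]
    covered <- seq.int((r - 1L) * config$layers_per_round + 1L,
                       min(r * config$layers_per_round, n_layers))
    stage <- sprintf("round %d", r)
    target <- tryCatch(
      .combine_round_target(layer_maps[covered],
                            segments[segments$layer %in% covered, ], config),
      error = function(e) stop(sprintf("[%s/target] %s", stage,
                                       conditionMessage(e)), call. = FALSE))
    recon <- tryCatch({
      if (!is.null(round_in$heightmap)) {
        if (!all(dim(round_in$heightmap) == c(config$grid$ny, config$grid$nx)))
          stop(sprintf("heightmap is %d x %d but the grid is %d x %d",
                       nrow(round_in$heightmap), ncol(round_in$heightmap),
                       config$grid$ny, config$grid$nx))
        recon_model_map(round_in$heightmap, grid = config$grid, round = r,
                        dz_mm = config$dz_mm)
      } else {
        vol <- round_in$volume
        meta <- NULL
        if (is.list(vol) && !inherits(vol, "oct_volume")) {
          meta <- vol$meta; vol <- vol$volume
        }
        base <- round_in$base
        if (is.matrix(base))
          base <- structure(list(surface_z_px = base,
                                 valid = matrix(TRUE, nrow(base), ncol(base))),
                            class = "surface_map")
        if (inherits(base, "oct_volume"))
          base <- detect_surface(base, threshold = round_in$threshold)
        surf <- detect_surface(vol, threshold = round_in$threshold)
        zset <- round_in$z_set_height_px %||% meta$z_set_height_px %||% 0
        compute_thickness(surf, base, acquisition_meta(r, zset),
                          dz_mm = vol$dz_mm, grid = config$grid)
      }
    }, error = function(e) stop(sprintf("[%s/reconstruct] %s", stage,
                                        conditionMessage(e)), call. = FALSE))
    dmap <- defect_map(recon, target, tolerance_mm = config$tolerance_mm,
                       dilation_radius_px = config$dilation_radius_px,
                       opening_size = config$opening_size, round = r)
    fid <- print_fidelity(target, recon, dmap = dmap,
                          window_px = config$window_px)
    runs <- measure_defect_runs(dmap, target)
    plan <- NULL; repair_gcode <- NULL
    if (repair) {
      sel <- select_repairable(runs, config$min_repair_length_mm)
      plan <- repair_plan(sel, speed_mm_s = config$speed_mm_s,
                          pressure_mpa = config$pressure_mpa,
                          table = config$calibration,
                          min_length_mm = config$min_repair_length_mm)
      repair_gcode <- generate_repair_gcode(plan, dialect = config$dialect)
    }
    out_rounds[[r]] <- list(round = r, target = target, recon = recon,
                            defects = dmap, fidelity = fid, runs = runs,
                            plan = plan, repair_gcode = repair_gcode)
  }
  fids <- fidelity_series(lapply(out_rounds, function(x) x$fidelity),
                          layer = seq_along(out_rounds))
  all_runs <- dplyr::bind_rows(lapply(out_rounds, function(x) {
    if (nrow(x$runs)) dplyr::mutate(x$runs, round = x$round) else NULL
  }))
  structure(list(config = config, rounds = out_rounds,
                 fidelity = fids, runs = all_runs),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d round(s), mean fidelity %.4f\n",
              length(x$rounds), mean(x$fidelity$mean_ssim)))
  invisible(x)
}

#' Per-round summary of a pipeline run
#'
#' @param x a \code{run_report}.
#' @param ... unused.
#' @return tibble with one row per round: fidelity, defect pixel counts,
#'   run and repair counts.
#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) {
  purrr::map_dfr(x$rounds, function(r) {
    g <- glance(r$defects)
    tibble::tibble(round = r$round, z_mm = r$target$z_mm,
                   mean_ssim = r$fidelity$mean_ssim,
                   n_defect_pixels = g$n_defect_pixels,
                   n_runs = nrow(r$runs),
                   n_repairs = if (is.null(r$plan)) NA_integer_ else nrow(r$plan))
  })
}

#' @method glance run_report
#' @export
glance.run_report <- function(x, ...) {
  s <- glance(x$fidelity)
  tibble::tibble(n_rounds = length(x$rounds), mean_fidelity = s$mean,
                 sd_fidelity = s$sd, sem_fidelity = s$sem,
                 n_runs = nrow(x$runs),
                 n_repairs = sum(vapply(x$rounds, function(r)
                   if (is.null(r$plan)) 0L else nrow(r$plan), integer(1))))
}

# ---- writers: float TIFF for mm fields, PNG for renderings ----

#' Write a thickness field as 32-bit float TIFF
#'
#' Thickness (mm) is stored as 32-bit float samples normalized by a fixed
#' full scale (default 10 mm, comfortably above any printable stack per
#' round), so round-tripping preserves values to float32 precision.
#'
#' @param m numeric matrix of mm values.
#' @param path output path.
#' @param scale_mm full-scale value mapped to 1.0 in the file.
#' @export
write_thickness_tiff <- function(m, path, scale_mm = 10) {
  m[is.na(m)] <- 0
  tiff::writeTIFF(m / scale_mm, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a thickness field written by [write_thickness_tiff()]
#' @param path TIFF path.
#' @param scale_mm full-scale value used when writing.
#' @return numeric matrix (mm).
#' @export
read_thickness_tiff <- function(path, scale_mm = 10) {
  tiff::readTIFF(path) * scale_mm
}

#' Render a defect map to an RGB array or PNG
#'
#' @param dmap a \code{defect_map}.
#' @param path optional PNG output path; when NULL the RGB array is
#'   returned. Rows are flipped so +y points up in the image.
#' @return ny x nx x 3 RGB array (invisibly, when writing).
#' @export
render_defect_png <- function(dmap, path = NULL) {
  cols <- grDevices::col2rgb(defect_classes()$color) / 255
  lab <- dmap$labels
  img <- array(0, c(nrow(lab), ncol(lab), 3))
  for (code in 0:5) {
    sel <- lab == code
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- cols[ch, code + 1]
      img[, , ch] <- plane
    }
  }
  img_up <- img[rev(seq_len(nrow(lab))), , , drop = FALSE]
  if (!is.null(path)) {
    png::writePNG(img_up, path)
    return(invisible(img_up))
  }
  img_up
}

#' Write a full pipeline report to disk
#'
#' Per round: target and reconstructed thickness (float TIFF), the defect
#' characterization map (PNG with the legend colours and an integer-code
#' TIFF), the defect-run table (CSV), repair GCode (if planned), and a
#' JSON summary with per-class areas and fidelity.
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (r in report$rounds) {
    tag <- sprintf("round%02d", r$round)
    write_thickness_tiff(r$target$thickness,
                         file.path(out_dir, paste0(tag, "_target.tif")))
    write_thickness_tiff(r$recon$thickness,
                         file.path(out_dir, paste0(tag, "_recon.tif")))
    render_defect_png(r$defects, file.path(out_dir, paste0(tag, "_defects.png")))
    tiff::writeTIFF(r$defects$labels / 255,
                    file.path(out_dir, paste0(tag, "_labels.tif")),
                    bits.per.sample = 8L)
    utils::write.csv(dplyr::select(r$runs, -"path"),
                     file.path(out_dir, paste0(tag, "_runs.csv")),
                     row.names = FALSE)
    if (!is.null(r$repair_gcode) && nrow(r$plan) > 0)
      writeLines(r$repair_gcode,
                 file.path(out_dir, paste0(tag, "_repair.gcode")))
  }
  summary <- list(
    per_round = tidy(report),
    overall = glance(report),
    per_class_areas = lapply(report$rounds, function(r) tidy(r$defects)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Render report figures
#'
#' Writes one defect-map panel per round plus a per-round fidelity chart
#' and a short Markdown summary.
#'
#' @param report a \code{run_report}.
#' @param out_dir output directory.
#' @return the output directory, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Print-imaging run summary", "")
  if (length(report$rounds) == 0) {
    md <- c(md, "Zero rounds analysed.")
  } else {
    for (r in report$rounds)
      render_defect_png(r$defects,
                        file.path(out_dir, sprintf("defects_round%02d.png", r$round)))
    p <- plot_fidelity_series(report$fidelity)
    ggplot2::ggsave(file.path(out_dir, "fidelity.png"), p,
                    width = 5, height = 3.5, dpi = 150)
    g <- glance(report)
    md <- c(md,
            sprintf("- rounds: %d", g$n_rounds),
            sprintf("- mean fidelity: %.4f +/- %.4f (sem)", g$mean_fidelity,
                    g$sem_fidelity),
            sprintf("- defect runs: %d; planned repairs: %d", g$n_runs,
                    g$n_repairs))
  }
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
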