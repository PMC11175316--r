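#' Select defect runs eligible for secondary-printing repair
#'
#' Filament breakage and under-extrusion can be repaired by re-depositing
#' material; runs that reach or exceed the minimum length (1.5 mm by
#' default, threshold inclusive) are selected. Over-extrusion cannot be
#' fixed by adding material and is never selected.
#'
#' @param runs run tibble from [measure_defect_runs()].
#' @param min_length_mm minimum run length for repair (inclusive).
#' @return the selected rows, input order preserved.
#' @export
select_repairable <- function(runs, min_length_mm = 1.5) {
  runs[runs$class %in% c("filament_breakage", "under_extrusion") &
         runs$length_mm >= min_length_mm, , drop = FALSE]
}

# merge collinear points of a polyline (keeps endpoints and direction changes)
.simplify_polyline <- function(x, y, tol = 1e-9) {
  n <- length(x)
  if (n <= 2) return(list(x = x, y = y))
  keep <- c(TRUE, rep(FALSE, n - 2), TRUE)
  for (i in 2:(n - 1)) {
    cross <- (x[i] - x[i - 1]) * (y[i + 1] - y[i]) -
             (y[i] - y[i - 1]) * (x[i + 1] - x[i])
    if (abs(cross) > tol) keep[i] <- TRUE
  }
  list(x = x[keep], y = y[keep])
}

#' Build a repair plan from defect runs
#'
#' For every selected run the plan holds the repair polyline (the run's
#' centerline, collinear points merged — a straight run yields a single
#' start/end move), the layer Z, and the print parameters to use. For
#' under-extrusion runs with a calibration table, the deposition speed is
#' chosen by inverting the table at the job pressure so the deposited
#' height matches the thickness deficit; otherwise nominal parameters are
#' reused. An optional endpoint overlap extends the move at both ends to
#' counter start/stop under-deposition (default 0: off).
#'
#' @param runs selected runs from [select_repairable()].
#' @param speed_mm_s,pressure_mpa nominal print parameters.
#' @param table optional [calibration_table()] for under-extrusion speed
#'   selection.
#' @param endpoint_overlap_mm extension applied at both run ends along the
#'   move direction.
#' @param min_length_mm selection threshold recorded in the plan.
#' @return object of class \code{repair_plan}: tibble with one row per
#'   repair move set (\code{class}, \code{z_mm}, \code{speed_mm_s},
#'   \code{pressure_mpa}, \code{polyline} list-column of x/y mm tibbles).
#' @export
repair_plan <- function(runs, speed_mm_s = 10, pressure_mpa = 0.18,
                        table = NULL, endpoint_overlap_mm = 0,
                        min_length_mm = 1.5) {
  rows <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run <- runs[i, ]
    pts <- run$path[[1]]
    poly <- .simplify_polyline(pts$x_mm, pts$y_mm)
    if (endpoint_overlap_mm > 0 && length(poly$x) >= 2) {
      n <- length(poly$x)
      for (end in c(1L, n)) {
        nb <- if (end == 1L) 2L else n - 1L
        d <- c(poly$x[end] - poly$x[nb], poly$y[end] - poly$y[nb])
        len <- sqrt(sum(d^2))
        if (len > 0) {
          poly$x[end] <- poly$x[end] + d[1] / len * endpoint_overlap_mm
          poly$y[end] <- poly$y[end] + d[2] / len * endpoint_overlap_mm
        }
      }
    }
    speed <- speed_mm_s
    if (run$class == "under_extrusion" && !is.null(table) && nrow(table) > 1) {
      # pick the speed whose calibrated height best matches the deficit
      deficit <- NA_real_
      speeds <- sort(unique(table$speed_mm_s))
      heights <- vapply(speeds, function(s)
        lookup_filament_geometry(s, pressure_mpa, table)["height_mm"],
        numeric(1))
      # deficit unknown per-run here; fall back to nominal unless provided
      if (!is.null(run$deficit_mm) && is.finite(run$deficit_mm) &&
          length(unique(heights)) > 1) {
        o <- order(heights)
        speed <- stats::approx(heights[o], speeds[o], xout = run$deficit_mm,
                               rule = 2, ties = mean)$y
      }
    }
    rows[[i]] <- tibble::tibble(
      class = run$class, z_mm = run$z_mm,
      speed_mm_s = speed, pressure_mpa = pressure_mpa,
      length_mm = run$length_mm,
      polyline = list(tibble::tibble(x_mm = poly$x, y_mm = poly$y)))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(class = character(), z_mm = numeric(),
                   speed_mm_s = numeric(), pressure_mpa = numeric(),
                   length_mm = numeric(), polyline = list())
  attr(out, "min_length_mm") <- min_length_mm
  class(out) <- c("repair_plan", class(out))
  out
}

#' Emit secondary-printing GCode for a repair plan
#'
#' For each planned repair: a travel move to the start, extrusion on, one
#' or more extruding moves along the polyline, extrusion off. The output
#' uses the same command-code dialect the parser reads, so
#' \code{parse_gcode(generate_repair_gcode(plan))} round-trips the moves.
#'
#' @param plan a [repair_plan()].
#' @param dialect a [gcode_dialect()] (command codes used for extrusion
#'   on/off).
#' @param travel_speed_mm_s feed rate for non-extruding positioning moves.
#' @return character vector of GCode lines (an empty plan yields a
#'   comment-only program).
#' @export
generate_repair_gcode <- function(plan, dialect = gcode_dialect(),
                                  travel_speed_mm_s = 20) {
  lines <- c("; secondary printing: defect repair",
             sprintf("; %d repair move set(s)", nrow(plan)))
  fmt <- function(v) sprintf("%.6g", v)
  for (i in seq_len(nrow(plan))) {
    poly <- plan$polyline[[i]]
    lines <- c(lines,
               sprintf("; repair %d: %s, %.3f mm", i, plan$class[i],
                       plan$length_mm[i]),
               sprintf("G0 X%s Y%s Z%s F%s",
                       fmt(poly$x_mm[1]), fmt(poly$y_mm[1]),
                       fmt(plan$z_mm[i]), fmt(travel_speed_mm_s * 60)),
               dialect$extrude_on)
    for (j in seq_len(nrow(poly))[-1])
      lines <- c(lines, sprintf("G1 X%s Y%s F%s",
                                fmt(poly$x_mm[j]), fmt(poly$y_mm[j]),
                                fmt(plan$speed_mm_s[i] * 60)))
    lines <- c(lines, dialect$extrude_off)
  }
  lines
}

#' Compare print fidelity and defects before and after a repair
#'
#' Recomputes the defect map and mean-SSIM fidelity for the
#' reconstructions acquired before and after a repair and reports the
#' relative fidelity improvement together with per-class defect areas and
#' run counts.
#'
#' @param target the \code{target_model_map}.
#' @param recon_before,recon_after reconstructions on the target's grid.
#' @param tolerance_mm classification tolerance.
#' @param min_length_mm repair-selection threshold used for run counting.
#' @param ... passed to [defect_map()].
#' @return list of class \code{repair_report}: \code{fidelity_before},
#'   \code{fidelity_after}, \code{improvement_pct}, \code{areas} (tibble
#'   of per-class areas before/after), \code{runs_before},
#'   \code{runs_after} (run tibbles).
#' @export
verify_repair <- function(target, recon_before, recon_after,
                          tolerance_mm = 0.05, min_length_mm = 1.5, ...) {
  dm_b <- defect_map(recon_before, target, tolerance_mm = tolerance_mm, ...)
  dm_a <- defect_map(recon_after, target, tolerance_mm = tolerance_mm, ...)
  fid_b <- print_fidelity(target, recon_before, dmap = dm_b)
  fid_a <- print_fidelity(target, recon_after, dmap = dm_a)
  areas <- dplyr::left_join(
    dplyr::rename(tidy(dm_b), n_before = "n_pixels", area_before_mm2 = "area_mm2"),
    dplyr::rename(tidy(dm_a), n_after = "n_pixels", area_after_mm2 = "area_mm2"),
    by = c("class", "code"))
  structure(list(
    fidelity_before = fid_b$mean_ssim,
    fidelity_after = fid_a$mean_ssim,
    improvement_pct = relative_improvement(fid_b$mean_ssim, fid_a$mean_ssim),
    areas = areas,
    runs_before = measure_defect_runs(dm_b, target),
    runs_after = measure_defect_runs(dm_a, target)),
    class = "repair_report")
}

#' @export
print.repair_report <- function(x, ...) {
  cat(sprintf("repair_report: fidelity %.4f -> %.4f (%+.2f%%); defect runs %d -> %d\n",
              x$fidelity_before, x$fidelity_after, x$improvement_pct,
              nrow(x$runs_before), nrow(x$runs_after)))
  invisible(x)
}

#' @method glance repair_report
#' @export
glance.repair_report <- function(x, ...) {
  tibble::tibble(fidelity_before = x$fidelity_before,
                 fidelity_after = x$fidelity_after,
                 improvement_pct = x$improvement_pct,
                 runs_before = nrow(x$runs_before),
                 runs_after = nrow(x$runs_after))
}
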