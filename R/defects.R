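#' Print-state classes and display colours
#'
#' The defect characterization map distinguishes six states: background,
#' normal extrusion, under-extrusion, over-extrusion, filament breakage
#' (all inside the programmed path) and stringing (material outside the
#' path). Display colours follow the standard legend: black, green, cyan,
#' yellow, dark blue and red respectively.
#'
#' @return a tibble with columns \code{code} (integer 0-5), \code{class},
#'   \code{color}.
#' @export
defect_classes <- function() {
  tibble::tibble(
    code = 0:5,
    class = c("background", "normal", "under_extrusion", "over_extrusion",
              "filament_breakage", "stringing"),
    color = c("black", "green", "cyan", "yellow", "darkblue", "red"))
}

.class_code <- function(class) {
  dc <- defect_classes()
  dc$code[match(class, dc$class)]
}

#' Restrict a reconstructed map to the target path
#'
#' Point-multiplies the reconstructed printed thickness with the target
#' path mask: thickness is kept where the path mask is true and set to 0
#' elsewhere.
#'
#' @param recon a [recon_model_map()] or thickness matrix.
#' @param target a \code{target_model_map}.
#' @return ny x nx thickness matrix (mm), zero off-path; invalid columns
#'   inside the path are carried as 0 (absent deposit).
#' @export
mask_recon_in_path <- function(recon, target) {
  th <- if (is.matrix(recon)) recon else recon$thickness
  if (!all(dim(th) == dim(target$thickness)))
    stop("reconstructed and target maps are on different grids", call. = FALSE)
  if (!is.matrix(recon) && !is.null(recon$grid) &&
      !.same_grid(recon$grid, target$grid))
    stop("reconstructed and target maps are on different grids", call. = FALSE)
  th[is.na(th)] <- 0
  th * target$path_mask
}

# classify a vector of measured vs target thickness (mm) -> integer codes
.classify_thickness <- function(t, T, tolerance_mm, zero_eps_mm) {
  code <- integer(length(t))
  on <- T > 0
  code[on & t < zero_eps_mm] <- 4L                         # filament breakage
  code[on & t >= zero_eps_mm & t < T - tolerance_mm] <- 2L # under-extrusion
  code[on & t > T + tolerance_mm] <- 3L                    # over-extrusion
  code[on & code == 0L & t >= zero_eps_mm] <- 1L           # normal band
  code
}

#' Classify print state inside the target path
#'
#' Print state is defined along the central path of the target model: at
#' every centerline pixel the measured in-path thickness t is compared with
#' the target thickness T under a tolerance band \eqn{\delta}
#' (0.05 mm by default):
#' \itemize{
#'   \item normal: \eqn{T - \delta \le t \le T + \delta} (band edges included)
#'   \item under-extrusion: \eqn{0 < t < T - \delta}
#'   \item over-extrusion: \eqn{t > T + \delta}
#'   \item filament breakage: \eqn{t = 0} while \eqn{T \ne 0}
#' }
#' The zero test is evaluated as \eqn{t < \epsilon} (an exact float zero is
#' fragile); \eqn{\epsilon} defaults to half the axial resolution when the
#' reconstruction carries one. Centerline labels are then propagated
#' laterally across the local filament width for display, using the
#' nearest-centerline assignment computed during rasterization.
#'
#' @param recon_in_path in-path thickness matrix from
#'   [mask_recon_in_path()] (or a \code{recon_model_map}, masked
#'   internally).
#' @param target a \code{target_model_map}.
#' @param tolerance_mm tolerance band half-width (mm).
#' @param zero_eps_mm threshold below which thickness counts as zero; NULL
#'   uses \code{dz_mm / 2} when available, else 1e-6.
#' @return list with \code{labels} (ny x nx integer code matrix, in-path
#'   part only) and \code{centerline_codes} (integer vector along the
#'   ordered centerline).
#' @export
classify_in_path <- function(recon_in_path, target, tolerance_mm = 0.05,
                             zero_eps_mm = NULL) {
  stopifnot(tolerance_mm >= 0)
  if (is.null(zero_eps_mm)) {
    dz <- if (!is.matrix(recon_in_path)) recon_in_path$dz_mm else NA_real_
    zero_eps_mm <- if (is.finite(dz)) dz / 2 else 1e-6
  }
  th <- if (is.matrix(recon_in_path)) recon_in_path else
    mask_recon_in_path(recon_in_path, target)
  cl <- target$centerline
  labels <- matrix(0L, target$grid$ny, target$grid$nx)
  if (nrow(cl) == 0)
    return(list(labels = labels, centerline_codes = integer()))
  lin <- cl$row + (cl$col - 1L) * target$grid$ny
  t_cl <- th[lin]
  T_cl <- target$thickness[lin]
  codes <- .classify_thickness(t_cl, T_cl, tolerance_mm, zero_eps_mm)
  # lateral propagation: each path pixel takes its owning centerline label
  on_path <- which(target$path_mask)
  labels[on_path] <- codes[target$owner[on_path]]
  list(labels = labels, centerline_codes = codes)
}

# logical-matrix wrappers around EBImage morphology
.mdilate <- function(m, brush) EBImage::dilate(m * 1, brush) > 0.5
.merode <- function(m, brush) EBImage::erode(m * 1, brush) > 0.5
.mopen <- function(m, brush) EBImage::opening(m * 1, brush) > 0.5

#' Morphological (Lantuejoul) skeleton of a binary image
#'
#' Classical morphological skeleton built from iterated erosions: the
#' union over n of \code{erode^n(X) \\ open(erode^n(X))} with a 3 x 3
#' structuring element. Used to reduce the reconstructed deposit to thin
#' centerlines before stringing detection.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels (subset of \code{mask}).
#' @export
skeletonize <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  brush <- EBImage::makeBrush(3, "box")
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  e <- mask
  while (any(e)) {
    skel <- skel | (e & !.mopen(e, brush))
    e <- .merode(e, brush)
  }
  skel
}

#' Detect stringing outside the target path
#'
#' Material deposited outside the programmed path is found by reducing the
#' binarized reconstructed deposit to its skeleton, dilating the skeleton
#' back to filament width, intersecting with the inverted target path
#' mask, and cleaning the result with a morphological opening. Surviving
#' pixels have out-of-path thickness > 0 and are labelled stringing.
#'
#' @param recon a [recon_model_map()] or thickness matrix.
#' @param target a \code{target_model_map}.
#' @param dilation_radius_px radius for re-dilating the skeleton; defaults
#'   to the target filament half-width in pixels.
#' @param opening_size side of the square opening element (default 3).
#' @param zero_eps_mm binarization threshold for the deposit.
#' @return logical ny x nx stringing mask (FALSE everywhere on the path).
#' @export
detect_stringing <- function(recon, target, dilation_radius_px = NULL,
                             opening_size = 3, zero_eps_mm = NULL) {
  th <- if (is.matrix(recon)) recon else recon$thickness
  if (!all(dim(th) == dim(target$thickness)))
    stop("reconstructed and target maps are on different grids", call. = FALSE)
  if (is.null(zero_eps_mm)) {
    dz <- if (!is.matrix(recon)) recon$dz_mm else NA_real_
    zero_eps_mm <- if (is.finite(dz)) dz / 2 else 1e-6
  }
  if (is.null(dilation_radius_px)) {
    w <- if (any(target$width > 0)) max(target$width) else 0
    dilation_radius_px <- round(w / (2 * target$grid$pitch_x))
  }
  th[is.na(th)] <- 0
  bin <- th > zero_eps_mm
  skel <- skeletonize(bin)
  if (dilation_radius_px >= 1) {
    brush <- EBImage::makeBrush(2 * as.integer(dilation_radius_px) + 1, "disc")
    skel <- .mdilate(skel, brush)
  }
  out <- skel & !target$path_mask
  if (opening_size >= 2)
    out <- .mopen(out, EBImage::makeBrush(opening_size, "box"))
  out <- out & !target$path_mask
  # keep only components backed by actual off-path deposit: re-dilating the
  # in-path skeleton can poke past path corners/ends over empty background,
  # while true stringing always contains its own material
  if (any(out)) {
    comp <- EBImage::bwlabel(out * 1)
    deposit <- bin & !target$path_mask
    real <- unique(comp[comp > 0 & deposit])
    out <- matrix(comp %in% real & comp > 0, nrow(out), ncol(out))
  }
  out
}

#' Compose the defect characterization map
#'
#' Merges the in-path classification with the out-of-path stringing mask
#' into the six-state label field.
#'
#' @param in_path result of [classify_in_path()].
#' @param stringing logical stringing mask from [detect_stringing()].
#' @param target the \code{target_model_map} the labels refer to.
#' @param tolerance_mm tolerance used (stored for provenance).
#' @param round round index.
#' @return object of class \code{defect_map}: list with \code{labels}
#'   (ny x nx integer codes 0-5), \code{grid}, \code{centerline_codes},
#'   \code{tolerance_mm}, \code{z_mm}, \code{round}.
#' @export
compose_defect_map <- function(in_path, stringing, target,
                               tolerance_mm = 0.05, round = 1L) {
  labels <- in_path$labels
  if (any(stringing & labels > 0L))
    stop("internal error: stringing overlaps in-path labels", call. = FALSE)
  labels[stringing] <- 5L
  structure(list(labels = labels, grid = target$grid,
                 centerline_codes = in_path$centerline_codes,
                 tolerance_mm = tolerance_mm,
                 z_mm = target$z_mm, round = as.integer(round)),
            class = "defect_map")
}

#' Build a defect map from reconstructed and target maps
#'
#' Convenience wrapper running [mask_recon_in_path()],
#' [classify_in_path()], [detect_stringing()] and [compose_defect_map()].
#'
#' @inheritParams classify_in_path
#' @inheritParams detect_stringing
#' @param recon a [recon_model_map()] or thickness matrix.
#' @param round round index stored in the result.
#' @return a \code{defect_map}.
#' @export
defect_map <- function(recon, target, tolerance_mm = 0.05,
                       zero_eps_mm = NULL, dilation_radius_px = NULL,
                       opening_size = 3, round = 1L) {
  in_path <- classify_in_path(mask_recon_in_path(recon, target), target,
                              tolerance_mm = tolerance_mm,
                              zero_eps_mm = zero_eps_mm %||%
                                (if (!is.matrix(recon) && is.finite(recon$dz_mm))
                                   recon$dz_mm / 2 else 1e-6))
  stringing <- detect_stringing(recon, target,
                                dilation_radius_px = dilation_radius_px,
                                opening_size = opening_size,
                                zero_eps_mm = zero_eps_mm)
  compose_defect_map(in_path, stringing, target,
                     tolerance_mm = tolerance_mm, round = round)
}

#' @export
print.defect_map <- function(x, ...) {
  counts <- tidy(x)
  cat(sprintf("defect_map: round %d, z = %g mm, tolerance %g mm\n",
              x$round, x$z_mm, x$tolerance_mm))
  print(as.data.frame(counts))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-class pixel counts and areas of a defect map
#'
#' @param x a \code{defect_map}.
#' @param ... unused.
#' @return tibble with one row per class: \code{class}, \code{code},
#'   \code{n_pixels}, \code{area_mm2}.
#' @method tidy defect_map
#' @export
tidy.defect_map <- function(x, ...) {
  dc <- defect_classes()
  n <- vapply(dc$code, function(code) sum(x$labels == code), integer(1))
  px_area <- x$grid$pitch_x * x$grid$pitch_y
  tibble::tibble(class = dc$class, code = dc$code, n_pixels = n,
                 area_mm2 = n * px_area)
}

#' @method glance defect_map
#' @export
glance.defect_map <- function(x, ...) {
  counts <- tidy(x)
  defect <- counts$n_pixels[counts$class %in%
    c("under_extrusion", "over_extrusion", "filament_breakage", "stringing")]
  in_path <- sum(counts$n_pixels[counts$code %in% 1:4])
  tibble::tibble(round = x$round, z_mm = x$z_mm,
                 tolerance_mm = x$tolerance_mm,
                 n_path_pixels = in_path,
                 n_defect_pixels = sum(defect),
                 defect_fraction = if (in_path > 0) sum(defect) / in_path else NA_real_)
}

#' Measure maximal defect runs along the centerline
#'
#' Walks the ordered target centerline and extracts maximal consecutive
#' runs of a defect class. A run's arc length is the sum of its centerline
#' step lengths (pixel pitch for axis-aligned steps, pitch * sqrt(2) for
#' diagonal steps); runs never bridge disconnected centerline jumps
#' (travel moves).
#'
#' @param dmap a \code{defect_map}.
#' @param target the \code{target_model_map} it was computed against.
#' @param classes which classes to report runs for (default: the three
#'   in-path defect classes).
#' @return tibble with one row per run: \code{class}, \code{z_mm},
#'   \code{x0_mm}, \code{y0_mm}, \code{x1_mm}, \code{y1_mm},
#'   \code{length_mm}, \code{n_pixels}, \code{start_index},
#'   \code{end_index} (indices into the centerline), and a \code{path}
#'   list-column of per-run centerline coordinates (tibble of
#'   \code{x_mm,y_mm}).
#' @export
measure_defect_runs <- function(dmap, target,
                                classes = c("under_extrusion",
                                            "over_extrusion",
                                            "filament_breakage")) {
  cl <- target$centerline
  codes <- dmap$centerline_codes
  stopifnot(length(codes) == nrow(cl))
  want <- .class_code(classes)
  if (nrow(cl) == 0) return(.empty_runs())
  # break runs at label changes and at disconnected steps
  grp <- cumsum(c(TRUE, codes[-1] != codes[-length(codes)] | !cl$connected[-1]))
  rows <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    code <- codes[idx[1]]
    if (!code %in% want) next
    i0 <- idx[1]; i1 <- idx[length(idx)]
    p0 <- pixel_to_mm(target$grid, cl$col[i0], cl$row[i0])
    p1 <- pixel_to_mm(target$grid, cl$col[i1], cl$row[i1])
    pp <- pixel_to_mm(target$grid, cl$col[idx], cl$row[idx])
    rows[[length(rows) + 1]] <- tibble::tibble(
      class = defect_classes()$class[match(code, defect_classes()$code)],
      z_mm = target$z_mm,
      x0_mm = p0$x_mm, y0_mm = p0$y_mm, x1_mm = p1$x_mm, y1_mm = p1$y_mm,
      length_mm = cl$arc_mm[i1] - cl$arc_mm[i0],
      n_pixels = length(idx),
      start_index = i0, end_index = i1,
      path = list(pp))
  }
  if (length(rows) == 0) return(.empty_runs())
  dplyr::bind_rows(rows)
}

.empty_runs <- function() {
  tibble::tibble(class = character(), z_mm = numeric(),
                 x0_mm = numeric(), y0_mm = numeric(),
                 x1_mm = numeric(), y1_mm = numeric(),
                 length_mm = numeric(), n_pixels = integer(),
                 start_index = integer(), end_index = integer(),
                 path = list())
}
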