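#' Box-window local mean with symmetric border padding
#'
#' @param m numeric matrix.
#' @param w odd window side length, \code{w <= min(dim(m))}.
#' @return matrix of the same size: mean of the w x w window centred on
#'   each pixel, borders reflected.
#' @keywords internal
.box_mean <- function(m, w) {
  r <- (w - 1L) / 2L
  n <- nrow(m); p <- ncol(m)
  if (r > 0) {
    ri <- c(r:1, 1:n, n:(n - r + 1))
    ci <- c(r:1, 1:p, p:(p - r + 1))
    m <- m[ri, ci, drop = FALSE]
  }
  # summed-area table with a leading zero row/column
  S <- apply(m, 2, cumsum)
  S <- t(apply(S, 1, cumsum))
  S <- rbind(0, cbind(0, S))
  (S[(1 + w):(n + w), (1 + w):(p + w)] -
     S[1:n, (1 + w):(p + w)] -
     S[(1 + w):(n + w), 1:p] +
     S[1:n, 1:p]) / w^2
}

#' SSIM parameters
#'
#' The moving-window size is determined by the target filament diameter
#' (width in mm divided by the pixel pitch, forced odd); the stability
#' constants default to the conventional \eqn{c_1 = (0.01 L)^2},
#' \eqn{c_2 = (0.03 L)^2} with dynamic range L taken from the compared
#' fields.
#'
#' @param window_px odd window side length (>= 3).
#' @param L dynamic range of the compared fields.
#' @param c1,c2 stability constants; defaults derived from \code{L}.
#' @return list of class \code{ssim_params}.
#' @export
ssim_params <- function(window_px, L, c1 = (0.01 * L)^2, c2 = (0.03 * L)^2) {
  window_px <- as.integer(window_px)
  if (window_px %% 2 == 0) window_px <- window_px + 1L
  stopifnot(window_px >= 3, c1 > 0, c2 > 0)
  structure(list(window_px = window_px, L = L, c1 = c1, c2 = c2),
            class = "ssim_params")
}

#' Window size from filament diameter
#'
#' @param width_mm target filament width (mm).
#' @param pitch_mm pixel pitch (mm).
#' @return odd integer window side, at least 3.
#' @export
ssim_window_from_filament <- function(width_mm, pitch_mm) {
  w <- round(width_mm / pitch_mm)
  w <- as.integer(w)
  if (w %% 2 == 0) w <- w + 1L
  max(w, 3L)
}

#' Structural similarity between two thickness fields
#'
#' Windowed SSIM:
#' \deqn{SSIM(x,y) = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
#'   {(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}}
#' with local means, variances and covariance computed over uniform (box)
#' windows with symmetric border padding. The mean of the per-pixel SSIM
#' map over the evaluation support is the fidelity value.
#'
#' @param x,y numeric matrices of equal shape (target and evaluation
#'   field).
#' @param params an [ssim_params()]; when NULL, the window is derived from
#'   \code{window_px} / \code{L} arguments.
#' @param window_px window side; default 11.
#' @param L dynamic range; default \code{max(x, y)} (1 if both fields are
#'   all zero).
#' @param support \code{"all"} (mean over every pixel, default) or a
#'   logical matrix restricting the mean.
#' @return object of class \code{fidelity_result}: list with
#'   \code{ssim_map}, \code{mean_ssim}, \code{params}, \code{support}.
#' @export
ssim <- function(x, y, params = NULL, window_px = 11L, L = NULL,
                 support = "all") {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)))
  if (is.null(params)) {
    if (is.null(L)) L <- max(x, y, na.rm = TRUE)
    if (!is.finite(L) || L <= 0) L <- 1
    params <- ssim_params(window_px, L)
  }
  w <- params$window_px
  if (w > min(dim(x)))
    stop(sprintf("SSIM window (%d px) larger than image (%d x %d)",
                 w, nrow(x), ncol(x)), call. = FALSE)
  mu_x <- .box_mean(x, w); mu_y <- .box_mean(y, w)
  var_x <- .box_mean(x * x, w) - mu_x^2
  var_y <- .box_mean(y * y, w) - mu_y^2
  cov_xy <- .box_mean(x * y, w) - mu_x * mu_y
  # clamp tiny negative variances from float cancellation
  var_x <- pmax(var_x, 0); var_y <- pmax(var_y, 0)
  c1 <- params$c1; c2 <- params$c2
  smap <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean_ssim <- if (is.matrix(support)) mean(smap[support]) else mean(smap)
  structure(list(ssim_map = smap, mean_ssim = mean_ssim,
                 params = params,
                 support = if (is.matrix(support)) "masked" else "all"),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("fidelity_result: mean SSIM %.4f (window %d px, support %s)\n",
              x$mean_ssim, x$params$window_px, x$support))
  invisible(x)
}

#' @method glance fidelity_result
#' @export
glance.fidelity_result <- function(x, ...) {
  tibble::tibble(mean_ssim = x$mean_ssim, window_px = x$params$window_px,
                 c1 = x$params$c1, c2 = x$params$c2, L = x$params$L)
}

#' Evaluation field for fidelity: reconstructed model in and out of path
#'
#' The binarized defect characterization map (any non-background label) is
#' point-multiplied with the reconstructed printed model, so the fidelity
#' comparison sees the deposit both inside the path and at stringing
#' locations outside it.
#'
#' @param dmap a \code{defect_map}.
#' @param recon a [recon_model_map()] or thickness matrix.
#' @return ny x nx thickness matrix.
#' @export
build_recon_full <- function(dmap, recon) {
  th <- if (is.matrix(recon)) recon else recon$thickness
  if (!all(dim(th) == dim(dmap$labels)))
    stop("defect map and reconstruction are on different grids", call. = FALSE)
  th[is.na(th)] <- 0
  th * (dmap$labels > 0L)
}

#' Fidelity of one print round
#'
#' Convenience wrapper: builds the evaluation field with
#' [build_recon_full()] and compares it against the target thickness map
#' with [ssim()], the window sized by the target filament diameter.
#'
#' @param target a \code{target_model_map}.
#' @param recon a [recon_model_map()] or thickness matrix.
#' @param dmap a \code{defect_map}; computed with defaults when NULL.
#' @param window_px optional window override.
#' @param ... passed to [defect_map()] when \code{dmap} is NULL.
#' @return a \code{fidelity_result}.
#' @export
print_fidelity <- function(target, recon, dmap = NULL, window_px = NULL, ...) {
  if (is.null(dmap)) dmap <- defect_map(recon, target, ...)
  if (is.null(window_px)) {
    w_mm <- if (any(target$width > 0)) max(target$width) else 0.41
    window_px <- ssim_window_from_filament(w_mm, target$grid$pitch_x)
  }
  eval_field <- build_recon_full(dmap, recon)
  L <- max(target$thickness)
  if (L <= 0) L <- 1
  ssim(target$thickness, eval_field, params = ssim_params(window_px, L))
}

#' Per-layer fidelity series
#'
#' @param x a list of \code{fidelity_result} (or numeric vector of mean
#'   SSIM values), one per layer/round.
#' @param layer optional layer/round ids.
#' @return tibble of class \code{fidelity_series} with columns
#'   \code{layer}, \code{mean_ssim}.
#' @export
fidelity_series <- function(x, layer = NULL) {
  vals <- if (is.numeric(x)) x else
    vapply(x, function(r) r$mean_ssim, numeric(1))
  stopifnot(length(vals) >= 1)
  if (is.null(layer)) layer <- seq_along(vals)
  out <- tibble::tibble(layer = layer, mean_ssim = vals)
  class(out) <- c("fidelity_series", class(out))
  out
}

#' Summary of a fidelity series (mean and spread)
#'
#' Reported as mean with standard error of the mean, the convention for
#' per-layer fidelity summaries; sd is included too. A single layer
#' reports zero spread by convention.
#'
#' @param x a [fidelity_series()].
#' @param ... unused.
#' @return one-row tibble: \code{n}, \code{mean}, \code{sd}, \code{sem}.
#' @method glance fidelity_series
#' @export
glance.fidelity_series <- function(x, ...) {
  n <- nrow(x)
  sd <- if (n > 1) stats::sd(x$mean_ssim) else 0
  tibble::tibble(n = n, mean = mean(x$mean_ssim), sd = sd,
                 sem = if (n > 1) sd / sqrt(n) else 0)
}

#' Relative improvement between two fidelity values
#'
#' \code{(after - before) / before * 100} — the percentage by which a
#' repair (or any intervention) improved mean SSIM.
#'
#' @param before,after mean SSIM before and after.
#' @return improvement in percent.
#' @export
relative_improvement <- function(before, after) {
  (after - before) / before * 100
}
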