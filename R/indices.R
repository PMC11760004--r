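#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline.  Defaults follow the
#' package's standard operating point: tile step size 70 per axis, tile
#' inclusion at 50 percent muscle coverage, 8-connectivity, no minimum
#' particle size.
#'
#' @param step tiles per axis for the F7 grid (integer >= 2).
#' @param min_coverage minimum fraction of a tile's pixels that must lie in
#'   the ROI for the tile to enter the F7 statistic, in (0, 1].
#' @param connectivity particle connectivity, 4 or 8.
#' @param min_area minimum particle area in pixels (>= 1).
#' @param pixels_per_cm optional scale calibration; required only for the
#'   Kuchida fineness index.
#' @param seed optional integer seed recorded in run logs.
#' @param threshold_method thresholding algorithm, currently `"otsu"`.
#' @return a `mf_config` list.
#' @export
mf_config <- function(step = 70, min_coverage = 0.5, connectivity = 8,
                      min_area = 1, pixels_per_cm = NULL, seed = NULL,
                      threshold_method = "otsu") {
  if (!is.numeric(step) || step < 2 || step != round(step))
    mf_stop("config", "step must be an integer >= 2")
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1)
    mf_stop("config", "min_coverage must be in (0, 1]")
  if (!connectivity %in% c(4, 8))
    mf_stop("config", "connectivity must be 4 or 8")
  if (!is.numeric(min_area) || min_area < 1)
    mf_stop("config", "min_area must be >= 1")
  if (!is.null(pixels_per_cm) && (!is.numeric(pixels_per_cm) || pixels_per_cm <= 0))
    mf_stop("config", "pixels_per_cm must be a positive number")
  threshold_method <- match.arg(threshold_method, c("otsu"))
  structure(list(step = as.integer(step), min_coverage = min_coverage,
                 connectivity = as.integer(connectivity),
                 min_area = as.integer(min_area),
                 pixels_per_cm = pixels_per_cm, seed = seed,
                 threshold_method = threshold_method),
            class = "mf_config")
}

#' Basic fineness index candidates F1a..F6
#'
#' Direct functions of the particle table and its cumulative statistics:
#' \describe{
#'   \item{F1a}{number of marbling particles, `n`}
#'   \item{F1b}{total marbling area, `A_total` (pixels)}
#'   \item{F2a}{`A50`, the particle area at 50 percent area cumulation}
#'   \item{F2b}{`A50 / A_total` (scale-corrected F2a)}
#'   \item{F3a}{`P50`, the particle perimeter at 50 percent perimeter cumulation}
#'   \item{F3b}{`P50 / P_total`}
#'   \item{F4}{number of smallest particles whose cumulative area fraction
#'     stays below 0.5 on the area-sorted sequence}
#'   \item{F5}{mean of squared perimeter to area, `avg(p_i^2 / a_i)`}
#'   \item{F6}{`A50 * P50`}
#' }
#'
#' @param table a `particle_table`.
#' @param stats its [cumulative_stats()]; computed if missing.
#' @return named list `F1a`..`F6`.
#' @export
basic_indices <- function(table, stats = cumulative_stats(table)) {
  if (nrow(table) == 0L)
    mf_stop("empty_marbling", "no marbling particles in mask")
  n <- nrow(table)
  list(F1a = n,
       F1b = stats$A_total,
       F2a = stats$A50,
       F2b = stats$A50 / stats$A_total,
       F3a = stats$P50,
       F3b = stats$P50 / stats$P_total,
       F4  = stats$i_A50 - 1L,
       F5  = mean(table$perimeter_px^2 / table$area_px),
       F6  = stats$A50 * stats$P50)
}

#' Build the tile grid for the F7 statistic
#'
#' The bounding box of the ROI is split into `step` x `step` tiles with
#' integer pixel boundaries at `floor(k * extent / step)` (half-open).  A
#' tile is included when at least `min_coverage` of its pixels lie inside
#' the ROI; for included tiles the fat-area ratio is
#' `x_i = fat pixels / ROI pixels` in the tile, so partially covered border
#' tiles are normalized by their muscle portion rather than their full
#' rectangle.
#'
#' @param mask a `marbling_mask` or logical fat matrix.
#' @param roi logical ROI matrix of the same dimensions.
#' @param step tiles per axis (integer >= 2); both bounding-box dimensions
#'   must be at least `step` pixels.
#' @param min_coverage tile inclusion threshold in (0, 1].
#' @return a `tile_grid` list: `step`, per-tile vectors `roi_px`, `fat_px`,
#'   `tile_px`, `included` (length `step^2`, row-major over tiles), the
#'   included ratios `x`, their count `n_tiles` and mean `x_bar`, and the
#'   bounding box `bbox`.
#' @export
build_tile_grid <- function(mask, roi, step, min_coverage = 0.5) {
  fat <- as_fat_matrix(mask)
  stopifnot(identical(dim(fat), dim(roi)))
  step <- as.integer(step)
  if (step < 2L) mf_stop("invalid_step_size", "step must be >= 2")
  if (min_coverage <= 0 || min_coverage > 1)
    mf_stop("config", "min_coverage must be in (0, 1]")
  idx <- which(roi, arr.ind = TRUE)
  if (nrow(idx) == 0L) mf_stop("no_tiles_included", "empty ROI")
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  ext_r <- r1 - r0 + 1L; ext_c <- c1 - c0 + 1L
  if (ext_r < step || ext_c < step)
    mf_stop("invalid_step_size",
            "ROI bounding box %dx%d smaller than step %d", ext_r, ext_c, step)
  b_r <- floor((0:step) * ext_r / step)   # boundaries of 0-based offsets
  b_c <- floor((0:step) * ext_c / step)
  # tile index (1..step) of each ROI pixel
  ti <- findInterval(idx[, 1] - r0, b_r[1:step])
  tj <- findInterval(idx[, 2] - c0, b_c[1:step])
  tile_id <- (ti - 1L) * step + tj
  roi_px <- tabulate(tile_id, nbins = step * step)
  fat_here <- fat[idx]
  fat_px <- tabulate(tile_id[fat_here], nbins = step * step)
  tile_px <- as.vector(t(outer(diff(b_r), diff(b_c))))  # row-major tile sizes
  included <- roi_px > 0 & roi_px / tile_px >= min_coverage
  if (!any(included)) mf_stop("no_tiles_included",
                              "no tile reaches coverage %.2f", min_coverage)
  x <- fat_px[included] / roi_px[included]
  structure(list(step = step, roi_px = roi_px, fat_px = fat_px,
                 tile_px = tile_px, included = included,
                 x = x, n_tiles = sum(included), x_bar = mean(x),
                 bbox = c(r0 = r0, c0 = c0, r1 = r1 + 1L, c1 = c1 + 1L)),
            class = "tile_grid")
}

#' F7: tile-grid heterogeneity of the fat-area ratio
#'
#' The sample standard deviation (denominator `n - 1`) of the per-tile
#' fat-area ratios of the included tiles:
#' `F7 = sqrt( sum (x_i - x_bar)^2 / (n_tiles - 1) )`.
#' Evenly distributed fine marbling gives near-equal tile ratios and a low
#' F7; coarse streaks concentrate fat in few tiles and raise it.
#'
#' @param grid a `tile_grid` from [build_tile_grid()].
#' @return non-negative scalar.
#' @export
compute_f7 <- function(grid) {
  if (grid$n_tiles < 2L)
    mf_stop("insufficient_tiles", "F7 needs at least 2 included tiles")
  stats::sd(grid$x)
}

#' F8: ratio of F2b to F7
#'
#' @param f2b scale-corrected half-cumulation area (see [basic_indices()]).
#' @param f7 tile heterogeneity (see [compute_f7()]); must be positive.
#' @return scalar `f2b / f7`.
#' @export
compute_f8 <- function(f2b, f7) {
  if (!is.finite(f7) || f7 <= 0)
    mf_stop("undefined_ratio", "F8 undefined for F7 = 0")
  f2b / f7
}

#' Kuchida fineness index
#'
#' Count of marbling particles sized between 0.01 and 0.5 cm^2, divided by
#' the loin-eye (ROI) area in cm^2 — the classical Wagyu-oriented fineness
#' measure, used here as an external reference: it correlates negatively
#' with F7.
#'
#' @param table a `particle_table`.
#' @param roi logical ROI matrix (loin-eye region).
#' @param pixels_per_cm scale calibration (pixels per centimeter).
#' @return particles per cm^2.
#' @export
kuchida_index <- function(table, roi, pixels_per_cm) {
  if (missing(pixels_per_cm) || is.null(pixels_per_cm))
    mf_stop("missing_scale", "kuchida_index requires pixels_per_cm")
  ppc2 <- pixels_per_cm^2
  a_cm2 <- table$area_px / ppc2
  n_small <- sum(a_cm2 >= 0.01 & a_cm2 <= 0.5)
  n_small / (sum(roi) / ppc2)
}

#' Compute the full index vector for one image
#'
#' End-to-end composition: segmentation (Otsu on ROI luminance), particle
#' labeling, cumulative statistics, F1a..F6, the tile grid and F7 at the
#' configured step size, F8, and (when a scale is configured) the Kuchida
#' index.  Identical to running each stage separately.
#'
#' @param img H x W x 3 intensity array (or H x W matrix), or a
#'   `marbling_mask` to skip segmentation.
#' @param roi logical ROI matrix.
#' @param config an [mf_config()].
#' @param image_id identifier attached to error messages and the output row.
#' @return an `index_vector`: one-row data frame with columns `image_id`,
#'   `F1a`..`F8`, `kuchida`, `step`, `threshold_used`, `n_tiles`.
#' @export
compute_all <- function(img, roi, config = mf_config(), image_id = NA_character_) {
  tryCatch({
    mask <- if (inherits(img, "marbling_mask")) img
            else segment_marbling(img, roi)
    tab <- label_particles(mask, connectivity = config$connectivity,
                           min_area = config$min_area)
    st <- cumulative_stats(tab)
    bi <- basic_indices(tab, st)
    grid <- build_tile_grid(mask, roi, step = config$step,
                            min_coverage = config$min_coverage)
    f7 <- compute_f7(grid)
    f8 <- if (f7 > 0) bi$F2b / f7 else NA_real_
    kuch <- if (!is.null(config$pixels_per_cm))
      kuchida_index(tab, roi, config$pixels_per_cm) else NA_real_
    out <- data.frame(image_id = image_id,
                      F1a = bi$F1a, F1b = bi$F1b, F2a = bi$F2a, F2b = bi$F2b,
                      F3a = bi$F3a, F3b = bi$F3b, F4 = bi$F4, F5 = bi$F5,
                      F6 = bi$F6, F7 = f7, F8 = f8, kuchida = kuch,
                      step = config$step,
                      threshold_used = if (inherits(mask, "marbling_mask"))
                        mask$threshold_used else NA_integer_,
                      n_tiles = grid$n_tiles)
    class(out) <- c("index_vector", "data.frame")
    out
  }, error = function(e) {
    if (inherits(e, "mf_error") && !is.na(image_id))
      e$message <- sprintf("[image %s] %s", image_id, e$message)
    stop(e)
  })
}
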