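#' Elliptical region-of-interest mask
#'
#' @param height,width mask dimensions in pixels.
#' @param center `(row, col)` of the ellipse center; defaults to the image
#'   center.
#' @param semiaxes `(row, col)` semi-axes in pixels; `NULL` gives a
#'   full-rectangle ROI.
#' @return logical `height` x `width` matrix.
#' @export
ellipse_roi <- function(height, width, center = NULL, semiaxes = NULL) {
  if (is.null(semiaxes)) return(matrix(TRUE, height, width))
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  dr <- ((seq_len(height) - center[1]) / semiaxes[1])^2
  dc <- ((seq_len(width) - center[2]) / semiaxes[2])^2
  outer(dr, dc, `+`) <= 1
}

#' Specification of a synthetic marbling image
#'
#' Describes a Boolean-model marbling texture: overlapping deformed disks
#' (fat flecks) placed uniformly inside an elliptical muscle ROI until a
#' target intramuscular-fat area fraction is reached, then rendered as a
#' bright-fat / dark-lean image with additive Gaussian noise so that the
#' Otsu segmentation stage is exercised end to end.
#'
#' Defaults render fat about 80 luminance levels above lean with noise
#' sd 8, comfortably inside the regime where Otsu recovers the truth mask.
#'
#' @param image_size `(H, W)` in pixels.
#' @param roi_semiaxes `(row, col)` ellipse semi-axes, or `NULL` for a
#'   full-rectangle ROI.
#' @param target_imf_fraction fat area fraction inside the ROI, in (0, 1).
#' @param particle_radius_mean,particle_radius_sd truncated-normal blob
#'   radius parameters in pixels (radii below 0.5 px are rejected).
#' @param shape_irregularity >= 0; blobs are ellipses with random
#'   orientation and aspect up to `1 + shape_irregularity`.
#' @param fat_intensity_mean,lean_intensity_mean 8-bit luminance levels;
#'   fat must be brighter than lean.
#' @param noise_sd Gaussian noise standard deviation (intensity levels).
#' @param seed integer; fully determines the image.
#' @param label fineness label attached to generated images.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_size = c(560, 560),
                           roi_semiaxes = c(200, 240),
                           target_imf_fraction = 0.35,
                           particle_radius_mean = 6,
                           particle_radius_sd = 1.5,
                           shape_irregularity = 0.3,
                           fat_intensity_mean = 200,
                           lean_intensity_mean = 120,
                           noise_sd = 8,
                           seed = 1,
                           label = "custom") {
  if (target_imf_fraction <= 0 || target_imf_fraction >= 1)
    mf_stop("config", "target_imf_fraction must be in (0, 1)")
  if (fat_intensity_mean <= lean_intensity_mean)
    mf_stop("config", "fat must be brighter than lean")
  if (particle_radius_mean <= 0 || particle_radius_sd < 0 || noise_sd < 0 ||
      shape_irregularity < 0)
    mf_stop("config", "negative synthetic parameter")
  structure(list(image_size = as.integer(image_size),
                 roi_semiaxes = roi_semiaxes,
                 target_imf_fraction = target_imf_fraction,
                 particle_radius_mean = particle_radius_mean,
                 particle_radius_sd = particle_radius_sd,
                 shape_irregularity = shape_irregularity,
                 fat_intensity_mean = fat_intensity_mean,
                 lean_intensity_mean = lean_intensity_mean,
                 noise_sd = noise_sd,
                 seed = as.integer(seed),
                 label = label),
            class = "synthetic_spec")
}

#' Fineness presets for the synthetic generator
#'
#' Three presets at a matched fat fraction of 0.35 so that only particle
#' size — not fat amount — separates the groups: fine (radius mean 2 px),
#' medium (6 px), coarse (12 px), each with radius sd of 25 percent of the
#' mean, on 560 x 560 images with a 400 x 480 elliptical ROI (every step
#' size from 5 to 95 is then valid).
#'
#' @param label `"fine"`, `"medium"` or `"coarse"`.
#' @param image_size `(H, W)`; smaller sizes scale the ROI proportionally.
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `synthetic_spec`.
#' @export
fineness_preset <- function(label = c("fine", "medium", "coarse"),
                            image_size = c(560, 560), seed = 1, ...) {
  label <- match.arg(label)
  radius <- c(fine = 2, medium = 6, coarse = 12)[[label]]
  scale <- min(image_size / c(560, 560))
  args <- list(image_size = image_size,
               roi_semiaxes = c(200, 240) * scale,
               target_imf_fraction = 0.35,
               particle_radius_mean = radius,
               particle_radius_sd = radius / 4,
               seed = seed, label = label)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_spec, args)
}

# sample a truncated-normal blob radius (lower bound 0.5 px)
sample_radius <- function(mean, sd) {
  for (i in 1:100) {
    r <- stats::rnorm(1, mean, sd)
    if (r >= 0.5) return(r)
  }
  0.5
}

#' Generate one synthetic marbling image
#'
#' Places deformed-disk fat blobs at uniform ROI locations until the
#' fat-pixel fraction first reaches the target; the last blob's overshoot
#' is trimmed back pixel-by-pixel so the realized fraction matches the
#' target to within rounding.  The rendered image is the truth mask drawn
#' at the fat/lean intensities (lean with a mild red tint, luminance
#' preserved) over a dark background, plus per-channel Gaussian noise.
#' Bit-identical for a fixed spec and seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_image` list: `image` (H x W x 3 integer array),
#'   `roi`, `truth_mask` (a `marbling_mask`), `truth_label`,
#'   `realized_imf`, `spec`.
#' @export
generate_image <- function(spec) {
  H <- spec$image_size[1]; W <- spec$image_size[2]
  roi <- ellipse_roi(H, W, semiaxes = spec$roi_semiaxes)
  roi_idx <- which(roi)
  n_roi <- length(roi_idx)
  ext <- c(diff(range((roi_idx - 1L) %% H)),
           diff(range((roi_idx - 1L) %/% H))) + 1L
  if (2 * spec$particle_radius_mean >= min(ext))
    mf_stop("unreachable_fraction",
            "blob radius %.1f exceeds ROI extent %d",
            spec$particle_radius_mean, min(ext))
  target_px <- max(1L, as.integer(round(spec$target_imf_fraction * n_roi)))

  out <- with_seed(spec$seed, {
    fat <- matrix(FALSE, H, W)
    count <- 0L
    guard <- 0L
    repeat {
      guard <- guard + 1L
      if (guard > 200000L)
        mf_stop("unreachable_fraction", "fat fraction target not reached")
      ctr <- roi_idx[sample.int(n_roi, 1L)]
      cr <- ((ctr - 1L) %% H) + 1L
      cc <- ((ctr - 1L) %/% H) + 1L
      r <- sample_radius(spec$particle_radius_mean, spec$particle_radius_sd)
      e <- 1 + spec$shape_irregularity * stats::runif(1)
      th <- stats::runif(1, 0, pi)
      Rw <- ceiling(r * e)
      dr <- (-Rw):Rw
      rr <- cr + dr; cs <- cc + dr
      ok_r <- rr >= 1L & rr <= H; ok_c <- cs >= 1L & cs <= W
      if (!any(ok_r) || !any(ok_c)) next
      drm <- matrix(dr[ok_r], nrow = sum(ok_r), ncol = sum(ok_c))
      dcm <- matrix(dr[ok_c], nrow = sum(ok_r), ncol = sum(ok_c), byrow = TRUE)
      u <- (drm * cos(th) + dcm * sin(th)) / (r * e)
      v <- (-drm * sin(th) + dcm * cos(th)) / (r / e)
      hit <- which(u * u + v * v <= 1, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      lin <- (cs[ok_c][hit[, 2]] - 1L) * H + rr[ok_r][hit[, 1]]
      lin <- lin[roi[lin] & !fat[lin]]
      if (length(lin) == 0L) next
      fat[lin] <- TRUE
      count <- count + length(lin)
      if (count >= target_px) {
        excess <- count - target_px
        if (excess > 0L) {
          drop <- lin[sample.int(length(lin), excess)]
          fat[drop] <- FALSE
          count <- target_px
        }
        break
      }
    }

    lum_tint <- 0.299 * 1.15 + 0.587 * 0.95 + 0.114 * 0.85  # ~= 1
    lean <- spec$lean_intensity_mean / lum_tint
    base_r <- matrix(8, H, W); base_g <- base_r; base_b <- base_r
    base_r[roi] <- lean * 1.15; base_g[roi] <- lean * 0.95
    base_b[roi] <- lean * 0.85
    base_r[fat] <- spec$fat_intensity_mean
    base_g[fat] <- spec$fat_intensity_mean
    base_b[fat] <- spec$fat_intensity_mean
    img <- array(0L, dim = c(H, W, 3))
    for (ch in 1:3) {
      b <- switch(ch, base_r, base_g, base_b)
      v <- round(b + stats::rnorm(H * W, 0, spec$noise_sd))
      v[v < 0] <- 0; v[v > 255] <- 255
      img[, , ch] <- as.integer(v)
    }
    list(img = img, fat = fat, count = count)
  })

  structure(list(image = out$img, roi = roi,
                 truth_mask = structure(list(fat = out$fat,
                                             threshold_used = NA_integer_),
                                        class = "marbling_mask"),
                 truth_label = spec$label,
                 realized_imf = out$count / n_roi,
                 spec = spec),
            class = "synthetic_image")
}

#' Generate a labeled three-group synthetic panel
#'
#' Mirrors a graded image panel: `n_per_group` images per fineness label,
#' with per-image seeds derived arithmetically from `base_seed` so the
#' whole panel is reproducible from one integer.
#'
#' @param n_per_group images per label (>= 2).
#' @param fine_spec,medium_spec,coarse_spec [synthetic_spec()]s sharing
#'   image size, ROI and target fat fraction; `medium_spec` may be `NULL`
#'   for a two-group panel.
#' @param base_seed integer.
#' @return list of `synthetic_image`; labels via
#'   `vapply(panel, function(s) s$truth_label, "")`.
#' @export
generate_panel <- function(n_per_group, fine_spec, medium_spec, coarse_spec,
                           base_seed = 1) {
  if (n_per_group < 2L) mf_stop("config", "n_per_group must be >= 2")
  specs <- Filter(Negate(is.null), list(fine_spec, medium_spec, coarse_spec))
  shared <- function(f) length(unique(vapply(specs, function(s)
    paste(s[[f]], collapse = ","), ""))) == 1L
  if (!shared("image_size") || !shared("roi_semiaxes") ||
      !shared("target_imf_fraction"))
    mf_stop("config", "panel specs must share image size, ROI and fat fraction")
  panel <- vector("list", length(specs) * n_per_group)
  k <- 0L
  for (s in specs) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      s$seed <- as.integer(base_seed + k)
      panel[[k]] <- generate_image(s)
    }
  }
  panel
}

#' Labels of a synthetic panel
#' @param panel list of `synthetic_image`.
#' @return character vector of truth labels.
#' @export
panel_labels <- function(panel) vapply(panel, function(s) s$truth_label, "")
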