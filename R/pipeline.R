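#' Load a JSON run configuration
#'
#' Recognized keys: `step`, `min_coverage`, `connectivity`, `min_area`,
#' `pixels_per_cm`, `seed`; unknown keys are rejected so typos fail loudly.
#'
#' @param path JSON file path.
#' @return an [mf_config()].
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("step", "min_coverage", "connectivity", "min_area",
             "pixels_per_cm", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) mf_stop("config", "unknown config keys: %s",
                           paste(bad, collapse = ", "))
  do.call(mf_config, cfg)
}

image_exts <- c("png", "tif", "tiff", "jpg", "jpeg")

pair_inputs <- function(images_dir, rois_dir) {
  imgs <- list.files(images_dir, full.names = TRUE)
  imgs <- imgs[tolower(tools::file_ext(imgs)) %in% image_exts]
  if (length(imgs) == 0L)
    mf_stop("pairing", "no images found in %s", images_dir)
  rois <- list.files(rois_dir, full.names = TRUE)
  roi_of <- function(img) {
    stem <- tools::file_path_sans_ext(basename(img))
    hit <- rois[tools::file_path_sans_ext(basename(rois)) == stem]
    if (length(hit) == 0L)
      mf_stop("pairing", "no ROI found for image %s", basename(img))
    hit[1]
  }
  data.frame(image = imgs, roi = vapply(imgs, roi_of, ""),
             id = tools::file_path_sans_ext(basename(imgs)),
             row.names = NULL)
}

#' Run the full marbling analysis pipeline over a directory of images
#'
#' For every image/ROI pair: segment (Otsu), write the binary mask and its
#' threshold sidecar, write the particle table, and append one row to
#' `indices.csv`.  With a manifest providing fineness labels, fine-versus-
#' coarse Welch tests and a three-group ANOVA on the chosen index are
#' written to `comparisons.csv`; with `steps`, a step-size sweep to
#' `sweep.csv` and a long-format `boxplot_data.tsv`.  A run log records the
#' configuration, seed and per-image thresholds; re-running with identical
#' inputs reproduces identical CSVs.  A degenerate image is logged and
#' skipped rather than aborting the panel.
#'
#' @param images_dir,rois_dir input directories; ROIs are matched to images
#'   by file stem.
#' @param out_dir output directory (created).
#' @param config an [mf_config()].
#' @param manifest optional CSV path with columns `image_id`, `label`
#'   (fine/medium/coarse) and optionally `bms`.
#' @param steps optional integer vector: run [step_size_sweep()].
#' @param compare_index index column used for group comparisons
#'   (default `"F7"`).
#' @return invisibly, a list with `indices` (data frame), `n_failed`, and
#'   file paths; errors per image are collected in `failures`.
#' @export
run_pipeline <- function(images_dir, rois_dir, out_dir,
                         config = mf_config(), manifest = NULL,
                         steps = NULL, compare_index = "F7") {
  pairs <- pair_inputs(images_dir, rois_dir)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "particles"), showWarnings = FALSE)

  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("image_id", "label") %in% names(man)))
      mf_stop("config", "manifest needs image_id and label columns")
  }

  rows <- list(); failures <- list()
  masks <- list(); rois <- list()
  for (i in seq_len(nrow(pairs))) {
    id <- pairs$id[i]
    res <- tryCatch({
      img <- read_rgb_image(pairs$image[i])
      roi <- read_roi_mask(pairs$roi[i], dim = dim(img)[1:2])
      mask <- segment_marbling(img, roi)
      write_mask(mask, file.path(out_dir, "masks", paste0(id, "_mask.png")))
      tab <- label_particles(mask, connectivity = config$connectivity,
                             min_area = config$min_area)
      write_particle_table(tab, file.path(out_dir, "particles",
                                          paste0(id, ".csv")))
      iv <- compute_all(mask, roi, config, image_id = id)
      list(iv = iv, mask = mask, roi = roi)
    }, mf_error = function(e) e)
    if (inherits(res, "mf_error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      rows[[id]] <- res$iv; masks[[id]] <- res$mask; rois[[id]] <- res$roi
    }
  }
  if (length(rows) == 0L)
    mf_stop("pairing", "all %d images failed; first error: %s",
            nrow(pairs), failures[[1]])

  indices <- do.call(rbind, rows)
  indices$group <- NA_character_; indices$bms <- NA_integer_
  if (!is.null(man)) {
    m <- match(indices$image_id, man$image_id)
    indices$group <- man$label[m]
    if ("bms" %in% names(man)) indices$bms <- man$bms[m]
  }
  front <- c("image_id", "group", "bms")
  indices <- indices[, c(front, setdiff(names(indices), front))]
  rownames(indices) <- NULL
  utils::write.csv(indices, file.path(out_dir, "indices.csv"),
                   row.names = FALSE)

  comparisons <- NULL
  if (!is.null(man) && sum(indices$group == "fine", na.rm = TRUE) >= 2 &&
      sum(indices$group == "coarse", na.rm = TRUE) >= 2) {
    comparisons <- compare_groups(indices, index = compare_index)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    long <- indices[!is.na(indices$group),
                    c("image_id", "group", "bms", compare_index)]
    names(long)[4] <- "value"
    long$index <- compare_index
    utils::write.table(long, file.path(out_dir, "boxplot_data.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  sweep <- NULL
  if (!is.null(steps) && !is.null(man)) {
    sweep <- step_size_sweep(unname(masks), unname(rois),
                             labels = indices$group, steps = steps,
                             min_coverage = config$min_coverage)
    utils::write.csv(as.data.frame(sweep), file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }

  log <- list(config = unclass(config)[!vapply(config, is.null, TRUE)],
              seed = config$seed,
              n_images = nrow(pairs), n_failed = length(failures),
              failures = failures,
              thresholds = stats::setNames(indices$threshold_used,
                                           indices$image_id))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(indices = indices, comparisons = comparisons, sweep = sweep,
                 n_failed = length(failures), failures = failures,
                 out_dir = out_dir))
}

#' Fine/medium/coarse comparisons of one index
#'
#' Welch fine-versus-coarse t test and three-group one-way ANOVA, overall
#' and within each BMS grade present in the table.
#'
#' @param indices data frame with columns `group`, optionally `bms`, and
#'   the index column.
#' @param index index column name (default `"F7"`).
#' @return data frame with columns `scope`, `test`, `statistic`, `df`,
#'   `p_value` and per-group means.
#' @export
compare_groups <- function(indices, index = "F7") {
  stopifnot(index %in% names(indices))
  scopes <- list(total = rep(TRUE, nrow(indices)))
  if ("bms" %in% names(indices) && any(!is.na(indices$bms)))
    for (b in sort(unique(stats::na.omit(indices$bms))))
      scopes[[paste0("bms", b)]] <- !is.na(indices$bms) & indices$bms == b
  out <- list()
  for (sc in names(scopes)) {
    sub <- indices[scopes[[sc]] & !is.na(indices$group), ]
    v <- function(g) sub[[index]][sub$group == g]
    if (length(v("fine")) >= 2 && length(v("coarse")) >= 2) {
      tt <- welch_t(v("fine"), v("coarse"))
      out[[length(out) + 1L]] <- data.frame(
        scope = sc, test = "welch_t", statistic = tt$statistic,
        df = tt$df, p_value = tt$p_value,
        mean_fine = mean(v("fine")), mean_medium = NA_real_,
        mean_coarse = mean(v("coarse")))
    }
    gl <- Filter(function(g) length(v(g)) >= 2, c("fine", "medium", "coarse"))
    if (length(gl) >= 2) {
      av <- one_way_anova(stats::setNames(lapply(gl, v), gl))
      out[[length(out) + 1L]] <- data.frame(
        scope = sc, test = "anova", statistic = av$statistic,
        df = av$df[2], p_value = av$p_value,
        mean_fine = if ("fine" %in% gl) mean(v("fine")) else NA_real_,
        mean_medium = if ("medium" %in% gl) mean(v("medium")) else NA_real_,
        mean_coarse = if ("coarse" %in% gl) mean(v("coarse")) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic panel to disk
#'
#' Writes per image the rendered PNG, the ROI mask PNG, the truth mask PNG,
#' and a `manifest.csv` (image_id, label, seed, realized_imf) — the file
#' layout [run_pipeline()] consumes.
#'
#' @param panel list of `synthetic_image` from [generate_panel()].
#' @param dir output directory; `images/`, `rois/`, `truth/` are created.
#' @return the manifest data frame, invisibly.
#' @export
write_panel <- function(panel, dir) {
  for (d in c("images", "rois", "truth"))
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  man <- data.frame(image_id = character(), label = character(),
                    seed = integer(), realized_imf = numeric())
  for (s in panel) {
    id <- sprintf("%s_%06d", s$truth_label, s$spec$seed)
    EBImage::writeImage(EBImage::Image(aperm(s$image, c(2, 1, 3)) / 255,
                                       colormode = "Color"),
                        file.path(dir, "images", paste0(id, ".png")),
                        type = "png")
    EBImage::writeImage(EBImage::Image(t(s$roi) * 1.0),
                        file.path(dir, "rois", paste0(id, ".png")),
                        type = "png")
    EBImage::writeImage(EBImage::Image(t(s$truth_mask$fat) * 1.0),
                        file.path(dir, "truth", paste0(id, ".png")),
                        type = "png")
    man <- rbind(man, data.frame(image_id = id, label = s$truth_label,
                                 seed = s$spec$seed,
                                 realized_imf = s$realized_imf))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
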