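# Shared synthetic panels, built once per test run (generation is seeded, so
# every test sees the same panel).

.panel_cache <- new.env(parent = emptyenv())

memoize <- function(key, build) {
  if (!exists(key, envir = .panel_cache)) assign(key, build(), .panel_cache)
  get(key, envir = .panel_cache)
}

# 60-image three-group panel at the standard presets, analysed end to end
# (rendered image -> Otsu -> particles -> indices at step 70)
standard_panel_results <- function() {
  memoize("standard60", function() {
    panel <- generate_panel(
      20,
      fineness_preset("fine"), fineness_preset("medium"),
      fineness_preset("coarse"),
      base_seed = 20000)
    cfg <- mf_config(step = 70, pixels_per_cm = 30)
    rows <- lapply(seq_along(panel), function(i) {
      s <- panel[[i]]
      compute_all(s$image, s$roi, cfg, image_id = sprintf("img%02d", i))
    })
    masks <- lapply(panel, function(s) segment_marbling(s$image, s$roi))
    list(panel = panel,
         labels = panel_labels(panel),
         indices = do.call(rbind, rows),
         masks = masks,
         roi = panel[[1]]$roi)
  })
}

# small panel for cheap mechanics tests
mini_panel <- function() {
  memoize("mini", function() {
    generate_panel(3,
                   fineness_preset("fine", image_size = c(200, 200)),
                   NULL,
                   fineness_preset("coarse", image_size = c(200, 200)),
                   base_seed = 555)
  })
}
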