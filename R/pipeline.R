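#' Pipeline configuration
#'
#' Validated bundle of every tunable parameter of the analysis pipeline, with
#' defaults set to the reference study conditions: 0.3086 um pixels on a
#' 3900 Pa, nu = 0.457 substrate; PIV windows 128/64/48 px with threshold
#' 0.6 and non-overlapping final windows (~14.8 um lattice); regularized
#' FTTC with 2x zero padding; 80 px ROI dilation and 12-48 h stress
#' averaging; and a 5% compression step per daily cycle, two cycles. The
#' `study` block sizes the synthetic contraction study (patch/neutral ROI
#' counts, field extent, traction levels, frame times).
#'
#' @param pixel_size_um,youngs_modulus_pa,poisson_ratio Substrate parameters.
#' @param piv List: `windows`, `threshold`, `spacing_rule`.
#' @param fttc List: `lambda`, `pad_factor`.
#' @param roi List: `dilation_px`, `window_h` (aggregation window, hours).
#' @param regimen List: `step_strain_pct`, `cycles` (mechanical stimulation).
#' @param study List sizing the synthetic study; see Details in the package
#'   vignette.
#' @param seed Integer master seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.3086,
                            youngs_modulus_pa = 3900,
                            poisson_ratio = 0.457,
                            piv = list(),
                            fttc = list(),
                            roi = list(),
                            regimen = list(),
                            study = list(),
                            seed = 1L) {
  piv <- utils::modifyList(
    list(windows = c(128L, 64L, 48L), threshold = 0.6,
         spacing_rule = "window"), piv)
  fttc <- utils::modifyList(list(lambda = 99, pad_factor = 2L), fttc)
  roi <- utils::modifyList(list(dilation_px = 80L, window_h = c(12, 48)), roi)
  regimen <- utils::modifyList(list(step_strain_pct = 5, cycles = 2L), regimen)
  study <- utils::modifyList(
    list(n_patch = 7L, n_neutral = 7L, field_extent = 1440L,
         patch_radius_um = 25, peak_traction_pa = 40, peak_sd_pa = 6,
         onset_h = 6, times_h = seq(0, 48, by = 4),
         bead_density = 0.08, noise_sd = 0.02, align = TRUE), study)
  # constructors validate the type invariants at load time
  piv_cfg <- piv_config(piv$windows, piv$threshold, pixel_size_um,
                        piv$spacing_rule)
  substrate <- elastic_substrate(youngs_modulus_pa, poisson_ratio,
                                 pixel_size_um)
  fttc_cfg <- fttc_config(fttc$lambda, fttc$pad_factor)
  if (roi$dilation_px < 0) stop("`roi$dilation_px` must be >= 0")
  if (length(roi$window_h) != 2L || diff(roi$window_h) <= 0)
    stop("`roi$window_h` must be an increasing (start, end) pair")
  if (regimen$cycles < 1L) stop("`regimen$cycles` must be >= 1")
  structure(list(pixel_size_um = pixel_size_um,
                 youngs_modulus_pa = youngs_modulus_pa,
                 poisson_ratio = poisson_ratio,
                 piv = piv, fttc = fttc, roi = roi, regimen = regimen,
                 study = study, seed = as.integer(seed),
                 piv_cfg = piv_cfg, substrate = substrate,
                 fttc_cfg = fttc_cfg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments
#' (`pixel_size_um`, `youngs_modulus_pa`, `poisson_ratio`, `piv`, `fttc`,
#' `roi`, `regimen`, `study`, `seed`); omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Cumulative strain of a stimulation regimen
#'
#' Total engineering strain achieved by repeating the per-cycle compression
#' step: strains across daily cycles combine additively (5% + 5% = 10%).
#'
#' @param cfg A [pipeline_config()] (its `regimen` block is used).
#' @return Overall strain in percent.
#' @export
cumulative_regimen_strain <- function(cfg) {
  sum(rep(cfg$regimen$step_strain_pct, cfg$regimen$cycles))
}

# Deterministic layout of the synthetic contraction study: patches and
# neutral ROIs on a slot grid. Returns centers in px plus per-patch peaks.
study_layout <- function(cfg) {
  st <- cfg$study
  ext <- st$field_extent
  n_slots_side <- ceiling(sqrt(st$n_patch + st$n_neutral))
  slot <- ext / n_slots_side
  centers <- expand.grid(
    x = slot * (seq_len(n_slots_side) - 0.5),
    y = slot * (seq_len(n_slots_side) - 0.5))
  set.seed(cfg$seed)
  ord <- sample(nrow(centers))
  peaks <- pmax(stats::rnorm(st$n_patch, st$peak_traction_pa, st$peak_sd_pa),
                st$peak_traction_pa / 4)
  list(patch_centers_px = as.matrix(centers[ord[seq_len(st$n_patch)], ]),
       neutral_centers_px = as.matrix(
         centers[ord[st$n_patch + seq_len(st$n_neutral)], ]),
       peaks_pa = peaks,
       patch_radius_px = st$patch_radius_um / cfg$pixel_size_um)
}

#' Run the staged analysis pipeline
#'
#' Executes a prefix of the stage chain `simulate -> piv -> fttc -> roi ->
#' report` against an output directory; every stage reads the previous
#' stage's files from `outdir`, so stages can be re-run individually and
#' every artifact is regenerable from config plus seed alone.
#'
#' * `simulate` — synthesizes the contraction study (a bead movie with
#'   `study$n_patch` contractile patches and `study$n_neutral` traction-free
#'   ROI positions), writing `beads.tif`, `scenario.json` and the
#'   ground-truth `truth_tractions.csv`.
#' * `piv` — drift-aligns the stack, recovers displacement fields against
#'   the t = 0 reference, threshold-validates them; writes
#'   `displacements.csv`.
#' * `fttc` — inverts the displacement series to tractions; writes
#'   `tractions.csv`.
#' * `roi` — dilates the patch and neutral ROIs, decomposes stresses about
#'   each ROI centroid, aggregates over the configured window and runs the
#'   two-group comparison; writes `roi_stats.csv`, `roi_aggregates.csv`,
#'   `comparison.json`.
#' * `report` — writes `run_log.json` (config hash, seed, package version,
#'   per-stage record counts).
#'
#' @param cfg A [pipeline_config()].
#' @param stages Character vector, a prefix of
#'   `c("simulate", "piv", "fttc", "roi", "report")`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the paths written and (when the `roi`
#'   stage ran) the per-ROI aggregates and group comparison.
#' @export
run_pipeline <- function(cfg = pipeline_config(),
                         stages = c("simulate", "piv", "fttc", "roi", "report"),
                         outdir = tempfile("fusemech")) {
  order_all <- c("simulate", "piv", "fttc", "roi", "report")
  stages <- match.arg(stages, order_all, several.ok = TRUE)
  idx <- match(stages, order_all)
  if (any(duplicated(idx)) || any(diff(idx) != 1L))
    stop("`stages` must be a contiguous run of simulate->piv->fttc->roi->report")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    beads = file.path(outdir, "beads.tif"),
    scenario = file.path(outdir, "scenario.json"),
    truth = file.path(outdir, "truth_tractions.csv"),
    displacements = file.path(outdir, "displacements.csv"),
    tractions = file.path(outdir, "tractions.csv"),
    roi_stats = file.path(outdir, "roi_stats.csv"),
    roi_aggregates = file.path(outdir, "roi_aggregates.csv"),
    comparison = file.path(outdir, "comparison.json"),
    log = file.path(outdir, "run_log.json"))
  counts <- list()
  result <- list(paths = paths, outdir = outdir)

  if ("simulate" %in% stages) {
    lay <- study_layout(cfg)
    st <- cfg$study
    scen <- contraction_scenario(
      patch_center = lay$patch_centers_px * cfg$pixel_size_um,
      patch_radius = st$patch_radius_um,
      peak_traction = lay$peaks_pa,
      onset_time = st$onset_h,
      field_extent = st$field_extent,
      pixel_size = cfg$pixel_size_um,
      seed = cfg$seed)
    bead_spec <- bead_image_spec(
      image_size = scen$field_extent, bead_density = st$bead_density,
      noise_sd = st$noise_sd, pixel_size = cfg$pixel_size_um,
      seed = cfg$seed)
    movie <- make_contraction_movie(scen, cfg$substrate, st$times_h,
                                    bead_spec, cfg$piv_cfg)
    # 16-bit quantization: brightest pixel of the stack mapped to full scale
    peak <- max(vapply(movie$stack, max, numeric(1)))
    write_image_stack(lapply(movie$stack, function(f) f / peak), paths$beads)
    jsonlite::write_json(
      list(times_h = st$times_h,
           patch_centers_px = lay$patch_centers_px,
           neutral_centers_px = lay$neutral_centers_px,
           peaks_pa = lay$peaks_pa,
           patch_radius_px = lay$patch_radius_px,
           onset_h = st$onset_h, field_extent = scen$field_extent,
           seed = cfg$seed),
      paths$scenario, auto_unbox = TRUE, digits = NA)
    write_traction_csv(movie$truth, paths$truth)
    counts$simulate <- length(movie$stack)
  }

  if ("piv" %in% stages) {
    for (p in c(paths$beads, paths$scenario))
      if (!file.exists(p))
        stop("piv stage: missing upstream artifact ", p,
             " (run the simulate stage first)")
    meta <- jsonlite::fromJSON(paths$scenario)
    stack <- read_image_stack(paths$beads, cfg$pixel_size_um)
    if (isTRUE(cfg$study$align)) stack <- align_to_reference(stack, 1L)$stack
    fields <- vector("list", length(stack) - 1L)
    for (i in seq_along(fields)) {
      f <- iterative_piv(stack[[1]], stack[[i + 1L]], cfg$piv_cfg)
      f <- validate_and_fill(f, cfg$piv_cfg)
      f$time <- meta$times_h[i + 1L]
      fields[[i]] <- f
    }
    write_displacement_csv(fields, paths$displacements)
    counts$piv <- length(fields)
  }

  if ("fttc" %in% stages) {
    if (!file.exists(paths$displacements))
      stop("fttc stage: missing upstream artifact ", paths$displacements,
           " (run the piv stage first)")
    fields <- read_displacement_csv(paths$displacements, cfg$pixel_size_um)
    tr <- traction_timeseries(fields, cfg$substrate, cfg$fttc_cfg)
    write_traction_csv(tr, paths$tractions)
    counts$fttc <- length(tr)
  }

  if ("roi" %in% stages) {
    for (p in c(paths$tractions, paths$scenario))
      if (!file.exists(p))
        stop("roi stage: missing upstream artifact ", p)
    meta <- jsonlite::fromJSON(paths$scenario)
    tr <- read_traction_csv(paths$tractions, cfg$pixel_size_um)
    dim_img <- rep(meta$field_extent, length.out = 2L)
    build <- function(centers, label, fused) {
      lapply(seq_len(nrow(centers)), function(i) {
        roi <- roi_disk(centers[i, ], meta$patch_radius_px, dim_img,
                        label = label, fused_fraction = fused,
                        pixel_size = cfg$pixel_size_um)
        dilate_roi(roi, cfg$roi$dilation_px)
      })
    }
    rois <- c(build(meta$patch_centers_px, "syncytial", 0.77),
              build(meta$neutral_centers_px, "mononucleated", 0.27))
    stats_rows <- list(); agg_rows <- list()
    for (i in seq_along(rois)) {
      ser <- stress_timeseries(tr, rois[[i]])
      ser$roi_id <- i
      ser$label <- rois[[i]]$label
      stats_rows[[i]] <- as.data.frame(ser)
      ag <- aggregate_window(ser, cfg$roi$window_h[1], cfg$roi$window_h[2])
      agg_rows[[i]] <- data.frame(
        roi_id = i, label = rois[[i]]$label,
        mean_radial_pa = ag$mean_radial,
        mean_abs_tangential_pa = ag$mean_abs_tangential,
        n_timepoints = ag$n_timepoints)
    }
    stats_df <- do.call(rbind, stats_rows)
    agg_df <- do.call(rbind, agg_rows)
    utils::write.csv(stats_df, paths$roi_stats, row.names = FALSE)
    utils::write.csv(agg_df, paths$roi_aggregates, row.names = FALSE)
    cmp <- compare_regions(
      agg_df$mean_radial_pa[agg_df$label == "syncytial"],
      agg_df$mean_radial_pa[agg_df$label == "mononucleated"])
    jsonlite::write_json(cmp, paths$comparison, auto_unbox = TRUE, digits = NA)
    counts$roi <- nrow(agg_df)
    result$aggregates <- agg_df
    result$comparison <- cmp
  }

  if ("report" %in% stages || length(counts)) {
    cfg_plain <- cfg[setdiff(names(cfg), c("piv_cfg", "substrate", "fttc_cfg"))]
    tf <- tempfile(fileext = ".yaml")
    yaml::write_yaml(cfg_plain, tf)
    jsonlite::write_json(
      list(config_hash = unname(tools::md5sum(tf)),
           seed = cfg$seed,
           package_version = as.character(utils::packageVersion("fusemech")),
           record_counts = counts,
           timestamp = format(Sys.time(), tz = "UTC")),
      paths$log, auto_unbox = TRUE, digits = NA)
    unlink(tf)
  }
  invisible(result)
}
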